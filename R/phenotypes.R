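DESIGN_COLS <- c("experiment", "block", "genotype_class", "line", "subline")

#' Construct and validate a phenotype table
#'
#' A phenotype table is a long-format data frame with one row per plant:
#' the design columns `experiment`, `block`, `genotype_class`
#' (`ma`/`founder`/`col0`), `line`, `subline`, and one column per declared
#' trait. Missing observations are `NA` (never 0: zero is a legal value
#' for every trait).
#'
#' Validation enforces: binary traits in \{0, 1\}; counts non-negative
#' integers; continuous traits non-negative; `survivors_only` traits
#' missing wherever `survival == 0`; and each subline id belonging to a
#' single line. If `fitness` is declared but absent it is computed as
#' `survival * fruits` with non-survivors set to 0.
#'
#' @param df A data frame with the design columns and trait columns.
#' @param traits Named list of [trait_spec()] objects (see [ma_traits()]).
#' @return A validated data frame of class `phenotype_tbl`.
#' @export
phenotype_table <- function(df, traits = ma_traits()) {
  traits <- as_trait_list(traits)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(DESIGN_COLS, names(df))
  if (length(missing_cols))
    stop_mutaccum(paste("missing design columns:",
                        paste(missing_cols, collapse = ", ")),
                  "mutaccum_validation_error")
  df <- add_fitness_column(df, traits)
  present <- intersect(names(traits), names(df))
  for (nm in present) df[[nm]] <- as.numeric(df[[nm]])
  validate_phenotypes(df, traits[present])
  structure(df, class = c("phenotype_tbl", "data.frame"),
            traits = traits[present])
}

add_fitness_column <- function(df, traits) {
  if ("fitness" %in% names(traits) && !"fitness" %in% names(df) &&
      all(c("survival", "fruits") %in% names(df))) {
    surv <- as.numeric(df$survival)
    fr <- as.numeric(df$fruits)
    df$fitness <- ifelse(!is.na(surv) & surv == 0, 0, surv * fr)
  }
  df
}

#' Validate phenotype-table invariants
#'
#' @param df Data frame with design and trait columns.
#' @param traits Named list of [trait_spec()] objects to check.
#' @return `df`, invisibly, if valid; otherwise an error of class
#'   `mutaccum_validation_error` listing offending rows.
#' @export
validate_phenotypes <- function(df, traits = ma_traits()) {
  traits <- as_trait_list(traits)
  bad <- function(rows, what) {
    if (any(rows, na.rm = TRUE))
      stop_mutaccum(sprintf("%s (rows %s)", what,
                            paste(utils::head(which(rows), 10L), collapse = ", ")),
                    "mutaccum_validation_error")
  }
  cls <- df$genotype_class
  bad(!is.na(cls) & !cls %in% c("ma", "founder", "col0"),
      "genotype_class must be one of ma/founder/col0")
  # a subline id must map to exactly one line
  sl <- unique(df[!is.na(df$subline), c("line", "subline")])
  dup <- sl$subline[duplicated(sl$subline)]
  if (length(dup))
    stop_mutaccum(paste("subline id assigned to more than one line:",
                        paste(unique(dup), collapse = ", ")),
                  "mutaccum_validation_error")
  for (nm in intersect(names(traits), names(df))) {
    v <- df[[nm]]
    fam <- traits[[nm]]$family
    if (fam == "binomial")
      bad(!is.na(v) & !v %in% c(0, 1),
          sprintf("binary trait '%s' outside {0,1}", nm))
    if (fam == "poisson")
      bad(!is.na(v) & (v < 0 | v != floor(v)),
          sprintf("count trait '%s' not a non-negative integer", nm))
    if (fam == "gaussian")
      bad(!is.na(v) & v < 0, sprintf("continuous trait '%s' negative", nm))
    if (traits[[nm]]$conditioning == "survivors_only" &&
        "survival" %in% names(df))
      bad(!is.na(df$survival) & df$survival == 0 & !is.na(v),
          sprintf("survivors-only trait '%s' recorded for a non-survivor", nm))
  }
  invisible(df)
}

#' Read a phenotype table from CSV/TSV
#'
#' Reads a UTF-8 delimited file with a header row, coerces trait columns
#' to numeric, preserves empty cells as `NA`, and validates the result.
#' The delimiter is taken from the file extension (`.tsv`/`.tab` = tab,
#' otherwise comma).
#'
#' @param path Path to the file.
#' @param traits Named list of [trait_spec()] objects.
#' @return A `phenotype_tbl`.
#' @export
read_phenotypes <- function(path, traits = ma_traits()) {
  if (!file.exists(path))
    stop_mutaccum(sprintf("file not found: %s", path), "mutaccum_io_error")
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      na.strings = c("", "NA"), colClasses = "character",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      fileEncoding = "UTF-8"),
    error = function(e) stop_mutaccum(
      sprintf("malformed file %s: %s", path, conditionMessage(e)),
      "mutaccum_parse_error"))
  traits <- as_trait_list(traits)
  for (nm in intersect(names(traits), names(df))) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    broke <- which(is.na(v) & !is.na(df[[nm]]))
    if (length(broke))
      stop_mutaccum(sprintf("non-numeric value for trait '%s' at line %s",
                            nm, paste(broke + 1L, collapse = ", ")),
                    "mutaccum_parse_error")
    df[[nm]] <- v
  }
  phenotype_table(df, traits)
}

#' Write a phenotype table to CSV/TSV
#'
#' Missing values are written as empty cells so that a round-trip through
#' [read_phenotypes()] preserves values and missingness.
#'
#' @param x A `phenotype_tbl` (or compatible data frame).
#' @param path Output path; extension selects the delimiter.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(x, path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(x), path, sep = sep, na = "",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Rows entering the analysis of one trait: conditioning filter plus an
# optional genotype-class filter (variance estimation uses MA rows alone).
condition_rows <- function(df, trait, classes = "ma") {
  keep <- rep(TRUE, nrow(df))
  if (!is.null(classes)) keep <- keep & df$genotype_class %in% classes
  if (trait$conditioning == "survivors_only" && "survival" %in% names(df))
    keep <- keep & !is.na(df$survival) & df$survival == 1
  keep & !is.na(df[[trait$name]])
}
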