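#' Declare a phenotypic trait
#'
#' A trait specification records the distribution family used to model a
#' trait, its (implied) link function, and the conditioning rule that
#' determines which plants contribute observations. Binary traits are
#' modelled as Bernoulli on the logit scale, counts as Poisson on the log
#' scale, and continuous measurements as Gaussian on the identity scale.
#'
#' Conditioning rules follow the field protocol: germination is scored on
#' every seed planted in the greenhouse (`all_planted`), survival and the
#' composite fitness measure on every individual transplanted to the field
#' (`field_planted`), and all remaining traits only on plants that survived
#' to flowering (`survivors_only`).
#'
#' @param name Trait name (column name in the phenotype table).
#' @param family One of `"gaussian"`, `"poisson"`, `"binomial"`.
#' @param conditioning One of `"all_planted"`, `"field_planted"`,
#'   `"survivors_only"`. Defaults by trait name where the protocol fixes it.
#' @return An object of class `trait_spec` with fields `name`, `family`,
#'   `link`, `conditioning`.
#' @examples
#' trait_spec("germination", "binomial")
#' trait_spec("biomass", "gaussian")
#' @export
trait_spec <- function(name, family, conditioning = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  family <- match.arg(family, c("gaussian", "poisson", "binomial"))
  link <- switch(family, gaussian = "identity", poisson = "log",
                 binomial = "logit")
  fixed <- c(germination = "all_planted", survival = "field_planted",
             fitness = "field_planted")
  default <- if (name %in% names(fixed)) unname(fixed[name]) else "survivors_only"
  if (is.null(conditioning)) conditioning <- default
  conditioning <- match.arg(conditioning,
                            c("all_planted", "field_planted", "survivors_only"))
  if (name %in% names(fixed) && conditioning != fixed[[name]])
    stop_mutaccum(sprintf("trait '%s' must use conditioning '%s'",
                          name, fixed[[name]]), "mutaccum_spec_error")
  structure(list(name = name, family = family, link = link,
                 conditioning = conditioning),
            class = "trait_spec")
}

#' @export
print.trait_spec <- function(x, ...) {
  cat(sprintf("<trait_spec> %s: %s(%s), %s\n",
              x$name, x$family, x$link, x$conditioning))
  invisible(x)
}

#' Standard trait registry for the MA field assays
#'
#' The nine traits scored in the seasonal field experiments: three binary
#' (germination, survival, flowering), four counts (flowers, fruits,
#' aborted fruits, and the composite fitness = survival x filled fruits),
#' and two continuous (biomass in g, fruit length in mm).
#'
#' @return Named list of [trait_spec()] objects.
#' @export
ma_traits <- function() {
  specs <- list(
    trait_spec("germination", "binomial"),
    trait_spec("survival", "binomial"),
    trait_spec("flowering", "binomial", "survivors_only"),
    trait_spec("flowers", "poisson", "survivors_only"),
    trait_spec("fruits", "poisson", "survivors_only"),
    trait_spec("aborted_fruits", "poisson", "survivors_only"),
    trait_spec("fitness", "poisson"),
    trait_spec("biomass", "gaussian", "survivors_only"),
    trait_spec("fruit_length", "gaussian", "survivors_only")
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Read trait declarations from a YAML/JSON config
#'
#' The file maps trait name to a family and optional conditioning, e.g.
#' `biomass: {family: gaussian, conditioning: survivors_only}`.
#'
#' @param path Path to a YAML (or JSON) file.
#' @return Named list of [trait_spec()] objects.
#' @export
read_trait_config <- function(path) {
  if (!file.exists(path))
    stop_mutaccum(sprintf("trait config not found: %s", path),
                  "mutaccum_io_error")
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop_mutaccum("empty trait config", "mutaccum_spec_error")
  out <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    if (is.character(entry)) entry <- list(family = entry)
    trait_spec(nm, entry$family, entry$conditioning)
  })
  stats::setNames(out, names(raw))
}

as_trait_list <- function(traits) {
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  if (!length(traits) || !all(vapply(traits, inherits, TRUE, "trait_spec")))
    stop_mutaccum("'traits' must be trait_spec objects", "mutaccum_spec_error")
  stats::setNames(traits, vapply(traits, `[[`, "", "name"))
}
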