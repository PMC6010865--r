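#' Untransformed group mean with 95% confidence interval
#'
#' Arithmetic mean on the raw measurement scale with the
#' normal-approximation interval `mean +/- 1.96 SE`. A single
#' observation yields a defined mean and a missing interval.
#'
#' @param table A `phenotype_tbl` (or data frame).
#' @param trait Trait column name.
#' @param group Genotype class (`"ma"`, `"founder"`, `"col0"`).
#' @param experiment Optional season label to restrict to.
#' @return Named numeric vector `c(mean, lower, upper, n)`.
#' @export
group_means <- function(table, trait, group, experiment = NULL) {
  d <- as.data.frame(table)
  keep <- d$genotype_class == group & !is.na(d[[trait]])
  if (!is.null(experiment)) keep <- keep & d$experiment %in% experiment
  v <- d[[trait]][keep]
  if (!length(v))
    stop_mutaccum(sprintf("no '%s' observations for group '%s'", trait, group),
                  "mutaccum_missing_data_error")
  m <- mean(v)
  if (length(v) < 2L) return(c(mean = m, lower = NA, upper = NA, n = 1))
  se <- stats::sd(v) / sqrt(length(v))
  c(mean = m, lower = m - 1.96 * se, upper = m + 1.96 * se, n = length(v))
}

#' Classical paired t test
#'
#' Two-sided paired t test on the within-pair differences, df = n - 1.
#'
#' @param a,b Numeric vectors of paired observations (same length >= 2).
#' @return Named numeric vector `c(t_stat, df, p_value)`.
#' @export
paired_ttest <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L)
    stop_mutaccum("need at least 2 complete pairs", "mutaccum_spec_error")
  if (stats::sd(a - b) == 0)
    stop_mutaccum("zero-variance differences: degenerate paired t test",
                  "mutaccum_degenerate_error")
  ht <- stats::t.test(a, b, paired = TRUE)
  c(t_stat = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value)
}

# Per-block class summaries: the MA value in a block is the mean of its
# line means (each line weighted equally), the founder/col0 value the
# mean of its (sub)line means.
block_class_means <- function(d, trait) {
  ok <- !is.na(d[[trait]])
  d <- d[ok, , drop = FALSE]
  if (!nrow(d)) return(NULL)
  line_means <- stats::aggregate(
    d[[trait]],
    by = list(experiment = d$experiment, block = d$block,
              class = d$genotype_class, line = d$line),
    FUN = mean)
  stats::aggregate(x ~ experiment + block + class, data = line_means,
                   FUN = mean)
}

#' Compare MA, founder, and reference-accession means
#'
#' Runs paired t tests between every pair of genotype classes present,
#' for each trait within each season and (optionally) pooled across
#' seasons, and reports untransformed group means with 95% CIs. The
#' pairing unit is the block: within each block the MA mean (mean of
#' line means), founder mean, and Col-0 mean form matched observations.
#' Comparisons involving the reference accession are emitted only for
#' seasons in which it was planted. Raw p-values are reported (as in the
#' original analysis); a Benjamini-Hochberg column is appended as
#' supplementary output.
#'
#' @param table A `phenotype_tbl` covering one or more seasons (rows
#'   from several seasons may be `rbind`-ed).
#' @param traits Character vector of trait columns to compare.
#' @param pooled Also run each comparison on the combined data, pairing
#'   on season x block.
#' @param sqrt_transform Traits to square-root transform before testing
#'   (e.g. `"fitness"`); group means stay on the raw scale.
#' @return Data frame with one row per class pair x trait x experiment
#'   (and `"pooled"`), columns `trait`, `experiment`, `group_a`,
#'   `group_b`, `n_pairs`, `t_stat`, `p_value`, `p_bh`, and the two
#'   groups' raw means with CIs.
#' @export
compare_all <- function(table, traits = NULL, pooled = TRUE,
                        sqrt_transform = character()) {
  d <- as.data.frame(table)
  if (is.null(traits))
    traits <- names(attr(table, "traits") %||%
                      stats::setNames(nm = intersect(names(ma_traits()),
                                                     names(d))))
  classes <- intersect(c("ma", "founder", "col0"),
                       unique(d$genotype_class))
  if (length(classes) < 2L)
    stop_mutaccum("need at least 2 genotype classes", "mutaccum_spec_error")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  seasons <- unique(d$experiment)
  scopes <- c(as.list(seasons), if (pooled && length(seasons) > 1L) "pooled")
  rows <- list()
  for (trait in traits) {
    td <- d
    if (trait %in% sqrt_transform) td[[trait]] <- sqrt(td[[trait]])
    bm <- block_class_means(td, trait)
    if (is.null(bm)) next
    for (scope in scopes) {
      sb <- if (identical(scope, "pooled")) bm
            else bm[bm$experiment == scope, , drop = FALSE]
      sd_ <- if (identical(scope, "pooled")) d
             else d[d$experiment == scope, , drop = FALSE]
      for (pr in pairs) {
        wide <- merge(sb[sb$class == pr[1], c("experiment", "block", "x")],
                      sb[sb$class == pr[2], c("experiment", "block", "x")],
                      by = c("experiment", "block"))
        if (nrow(wide) < 2L) next
        tt <- tryCatch(paired_ttest(wide$x.x, wide$x.y),
                       error = function(e) c(t_stat = NA, df = NA,
                                             p_value = NA))
        gm <- function(g) tryCatch(
          group_means(sd_, trait, g),
          error = function(e) c(mean = NA, lower = NA, upper = NA, n = 0))
        ma_ <- gm(pr[1]); fo_ <- gm(pr[2])
        rows[[length(rows) + 1L]] <- data.frame(
          trait = trait,
          experiment = if (identical(scope, "pooled")) "pooled" else scope,
          group_a = pr[1], group_b = pr[2], n_pairs = nrow(wide),
          t_stat = unname(tt["t_stat"]), p_value = unname(tt["p_value"]),
          mean_a = ma_[["mean"]], mean_a_lo = ma_[["lower"]],
          mean_a_hi = ma_[["upper"]],
          mean_b = fo_[["mean"]], mean_b_lo = fo_[["lower"]],
          mean_b_hi = fo_[["upper"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$p_bh <- stats::p.adjust(out$p_value, "BH")
  out
}
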