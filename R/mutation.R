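#' Per-generation mutational variance
#'
#' `V_m = V_l / (2t)`: the among-line variance accumulated over `t`
#' generations of mutation accumulation, converted to the per-generation
#' input of genetic variance (the factor 2 reflects the doubling of the
#' fixation rate of new mutations in selfing MA lines).
#'
#' @param v_l Among-line variance (link scale); may be a vector of
#'   posterior draws.
#' @param t Generations of divergence (>= 1).
#' @return `v_l / (2 * t)`.
#' @examples
#' compute_vm(0.4578, 25)  # 0.009156
#' @export
compute_vm <- function(v_l, t) {
  if (any(v_l < 0, na.rm = TRUE))
    stop_mutaccum("v_l must be non-negative", "mutaccum_domain_error")
  if (t < 1) stop_mutaccum("t must be >= 1", "mutaccum_domain_error")
  v_l / (2 * t)
}

#' Mutational heritability
#'
#' `h2_m = V_m / V_e`: the per-generation rate of increase in
#' heritability from new mutations. For binary traits the residual is the
#' fixed latent logit-scale variance 1, so `h2_m` equals `V_m`
#' numerically.
#'
#' @param v_m Mutational variance (scalar or draws).
#' @param v_e Residual (environmental) variance, > 0.
#' @return `v_m / v_e`.
#' @export
compute_hm2 <- function(v_m, v_e) {
  if (any(v_e <= 0, na.rm = TRUE))
    stop_mutaccum("v_e must be positive: heritability undefined",
                  "mutaccum_domain_error")
  v_m / v_e
}

#' Mutational coefficient of variation
#'
#' Mean-standardized mutational variation, in percent: for Gaussian
#' traits `100 * sqrt(V_m) / mean`; for Poisson (ln-scale) traits
#' `100 * sqrt(exp(V_m) - 1)` (the lognormal CV), with the no-radical
#' variant `100 * (exp(V_m) - 1)` switchable. Not defined for binomial
#' traits, whose latent-scale mean can be non-positive.
#'
#' @param v_m Mutational variance (link scale for Poisson).
#' @param trait_mean Trait mean (Gaussian only; must be > 0).
#' @param family `"gaussian"` or `"poisson"`.
#' @param radical Apply the square root in the Poisson rule (default).
#' @return CV_m in percent.
#' @examples
#' compute_cvm(log(2), family = "poisson")  # 100
#' @export
compute_cvm <- function(v_m, trait_mean = NULL,
                        family = c("gaussian", "poisson"), radical = TRUE) {
  family <- match.arg(family)
  if (family == "gaussian") {
    if (is.null(trait_mean) || any(trait_mean <= 0, na.rm = TRUE))
      stop_mutaccum("gaussian CV_m needs a positive trait mean",
                    "mutaccum_domain_error")
    100 * sqrt(v_m) / trait_mean
  } else {
    if (radical) 100 * sqrt(exp(v_m) - 1) else 100 * (exp(v_m) - 1)
  }
}

#' Mutation parameters from a posterior fit
#'
#' Applies [compute_vm()], [compute_hm2()], and [compute_cvm()] to every
#' posterior draw of the variance components, then summarizes by
#' posterior mean and equal-tailed interval (transform-then-summarize:
#' intervals are quantiles of the transformed draws, so the `V_m`
#' interval endpoints are exactly the `V_l` endpoints divided by `2t`).
#' The residual entering `h2_m` is the latent variance 1 for binomial
#' traits and the sampled residual otherwise; `CV_m` is reported for
#' Gaussian (identity-scale mean) and Poisson (ln scale) traits only.
#'
#' @param vc An `ma_mcmc_fit` from [fit_mcmc()] containing `v_line`.
#' @param t Generations of divergence.
#' @param level Interval probability.
#' @param trait,experiment Labels carried into the output.
#' @param boot Optional `boot_lrt` for the line term; its p-value is
#'   reported as `p_among_line`.
#' @param radical Poisson CV_m rule, see [compute_cvm()].
#' @return An object of class `mutation_params`: a one-row data frame
#'   with `trait`, `experiment`, and `<param>`, `<param>_lo`,
#'   `<param>_hi` for `v_l`, `mean` (link-scale intercept), `v_m`,
#'   `h2_m`, `cv_m`, plus `p_among_line` and `level`.
#' @export
summarize_mutation_params <- function(vc, t, level = 0.95, trait = NULL,
                                      experiment = NULL, boot = NULL,
                                      radical = TRUE) {
  if (!inherits(vc, "ma_mcmc_fit"))
    stop_mutaccum("vc must be an ma_mcmc_fit", "mutaccum_state_error")
  if (!"v_line" %in% colnames(vc$draws))
    stop_mutaccum("fit has no among-line variance draws",
                  "mutaccum_state_error")
  fam <- vc$spec$trait$family
  v_l <- vc$draws[, "v_line"]
  mu <- vc$draws[, "mu"]
  v_e <- if (fam == "binomial") rep(1, length(v_l)) else vc$draws[, "v_resid"]
  v_m <- compute_vm(v_l, t)
  h2_m <- compute_hm2(v_m, v_e)
  cv_m <- switch(fam,
    gaussian = if (all(mu > 0)) compute_cvm(v_m, mu, "gaussian") else NULL,
    poisson = compute_cvm(v_m, family = "poisson", radical = radical),
    binomial = NULL)
  alpha <- (1 - level) / 2
  summ <- function(x) {
    if (is.null(x)) return(c(NA_real_, NA_real_, NA_real_))
    c(mean(x), unname(stats::quantile(x, c(alpha, 1 - alpha))))
  }
  vals <- list(v_l = summ(v_l), mean = summ(mu), v_m = summ(v_m),
               h2_m = summ(h2_m), cv_m = summ(cv_m))
  out <- data.frame(trait = trait %||% vc$spec$trait$name,
                    experiment = experiment %||% NA_character_,
                    stringsAsFactors = FALSE)
  for (nm in names(vals)) {
    out[[nm]] <- vals[[nm]][1]
    out[[paste0(nm, "_lo")]] <- vals[[nm]][2]
    out[[paste0(nm, "_hi")]] <- vals[[nm]][3]
  }
  out$p_among_line <- if (!is.null(boot)) boot$p_value else NA_real_
  out$level <- level
  class(out) <- c("mutation_params", "data.frame")
  out
}

# Format a number the way the study's tables print them: rounded to four
# decimals, trailing zeros dropped, values below 1e-3 in one-significant-
# figure scientific notation ("3e-04").
fmt_param <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    r <- round(v, 4)
    if (r == 0) return("0")
    if (abs(r) < 1e-3)
      return(sub("e([+-])0*(\\d\\d)$", "e\\1\\2",
                 format(signif(v, 1), scientific = TRUE)))
    sub("\\.$", "", sub("0+$", "", sprintf("%.4f", r)))
  }, "")
}

fmt_est <- function(est, lo, hi) {
  ifelse(is.na(est), "",
         sprintf("%s (%s–%s)", fmt_param(est), fmt_param(lo),
                 fmt_param(hi)))
}

#' Assemble report tables of mutation parameters
#'
#' Builds the two standard report grids: a trait-by-season grid of
#' among-line bootstrap p-values with significance flags (`*` marks p
#' below `alpha`), and a long estimates table with
#' `"estimate (lower-upper)"` strings for V_l, mean, V_m, and h2_m.
#'
#' @param params List of `mutation_params` rows (or a data frame binding
#'   them); duplicate trait-by-experiment entries are an error.
#' @param alpha Significance threshold for the p-value grid.
#' @return A list of class `ma_report` with `p_values` (wide data frame,
#'   character) and `estimates` (long data frame).
#' @export
build_report <- function(params, alpha = 0.05) {
  if (is.list(params) && !is.data.frame(params))
    params <- if (length(params)) do.call(rbind, params) else NULL
  if (!NROW(params))
    stop_mutaccum("no mutation parameters to report", "mutaccum_spec_error")
  key <- paste(params$trait, params$experiment)
  if (anyDuplicated(key))
    stop_mutaccum(sprintf("duplicate trait x experiment entries: %s",
                          paste(unique(key[duplicated(key)]), collapse = ", ")),
                  "mutaccum_key_error")
  traits <- unique(params$trait)
  seasons <- unique(params$experiment)
  pgrid <- data.frame(trait = traits, stringsAsFactors = FALSE)
  for (s in seasons) {
    col <- vapply(traits, function(tr) {
      i <- which(params$trait == tr & params$experiment == s)
      if (!length(i) || is.na(params$p_among_line[i])) return("")
      p <- params$p_among_line[i]
      paste0(sub("^0\\.", ".", fmt_param(p)), if (p < alpha) "*" else "")
    }, "")
    pgrid[[s]] <- unname(col)
  }
  est <- data.frame(trait = params$trait, experiment = params$experiment,
                    v_l = fmt_est(params$v_l, params$v_l_lo, params$v_l_hi),
                    mean = fmt_est(params$mean, params$mean_lo,
                                   params$mean_hi),
                    v_m = fmt_est(params$v_m, params$v_m_lo, params$v_m_hi),
                    h2_m = fmt_est(params$h2_m, params$h2_m_lo,
                                   params$h2_m_hi),
                    stringsAsFactors = FALSE)
  structure(list(p_values = pgrid, estimates = est, alpha = alpha),
            class = "ma_report")
}

#' @export
print.ma_report <- function(x, ...) {
  cat("Among-line variance p-values (* = significant):\n")
  print(x$p_values, row.names = FALSE)
  cat("\nParameter estimates (95% CI):\n")
  print(x$estimates, row.names = FALSE)
  invisible(x)
}
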