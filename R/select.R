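#' Likelihood-ratio statistic for a nested model pair
#'
#' Twice the difference in maximized log-likelihood between a full model
#' and a reduced model nested within it, clamped at zero (boundary
#' estimates can leave the difference negative by numerical noise).
#'
#' @param full_fit,reduced_fit `ma_ml_fit` objects from [fit_ml()]; the
#'   reduced model's random terms must be a strict subset of the full
#'   model's, for the same trait.
#' @return Non-negative deviance difference.
#' @export
lr_statistic <- function(full_fit, reduced_fit) {
  stopifnot(inherits(full_fit, "ma_ml_fit"), inherits(reduced_fit, "ma_ml_fit"))
  ft <- full_fit$spec$random_terms
  rt <- reduced_fit$spec$random_terms
  if (!all(rt %in% ft) || length(rt) >= length(ft) ||
      full_fit$spec$trait$name != reduced_fit$spec$trait$name)
    stop_mutaccum("reduced model is not nested in the full model",
                  "mutaccum_spec_error")
  max(0, 2 * (full_fit$loglik - reduced_fit$loglik))
}

#' Parametric bootstrap test of one random term
#'
#' Fits the full model and the model with `term` removed on the observed
#' data, then simulates `B` datasets from the fitted reduced (null)
#' model — same design, same family — refits both models on each
#' replicate, and collects the null likelihood-ratio distribution. The
#' p-value is the plain fraction of simulated ratios at least as large as
#' the observed one (ties count toward the null, exactly the published
#' counting rule; the `(1 + #)/(B + 1)` correction is available via
#' `correction = TRUE`). Replicates whose refits fail to converge are
#' dropped and counted; more than 10% failures aborts the test.
#'
#' @param table A `phenotype_tbl`.
#' @param full_spec A [model_spec()] containing `term`.
#' @param term Random term to test (`"block"`, `"line"`,
#'   `"subline_in_line"`).
#' @param B Number of bootstrap replicates (the study used 1,000).
#' @param seed Integer seed; each replicate uses a derived sub-seed.
#' @param alpha Retention threshold.
#' @param correction Use the `(1 + #)/(B + 1)` finite-sample p-value.
#' @return An object of class `boot_lrt`: `term`, `lr_observed`,
#'   `lr_null`, `p_value`, `retained`, `B`, `B_effective`, `n_failed`.
#' @export
parametric_bootstrap <- function(table, full_spec, term, B = 1000L,
                                 seed = 1L, alpha = 0.05,
                                 correction = FALSE) {
  if (B < 1) stop_mutaccum("B must be >= 1", "mutaccum_spec_error")
  if (!term %in% full_spec$random_terms)
    stop_mutaccum(sprintf("term '%s' not in full model", term),
                  "mutaccum_spec_error")
  reduced_spec <- drop_term(full_spec, term)
  full_fit <- fit_ml(table, full_spec)
  reduced_fit <- fit_ml(table, reduced_spec)
  lr_obs <- lr_statistic(full_fit, reduced_fit)
  lr_null <- rep(NA_real_, B)
  for (i in seq_len(B)) {
    set.seed(derive_seed(seed, "pboot", term, i))
    lr_null[i] <- tryCatch({
      y <- simulate_ml(reduced_fit, 1L)[[1]]
      ll_r <- refit_loglik(reduced_fit, y)
      ll_f <- refit_loglik(full_fit, y)
      max(0, 2 * (ll_f - ll_r))
    }, error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(lr_null))
  if (n_failed > 0.1 * B)
    stop_mutaccum(sprintf("%d of %d bootstrap replicates failed", n_failed, B),
                  "mutaccum_reliability_error")
  lr_null <- lr_null[!is.na(lr_null)]
  Beff <- length(lr_null)
  p <- if (correction) (1 + sum(lr_null >= lr_obs)) / (Beff + 1)
       else sum(lr_null >= lr_obs) / Beff
  structure(list(term = term, lr_observed = lr_obs, lr_null = lr_null,
                 p_value = p, retained = p < alpha, alpha = alpha,
                 B = B, B_effective = Beff, n_failed = n_failed),
            class = "boot_lrt")
}

#' @export
print.boot_lrt <- function(x, ...) {
  cat(sprintf("<boot_lrt> term %s: LR = %.3f, p = %.4g (B = %d), %s\n",
              x$term, x$lr_observed, x$p_value, x$B_effective,
              if (x$retained) "retained" else "dropped"))
  invisible(x)
}

#' Select random effects for the final estimation model
#'
#' Bootstrap-tests each candidate explanatory term (block, field subline)
#' and keeps those with p below `alpha`. The among-line term is exempt
#' from removal: its variance is the estimand. By default candidates are
#' tested marginally, each deleted from the full model; `sequential =
#' TRUE` instead tests against the progressively reduced model.
#'
#' @inheritParams parametric_bootstrap
#' @param sequential Test terms against the shrinking model rather than
#'   marginally against the full model.
#' @return A list with `spec` (the final [model_spec()]) and `results`
#'   (list of `boot_lrt`).
#' @export
select_model <- function(table, full_spec, B = 1000L, seed = 1L,
                         alpha = 0.05, sequential = FALSE) {
  if (!"line" %in% full_spec$random_terms)
    stop_mutaccum("full model must contain the line term",
                  "mutaccum_spec_error")
  candidates <- intersect(c("subline_in_line", "block"),
                          full_spec$random_terms)
  results <- list()
  current <- full_spec
  for (term in candidates) {
    base <- if (sequential) current else full_spec
    if (!term %in% base$random_terms) next
    res <- parametric_bootstrap(table, base, term, B = B,
                                seed = derive_seed(seed, "select", term),
                                alpha = alpha)
    results[[term]] <- res
    if (!res$retained) current <- drop_term(current, term)
  }
  list(spec = current, results = results)
}
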