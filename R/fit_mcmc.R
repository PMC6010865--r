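#' MCMC sampler settings
#'
#' @param n_iter Total iterations (including burn-in).
#' @param burn_in Iterations discarded before storage.
#' @param thin Storage interval.
#' @param prior Variance prior: list with `v` (scale), `nu` (degrees of
#'   freedom), and optionally `alpha_v`. Every variance component gets an
#'   inverse-gamma(`nu/2`, `nu*v/2`) prior; when `alpha_v` is non-`NULL`
#'   the random-effect variances are parameter-expanded with a
#'   `N(0, alpha_v)` working scale, giving a heavier-shouldered scaled-F
#'   implied prior that avoids the inverse-gamma spike at zero for weakly
#'   identified components (the residual variance is never expanded). The
#'   default (`v = 1`, `nu = 0.002`, `alpha_v = 625`) is weakly
#'   informative; `alpha_v = NULL` is the documented plain
#'   inverse-gamma alternative.
#' @param seed Integer seed (`NULL` = leave RNG state alone).
#' @param ess_floor Effective-sample-size threshold below which the fit
#'   is flagged (`low_ess = TRUE`), not failed.
#' @param mu_prior_var Variance of the Gaussian prior on the intercept;
#'   `Inf` (default) is the improper flat prior.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 50000L, burn_in = 10000L, thin = 10L,
                          prior = list(v = 1, nu = 0.002, alpha_v = 625),
                          seed = NULL,
                          ess_floor = 100, mu_prior_var = Inf) {
  if (n_iter <= burn_in)
    stop_mutaccum("n_iter must exceed burn_in", "mutaccum_spec_error")
  if (thin < 1) stop_mutaccum("thin must be >= 1", "mutaccum_spec_error")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), prior = prior, seed = seed,
                 ess_floor = ess_floor, mu_prior_var = mu_prior_var),
            class = "mcmc_settings")
}

rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape, rate = rate)

log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Fit a variance-component model by MCMC
#'
#' Bayesian fit of the block/line/subline random-intercept model.
#' Gaussian traits use a fully conjugate blocked Gibbs sampler
#' (normal updates for the intercept and each random-effect vector,
#' inverse-gamma updates for every variance). Poisson and binomial traits
#' introduce a latent linear predictor per observation, updated by
#' vectorized random-walk Metropolis steps (adapted to ~44% acceptance
#' during burn-in); conditional on the latent values the model is the
#' Gaussian one and all remaining updates are conjugate. The latent
#' residual variance is the Poisson lognormal overdispersion V_e, and is
#' fixed at 1 for binomial traits (it is non-identifiable for Bernoulli
#' responses).
#'
#' @param table A `phenotype_tbl`.
#' @param spec A [model_spec()].
#' @param settings An [mcmc_settings()].
#' @return An object of class `ma_mcmc_fit`: `draws` (matrix, one column
#'   per parameter: `mu`, `v_block`, `v_line`, `v_subline`, `v_resid` as
#'   present), posterior `means`, effective sample sizes `ess`,
#'   split-chain `rhat`, `low_ess` flag, and MH `accept_rate` (NA for
#'   Gaussian).
#' @export
fit_mcmc <- function(table, spec, settings = mcmc_settings()) {
  stopifnot(inherits(spec, "model_spec"), inherits(settings, "mcmc_settings"))
  if (!is.null(settings$seed)) set.seed(as.integer(settings$seed))
  fam <- spec$trait$family
  a0 <- settings$prior$nu / 2
  b0 <- settings$prior$nu * settings$prior$v / 2
  n_keep <- (settings$n_iter - settings$burn_in) %/% settings$thin
  term_map <- c(block = "v_block", line = "v_line",
                subline_in_line = "v_subline")
  terms <- spec$random_terms
  est_resid <- fam != "binomial"
  par_names <- c("mu", unname(term_map[terms]), "v_resid")

  d <- tryCatch(model_frame(table, spec), error = function(e) e)
  if (inherits(d, "error") &&
      inherits(d, "mutaccum_error") && grepl("no rows", conditionMessage(d))) {
    # prior-only run: no data, draws come straight from the prior
    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    alpha_v <- settings$prior$alpha_v
    for (v in setdiff(par_names, c("mu", "v_resid"))) {
      draws[, v] <- rinvgamma(n_keep, a0, b0)
      if (!is.null(alpha_v))
        draws[, v] <- draws[, v] * stats::rnorm(n_keep, 0, sqrt(alpha_v))^2
    }
    if (est_resid) draws[, "v_resid"] <- rinvgamma(n_keep, a0, b0)
    else draws[, "v_resid"] <- 1
    if (is.finite(settings$mu_prior_var))
      draws[, "mu"] <- stats::rnorm(n_keep, 0, sqrt(settings$mu_prior_var))
    return(new_mcmc_fit(draws, spec, settings, accept_rate = NA_real_))
  }
  if (inherits(d, "error")) stop(d)

  y <- d$.y
  n <- length(y)
  idx <- lapply(terms, function(tm) switch(tm,
    block = as.integer(droplevels(d$block)),
    line = as.integer(droplevels(d$line)),
    subline_in_line = as.integer(droplevels(factor(
      paste(d$line, d$subline, sep = ":")))) ))
  names(idx) <- terms
  m <- vapply(idx, max, 1L)
  nj <- lapply(idx, tabulate)
  u <- lapply(m, function(k) numeric(k))
  cvec <- lapply(idx, function(i) numeric(n))

  # initialization on the link scale
  l <- switch(fam, gaussian = y, poisson = log(y + 0.5),
              binomial = (2 * y - 1) * 0.8)
  mu <- mean(l)
  vf <- stats::setNames(rep(max(stats::var(l), 1e-3) / (length(terms) + 1),
                            length(terms)), terms)
  ve <- if (fam == "binomial") 1 else max(stats::var(l) / 2, 1e-3)
  # parameter expansion: u_f = alpha_f * ut_f with ut ~ N(0, vt_f) and a
  # N(0, alpha_v) working prior on alpha_f; reported v_f = alpha_f^2 vt_f
  alpha_v <- settings$prior$alpha_v
  px <- !is.null(alpha_v)
  alpha <- stats::setNames(rep(1, length(terms)), terms)
  vt <- vf
  step <- 0.8
  acc_tot <- 0L; acc_win <- 0L; win <- 0L
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  k <- 0L

  loglik_latent <- function(lv) switch(fam,
    poisson = y * lv - exp(lv),
    binomial = y * lv - log1pexp(lv))

  for (it in seq_len(settings$n_iter)) {
    zu <- if (length(cvec)) Reduce(`+`, cvec) else numeric(n)
    if (fam != "gaussian") {
      mvec <- mu + zu
      prop <- l + step * stats::rnorm(n)
      logr <- loglik_latent(prop) - loglik_latent(l) -
        ((prop - mvec)^2 - (l - mvec)^2) / (2 * ve)
      acc <- log(stats::runif(n)) < logr
      l[acc] <- prop[acc]
      win <- win + 1L
      acc_win <- acc_win + mean(acc)
      if (it <= settings$burn_in && win == 50L) {
        step <- min(10, max(1e-3, step * exp(acc_win / win - 0.44)))
        acc_win <- 0; win <- 0L
      } else if (it > settings$burn_in) acc_tot <- acc_tot + mean(acc)
    }
    w <- if (fam == "gaussian") y else l
    # intercept
    r <- w - zu
    if (is.finite(settings$mu_prior_var)) {
      prec <- n / ve + 1 / settings$mu_prior_var
      mu <- stats::rnorm(1, (sum(r) / ve) / prec, sqrt(1 / prec))
    } else mu <- stats::rnorm(1, mean(r), sqrt(ve / n))
    # random-effect vectors and their variances
    for (tm in terms) {
      p <- w - mu - (zu - cvec[[tm]])
      s <- as.vector(rowsum(p, idx[[tm]], reorder = TRUE))
      if (px) {
        # working-scale representation: contribution is alpha * ut[idx]
        varj <- 1 / (alpha[[tm]]^2 * nj[[tm]] / ve + 1 / vt[[tm]])
        u[[tm]] <- stats::rnorm(m[[tm]], varj * alpha[[tm]] * s / ve,
                                sqrt(varj))
        ux <- u[[tm]][idx[[tm]]]
        prec_a <- sum(nj[[tm]] * u[[tm]]^2) / ve + 1 / alpha_v
        mean_a <- sum(ux * p) / ve / prec_a
        alpha[[tm]] <- stats::rnorm(1, mean_a, sqrt(1 / prec_a))
        vt[[tm]] <- rinvgamma(1, a0 + m[[tm]] / 2,
                              b0 + sum(u[[tm]]^2) / 2)
        cvec[[tm]] <- alpha[[tm]] * ux
        vf[[tm]] <- alpha[[tm]]^2 * vt[[tm]]
      } else {
        varj <- 1 / (nj[[tm]] / ve + 1 / vf[[tm]])
        u[[tm]] <- stats::rnorm(m[[tm]], varj * s / ve, sqrt(varj))
        cvec[[tm]] <- u[[tm]][idx[[tm]]]
        vf[[tm]] <- rinvgamma(1, a0 + m[[tm]] / 2,
                              b0 + sum(u[[tm]]^2) / 2)
      }
      zu <- Reduce(`+`, cvec)
    }
    if (est_resid) {
      resid <- w - mu - zu
      ve <- rinvgamma(1, a0 + n / 2, b0 + sum(resid^2) / 2)
    }
    if (it > settings$burn_in &&
        (it - settings$burn_in) %% settings$thin == 0L) {
      k <- k + 1L
      draws[k, ] <- c(mu, unlist(vf, use.names = FALSE), ve)
    }
  }
  if (any(!is.finite(draws)))
    stop_mutaccum("divergent chain: non-finite draws", "mutaccum_sampler_error")
  acc_rate <- if (fam == "gaussian") NA_real_
              else acc_tot / (settings$n_iter - settings$burn_in)
  new_mcmc_fit(draws, spec, settings, accept_rate = acc_rate)
}

new_mcmc_fit <- function(draws, spec, settings, accept_rate) {
  es <- apply(draws, 2, mcmc_ess)
  rh <- apply(draws, 2, split_rhat)
  structure(list(draws = draws, means = colMeans(draws),
                 ess = es, rhat = rh,
                 low_ess = any(es[!is.na(es)] < settings$ess_floor),
                 accept_rate = accept_rate, spec = spec,
                 settings = settings),
            class = "ma_mcmc_fit")
}

#' @export
print.ma_mcmc_fit <- function(x, ...) {
  cat(sprintf("<ma_mcmc_fit> %s (%s), %d draws%s\n",
              x$spec$trait$name, x$spec$trait$family, nrow(x$draws),
              if (isTRUE(x$low_ess)) " [low ESS]" else ""))
  print(data.frame(mean = round(x$means, 5), ess = round(x$ess, 1),
                   rhat = round(x$rhat, 3)))
  invisible(x)
}

# Effective sample size by Geyer's initial positive sequence.
mcmc_ess <- function(x) {
  n <- length(x)
  if (all(is.na(x))) return(NA_real_)
  if (n < 10 || stats::var(x) == 0) return(n)
  lag_max <- min(n - 2L, 1000L)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  np <- (length(ac)) %/% 2L
  if (np < 1L) return(n)
  G <- ac[2 * seq_len(np) - 1] + ac[2 * seq_len(np)]
  cut <- which(G <= 0)[1]
  if (!is.na(cut)) G <- G[seq_len(cut - 1L)]
  tau <- max(2 * sum(G) - 1, 1)
  min(n, n / tau)
}

# Split-chain potential scale reduction factor.
split_rhat <- function(x) {
  x <- x[!is.na(x)]
  n2 <- length(x) %/% 2L
  if (n2 < 2L || stats::var(x) == 0) return(1)
  ch <- cbind(x[seq_len(n2)], x[seq_len(n2) + n2])
  W <- mean(apply(ch, 2, stats::var))
  B <- n2 * stats::var(colMeans(ch))
  if (W == 0) return(1)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

#' Summarize a posterior fit
#'
#' Posterior mean and equal-tailed quantile interval for every sampled
#' parameter.
#'
#' @param vc An `ma_mcmc_fit` from [fit_mcmc()].
#' @param level Interval probability (default 0.95).
#' @return Data frame with `parameter`, `mean`, `lower`, `upper`.
#' @export
posterior_summary <- function(vc, level = 0.95) {
  if (!inherits(vc, "ma_mcmc_fit") || is.null(vc$draws))
    stop_mutaccum("posterior draws are not available", "mutaccum_state_error")
  alpha <- (1 - level) / 2
  qs <- apply(vc$draws, 2, stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE)
  data.frame(parameter = colnames(vc$draws),
             mean = unname(colMeans(vc$draws)),
             lower = unname(qs[1, ]), upper = unname(qs[2, ]),
             row.names = NULL, stringsAsFactors = FALSE)
}
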