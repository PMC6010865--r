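#' Specify a variance-component model for one trait
#'
#' The full model for a trait in one season has random intercepts for
#' block, line, and field subline nested within line, plus residual
#' error. Reduced models drop terms; a model used to *estimate* mutation
#' parameters must retain `line` (its variance is the estimand), but
#' reduced models without `line` are legal so the among-line term itself
#' can be bootstrap-tested.
#'
#' @param trait A [trait_spec()].
#' @param random_terms Subset of `c("block", "line", "subline_in_line")`.
#'   `subline_in_line` requires `line`.
#' @param classes Genotype classes entering the fit (variance estimation
#'   uses the MA lines alone).
#' @param poisson_olre Include an observation-level lognormal random
#'   effect as the Poisson residual variance V_e.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(trait,
                       random_terms = c("block", "line", "subline_in_line"),
                       classes = "ma",
                       poisson_olre = FALSE) {
  stopifnot(inherits(trait, "trait_spec"))
  ok <- c("block", "line", "subline_in_line")
  if (length(random_terms) && !all(random_terms %in% ok))
    stop_mutaccum("random_terms must be among block/line/subline_in_line",
                  "mutaccum_spec_error")
  if ("subline_in_line" %in% random_terms && !"line" %in% random_terms)
    stop_mutaccum("subline_in_line requires line", "mutaccum_spec_error")
  structure(list(trait = trait, random_terms = unique(random_terms),
                 classes = classes,
                 poisson_olre = isTRUE(poisson_olre) &&
                   trait$family == "poisson"),
            class = "model_spec")
}

drop_term <- function(spec, term) {
  if (!term %in% spec$random_terms)
    stop_mutaccum(sprintf("term '%s' not in model", term),
                  "mutaccum_spec_error")
  terms <- setdiff(spec$random_terms, term)
  if (term == "line") terms <- setdiff(terms, "subline_in_line")
  model_spec(spec$trait, terms, spec$classes, spec$poisson_olre)
}

model_frame <- function(table, spec) {
  trait <- spec$trait
  if (!trait$name %in% names(table))
    stop_mutaccum(sprintf("trait column '%s' absent from table", trait$name),
                  "mutaccum_spec_error")
  keep <- condition_rows(table, trait, spec$classes)
  d <- as.data.frame(table)[keep, , drop = FALSE]
  if (!nrow(d))
    stop_mutaccum("no rows left after conditioning", "mutaccum_spec_error")
  d$.y <- d[[trait$name]]
  d$block <- factor(d$block)
  d$line <- factor(d$line)
  d$subline <- factor(d$subline)
  d$.obs <- factor(seq_len(nrow(d)))
  for (term in spec$random_terms) {
    f <- switch(term, block = d$block, line = d$line,
                subline_in_line = d$subline)
    if (nlevels(droplevels(f)) < 2L)
      stop_mutaccum(sprintf("random term '%s' has fewer than 2 levels", term),
                    "mutaccum_spec_error")
  }
  d
}

model_formula <- function(spec) {
  terms <- c(block = "(1 | block)", line = "(1 | line)",
             subline_in_line = "(1 | line:subline)")[spec$random_terms]
  if (spec$poisson_olre) terms <- c(terms, "(1 | .obs)")
  stats::reformulate(c("1", unname(terms)), response = ".y")
}

#' Fit a variance-component model by (approximate) maximum likelihood
#'
#' Gaussian traits are fitted with `lme4::lmer` (ML by default so
#' deviances of nested model pairs are comparable; REML available),
#' Poisson and binomial traits with `lme4::glmer` (Laplace approximation
#' to the integrated likelihood). A model with no random terms falls back
#' to `lm`/`glm`, whose log-likelihood is on the same objective. Variance
#' estimates are non-negative by construction; boundary estimates are
#' reported as 0. For binomial traits the residual variance is the fixed
#' latent logit-scale variance 1.
#'
#' @param table A `phenotype_tbl`.
#' @param spec A [model_spec()].
#' @param REML Use REML for Gaussian fits (default `FALSE`: ML, required
#'   for likelihood-ratio comparisons).
#' @return An object of class `ma_ml_fit`: variance components `vc`
#'   (named: block, line, subline, resid), intercept `mu`, `loglik`,
#'   `converged`, and the underlying fitted model.
#' @export
fit_ml <- function(table, spec, REML = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  d <- model_frame(table, spec)
  fam <- spec$trait$family
  # a constant response (e.g. every plant germinated) is the degenerate
  # ML limit: all variances 0, intercept-only fit; glmer refuses it
  intercept_only <- stats::var(d$.y) == 0 ||
    (!length(spec$random_terms) && !spec$poisson_olre)
  fit <- if (intercept_only) {
    if (fam == "gaussian") stats::lm(.y ~ 1, data = d)
    else suppressWarnings(stats::glm(.y ~ 1, data = d, family = fam))
  } else {
    form <- model_formula(spec)
    if (fam == "gaussian")
      fit_with_restarts(function(ctrl) lme4::lmer(
        form, data = d, REML = REML, control = ctrl), gaussian = TRUE)
    else
      fit_with_restarts(function(ctrl) lme4::glmer(
        form, data = d, family = fam, control = ctrl), gaussian = FALSE)
  }
  as_ml_fit(fit, spec, d)
}

fit_with_restarts <- function(fitter, gaussian) {
  ctrl_fun <- if (gaussian) lme4::lmerControl else lme4::glmerControl
  quiet <- function(ctrl) suppressWarnings(suppressMessages(fitter(ctrl)))
  optimizers <- if (gaussian) list(NULL, "bobyqa")
                else list(NULL, "bobyqa", "Nelder_Mead")
  best <- NULL
  for (opt in optimizers) {
    ctrl <- if (is.null(opt)) ctrl_fun(calc.derivs = FALSE)
            else ctrl_fun(optimizer = opt, calc.derivs = FALSE)
    f <- tryCatch(quiet(ctrl), error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || stats::logLik(f) > stats::logLik(best)) best <- f
    if (ml_converged(f)) return(f)
  }
  if (is.null(best))
    stop_mutaccum("model fit failed in every restart",
                  "mutaccum_convergence_error")
  stop_mutaccum("model did not converge after restarts",
                "mutaccum_convergence_error", best = best)
}

ml_converged <- function(fit) {
  if (!inherits(fit, "merMod")) return(TRUE)
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  # boundary (singular) fits are valid maxima, not convergence failures
  msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  length(msgs) == 0L && fit@optinfo$conv$opt == 0L
}

as_ml_fit <- function(fit, spec, d) {
  fam <- spec$trait$family
  vc <- c(block = 0, line = 0, subline = 0,
          resid = if (fam == "binomial") 1 else NA_real_)
  if (inherits(fit, "merMod")) {
    vv <- lme4::VarCorr(fit)
    get_v <- function(g) if (g %in% names(vv)) as.numeric(vv[[g]][1, 1]) else 0
    vc["block"] <- get_v("block")
    vc["line"] <- get_v("line")
    vc["subline"] <- get_v("line:subline")
    if (fam == "gaussian") vc["resid"] <- stats::sigma(fit)^2
    if (fam == "poisson" && spec$poisson_olre) vc["resid"] <- get_v(".obs")
    mu <- unname(lme4::fixef(fit)[1])
  } else {
    if (fam == "gaussian") {
      n <- length(stats::residuals(fit))
      vc["resid"] <- sum(stats::residuals(fit)^2) / n  # ML, not n - 1
    }
    mu <- unname(stats::coef(fit)[1])
  }
  structure(list(vc = vc, mu = mu, loglik = as.numeric(stats::logLik(fit)),
                 spec = spec, fit = fit, n = nrow(d),
                 converged = ml_converged(fit)),
            class = "ma_ml_fit")
}

#' @export
print.ma_ml_fit <- function(x, ...) {
  cat(sprintf("<ma_ml_fit> %s (%s), n = %d, logLik = %.3f\n",
              x$spec$trait$name, x$spec$trait$family, x$n, x$loglik))
  print(round(x$vc, 6))
  invisible(x)
}

# Simulate response vectors from a fitted null model (new random-effect
# and residual draws each replicate), and refit a model on a new response
# returning only the maximized log-likelihood. Fast paths for the
# bootstrap stage.
simulate_ml <- function(ml_fit, nsim = 1L) {
  # simulate.merMod's default re.form = NA draws fresh random effects,
  # which is exactly the parametric-bootstrap null resampling scheme
  sims <- stats::simulate(ml_fit$fit, nsim = nsim)
  lapply(seq_len(nsim), function(i) {
    y <- sims[[i]]
    if (is.factor(y)) y <- as.numeric(as.character(y))
    as.numeric(y)
  })
}

refit_loglik <- function(ml_fit, y) {
  fit <- ml_fit$fit
  if (inherits(fit, "merMod")) {
    new <- suppressWarnings(suppressMessages(lme4::refit(fit, y)))
    if (!ml_converged(new))
      stop_mutaccum("refit did not converge", "mutaccum_convergence_error")
    return(as.numeric(stats::logLik(new)))
  }
  n <- length(y)
  if (ml_fit$spec$trait$family == "gaussian") {
    rss <- sum((y - mean(y))^2)
    return(-n / 2 * (log(2 * pi) + log(rss / n) + 1))
  }
  # constant simulated responses make the intercept estimate run to the
  # boundary; the warning is expected and the log-likelihood is exact
  g <- suppressWarnings(stats::glm(y ~ 1,
                                   family = ml_fit$spec$trait$family))
  as.numeric(stats::logLik(g))
}
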