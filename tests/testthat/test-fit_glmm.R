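test_that("balanced one-way REML fit matches the closed-form ANOVA oracle", {
  tab <- one_way_table(50, 10, v_line = 2, v_resid = 1, seed = 31)
  spec <- model_spec(gaussian_field_trait(), "line")
  fit <- fit_ml(tab, spec, REML = TRUE)
  oracle <- anova_oracle(tab$mass, tab$line, 10)
  expect_equal(unname(fit$vc["line"]), unname(oracle["v_line"]),
               tolerance = 1e-6)
  expect_equal(unname(fit$vc["resid"]), unname(oracle["v_resid"]),
               tolerance = 1e-6)
  expect_equal(fit$mu, mean(tab$mass), tolerance = 1e-6)
})

test_that("constant responses give zero variances and mu at the constant", {
  df <- data.frame(experiment = "s1", block = rep(c("B1", "B2"), 10),
                   genotype_class = "ma",
                   line = rep(sprintf("L%d", 1:5), each = 4),
                   subline = rep(sprintf("L%d.s1", 1:5), each = 4),
                   survival = 1, mass = 7)
  tab <- phenotype_table(df, list(gaussian_field_trait()))
  fit <- fit_ml(tab, model_spec(gaussian_field_trait(), c("block", "line")))
  expect_equal(unname(fit$vc[c("block", "line", "resid")]), c(0, 0, 0),
               tolerance = 1e-8)
  expect_equal(fit$mu, 7, tolerance = 1e-8)
})

test_that("Poisson Laplace fits recover the generating line variance", {
  errs <- vapply(1:12, function(i) {
    d <- experiment_design(n_blocks = 1, n_ma_lines = 100,
                           progenitor_sublines = 0,
                           field_sublines_per_line = 1,
                           ma_plants_per_line_per_block = 10,
                           progenitor_plants_per_subline_per_block = 0)
    skel <- generate_design(d, seed = i)
    tr <- trait_spec("seeds", "poisson", "field_planted")
    skel$seeds <- simulate_trait(
      skel, tr, single_trait_season("seeds", mu = 2, 0, 0.3, 0, 0),
      seed = 100 + i)
    tab <- phenotype_table(skel, list(tr))
    fit <- fit_ml(tab, model_spec(tr, "line"))
    unname(fit$vc["line"])
  }, 0)
  expect_equal(mean(errs), 0.3, tolerance = 0.2 * 0.3)
})

test_that("adding a random term never decreases the log-likelihood", {
  cfg <- sim_config(design = small_design(), seasons = default_seasons()[1],
                    seed = 37)
  tab <- simulate_experiment(cfg)$tables[[1]]
  tr <- ma_traits()$survival
  lls <- vapply(list("line", c("block", "line"),
                     c("block", "line", "subline_in_line")),
                function(terms) fit_ml(tab, model_spec(tr, terms))$loglik, 0)
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("estimates are invariant to relabeling blocks and lines", {
  tab <- one_way_table(20, 5, v_line = 1, v_resid = 1, seed = 41)
  fit1 <- fit_ml(tab, model_spec(gaussian_field_trait(), "line"))
  relab <- as.data.frame(tab)
  key <- setNames(sprintf("Z%03d", sample(20)), unique(relab$line))
  relab$line <- unname(key[relab$line])
  relab$subline <- paste0(relab$line, ".s1")
  tab2 <- phenotype_table(relab, list(gaussian_field_trait()))
  fit2 <- fit_ml(tab2, model_spec(gaussian_field_trait(), "line"))
  expect_equal(fit1$vc, fit2$vc, tolerance = 1e-6)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
})

test_that("single-level terms are rejected", {
  tab <- one_way_table(10, 4, 1, 1, seed = 43)  # single block
  expect_error(fit_ml(tab, model_spec(gaussian_field_trait(),
                                      c("block", "line"))),
               class = "mutaccum_spec_error")
})

test_that("binomial fits always report latent residual variance 1", {
  cfg <- sim_config(design = small_design(), seasons = default_seasons()[1],
                    seed = 47)
  tab <- simulate_experiment(cfg)$tables[[1]]
  tr <- ma_traits()$survival
  fit <- fit_ml(tab, model_spec(tr, c("block", "line")))
  expect_identical(unname(fit$vc["resid"]), 1)
  mfit <- fit_mcmc(tab, model_spec(tr, "line"),
                   mcmc_settings(600, 100, 1, seed = 5))
  expect_true(all(mfit$draws[, "v_resid"] == 1))
})

test_that("Gaussian Gibbs matches the analytic inverse-gamma posterior", {
  # intercept-only model: with a flat prior on mu, the marginal posterior
  # of v_resid is IG(a0 + (n-1)/2, b0 + SS/2)
  set.seed(53)
  n <- 200
  y <- pmax(0, 10 + rnorm(n, 0, 2))
  df <- data.frame(experiment = "s1", block = "B1", genotype_class = "ma",
                   line = rep(sprintf("L%d", 1:10), each = 20),
                   subline = rep(sprintf("L%d.s1", 1:10), each = 20),
                   survival = 1, mass = y)
  tab <- phenotype_table(df, list(gaussian_field_trait()))
  prior <- list(v = 1, nu = 0.002)
  fit <- fit_mcmc(tab, model_spec(gaussian_field_trait(), character()),
                  mcmc_settings(12000, 2000, 1, prior = prior, seed = 7))
  a_post <- prior$nu / 2 + (n - 1) / 2
  b_post <- prior$nu * prior$v / 2 + sum((y - mean(y))^2) / 2
  true_mean <- b_post / (a_post - 1)
  true_var <- b_post^2 / ((a_post - 1)^2 * (a_post - 2))
  draws <- fit$draws[, "v_resid"]
  mcse_mean <- sd(draws) / sqrt(fit$ess["v_resid"])
  expect_lt(abs(mean(draws) - true_mean), 3 * mcse_mean)
  mcse_var <- var(draws) * sqrt(2 / fit$ess["v_resid"])
  expect_lt(abs(var(draws) - true_var), 3 * mcse_var)
})

test_that("with no data the sampler reproduces its prior", {
  tab <- phenotype_table(tiny_table()[0, ], tiny_traits())
  # plain (non-expanded) proper IG(2, 1) prior: mean 1, finite variance
  prior <- list(v = 0.5, nu = 4, alpha_v = NULL)
  fit <- fit_mcmc(tab, model_spec(ma_traits()$biomass, "line"),
                  mcmc_settings(6000, 1000, 1, prior = prior, seed = 11))
  draws <- fit$draws[, "v_line"]
  a <- prior$nu / 2; b <- prior$nu * prior$v / 2
  expect_equal(mean(draws), b / (a - 1), tolerance = 0.1)
  expect_equal(mean(1 / draws), a / b, tolerance = 0.05)
})

test_that("posterior_summary follows order statistics", {
  fake <- structure(list(draws = cbind(v_line = as.numeric(1:100))),
                    class = "ma_mcmc_fit")
  s <- posterior_summary(fake, level = 0.95)
  expect_equal(s$mean, 50.5)
  expect_equal(s$lower, unname(quantile(1:100, 0.025)))
  expect_equal(s$upper, unname(quantile(1:100, 0.975)))
  const <- structure(list(draws = cbind(v_line = rep(3, 50))),
                     class = "ma_mcmc_fit")
  sc <- posterior_summary(const)
  expect_equal(unlist(sc[, c("mean", "lower", "upper")]), c(3, 3, 3),
               ignore_attr = TRUE)
  expect_error(posterior_summary(structure(list(), class = "list")),
               class = "mutaccum_state_error")
  # large normal draw set: interval matches the normal quantile oracle
  set.seed(59)
  nd <- structure(list(draws = cbind(v_line = rnorm(50000, 0.46, 0.01))),
                  class = "ma_mcmc_fit")
  sn <- posterior_summary(nd)
  expect_equal(sn$lower, qnorm(0.025, 0.46, 0.01), tolerance = 0.002)
  expect_equal(sn$upper, qnorm(0.975, 0.46, 0.01), tolerance = 0.002)
})

test_that("ML and MCMC agree on large balanced Gaussian data", {
  tab <- one_way_table(60, 12, v_line = 2, v_resid = 1, seed = 61)
  spec <- model_spec(gaussian_field_trait(), "line")
  ml <- fit_ml(tab, spec, REML = TRUE)
  mc <- fit_mcmc(tab, spec, mcmc_settings(8000, 2000, 2, seed = 13))
  expect_equal(mc$means[["v_line"]], unname(ml$vc["line"]), tolerance = 0.2)
  expect_equal(mc$means[["v_resid"]], unname(ml$vc["resid"]),
               tolerance = 0.05)
  expect_equal(mc$means[["mu"]], ml$mu, tolerance = 0.05)
})

test_that("binomial MCMC intervals cover a small true line variance", {
  covered <- vapply(1:20, function(i) {
    d <- experiment_design(n_blocks = 1, n_ma_lines = 100,
                           progenitor_sublines = 0,
                           field_sublines_per_line = 1,
                           ma_plants_per_line_per_block = 50,
                           progenitor_plants_per_subline_per_block = 0)
    skel <- generate_design(d, seed = i)
    tr <- trait_spec("alive", "binomial", "field_planted")
    skel$alive <- simulate_trait(
      skel, tr, single_trait_season("alive", mu = 0.5, 0, 0.05, v_resid = 1),
      seed = 300 + i)
    tab <- phenotype_table(skel, list(tr))
    fit <- fit_mcmc(tab, model_spec(tr, "line"),
                    mcmc_settings(4000, 1000, 3, seed = i))
    s <- posterior_summary(fit)
    vl <- s[s$parameter == "v_line", ]
    vl$lower <= 0.05 && 0.05 <= vl$upper
  }, TRUE)
  expect_gte(sum(covered), 18)
})
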