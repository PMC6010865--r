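test_that("trait specs pair family with its canonical link and conditioning", {
  reg <- ma_traits()
  expect_named(reg)
  links <- vapply(reg, `[[`, "", "link")
  fams <- vapply(reg, `[[`, "", "family")
  expect_true(all(links[fams == "gaussian"] == "identity"))
  expect_true(all(links[fams == "poisson"] == "log"))
  expect_true(all(links[fams == "binomial"] == "logit"))
  expect_equal(reg$germination$conditioning, "all_planted")
  expect_equal(reg$survival$conditioning, "field_planted")
  expect_equal(reg$fitness$conditioning, "field_planted")
  others <- setdiff(names(reg), c("germination", "survival", "fitness"))
  expect_true(all(vapply(reg[others], `[[`, "", "conditioning") ==
                    "survivors_only"))
  expect_error(trait_spec("germination", "binomial", "survivors_only"),
               class = "mutaccum_spec_error")
})

test_that("trait config YAML round-trips into trait specs", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("mass:", "  family: gaussian",
               "seeds: {family: poisson, conditioning: survivors_only}",
               "alive: binomial"), path)
  cfg <- read_trait_config(path)
  expect_equal(cfg$mass$family, "gaussian")
  expect_equal(cfg$seeds$conditioning, "survivors_only")
  expect_equal(cfg$alive$family, "binomial")
  expect_equal(cfg$alive$link, "logit")
})

test_that("a 3-row table round-trips through CSV with values and NAs intact", {
  tab <- phenotype_table(tiny_table(), tiny_traits())
  expect_s3_class(tab, "phenotype_tbl")
  expect_equal(nrow(tab), 3L)
  # composite fitness computed at load: dead plant scores 0
  expect_equal(tab$fitness, c(12, 0, 30))
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(tab, path)
  back <- read_phenotypes(path, tiny_traits())
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("a simulated table survives a write/read round-trip", {
  cfg <- sim_config(design = small_design(), seasons = default_seasons()[1],
                    seed = 42)
  tab <- simulate_experiment(cfg)$tables[[1]]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(tab, path)
  back <- read_phenotypes(path, ma_traits())
  df_a <- as.data.frame(tab)
  df_b <- as.data.frame(back)[names(df_a)]
  expect_equal(df_b, df_a, ignore_attr = TRUE)
})

test_that("validation rejects each class of invariant violation", {
  base <- tiny_table()
  tr <- tiny_traits()
  bad_binary <- base; bad_binary$germination[1] <- 2
  expect_error(phenotype_table(bad_binary, tr),
               class = "mutaccum_validation_error")
  bad_count <- base; bad_count$fruits[1] <- -3
  expect_error(phenotype_table(bad_count, tr),
               class = "mutaccum_validation_error")
  bad_frac <- base; bad_frac$fruits[1] <- 2.5
  expect_error(phenotype_table(bad_frac, tr),
               class = "mutaccum_validation_error")
  bad_cont <- base; bad_cont$biomass[1] <- -0.1
  expect_error(phenotype_table(bad_cont, tr),
               class = "mutaccum_validation_error")
  # survivors-only trait recorded for a dead plant
  bad_dead <- base; bad_dead$biomass[2] <- 0.5
  expect_error(phenotype_table(bad_dead, tr),
               class = "mutaccum_validation_error")
  bad_class <- base; bad_class$genotype_class[1] <- "mutant"
  expect_error(phenotype_table(bad_class, tr),
               class = "mutaccum_validation_error")
  bad_sub <- base; bad_sub$subline[3] <- "MA001.s1"
  expect_error(phenotype_table(bad_sub, tr),
               class = "mutaccum_validation_error")
})

test_that("random corruptions of a valid table are always caught", {
  cfg <- sim_config(design = small_design(), seasons = default_seasons()[1],
                    seed = 9)
  tab <- as.data.frame(simulate_experiment(cfg)$tables[[1]])
  set.seed(99)
  corruptions <- list(
    function(d) { i <- sample(which(!is.na(d$germination)), 1)
                  d$germination[i] <- 7; d },
    function(d) { i <- sample(which(!is.na(d$fruits)), 1)
                  d$fruits[i] <- -1; d },
    function(d) { i <- sample(which(!is.na(d$fruits)), 1)
                  d$fruits[i] <- 1.5; d },
    function(d) { i <- sample(which(!is.na(d$survival) & d$survival == 0), 1)
                  d$biomass[i] <- 0.2; d },
    function(d) { i <- sample(which(!is.na(d$biomass)), 1)
                  d$biomass[i] <- -d$biomass[i] - 0.1; d })
  for (rep in 1:10) {
    corrupt <- sample(corruptions, 1)[[1]]
    expect_error(phenotype_table(corrupt(tab), ma_traits()),
                 class = "mutaccum_validation_error")
  }
})

test_that("parse errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("experiment,block,genotype_class,line,subline,biomass",
               "s1,B1,ma,L1,L1.s1,0.5",
               "s1,B1,ma,L2,L2.s1,abc"), path)
  expect_error(read_phenotypes(path, list(trait_spec("biomass", "gaussian"))),
               "line 3", class = "mutaccum_parse_error")
})

test_that("fruit imputation recovers an exact line and clamps at zero", {
  cal <- data.frame(biomass = c(1, 2, 3), fruits = c(10, 20, 30))
  res <- impute_fruit_from_biomass(cal, c(2.5, 0))
  expect_equal(res$fit$slope, 10)
  expect_equal(res$fit$intercept, 0, tolerance = 1e-12)
  expect_equal(res$fit$r_squared, 1)
  expect_identical(res$imputed, c(25L, 0L))
  # negative prediction clamps to zero
  cal2 <- data.frame(biomass = c(1, 2, 3, 4), fruits = c(0, 9, 22, 30))
  res2 <- impute_fruit_from_biomass(cal2, 0)
  expect_identical(res2$imputed, 0L)
  expect_error(impute_fruit_from_biomass(
    data.frame(biomass = c(2, 2, 2), fruits = c(1, 2, 3)), 1),
    class = "mutaccum_degenerate_error")
  expect_error(impute_fruit_from_biomass(cal[1:2, ], 1),
               class = "mutaccum_spec_error")
})

test_that("noisy imputation matches the normal-equations oracle", {
  set.seed(21)
  x <- runif(20, 0.5, 3)
  y <- round(5 + 12 * x + rnorm(20, 0, 2))
  cal <- data.frame(biomass = x, fruits = y)
  res <- impute_fruit_from_biomass(cal, x)
  # closed-form least squares via the normal equations
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res$fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(res$fit$slope, beta[2], tolerance = 1e-10)
  expect_true(res$fit$r_squared > 0 && res$fit$r_squared <= 1)
})
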