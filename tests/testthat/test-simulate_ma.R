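test_that("the study design lays out 500 MA + 36 progenitor plants per block", {
  d <- experiment_design()
  skel <- generate_design(d, seed = 1)
  expect_equal(nrow(skel), 7504L)
  per_block <- table(skel$genotype_class, skel$block)
  expect_true(all(per_block["ma", ] == 500))
  expect_true(all(per_block["founder", ] == 36))
  # each MA line: 5 plants per block spread over 3-5 sublines, 1-3 each
  ma <- skel[skel$genotype_class == "ma" & skel$block == "B01", ]
  per_line <- table(ma$line)
  expect_true(all(per_line == 5))
  sub_counts <- table(ma$line, ma$subline)
  expect_true(all(sub_counts[sub_counts > 0] %in% 1:3))
  n_sub <- tapply(ma$subline, ma$line, function(s) length(unique(s)))
  expect_true(all(n_sub >= 3 & n_sub <= 5))
})

test_that("row counts satisfy the closed-form design formula", {
  set.seed(5)
  for (i in 1:8) {
    B <- sample(1:5, 1); L <- sample(1:20, 1); p <- sample(1:6, 1)
    S <- sample(0:4, 1); q <- if (S > 0) sample(1:6, 1) else 0
    c0 <- sample(0:3, 1)
    d <- experiment_design(n_blocks = B, n_ma_lines = L,
                           progenitor_sublines = S,
                           field_sublines_per_line = c(1, min(3, p)),
                           ma_plants_per_line_per_block = p,
                           progenitor_plants_per_subline_per_block = q,
                           col0_plants_per_block = c0)
    skel <- generate_design(d, seed = i)
    expect_equal(nrow(skel), B * (L * p + S * q + c0))
    # brute-force enumeration agrees with the closed form
    expect_equal(nrow(skel), sum(table(skel$block, skel$line)))
  }
  expect_equal(nrow(generate_design(experiment_design(
    n_blocks = 1, n_ma_lines = 1, progenitor_sublines = 0,
    field_sublines_per_line = 1, ma_plants_per_line_per_block = 1,
    progenitor_plants_per_subline_per_block = 0))), 1L)
  expect_error(generate_design(experiment_design(n_blocks = 0)),
               class = "mutaccum_empty_design_error")
})

test_that("zero variances make every trait deterministic at its mean", {
  d <- small_design()
  skel <- generate_design(d, seed = 1)
  g <- simulate_trait(skel, gaussian_field_trait(),
                      single_trait_season("mass", mu = 5, 0, 0, 0, 0),
                      seed = 3)
  expect_true(all(g == 5))
  p <- simulate_trait(skel, trait_spec("seeds", "poisson", "field_planted"),
                      single_trait_season("seeds", mu = 0, 0, 0, 0, 0),
                      seed = 3)
  expect_true(all(p >= 0))
  expect_equal(mean(p), 1, tolerance = 0.2)  # Poisson(1) sampling noise
})

test_that("binomial simulation hits its intercept probability", {
  d <- experiment_design(n_blocks = 1, n_ma_lines = 1000,
                         progenitor_sublines = 0,
                         field_sublines_per_line = 1,
                         ma_plants_per_line_per_block = 100,
                         progenitor_plants_per_subline_per_block = 0)
  skel <- generate_design(d, seed = 2)
  expect_equal(nrow(skel), 1e5)
  tr <- trait_spec("alive", "binomial", "field_planted")
  y <- simulate_trait(skel, tr,
                      single_trait_season("alive", mu = qlogis(0.8), 0, 0),
                      seed = 4)
  se <- sqrt(0.8 * 0.2 / 1e5)
  expect_lt(abs(mean(y) - 0.8), 3 * se)
})

test_that("among-line variance of simulated line effects matches the target", {
  d <- experiment_design(n_blocks = 1, n_ma_lines = 100,
                         progenitor_sublines = 0,
                         field_sublines_per_line = 1,
                         ma_plants_per_line_per_block = 50,
                         progenitor_plants_per_subline_per_block = 0)
  skel <- generate_design(d, seed = 6)
  y <- simulate_trait(skel, gaussian_field_trait(),
                      single_trait_season("mass", mu = 100, 0, 2, 0, 0),
                      seed = 8)
  line_means <- tapply(y, skel$line, mean)
  expect_equal(var(as.vector(line_means)), 2, tolerance = 0.25 * 2)
})

test_that("experiments are deterministic and share scaled line effects", {
  seasons <- list(
    single_trait_season("mass", 50, 0, 4, 0, 0, label = "sA"),
    single_trait_season("mass", 50, 0, 1, 0, 0, label = "sB"))
  cfg <- sim_config(design = small_design(), seasons = seasons,
                    traits = list(gaussian_field_trait()), seed = 13)
  sim1 <- simulate_experiment(cfg)
  sim2 <- simulate_experiment(cfg)
  expect_identical(sim1$tables, sim2$tables)
  # shared_scaled: per-line effect in season B is exactly half of season A
  eff <- function(tab) {
    ma <- tab[tab$genotype_class == "ma", ]
    tapply(ma$mass, ma$line, mean) - 50
  }
  ea <- eff(sim1$tables$sA); eb <- eff(sim1$tables$sB)
  expect_equal(unname(eb), unname(ea) / 2, tolerance = 1e-10)
  # independent mode breaks the proportionality
  cfg_ind <- sim_config(design = small_design(), seasons = seasons,
                        traits = list(gaussian_field_trait()),
                        line_effect_model = "independent", seed = 13)
  sim3 <- simulate_experiment(cfg_ind)
  expect_gt(max(abs(eff(sim3$tables$sB) - eff(sim3$tables$sA) / 2)), 1e-6)
})

test_that("founder and col0 rows carry zero line effect", {
  d <- small_design(col0 = 3)
  seasons <- list(single_trait_season("mass", 50, 0, 9, 0, 0))
  cfg <- sim_config(design = d, seasons = seasons,
                    traits = list(gaussian_field_trait()), seed = 17)
  tab <- simulate_experiment(cfg)$tables[[1]]
  expect_true(all(tab$mass[tab$genotype_class != "ma"] == 50))
  expect_true(any(tab$mass[tab$genotype_class == "ma"] != 50))
})

test_that("truth record carries v_m = v_line / (2t)", {
  seasons <- list(single_trait_season("mass", 50, 0.1, 0.45, 0, 1))
  cfg <- sim_config(design = small_design(), seasons = seasons,
                    traits = list(gaussian_field_trait()), seed = 19)
  truth <- simulate_experiment(cfg)$truth
  expect_equal(truth$t_generations, 25)
  expect_equal(truth$params$v_m_true, 0.45 / 50)
  expect_equal(truth$params$v_m_true, 0.009)
})

test_that("survivors-only traits are missing for non-survivors", {
  cfg <- sim_config(design = small_design(n_blocks = 3, n_lines = 20),
                    seasons = default_seasons()["fall_2005"], seed = 23)
  tab <- simulate_experiment(cfg)$tables[[1]]
  dead <- !is.na(tab$survival) & tab$survival == 0
  expect_gt(sum(dead), 0)
  expect_true(all(is.na(tab$biomass[dead])))
  expect_true(all(is.na(tab$fruits[dead])))
  expect_true(all(tab$fitness[dead] == 0))
  alive <- tab$survival == 1
  expect_equal(tab$fitness[alive], tab$fruits[alive])
})
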