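# Fixture builders shared across test files. All data are generated in
# code; nothing is read from disk except files the tests write themselves.

# A minimal one-season table with explicit values for I/O and validation
# tests. Means are kept positive so Gaussian traits satisfy the
# non-negativity invariant.
tiny_table <- function() {
  data.frame(
    experiment = "spring_2004",
    block = c("B1", "B1", "B2"),
    genotype_class = c("ma", "ma", "founder"),
    line = c("MA001", "MA002", "P1"),
    subline = c("MA001.s1", "MA002.s1", "P1.s1"),
    germination = c(1, 0, 1),
    survival = c(1, 0, 1),
    fruits = c(12, NA, 30),
    biomass = c(0.08, NA, 0.11),
    stringsAsFactors = FALSE)
}

tiny_traits <- function() {
  ma_traits()[c("germination", "survival", "fruits", "biomass", "fitness")]
}

# Balanced one-factor Gaussian layout: n_lines lines x n_per plants, with
# line variance v_line and residual v_resid around a positive mean.
one_way_table <- function(n_lines, n_per, v_line, v_resid, mu = 50,
                          seed = 1, trait_name = "mass") {
  set.seed(seed)
  line <- rep(sprintf("L%03d", seq_len(n_lines)), each = n_per)
  eff <- rnorm(n_lines, 0, sqrt(v_line))
  y <- mu + eff[as.integer(factor(line))] + rnorm(n_lines * n_per, 0,
                                                  sqrt(v_resid))
  df <- data.frame(experiment = "s1", block = "B1", genotype_class = "ma",
                   line = line, subline = paste0(line, ".s1"),
                   survival = 1, stringsAsFactors = FALSE)
  df[[trait_name]] <- pmax(0, y)
  phenotype_table(df, list(trait_spec(trait_name, "gaussian",
                                      "field_planted")))
}

gaussian_field_trait <- function(name = "mass") {
  trait_spec(name, "gaussian", "field_planted")
}

# Closed-form balanced one-way ANOVA variance components (REML):
# v_line = (MS_between - MS_within) / n_per, v_resid = MS_within.
anova_oracle <- function(y, line, n_per) {
  means <- tapply(y, line, mean)
  grand <- mean(y)
  k <- length(means)
  msb <- n_per * sum((means - grand)^2) / (k - 1)
  msw <- sum((y - means[line])^2) / (k * (n_per - 1))
  c(v_line = max(0, (msb - msw) / n_per), v_resid = msw)
}

# Small multi-block MA design for selection / comparison tests.
small_design <- function(n_blocks = 4, n_lines = 15, plants = 2,
                         col0 = 0) {
  experiment_design(n_blocks = n_blocks, n_ma_lines = n_lines,
                    progenitor_sublines = 3,
                    field_sublines_per_line = c(2, 3),
                    ma_plants_per_line_per_block = plants,
                    progenitor_plants_per_subline_per_block = 2,
                    col0_plants_per_block = col0,
                    t_generations = 25)
}

# One-season simulation config with a single configurable trait.
single_trait_season <- function(trait, mu, v_block, v_line, v_subline = 0,
                                v_resid = NA, col0_offset = 0,
                                label = "s1") {
  season_params(label, data.frame(
    trait = trait, mu = mu, v_block = v_block, v_line_expressed = v_line,
    v_subline = v_subline, v_resid = v_resid, col0_offset = col0_offset,
    stringsAsFactors = FALSE))
}
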