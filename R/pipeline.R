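#' Assemble a pipeline configuration
#'
#' Exactly one of `input` (named character vector/list of season ->
#' phenotype CSV path) or `sim` (a [sim_config()]) must be supplied.
#'
#' @param sim A [sim_config()] to generate data from, or `NULL`.
#' @param input Named list of season label -> CSV/TSV path, or `NULL`.
#' @param traits Named list of [trait_spec()]s (or a trait-config YAML
#'   path) declaring the traits to analyze.
#' @param analyze_traits Optional character subset of trait names to fit.
#' @param seasons Optional character subset of season labels to analyze.
#' @param t_generations Generations of divergence used for V_m.
#' @param mcmc An [mcmc_settings()].
#' @param boot_B,boot_alpha Parametric-bootstrap replicates and retention
#'   threshold.
#' @param sqrt_transform Traits square-root transformed in the mean
#'   comparisons.
#' @param seed Master seed.
#' @param outdir Output directory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input = NULL, traits = ma_traits(),
                            analyze_traits = NULL, seasons = NULL,
                            t_generations = 25, mcmc = mcmc_settings(),
                            boot_B = 1000L, boot_alpha = 0.05,
                            sqrt_transform = character(), seed = 1L,
                            outdir = "mutaccum_run") {
  if (is.null(sim) == is.null(input))
    stop_mutaccum("exactly one of 'sim' or 'input' must be given",
                  "mutaccum_config_error")
  if (t_generations < 1)
    stop_mutaccum("t_generations must be >= 1", "mutaccum_config_error")
  if (is.character(traits)) traits <- read_trait_config(traits)
  structure(list(sim = sim, input = input, traits = as_trait_list(traits),
                 analyze_traits = analyze_traits, seasons = seasons,
                 t_generations = t_generations, mcmc = mcmc,
                 boot_B = as.integer(boot_B), boot_alpha = boot_alpha,
                 sqrt_transform = sqrt_transform, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

pipe_log <- function(stage, ..., t0 = NULL) {
  elapsed <- if (is.null(t0)) ""
             else sprintf(" [%.1fs]", as.numeric(Sys.time() - t0, units = "secs"))
  message(sprintf("[mutaccum] %s %s%s", stage, paste(..., collapse = " "),
                  elapsed))
}

with_stage <- function(stage, trait, season, expr) {
  tryCatch(expr, error = function(e) stop_mutaccum(
    sprintf("stage %s (trait %s, season %s): %s", stage,
            trait %||% "-", season %||% "-", conditionMessage(e)),
    "mutaccum_stage_error"))
}

#' Simulate stage: write per-season phenotype CSVs and the truth record
#'
#' @param config A [pipeline_config()] with a `sim` component.
#' @param outdir Output directory (defaults to the config's).
#' @return Named list of written CSV paths (plus `truth.json`), invisibly.
#' @export
pipeline_simulate <- function(config, outdir = config$outdir) {
  if (is.null(config$sim))
    stop_mutaccum("config has no simulation component", "mutaccum_config_error")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  sim <- simulate_experiment(config$sim)
  paths <- list()
  for (season in names(sim$tables)) {
    p <- file.path(outdir, paste0("phenotypes_", season, ".csv"))
    write_phenotypes(sim$tables[[season]], p)
    paths[[season]] <- p
  }
  truth <- sim$truth
  truth$params <- as.list(as.data.frame(truth$params))
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  pipe_log("simulate", sprintf("%d seasons -> %s", length(paths), outdir),
           t0 = t0)
  invisible(paths)
}

load_season_tables <- function(config) {
  if (!is.null(config$sim)) {
    sim <- simulate_experiment(config$sim)
    return(sim$tables)
  }
  tabs <- lapply(config$input, read_phenotypes, traits = config$traits)
  stats::setNames(tabs, names(config$input))
}

#' Fit stage: selection, MCMC estimation, and mutation parameters
#'
#' For every analyzed trait x season: runs the parametric-bootstrap
#' selection over block and subline, bootstrap-tests the among-line term
#' itself (reported as `p_among_line`), fits the selected model by MCMC,
#' and transforms the posterior into mutation parameters.
#'
#' @param config A [pipeline_config()].
#' @param tables Optional pre-loaded named list of `phenotype_tbl` (one
#'   per season); loaded/simulated from the config when `NULL`.
#' @return A list with `params` (data frame of [summarize_mutation_params()]
#'   rows), `selection` (nested list of `boot_lrt` records), and `fits`.
#' @export
pipeline_fit <- function(config, tables = NULL) {
  unknown <- setdiff(config$analyze_traits %||% character(),
                     names(config$traits))
  if (length(unknown))
    stop_mutaccum(paste("analyzed traits lack declarations (trait_model):",
                        paste(unknown, collapse = ", ")),
                  "mutaccum_config_error")
  tables <- tables %||% load_season_tables(config)
  seasons <- config$seasons %||% names(tables)
  params <- list()
  selection <- list()
  fits <- list()
  for (season in seasons) {
    tab <- tables[[season]]
    if (is.null(tab))
      stop_mutaccum(sprintf("no data for season '%s'", season),
                    "mutaccum_config_error")
    trait_names <- config$analyze_traits %||%
      intersect(names(config$traits), names(tab))
    for (tn in trait_names) {
      if (!tn %in% names(tab) || all(is.na(tab[[tn]]))) next
      t0 <- Sys.time()
      trait <- config$traits[[tn]]
      full <- with_stage("trait_model", tn, season,
                         model_spec(trait, c("block", "line",
                                             "subline_in_line")))
      sel <- with_stage("select_effects", tn, season,
        select_model(tab, full, B = config$boot_B,
                     seed = derive_seed(config$seed, "select", season, tn),
                     alpha = config$boot_alpha))
      line_boot <- with_stage("select_effects", tn, season,
        parametric_bootstrap(tab, sel$spec, "line", B = config$boot_B,
                             seed = derive_seed(config$seed, "line", season,
                                                tn),
                             alpha = config$boot_alpha))
      settings <- config$mcmc
      settings$seed <- derive_seed(config$seed, "mcmc", season, tn)
      fit <- with_stage("fit_glmm", tn, season,
                        fit_mcmc(tab, sel$spec, settings))
      mp <- with_stage("mutation_params", tn, season,
        summarize_mutation_params(fit, t = config$t_generations,
                                  trait = tn, experiment = season,
                                  boot = line_boot))
      params[[paste(season, tn)]] <- mp
      selection[[season]][[tn]] <- c(sel$results, list(line = line_boot))
      fits[[season]][[tn]] <- fit
      pipe_log("fit", sprintf("%s/%s p_line=%.3g", season, tn,
                              line_boot$p_value), t0 = t0)
    }
  }
  list(params = do.call(rbind, params), selection = selection, fits = fits)
}

md_table <- function(df) {
  esc <- function(x) gsub("\\|", "\\\\|", as.character(x))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sepr <- paste0("|", paste(rep(" --- ", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(esc(r), collapse = " | "),
                                          " |"))
  c(header, sepr, body)
}

#' Report stage: write parameter and comparison tables
#'
#' @param results Output of [pipeline_fit()].
#' @param comparisons Output of [compare_all()], or `NULL`.
#' @param outdir Output directory.
#' @param alpha Significance threshold for the p-value grid.
#' @return The [build_report()] object, invisibly.
#' @export
pipeline_report <- function(results, comparisons = NULL, outdir,
                            alpha = 0.05) {
  if (is.null(results$params) || !nrow(results$params))
    stop_mutaccum("no fitted parameters to report", "mutaccum_config_error")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- build_report(results$params, alpha = alpha)
  utils::write.csv(results$params, file.path(outdir, "mutation_params.csv"),
                   row.names = FALSE)
  utils::write.csv(report$p_values, file.path(outdir, "report_pvalues.csv"),
                   row.names = FALSE)
  utils::write.csv(report$estimates, file.path(outdir, "report_estimates.csv"),
                   row.names = FALSE)
  md <- c("# Mutation parameter report", "",
          "## Among-line variance p-values", "", md_table(report$p_values),
          "", "## Parameter estimates (95% CI)", "",
          md_table(report$estimates))
  if (!is.null(comparisons) && nrow(comparisons)) {
    utils::write.csv(comparisons, file.path(outdir, "comparisons.csv"),
                     row.names = FALSE)
    cmp <- comparisons
    for (col in c("t_stat", "p_value", "p_bh", "mean_a", "mean_a_lo",
                  "mean_a_hi", "mean_b", "mean_b_lo", "mean_b_hi"))
      cmp[[col]] <- signif(cmp[[col]], 4)
    md <- c(md, "", "## Group mean comparisons", "", md_table(cmp))
  }
  writeLines(md, file.path(outdir, "report.md"))
  invisible(report)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) per-season phenotype tables, select random effects
#' by parametric bootstrap, fit the selected models by MCMC, compute
#' mutation parameters, compare MA/founder/Col-0 means, and write all
#' artifacts plus a reproducibility manifest to the output directory.
#' Re-running with the same configuration reproduces every number.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `params`, `selection`, `comparisons`,
#'   `report`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$sim)) pipeline_simulate(config, outdir)
  tables <- load_season_tables(config)
  results <- pipeline_fit(config, tables)
  seasons <- config$seasons %||% names(tables)
  # seasons can differ in measured traits; pad the missing columns
  all_cols <- unique(unlist(lapply(seasons, function(s)
    names(tables[[s]]))))
  combined <- do.call(rbind, lapply(seasons, function(s) {
    df <- as.data.frame(tables[[s]])
    for (cl in setdiff(all_cols, names(df))) df[[cl]] <- NA_real_
    df[all_cols]
  }))
  comparisons <- tryCatch(
    compare_all(phenotype_table(combined, config$traits),
                traits = config$analyze_traits %||% names(config$traits),
                pooled = TRUE, sqrt_transform = config$sqrt_transform),
    mutaccum_error = function(e) NULL)
  report <- pipeline_report(results, comparisons, outdir,
                            alpha = config$boot_alpha)
  sel_flat <- lapply(results$selection, function(by_trait)
    lapply(by_trait, function(tests) lapply(tests, function(b)
      list(term = b$term, lr_observed = b$lr_observed, p_value = b$p_value,
           retained = b$retained, B_effective = b$B_effective,
           lr_null = b$lr_null))))
  jsonlite::write_json(sel_flat, file.path(outdir, "selection.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg_json <- jsonlite::serializeJSON(config)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package = "mutaccum",
    version = as.character(utils::packageVersion("mutaccum")),
    r_version = R.version.string,
    seed = config$seed,
    t_generations = config$t_generations,
    boot_B = config$boot_B,
    config_md5 = unname(tools::md5sum(tmp)))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  pipe_log("done", outdir)
  invisible(list(params = results$params, selection = results$selection,
                 comparisons = comparisons, report = report,
                 manifest = manifest))
}
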