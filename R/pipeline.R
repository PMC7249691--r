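#' @title Pipeline orchestration and run manifests
#' @description Thin orchestration over the analysis stages: each runner
#'   reads its inputs, executes the stage, and writes CSV/JSON artifacts
#'   plus a run manifest (seed, configuration snapshot, input digests,
#'   package version) sufficient to re-run deterministic stages
#'   bit-identically. The package's R functions are its interface; these
#'   runners compose them for scripted use.
#' @name pipeline
NULL

#' Write a run manifest
#'
#' @param dir Output directory (created if needed).
#' @param subcommand Stage name.
#' @param config List snapshot of the configuration used.
#' @param seed Integer root seed of the run.
#' @param inputs Character vector of input file paths; MD5 digests are
#'   recorded.
#' @return Invisibly, the manifest path.
#' @export
write_run_manifest <- function(dir, subcommand, config, seed,
                               inputs = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  digests <- if (length(inputs) > 0L)
    as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    subcommand = subcommand,
    seed = seed,
    config = config,
    input_digests = digests,
    package_version = as.character(utils::packageVersion("il12rewire")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the viability-inference stage end to end
#'
#' Reads (or accepts) a viability table, fits the IL-12 rescue model by
#' MCMC, and writes per-chain trace CSVs
#' (`step, ec50, alpha, logpost`), a posterior-summary JSON and a run
#' manifest into `out_dir`.
#'
#' @param data Viability table or CSV path.
#' @param out_dir Output directory.
#' @param n_steps,n_chains,kd,seed Passed to [fit_viability_mcmc()].
#' @return The `viability_fit` object, invisibly.
#' @export
run_viability_pipeline <- function(data, out_dir, n_steps = 50000L,
                                   n_chains = 3L, kd = 40, seed = 1L) {
  input_path <- character()
  if (is.character(data)) {
    input_path <- data
    data <- read_viability_csv(data)
  }
  fit <- fit_viability_mcmc(data, n_steps = n_steps, n_chains = n_chains,
                            kd = kd, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(fit$chains$n_chains)) {
    tr <- data.frame(step = seq_len(fit$chains$n_steps),
                     fit$chains$samples[[i]],
                     logpost = fit$chains$log_post[[i]])
    names(tr)[2:3] <- c("ec50", "alpha")
    utils::write.csv(tr, file.path(out_dir, sprintf("chain_%d.csv", i)),
                     row.names = FALSE)
  }
  s <- fit$summary
  jsonlite::write_json(list(
    median = as.list(s$median), ml_value = as.list(s$ml_value),
    ci_95 = list(ec50 = unname(s$ci_95[, "ec50"]),
                 alpha = unname(s$ci_95[, "alpha"])),
    p_alpha_below_0 = unname(s$tail_prob["alpha"]),
    psrf = as.list(fit$psrf),
    acceptance = fit$chains$accept_fraction
  ), file.path(out_dir, "posterior_summary.json"),
  auto_unbox = TRUE, digits = NA)
  write_run_manifest(out_dir, "fit-viability",
                     list(n_steps = n_steps, n_chains = n_chains, kd = kd),
                     seed, input_path)
  invisible(fit)
}

#' Run mechanism selection and write a report
#'
#' @param data Phospho table or CSV path (single cell line / readout).
#' @param ctx A [receptor_context()].
#' @param out_dir Output directory.
#' @param tots_correction Passed to [select_mechanism()].
#' @return The `mechanism_selection` object, invisibly.
#' @export
run_selection_pipeline <- function(data, ctx, out_dir,
                                   tots_correction = FALSE) {
  input_path <- character()
  if (is.character(data)) {
    input_path <- data
    data <- read_phospho_csv(data)
  }
  sel <- select_mechanism(data, ctx, tots_correction)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fits <- lapply(sel$fits, function(f) {
    p <- f$params
    list(model_id = f$model_id, sse = f$sse, n_obs = f$n_obs,
         n_free = f$n_free,
         params = list(k_c = p$k_c, k_n = p$k_n, tots = p$tots,
                       k_d_phos = p$k_d_phos))
  })
  jsonlite::write_json(list(
    fits = fits,
    log_bayes_factors = apply(sel$log_bf, 1, as.list),
    grades = apply(sel$grades, 1, as.list),
    ranking = sel$ranking
  ), file.path(out_dir, "selection_report.json"),
  auto_unbox = TRUE, digits = NA)
  write_run_manifest(out_dir, "select-model",
                     list(cell_line = ctx$cell_line,
                          stoichiometry = ctx$stoichiometry,
                          tots_correction = tots_correction),
                     seed = NA, input_path)
  invisible(sel)
}

#' Run the receptor-skew stage and write a report
#'
#' @param records Expression records (from [load_expression()] or
#'   [gen_scrna()]).
#' @param out_dir Output directory.
#' @return List with the class table, ratio summary and the contingency
#'   test, invisibly.
#' @export
run_scrna_pipeline <- function(records, out_dir) {
  cls <- classify_cells(records)
  rd <- ratio_distribution(records)
  test <- chi_squared_contingency(cls)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(cls),
                   file.path(out_dir, "class_fractions.csv"),
                   row.names = FALSE)
  utils::write.csv(rd$ratios, file.path(out_dir, "ratios.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    contingency = list(statistic = test$statistic, df = test$df,
                       p_value = test$p_value, method = test$method),
    ratio_summary = rd$summary
  ), file.path(out_dir, "scrna_report.json"), auto_unbox = TRUE,
  digits = NA)
  write_run_manifest(out_dir, "scrna", list(), seed = NA)
  invisible(list(class_table = cls, ratios = rd, test = test))
}
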