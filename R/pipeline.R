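# Pipeline driver and command-line interface.
#
# A run is described by one JSON config: a root seed, an output directory,
# and a `stages` object naming any of screen / synergy / enrichment / qpcr.
# Each stage either reads the CSV/TSV dialects documented in the readers or
# simulates its input (with ground truth written alongside). All randomness
# flows from the root seed through deterministic substreams, so identical
# config + seed reproduce byte-identical numeric outputs. A machine-readable
# manifest (inputs, parameters, output paths, record counts, package
# version, seed) is written last; on failure the manifest marks the failed
# stage.

STAGE_ORDER <- c("screen", "synergy", "enrichment", "qpcr")

#' Run the full pipeline from a config
#'
#' @param config a config list or path to a JSON config file. Top-level
#'   fields: `seed` (integer), `outdir` (directory, created if needed) and
#'   `stages`, an object with any of:
#'   \describe{
#'     \item{screen}{`wells` (CSV path) or `simulate` (arguments to
#'       [simulate_screen()]); optional `enhancer_threshold`, `squared`,
#'       `background_subtract`.}
#'     \item{synergy}{`dose_response` + `combinations` (CSV paths) or
#'       `simulate` (`agent1`/`agent2` as `{Dm, m}`, `alpha`, optional
#'       `fa_levels`, `lambdas`, `doses`, `y_noise_sd`); optional `form`,
#'       `tol`.}
#'     \item{enrichment}{`expression` + `annotations` + `gmt` (paths) or
#'       `simulate` (arguments to [simulate_expression()]); optional
#'       `n_permutations`, `treated_label`, `control_label`.}
#'     \item{qpcr}{`ct` (CSV path) or `simulate` (arguments to
#'       [simulate_ct()]); optional `ref_gene`, `calibrator`.}
#'   }
#' @param outdir overrides the config's output directory.
#' @param seed overrides the config's root seed.
#' @return the run manifest, invisibly (also written to
#'   `<outdir>/manifest.json`).
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      abort(sprintf("config file not found: %s", config),
            "tilscreen_config_error")
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  if (!is.list(config) || is.null(config$stages) || !length(config$stages))
    abort("config must be a list with a non-empty `stages` object",
          "tilscreen_config_error")
  if (!is.null(outdir)) config$outdir <- outdir
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$outdir))
    abort("config needs an `outdir`", "tilscreen_config_error")
  if (is.null(config$seed)) config$seed <- 1L
  stopifnot_scalar_number(config$seed, "seed")

  stages <- config$stages[intersect(STAGE_ORDER, names(config$stages))]
  unknown <- setdiff(names(config$stages), STAGE_ORDER)
  if (length(unknown))
    abort(paste0("unknown stage(s): ", paste(unknown, collapse = ", ")),
          "tilscreen_config_error")
  validate_stage_inputs(stages)

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, length(STAGE_ORDER))
  names(seeds) <- STAGE_ORDER

  manifest <- list(package = "tilscreen",
                   version = as.character(utils::packageVersion("tilscreen")),
                   seed = as.integer(config$seed),
                   outdir = config$outdir,
                   stages = list(),
                   status = "ok")
  for (stage in names(stages)) {
    rec <- tryCatch(
      run_stage(stage, stages[[stage]], config$outdir, seeds[[stage]]),
      error = function(e) e)
    if (inherits(rec, "error")) {
      manifest$status <- "failed"
      manifest$failed_stage <- stage
      manifest$error <- conditionMessage(rec)
      write_json_file(manifest, file.path(config$outdir, "manifest.json"))
      abort(sprintf("stage `%s` failed: %s", stage, conditionMessage(rec)),
            "tilscreen_stage_error")
    }
    manifest$stages[[stage]] <- rec
  }
  write_json_file(manifest, file.path(config$outdir, "manifest.json"))
  invisible(manifest)
}

# fail fast: every referenced input file must exist before any stage runs
validate_stage_inputs <- function(stages) {
  path_keys <- c("wells", "dose_response", "combinations", "expression",
                 "annotations", "gmt", "ct", "models")
  for (stage in names(stages)) {
    cfg <- stages[[stage]]
    for (key in intersect(path_keys, names(cfg))) {
      if (!file.exists(cfg[[key]]))
        abort(sprintf("stage `%s`: input file `%s` not found: %s",
                      stage, key, cfg[[key]]),
              "tilscreen_config_error")
    }
    if (stage == "screen" && is.null(cfg$simulate) && is.null(cfg$wells))
      abort("screen stage needs `wells` or `simulate`",
            "tilscreen_config_error")
  }
  invisible(TRUE)
}

run_stage <- function(stage, cfg, outdir, stage_seed) {
  switch(stage,
         screen = stage_screen(cfg, outdir, stage_seed),
         synergy = stage_synergy(cfg, outdir, stage_seed),
         enrichment = stage_enrichment(cfg, outdir, stage_seed),
         qpcr = stage_qpcr(cfg, outdir, stage_seed))
}

cfg_get <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

as_named_numeric <- function(x) {
  if (is.null(x)) return(NULL)
  stats::setNames(as.numeric(unlist(x)), names(unlist(x)))
}

stage_screen <- function(cfg, outdir, stage_seed) {
  inputs <- list()
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$gamma_enhancers <- as_named_numeric(sim_args$gamma_enhancers)
    if (is.null(sim_args$seed)) sim_args$seed <- stage_seed
    sim <- do.call(simulate_screen, sim_args)
    wells <- sim$wells
    wells_path <- file.path(outdir, "wells.csv")
    utils::write.csv(wells, wells_path, row.names = FALSE, quote = FALSE)
    truth <- c(as.list(attr(sim$truth, "config")),
               list(n_clamped = attr(sim$truth, "n_clamped"),
                    compounds = sim$truth))
    write_json_file(truth, file.path(outdir, "screen_truth.json"))
    inputs$simulated <- TRUE
  } else {
    wells <- read_wells(cfg$wells)
    inputs$wells <- cfg$wells
  }
  params <- list(enhancer_threshold = cfg_get(cfg, "enhancer_threshold", 1),
                 squared = isTRUE(cfg$squared),
                 background_subtract = isTRUE(cfg$background_subtract))
  res <- score_screen(summarize_conditions(wells),
                      enhancer_threshold = params$enhancer_threshold,
                      squared = params$squared,
                      background_subtract = params$background_subtract)
  out_path <- file.path(outdir, "screen_results.csv")
  write_screen_results(res, out_path, params)
  list(inputs = inputs, params = params,
       outputs = list(results = out_path),
       n_wells_in = nrow(wells), n_results_out = nrow(res),
       n_enhancers = sum(res$is_enhancer, na.rm = TRUE))
}

stage_synergy <- function(cfg, outdir, stage_seed) {
  inputs <- list()
  if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    m1 <- medeff_model(s$agent1$Dm, s$agent1$m, "agent1")
    m2 <- medeff_model(s$agent2$Dm, s$agent2$m, "agent2")
    doses1 <- cfg_get(s, "doses", s$agent1$Dm * 10^seq(-1, 1, length.out = 8))
    doses2 <- cfg_get(s, "doses2", s$agent2$Dm * 10^seq(-1, 1, length.out = 8))
    sub <- derive_seeds(stage_seed, 2L)
    dr <- rbind(
      simulate_dose_response(s$agent1$Dm, s$agent1$m, doses1,
                             cfg_get(s, "y_noise_sd", 0), sub[1L], "agent1"),
      simulate_dose_response(s$agent2$Dm, s$agent2$m, doses2,
                             cfg_get(s, "y_noise_sd", 0), sub[2L], "agent2"))
    combos <- simulate_combination(
      m1, m2, s$alpha,
      fa_levels = cfg_get(s, "fa_levels", c(0.25, 0.5, 0.75)),
      lambdas = cfg_get(s, "lambdas", c(0.25, 0.5, 0.75)))
    utils::write.csv(dr, file.path(outdir, "dose_response.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(combos[, c("d1", "d2", "fa")],
                     file.path(outdir, "combinations.csv"),
                     row.names = FALSE, quote = FALSE)
    write_json_file(list(alpha = s$alpha, true_ci = 1 / s$alpha,
                         agent1 = s$agent1, agent2 = s$agent2),
                    file.path(outdir, "synergy_truth.json"))
    inputs$simulated <- TRUE
  } else {
    dr <- read_dose_response(cfg$dose_response)
    combos <- read_combinations(cfg$combinations)
    inputs[c("dose_response", "combinations")] <-
      cfg[c("dose_response", "combinations")]
  }
  models <- fit_all_agents(dr)
  if (length(models) < 2L)
    abort("synergy stage needs dose-response data for two agents",
          "tilscreen_validation_error")
  params <- list(form = cfg_get(cfg, "form", "exclusive"),
                 tol = cfg_get(cfg, "tol", 0.05))
  ci <- combination_index(models[[1L]], models[[2L]], combos,
                          form = params$form, tol = params$tol)
  iso <- isobologram(models[[1L]], models[[2L]], combos)
  write_models(models, file.path(outdir, "models.json"))
  utils::write.csv(ci, file.path(outdir, "ci.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(iso, file.path(outdir, "isobologram.csv"),
                   row.names = FALSE, quote = FALSE)
  list(inputs = inputs, params = params,
       outputs = list(models = file.path(outdir, "models.json"),
                      ci = file.path(outdir, "ci.csv"),
                      isobologram = file.path(outdir, "isobologram.csv")),
       n_dr_points = nrow(dr), n_combinations = nrow(combos))
}

stage_enrichment <- function(cfg, outdir, stage_seed) {
  inputs <- list()
  sub <- derive_seeds(stage_seed, 2L)
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- sub[1L]
    sim <- do.call(simulate_expression, sim_args)
    expr <- sim$expr
    annot <- sim$annot
    gene_sets <- list(planted = sim$truth$planted)
    write_expression(expr, file.path(outdir, "expression.tsv"))
    utils::write.csv(annot, file.path(outdir, "annotations.csv"),
                     row.names = FALSE, quote = FALSE)
    write_json_file(sim$truth, file.path(outdir, "expression_truth.json"))
    inputs$simulated <- TRUE
  } else {
    expr <- read_expression(cfg$expression)
    annot <- read_sample_annotations(
      cfg$annotations,
      treated_label = cfg_get(cfg, "treated_label", "treated"),
      control_label = cfg_get(cfg, "control_label", "control"))
    gene_sets <- read_gmt(cfg$gmt)
    inputs[c("expression", "annotations", "gmt")] <-
      cfg[c("expression", "annotations", "gmt")]
  }
  rank <- cross_line_rank(expr, annot)
  params <- list(n_permutations = cfg_get(cfg, "n_permutations", 1000L))
  res <- enrich_collection(rank, gene_sets,
                           n_permutations = params$n_permutations,
                           seed = sub[2L])
  write_rank(rank, file.path(outdir, "rank.tsv"))
  write_enrichment(res, file.path(outdir, "enrichment.json"))
  list(inputs = inputs, params = c(params, list(seed = sub[2L])),
       outputs = list(rank = file.path(outdir, "rank.tsv"),
                      enrichment = file.path(outdir, "enrichment.json")),
       n_probes = nrow(rank), n_sets = length(gene_sets))
}

stage_qpcr <- function(cfg, outdir, stage_seed) {
  inputs <- list()
  params <- list(ref_gene = cfg_get(cfg, "ref_gene", "GAPDH"),
                 calibrator = cfg_get(cfg, "calibrator", "DMSO"))
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$true_folds <- as_named_numeric(sim_args$true_folds)
    sim_args$ref_gene <- params$ref_gene
    sim_args$calibrator <- params$calibrator
    if (is.null(sim_args$seed)) sim_args$seed <- stage_seed
    sim <- do.call(simulate_ct, sim_args)
    ct <- sim$ct
    utils::write.csv(ct, file.path(outdir, "ct.csv"), row.names = FALSE,
                     quote = FALSE)
    write_json_file(as.list(sim$truth), file.path(outdir, "qpcr_truth.json"))
    inputs$simulated <- TRUE
  } else {
    ct <- read_ct(cfg$ct)
    inputs$ct <- cfg$ct
  }
  folds <- qpcr_ddct(ct, ref_gene = params$ref_gene,
                     calibrator = params$calibrator)
  out_path <- file.path(outdir, "fold_changes.csv")
  utils::write.csv(folds, out_path, row.names = FALSE, quote = FALSE)
  list(inputs = inputs, params = params,
       outputs = list(fold_changes = out_path),
       n_ct_rows = nrow(ct), n_fold_changes = nrow(folds))
}

#' Write an expression matrix as TSV (probe_id + one column per sample)
#' @param expr numeric matrix with probe rownames and sample colnames.
#' @param path output TSV path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(probe_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
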