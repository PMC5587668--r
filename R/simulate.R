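# Seeded synthetic-data generators with ground truth, one per pipeline
# stage. Every simulator is a deterministic function of (config, seed) and
# returns the generated data together with the truth needed to score
# recovery without re-deriving it.

#' Simulate a compound screen with planted enhancers
#'
#' Generative model for the percent-cleaved-caspase-3 means, for compound i
#' with own killing effect `c_i`, baseline (vehicle) apoptosis `b`,
#' TIL-alone incremental apoptosis `t` and TIL interaction `gamma_i`:
#' \preformatted{
#'   vehicle (DMSO)        : b
#'   compound alone        : b + c_i
#'   vehicle + TILs        : b + t
#'   compound + TILs       : b + c_i + gamma_i * t
#' }
#' Replicate wells add Normal(0, `noise_sd`) noise and are clamped to
#' \[0, 100\] (clamping events are counted and reported in the truth).
#' The interaction is multiplicative on the TIL increment, so the noise-free
#' comboscore of compound i equals `gamma_i` exactly (when `b = 0`, or with
#' background subtraction on). `gamma = 1` is the null (no interaction);
#' `gamma > 1` plants an enhancer.
#'
#' @param n_compounds number of compounds (besides the DMSO vehicle).
#' @param n_replicates wells per condition (default 3, i.e. triplicate).
#' @param baseline_pct vehicle-alone apoptosis `b` in percent (default 0).
#' @param til_pct TIL-alone incremental apoptosis `t` in percent
#'   (default 30; must be > 0).
#' @param compound_effect_range interval the compound-alone effects `c_i`
#'   are drawn uniformly from (default `c(2, 15)` percent).
#' @param gamma_null interaction for unplanted compounds (default 1).
#' @param gamma_enhancers named numeric vector `compound_id -> gamma` of
#'   planted enhancers (ids like `"C0001"`); an unnamed vector is assigned
#'   to the first compounds in id order.
#' @param noise_sd replicate noise, percentage points (default 1).
#' @param seed RNG seed.
#' @param tumor_line_id tumor line label (default `"TL01"`).
#' @param dose_nM compound dose recorded in the wells table (default 1000,
#'   i.e. the 1 uM single-dose screen design).
#' @return list with `wells` (a validated wells data.frame) and `truth`
#'   (data.frame `compound_id, c, gamma, true_comboscore` with the config
#'   and the clamping count as attributes).
#' @export
#' @examples
#' sim <- simulate_screen(n_compounds = 20, gamma_enhancers = c(C0003 = 2.5),
#'                        noise_sd = 0.5, seed = 42)
#' head(sim$truth)
simulate_screen <- function(n_compounds = 850, n_replicates = 3,
                            baseline_pct = 0, til_pct = 30,
                            compound_effect_range = c(2, 15),
                            gamma_null = 1, gamma_enhancers = NULL,
                            noise_sd = 1, seed = 1,
                            tumor_line_id = "TL01", dose_nM = 1000) {
  stopifnot_scalar_number(n_compounds, "n_compounds", positive = TRUE)
  stopifnot_scalar_number(til_pct, "til_pct")
  if (til_pct <= 0)
    abort("til_pct must be > 0: TILs must kill for the comboscore to exist",
          "tilscreen_config_error")
  stopifnot_scalar_number(baseline_pct, "baseline_pct")
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0)
    abort("noise_sd must be >= 0", "tilscreen_config_error")

  n_compounds <- as.integer(n_compounds)
  ids <- sprintf("C%04d", seq_len(n_compounds))
  gamma <- rep(gamma_null, n_compounds)
  names(gamma) <- ids
  if (!is.null(gamma_enhancers)) {
    if (is.null(names(gamma_enhancers)))
      names(gamma_enhancers) <- ids[seq_along(gamma_enhancers)]
    unknown <- setdiff(names(gamma_enhancers), ids)
    if (length(unknown))
      abort(paste0("gamma_enhancers names not among compound ids: ",
                   paste(unknown, collapse = ", ")),
            "tilscreen_config_error")
    gamma[names(gamma_enhancers)] <- gamma_enhancers
  }

  with_seed(seed, {
    c_i <- runif(n_compounds, compound_effect_range[1L],
                 compound_effect_range[2L])
    names(c_i) <- ids
    # condition means, DMSO first then compounds; NOTIL then TIL within each
    cmpd_col <- c(VEHICLE_ID, ids)
    mu_notil <- c(baseline_pct, baseline_pct + c_i)
    mu_til <- c(baseline_pct + til_pct, baseline_pct + c_i + gamma * til_pct)
    mu <- rep(c(mu_notil, mu_til), each = n_replicates)
    cond <- data.frame(
      compound_id = rep(rep(cmpd_col, 2L), each = n_replicates),
      til_status = rep(c("NOTIL", "TIL"), each = (n_compounds + 1L) * n_replicates),
      replicate = rep(seq_len(n_replicates), times = 2L * (n_compounds + 1L)),
      stringsAsFactors = FALSE)
    pct <- mu + if (noise_sd > 0) rnorm(length(mu), 0, noise_sd) else 0
    clamped <- sum(pct < 0 | pct > 100)
    pct <- pmin(pmax(pct, 0), 100)
    wells <- data.frame(
      plate_id = "P001",
      well_id = sprintf("W%06d", seq_along(pct)),
      tumor_line_id = tumor_line_id,
      compound_id = cond$compound_id,
      dose_nM = ifelse(cond$compound_id == VEHICLE_ID, 0, dose_nM),
      til_status = cond$til_status,
      replicate = cond$replicate,
      pct_caspase3 = pct,
      stringsAsFactors = FALSE)
    truth <- data.frame(compound_id = ids, c = unname(c_i),
                        gamma = unname(gamma),
                        true_comboscore = unname(gamma),
                        stringsAsFactors = FALSE)
    attr(truth, "config") <- list(
      n_compounds = n_compounds, n_replicates = n_replicates,
      baseline_pct = baseline_pct, til_pct = til_pct,
      compound_effect_range = compound_effect_range,
      gamma_null = gamma_null, noise_sd = noise_sd, seed = seed)
    attr(truth, "n_clamped") <- clamped
    list(wells = validate_wells(wells), truth = truth)
  })
}

#' Simulate dose-response points on the median-effect curve
#'
#' Forward model `fa = 1 / (1 + (Dm/d)^m)`. Noise is Normal(0,
#' `y_noise_sd`) added by default on the linearized scale
#' `y = log10(fa/fu)` — the scale on which [fit_median_effect()] fits, so
#' recovery tests are correctly specified. `noise_scale = "fa"` instead
#' perturbs fa directly (a deliberately misspecified option for robustness
#' testing; values are clamped into (0, 1)).
#'
#' @param Dm,m true median-effect parameters (both > 0).
#' @param doses positive dose vector.
#' @param y_noise_sd noise standard deviation (default 0 = noise-free).
#' @param seed RNG seed.
#' @param agent_id label for the output rows.
#' @param noise_scale `"linear"` (default) or `"fa"`.
#' @return data.frame `agent_id, dose, fa`.
#' @export
simulate_dose_response <- function(Dm, m, doses, y_noise_sd = 0, seed = 1,
                                   agent_id = "agent",
                                   noise_scale = c("linear", "fa")) {
  noise_scale <- match.arg(noise_scale)
  stopifnot_scalar_number(Dm, "Dm", positive = TRUE)
  stopifnot_scalar_number(m, "m", positive = TRUE)
  if (!all(is.finite(doses)) || any(doses <= 0))
    abort("doses must be > 0", "tilscreen_validation_error")
  with_seed(seed, {
    y <- m * (log10(doses) - log10(Dm))
    if (noise_scale == "linear") {
      if (y_noise_sd > 0) y <- y + rnorm(length(doses), 0, y_noise_sd)
      fa <- 10^y / (1 + 10^y)
    } else {
      fa <- 10^y / (1 + 10^y)
      if (y_noise_sd > 0) fa <- fa + rnorm(length(doses), 0, y_noise_sd)
      fa <- pmin(pmax(fa, 1e-6), 1 - 1e-6)
    }
    data.frame(agent_id = agent_id, dose = doses, fa = fa,
               stringsAsFactors = FALSE)
  })
}

#' Simulate combination measurements with a known Loewe interaction
#'
#' Constructs dose pairs on the Loewe additivity line scaled by an
#' interaction factor `alpha`: at effect level fa and mixing fraction
#' lambda,
#' `d1 = lambda * Dx1(fa) / alpha`, `d2 = (1 - lambda) * Dx2(fa) / alpha`,
#' so the true (exclusive-form) combination index is `1/alpha` at every
#' (fa, lambda): `alpha > 1` plants synergy, `alpha = 1` additivity,
#' `alpha < 1` antagonism. The construction is deterministic.
#'
#' @param model1,model2 `medeff_model` objects for the two agents.
#' @param alpha positive interaction factor.
#' @param fa_levels effect levels in (0, 1) (default `c(0.25, 0.5, 0.75)`).
#' @param lambdas mixing fractions in (0, 1) (default `c(0.25, 0.5, 0.75)`).
#' @return data.frame `d1, d2, fa, lambda` with `true_ci` (= 1/alpha)
#'   attached as an attribute.
#' @export
simulate_combination <- function(model1, model2, alpha,
                                 fa_levels = c(0.25, 0.5, 0.75),
                                 lambdas = c(0.25, 0.5, 0.75)) {
  stopifnot_scalar_number(alpha, "alpha", positive = TRUE)
  grid <- expand.grid(fa = fa_levels, lambda = lambdas,
                      KEEP.OUT.ATTRS = FALSE)
  Dx1 <- dose_for_effect(model1, grid$fa)
  Dx2 <- dose_for_effect(model2, grid$fa)
  out <- data.frame(d1 = grid$lambda * Dx1 / alpha,
                    d2 = (1 - grid$lambda) * Dx2 / alpha,
                    fa = grid$fa, lambda = grid$lambda)
  attr(out, "true_ci") <- 1 / alpha
  attr(out, "alpha") <- alpha
  out
}

#' Simulate a log2 expression matrix with a planted up-regulated gene set
#'
#' Emulates the array design the ranking stage expects: `n_lines` cell
#' lines, each with `duplicates` treated and `duplicates` control samples.
#' Model per (probe, sample):
#' `log2 value = probe baseline + delta * 1{planted probe, treated sample}
#' + Normal(0, noise_sd)`, with probe baselines drawn once from
#' Uniform(6, 12) (typical normalized array intensities). The expected rank
#' score of a planted probe is therefore `delta`.
#'
#' @param n_probes number of probes.
#' @param n_lines number of cell lines (default 4).
#' @param duplicates samples per (line, treatment) arm (default 2).
#' @param planted_set_size number of planted up-regulated probes
#'   (must be < `n_probes`).
#' @param delta planted log2 shift in treated samples.
#' @param noise_sd per-observation noise sd (log2 units).
#' @param seed RNG seed.
#' @return list with `expr` (matrix), `annot` (sample annotations) and
#'   `truth` (list: `planted` probe ids, `delta`, `noise_sd`, `seed`).
#' @export
simulate_expression <- function(n_probes, n_lines = 4, duplicates = 2,
                                planted_set_size, delta, noise_sd, seed = 1) {
  stopifnot_scalar_number(n_probes, "n_probes", positive = TRUE)
  stopifnot_scalar_number(planted_set_size, "planted_set_size",
                          positive = TRUE)
  if (planted_set_size >= n_probes)
    abort("planted_set_size must be < n_probes", "tilscreen_config_error")
  n_probes <- as.integer(n_probes)
  probes <- sprintf("P%05d", seq_len(n_probes))
  with_seed(seed, {
    planted <- sort(sample(probes, planted_set_size))
    annot <- expand.grid(
      replicate = seq_len(duplicates),
      treatment = c("control", "treated"),
      cell_line_id = sprintf("L%d", seq_len(n_lines)),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    annot$sample_id <- sprintf("%s_%s_%d", annot$cell_line_id,
                               annot$treatment, annot$replicate)
    annot <- annot[, c("sample_id", "cell_line_id", "treatment", "replicate")]
    baseline <- runif(n_probes, 6, 12)
    mu <- matrix(baseline, nrow = n_probes, ncol = nrow(annot))
    is_planted <- probes %in% planted
    treated_cols <- annot$treatment == "treated"
    mu[is_planted, treated_cols] <- mu[is_planted, treated_cols] + delta
    vals <- mu + if (noise_sd > 0)
      matrix(rnorm(length(mu), 0, noise_sd), nrow = n_probes) else 0
    dimnames(vals) <- list(probes, annot$sample_id)
    list(expr = vals, annot = annot,
         truth = list(planted = planted, delta = delta, noise_sd = noise_sd,
                      seed = seed))
  })
}

#' Simulate a qPCR CT table with known fold changes
#'
#' One calibrator sample and one treated sample. CT values derive from
#' expression on the log2 scale: the treated sample's target-gene CT is
#' lowered by `log2(fold)` relative to the calibrator (one PCR cycle per
#' doubling), while the reference gene is constant across samples.
#' Triplicate CTs add Normal(0, `ct_noise_sd`) noise. Noise-free,
#' [qpcr_ddct()] recovers `true_folds` exactly.
#'
#' @param true_folds named positive numeric vector `gene -> fold change`
#'   of the treated sample relative to the calibrator.
#' @param ref_gene reference gene id (default `"GAPDH"`).
#' @param calibrator calibrator sample id (default `"DMSO"`).
#' @param treated_sample treated sample id (default `"treated"`).
#' @param n_replicates CT replicates per (sample, gene) (default 3).
#' @param ct_noise_sd CT noise sd in cycles (default 0).
#' @param seed RNG seed.
#' @param ct_base_target,ct_base_ref calibrator-sample mean CTs (defaults
#'   25 and 20 cycles).
#' @return list with `ct` (data.frame `sample_id, gene, replicate, ct`) and
#'   `truth` (the `true_folds` vector).
#' @export
simulate_ct <- function(true_folds, ref_gene = "GAPDH", calibrator = "DMSO",
                        treated_sample = "treated", n_replicates = 3,
                        ct_noise_sd = 0, seed = 1,
                        ct_base_target = 25, ct_base_ref = 20) {
  if (is.null(names(true_folds)) || !all(is.finite(true_folds)) ||
      any(true_folds <= 0))
    abort("true_folds must be a named vector of positive fold changes",
          "tilscreen_validation_error")
  if (ref_gene %in% names(true_folds))
    abort("the reference gene cannot carry a fold change",
          "tilscreen_config_error")
  genes <- names(true_folds)
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        gene = c(genes, ref_gene),
                        sample_id = c(calibrator, treated_sample),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    base_ct <- ifelse(grid$gene == ref_gene, ct_base_ref, ct_base_target)
    shift <- ifelse(grid$sample_id == treated_sample & grid$gene != ref_gene,
                    -log2(true_folds[match(grid$gene, genes)]), 0)
    shift[is.na(shift)] <- 0
    ct <- base_ct + shift + if (ct_noise_sd > 0)
      rnorm(nrow(grid), 0, ct_noise_sd) else 0
    out <- data.frame(sample_id = grid$sample_id, gene = grid$gene,
                      replicate = grid$replicate, ct = ct,
                      stringsAsFactors = FALSE)
    list(ct = out, truth = true_folds)
  })
}
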