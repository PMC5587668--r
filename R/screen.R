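# Screen scoring: well-level cleaved-caspase-3 readouts -> per-compound
# comboscores, ranks and enhancer calls.
#
# The screen measures apoptosis (percent cleaved caspase 3) of tumor cells
# under four conditions: vehicle (DMSO), compound alone, vehicle + TILs, and
# compound + TILs. The comboscore of a compound is the TIL-attributable
# incremental apoptosis under compound treatment divided by the apoptosis
# induced by TILs alone:
#
#   comboscore = (caspase_combo - caspase_compound) / caspase_til
#
# Compounds with comboscore > 1 sensitize tumor cells to T-cell killing.

TIL_LEVELS <- c("TIL", "NOTIL")
VEHICLE_ID <- "DMSO"

WELLS_COLUMNS <- c("plate_id", "well_id", "tumor_line_id", "compound_id",
                   "dose_nM", "til_status", "replicate", "pct_caspase3")

#' Validate a well-level screen table
#'
#' Checks the invariants of the well measurement table: percent readouts in
#' \[0, 100\], non-negative doses, dose 0 exactly for the DMSO vehicle, and
#' til_status in `TIL`/`NOTIL`. Errors name the offending wells.
#'
#' @param wells data.frame with columns
#'   `plate_id, well_id, tumor_line_id, compound_id, dose_nM, til_status,
#'   replicate, pct_caspase3`.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_wells <- function(wells) {
  if (!is.data.frame(wells))
    abort("`wells` must be a data.frame", "tilscreen_validation_error")
  missing_cols <- setdiff(WELLS_COLUMNS, names(wells))
  if (length(missing_cols))
    abort(paste0("wells table is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          "tilscreen_validation_error")
  if (nrow(wells) == 0L)
    abort("wells table is empty", "tilscreen_empty_input_error")
  bad_pct <- which(!is.finite(wells$pct_caspase3) |
                     wells$pct_caspase3 < 0 | wells$pct_caspase3 > 100)
  if (length(bad_pct))
    abort(sprintf(
      "pct_caspase3 outside [0, 100] in well(s): %s",
      paste(utils::head(wells$well_id[bad_pct], 5L), collapse = ", ")),
      "tilscreen_validation_error")
  bad_til <- which(!wells$til_status %in% TIL_LEVELS)
  if (length(bad_til))
    abort(sprintf("til_status must be one of %s (well %s)",
                  paste(TIL_LEVELS, collapse = "/"),
                  wells$well_id[bad_til[1L]]),
          "tilscreen_validation_error")
  bad_dose <- which(!is.finite(wells$dose_nM) | wells$dose_nM < 0 |
                      (wells$dose_nM == 0) != (wells$compound_id == VEHICLE_ID))
  if (length(bad_dose))
    abort(sprintf(
      "dose_nM must be >= 0 and 0 exactly for %s (well %s)",
      VEHICLE_ID, wells$well_id[bad_dose[1L]]),
      "tilscreen_validation_error")
  wells
}

#' Summarize replicate wells into condition means
#'
#' Aggregates well-level readouts to one row per
#' (tumor line, compound, TIL status) condition: replicate count, mean and
#' sample standard deviation (0 for a single replicate). Output is sorted by
#' tumor line, compound, then TIL status, so downstream results are
#' deterministic.
#'
#' @inheritParams validate_wells
#' @return data.frame with columns `tumor_line_id, compound_id, til_status,
#'   n_replicates, mean_pct, sd_pct`.
#' @export
#' @examples
#' wells <- simulate_screen(n_compounds = 4, seed = 1)$wells
#' head(summarize_conditions(wells))
summarize_conditions <- function(wells) {
  wells <- validate_wells(wells)
  dt <- data.table::as.data.table(wells)
  out <- dt[, .(n_replicates = .N,
                mean_pct = mean(pct_caspase3),
                sd_pct = if (.N > 1L) stats::sd(pct_caspase3) else 0),
            by = .(tumor_line_id, compound_id, til_status)]
  data.table::setorder(out, tumor_line_id, compound_id, til_status)
  data.table::setDF(out)
  out
}

#' Comboscore of a compound
#'
#' The screen statistic: TIL-attributable incremental apoptosis under
#' compound treatment, relative to apoptosis induced by TILs alone,
#' `(caspase_combo - caspase_compound) / caspase_til`. Values > 1 flag
#' compounds that enhance T-cell-mediated killing; negative values indicate
#' protection. With `squared = TRUE` the square of the ratio is returned (an
#' alternative reading of the statistic; see the methods vignette for why the
#' unsquared ratio is the default).
#'
#' @param caspase_combo percent apoptosis, compound + TILs.
#' @param caspase_compound percent apoptosis, compound alone.
#' @param caspase_til percent apoptosis, vehicle + TILs (must be > 0).
#' @param squared square the ratio (default `FALSE`).
#' @return numeric vector of comboscores.
#' @export
#' @examples
#' comboscore(60, 20, 40)  # 1: boundary of the enhancer call
#' comboscore(50, 10, 20)  # 2: enhancer
comboscore <- function(caspase_combo, caspase_compound, caspase_til,
                       squared = FALSE) {
  vals <- c(caspase_combo, caspase_compound, caspase_til)
  if (!all(is.finite(vals)) || any(vals < 0) || any(vals > 100))
    abort("caspase percentages must be finite and in [0, 100]",
          "tilscreen_validation_error")
  if (any(caspase_til == 0))
    abort("caspase_til is 0: comboscore undefined (unscorable compound)",
          "tilscreen_unscorable_error")
  .combo_ratio(caspase_combo, caspase_compound, caspase_til, squared)
}

# core ratio without range checks (used after background subtraction, where
# terms may legitimately fall outside [0, 100])
.combo_ratio <- function(combo, compound, til, squared = FALSE) {
  s <- (combo - compound) / til
  if (squared) s * s else s
}

#' Score a screen: comboscores, ranks and enhancer calls
#'
#' Computes, for every (tumor line, compound) pair, the comboscore from
#' condition means, ranks compounds within each tumor line (rank 1 = highest
#' comboscore, ties broken lexicographically by compound id) and calls
#' enhancers at `comboscore > enhancer_threshold`. Compounds missing a
#' required condition, or scored against a zero TIL-alone mean, are kept in
#' the output with a reason code in `flag` and `NA` score/rank rather than
#' silently dropped. A missing vehicle+TILs condition for a tumor line is a
#' hard error, since no compound on that line can be scored.
#'
#' @param summaries condition summaries from [summarize_conditions()] (a raw
#'   wells table is also accepted and summarized first).
#' @param enhancer_threshold comboscore cut-off for the enhancer call
#'   (default 1).
#' @param squared use the squared ratio (see [comboscore()]).
#' @param background_subtract subtract the DMSO-alone (vehicle, no TILs) mean
#'   from all three terms before scoring (default `FALSE`; the plain formula
#'   has no baseline term).
#' @return data.frame with one row per (tumor line, compound):
#'   `tumor_line_id, compound_id, caspase_compound, caspase_til,
#'   caspase_combo, caspase_vehicle, comboscore, rank, is_enhancer, flag`,
#'   sorted by tumor line then rank.
#' @export
#' @examples
#' sim <- simulate_screen(n_compounds = 10, noise_sd = 0,
#'                        gamma_enhancers = c(C0001 = 3), seed = 1)
#' res <- score_screen(summarize_conditions(sim$wells))
#' head(res)
score_screen <- function(summaries, enhancer_threshold = 1, squared = FALSE,
                         background_subtract = FALSE) {
  if (is.data.frame(summaries) && "pct_caspase3" %in% names(summaries))
    summaries <- summarize_conditions(summaries)
  need <- c("tumor_line_id", "compound_id", "til_status", "mean_pct")
  if (!is.data.frame(summaries) || !all(need %in% names(summaries)))
    abort("`summaries` must come from summarize_conditions()",
          "tilscreen_validation_error")
  stopifnot_scalar_number(enhancer_threshold, "enhancer_threshold")

  res_by_line <- lapply(split(summaries, summaries$tumor_line_id),
                        score_one_line,
                        enhancer_threshold = enhancer_threshold,
                        squared = squared,
                        background_subtract = background_subtract)
  out <- do.call(rbind, res_by_line)
  rownames(out) <- NULL
  out
}

score_one_line <- function(s, enhancer_threshold, squared,
                           background_subtract) {
  line <- s$tumor_line_id[1L]
  cond_mean <- function(cmpd, til) {
    i <- which(s$compound_id == cmpd & s$til_status == til)
    if (length(i)) s$mean_pct[i[1L]] else NA_real_
  }
  til_mean <- cond_mean(VEHICLE_ID, "TIL")
  if (is.na(til_mean))
    abort(sprintf("tumor line %s has no vehicle+TILs (%s/TIL) condition",
                  line, VEHICLE_ID),
          "tilscreen_missing_condition_error")
  veh_mean <- cond_mean(VEHICLE_ID, "NOTIL")
  if (background_subtract && is.na(veh_mean))
    abort(sprintf(
      "background_subtract requires a %s/NOTIL condition (tumor line %s)",
      VEHICLE_ID, line), "tilscreen_missing_condition_error")

  compounds <- sort(setdiff(unique(s$compound_id), VEHICLE_ID))
  cmp_alone <- vapply(compounds, cond_mean, numeric(1L), til = "NOTIL")
  cmp_combo <- vapply(compounds, cond_mean, numeric(1L), til = "TIL")

  flag <- rep("ok", length(compounds))
  flag[is.na(cmp_alone)] <- "missing_compound_alone"
  flag[is.na(cmp_combo)] <- "missing_combo"
  flag[is.na(cmp_alone) & is.na(cmp_combo)] <- "missing_both_conditions"

  b <- if (background_subtract) veh_mean else 0
  til_eff <- til_mean - b
  score <- rep(NA_real_, length(compounds))
  if (til_eff == 0) {
    flag[flag == "ok"] <- "unscorable_til_zero"
  } else {
    ok <- flag == "ok"
    score[ok] <- .combo_ratio(cmp_combo[ok] - b, cmp_alone[ok] - b, til_eff,
                              squared)
  }

  rnk <- rep(NA_integer_, length(compounds))
  scored <- which(!is.na(score))
  if (length(scored)) {
    ord <- scored[order(-score[scored], compounds[scored])]
    rnk[ord] <- seq_along(ord)
  }
  out <- data.frame(
    tumor_line_id = line,
    compound_id = compounds,
    caspase_compound = unname(cmp_alone),
    caspase_til = til_mean,
    caspase_combo = unname(cmp_combo),
    caspase_vehicle = veh_mean,
    comboscore = score,
    rank = rnk,
    is_enhancer = !is.na(score) & score > enhancer_threshold,
    flag = flag,
    stringsAsFactors = FALSE)
  out[order(is.na(out$rank), out$rank, out$compound_id), , drop = FALSE]
}
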