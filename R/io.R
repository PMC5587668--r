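# Readers and writers for the plain-text dialects used by the pipeline:
# wells CSV, dose-response CSV, combination CSV, expression TSV +
# sample-annotation CSV, GMT gene sets, CT CSV, and the results CSV/JSON
# outputs.

check_file <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    abort(sprintf("input file not found: %s", paste(path, collapse = ", ")),
          "tilscreen_validation_error")
  invisible(path)
}

#' Read a well-level screen CSV
#'
#' Expected header:
#' `plate_id,well_id,tumor_line_id,compound_id,dose_nM,til_status,replicate,pct_caspase3`
#' with til_status literals `TIL`/`NOTIL`. The table is validated on read.
#'
#' @param path CSV file path.
#' @return validated wells data.frame.
#' @export
read_wells <- function(path) {
  check_file(path)
  validate_wells(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write screen results and a JSON run summary
#'
#' @param results data.frame from [score_screen()].
#' @param path output CSV path; the JSON summary is written next to it as
#'   `<path>.summary.json`.
#' @param params list of scoring parameters to record (threshold, flags).
#' @return invisibly, the CSV path.
#' @export
write_screen_results <- function(results, path, params = list()) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  summary <- c(params, list(
    n_results = nrow(results),
    n_scored = sum(!is.na(results$comboscore)),
    n_enhancers = sum(results$is_enhancer, na.rm = TRUE),
    flags = as.list(table(results$flag))))
  write_json_file(summary, paste0(path, ".summary.json"))
  invisible(path)
}

#' Read a dose-response CSV (`agent_id,dose,fa`)
#'
#' Rows with fa outside the open interval (0, 1) or non-positive dose are
#' rejected; use [clamp_fa()] beforehand if saturated observations must be
#' kept.
#'
#' @param path CSV file path.
#' @return data.frame `agent_id, dose, fa`.
#' @export
read_dose_response <- function(path) {
  check_file(path)
  dr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("agent_id", "dose", "fa")
  if (!all(need %in% names(dr)))
    abort("dose-response CSV needs columns agent_id,dose,fa",
          "tilscreen_validation_error")
  if (nrow(dr) == 0L)
    abort("dose-response table is empty", "tilscreen_empty_input_error")
  median_effect_transform(dr$dose, dr$fa)  # validation only
  dr
}

#' Read a combination CSV (`d1,d2,fa`)
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_combinations <- function(path) {
  check_file(path)
  validate_combos(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Fit median-effect models for every agent in a dose-response table
#' @param dr data.frame `agent_id, dose, fa` (see [read_dose_response()]).
#' @return named list of `medeff_model`, one per agent.
#' @export
fit_all_agents <- function(dr) {
  agents <- sort(unique(dr$agent_id))
  models <- lapply(agents, function(a) {
    rows <- dr[dr$agent_id == a, , drop = FALSE]
    fit_median_effect(rows$dose, rows$fa, agent_id = a)
  })
  names(models) <- agents
  models
}

#' Write / read fitted median-effect models as JSON
#' @param models named list of `medeff_model`.
#' @param path JSON file path.
#' @return invisibly (write) or the model list (read).
#' @export
write_models <- function(models, path) {
  write_json_file(lapply(models, function(m)
    m[c("agent_id", "Dm", "m", "r", "n_points", "dose_range")]), path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  check_file(path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(m) {
    m$dose_range <- as.numeric(m$dose_range)
    structure(m, class = "medeff_model")
  })
}

#' Read a normalized log2 expression TSV
#'
#' First column `probe_id`, remaining columns one per sample. Probes with
#' any missing value are dropped; the count is attached as attribute
#' `n_dropped_missing` and reported by message.
#'
#' @param path TSV file path.
#' @return numeric matrix, probes x samples.
#' @export
read_expression <- function(path) {
  check_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "probe_id")
    abort("expression TSV must have probe_id as its first column",
          "tilscreen_validation_error")
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$probe_id
  keep <- stats::complete.cases(m)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("read_expression: dropped %d probe(s) with missing values",
                    n_dropped))
  m <- m[keep, , drop = FALSE]
  attr(m, "n_dropped_missing") <- n_dropped
  m
}

#' Read a sample-annotation CSV (`sample_id,cell_line_id,treatment,replicate`)
#'
#' Treatment labels other than `treated`/`control` can be mapped with
#' `treated_label`/`control_label` (e.g. a drug name vs `DMSO`).
#'
#' @param path CSV file path.
#' @param treated_label,control_label labels in the file to map onto
#'   `treated`/`control` (default: already canonical).
#' @return data.frame with canonical `treatment` values.
#' @export
read_sample_annotations <- function(path, treated_label = "treated",
                                    control_label = "control") {
  check_file(path)
  annot <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_line_id", "treatment")
  if (!all(need %in% names(annot)))
    abort("annotation CSV needs columns sample_id,cell_line_id,treatment",
          "tilscreen_validation_error")
  annot$treatment <- ifelse(annot$treatment == treated_label, "treated",
                            ifelse(annot$treatment == control_label,
                                   "control", annot$treatment))
  bad <- setdiff(unique(annot$treatment), c("treated", "control"))
  if (length(bad))
    abort(paste0("unrecognized treatment label(s): ",
                 paste(bad, collapse = ", ")),
          "tilscreen_validation_error")
  annot
}

#' Read gene sets in GMT format
#'
#' One set per line: `name <tab> description <tab> member1 <tab> member2 ...`.
#'
#' @param path GMT file path.
#' @return named list of character member vectors; descriptions kept as
#'   attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  check_file(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    abort("GMT file is empty", "tilscreen_empty_input_error")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1L)) < 3L)
  if (length(bad))
    abort(sprintf("GMT line %d has fewer than 3 fields", bad[1L]),
          "tilscreen_validation_error")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1L), 2L), names(sets))
  sets
}

#' Write a gene rank as TSV (`probe_id, score, rank`)
#' @param rank a `gene_rank`.
#' @param path output TSV path.
#' @export
write_rank <- function(rank, path) {
  utils::write.table(as.data.frame(rank)[, c("probe_id", "score", "rank")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene rank TSV written by [write_rank()]
#' @param path TSV path.
#' @return a `gene_rank` data.frame.
#' @export
read_rank <- function(path) {
  check_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "score") %in% names(df)))
    abort("rank TSV needs columns probe_id,score", "tilscreen_validation_error")
  df <- df[order(-df$score, df$probe_id, method = "radix"), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  class(df) <- c("gene_rank", "data.frame")
  df
}

#' Write enrichment results as JSON
#' @param results list of `enrichment_result` (e.g. [enrich_collection()]).
#' @param path JSON path.
#' @export
write_enrichment <- function(results, path) {
  write_json_file(lapply(results, unclass), path)
  invisible(path)
}

#' Read a CT table CSV (`sample_id,gene,replicate,ct`)
#' @param path CSV path.
#' @return data.frame.
#' @export
read_ct <- function(path) {
  check_file(path)
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "replicate", "ct")
  if (!all(need %in% names(ct)))
    abort("CT CSV needs columns sample_id,gene,replicate,ct",
          "tilscreen_validation_error")
  ct
}
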