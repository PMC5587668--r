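# 2^-ddCT relative qPCR quantification.
#
# Replicate CT values are averaged first. For each condition,
#   dCT = mean(CT_target) - mean(CT_reference)
# normalizes the target to the reference gene (e.g. GAPDH); the second
# normalization to a calibrator sample gives
#   ddCT = dCT_sample - dCT_calibrator,  fold = 2^(-ddCT).

#' Fold change by the 2^-ddCT method
#'
#' @param ct_target_sample CT replicate values of the target gene in the
#'   sample of interest.
#' @param ct_ref_sample CT replicates of the reference gene in the sample.
#' @param ct_target_calibrator CT replicates of the target gene in the
#'   calibrator condition.
#' @param ct_ref_calibrator CT replicates of the reference gene in the
#'   calibrator condition.
#' @return single positive fold change.
#' @export
#' @examples
#' ddct_fold_change(c(25, 25, 25), c(20, 20, 20),
#'                  c(22, 22, 22), c(20, 20, 20))  # 0.125
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_calibrator, ct_ref_calibrator) {
  all_ct <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
              ct_ref_calibrator)
  if (!length(ct_target_sample) || !length(ct_ref_sample) ||
      !length(ct_target_calibrator) || !length(ct_ref_calibrator) ||
      !all(is.finite(all_ct)))
    abort("all CT values must be present and finite",
          "tilscreen_validation_error")
  dct_sample <- mean(ct_target_sample) - mean(ct_ref_sample)
  dct_calib <- mean(ct_target_calibrator) - mean(ct_ref_calibrator)
  2^(-(dct_sample - dct_calib))
}

#' 2^-ddCT fold changes from a CT table
#'
#' Applies [ddct_fold_change()] to every (sample, gene) pair of a long CT
#' table, normalizing to `ref_gene` within sample and to the `calibrator`
#' sample across conditions. The calibrator's own fold changes are 1 by
#' construction and are included for QC.
#'
#' @param ct data.frame with columns `sample_id, gene, replicate, ct`.
#' @param ref_gene reference (housekeeping) gene id, e.g. `"GAPDH"`.
#' @param calibrator sample id of the calibrator condition, e.g. `"DMSO"`.
#' @return data.frame `sample_id, gene, fold_change`.
#' @export
qpcr_ddct <- function(ct, ref_gene = "GAPDH", calibrator = "DMSO") {
  need <- c("sample_id", "gene", "replicate", "ct")
  if (!is.data.frame(ct) || !all(need %in% names(ct)))
    abort("`ct` must have columns sample_id, gene, replicate, ct",
          "tilscreen_validation_error")
  if (nrow(ct) == 0L)
    abort("CT table is empty", "tilscreen_empty_input_error")
  if (!all(is.finite(ct$ct)))
    abort("non-finite CT value in table", "tilscreen_validation_error")
  if (!ref_gene %in% ct$gene)
    abort(sprintf("reference gene %s not present in CT table", ref_gene),
          "tilscreen_validation_error")
  if (!calibrator %in% ct$sample_id)
    abort(sprintf("calibrator sample %s not present in CT table", calibrator),
          "tilscreen_validation_error")
  dt <- data.table::as.data.table(ct)
  means <- dt[, .(mean_ct = mean(ct)), by = .(sample_id, gene)]
  ref <- means[gene == ref_gene]
  if (!all(unique(means$sample_id) %in% ref$sample_id))
    abort(sprintf("every sample needs %s CT values", ref_gene),
          "tilscreen_validation_error")
  targets <- means[gene != ref_gene]
  targets <- merge(targets, ref[, .(sample_id, ref_ct = mean_ct)],
                   by = "sample_id")
  targets[, dct := mean_ct - ref_ct]
  calib <- targets[sample_id == calibrator, .(gene, dct_calib = dct)]
  missing_genes <- setdiff(unique(targets$gene), calib$gene)
  if (length(missing_genes))
    abort(paste0("calibrator lacks CT values for gene(s): ",
                 paste(missing_genes, collapse = ", ")),
          "tilscreen_validation_error")
  targets <- merge(targets, calib, by = "gene")
  targets[, fold_change := 2^(-(dct - dct_calib))]
  out <- as.data.frame(targets[, .(sample_id, gene, fold_change)])
  out[order(out$sample_id, out$gene), , drop = FALSE]
}
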