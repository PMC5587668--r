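# Cross-cell-line differential-expression ranking and KS-type gene-set
# enrichment with a permutation null.
#
# Ranking: for each cell line, average the treated replicates' log2 values
# and subtract the average of the control replicates per probe; the mean of
# these per-line differences across lines scores each probe, and probes are
# ranked by descending score (ties broken lexicographically by probe id).
#
# Enrichment: the classic unweighted Kolmogorov-Smirnov-type running sum.
# Walking the rank from top to bottom, add 1/k at each of the k in-set
# probes and subtract 1/(N - k) at each of the N - k others; the enrichment
# score (ES) is the running-sum value of maximal absolute magnitude, signed.
# Significance comes from a gene-label permutation null: ES of random
# same-size sets, with the add-one p-value (1 + #{|ES_null| >= |ES_obs|}) /
# (n_permutations + 1).

#' Per-line treated-minus-control log2 difference
#'
#' For one cell line, averages the treated samples' log2 values per probe,
#' averages the control samples' values, and returns the difference.
#'
#' @param expr numeric matrix of log2 expression, probes in rows (rownames =
#'   probe ids), samples in columns (colnames = sample ids).
#' @param annot data.frame with columns `sample_id, cell_line_id, treatment`
#'   (`treatment` in `"treated"`/`"control"`) and optionally `replicate`.
#' @param cell_line cell line id to difference.
#' @return named numeric vector, one delta-log2 per probe.
#' @export
delta_log2 <- function(expr, annot, cell_line) {
  check_expression(expr, annot)
  for (trt in c("treated", "control")) {
    if (!any(annot$cell_line_id == cell_line & annot$treatment == trt))
      abort(sprintf("cell line %s has no %s samples", cell_line, trt),
            "tilscreen_missing_group_error")
  }
  pick <- function(trt)
    annot$sample_id[annot$cell_line_id == cell_line & annot$treatment == trt]
  rowMeans(expr[, pick("treated"), drop = FALSE]) -
    rowMeans(expr[, pick("control"), drop = FALSE])
}

check_expression <- function(expr, annot) {
  if (!is.matrix(expr) || !is.numeric(expr) || is.null(rownames(expr)) ||
      is.null(colnames(expr)))
    abort("`expr` must be a numeric matrix with probe rownames and sample colnames",
          "tilscreen_validation_error")
  if (anyNA(expr))
    abort("`expr` contains missing values; use read_expression(), which drops and counts such probes",
          "tilscreen_validation_error")
  need <- c("sample_id", "cell_line_id", "treatment")
  if (!is.data.frame(annot) || !all(need %in% names(annot)))
    abort("`annot` must have columns sample_id, cell_line_id, treatment",
          "tilscreen_validation_error")
  missing_samples <- setdiff(annot$sample_id, colnames(expr))
  if (length(missing_samples))
    abort(paste0("annotated samples absent from matrix: ",
                 paste(missing_samples, collapse = ", ")),
          "tilscreen_validation_error")
  invisible(TRUE)
}

#' Cross-cell-line gene rank
#'
#' Scores each probe by the mean, across cell lines, of its per-line
#' treated-minus-control log2 difference, and returns the probes sorted by
#' descending score. Ties are broken lexicographically by probe id so the
#' rank is deterministic.
#'
#' @inheritParams delta_log2
#' @param cell_lines cell lines to average over (default: all annotated).
#' @return data.frame of class `gene_rank` with columns
#'   `probe_id, score, rank`, sorted by descending score.
#' @export
#' @examples
#' sim <- simulate_expression(n_probes = 100, planted_set_size = 10,
#'                            delta = 2, noise_sd = 0.25, seed = 1)
#' rk <- cross_line_rank(sim$expr, sim$annot)
#' head(rk)
cross_line_rank <- function(expr, annot, cell_lines = NULL) {
  check_expression(expr, annot)
  if (is.null(cell_lines)) cell_lines <- sort(unique(annot$cell_line_id))
  deltas <- vapply(cell_lines, function(cl) delta_log2(expr, annot, cl),
                   numeric(nrow(expr)))
  score <- rowMeans(as.matrix(deltas))
  ord <- order(-score, rownames(expr), method = "radix")
  out <- data.frame(probe_id = rownames(expr)[ord],
                    score = unname(score[ord]),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  attr(out, "n_lines_used") <- length(cell_lines)
  class(out) <- c("gene_rank", "data.frame")
  out
}

rank_probes <- function(rank) {
  if (inherits(rank, "gene_rank") ||
      (is.data.frame(rank) && "probe_id" %in% names(rank)))
    return(as.character(rank$probe_id))
  if (is.character(rank)) return(rank)
  abort("`rank` must be a gene_rank data.frame or an ordered character vector",
        "tilscreen_validation_error")
}

#' Enrichment score of a gene set against a rank
#'
#' The classic unweighted KS-type statistic: the signed extremum of the
#' running sum that gains 1/k at each of the k set members and loses
#' 1/(N - k) at each of the N - k non-members while walking the rank from
#' top to bottom. ES is 1 when the set occupies exactly the top of the rank,
#' -1 at the bottom; ties between equal positive and negative extrema
#' resolve to the positive one.
#'
#' Set members absent from the rank are ignored (the count retained is
#' reported by [permutation_pvalue()]).
#'
#' @param rank a `gene_rank` (from [cross_line_rank()]) or an ordered
#'   character vector of probe ids, best first.
#' @param members character vector of set member ids.
#' @return single numeric ES in `[-1, 1]`.
#' @export
enrichment_score <- function(rank, members) {
  probes <- rank_probes(rank)
  pos <- which(probes %in% members)
  N <- length(probes)
  if (length(pos) == 0L)
    abort("gene set has no members in the rank", "tilscreen_no_overlap_error")
  if (length(pos) >= N)
    abort("gene set must be smaller than the rank",
          "tilscreen_validation_error")
  es_from_positions(pos, N)$es
}

# ES from sorted in-set positions. The running sum is linear between hits,
# so its positive extremum is attained at a hit and its negative extremum
# just before a hit (or 0 at the ends); both are evaluated in O(k).
es_from_positions <- function(pos, N) {
  k <- length(pos)
  pos <- sort.int(pos)
  i <- seq_len(k)
  at_hit <- i / k - (pos - i) / (N - k)     # value of the sum at hit i
  before_hit <- at_hit - 1 / k              # value just before hit i
  max_pos <- max(at_hit, 0)
  min_neg <- min(before_hit, 0)
  # positive extremum wins an (exact, up to rounding) magnitude tie
  if (max_pos >= -min_neg - 1e-12) {
    peak <- pos[which.max(at_hit)]
    list(es = max_pos, peak = peak)
  } else {
    peak <- pos[which.min(before_hit)] - 1L
    list(es = min_neg, peak = peak)
  }
}

#' Permutation p-value for a gene-set enrichment score
#'
#' Null distribution: ES of `n_permutations` random sets of the same size,
#' drawn uniformly without replacement from the rank (gene-label
#' permutation). Two-sided add-one p-value:
#' `p = (1 + #{|ES_null| >= |ES_obs|}) / (n_permutations + 1)`, so the
#' smallest attainable p is `1/(n_permutations + 1)`. The leading edge is
#' the in-set members at or before the running-sum peak (after the peak for
#' a negative ES).
#'
#' @inheritParams enrichment_score
#' @param set_name label carried into the result.
#' @param n_permutations number of null draws (>= 100; default 1000).
#' @param seed RNG seed (required, for reproducibility).
#' @return object of class `enrichment_result`: list with `set_name`, `es`,
#'   `p_value`, `n_permutations`, `seed`, `leading_edge`,
#'   `n_members_in_rank`.
#' @export
#' @examples
#' probes <- sprintf("P%03d", 1:200)
#' res <- permutation_pvalue(probes, probes[1:10], seed = 7)
#' res$p_value
permutation_pvalue <- function(rank, members, set_name = "set",
                               n_permutations = 1000, seed) {
  if (missing(seed))
    abort("`seed` is required for a reproducible permutation p-value",
          "tilscreen_validation_error")
  stopifnot_scalar_number(n_permutations, "n_permutations", positive = TRUE)
  if (n_permutations < 100)
    abort("n_permutations must be >= 100", "tilscreen_validation_error")
  probes <- rank_probes(rank)
  N <- length(probes)
  pos <- which(probes %in% members)
  if (length(pos) == 0L)
    abort("gene set has no members in the rank", "tilscreen_no_overlap_error")
  if (length(pos) >= N)
    abort("gene set must be smaller than the rank",
          "tilscreen_validation_error")
  obs <- es_from_positions(pos, N)
  k <- length(pos)
  null_abs <- with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(b) abs(es_from_positions(sample.int(N, k), N)$es),
           numeric(1L))
  })
  p <- (1 + sum(null_abs >= abs(obs$es))) / (n_permutations + 1)
  in_set <- probes[pos]
  leading <- if (obs$es >= 0) probes[pos[pos <= obs$peak]]
             else probes[pos[pos > obs$peak]]
  structure(list(set_name = set_name,
                 es = obs$es,
                 p_value = p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 leading_edge = leading,
                 n_members_in_rank = k),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Enrichment [%s]: ES = %.4f, p = %.4g (%d members in rank, %d permutations, seed %d)\n",
    x$set_name, x$es, x$p_value, x$n_members_in_rank, x$n_permutations,
    x$seed))
  invisible(x)
}

#' Score every set of a GMT collection against a rank
#'
#' @inheritParams permutation_pvalue
#' @param gene_sets named list of member vectors, e.g. from [read_gmt()].
#' @return list of `enrichment_result`, one per set (sets with no overlap
#'   are reported with `NA` ES and a message rather than an error).
#' @export
enrich_collection <- function(rank, gene_sets, n_permutations = 1000, seed) {
  seeds <- derive_seeds(seed, length(gene_sets))
  out <- vector("list", length(gene_sets))
  names(out) <- names(gene_sets)
  for (i in seq_along(gene_sets)) {
    out[[i]] <- tryCatch(
      permutation_pvalue(rank, gene_sets[[i]], set_name = names(gene_sets)[i],
                         n_permutations = n_permutations, seed = seeds[i]),
      tilscreen_no_overlap_error = function(e) {
        structure(list(set_name = names(gene_sets)[i], es = NA_real_,
                       p_value = NA_real_,
                       n_permutations = as.integer(n_permutations),
                       seed = seeds[i], leading_edge = character(0),
                       n_members_in_rank = 0L),
                  class = "enrichment_result")
      })
  }
  out
}

#' Collapse a probe-level rank score to gene level (optional)
#'
#' Probe-level ranking is the default; when a probe-to-gene map is supplied,
#' this keeps the probe with the maximal absolute score per gene.
#'
#' @param rank a `gene_rank`.
#' @param probe2gene named character vector mapping probe id to gene symbol.
#' @return a new `gene_rank` with gene symbols as `probe_id`.
#' @export
collapse_to_genes <- function(rank, probe2gene) {
  stopifnot(inherits(rank, "gene_rank"))
  gene <- unname(probe2gene[rank$probe_id])
  keep <- !is.na(gene)
  df <- data.frame(probe_id = gene[keep], score = rank$score[keep],
                   stringsAsFactors = FALSE)
  dt <- data.table::as.data.table(df)
  best <- dt[, .(score = score[which.max(abs(score))]), by = probe_id]
  ord <- order(-best$score, best$probe_id, method = "radix")
  out <- data.frame(probe_id = best$probe_id[ord], score = best$score[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  class(out) <- c("gene_rank", "data.frame")
  out
}
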