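# Independent oracles used across the suite. Each recomputes a quantity by
# the most literal route available (explicit loops, cumulative sums, direct
# formula evaluation) so that the package's vectorized/closed-form paths are
# checked against something they do not share code with.

# KS running sum walked element by element; extremum tie (equal positive and
# negative magnitude) resolves to the positive value, the package's
# documented convention.
brute_force_es <- function(in_set, ...) {
  N <- length(in_set)
  k <- sum(in_set)
  stopifnot(k >= 1, k < N)
  rs <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (in_set[i]) 1 / k else -1 / (N - k)
    rs[i] <- cur
  }
  # magnitude ties (up to rounding) resolve to the positive extremum,
  # matching the package's documented convention
  if (max(rs) >= -min(rs) - 1e-12) max(rs) else min(rs)
}

# two-loop mean-of-differences rank score: for every probe, average over
# cell lines of (mean treated - mean control)
brute_force_rank_scores <- function(expr, annot) {
  lines <- sort(unique(annot$cell_line_id))
  scores <- numeric(nrow(expr))
  for (p in seq_len(nrow(expr))) {
    deltas <- numeric(length(lines))
    for (li in seq_along(lines)) {
      trt <- annot$sample_id[annot$cell_line_id == lines[li] &
                               annot$treatment == "treated"]
      ctl <- annot$sample_id[annot$cell_line_id == lines[li] &
                               annot$treatment == "control"]
      deltas[li] <- mean(expr[p, trt]) - mean(expr[p, ctl])
    }
    scores[p] <- mean(deltas)
  }
  names(scores) <- rownames(expr)
  scores
}

# random small expression matrix with annotations, for property tests
random_expr_fixture <- function(n_probes = 12, n_lines = 3, duplicates = 2) {
  probes <- sprintf("P%03d", seq_len(n_probes))
  annot <- expand.grid(replicate = seq_len(duplicates),
                       treatment = c("control", "treated"),
                       cell_line_id = sprintf("L%d", seq_len(n_lines)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  annot$sample_id <- sprintf("%s_%s_%d", annot$cell_line_id, annot$treatment,
                             annot$replicate)
  expr <- matrix(rnorm(n_probes * nrow(annot), 8, 1), nrow = n_probes,
                 dimnames = list(probes, annot$sample_id))
  list(expr = expr, annot = annot[, c("sample_id", "cell_line_id",
                                      "treatment", "replicate")])
}

# small hand-buildable wells table
make_wells <- function(compound_id, til_status, pct, tumor_line_id = "L1",
                       replicate = seq_along(pct)) {
  data.frame(plate_id = "P1",
             well_id = sprintf("W%03d", seq_along(pct)),
             tumor_line_id = tumor_line_id,
             compound_id = compound_id,
             dose_nM = ifelse(compound_id == "DMSO", 0, 1000),
             til_status = til_status,
             replicate = replicate,
             pct_caspase3 = pct,
             stringsAsFactors = FALSE)
}

# wells for a full 4-condition design given condition means (no noise)
wells_from_means <- function(means, n_rep = 1) {
  # means: data.frame(compound_id, til_status, pct)
  do.call(rbind, lapply(seq_len(nrow(means)), function(i)
    make_wells(rep(means$compound_id[i], n_rep),
               rep(means$til_status[i], n_rep),
               rep(means$pct[i], n_rep))))
}
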