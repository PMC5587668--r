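test_that("delta_log2 averages duplicates then differences", {
  expr <- rbind(P1 = c(8.0, 8.4, 7.0, 7.4),
                P2 = c(5, 5, 5, 5))
  colnames(expr) <- c("t1", "t2", "c1", "c2")
  annot <- data.frame(sample_id = colnames(expr), cell_line_id = "L1",
                      treatment = c("treated", "treated", "control",
                                    "control"),
                      replicate = c(1, 2, 1, 2))
  d <- delta_log2(expr, annot, "L1")
  expect_equal(unname(d["P1"]), 1.0)
  expect_equal(unname(d["P2"]), 0)

  # single sample per arm degenerates to a plain difference
  one <- delta_log2(expr[, c("t1", "c1"), drop = FALSE],
                    annot[c(1, 3), ], "L1")
  expect_equal(unname(one["P1"]), 1.0)

  expect_error(delta_log2(expr, annot[annot$treatment == "treated", ], "L1"),
               class = "tilscreen_missing_group_error")
  expect_error(delta_log2(expr, annot, "L9"),
               class = "tilscreen_missing_group_error")
})

test_that("cross_line_rank averages per-line deltas and breaks ties", {
  # two lines, one probe with deltas 1 and 3 -> score 2
  fix <- random_expr_fixture(n_probes = 4, n_lines = 2)
  expr <- fix$expr
  expr[] <- 8
  treated1 <- fix$annot$sample_id[fix$annot$cell_line_id == "L1" &
                                    fix$annot$treatment == "treated"]
  treated2 <- fix$annot$sample_id[fix$annot$cell_line_id == "L2" &
                                    fix$annot$treatment == "treated"]
  expr["P001", treated1] <- 9   # delta 1 in L1
  expr["P001", treated2] <- 11  # delta 3 in L2
  rk <- cross_line_rank(expr, fix$annot)
  expect_equal(rk$score[rk$probe_id == "P001"], 2)
  expect_equal(rk$rank[rk$probe_id == "P001"], 1L)
  # remaining probes all tie at 0 and sort lexicographically
  expect_equal(rk$probe_id[-1L], c("P002", "P003", "P004"))
})

test_that("cross_line_rank equals the two-loop brute force on random data", {
  withr::with_seed(21, {
    for (i in 1:20) {
      fix <- random_expr_fixture(n_probes = sample(3:15, 1),
                                 n_lines = sample(1:4, 1),
                                 duplicates = sample(1:3, 1))
      rk <- cross_line_rank(fix$expr, fix$annot)
      oracle <- brute_force_rank_scores(fix$expr, fix$annot)
      expect_equal(rk$score, unname(oracle[rk$probe_id]), tolerance = 1e-12)
      expect_true(all(diff(rk$score) <= 1e-12))
      # invariance to sample column order
      perm <- sample(ncol(fix$expr))
      rk2 <- cross_line_rank(fix$expr[, perm, drop = FALSE], fix$annot)
      expect_equal(rk2, rk)
    }
  })
})

test_that("enrichment score matches the hand-walked running sum", {
  probes <- sprintf("p%d", 1:4)
  expect_equal(enrichment_score(probes, c("p1", "p3")), 0.5)
  # top-k and bottom-k extremes
  N <- 40
  probes <- sprintf("p%02d", 1:N)
  for (k in c(1, 7, 20)) {
    expect_equal(enrichment_score(probes, probes[1:k]), 1)
    expect_equal(enrichment_score(probes, probes[(N - k + 1):N]), -1)
  }
  expect_error(enrichment_score(probes, "absent"),
               class = "tilscreen_no_overlap_error")
  expect_error(enrichment_score(probes, probes),
               class = "tilscreen_validation_error")
})

test_that("enrichment score agrees with brute force on random sets", {
  withr::with_seed(31, {
    for (i in 1:200) {
      N <- sample(5:60, 1)
      k <- sample(1:(N - 1), 1)
      pos <- sort(sample(N, k))
      probes <- sprintf("q%03d", 1:N)
      expect_equal(enrichment_score(probes, probes[pos]),
                   brute_force_es(seq_len(N) %in% pos), tolerance = 1e-12)
    }
  })
})

test_that("reversing the rank negates the ES", {
  withr::with_seed(41, {
    for (i in 1:25) {
      N <- sample(6:50, 1)
      k <- sample(1:(N - 1), 1)
      probes <- sprintf("r%03d", 1:N)
      members <- sample(probes, k)
      es_f <- enrichment_score(probes, members)
      es_r <- enrichment_score(rev(probes), members)
      expect_equal(es_r, -es_f, tolerance = 1e-12)
    }
  })
})

test_that("a uniformly interleaved set has near-zero ES at large N", {
  N <- 10000
  probes <- sprintf("s%05d", 1:N)
  members <- probes[seq(5, N, by = 10)]  # every 10th probe
  expect_lt(abs(enrichment_score(probes, members)), 0.05)
})

test_that("permutation p-values are reproducible, bounded and sensible", {
  withr::with_seed(51, {
    N <- 400
    probes <- sprintf("t%04d", 1:N)
    top <- probes[1:20]
    res <- permutation_pvalue(probes, top, set_name = "top20",
                              n_permutations = 200, seed = 7)
    expect_s3_class(res, "enrichment_result")
    expect_equal(res$es, 1)
    expect_equal(res$p_value, 1 / 201)  # minimum attainable
    expect_equal(res$n_members_in_rank, 20L)
    expect_setequal(res$leading_edge, top)
    # reproducible under the same seed, different under another
    res2 <- permutation_pvalue(probes, top, n_permutations = 200, seed = 7)
    expect_identical(res$p_value, res2$p_value)

    rand <- sample(probes, 25)
    pr <- permutation_pvalue(probes, rand, n_permutations = 200, seed = 9)
    expect_gte(pr$p_value, 1 / 201)
    expect_lte(pr$p_value, 1)
  })
  expect_error(permutation_pvalue(sprintf("u%d", 1:50), "u1",
                                  n_permutations = 10, seed = 1),
               class = "tilscreen_validation_error")
  expect_error(permutation_pvalue(sprintf("u%d", 1:50), "u1",
                                  n_permutations = 200),
               class = "tilscreen_validation_error")
})

test_that("a saturated set (all but one probe) is never significant", {
  # with k = N - 1 the running sum is driven entirely by where the single
  # non-member sits: the extremum is max(j-1, N-j) / (N-1) for exclusion at
  # position j, so |ES| >= 0.5 for EVERY same-size set and the permutation
  # p-value of a central exclusion is ~1
  N <- 200
  probes <- sprintf("v%03d", 1:N)
  res <- permutation_pvalue(probes, probes[-(N / 2)], n_permutations = 100,
                            seed = 3)
  expect_equal(res$es, brute_force_es(seq_len(N) != N / 2), tolerance = 1e-12)
  expect_equal(abs(res$es), 0.5, tolerance = 0.01)
  expect_gt(res$p_value, 0.9)
})

test_that("leading edge follows the peak on the correct side", {
  probes <- sprintf("w%02d", 1:20)
  bottom <- probes[16:20]
  res <- permutation_pvalue(probes, bottom, n_permutations = 100, seed = 5)
  expect_equal(res$es, -1)
  expect_setequal(res$leading_edge, bottom)
})

test_that("enrich_collection scores GMT-style collections per set", {
  probes <- sprintf("x%03d", 1:100)
  sets <- list(top = probes[1:10], none = c("absent1", "absent2"))
  res <- enrich_collection(probes, sets, n_permutations = 100, seed = 13)
  expect_equal(res$top$es, 1)
  expect_true(is.na(res$none$es))
  expect_equal(res$none$n_members_in_rank, 0L)
})

test_that("collapse_to_genes keeps the max-|score| probe per gene", {
  rk <- structure(data.frame(probe_id = c("p1", "p2", "p3"),
                             score = c(2, -3, 1), rank = 1:3),
                  class = c("gene_rank", "data.frame"))
  map <- c(p1 = "G1", p2 = "G1", p3 = "G2")
  out <- collapse_to_genes(rk, map)
  expect_equal(out$score[out$probe_id == "G1"], -3)
  expect_equal(out$score[out$probe_id == "G2"], 1)
})
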