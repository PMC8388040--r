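scg <- scoring_scheme(1, -2, -2, 20)

test_that("banded global alignment matches hand-derived scores", {
  r <- banded_align("ACGTT", "ACGTT", scg, 8)
  expect_equal(r$score, 5L)
  expect_false(grepl("-", r$aligned_a))
  r2 <- banded_align("ACGTT", "ACGAT", scg, 8)
  expect_equal(r2$score, 2L)  # 4 matches + 1 mismatch
  r3 <- banded_align("ACGT", "ACT", scg, 8)
  expect_equal(r3$score, 1L)  # 3 matches + 1 gap
  expect_error(banded_align(strrep("A", 40), "A", scg, 2), "band")
})

test_that("banded equals full DP whenever the band is wide enough", {
  set.seed(61)
  for (rep in 1:30) {
    la <- sample(3:40, 1)
    a <- paste(sample(c("A", "C", "G", "T"), la, replace = TRUE),
               collapse = "")
    # derive b from a by a few edits so the optimum stays near the diagonal
    b <- generate_query(a, max(2, la - sample(0:2, 1)), 0.15)$query
    band <- abs(nchar(a) - nchar(b)) + 8L
    got <- banded_align(a, b, scg, band)
    expect_equal(got$score, oracle_global_dp(a, b, scg))
    # transcript round-trip: degapping reproduces the inputs
    expect_equal(gsub("-", "", got$aligned_a), a)
    expect_equal(gsub("-", "", got$aligned_b), b)
    # score is consistent with the scheme
    ops <- strsplit(got$transcript, "")[[1]]
    recomputed <- sum(ifelse(ops == "M", scg$match,
                             ifelse(ops == "R", scg$mismatch, scg$gap)))
    expect_equal(recomputed, got$score)
  }
})

test_that("the band widens with HSP non-identity and is clamped", {
  perfect <- data.frame(query_begin = 0L, query_end = 100L, score = 100L)
  expect_equal(choose_band(perfect, scg), 8L)
  mid <- data.frame(query_begin = 0L, query_end = 100L,
                    score = 100L - 20L * 3L)  # 20 mismatches
  expect_equal(choose_band(mid, scg), 28L)
  awful <- data.frame(query_begin = 0L, query_end = 300L, score = 0L)
  expect_equal(choose_band(awful, scg), 64L)
})

test_that("checkpoints partition the path into maximal equal-color runs", {
  g <- toy_graph()
  vA <- which(g$labels == "ACG"); vT <- which(g$labels == "CGTT")
  ck <- compute_checkpoints(g, truncated_path(c(vA, vT), 0, 4), c(0, 1), 1)
  expect_equal(ck$path_offset, c(0L, 1L))
  expect_equal(ck$colors[[1]], c(0L, 1L))
  expect_equal(ck$colors[[2]], 0L)
  # single-vertex uniform path: exactly one checkpoint at 0
  ck2 <- compute_checkpoints(g, truncated_path(vA, 0, 3), c(0, 1), 1)
  expect_equal(ck2$path_offset, 0L)
  expect_error(compute_checkpoints(g, truncated_path(c(vA, vT), 0, 4),
                                   c(0, 1), 2), "quorum")
})

test_that("checkpoint invariants hold on random quorum-fulfilling paths", {
  set.seed(67)
  genomes <- random_genome_set(4, 150, 5, snp_rate = 0.05)
  g <- build_graph(genomes, 5)
  search <- 0:3
  for (v in seq_len(min(10, length(g$labels)))) {
    t <- truncated_path(v, 0, nchar(g$labels[v]))
    if (!is_quorum_fulfilling(g, t, search, 1)) next
    ck <- compute_checkpoints(g, t, search, 1)
    expect_equal(ck$path_offset[1], 0L)
    expect_true(all(diff(ck$path_offset) > 0))
    expect_true(all(ck$path_offset < nchar(path_sequence(g, t))))
    expect_true(all(ck$n_colors >= 1))
    if (nrow(ck) > 1) {
      for (i in 2:nrow(ck)) {
        expect_false(identical(ck$colors[[i]], ck$colors[[i - 1]]))
      }
    }
  }
})

test_that("select_significant ranks by E-value and applies the cutoff", {
  params <- stat_params(1.0, log(0.1 * 1e4 * 1e2), M_cal = 1e4, n_cal = 1e2)
  g <- toy_graph()
  vA <- which(g$labels == "ACG")
  mk <- function(s, qb = 0L) {
    tibble::tibble(query_begin = qb, query_end = qb + 3L, score = s,
                   path = list(truncated_path(vA, 0, 3)), strand = "+",
                   truncated = FALSE)
  }
  hsps <- rbind(mk(25L), mk(10L))
  out <- select_significant(hsps, params, M = 1e4, n = 1e2,
                            evalue_cutoff = 0.01)
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 25L)
  expect_equal(out$evalue, 1e5 * exp(-25), tolerance = 1e-12)
  expect_equal(nrow(select_significant(hsps[0, ], params, 1e4, 1e2)), 0)
  # equal scores tie-break on query_begin
  out2 <- select_significant(rbind(mk(25L, 2L), mk(25L, 0L)), params,
                             1e4, 1e2, evalue_cutoff = 1)
  expect_equal(out2$query_begin, c(0L, 2L))
  expect_error(select_significant(hsps, NULL, 1e4, 1e2), "stat_params")
})

test_that("gapped recomputation reproduces scores on planted homologies", {
  set.seed(71)
  genomes <- random_genome_set(1, 400, 9, snp_rate = 0)
  g <- build_graph(genomes, 9)
  idx <- build_index(g, 5)
  # perfect query: gap-free full-length alignment at match * length
  q <- generate_query(genomes[[1]], 80, 0)$query
  seeds <- find_seeds(q, g, idx)
  hsps <- filter_hsps(dplyr::bind_rows(lapply(seed_rows(seeds), function(s)
    extend_seed(g, q, s, scg))), g)
  out <- recompute(hsps[1, ], g, q, scg)
  expect_equal(out$score[1], 80L)
  expect_false(grepl("-", out$aligned_query[1]))
  expect_equal(out$pct_identity[1], 100)
  expect_equal(out$query_begin[1], 0L)
  expect_equal(out$query_end[1], 80L)
  # degapping the alignment reproduces query and path substrings
  t <- out$path[[1]]
  expect_equal(gsub("-", "", out$aligned_target[1]), path_sequence(g, t))
  # one-substitution query: gapped score equals full DP on the path sequence
  q2 <- q
  substr(q2, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                substr(q2, 40, 40))[1]
  seeds2 <- find_seeds(q2, g, idx)
  hsps2 <- filter_hsps(dplyr::bind_rows(lapply(seed_rows(seeds2),
    function(s) extend_seed(g, q2, s, scg))), g)
  out2 <- recompute(hsps2[1, ], g, q2, scg)
  expect_equal(out2$score[1],
               oracle_global_dp(substr(q2, out2$query_begin[1] + 1,
                                       out2$query_end[1]),
                                path_sequence(g, out2$path[[1]]), scg))
})

test_that("gapped results carry consistent E-values and checkpoints", {
  set.seed(73)
  genomes <- random_genome_set(3, 300, 9, snp_rate = 0.02)
  g <- build_graph(genomes, 9)
  idx <- build_index(g, 5)
  q <- generate_query(genomes[[1]], 60, 0.03)$query
  params <- stat_params(1.0, 2, regime = "gapped", M_cal = g$M, n_cal = 60)
  hsps <- filter_hsps(dplyr::bind_rows(lapply(
    seed_rows(find_seeds(q, g, idx)),
    function(s) extend_seed(g, q, s, scg))), g)
  out <- recompute(hsps, g, q, scg, params)
  expect_true(all(diff(out$evalue) >= 0))
  expect_equal(out$pvalue, -expm1(-out$evalue))
  for (i in seq_len(nrow(out))) {
    ck <- out$checkpoints[[i]]
    expect_equal(ck$path_offset[1], 0L)
    expect_true(all(ck$path_offset <
                      nchar(path_sequence(g, out$path[[i]]))))
    expect_true(all(ck$n_colors >= 1))
  }
})
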