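test_that("the toy search composes all stages on both strands", {
  g <- toy_graph()
  idx <- build_index(g, 2)
  cfg <- search_config(k = 3, w = 2, scoring = scoring_scheme(1, -2, -2, 3),
                       evalue_cutoff = NULL)
  res <- run_search("ACGTT", g, idx, cfg)
  top <- res[1, ]
  expect_equal(top$score, 5L)
  expect_equal(c(top$query_begin, top$query_end), c(0L, 5L))
  expect_equal(g$labels[top$path[[1]]$vertices], c("ACG", "CGTT"))
  ck <- top$checkpoints[[1]]
  expect_equal(ck$path_offset, c(0L, 1L))
  expect_equal(ck$colors[[1]], c(0L, 1L))
  expect_equal(ck$colors[[2]], 0L)
  # quorum 2: no record spans beyond the shared vertex
  cfg2 <- search_config(k = 3, w = 2,
                        scoring = scoring_scheme(1, -2, -2, 3),
                        evalue_cutoff = NULL, quorum = 2)
  res2 <- run_search("ACGTT", g, idx, cfg2)
  for (t in res2$path) expect_length(t$vertices, 1)
  # reverse complemented query: same top score on the minus strand
  res3 <- run_search(reverse_complement("ACGTT"), g, idx, cfg)
  expect_equal(res3$score[1], 5L)
  expect_equal(res3$strand[1], "-")
})

test_that("searches refuse E-value filtering without calibrated statistics", {
  g <- toy_graph()
  idx <- build_index(g, 2)
  cfg <- search_config(k = 3, w = 2, scoring = scoring_scheme(1, -2, -2, 3),
                       evalue_cutoff = 0.01)
  expect_error(run_search("ACGTT", g, idx, cfg), "calibrated")
  expect_error(run_search("ACGTT", g, build_index(g, 3),
                          search_config(k = 3, w = 2,
                                        evalue_cutoff = NULL)), "w")
})

test_that("single-genome search reduces to pairwise alignment", {
  set.seed(91)
  genome <- pangaln:::random_dna(1, 1500)
  g <- build_graph(list(gen = genome), k = 21)
  expect_length(g$labels, 1)  # distinct k-mers: one unitig
  idx <- build_index(g, 11)
  sc <- scoring_scheme()
  for (rep in 1:5) {
    q <- generate_query(genome, 150, divergence = 0.04)$query
    seeds <- find_seeds(q, g, idx)
    hsps <- dplyr::bind_rows(lapply(seed_rows(seeds), function(s) {
      extend_seed(g, q, s, sc)
    }))
    # graph extension equals the pairwise X-drop primitive per seed
    for (i in seq_len(nrow(seeds))) {
      s <- seeds[i, ]
      p <- ungapped_xdrop_pair(q, genome,
                               c(s$query_begin, s$query_end, s$v_begin,
                                 s$v_end), sc)
      match_rows <- hsps[hsps$query_begin == p$a_begin &
                           hsps$query_end == p$a_end, ]
      expect_true(p$score %in% match_rows$score)
    }
    # top gapped alignment covers the planted interval
    out <- recompute(filter_hsps(hsps, g)[1, ], g, q, sc)
    expect_gte(out$score[1], max(hsps$score))
  }
})

test_that("planted homologies are recovered at their true location", {
  set.seed(97)
  cfg_sim <- pangenome_sim_config(num_genomes = 3, genome_length = 3000,
                                  snp_rate = 0.005)
  pg <- generate_pangenome(cfg_sim, seed = 17)
  g <- build_graph(pg$genomes, k = 21)
  idx <- build_index(g, 11)
  cfg <- search_config(k = 21, w = 11, evalue_cutoff = NULL)
  for (rep in 1:3) {
    tr <- generate_query(pg$genomes[[1]], 300, divergence = 0)
    res <- run_search(tr$query, g, idx, cfg, both_strands = FALSE)
    expect_equal(res$score[1], 300L)
    expect_equal(res$pct_identity[1], 100)
    expect_equal(c(res$query_begin[1], res$query_end[1]), c(0L, 300L))
  }
  # a reverse complemented planted query is found on the minus strand
  tr <- generate_query(pg$genomes[[2]], 250, divergence = 0,
                       revcomp = TRUE)
  res <- run_search(tr$query, g, idx, cfg)
  expect_equal(res$strand[1], "-")
  expect_equal(res$score[1], 250L)
})

test_that("search color sets confine alignments to the chosen genomes", {
  set.seed(101)
  # genome 2 carries a private insert foreign to genomes 0 and 1
  base <- pangaln:::random_dna(1, 800)
  insert <- pangaln:::random_dna(1, 120)
  genomes <- list(g1 = base, g2 = base,
                  g3 = paste0(substr(base, 1, 400), insert,
                              substr(base, 401, 800)))
  g <- build_graph(genomes, k = 15)
  idx <- build_index(g, 9)
  cfg_all <- search_config(k = 15, w = 9, evalue_cutoff = NULL)
  res_all <- run_search(insert, g, idx, cfg_all, both_strands = FALSE)
  expect_equal(res_all$score[1], 120L)
  # restricted to the two genomes lacking the insert: no full-length hit
  cfg_r <- search_config(k = 15, w = 9, evalue_cutoff = NULL,
                         search_colors = c(0L, 1L))
  res_r <- run_search(insert, g, idx, cfg_r, both_strands = FALSE)
  expect_true(nrow(res_r) == 0 || max(res_r$score) < 120L)
  # restricted to the carrier: found again
  cfg_c <- search_config(k = 15, w = 9, evalue_cutoff = NULL,
                         search_colors = 2L)
  res_c <- run_search(insert, g, idx, cfg_c, both_strands = FALSE)
  expect_equal(res_c$score[1], 120L)
  # checkpoints report the private color set
  expect_true(all(vapply(res_c$checkpoints[[1]]$colors,
                         function(cs) 2L %in% cs, TRUE)))
})

test_that("E-value filtering with calibrated statistics keeps strong hits only", {
  set.seed(103)
  pg <- generate_pangenome(pangenome_sim_config(num_genomes = 2,
                                                genome_length = 4000,
                                                snp_rate = 0.01), seed = 23)
  g <- build_graph(pg$genomes, k = 21)
  idx <- build_index(g, 11)
  # plausible synthetic parameters at this graph size
  su <- stat_params(1.1, log(0.3 * g$M * 200), M_cal = g$M, n_cal = 200)
  sg <- stat_params(0.9, log(0.3 * g$M * 200), M_cal = g$M, n_cal = 200,
                    regime = "gapped")
  cfg <- search_config(k = 21, w = 11, evalue_cutoff = 0.01)
  tr <- generate_query(pg$genomes[[1]], 200, divergence = 0.02)
  res <- run_search(tr$query, g, idx, cfg, su, sg)
  expect_gte(nrow(res), 1)
  expect_true(all(res$evalue <= 0.01))
  # a random query yields nothing significant
  rq <- pangaln:::random_dna(1, 200)
  res0 <- run_search(rq, g, idx, cfg, su, sg)
  expect_true(nrow(res0) == 0 || all(res0$evalue <= 0.01))
})
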