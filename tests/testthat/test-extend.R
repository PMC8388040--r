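sc3 <- scoring_scheme(1, -2, -2, 3)

test_that("scoring_scheme enforces a negative expected pair score", {
  expect_error(scoring_scheme(3, -1, -2, 20), "negative")
  expect_error(scoring_scheme(0, -2, -2, 20), "match")
  expect_error(scoring_scheme(1, -2, -2, 0), "xdrop")
  s <- scoring_scheme()
  expect_equal(c(s$match, s$mismatch, s$gap, s$xdrop), c(1L, -2L, -2L, 20L))
})

test_that("pairwise X-drop extension follows the BLAST recurrence", {
  p <- ungapped_xdrop_pair("ACGTT", "ACGTT", c(1, 3, 1, 3), sc3)
  expect_equal(p$score, 5L)
  expect_equal(c(p$a_begin, p$a_end), c(0L, 5L))
  # hand trace: extends through pos 2 (run 1), mismatch at 3 (run -1),
  # match at 4 (run 0); best right extension is +1 at extent [0..3)
  p2 <- ungapped_xdrop_pair("ACGTT", "ACGAT", c(0, 2, 0, 2), sc3)
  expect_equal(p2$score, 3L)
  expect_equal(c(p2$a_begin, p2$a_end), c(0L, 3L))
  # anchor at the string ends: no extension possible
  p3 <- ungapped_xdrop_pair("ACG", "ACG", c(0, 3, 0, 3), sc3)
  expect_equal(p3$score, 3L)
  expect_error(ungapped_xdrop_pair("ACGT", "AGGT", c(0, 2, 0, 2), sc3),
               "differ")
  # the X-drop rule actually truncates: long mismatch run then match
  a <- paste0("AAAA", "CCCCCC", "AAAA")
  b <- paste0("AAAA", "GGGGGG", "AAAA")
  p4 <- ungapped_xdrop_pair(a, b, c(0, 4, 0, 4), sc3)
  expect_equal(p4$score, 4L)  # stops inside the mismatch run
  expect_equal(p4$a_end, 4L)
})

test_that("seed extension over the toy graph crosses vertex overlaps", {
  g <- toy_graph()
  vT <- which(g$labels == "CGTT")
  seed <- data.frame(query_begin = 1L, query_end = 5L, vertex = vT,
                     v_begin = 0L, v_end = 4L, strand = "+")
  h <- extend_seed(g, "ACGTT", seed, sc3)
  expect_equal(nrow(h), 1)
  expect_equal(h$score, 5L)
  expect_equal(c(h$query_begin, h$query_end), c(0L, 5L))
  t <- h$path[[1]]
  expect_equal(g$labels[t$vertices], c("ACG", "CGTT"))
  expect_equal(c(t$begin, t$end), c(0L, 4L))
  # quorum 2: the seed vertex itself fails the per-location test
  expect_equal(nrow(extend_seed(g, "ACGTT", seed, sc3, quorum = 2)), 0)
  # query exhausted at the seed vertex: no branch adds query characters
  vA <- which(g$labels == "ACG")
  sA <- data.frame(query_begin = 0L, query_end = 3L, vertex = vA,
                   v_begin = 0L, v_end = 3L, strand = "+")
  hA <- extend_seed(g, "ACG", sA, sc3)
  expect_equal(nrow(hA), 1)
  expect_equal(hA$score, 3L)
})

test_that("every reported HSP path is quorum fulfilling", {
  set.seed(41)
  genomes <- random_genome_set(3, 150, 5, snp_rate = 0.05)
  g <- build_graph(genomes, 5)
  idx <- build_index(g, 3)
  q <- generate_query(genomes[[1]], 40, 0.05)$query
  for (m in 1:2) {
    seeds <- find_seeds(q, g, idx, 0:2, m)
    ok <- TRUE
    for (srow in seed_rows(seeds)) {
      h <- extend_seed(g, q, srow, sc3, 0:2, m)
      for (i in seq_len(nrow(h))) {
        ok <- ok && is_quorum_fulfilling(g, h$path[[i]], 0:2, m) &&
          # ungapped: path sequence length equals the query interval length
          nchar(path_sequence(g, h$path[[i]])) ==
            h$query_end[i] - h$query_begin[i]
      }
    }
    expect_true(ok)
  }
})

test_that("DFS extension equals brute-force path enumeration + pairwise X-drop", {
  set.seed(43)
  reps <- 0L
  while (reps < 6L) {
    k <- 5L
    genomes <- random_genome_set(2L, sample(40:80, 1), k,
                                 snp_rate = 0.03)
    g <- build_graph(genomes, k)
    if (length(g$labels) > 12L) next
    reps <- reps + 1L
    idx <- build_index(g, 3L)
    q <- generate_query(genomes[[1]], sample(25:40, 1), 0.08)$query
    quorum <- sample(1:2, 1)
    search <- seq_len(g$colors$size) - 1L
    seeds <- find_seeds(q, g, idx, search, quorum)
    if (nrow(seeds) > 4L) seeds <- seeds[sample.int(nrow(seeds), 4L), ]
    res <- tryCatch({
      lapply(seed_rows(seeds), function(srow) {
        want <- oracle_extend_seed(g, q, srow, sc3, search, quorum)
        got <- extend_seed(g, q, srow, sc3, search, quorum,
                           max_vertices = 1e6, max_hsps = Inf)
        list(got = unique(paste(got$score, got$query_begin, got$query_end)),
             want = unique(paste(want$score, want$query_begin,
                                 want$query_end)))
      })
    }, oracle_path_limit = function(e) NULL)
    if (is.null(res)) { reps <- reps - 1L; next }  # cyclic blow-up: redraw
    for (r in res) expect_setequal(r$got, r$want)
  }
})

test_that("HSP scores are monotone non-increasing in the quorum", {
  set.seed(47)
  genomes <- random_genome_set(4, 200, 7, snp_rate = 0.04)
  g <- build_graph(genomes, 7)
  idx <- build_index(g, 4)
  q <- generate_query(genomes[[2]], 60, 0.03)$query
  best <- vapply(1:4, function(m) {
    seeds <- find_seeds(q, g, idx, 0:3, m)
    if (nrow(seeds) == 0) return(0L)
    max(vapply(seed_rows(seeds), function(srow) {
      h <- extend_seed(g, q, srow, sc3, 0:3, m)
      if (nrow(h) == 0) 0L else max(h$score)
    }, 1L))
  }, 1L)
  expect_true(all(diff(best) <= 0))
})

test_that("filter_hsps removes duplicates and dominated HSPs", {
  g <- toy_graph()
  vA <- which(g$labels == "ACG"); vT <- which(g$labels == "CGTT")
  big <- tibble::tibble(query_begin = 0L, query_end = 5L, score = 5L,
                        path = list(truncated_path(c(vA, vT), 0, 4)),
                        strand = "+", truncated = FALSE)
  inner <- tibble::tibble(query_begin = 1L, query_end = 4L, score = 3L,
                          path = list(truncated_path(vT, 0, 3)),
                          strand = "+", truncated = FALSE)
  vG <- which(g$labels == "CGAT")
  other <- tibble::tibble(query_begin = 3L, query_end = 5L, score = 2L,
                          path = list(truncated_path(vG, 0, 3)),
                          strand = "+", truncated = FALSE)
  hsps <- rbind(big, big, inner, other)
  out <- filter_hsps(hsps, g)
  expect_equal(nrow(out), 2)  # duplicate collapsed, inner dominated
  expect_equal(out$score, c(5L, 2L))
  # overlapping but non-nested HSPs are both kept
  a <- tibble::tibble(query_begin = 0L, query_end = 4L, score = 4L,
                      path = list(truncated_path(vT, 0, 4)), strand = "+",
                      truncated = FALSE)
  b <- tibble::tibble(query_begin = 2L, query_end = 5L, score = 3L,
                      path = list(truncated_path(vA, 0, 3)), strand = "+",
                      truncated = FALSE)
  expect_equal(nrow(filter_hsps(rbind(a, b), g)), 2)
})

test_that("the vertex budget truncates extension and flags the HSP", {
  set.seed(53)
  genomes <- random_genome_set(2, 150, 5, snp_rate = 0.05)
  g <- build_graph(genomes, 5)
  idx <- build_index(g, 3)
  q <- generate_query(genomes[[1]], 50, 0)$query
  seeds <- find_seeds(q, g, idx)
  srow <- seeds[which.max(seeds$length), ]
  unbounded <- extend_seed(g, q, srow, sc3, max_vertices = 1e9)
  bounded <- extend_seed(g, q, srow, sc3, max_vertices = 1L)
  expect_true(all(!unbounded$truncated) || any(bounded$truncated))
  expect_true(max(bounded$score) <= max(unbounded$score))
})
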