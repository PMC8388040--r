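# Search orchestration: seeding -> ungapped extension -> filtering ->
# significance selection -> gapped recomputation -> checkpoints, on both
# strands.

#' Search configuration
#'
#' @param k k-mer length of the graph (default 31)
#' @param w minimal seed length (default 11)
#' @param scoring a [scoring_scheme()]
#' @param quorum minimum number of search colors per location (default 1)
#' @param search_colors 0-based color ids (NULL: all colors of the graph)
#' @param evalue_cutoff E-value threshold for reported alignments (default
#'   0.01; NULL disables statistical filtering)
#' @param max_vertices per-seed vertex-visit budget of the extension DFS
#' @param max_results cap on reported alignments per query
#' @param band_base,band_min,band_max band formula of [choose_band()]
#' @param seed RNG seed recorded in outputs
#' @return list of class `search_config`
#' @export
search_config <- function(k = 31L, w = 11L, scoring = scoring_scheme(),
                          quorum = 1L, search_colors = NULL,
                          evalue_cutoff = 0.01, max_vertices = 1000L,
                          max_results = 100L, band_base = 8L, band_min = 8L,
                          band_max = 64L, seed = NULL) {
  if (w < 2L || w > k) stop("need 2 <= w <= k")
  if (!is.null(evalue_cutoff) && evalue_cutoff <= 0) {
    stop("evalue_cutoff must be positive")
  }
  structure(list(k = as.integer(k), w = as.integer(w), scoring = scoring,
                 quorum = as.integer(quorum), search_colors = search_colors,
                 evalue_cutoff = evalue_cutoff,
                 max_vertices = as.integer(max_vertices),
                 max_results = max_results,
                 band_base = as.integer(band_base),
                 band_min = as.integer(band_min),
                 band_max = as.integer(band_max), seed = seed),
            class = "search_config")
}

# all HSPs of one oriented query: seeds, extension, filtering
query_hsps <- function(query, graph, index, search_colors, quorum, scoring,
                       max_vertices, strand = "+") {
  seeds <- find_seeds(query, graph, index, search_colors, quorum,
                      strand = strand)
  if (nrow(seeds) == 0L) {
    return(tibble(query_begin = integer(0), query_end = integer(0),
                  score = integer(0), path = list(), strand = character(0),
                  truncated = logical(0)))
  }
  hsp_list <- lapply(seq_len(nrow(seeds)), function(i) {
    extend_seed(graph, query, seeds[i, ], scoring, search_colors, quorum,
                max_vertices)
  })
  hsps <- dplyr::bind_rows(hsp_list)
  if (nrow(hsps) > 2000L) {
    # keep the quadratic dominance filter tractable; deterministic order
    keys <- vapply(hsps$path, path_key, character(1))
    hsps <- hsps[order(-hsps$score, hsps$query_begin, keys,
                       method = "radix")[seq_len(2000L)], ]
  }
  filter_hsps(hsps, graph)
}

#' Search a query against the pangenome graph
#'
#' Runs the full pipeline on the query and its reverse complement, merges
#' the strand results and sorts by E-value (score, if no statistics are
#' supplied). Coordinates of reverse-strand alignments refer to the
#' original query orientation; their aligned sequences are reported in
#' reverse-complemented query orientation.
#'
#' @param query DNA string
#' @param graph a `cdbg`
#' @param index a `wmer_index` built from `graph` (with `w = config$w`)
#' @param config a [search_config()]
#' @param stats_ungapped,stats_gapped calibrated [stat_params()] for the
#'   two regimes; required when `config$evalue_cutoff` is not NULL
#' @param query_id identifier recorded on the output rows
#' @param both_strands search the reverse complement too (default TRUE)
#' @return tibble of alignment records (one row per reported alignment)
#' @export
run_search <- function(query, graph, index, config = search_config(),
                       stats_ungapped = NULL, stats_gapped = NULL,
                       query_id = "query", both_strands = TRUE) {
  if (index$w != config$w) stop("index w does not match config w")
  if (graph$k != config$k) stop("graph k does not match config k")
  if (!is.null(config$evalue_cutoff) &&
      (is.null(stats_ungapped) || is.null(stats_gapped))) {
    stop("E-value filtering requires calibrated ungapped and gapped statistics")
  }
  search_colors <- config$search_colors %||% (seq_len(graph$colors$size) - 1L)
  n <- nchar(query)
  strands <- if (both_strands) c("+", "-") else "+"
  res <- lapply(strands, function(st) {
    q <- if (st == "+") query else reverse_complement(query)
    hsps <- query_hsps(q, graph, index, search_colors, config$quorum,
                       config$scoring, config$max_vertices, strand = st)
    if (nrow(hsps) == 0L) return(NULL)
    if (!is.null(stats_ungapped)) {
      hsps <- select_significant(hsps, stats_ungapped, graph$M, n,
                                 config$evalue_cutoff, config$max_results)
    } else {
      hsps <- head(hsps, config$max_results)
    }
    if (nrow(hsps) == 0L) return(NULL)
    out <- recompute(hsps, graph, q, config$scoring, stats_gapped,
                     M = graph$M, n = n, search_colors = search_colors,
                     quorum = config$quorum, band_base = config$band_base,
                     band_min = config$band_min, band_max = config$band_max)
    if (!is.null(config$evalue_cutoff)) {
      out <- out[out$evalue <= config$evalue_cutoff, ]
    }
    if (st == "-" && nrow(out) > 0L) {
      qb <- out$query_begin; qe <- out$query_end
      out$query_begin <- n - qe
      out$query_end <- n - qb
    }
    out
  })
  out <- dplyr::bind_rows(res[!vapply(res, is.null, TRUE)])
  if (nrow(out) == 0L) return(out)
  ord <- if (!is.null(stats_gapped)) order(out$evalue, -out$score)
         else order(-out$score)
  out <- out[ord, ]
  if (nrow(out) > config$max_results) out <- out[seq_len(config$max_results), ]
  dplyr::bind_cols(tibble(query_id = rep(query_id, nrow(out))), out)
}

# raw HSP list of a query (no dominance filtering, no tibbles);
# calibration only needs scores, so the overhead is kept minimal
raw_hsps <- function(query, graph, index, scoring, max_vertices) {
  search <- seq_len(graph$colors$size) - 1L
  m <- index_matches(query, graph, index, search, 1L)
  s <- merge_matches_core(m$qpos, m$v, m$o, index$w)
  if (length(s$vertex) == 0L) return(list())
  ok <- quorum_ok_positions(graph, search, 1L)
  qcodes <- dna_codes(toupper(query))
  out <- list()
  for (i in seq_along(s$vertex)) {
    out <- c(out, extend_seed_core(graph, qcodes, s$query_begin[i],
                                   s$query_end[i], s$vertex[i],
                                   s$v_begin[i], s$v_end[i], scoring, ok,
                                   max_vertices))
  }
  out
}

# best ungapped score of a query (0 when no seed extends); used for
# statistical calibration, which runs without color or quorum constraints
best_ungapped_score <- function(query, graph, index, scoring, max_vertices) {
  hsps <- raw_hsps(query, graph, index, scoring, max_vertices)
  if (length(hsps) == 0L) 0L
  else max(vapply(hsps, `[[`, 1L, "score"))
}

# score-only gapped recomputation of one HSP: flank extension, banded
# global alignment, trim to the best window containing the ungapped core.
# The ungapped alignment is itself a candidate, so the result is never
# below the HSP score.
gapped_score_hsp <- function(graph, query, hsp, scoring, ok,
                             band_base = 8L, band_min = 8L, band_max = 64L) {
  t <- hsp$path
  band <- choose_band(data.frame(query_begin = hsp$query_begin,
                                 query_end = hsp$query_end,
                                 score = hsp$score),
                      scoring, band_base, band_min, band_max)
  lf <- flank_left(graph, t, ok, band)
  rf <- flank_right(graph, t, ok, band)
  t_ext <- truncated_path(t$vertices, t$begin - lf, t$end + rf)
  qb2 <- max(0L, hsp$query_begin - band)
  qe2 <- min(nchar(query), hsp$query_end + band)
  A <- substr(query, qb2 + 1L, qe2)
  B <- path_sequence(graph, t_ext)
  band_used <- max(band, abs(nchar(A) - nchar(B)))
  res <- banded_align_cpp(dna_codes(A), dna_codes(B), scoring$match,
                          scoring$mismatch, scoring$gap, band_used)
  ops <- utf8ToInt(res$transcript)  # M=77 R=82 D=68 I=73
  colsc <- integer(length(ops))
  colsc[ops == 77L] <- scoring$match
  colsc[ops == 82L] <- scoring$mismatch
  colsc[ops == 68L | ops == 73L] <- scoring$gap
  a_cons <- cumsum(ops != 73L)
  first_core <- match(hsp$query_begin - qb2 + 1L, a_cons)
  last_core <- match(hsp$query_end - qb2, a_cons)
  P <- c(0L, cumsum(colsc))
  pre_cut <- which.min(P[seq_len(first_core)]) - 1L
  post_opts <- last_core:length(ops)
  post_end <- post_opts[which.max(P[post_opts + 1L])]
  max(P[post_end + 1L] - P[pre_cut + 1L], hsp$score)
}

best_gapped_score <- function(query, graph, index, scoring, max_vertices,
                              top = 5L) {
  hsps <- raw_hsps(query, graph, index, scoring, max_vertices)
  if (length(hsps) == 0L) return(0L)
  scores <- vapply(hsps, `[[`, 1L, "score")
  hsps <- hsps[order(-scores)[seq_len(min(top, length(hsps)))]]
  ok <- quorum_ok_positions(graph, seq_len(graph$colors$size) - 1L, 1L)
  max(vapply(hsps, function(h) {
    as.integer(gapped_score_hsp(graph, query, h, scoring, ok))
  }, 1L))
}

#' Score function of the full search pipeline, for calibration
#'
#' Returns a black-box score function mapping a random query to its top
#' alignment score against the graph: the best HSP score in the ungapped
#' regime, the best recomputed banded score in the gapped regime. Searches
#' run with quorum 1 and the full color set (calibration is performed
#' without color or quorum constraints), forward strand.
#'
#' @param graph a `cdbg`
#' @param index a `wmer_index`
#' @param regime `"ungapped"` or `"gapped"`
#' @param scoring a [scoring_scheme()]
#' @param max_vertices extension budget
#' @return function(query string) -> integer score
#' @export
graph_score_fn <- function(graph, index, regime = c("ungapped", "gapped"),
                           scoring = scoring_scheme(),
                           max_vertices = 1000L) {
  regime <- match.arg(regime)
  if (regime == "ungapped") {
    function(q) best_ungapped_score(q, graph, index, scoring, max_vertices)
  } else {
    function(q) best_gapped_score(q, graph, index, scoring, max_vertices)
  }
}

#' Calibrate both score regimes on one shared query sample
#'
#' Draws iid uniform random queries once and, for each, computes the best
#' ungapped HSP score and the best banded-gapped recomputed score in a
#' single pipeline pass, then fits the exponential tail of each regime.
#' The paired design makes regime comparisons (such as the expected
#' `lambda_gapped < lambda_ungapped` ordering) insensitive to
#' sample-to-sample noise, since the gapped score of a query is never
#' below its ungapped score by construction.
#'
#' @inheritParams graph_score_fn
#' @param n calibration query length
#' @param num_samples number of random queries
#' @param top number of top HSPs recomputed for the gapped score
#' @return list with `ungapped` and `gapped` (`naive_calibration` objects
#'   sharing the query sample) and `scores` (tibble of per-query score
#'   pairs)
#' @export
calibrate_regimes <- function(graph, index, n = 100L, num_samples = 1e4,
                              scoring = scoring_scheme(),
                              max_vertices = 1000L, top = 5L) {
  search <- seq_len(graph$colors$size) - 1L
  ok <- quorum_ok_positions(graph, search, 1L)
  num_samples <- as.integer(num_samples)
  su <- integer(num_samples); sg <- integer(num_samples)
  for (i in seq_len(num_samples)) {
    q <- random_dna(1L, n)
    hsps <- raw_hsps(q, graph, index, scoring, max_vertices)
    if (length(hsps) == 0L) next
    scores <- vapply(hsps, `[[`, 1L, "score")
    su[i] <- max(scores)
    keep <- order(-scores)[seq_len(min(top, length(hsps)))]
    sg[i] <- max(vapply(hsps[keep], function(h) {
      as.integer(gapped_score_hsp(graph, q, h, scoring, ok))
    }, 1L))
  }
  wrap <- function(scores, regime) {
    fit <- fit_ccdf_tail(scores)
    params <- stat_params(fit$lam, fit$C, regime = regime,
                          M_cal = graph$M, n_cal = n,
                          provenance = "naive",
                          num_samples = num_samples)
    structure(list(params = params, scores = scores, fit = fit$points),
              class = "naive_calibration")
  }
  list(ungapped = wrap(su, "ungapped"), gapped = wrap(sg, "gapped"),
       scores = tibble(ungapped = su, gapped = sg))
}

#' Calibrate score statistics for a graph
#'
#' Convenience wrapper: builds the pipeline score function for the given
#' regime and calibrates it, either by naive sampling only or by the full
#' naive + importance-sampling pipeline.
#'
#' @inheritParams graph_score_fn
#' @param n calibration query length
#' @param num_samples naive sample count
#' @param mode `"naive"` or `"importance"`
#' @param is_samples importance samples (mode `"importance"`)
#' @return a `naive_calibration` or `is_calibration` object
#' @export
calibrate_graph <- function(graph, index, regime = c("ungapped", "gapped"),
                            n = 200L, num_samples = 1e4, mode = c("naive", "importance"),
                            is_samples = 2e4, scoring = scoring_scheme(),
                            max_vertices = 1000L) {
  regime <- match.arg(regime)
  mode <- match.arg(mode)
  fn <- graph_score_fn(graph, index, regime, scoring, max_vertices)
  if (mode == "naive") {
    naive_calibrate(fn, n, num_samples, M_cal = graph$M, regime = regime)
  } else {
    calibrate_importance(fn, n, num_samples, is_samples, M_cal = graph$M,
                         regime = regime)
  }
}
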