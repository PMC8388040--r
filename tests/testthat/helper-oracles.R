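# Brute-force oracles, independent of the package's index/DFS machinery.

# all distinct k-mers of a genome set, with their color sets, by plain
# substring scanning (vectorized, but independent of the package's
# construction machinery)
oracle_kmer_colors <- function(genomes, k) {
  km_all <- character(0); col_all <- integer(0)
  for (ci in seq_along(genomes)) {
    for (s in genomes[[ci]]) {
      if (nchar(s) < k) next
      starts <- seq_len(nchar(s) - k + 1L)
      km <- unique(substring(s, starts, starts + k - 1L))
      km_all <- c(km_all, km)
      col_all <- c(col_all, rep(ci - 1L, length(km)))
    }
  }
  keep <- !duplicated(paste(km_all, col_all))
  lapply(split(col_all[keep], km_all[keep]), function(x) sort(unique(x)))
}

# brute-force w-mer occurrence scan with the overlap suppression rule
oracle_wmer_occurrences <- function(graph, wmer) {
  w <- nchar(wmer)
  hits <- NULL
  for (v in seq_along(graph$labels)) {
    lab <- graph$labels[v]
    L <- nchar(lab)
    if (L < w) next
    for (o in 0:(L - w)) {
      if (substr(lab, o + 1L, o + w) != wmer) next
      suppressed <- o >= L - graph$k + 1L &&
        length(graph$out_edges[[v]]) > 0L
      if (!suppressed) hits <- rbind(hits, c(v, o))
    }
  }
  if (is.null(hits)) {
    data.frame(vertex = integer(0), offset = integer(0))
  } else {
    df <- data.frame(vertex = hits[, 1L], offset = hits[, 2L])
    df[order(df$vertex, df$offset), , drop = FALSE]
  }
}

# maximal exact matches of length >= w between a query and single vertex
# labels (naive O(n * sum |v|) scan)
oracle_mems <- function(query, graph, w) {
  nq <- nchar(query)
  res <- NULL
  for (v in seq_along(graph$labels)) {
    lab <- graph$labels[v]
    L <- nchar(lab)
    for (qi in 0:(nq - 1L)) {
      for (oi in 0:(L - 1L)) {
        # extendable left? then not maximal start
        if (qi > 0L && oi > 0L &&
            substr(query, qi, qi) == substr(lab, oi, oi)) next
        len <- 0L
        while (qi + len < nq && oi + len < L &&
               substr(query, qi + len + 1L, qi + len + 1L) ==
                 substr(lab, oi + len + 1L, oi + len + 1L)) {
          len <- len + 1L
        }
        if (len >= w) {
          res <- rbind(res, c(qi, qi + len, v, oi, oi + len))
        }
      }
    }
  }
  if (is.null(res)) {
    data.frame(query_begin = integer(0), query_end = integer(0),
               vertex = integer(0), v_begin = integer(0),
               v_end = integer(0))
  } else {
    df <- data.frame(query_begin = res[, 1L], query_end = res[, 2L],
                     vertex = res[, 3L], v_begin = res[, 4L],
                     v_end = res[, 5L])
    df <- unique(df)
    df[order(df$vertex, df$v_begin, df$query_begin), , drop = FALSE]
  }
}

# enumerate the sequences of all maximal truncated-path extensions from a
# seed, forward (right = TRUE) or backward, bounded by the query horizon;
# returns a character vector of extension strings (possibly ""). Instances
# whose cyclic regions spawn more than `limit` extensions signal
# "oracle_path_limit" so callers can restrict the tested instance class
# (the same kind of bound as the 12-vertex cap).
oracle_extensions <- function(graph, v, off, horizon, right, ok,
                              limit = 2000) {
  k <- graph$k
  out <- character(0)
  recur <- function(v, off, acc, left_chars) {
    if (length(out) > limit) {
      stop(structure(class = c("oracle_path_limit", "error", "condition"),
                     list(message = "path enumeration limit", call = NULL)))
    }
    lab <- graph$labels[v]
    L <- nchar(lab)
    repeat {
      if (left_chars == 0L) { out <<- c(out, acc); return(invisible()) }
      at_boundary <- if (right) off == L else off == 0L
      if (!at_boundary) {
        locpos <- if (right) off else off - 1L
        if (!ok[[v]][locpos + 1L]) { out <<- c(out, acc); return(invisible()) }
        ch <- substr(lab, locpos + 1L, locpos + 1L)
        acc <- if (right) paste0(acc, ch) else paste0(ch, acc)
        off <- off + if (right) 1L else -1L
        left_chars <- left_chars - 1L
      } else {
        nbrs <- if (right) graph$out_edges[[v]] else graph$in_edges[[v]]
        went <- FALSE
        for (wv in nbrs) {
          Lw <- nchar(graph$labels[wv])
          okw <- ok[[wv]]
          entry_ok <- if (right) all(okw[1:(k - 1L)])
                      else all(okw[(Lw - k + 2L):Lw])
          if (!entry_ok) next
          recur(wv, if (right) k - 1L else Lw - k + 1L, acc, left_chars)
          went <- TRUE
        }
        if (!went) out <<- c(out, acc)
        return(invisible())
      }
    }
  }
  recur(v, off, "", horizon)
  unique(out)
}

# brute-force oracle for one seed: enumerate all maximal truncated paths
# through the seed and apply the pairwise X-drop primitive; returns the set
# of distinct (score, query_begin, query_end) triples
oracle_extend_seed <- function(graph, query, seed, scoring, search_colors,
                               quorum) {
  ok <- pangaln:::quorum_ok_positions(graph, search_colors, quorum)
  if (!all(ok[[seed$vertex]][(seed$v_begin + 1L):seed$v_end])) {
    return(data.frame(score = integer(0), query_begin = integer(0),
                      query_end = integer(0)))
  }
  nq <- nchar(query)
  rights <- oracle_extensions(graph, seed$vertex, seed$v_end,
                              nq - seed$query_end, TRUE, ok)
  lefts <- oracle_extensions(graph, seed$vertex, seed$v_begin,
                             seed$query_begin, FALSE, ok)
  if (length(lefts) * length(rights) > 5e4) {
    stop(structure(class = c("oracle_path_limit", "error", "condition"),
                   list(message = "path combination limit", call = NULL)))
  }
  seed_str <- substr(graph$labels[seed$vertex], seed$v_begin + 1L,
                     seed$v_end)
  base <- scoring$match * nchar(seed_str)
  # anchored ungapped X-drop extension is independent per direction, so
  # score each maximal one-sided path once and combine arithmetically
  left_res <- lapply(lefts, function(lft) {
    r <- ungapped_xdrop_pair(query, paste0(lft, seed_str),
                             c(seed$query_begin, seed$query_end,
                               nchar(lft), nchar(lft) + nchar(seed_str)),
                             scoring)
    c(gain = r$score - base, qb = r$a_begin)
  })
  right_res <- lapply(rights, function(rgt) {
    r <- ungapped_xdrop_pair(query, paste0(seed_str, rgt),
                             c(seed$query_begin, seed$query_end, 0L,
                               nchar(seed_str)), scoring)
    c(gain = r$score - base, qe = r$a_end)
  })
  lg <- vapply(left_res, `[[`, 1, "gain")
  lqb <- vapply(left_res, `[[`, 1, "qb")
  rg <- vapply(right_res, `[[`, 1, "gain")
  rqe <- vapply(right_res, `[[`, 1, "qe")
  nl <- length(lg); nr <- length(rg)
  df <- unique(data.frame(
    score = base + rep(lg, times = nr) + rep(rg, each = nl),
    query_begin = rep(lqb, times = nr),
    query_end = rep(rqe, each = nl)))
  df[order(df$score, df$query_begin, df$query_end), , drop = FALSE]
}

# gapped recomputation of a top HSP against the linear genome, entirely in
# linear-sequence coordinates (no graph machinery): band from the HSP
# quality, flank extension clipped at the sequence ends, banded global
# alignment, trim to the best window containing the ungapped core, and the
# ungapped score as a floor
linear_gapped_oracle <- function(q, genome, hsp, scoring) {
  t <- hsp$path[[1]]
  band <- choose_band(hsp, scoring)
  lf <- min(band, t$begin)
  rf <- min(band, nchar(genome) - t$end)
  qb2 <- max(0L, hsp$query_begin - band)
  qe2 <- min(nchar(q), hsp$query_end + band)
  A <- substr(q, qb2 + 1L, qe2)
  B <- substr(genome, t$begin - lf + 1L, t$end + rf)
  band_used <- max(band, abs(nchar(A) - nchar(B)))
  aln <- banded_align(A, B, scoring, band_used)
  tr <- strsplit(aln$transcript, "")[[1]]
  colsc <- ifelse(tr == "M", scoring$match,
                  ifelse(tr == "R", scoring$mismatch, scoring$gap))
  a_cons <- cumsum(tr != "I")
  first_core <- match(hsp$query_begin - qb2 + 1L, a_cons)
  last_core <- match(hsp$query_end - qb2, a_cons)
  P <- c(0L, cumsum(colsc))
  pre_cut <- which.min(P[seq_len(first_core)]) - 1L
  post_opts <- last_core:length(tr)
  post_end <- post_opts[which.max(P[post_opts + 1L])]
  max(P[post_end + 1L] - P[pre_cut + 1L], hsp$score)
}

# unrestricted global alignment DP with linear gap costs (score only);
# independent of the banded C++ kernel
oracle_global_dp <- function(a, b, scoring) {
  ca <- pangaln:::dna_codes(a); cb <- pangaln:::dna_codes(b)
  la <- length(ca); lb <- length(cb)
  prev <- (0:lb) * scoring$gap
  for (i in seq_len(la)) {
    cur <- numeric(lb + 1L)
    cur[1L] <- i * scoring$gap
    for (j in seq_len(lb)) {
      d <- prev[j] + if (ca[i] == cb[j]) scoring$match else scoring$mismatch
      cur[j + 1L] <- max(d, prev[j + 1L] + scoring$gap,
                         cur[j] + scoring$gap)
    }
    prev <- cur
  }
  as.integer(prev[lb + 1L])
}

# random genome set: related genomes derived from one ancestor
random_genome_set <- function(num_genomes, len, k, snp_rate = 0.02) {
  cfg <- pangenome_sim_config(num_genomes = num_genomes, genome_length = len,
                              snp_rate = snp_rate)
  generate_pangenome(cfg, seed = sample.int(1e6, 1L))$genomes
}

toy_graph <- function() build_graph(list(g1 = "ACGTT", g2 = "ACGAT"), k = 3)

seed_rows <- function(seeds) split(seeds, seq_len(nrow(seeds)))
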