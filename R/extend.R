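# Ungapped X-drop extension of seeds along the query and all
# quorum-fulfilling truncated paths of the graph.

#' Alignment scoring scheme
#'
#' Integer match/mismatch scores, a linear (per-character) gap penalty used
#' by the gapped recomputation, and the X-drop threshold for ungapped
#' extension. The expected score of a random nucleotide pair,
#' match/4 + 3 mismatch/4, must be negative, otherwise arbitrarily long
#' high-scoring matches exist and the exponential-tail score statistics do
#' not apply.
#'
#' @param match match score (> 0)
#' @param mismatch mismatch score (< 0)
#' @param gap per-character gap penalty (< 0)
#' @param xdrop X-drop threshold (> 0): an extension direction stops once
#'   its running score falls more than `xdrop` below the best seen
#' @return an object of class `scoring_scheme`
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L, gap = -2L, xdrop = 20L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap <- as.integer(gap); xdrop <- as.integer(xdrop)
  if (match <= 0L) stop("match score must be positive")
  if (mismatch >= 0L) stop("mismatch score must be negative")
  if (gap >= 0L) stop("gap penalty must be negative")
  if (xdrop <= 0L) stop("xdrop must be positive")
  if (match / 4 + 3 * mismatch / 4 >= 0) {
    stop("expected score of a random pair must be negative ",
         "(match/4 + 3*mismatch/4 < 0)")
  }
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 xdrop = xdrop), class = "scoring_scheme")
}

#' X-drop ungapped extension of an anchor between two plain sequences
#'
#' The linear-sequence reference primitive: extends an identical anchored
#' pair of substrings left and right one character pair at a time, keeping
#' the best running score, and stops a direction once the running score
#' drops more than `xdrop` below the best.
#'
#' @param a,b DNA strings
#' @param anchor integer vector `c(a_begin, a_end, b_begin, b_end)`, 0-based
#'   half-open; the two anchored substrings must be identical
#' @param scoring a [scoring_scheme()]
#' @return list with `score`, `a_begin`, `a_end`, `b_begin`, `b_end`
#'   (0-based half-open extents of the best-scoring ungapped alignment)
#' @export
ungapped_xdrop_pair <- function(a, b, anchor, scoring) {
  ca <- dna_codes(toupper(a)); cb <- dna_codes(toupper(b))
  ab <- anchor[1L]; ae <- anchor[2L]; bb <- anchor[3L]; be <- anchor[4L]
  if (ae - ab != be - bb || ab < 0L || bb < 0L ||
      ae > length(ca) || be > length(cb)) stop("invalid anchor")
  if (!identical(ca[(ab + 1L):ae], cb[(bb + 1L):be])) {
    stop("anchored substrings differ")
  }
  m <- scoring$match; mm <- scoring$mismatch; X <- scoring$xdrop
  base <- m * (ae - ab)

  run <- 0L; best <- 0L; rext <- 0L; i <- ae; j <- be
  while (i < length(ca) && j < length(cb)) {
    run <- run + if (ca[i + 1L] == cb[j + 1L]) m else mm
    i <- i + 1L; j <- j + 1L
    if (run > best) { best <- run; rext <- i - ae }
    else if (run < best - X) break
  }
  best_r <- best

  run <- 0L; best <- 0L; lext <- 0L; i <- ab; j <- bb
  while (i > 0L && j > 0L) {
    run <- run + if (ca[i] == cb[j]) m else mm
    i <- i - 1L; j <- j - 1L
    if (run > best) { best <- run; lext <- ab - i }
    else if (run < best - X) break
  }
  best_l <- best

  list(score = base + best_l + best_r,
       a_begin = ab - lext, a_end = ae + rext,
       b_begin = bb - lext, b_end = be + rext)
}

# one direction of the graph DFS; returns list of distinct best extensions:
# each is list(gain, chain (vertices from the seed vertex outward, trimmed
# to the best extent), off (b or e in the last chain vertex), qext
# (characters of the query consumed by the best extent), truncated)
xdrop_dfs <- function(graph, qcodes, seed_v, off0, q0, right,
                      scoring, ok, max_vertices, budget_env) {
  m <- scoring$match; mm <- scoring$mismatch; X <- scoring$xdrop
  k <- graph$k
  nq <- length(qcodes)
  qlimit <- if (right) nq - q0 else q0  # query characters available
  results <- list()
  seen <- new.env(parent = emptyenv())

  record <- function(gain, chain, off, qext, trunc) {
    key <- paste(gain, qext, paste(chain, collapse = ","), off, trunc,
                 sep = "|")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      results[[length(results) + 1L]] <<-
        list(gain = gain, chain = chain, off = off, qext = qext,
             truncated = trunc)
    }
  }

  # state: chain of vertices (seed vertex first), current offset in last
  # vertex, current query cursor (0-based count of consumed characters),
  # running score, best score and the state at the best
  recurse <- function(chain, cur_off, qcur, run, best, bstate, trunc) {
    v <- chain[length(chain)]
    codes_v <- graph$codes[[v]]
    L <- length(codes_v)
    okv <- ok[[v]]
    repeat {
      boundary <- if (right) cur_off == L else cur_off == 0L
      if (!boundary) {
        if (qcur == qlimit) break
        if (right) {
          if (!okv[cur_off + 1L]) break      # location (v, cur_off)
          delta <- if (codes_v[cur_off + 1L] == qcodes[q0 + qcur + 1L]) m else mm
          cur_off <- cur_off + 1L
        } else {
          if (!okv[cur_off]) break           # location (v, cur_off - 1)
          delta <- if (codes_v[cur_off] == qcodes[q0 - qcur]) m else mm
          cur_off <- cur_off - 1L
        }
        qcur <- qcur + 1L
        run <- run + delta
        if (run > best) {
          best <- run
          bstate <- list(len = length(chain), off = cur_off, qext = qcur)
        } else if (run < best - X) break
      } else {
        if (qcur == qlimit) break
        nbrs <- if (right) graph$out_edges[[v]] else graph$in_edges[[v]]
        if (length(nbrs) == 0L) break
        descended <- FALSE
        for (wv in nbrs) {
          Lw <- length(graph$codes[[wv]])
          okw <- ok[[wv]]
          ovl_ok <- if (right) all(okw[1:(k - 1L)])
                    else all(okw[(Lw - k + 2L):Lw])
          if (!ovl_ok) next
          if (budget_env$visited >= max_vertices) {
            record(best, chain[seq_len(bstate$len)], bstate$off,
                   bstate$qext, TRUE)
            descended <- TRUE
            next
          }
          budget_env$visited <- budget_env$visited + 1L
          recurse(c(chain, wv),
                  if (right) k - 1L else Lw - k + 1L,
                  qcur, run, best, bstate, trunc)
          descended <- TRUE
        }
        if (!descended) break
        return(invisible(NULL))
      }
    }
    record(best, chain[seq_len(bstate$len)], bstate$off, bstate$qext, trunc)
    invisible(NULL)
  }

  recurse(seed_v, off0, 0L, 0L, 0L,
          list(len = 1L, off = off0, qext = 0L), FALSE)
  results
}

#' Extend a seed along the query and all quorum-fulfilling truncated paths
#'
#' Performs BLAST-style X-drop ungapped extension of a seed, rightward by
#' depth-first search over outgoing edges and leftward over incoming edges.
#' A branch is pruned when the X-drop rule triggers, when the next graph
#' location fails the quorum test in the search color set, or when the
#' per-seed vertex-visit budget is exhausted (affected HSPs carry a
#' `truncated` flag). Each maximal explored left/right branch contributes
#' its best-scoring extent; left and right bests are combined into one HSP
#' per combination.
#'
#' @param graph a `cdbg`
#' @param query DNA string
#' @param seed one-row data frame as produced by [find_seeds()]
#' @param scoring a [scoring_scheme()]
#' @inheritParams find_seeds
#' @param max_vertices per-seed budget of vertices entered during the DFS
#' @param max_hsps cap on reported left/right branch combinations per seed
#'   (highest-gain branches are kept, so the best-scoring HSPs are exact;
#'   `Inf` reports every combination — on bubble-dense homologous paths
#'   their number grows combinatorially)
#' @return tibble of HSPs with columns `query_begin`, `query_end`, `score`,
#'   `path` (list of `truncated_path`), `strand`, `truncated`
#' @export
extend_seed <- function(graph, query, seed, scoring,
                        search_colors = seq_len(graph$colors$size) - 1L,
                        quorum = 1L, max_vertices = 1000L,
                        max_hsps = 256L) {
  sc <- check_search_colors(graph, search_colors, quorum)
  if (max_vertices < 1L) stop("max_vertices must be at least 1")
  ok <- quorum_ok_positions(graph, sc$search, sc$quorum)
  out <- extend_seed_core(graph, dna_codes(toupper(query)),
                          seed$query_begin[1L], seed$query_end[1L],
                          seed$vertex[1L], seed$v_begin[1L],
                          seed$v_end[1L], scoring, ok, max_vertices,
                          max_hsps)
  tibble(
    query_begin = vapply(out, `[[`, 1L, "query_begin"),
    query_end = vapply(out, `[[`, 1L, "query_end"),
    score = vapply(out, function(x) as.integer(x$score), 1L),
    path = lapply(out, `[[`, "path"),
    strand = if (length(out)) seed$strand[1L] %||% "+" else character(0),
    truncated = vapply(out, `[[`, TRUE, "truncated")
  )
}

# plain-list workhorse behind extend_seed; `ok` is the cached per-vertex
# quorum mask for the active (search set, quorum)
extend_seed_core <- function(graph, qcodes, qb, qe, v, vb, ve, scoring, ok,
                             max_vertices, max_hsps = 256L) {
  # the seed's own locations must pass the quorum test
  if (!all(ok[[v]][(vb + 1L):ve])) return(list())

  budget <- new.env(parent = emptyenv())
  budget$visited <- 1L
  rights <- xdrop_dfs(graph, qcodes, v, ve, qe, TRUE, scoring, ok,
                      max_vertices, budget)
  lefts <- xdrop_dfs(graph, qcodes, v, vb, qb, FALSE, scoring, ok,
                     max_vertices, budget)

  if (is.finite(max_hsps) &&
      length(lefts) * length(rights) > max_hsps) {
    by_gain <- function(xs) {
      xs[order(-vapply(xs, `[[`, 1, "gain"),
               vapply(xs, `[[`, 1L, "qext"),
               vapply(xs, function(x) paste(x$chain, collapse = ","),
                      character(1)))]
    }
    lefts <- by_gain(lefts)
    rights <- by_gain(rights)
    nl <- min(length(lefts), max(1L, ceiling(sqrt(max_hsps))))
    nr <- min(length(rights), max(1L, floor(max_hsps / nl)))
    nl <- min(length(lefts), max(1L, floor(max_hsps / nr)))
    lefts <- lefts[seq_len(nl)]
    rights <- rights[seq_len(nr)]
  }

  base <- scoring$match * (qe - qb)
  out <- vector("list", length(lefts) * length(rights))
  n <- 0L
  for (lf in lefts) {
    for (rt in rights) {
      lchain <- lf$chain; rchain <- rt$chain
      verts <- c(rev(lchain[-1L]), rchain)
      p <- truncated_path(verts, lf$off, rt$off)
      n <- n + 1L
      out[[n]] <- list(query_begin = qb - lf$qext,
                       query_end = qe + rt$qext,
                       score = as.integer(base + lf$gain + rt$gain),
                       path = p,
                       truncated = lf$truncated || rt$truncated)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

path_key <- function(p) {
  paste(paste(p$vertices, collapse = ","), p$begin, p$end, sep = ":")
}

#' Deduplicate and prune dominated HSPs
#'
#' Removes exact duplicates and HSPs whose query interval and path location
#' set are both contained in those of an HSP scoring at least as high.
#' Output is ordered by (score descending, query_begin, path). The
#' containment pruning is restricted to the `containment_cap` top-scoring
#' HSPs; lower-ranked HSPs are only deduplicated (they sit below the
#' reporting horizon anyway).
#'
#' @param hsps tibble of HSPs as returned by [extend_seed()]
#' @param graph the `cdbg` the HSPs refer to
#' @param containment_cap number of top HSPs entering the pairwise
#'   containment check
#' @return filtered tibble
#' @export
filter_hsps <- function(hsps, graph, containment_cap = 200L) {
  if (nrow(hsps) == 0L) return(hsps)
  keys <- vapply(hsps$path, path_key, character(1))
  strand <- if ("strand" %in% names(hsps)) hsps$strand else rep("+", nrow(hsps))
  dup <- duplicated(data.frame(hsps$query_begin, hsps$query_end,
                               hsps$score, strand, keys))
  hsps <- hsps[!dup, ]
  keys <- keys[!dup]
  ord <- order(-hsps$score, hsps$query_begin, keys, method = "radix")
  hsps <- hsps[ord, ]
  strand <- strand[!dup][ord]

  n <- nrow(hsps)
  m <- min(n, containment_cap)
  locsets <- vector("list", m)  # computed lazily: (vertex, position) codes
  locset_of <- function(i) {
    if (is.null(locsets[[i]])) {
      pl <- path_locations_int(graph, hsps$path[[i]])
      locsets[[i]] <<- unique(pl$v * 1e6 + pl$pos)
    }
    locsets[[i]]
  }
  keep <- rep(TRUE, n)
  for (i in seq_len(m)) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (strand[i] != strand[j]) next
      if (hsps$query_begin[i] < hsps$query_begin[j] ||
          hsps$query_end[i] > hsps$query_end[j]) next
      li <- locset_of(i); lj <- locset_of(j)
      if (length(li) <= length(lj) && all(li %in% lj)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  hsps[keep, ]
}
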