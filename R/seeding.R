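# Seed detection: quorum-passing w-mer matches between query and graph,
# merged into maximal exact-match seeds.

# per-vertex logical vectors: TRUE at 0-based w-mer offset o when all w
# covered locations o..o+w-1 pass the quorum test
quorum_ok_windows <- function(graph, search_colors, quorum, w) {
  key <- paste0("w", w, "_q", quorum, "_s", paste(search_colors, collapse = ","))
  hit <- graph$cache[[key]]
  if (!is.null(hit)) return(hit)
  ok <- quorum_ok_positions(graph, search_colors, quorum)
  res <- lapply(ok, function(p) {
    L <- length(p)
    nw <- L - w + 1L
    if (nw < 1L) return(logical(0))
    acc <- rep(TRUE, nw)
    for (d in 0:(w - 1L)) acc <- acc & p[(1L + d):(nw + d)]
    acc
  })
  assign(key, res, envir = graph$cache)
  res
}

# base-vector merge of consecutive matches; returns parallel vectors of
# seed fields (used by the hot search path; merge_consecutive wraps it)
merge_matches_core <- function(qpos, v, o, w) {
  if (length(qpos) == 0L) {
    return(list(query_begin = integer(0), query_end = integer(0),
                vertex = integer(0), v_begin = integer(0),
                v_end = integer(0)))
  }
  d <- qpos - o
  ord <- order(v, d, qpos, method = "radix")
  qpos <- qpos[ord]; v <- v[ord]; o <- o[ord]; d <- d[ord]
  n <- length(qpos)
  brk <- c(TRUE, diff(qpos) != 1L | diff(v) != 0L | diff(d) != 0L)
  run <- cumsum(brk)
  first <- which(brk)
  last <- c(first[-1L] - 1L, n)
  list(query_begin = qpos[first], query_end = qpos[last] + w,
       vertex = v[first], v_begin = o[first], v_end = o[last] + w)
}

# raw retained matches of a query against the index: list of parallel
# vectors (qpos, v, o), already quorum filtered
index_matches <- function(query, graph, index, search_colors, quorum) {
  w <- index$w
  codes <- dna_codes(toupper(query))
  r <- rolling_ranks(codes, w)
  qoff <- which(!is.na(r)) - 1L
  r <- r[!is.na(r)]
  if (length(r) == 0L) return(list(qpos = integer(0), v = integer(0),
                                   o = integer(0)))
  lo <- ifelse(r == 0L, 0L, index$prof[pmax(r, 1L)])
  hi <- index$prof[r + 1L]
  cnt <- hi - lo
  if (sum(cnt) == 0L) return(list(qpos = integer(0), v = integer(0),
                                  o = integer(0)))
  idx <- sequence(cnt) + rep(lo, cnt)
  qpos <- rep(qoff, cnt)
  v <- index$occ_v[idx]; o <- index$occ_o[idx]
  trivial <- quorum == 1L && length(search_colors) == graph$colors$size
  if (!trivial) {
    okw <- quorum_ok_windows(graph, search_colors, quorum, w)
    keep <- vapply(seq_along(v), function(i) okw[[v[i]]][o[i] + 1L], TRUE)
    qpos <- qpos[keep]; v <- v[keep]; o <- o[keep]
  }
  list(qpos = qpos, v = v, o = o)
}

#' Merge consecutive w-mer matches into maximal seeds
#'
#' Matches at (query position i, vertex v, offset o) and
#' (i+1, v, o+1) belong to the same run; maximal runs become seeds of length
#' `w + run length - 1`.
#'
#' @param matches data frame with columns `qpos` (0-based query offset),
#'   `vertex`, `offset` (0-based label offset); rows must be distinct
#' @param w the w-mer length of the matches
#' @param strand `"+"` or `"-"`; recorded on the output seeds
#' @return tibble of seeds with columns `query_begin`, `query_end`,
#'   `vertex`, `v_begin`, `v_end` (all 0-based half-open), `length`,
#'   `strand`, sorted by (vertex, v_begin)
#' @export
merge_consecutive <- function(matches, w, strand = "+") {
  empty <- tibble(query_begin = integer(0), query_end = integer(0),
                  vertex = integer(0), v_begin = integer(0),
                  v_end = integer(0), length = integer(0),
                  strand = character(0))
  if (nrow(matches) == 0L) return(empty)
  dt <- data.table(qpos = as.integer(matches$qpos),
                   vertex = as.integer(matches$vertex),
                   offset = as.integer(matches$offset))
  dt <- unique(dt)
  dt[, diag := qpos - offset]
  setorder(dt, vertex, diag, qpos)
  brk <- c(TRUE, diff(dt$qpos) != 1L |
             diff(dt$vertex) != 0L | diff(dt$diag) != 0L)
  dt[, run := cumsum(brk)]
  seeds <- dt[, .(query_begin = qpos[1L], query_end = qpos[.N] + w,
                  vertex = vertex[1L], v_begin = offset[1L],
                  v_end = offset[.N] + w), by = run][, run := NULL]
  seeds[, length := query_end - query_begin]
  seeds[, strand := strand]
  setorder(seeds, vertex, v_begin)
  as_tibble(seeds)
}

#' Find quorum-passing seeds between a query and the graph
#'
#' Looks up every w-mer of the query in the occurrence index, keeps a match
#' only when all w locations of the graph it covers carry at least `quorum`
#' colors of the search color set, and merges runs of consecutive matches
#' into maximal exact-match seeds.
#'
#' @param query DNA string (length >= w)
#' @param graph a `cdbg`
#' @param index a `wmer_index` built from `graph`
#' @param search_colors 0-based color ids to restrict the search to
#'   (default: all colors)
#' @param quorum minimum number of search colors per location (default 1)
#' @param strand strand tag recorded on the seeds
#' @return tibble of seeds, see [merge_consecutive()]
#' @export
find_seeds <- function(query, graph, index,
                       search_colors = seq_len(graph$colors$size) - 1L,
                       quorum = 1L, strand = "+") {
  sc <- check_search_colors(graph, search_colors, quorum)
  w <- index$w
  if (nchar(query) < w) stop("query shorter than w")
  m <- index_matches(query, graph, index, sc$search, sc$quorum)
  s <- merge_matches_core(m$qpos, m$v, m$o, w)
  ord <- order(s$vertex, s$v_begin, method = "radix")
  tibble(query_begin = s$query_begin[ord], query_end = s$query_end[ord],
         vertex = s$vertex[ord], v_begin = s$v_begin[ord],
         v_end = s$v_end[ord],
         length = s$query_end[ord] - s$query_begin[ord],
         strand = if (length(ord)) strand else character(0))
}
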