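# PROF/OCC occurrence index over all 4^w w-mers.
#
# PROF is a cumulative profile: entry i (1-based R index) holds the number of
# stored occurrences of all w-mers with lexicographic rank < i. OCC stores the
# occurrences themselves, contiguously per w-mer, ordered by (vertex, offset).

#' Lexicographic rank of a w-mer
#'
#' Base-4 value with A=0, C=1, G=2, T=3; ranks run 0..4^w-1 in lexicographic
#' order of the w-mers.
#'
#' @param wmer DNA string over A,C,G,T
#' @return 0-based integer rank
#' @seealso [wmer_unrank()]
#' @export
wmer_rank <- function(wmer) {
  codes <- dna_codes(wmer)
  if (any(codes == 0L)) stop("w-mer contains characters outside A,C,G,T")
  r <- 0
  for (c in codes) r <- r * 4 + (c - 1L)
  as.integer(r)
}

#' Inverse of [wmer_rank()]
#' @param rank 0-based rank
#' @param w w-mer length
#' @return the w-mer string
#' @export
wmer_unrank <- function(rank, w) {
  codes <- integer(w)
  for (i in w:1) {
    codes[i] <- rank %% 4L
    rank <- rank %/% 4L
  }
  paste(.bases[codes + 1L], collapse = "")
}

# vectorized ranks of all w-mers of a code vector; NA where any position is
# not a nucleotide
rolling_ranks <- function(codes, w) {
  n <- length(codes)
  if (n < w) return(integer(0))
  nw <- n - w + 1L
  r <- numeric(nw)
  bad <- logical(nw)
  for (j in 0:(w - 1L)) {
    cc <- codes[(1L + j):(nw + j)]
    bad <- bad | cc == 0L
    r <- r * 4 + (cc - 1L)
  }
  r[bad] <- NA
  as.integer(r)
}

#' Build the w-mer occurrence index of a graph
#'
#' Stores every w-mer occurrence (vertex, 0-based offset) in every vertex
#' label, except occurrences suppressed by the overlap rule: a w-mer lying
#' entirely within the last (k-1) characters of a vertex that has at least
#' one outgoing edge is stored only in the successor vertex (where it
#' reappears in the prefix), never upstream.
#'
#' @param graph a `cdbg`
#' @param w minimal seed length, 2 <= w <= k (and at most 13, since the
#'   profile is a dense array of 4^w counters)
#' @return an object of class `wmer_index` with fields `w`, `prof`
#'   (integer vector of length 4^w, cumulative), `occ_v`, `occ_o`
#' @export
build_index <- function(graph, w) {
  w <- as.integer(w)
  if (w < 2L || w > graph$k) stop("w must satisfy 2 <= w <= k")
  if (w > 13L) stop("w > 13 would need a dense profile of more than 4^13 entries")
  nv <- length(graph$labels)
  rs <- vector("list", nv); vs <- vector("list", nv); os <- vector("list", nv)
  for (v in seq_len(nv)) {
    codes <- graph$codes[[v]]
    L <- length(codes)
    r <- rolling_ranks(codes, w)
    o <- seq_along(r) - 1L
    if (length(graph$out_edges[[v]]) > 0L) {
      keep <- o < L - graph$k + 1L
      r <- r[keep]; o <- o[keep]
    }
    rs[[v]] <- r; vs[[v]] <- rep(v, length(r)); os[[v]] <- o
  }
  r <- unlist(rs); v <- unlist(vs); o <- unlist(os)
  ord <- order(r, v, o, method = "radix")
  r <- r[ord]; v <- v[ord]; o <- o[ord]
  prof <- cumsum(tabulate(r + 1L, nbins = 4L^w))
  structure(list(w = w, k = graph$k, prof = as.integer(prof),
                 occ_v = v, occ_o = o),
            class = "wmer_index")
}

#' @export
print.wmer_index <- function(x, ...) {
  cat(sprintf("w-mer index: w = %d, %d stored occurrences\n",
              x$w, length(x$occ_v)))
  invisible(x)
}

#' Look up the stored occurrences of a w-mer
#'
#' @param index a `wmer_index`
#' @param wmer DNA string of length w
#' @return tibble with columns `vertex`, `offset` (0-based), ordered by
#'   (vertex, offset); zero rows when the w-mer does not occur
#' @export
lookup <- function(index, wmer) {
  if (nchar(wmer) != index$w) stop("w-mer must have length w = ", index$w)
  r <- wmer_rank(wmer)
  lo <- if (r == 0L) 0L else index$prof[r]
  hi <- index$prof[r + 1L]
  if (hi == lo) return(tibble(vertex = integer(0), offset = integer(0)))
  idx <- (lo + 1L):hi
  tibble(vertex = index$occ_v[idx], offset = index$occ_o[idx])
}
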