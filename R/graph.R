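#' @import data.table
NULL

# popcount lookup for 16-bit halves (color-set masks hold at most 30 bits)
.pc16 <- local({
  pc <- integer(65536L)
  for (b in 0:15) pc <- pc + bitwAnd(bitwShiftR(0:65535, b), 1L)
  pc
})

popcount32 <- function(x) {
  .pc16[bitwAnd(x, 65535L) + 1L] + .pc16[bitwShiftR(x, 16L) + 1L]
}

# maximum universe size for the integer bitmask fast path
.MASK_MAX <- 30L

decode_mask <- function(mask) {
  if (mask == 0L) return(integer(0))
  which(bitwAnd(mask, bitwShiftL(1L, 0:(.MASK_MAX - 1L))) != 0L) - 1L
}

encode_mask <- function(ids) {
  if (length(ids) == 0L) return(0L)
  sum(bitwShiftL(1L, as.integer(ids)))
}

#' Truncated graph path
#'
#' A path through the graph with the first vertex label truncated at `begin`
#' (0-based start offset) and the last at `end` (0-based exclusive end
#' offset). The spelled-out sequence splices vertex labels, dropping the
#' (k-1)-character overlap between consecutive vertices.
#'
#' @param vertices integer vector of vertex ids (1-based, in path order)
#' @param begin 0-based start offset within the first vertex label
#' @param end 0-based exclusive end offset within the last vertex label
#' @return an object of class `truncated_path`
#' @export
truncated_path <- function(vertices, begin, end) {
  vertices <- as.integer(vertices)
  if (length(vertices) == 0L) stop("a truncated path needs at least one vertex")
  structure(list(vertices = vertices, begin = as.integer(begin),
                 end = as.integer(end)),
            class = "truncated_path")
}

#' @export
format.truncated_path <- function(x, ...) {
  sprintf("<path %s [%d,%d)>", paste(x$vertices, collapse = ">"), x$begin, x$end)
}

#' @export
print.truncated_path <- function(x, ...) cat(format(x), "\n")

validate_path <- function(graph, t) {
  v <- t$vertices
  nv <- length(graph$labels)
  if (any(v < 1L | v > nv)) stop("path contains unknown vertex ids")
  if (length(v) > 1L) {
    for (i in seq_len(length(v) - 1L)) {
      if (!(v[i + 1L] %in% graph$out_edges[[v[i]]])) {
        stop("invalid path: no edge ", v[i], " -> ", v[i + 1L])
      }
    }
  }
  len1 <- nchar(graph$labels[v[1L]])
  lenz <- nchar(graph$labels[v[length(v)]])
  if (t$begin < 0L || t$begin >= len1) stop("path begin offset out of range")
  if (t$end <= 0L || t$end > lenz) stop("path end offset out of range")
  if (length(v) == 1L && t$begin >= t$end) stop("single-vertex path needs begin < end")
  invisible(t)
}

#' Build a compacted colored de Bruijn graph from genome sequences
#'
#' Vertices are unitigs (maximal non-branching paths of the node-centric
#' k-mer graph), each k-mer of the input occurs at exactly one
#' (vertex, offset), edges connect vertices whose labels overlap by k-1
#' characters, and every k-mer carries the set of genomes (colors) that
#' contain it. K-mers are indexed in the orientation in which they occur; a
#' k-mer and its reverse complement are distinct. Characters outside A,C,G,T
#' split sequences, so no k-mer spans them.
#'
#' Vertex ids are assigned deterministically by sorting unitigs by the
#' lexicographically smallest k-mer in their label, ties broken by label.
#'
#' @param genomes named list; each element is a character vector of DNA
#'   sequences belonging to one genome. Names are the genome identifiers and
#'   define color ids 0,1,... in list order.
#' @param k k-mer length, at least 2
#' @return an object of class `cdbg` with fields `k`, `labels`, `out_edges`,
#'   `in_edges`, `colors` (names, size), and `M` (total label length, the
#'   reference size used by the alignment statistics)
#' @examples
#' g <- build_graph(list(g1 = "ACGTT", g2 = "ACGAT"), k = 3)
#' g$labels
#' @export
build_graph <- function(genomes, k) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (length(genomes) == 0L) stop("empty genome list")
  if (is.null(names(genomes)) || any(!nzchar(names(genomes)))) {
    stop("genomes must be a named list (one name per genome)")
  }
  if (anyDuplicated(names(genomes))) stop("genome names must be unique")

  kmer_v <- list(); color_v <- list()
  for (ci in seq_along(genomes)) {
    seqs <- toupper(as.character(genomes[[ci]]))
    short <- nchar(seqs) < k
    if (any(short)) {
      warning("genome '", names(genomes)[ci], "': skipping ", sum(short),
              " sequence(s) shorter than k")
      seqs <- seqs[!short]
    }
    km <- unlist(lapply(seqs, extract_kmers, k = k), use.names = FALSE)
    if (length(km)) {
      km <- unique(km)
      kmer_v[[length(kmer_v) + 1L]] <- km
      color_v[[length(color_v) + 1L]] <- rep(ci - 1L, length(km))
    }
  }
  K <- sort(unique(unlist(kmer_v, use.names = FALSE)))
  n <- length(K)
  if (n == 0L) stop("no k-mers could be extracted from the input genomes")

  ncol <- length(genomes)
  use_mask <- ncol <= .MASK_MAX
  kcol_dt <- data.table(kmer = unlist(kmer_v, use.names = FALSE),
                        color = unlist(color_v, use.names = FALSE))
  if (use_mask) {
    msk <- kcol_dt[, .(mask = sum(bitwShiftL(1L, color))), by = kmer]
    kmask <- msk$mask[match(K, msk$kmer)]
    kcols <- NULL
  } else {
    cl <- kcol_dt[, .(cols = list(sort(color))), by = kmer]
    kcols <- cl$cols[match(K, cl$kmer)]
    kmask <- NULL
  }

  # node-centric k-mer graph: successors share a (k-1)-overlap
  pref <- substr(K, 1L, k - 1L)
  suf <- substr(K, 2L, k)
  by_pref <- split(seq_len(n), pref)
  by_suf <- split(seq_len(n), suf)
  out_n <- by_pref[suf]; in_n <- by_suf[pref]
  outdeg <- lengths(out_n); indeg <- lengths(in_n)
  next_id <- ifelse(outdeg == 1L, vapply(out_n, function(x)
    if (length(x) == 1L) x else NA_integer_, 1L), NA_integer_)
  pred1 <- vapply(in_n, function(x) if (length(x) == 1L) x else NA_integer_, 1L)
  is_start <- indeg != 1L | outdeg[ifelse(is.na(pred1), 1L, pred1)] != 1L
  is_start[!is.na(pred1)] <- indeg[!is.na(pred1)] != 1L |
    outdeg[pred1[!is.na(pred1)]] != 1L
  is_start[is.na(pred1) & indeg == 1L] <- TRUE  # defensive; cannot happen

  visited <- logical(n)
  chains <- list()
  walk <- function(start) {
    buf <- integer(64L); m <- 0L; cur <- start
    repeat {
      m <- m + 1L
      if (m > length(buf)) buf <- c(buf, integer(length(buf)))
      buf[m] <- cur; visited[cur] <<- TRUE
      if (outdeg[cur] != 1L) break
      nxt <- next_id[cur]
      if (indeg[nxt] != 1L || visited[nxt]) break
      cur <- nxt
    }
    buf[seq_len(m)]
  }
  for (s in which(is_start)) {
    if (!visited[s]) chains[[length(chains) + 1L]] <- walk(s)
  }
  # remaining k-mers lie on isolated cycles; break each at its smallest k-mer
  while (any(!visited)) {
    s <- which(!visited)[1L]  # K is sorted, so first unvisited is smallest
    chains[[length(chains) + 1L]] <- walk(s)
  }

  labels <- vapply(chains, function(ch) {
    if (length(ch) == 1L) K[ch[1L]]
    else paste0(K[ch[1L]], paste(substr(K[ch[-1L]], k, k), collapse = ""))
  }, character(1))
  first_kmer <- vapply(chains, function(ch) min(K[ch]), character(1))
  ord <- order(first_kmer, labels, method = "radix")
  chains <- chains[ord]; labels <- labels[ord]
  nv <- length(labels)

  # per-kmer location
  v_of <- integer(n); o_of <- integer(n)
  for (v in seq_len(nv)) {
    ch <- chains[[v]]
    v_of[ch] <- v
    o_of[ch] <- seq_along(ch) - 1L
  }
  kmap <- data.table(kmer = K, v = v_of, o = o_of, key = "kmer")

  # edges: purely sequence-defined (k-1)-overlaps between labels
  lab_pref <- substr(labels, 1L, k - 1L)
  lab_suf <- substr(labels, nchar(labels) - k + 2L, nchar(labels))
  lp_by <- split(seq_len(nv), lab_pref)
  out_edges <- lapply(lab_suf, function(s) {
    e <- lp_by[[s]]
    if (is.null(e)) integer(0) else sort(e)
  })
  ls_by <- split(seq_len(nv), lab_suf)
  in_edges <- lapply(lab_pref, function(p) {
    e <- ls_by[[p]]
    if (is.null(e)) integer(0) else sort(e)
  })

  vmask <- NULL; vcols <- NULL
  if (use_mask) {
    vmask <- lapply(chains, function(ch) kmask[ch])
  } else {
    vcols <- lapply(chains, function(ch) kcols[ch])
  }

  g <- structure(list(
    k = k,
    labels = labels,
    codes = lapply(labels, dna_codes),
    out_edges = out_edges,
    in_edges = in_edges,
    kmap = kmap,
    colors = list(names = names(genomes), size = ncol),
    vmask = vmask,
    vcols = vcols,
    M = sum(nchar(labels)),
    cache = new.env(parent = emptyenv())
  ), class = "cdbg")
  g
}

#' @export
print.cdbg <- function(x, ...) {
  cat(sprintf(
    "Compacted colored de Bruijn graph (k = %d)\n  %d vertices, %d edges, %d colors, total label length M = %d\n",
    x$k, length(x$labels), sum(lengths(x$out_edges)), x$colors$size, x$M))
  invisible(x)
}

#' Locate a k-mer in the graph
#'
#' Each k-mer occurs in at most one vertex label; returns its unique
#' occurrence or `NULL` when absent.
#'
#' @param graph a `cdbg`
#' @param kmer DNA string of length k
#' @return `NULL`, or a list with `vertex` (1-based id) and `offset`
#'   (0-based position in the label)
#' @export
locate_kmer <- function(graph, kmer) {
  if (nchar(kmer) != graph$k) stop("kmer must have length k = ", graph$k)
  .query_kmer <- kmer
  hit <- graph$kmap[list(.query_kmer), on = "kmer", nomatch = NULL]
  if (nrow(hit) == 0L) return(NULL)
  list(vertex = hit$v[1L], offset = hit$o[1L])
}

# color set of the k-mer at 0-based offset o of vertex v
kmer_colors_at <- function(graph, v, o) {
  if (!is.null(graph$vmask)) decode_mask(graph$vmask[[v]][o + 1L])
  else sort(graph$vcols[[v]][[o + 1L]])
}

# cached per-vertex location color masks (union of the masks of all k-mers
# overlapping each position); only available when the graph uses bitmasks
location_masks <- function(graph, v) {
  key <- paste0("lm", v)
  hit <- graph$cache[[key]]
  if (!is.null(hit)) return(hit)
  km <- graph$vmask[[v]]
  L <- nchar(graph$labels[v])
  k <- graph$k
  loc <- integer(L)
  nk <- L - k + 1L
  for (d in 0:(k - 1L)) {
    idx <- (1:nk) + d
    loc[idx] <- bitwOr(loc[idx], km)
  }
  assign(key, loc, envir = graph$cache)
  loc
}

#' Color set of a graph location
#'
#' The color set of location (vertex, position) is the union of the color
#' sets of all k-mers overlapping that position.
#'
#' @param graph a `cdbg`
#' @param vertex 1-based vertex id
#' @param position 0-based position within the vertex label
#' @return sorted integer vector of 0-based color ids
#' @export
location_colors <- function(graph, vertex, position) {
  L <- nchar(graph$labels[vertex])
  if (position < 0L || position >= L) stop("position out of range")
  k <- graph$k
  lo <- max(0L, position - k + 1L); hi <- min(position, L - k)
  if (!is.null(graph$vmask)) {
    m <- Reduce(bitwOr, graph$vmask[[vertex]][(lo:hi) + 1L], 0L)
    decode_mask(m)
  } else {
    sort(unique(unlist(graph$vcols[[vertex]][(lo:hi) + 1L], use.names = FALSE)))
  }
}

#' Sequence spelled by a truncated path
#'
#' Concatenates vertex labels along the path, dropping the (k-1)-character
#' overlap between consecutive vertices, and applies the begin/end
#' truncation offsets.
#'
#' @param graph a `cdbg`
#' @param t a `truncated_path`
#' @return DNA string
#' @export
path_sequence <- function(graph, t) {
  validate_path(graph, t)
  v <- t$vertices; k <- graph$k
  if (length(v) == 1L) {
    return(substr(graph$labels[v], t$begin + 1L, t$end))
  }
  first <- substr(graph$labels[v[1L]], t$begin + 1L,
                  nchar(graph$labels[v[1L]]) - k + 1L)
  mid <- if (length(v) > 2L) {
    ints <- v[-c(1L, length(v))]
    paste(substr(graph$labels[ints], 1L, nchar(graph$labels[ints]) - k + 1L),
          collapse = "")
  } else ""
  last <- substr(graph$labels[v[length(v)]], 1L, t$end)
  paste0(first, mid, last)
}

# internal: locations of a truncated path as parallel integer vectors
# (vertex, 0-based position); overlap characters appear in both flanking
# vertices, matching the union definition of the path location
path_locations_int <- function(graph, t) {
  v <- t$vertices
  lens <- nchar(graph$labels)[v]
  if (length(v) == 1L) {
    pos <- t$begin:(t$end - 1L)
    return(list(v = rep(v, length(pos)), pos = pos))
  }
  vs <- list(); ps <- list()
  vs[[1L]] <- rep(v[1L], lens[1L] - t$begin)
  ps[[1L]] <- t$begin:(lens[1L] - 1L)
  if (length(v) > 2L) {
    for (i in 2:(length(v) - 1L)) {
      vs[[i]] <- rep(v[i], lens[i])
      ps[[i]] <- 0:(lens[i] - 1L)
    }
  }
  z <- length(v)
  vs[[z]] <- rep(v[z], t$end)
  ps[[z]] <- 0:(t$end - 1L)
  list(v = unlist(vs), pos = unlist(ps))
}

#' Locations covered by a truncated path
#'
#' Every (vertex, position) pair belonging to the path: all of the first
#' vertex from `begin`, all positions of interior vertices, and positions up
#' to `end` of the last vertex. The (k-1)-overlap characters between
#' consecutive vertices contribute locations in both flanking vertices, so
#' the number of locations is `nchar(path_sequence(t)) + (z)*(k-1)` for a
#' path over z+1 vertices.
#'
#' @inheritParams path_sequence
#' @return tibble with columns `vertex`, `position`
#' @export
path_locations <- function(graph, t) {
  validate_path(graph, t)
  pl <- path_locations_int(graph, t)
  tibble(vertex = pl$v, position = pl$pos)
}

# cached per-vertex logical vectors: position passes the quorum test in the
# given search color set
quorum_ok_positions <- function(graph, search_colors, quorum) {
  key <- paste0("q", quorum, "_s", paste(search_colors, collapse = ","))
  hit <- graph$cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- graph$k
  nv <- length(graph$labels)
  res <- vector("list", nv)
  if (!is.null(graph$vmask)) {
    smask <- encode_mask(search_colors)
    for (v in seq_len(nv)) {
      km <- bitwAnd(graph$vmask[[v]], smask)
      L <- nchar(graph$labels[v])
      loc <- integer(L)
      nk <- L - k + 1L
      for (d in 0:(k - 1L)) {
        idx <- (1:nk) + d
        loc[idx] <- bitwOr(loc[idx], km)
      }
      res[[v]] <- popcount32(loc) >= quorum
    }
  } else {
    for (v in seq_len(nv)) {
      L <- nchar(graph$labels[v])
      ok <- logical(L)
      for (i in 0:(L - 1L)) {
        ok[i + 1L] <- length(intersect(location_colors(graph, v, i),
                                       search_colors)) >= quorum
      }
      res[[v]] <- ok
    }
  }
  assign(key, res, envir = graph$cache)
  res
}

check_search_colors <- function(graph, search_colors, quorum) {
  search_colors <- sort(unique(as.integer(search_colors)))
  if (length(search_colors) == 0L) stop("search color set must be non-empty")
  if (any(search_colors < 0L | search_colors >= graph$colors$size)) {
    stop("search colors must be within 0..", graph$colors$size - 1L)
  }
  quorum <- as.integer(quorum)
  if (quorum < 1L || quorum > length(search_colors)) {
    stop("quorum must be between 1 and |search color set| = ",
         length(search_colors))
  }
  list(search = search_colors, quorum = quorum)
}

#' Does a truncated path fulfill the quorum?
#'
#' A path is quorum fulfilling when every one of its locations is covered by
#' at least `quorum` colors of the search color set.
#'
#' @inheritParams path_sequence
#' @param search_colors integer vector of 0-based color ids to restrict the
#'   search to
#' @param quorum minimum number of search colors required at every location
#' @return logical scalar
#' @export
is_quorum_fulfilling <- function(graph, t, search_colors, quorum) {
  sc <- check_search_colors(graph, search_colors, quorum)
  validate_path(graph, t)
  ok <- quorum_ok_positions(graph, sc$search, sc$quorum)
  pl <- path_locations_int(graph, t)
  for (i in seq_along(pl$v)) {
    if (!ok[[pl$v[i]]][pl$pos[i] + 1L]) return(FALSE)
  }
  TRUE
}
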