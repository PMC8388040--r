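# Ranking of HSPs by significance, banded gapped recomputation, and
# color-set checkpoints along the final paths.

#' Rank HSPs by E-value and keep the significant ones
#'
#' @param hsps tibble of HSPs ([extend_seed()] / [filter_hsps()])
#' @param params calibrated ungapped [stat_params()]
#' @param M graph size (total label length)
#' @param n query length
#' @param evalue_cutoff keep HSPs with E <= cutoff (NULL: keep all)
#' @param max_results cap on the number of HSPs returned
#' @return the HSP tibble with an `evalue` column, sorted by ascending
#'   E-value (ties by query_begin, then path)
#' @export
select_significant <- function(hsps, params, M, n, evalue_cutoff = 0.01,
                               max_results = Inf) {
  if (!inherits(params, "stat_params")) {
    stop("calibrated ungapped stat_params are required to rank HSPs")
  }
  if (nrow(hsps) == 0L) {
    hsps$evalue <- numeric(0)
    return(hsps)
  }
  hsps$evalue <- evalue(hsps$score, params, M, n)
  keys <- vapply(hsps$path, path_key, character(1))
  ord <- order(hsps$evalue, hsps$query_begin, keys, method = "radix")
  hsps <- hsps[ord, ]
  if (!is.null(evalue_cutoff)) hsps <- hsps[hsps$evalue <= evalue_cutoff, ]
  if (nrow(hsps) > max_results) hsps <- hsps[seq_len(max_results), ]
  hsps
}

#' Band width for the gapped recomputation of an HSP
#'
#' `band = clamp(base + ceil(fraction_nonidentity * length), min, max)`:
#' low-quality (mismatch-rich) HSPs get a wider band. The number of
#' mismatches is recovered from the ungapped score.
#'
#' @param hsp one-row HSP data frame (columns `score`, `query_begin`,
#'   `query_end`)
#' @param scoring the [scoring_scheme()] the HSP was scored with
#' @param base,min_band,max_band band formula parameters
#' @return integer band width
#' @export
choose_band <- function(hsp, scoring, base = 8L, min_band = 8L,
                        max_band = 64L) {
  len <- hsp$query_end[1L] - hsp$query_begin[1L]
  mm <- (scoring$match * len - hsp$score[1L]) /
    (scoring$match - scoring$mismatch)
  band <- base + as.integer(ceiling(mm))
  as.integer(min(max(band, min_band), max_band))
}

#' Banded global alignment with linear gap costs
#'
#' Global alignment of two sequences restricted to the diagonal band
#' `|i - j - delta| <= band`, with `delta` centering the band between the
#' two corners. Equal to unrestricted dynamic programming whenever the band
#' covers the unrestricted optimum's diagonal range.
#'
#' @param a,b DNA strings
#' @param scoring a [scoring_scheme()] (linear gap cost `gap` per gap
#'   character)
#' @param band band half-width (>= 1)
#' @return list with `score`, `aligned_a`, `aligned_b` (gapped with `-`),
#'   and `transcript` over M (match), R (mismatch), D (gap in b), I (gap
#'   in a)
#' @export
banded_align <- function(a, b, scoring, band) {
  if (band < 1L) stop("band must be at least 1")
  ca <- dna_codes(toupper(a)); cb <- dna_codes(toupper(b))
  res <- banded_align_cpp(ca, cb, scoring$match, scoring$mismatch,
                          scoring$gap, as.integer(band))
  tr <- strsplit(res$transcript, "", fixed = TRUE)[[1L]]
  av <- character(length(tr)); bv <- character(length(tr))
  i <- 0L; j <- 0L
  for (t in seq_along(tr)) {
    op <- tr[t]
    if (op == "M" || op == "R") {
      i <- i + 1L; j <- j + 1L
      av[t] <- .bases[ca[i]]; bv[t] <- .bases[cb[j]]
    } else if (op == "D") {
      i <- i + 1L
      av[t] <- .bases[ca[i]]; bv[t] <- "-"
    } else {
      j <- j + 1L
      av[t] <- "-"; bv[t] <- .bases[cb[j]]
    }
  }
  list(score = as.integer(res$score),
       aligned_a = paste(av, collapse = ""),
       aligned_b = paste(bv, collapse = ""),
       transcript = res$transcript)
}

# owner decomposition of a path sequence: for each character of lambda(t),
# the (vertex, label position) that owns it (overlap characters belong to
# the downstream vertex); returns chain index, vertex and label position
path_owners <- function(graph, t) {
  v <- t$vertices; k <- graph$k
  lens <- nchar(graph$labels)[v]
  if (length(v) == 1L) {
    pos <- t$begin:(t$end - 1L)
    return(list(chain = rep(1L, length(pos)), vertex = rep(v, length(pos)),
                pos = pos))
  }
  chain <- list(); vert <- list(); pos <- list()
  n0 <- lens[1L] - k + 1L - t$begin  # characters owned by the first vertex
  chain[[1L]] <- rep(1L, n0); vert[[1L]] <- rep(v[1L], n0)
  pos[[1L]] <- if (n0 > 0L) t$begin:(lens[1L] - k) else integer(0)
  if (length(v) > 2L) {
    for (i in 2:(length(v) - 1L)) {
      ni <- lens[i] - k + 1L
      chain[[i]] <- rep(i, ni); vert[[i]] <- rep(v[i], ni)
      pos[[i]] <- 0:(lens[i] - k)
    }
  }
  z <- length(v)
  chain[[z]] <- rep(z, t$end); vert[[z]] <- rep(v[z], t$end)
  pos[[z]] <- 0:(t$end - 1L)
  list(chain = unlist(chain), vertex = unlist(vert), pos = unlist(pos))
}

#' Color-set checkpoints of a truncated path
#'
#' Assigns every character of the path sequence the color set (restricted
#' to the search color set) of its owning location and reports the starts
#' of maximal runs of equal color sets. The checkpoints partition the path;
#' adjacent checkpoints carry different color sets and every color set has
#' at least `quorum` members.
#'
#' @inheritParams is_quorum_fulfilling
#' @return tibble with `path_offset` (0-based start in the path sequence),
#'   `colors` (list of 0-based color id vectors), `n_colors`
#' @export
compute_checkpoints <- function(graph, t, search_colors, quorum) {
  sc <- check_search_colors(graph, search_colors, quorum)
  if (!is_quorum_fulfilling(graph, t, sc$search, sc$quorum)) {
    stop("path is not quorum fulfilling")
  }
  own <- path_owners(graph, t)
  nloc <- length(own$vertex)
  if (!is.null(graph$vmask)) {
    smask <- encode_mask(sc$search)
    msk <- integer(nloc)
    for (v in unique(own$vertex)) {
      sel <- own$vertex == v
      msk[sel] <- location_masks(graph, v)[own$pos[sel] + 1L]
    }
    msearch <- bitwAnd(msk, smask)
    starts <- which(c(TRUE, diff(msearch) != 0L))
    sets <- lapply(msearch[starts], decode_mask)
  } else {
    sets_all <- vector("list", nloc)
    for (i in seq_len(nloc)) {
      sets_all[[i]] <- intersect(
        location_colors(graph, own$vertex[i], own$pos[i]), sc$search)
    }
    keysets <- vapply(sets_all, paste, character(1), collapse = ",")
    starts <- which(c(TRUE, keysets[-1L] != keysets[-nloc]))
    sets <- sets_all[starts]
  }
  tibble(path_offset = starts - 1L,
         colors = sets,
         n_colors = lengths(sets))
}

# quorum-limited flank extension along the end vertices of a path:
# how far can begin decrease / end increase while staying in the first/last
# vertex and passing the quorum test
flank_left <- function(graph, t, ok, flank) {
  b <- t$begin
  lim <- min(flank, b)
  okv <- ok[[t$vertices[1L]]]
  ext <- 0L
  while (ext < lim && okv[b - ext]) ext <- ext + 1L
  ext
}

flank_right <- function(graph, t, ok, flank) {
  vz <- t$vertices[length(t$vertices)]
  L <- nchar(graph$labels[vz])
  e <- t$end
  lim <- min(flank, L - e)
  okv <- ok[[vz]]
  ext <- 0L
  while (ext < lim && okv[e + ext + 1L]) ext <- ext + 1L
  ext
}

# per-column scores of a transcript
transcript_scores <- function(tr, scoring) {
  vapply(tr, function(op) switch(op, M = scoring$match,
                                 R = scoring$mismatch,
                                 scoring$gap), 1L, USE.NAMES = FALSE)
}

#' Gapped recomputation of significant HSPs
#'
#' Re-aligns each selected HSP with banded gapped dynamic programming. The
#' query substring and the path sequence are extended by up to one band
#' width on each side (clipped at the query ends, the path's end vertices
#' and the quorum boundary), globally aligned within the band, and the
#' alignment is then trimmed to its best-scoring window containing the
#' ungapped core, so that junk flanks never penalize the reported score.
#' Gapped E-values/p-values and color checkpoints are attached.
#'
#' @param hsps selected HSP tibble ([select_significant()], or any HSP
#'   tibble when `params` is NULL)
#' @param graph a `cdbg`
#' @param query the query string the HSPs belong to
#' @param scoring a [scoring_scheme()]
#' @param params calibrated gapped [stat_params()], or NULL to skip
#'   E-values
#' @param M,n reference size and query length for the E-value
#' @inheritParams find_seeds
#' @param band_base,band_min,band_max band formula, see [choose_band()]
#' @return tibble of gapped results sorted by E-value (score when `params`
#'   is NULL): query interval, `score`, `evalue`, `pvalue`, `path`,
#'   `aligned_query`, `aligned_target`, `transcript`, `pct_identity`,
#'   `align_length`, `band`, `checkpoints`, `strand`
#' @export
recompute <- function(hsps, graph, query, scoring, params = NULL,
                      M = graph$M, n = nchar(query),
                      search_colors = seq_len(graph$colors$size) - 1L,
                      quorum = 1L, band_base = 8L, band_min = 8L,
                      band_max = 64L) {
  sc <- check_search_colors(graph, search_colors, quorum)
  ok <- quorum_ok_positions(graph, sc$search, sc$quorum)
  rows <- vector("list", nrow(hsps))
  for (hi in seq_len(nrow(hsps))) {
    hsp <- hsps[hi, ]
    t <- hsp$path[[1L]]
    band <- choose_band(hsp, scoring, band_base, band_min, band_max)
    lf <- flank_left(graph, t, ok, band)
    rf <- flank_right(graph, t, ok, band)
    t_ext <- truncated_path(t$vertices, t$begin - lf, t$end + rf)
    qb2 <- max(0L, hsp$query_begin - band)
    qe2 <- min(nchar(query), hsp$query_end + band)
    A <- substr(query, qb2 + 1L, qe2)
    B <- path_sequence(graph, t_ext)
    band_used <- max(band, abs(nchar(A) - nchar(B)))
    aln <- banded_align(A, B, scoring, band_used)
    tr <- strsplit(aln$transcript, "", fixed = TRUE)[[1L]]
    colsc <- transcript_scores(tr, scoring)
    a_cons <- cumsum(tr != "I")   # query characters consumed through column
    b_cons <- cumsum(tr != "D")
    core_a_begin <- hsp$query_begin - qb2   # 0-based within A
    core_a_end <- hsp$query_end - qb2
    first_core <- match(core_a_begin + 1L, a_cons)
    last_core <- match(core_a_end, a_cons)
    P <- c(0L, cumsum(colsc))
    pre_cut <- which.min(P[seq_len(first_core)]) - 1L  # drop columns 1..pre_cut
    post_opts <- last_core:length(tr)
    post_end <- post_opts[which.max(P[post_opts + 1L])]
    win <- (pre_cut + 1L):post_end
    score <- P[post_end + 1L] - P[pre_cut + 1L]

    if (score < hsp$score) {
      # the banded realignment did not improve on the ungapped alignment;
      # keep the ungapped one (its diagonal is a feasible gapped solution)
      qsub <- substr(query, hsp$query_begin + 1L, hsp$query_end)
      tsub <- path_sequence(graph, t)
      ops <- ifelse(strsplit(qsub, "")[[1L]] == strsplit(tsub, "")[[1L]],
                    "M", "R")
      ckp <- compute_checkpoints(graph, t, sc$search, sc$quorum)
      ev <- if (!is.null(params)) evalue(hsp$score, params, M, n) else NA_real_
      rows[[hi]] <- list(
        query_begin = hsp$query_begin, query_end = hsp$query_end,
        score = hsp$score, evalue = ev,
        pvalue = if (!is.null(params)) pvalue_from_evalue(ev) else NA_real_,
        path = t, aligned_query = qsub, aligned_target = tsub,
        transcript = paste(ops, collapse = ""),
        pct_identity = 100 * sum(ops == "M") / length(ops),
        align_length = length(ops), band = band_used,
        checkpoints = ckp, strand = hsp$strand %||% "+",
        truncated = isTRUE(hsp$truncated))
      next
    }

    qb_f <- qb2 + (if (pre_cut > 0L) a_cons[pre_cut] else 0L)
    qe_f <- qb2 + a_cons[post_end]
    b_off_first <- if (pre_cut > 0L) b_cons[pre_cut] else 0L  # B chars dropped
    b_off_last <- b_cons[post_end]                            # B chars kept through
    if (b_off_last <= b_off_first) {
      stop("degenerate gapped realignment: no target characters in the core")
    }
    own <- path_owners(graph, t_ext)
    first_char <- b_off_first + 1L
    last_char <- b_off_last
    ci1 <- own$chain[first_char]; ci2 <- own$chain[last_char]
    t_f <- truncated_path(t_ext$vertices[ci1:ci2],
                          own$pos[first_char],
                          own$pos[last_char] + 1L)

    trw <- tr[win]
    nmatch <- sum(trw == "M")
    alen <- length(trw)
    ev <- if (!is.null(params)) evalue(score, params, M, n) else NA_real_
    pv <- if (!is.null(params)) pvalue_from_evalue(ev) else NA_real_
    ckp <- compute_checkpoints(graph, t_f, sc$search, sc$quorum)

    rows[[hi]] <- list(
      query_begin = qb_f, query_end = qe_f, score = score,
      evalue = ev, pvalue = pv, path = t_f,
      aligned_query = substr(aln$aligned_a, pre_cut + 1L, post_end),
      aligned_target = substr(aln$aligned_b, pre_cut + 1L, post_end),
      transcript = paste(trw, collapse = ""),
      pct_identity = 100 * nmatch / alen,
      align_length = alen, band = band_used,
      checkpoints = ckp,
      strand = hsp$strand %||% "+",
      truncated = isTRUE(hsp$truncated)
    )
  }
  out <- tibble(
    query_begin = vapply(rows, `[[`, 1L, "query_begin"),
    query_end = vapply(rows, `[[`, 1L, "query_end"),
    score = vapply(rows, function(r) as.integer(r$score), 1L),
    evalue = vapply(rows, `[[`, 1, "evalue"),
    pvalue = vapply(rows, `[[`, 1, "pvalue"),
    path = lapply(rows, `[[`, "path"),
    aligned_query = vapply(rows, `[[`, "", "aligned_query"),
    aligned_target = vapply(rows, `[[`, "", "aligned_target"),
    transcript = vapply(rows, `[[`, "", "transcript"),
    pct_identity = vapply(rows, `[[`, 1, "pct_identity"),
    align_length = vapply(rows, `[[`, 1L, "align_length"),
    band = vapply(rows, `[[`, 1L, "band"),
    checkpoints = lapply(rows, `[[`, "checkpoints"),
    strand = vapply(rows, `[[`, "", "strand"),
    truncated = vapply(rows, `[[`, TRUE, "truncated")
  )
  if (nrow(out) > 0L) {
    ord <- if (!is.null(params)) order(out$evalue, out$query_begin)
           else order(-out$score, out$query_begin)
    out <- out[ord, ]
  }
  out
}
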