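# File formats: FASTA input, GFA 1.0 + color table serialization of the
# graph, JSON serialization of the index and statistics, TSV results.

#' Read a (multi-)FASTA file
#'
#' @param path FASTA file (gzip allowed)
#' @return tibble with columns `id` (first word of the header) and `seq`
#'   (upper-cased)
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[[`, "", 1L)
  tibble(id = ids, seq = unname(toupper(as.character(x))))
}

#' Read one FASTA file per genome into a genome list
#'
#' Genome names are the file stems; list order defines color ids 0,1,...
#' @param paths character vector of FASTA paths
#' @return named list of character vectors, ready for [build_graph()]
#' @export
read_genomes <- function(paths) {
  stems <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(paths))
  out <- lapply(paths, function(p) read_fasta(p)$seq)
  names(out) <- stems
  out
}

#' Write / read the graph as GFA 1.0 with color sidecar tables
#'
#' S-lines carry the unitig labels, L-lines the (k-1)M overlaps; the header
#' records k. `colors_path` gets one row per k-mer (k-mer, comma-separated
#' 0-based color ids); `names_path` maps color ids to genome names.
#'
#' @param graph a `cdbg`
#' @param gfa_path,colors_path,names_path output paths
#' @return invisibly, the gfa path
#' @export
write_gfa <- function(graph, gfa_path, colors_path, names_path) {
  con <- file(gfa_path, "w")
  on.exit(close(con))
  writeLines(sprintf("H\tVN:Z:1.0\tKL:i:%d", graph$k), con)
  writeLines(sprintf("S\t%d\t%s", seq_along(graph$labels), graph$labels), con)
  ov <- sprintf("%dM", graph$k - 1L)
  for (v in seq_along(graph$out_edges)) {
    for (w in graph$out_edges[[v]]) {
      writeLines(sprintf("L\t%d\t+\t%d\t+\t%s", v, w, ov), con)
    }
  }
  km <- graph$kmap
  ids <- vapply(seq_len(nrow(km)), function(i) {
    paste(kmer_colors_at(graph, km$v[i], km$o[i]), collapse = ",")
  }, character(1))
  data.table::fwrite(data.table(kmer = km$kmer, colors = ids), colors_path,
                     sep = "\t")
  data.table::fwrite(data.table(id = seq_len(graph$colors$size) - 1L,
                                name = graph$colors$names), names_path,
                     sep = "\t")
  invisible(gfa_path)
}

#' @rdname write_gfa
#' @export
read_gfa <- function(gfa_path, colors_path, names_path) {
  lines <- readLines(gfa_path)
  tags <- strsplit(lines, "\t", fixed = TRUE)
  types <- vapply(tags, `[[`, "", 1L)
  h <- tags[[which(types == "H")[1L]]]
  kfield <- grep("^KL:i:", h, value = TRUE)
  if (length(kfield) == 0L) stop("GFA header lacks the KL:i: k-mer tag")
  k <- as.integer(sub("^KL:i:", "", kfield[1L]))
  s <- tags[types == "S"]
  sid <- vapply(s, function(x) as.integer(x[2L]), 1L)
  labels <- vapply(s, `[[`, "", 3L)[order(sid)]
  nm <- data.table::fread(names_path, sep = "\t", colClasses = list(
    integer = "id", character = "name"))
  cl <- data.table::fread(colors_path, sep = "\t",
                          colClasses = list(character = c("kmer", "colors")))
  rebuild_graph(labels, k, nm$name[order(nm$id)], cl$kmer, cl$colors)
}

# reconstruct a cdbg object from labels + per-kmer color strings
rebuild_graph <- function(labels, k, color_names, kmers, color_strings) {
  nv <- length(labels)
  ncol <- length(color_names)
  col_list <- lapply(strsplit(color_strings, ",", fixed = TRUE), as.integer)
  cmap <- data.table(kmer = kmers, ci = seq_along(kmers), key = "kmer")

  v_all <- list(); o_all <- list(); km_all <- list()
  for (v in seq_len(nv)) {
    km <- extract_kmers(labels[v], k)
    km_all[[v]] <- km
    v_all[[v]] <- rep(v, length(km))
    o_all[[v]] <- seq_along(km) - 1L
  }
  kmap <- data.table(kmer = unlist(km_all), v = unlist(v_all),
                     o = unlist(o_all), key = "kmer")
  use_mask <- ncol <= .MASK_MAX
  # per-vertex color structures in label-offset order
  ci_of <- function(km) {
    ci <- cmap[list(km), on = "kmer"]$ci
    if (anyNA(ci)) stop("color table misses graph k-mers")
    ci
  }
  if (use_mask) {
    vmask <- lapply(km_all, function(km) {
      vapply(col_list[ci_of(km)], encode_mask, 1L)
    })
    vcols <- NULL
  } else {
    vmask <- NULL
    vcols <- lapply(km_all, function(km) col_list[ci_of(km)])
  }
  lab_pref <- substr(labels, 1L, k - 1L)
  lab_suf <- substr(labels, nchar(labels) - k + 2L, nchar(labels))
  lp_by <- split(seq_len(nv), lab_pref)
  out_edges <- lapply(lab_suf, function(s) {
    e <- lp_by[[s]]; if (is.null(e)) integer(0) else sort(e)
  })
  ls_by <- split(seq_len(nv), lab_suf)
  in_edges <- lapply(lab_pref, function(p) {
    e <- ls_by[[p]]; if (is.null(e)) integer(0) else sort(e)
  })
  structure(list(k = k, labels = labels,
                 codes = lapply(labels, dna_codes),
                 out_edges = out_edges, in_edges = in_edges, kmap = kmap,
                 colors = list(names = color_names, size = ncol),
                 vmask = vmask, vcols = vcols,
                 M = sum(nchar(labels)),
                 cache = new.env(parent = emptyenv())),
            class = "cdbg")
}

#' Serialize / load the w-mer index as versioned JSON
#' @param index a `wmer_index`
#' @param path output path
#' @export
write_index <- function(index, path) {
  jsonlite::write_json(list(format = "pangaln-index", version = 1L,
                            w = index$w, k = index$k, prof = index$prof,
                            occ_v = index$occ_v, occ_o = index$occ_o),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "pangaln-index")) stop("not a pangaln index file")
  structure(list(w = as.integer(x$w), k = as.integer(x$k),
                 prof = as.integer(x$prof), occ_v = as.integer(x$occ_v),
                 occ_o = as.integer(x$occ_o)),
            class = "wmer_index")
}

#' Serialize / load calibrated statistics as JSON
#' @param params a [stat_params()]
#' @param path output path
#' @param seed RNG seed used during calibration (recorded)
#' @export
write_stats <- function(params, path, seed = NA_integer_) {
  jsonlite::write_json(list(format = "pangaln-stats", version = 1L,
                            regime = params$regime, lambda = params$lam,
                            C = params$C, K = params$K,
                            M_cal = params$M_cal, n_cal = params$n_cal,
                            provenance = params$provenance,
                            lambda0 = params$lambda0,
                            num_samples = params$num_samples, seed = seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stats
#' @export
read_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "pangaln-stats")) stop("not a pangaln stats file")
  stat_params(x$lambda, x$C, regime = x$regime, M_cal = x$M_cal,
              n_cal = x$n_cal, provenance = x$provenance,
              lambda0 = x$lambda0 %||% NA_real_,
              num_samples = x$num_samples %||% NA_integer_)
}

format_checkpoints <- function(ckp) {
  paste(sprintf("%d:%s", ckp$path_offset + 1L,
                vapply(ckp$colors, paste, character(1), collapse = ",")),
        collapse = ";")
}

#' Write alignment records as TSV
#'
#' One row per alignment; coordinates are 1-based inclusive. The `path`
#' column lists the vertex ids joined by `>` with the (1-based) begin
#' offset in the first and end offset in the last vertex; checkpoints are
#' `offset:color-ids` pairs (1-based path offsets) joined by `;`. Header
#' comment lines record the configuration.
#'
#' @param records tibble from [run_search()]
#' @param path output path
#' @param config the [search_config()] used (recorded in the header)
#' @param graph the graph (its size M is recorded)
#' @export
write_results <- function(records, path, config = NULL, graph = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(sprintf(
      "# pangaln results; k=%d w=%d match=%d mismatch=%d gap=%d xdrop=%d quorum=%d evalue_cutoff=%s seed=%s",
      config$k, config$w, config$scoring$match, config$scoring$mismatch,
      config$scoring$gap, config$scoring$xdrop, config$quorum,
      format(config$evalue_cutoff %||% NA), format(config$seed %||% NA)),
      con)
  }
  if (!is.null(graph)) {
    writeLines(sprintf("# graph: %d vertices, M=%d, %d colors",
                       length(graph$labels), graph$M, graph$colors$size), con)
  }
  header <- c("query_id", "strand", "query_start", "query_end", "path",
              "score", "evalue", "pvalue", "pct_identity", "align_length",
              "checkpoints")
  writeLines(paste(header, collapse = "\t"), con)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    t <- r$path[[1L]]
    pstr <- sprintf("%s[%d..%d]", paste(t$vertices, collapse = ">"),
                    t$begin + 1L, t$end)
    writeLines(paste(c(r$query_id, r$strand, r$query_begin + 1L,
                       r$query_end, pstr, r$score,
                       formatC(r$evalue, format = "g", digits = 6),
                       formatC(r$pvalue, format = "g", digits = 6),
                       sprintf("%.2f", r$pct_identity), r$align_length,
                       format_checkpoints(r$checkpoints[[1L]])),
                     collapse = "\t"), con)
  }
  invisible(path)
}
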