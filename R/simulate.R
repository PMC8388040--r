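# Synthetic pangenomes, queries with planted homologies, and a synthetic
# exponential-tail score function, so that every pipeline stage can be
# exercised with known ground truth.

#' Configuration for the pangenome simulator
#'
#' A uniform random ancestral sequence is drawn and each genome is derived
#' from it by iid substitutions and (optionally) short indels, emulating a
#' pangenome of strongly related, highly similar genomes.
#'
#' @param num_genomes number of genomes (colors)
#' @param genome_length ancestral sequence length in bp
#' @param snp_rate per-site substitution probability per genome
#' @param indel_rate per-site indel probability per genome (default 0:
#'   substitution-only pangenomes keep the graph's truncated-path structure
#'   small, which the exact oracles rely on; turn on for robustness tests)
#' @param indel_geom_p geometric length parameter for indels (mean length
#'   `1/indel_geom_p`)
#' @return list of class `pangenome_sim_config`
#' @export
pangenome_sim_config <- function(num_genomes = 5L, genome_length = 50000L,
                                 snp_rate = 0.01, indel_rate = 0,
                                 indel_geom_p = 0.5) {
  stopifnot(num_genomes >= 1L, genome_length >= 2L,
            snp_rate >= 0, snp_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            indel_geom_p > 0, indel_geom_p <= 1)
  structure(list(num_genomes = as.integer(num_genomes),
                 genome_length = as.integer(genome_length),
                 snp_rate = snp_rate, indel_rate = indel_rate,
                 indel_geom_p = indel_geom_p),
            class = "pangenome_sim_config")
}

#' Simulate a pangenome
#'
#' @param cfg a [pangenome_sim_config()]
#' @param seed integer seed; the simulation is deterministic given the seed
#' @return list with `genomes` (named list of sequences, names `g1..gN`),
#'   `ancestor`, and `mutations` (tibble log with genome, type, 1-based
#'   ancestral position, ref and alt)
#' @export
generate_pangenome <- function(cfg = pangenome_sim_config(), seed = 1L) {
  set.seed(seed)
  anc_codes <- sample.int(4L, cfg$genome_length, replace = TRUE)
  genomes <- vector("list", cfg$num_genomes)
  logs <- vector("list", cfg$num_genomes)
  for (gi in seq_len(cfg$num_genomes)) {
    codes <- anc_codes
    sub_pos <- which(runif(length(codes)) < cfg$snp_rate)
    if (length(sub_pos)) {
      shift <- sample.int(3L, length(sub_pos), replace = TRUE)
      old <- codes[sub_pos]
      codes[sub_pos] <- ((old - 1L + shift) %% 4L) + 1L
      logs[[gi]] <- tibble(genome = paste0("g", gi), type = "sub",
                           pos = sub_pos,
                           ref = .bases[old],
                           alt = .bases[codes[sub_pos]])
    } else {
      logs[[gi]] <- tibble(genome = character(0), type = character(0),
                           pos = integer(0), ref = character(0),
                           alt = character(0))
    }
    if (cfg$indel_rate > 0) {
      idl_pos <- which(runif(length(anc_codes)) < cfg$indel_rate)
      if (length(idl_pos)) {
        # apply from right to left so earlier positions stay valid
        idl_pos <- sort(idl_pos, decreasing = TRUE)
        lens <- stats::rgeom(length(idl_pos), cfg$indel_geom_p) + 1L
        is_ins <- runif(length(idl_pos)) < 0.5
        idl_log <- tibble(genome = paste0("g", gi),
                          type = ifelse(is_ins, "ins", "del"),
                          pos = idl_pos,
                          ref = "", alt = "")
        for (ii in seq_along(idl_pos)) {
          p <- idl_pos[ii]; L <- lens[ii]
          if (is_ins[ii]) {
            ins <- sample.int(4L, L, replace = TRUE)
            codes <- append(codes, ins, after = p)
          } else {
            drop <- p:min(p + L - 1L, length(codes))
            codes <- codes[-drop]
          }
        }
        logs[[gi]] <- rbind(logs[[gi]], idl_log)
      }
    }
    genomes[[gi]] <- codes_to_dna(codes)
  }
  names(genomes) <- paste0("g", seq_len(cfg$num_genomes))
  list(genomes = genomes, ancestor = codes_to_dna(anc_codes),
       mutations = do.call(rbind, logs))
}

#' Draw a query with a planted homology from a genome
#'
#' Takes a uniform random substring of the genome, applies iid
#' substitutions at the given divergence, and optionally reverse
#' complements it. The true origin interval is returned for recall checks.
#'
#' @param genome_sequence DNA string
#' @param length query length (<= genome length)
#' @param divergence per-site substitution probability applied to the query
#' @param seed integer seed (optional; uses the current RNG state if NULL)
#' @param revcomp reverse complement the query?
#' @return list with `query`, `start`, `end` (1-based inclusive interval on
#'   the genome), `strand`
#' @export
generate_query <- function(genome_sequence, length, divergence = 0,
                           seed = NULL, revcomp = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  gl <- nchar(genome_sequence)
  if (length > gl) stop("query length exceeds genome length")
  start <- sample.int(gl - length + 1L, 1L)
  codes <- dna_codes(substr(genome_sequence, start, start + length - 1L))
  mut <- which(runif(length) < divergence)
  if (length(mut)) {
    codes[mut] <- ((codes[mut] - 1L +
                      sample.int(3L, length(mut), replace = TRUE)) %% 4L) + 1L
  }
  q <- codes_to_dna(codes)
  if (revcomp) q <- reverse_complement(q)
  list(query = q, start = start, end = start + length - 1L,
       strand = if (revcomp) "-" else "+")
}

# hash parameters shared by the R and compiled scorers; the modulus is a
# prime just below 2^40, large enough that even the deepest scores the
# Markov chain can reach map to very many hash states, yet small enough
# that all modular arithmetic stays exact in doubles
.ET_P <- 1099511627689  # 2^40 - 87
.ET_BASE <- 1103L

#' Synthetic exponential-tail score function
#'
#' A deterministic pseudo-score used to validate the calibration machinery:
#' the sequence is hashed to a uniform value u in (0,1) and scored
#' `floor(-log(u) / lam_true)`, so that over uniform random sequences
#' `P[S >= s] = exp(-lam_true * s)` exactly at integer s (up to the 2^-26
#' granularity of the hash). Single-character changes rehash the sequence,
#' so the Metropolis-Hastings chain mixes.
#'
#' @param n sequence length the function expects
#' @param lam_true true tail rate (> 0)
#' @param seed integer mixed into the hash
#' @return scoring function of class `exp_tail_score_fn`
#' @export
exp_tail_score_fn <- function(n, lam_true, seed = 0L) {
  if (lam_true <= 0) stop("lam_true must be positive")
  pw <- numeric(n)
  pw[1L] <- 1
  for (i in seq_len(n - 1L)) pw[i + 1L] <- (pw[i] * .ET_BASE) %% .ET_P
  # spread the seed over the hash range so different seeds give unrelated
  # score functions (a small additive offset would barely move any score)
  off <- (as.numeric(seed) * 2654435761) %% .ET_P
  f <- function(x) {
    codes <- if (is.character(x)) dna_codes(x) else as.integer(x)
    if (length(codes) != n) stop("sequence must have length ", n)
    h <- (off + sum(codes * pw)) %% .ET_P
    u <- (h + 0.5) / .ET_P
    as.integer(floor(-log(u) / lam_true))
  }
  batch <- function(codes_matrix) {  # one sequence per column
    h <- (off + colSums(codes_matrix * pw)) %% .ET_P
    as.integer(floor(-log((h + 0.5) / .ET_P) / lam_true))
  }
  structure(f, class = c("exp_tail_score_fn", "function"),
            n = n, lam_true = lam_true, off = off,
            base = .ET_BASE, p = .ET_P, batch = batch)
}
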