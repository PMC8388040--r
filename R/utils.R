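#' @importFrom Rcpp evalCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom stats lm coef runif setNames
#' @importFrom utils head tail
#' @useDynLib pangaln, .registration = TRUE
NULL

# nucleotide code maps: A,C,G,T -> 1..4 (0 marks invalid)
.code_map <- local({
  m <- integer(256L)
  m[utf8ToInt("A")] <- 1L; m[utf8ToInt("C")] <- 2L
  m[utf8ToInt("G")] <- 3L; m[utf8ToInt("T")] <- 4L
  m
})
.bases <- c("A", "C", "G", "T")

#' Encode a DNA string as integer codes
#'
#' Maps A,C,G,T to 1..4. Any other character becomes 0, which downstream
#' k-mer extraction treats as a sequence break.
#' @param s a single DNA string
#' @return integer vector of codes
#' @keywords internal
dna_codes <- function(s) {
  if (!nzchar(s)) return(integer(0))
  .code_map[utf8ToInt(s)]
}

codes_to_dna <- function(codes) {
  if (length(codes) == 0L) return("")
  paste(.bases[codes], collapse = "")
}

assert_dna <- function(s, what = "sequence") {
  if (length(s) != 1L || !is.character(s)) stop(what, " must be a single string")
  if (nzchar(s) && any(dna_codes(s) == 0L)) {
    stop(what, " contains characters outside A,C,G,T")
  }
  invisible(s)
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick reverse complement; an involution on strings over
#' A,C,G,T. Searches on the reverse strand are performed by querying the
#' reverse complement of the query.
#'
#' @param s a DNA string over A,C,G,T (upper case)
#' @return the reverse complemented string
#' @examples
#' reverse_complement("ACGTT")
#' @export
reverse_complement <- function(s) {
  assert_dna(s)
  if (!nzchar(s)) return("")
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# all k-mers of a sequence, split at non-ACGT characters; returns character(0)
# when nothing of length >= k survives
extract_kmers <- function(s, k, with_pos = FALSE) {
  codes <- dna_codes(toupper(s))
  n <- length(codes)
  if (n < k) return(if (with_pos) list(kmer = character(0), pos = integer(0)) else character(0))
  bad <- which(codes == 0L)
  ok_start <- rep(TRUE, n - k + 1L)
  for (b in bad) {
    lo <- max(1L, b - k + 1L); hi <- min(n - k + 1L, b)
    if (lo <= hi) ok_start[lo:hi] <- FALSE
  }
  starts <- which(ok_start)
  if (length(starts) == 0L) return(if (with_pos) list(kmer = character(0), pos = integer(0)) else character(0))
  km <- substring(toupper(s), starts, starts + k - 1L)
  if (with_pos) list(kmer = km, pos = starts) else km
}

# uniform random DNA string(s)
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(.bases, len, replace = TRUE), collapse = "")
  }, character(1))
}
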