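# Internal helpers shared across modules. Coordinates are 0-based half-open
# everywhere inside the package; GFF (1-based closed) is converted at the I/O
# boundary only.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, msg, class = "prophagr_error") {
  if (cond) rlang::abort(msg, class = class)
}

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

validate_dna <- function(seq, what = "sequence") {
  abort_if(length(seq) != 1L || is.na(seq) || !nzchar(seq),
           paste0(what, " must be a single non-empty string"))
  bad <- stringr::str_remove_all(toupper(seq), "[ACGTN]")
  abort_if(nzchar(bad),
           sprintf("%s contains characters outside {A,C,G,T,N}: '%s'",
                   what, substr(bad, 1, 10)))
  toupper(seq)
}

#' Extract a 0-based half-open substring
#' @noRd
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

#' Fraction of G+C over unambiguous bases; NA bases (N) excluded from the
#' denominator. Returns NA for all-N input.
#' @param seq nucleotide string
#' @return a fraction in \[0, 1\], or `NA` if no unambiguous base is present
#' @export
gc_content <- function(seq) {
  seq <- validate_dna(seq)
  counts <- table(strsplit(seq, "", fixed = TRUE)[[1]])
  gc <- sum(counts[names(counts) %in% c("G", "C")])
  acgt <- sum(counts[names(counts) %in% c("A", "C", "G", "T")])
  if (acgt == 0) return(NA_real_)
  gc / acgt
}

# Positionwise match indicator under the package's ambiguity rule:
# N never counts as a match, on either side. Sequences must be equal length.
match_vector <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  n <- charToRaw("N")
  ra == rb & ra != n & rb != n
}

hamming_mismatches <- function(a, b) {
  sum(!match_vector(a, b))
}

# All start positions (0-based) of exact occurrences of `motif` in `seq`,
# overlapping occurrences included.
motif_positions <- function(seq, motif) {
  if (nchar(seq) < nchar(motif)) return(integer(0))
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq))
  BiocGenerics::start(hits) - 1L
}

# Longest common substring of two strings that occurs exactly once in each;
# returns list(s = substring, pos_a, pos_b) with 0-based positions, or NULL.
# Used for att-core search in 500 bp windows, so quadratic scanning is fine.
longest_unique_common_substring <- function(a, b, min_len = 15L) {
  na <- nchar(a); nb <- nchar(b)
  hi <- min(na, nb)
  best <- NULL
  kmers_at <- function(s, k) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character(0))
    substring(s, 1:n, k:(k + n - 1L))
  }
  lo <- min_len
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    ka <- kmers_at(a, mid); kb <- kmers_at(b, mid)
    common <- intersect(ka[!duplicated(ka) & !duplicated(ka, fromLast = TRUE)],
                        kb[!duplicated(kb) & !duplicated(kb, fromLast = TRUE)])
    if (length(common) > 0) {
      s <- common[[1]]
      best <- list(s = s,
                   pos_a = which(ka == s)[[1]] - 1L,
                   pos_b = which(kb == s)[[1]] - 1L)
      lo <- mid + 1L
    } else {
      hi <- mid - 1L
    }
  }
  best
}

# Run body with a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
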