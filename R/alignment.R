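# Shared pairwise-alignment machinery. Protein alignment (BLOSUM62, gap
# open 11 / extend 1) backs the ortholog clustering; blastn-style nucleotide
# scoring (+1 match, -3 mismatch) backs fragmented similarity and spacer
# matching, so the two modules share one scoring definition.

BLASTN_MATCH <- 1
BLASTN_MISMATCH <- -3
# Ungapped Karlin-Altschul constants for the +1/-3 scoring system, as used by
# blastn-short bit scores.
KA_LAMBDA <- 1.374
KA_K <- 0.711

#' Local protein alignment identity and coverage
#'
#' Smith-Waterman local alignment under BLOSUM62 with gap open 11 / extend 1.
#' Identity is matches over aligned columns; coverage is the aligned span of
#' the shorter sequence over its length.
#'
#' @param a,b protein strings
#' @return a list with `identity`, `coverage`, and the raw `score`
#' @export
#' @examples
#' protein_similarity("MKLVSTDEQRALW", "MKLVSTDEQRALW")
protein_similarity <- function(a, b) {
  abort_if(!nzchar(a) || !nzchar(b), "protein sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  shorter <- min(nchar(a), nchar(b))
  span <- if (nchar(a) <= nchar(b)) {
    Biostrings::width(Biostrings::pattern(aln))
  } else {
    Biostrings::width(Biostrings::subject(aln))
  }
  list(
    identity = if (cols > 0) Biostrings::nmatch(aln) / cols else 0,
    coverage = span / shorter,
    score = Biostrings::score(aln)
  )
}

#' Local nucleotide alignment with blastn default scores
#'
#' Smith-Waterman with match +1, mismatch -3, gap open 5, gap extend 2
#' (blastn defaults). Used as the gapped reference scorer; the fragment
#' tiling path uses the seeded ungapped equivalent for speed.
#'
#' @param a,b nucleotide strings
#' @return list with `score`, `identity` (matches / aligned columns) and
#'   `matches`
#' @export
nt_local_align <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = BLASTN_MATCH, mismatch = BLASTN_MISMATCH, baseOnly = FALSE
  )
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2
  )
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  list(
    score = Biostrings::score(aln),
    identity = if (cols > 0) Biostrings::nmatch(aln) / cols else 0,
    matches = Biostrings::nmatch(aln)
  )
}

# ---- k-mer index for seeded diagonal scoring --------------------------------

# Hash of all k-mer start positions (0-based) of a subject sequence.
kmer_index <- function(seq, k = 15L) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(list(env = new.env(), k = k, n = nchar(seq), seq = seq))
  kmers <- substring(seq, 1:n, k:(k + n - 1L))
  env <- new.env(hash = TRUE, size = n)
  split_pos <- split(0:(n - 1L), kmers)
  list2env(split_pos, envir = env)
  list(env = env, k = k, n = nchar(seq), seq = seq)
}

# Best ungapped local-segment score of `fragment` against the indexed subject
# under +1/-3 scoring: candidate diagonals come from shared k-mers; on the
# best diagonal the maximal-scoring run is found by a prefix-sum scan.
# Returns 0 when no seed is shared (no detectable homology).
fragment_best_score <- function(fragment, index) {
  k <- index$k
  flen <- nchar(fragment)
  if (flen < k) return(0)
  nf <- flen - k + 1L
  fk <- substring(fragment, 1:nf, k:(k + nf - 1L))
  keep <- exists_mask(fk, index$env)
  if (!any(keep)) return(0)
  qpos <- (0:(nf - 1L))[keep]
  spos <- mget(fk[keep], envir = index$env)
  diags <- unlist(Map(function(s, q) s - q, spos, qpos), use.names = FALSE)
  diag_tab <- table(diags)
  best <- 0
  # score at most the 3 most seed-supported diagonals
  top <- as.integer(names(sort(diag_tab, decreasing = TRUE)))
  for (d in utils::head(top, 3L)) {
    s0 <- max(0L, d)
    q0 <- s0 - d
    len <- min(flen - q0, index$n - s0)
    if (len <= 0) next
    m <- match_vector(substring(fragment, q0 + 1L, q0 + len),
                      substring(index$seq, s0 + 1L, s0 + len))
    sc <- ifelse(m, BLASTN_MATCH, BLASTN_MISMATCH)
    cs <- cumsum(sc)
    run_best <- max(cs - cummin(c(0, cs[-length(cs)])))
    best <- max(best, run_best)
  }
  best
}

exists_mask <- function(keys, env) {
  vapply(keys, function(k) exists(k, envir = env, inherits = FALSE), logical(1),
         USE.NAMES = FALSE)
}
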