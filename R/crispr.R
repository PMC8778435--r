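# CRISPR repeat-spacer array detection, spacer-protospacer matching under
# the <=3-mismatch AND bit-score >= 44.1 rule, PAM annotation, and the
# host x clade targeting matrix.

MIN_BITSCORE <- 44.1
MAX_MISMATCHES <- 3L

#' Ungapped blastn-short bit score for a full-length spacer alignment
#'
#' Raw score `S = (len - m) * (+1) + m * (-3) = len - 4m`, converted to bits
#' with the ungapped Karlin-Altschul constants for the +1/-3 scoring system
#' (lambda = 1.374, K = 0.711): `bits = (lambda * S - ln K) / ln 2`. At the
#' median spacer length of 34 nt, exactly 3 mismatches give 44.1 bits - the
#' protospacer acceptance cutoff.
#'
#' @param spacer_len spacer length (nt)
#' @param mismatches number of mismatched bases
#' @return the bit score
#' @export
#' @examples
#' spacer_bitscore(34, 3)   # the cutoff case
#' spacer_bitscore(34, 0)
spacer_bitscore <- function(spacer_len, mismatches) {
  abort_if(any(mismatches > spacer_len),
           "mismatches cannot exceed spacer length")
  s <- spacer_len - 4 * mismatches
  (KA_LAMBDA * s - log(KA_K)) / log(2)
}

# ---- array detection --------------------------------------------------------

# Candidate tandem periods: lag-correlation runs of exact matches whose
# length fits a CRISPR repeat (23-47 nt) at a period compatible with a
# 26-50 nt spacer between copies.
candidate_repeats <- function(seq, min_rep = 23L, max_rep = 47L,
                              min_sp = 26L, max_sp = 50L) {
  r <- charToRaw(seq)
  n <- length(r)
  cands <- list()
  for (p in (min_rep + min_sp):(max_rep + max_sp)) {
    if (n <= p + min_rep) break
    eq <- r[1:(n - p)] == r[(p + 1):n]
    rl <- rle(eq)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values & rl$lengths >= min_rep
    for (i in which(keep)) {
      len <- min(rl$lengths[i], max_rep)
      cands[[length(cands) + 1L]] <- tibble::tibble(
        start = starts[i] - 1L, rep_len = len, period = p)
    }
  }
  if (length(cands) == 0) {
    return(tibble::tibble(start = integer(), rep_len = integer(),
                          period = integer()))
  }
  dplyr::distinct(dplyr::bind_rows(cands), .data$start, .data$rep_len,
                  .keep_all = TRUE)
}

#' Detect CRISPR repeat-spacer arrays in a genome
#'
#' CRT-style detection: a lag-correlation scan over tandem periods seeds
#' candidate repeats (>= 23 nt exact match between adjacent copies), whose
#' occurrences across the genome (allowing one mismatch per copy) are then
#' chained into arrays wherever consecutive copies are separated by
#' 26-50 nt spacer gaps. Arrays need at least three repeat copies. The
#' repeat consensus is the per-column majority over copies.
#'
#' @param genome one-row genomes tibble (sequence >= 200 nt)
#' @return tibble with one row per array: `genome_id`, `start`, `end`,
#'   `repeat_consensus`, `n_spacers`, and a `spacers` list-column of the
#'   ordered spacer strings
#' @export
detect_arrays <- function(genome) {
  seq <- genome$sequence[[1]]
  abort_if(nchar(seq) < 200, "genome must be at least 200 nt")
  cands <- candidate_repeats(seq)
  empty <- tibble::tibble(genome_id = character(), start = integer(),
                          end = integer(), repeat_consensus = character(),
                          n_spacers = integer(), spacers = list())
  if (nrow(cands) == 0) return(empty)
  out <- list()
  claimed <- integer(0)
  for (i in seq_len(nrow(cands))) {
    if (cands$start[i] %in% claimed) next
    rep_seq <- subseq0(seq, cands$start[i], cands$start[i] + cands$rep_len[i])
    hits <- Biostrings::matchPattern(rep_seq, Biostrings::DNAString(seq),
                                     max.mismatch = 1)
    pos <- BiocGenerics::start(hits) - 1L
    if (length(pos) < 3) next
    pos <- sort(pos)
    # chain copies whose gaps look like spacers
    rl <- cands$rep_len[i]
    gaps <- diff(pos) - rl
    grp <- cumsum(c(0, !(gaps >= 26 & gaps <= 50)))
    for (g in unique(grp)) {
      p <- pos[grp == g]
      if (length(p) < 3) next
      ref <- refine_repeat(seq, p, rl)
      p <- ref$pos; rl <- ref$rep_len
      copies <- vapply(p, function(s) subseq0(seq, s, s + rl), character(1))
      cons <- consensus_string(copies)
      spacers <- vapply(seq_len(length(p) - 1L), function(j) {
        subseq0(seq, p[j] + rl, p[j + 1])
      }, character(1))
      out[[length(out) + 1L]] <- tibble::tibble(
        genome_id = genome$genome_id[[1]],
        start = p[1], end = p[length(p)] + rl,
        repeat_consensus = cons,
        n_spacers = length(spacers),
        spacers = list(spacers))
      claimed <- c(claimed, p)
    }
  }
  if (length(out) == 0) return(empty)
  res <- dplyr::arrange(dplyr::bind_rows(out),
                        dplyr::desc(.data$n_spacers),
                        dplyr::desc(.data$end - .data$start))
  # overlapping detections of the same locus: keep the best-supported one
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    if (i < nrow(res)) for (j in (i + 1):nrow(res)) {
      if (keep[j] && intervals_overlap(res$start[i], res$end[i],
                                       res$start[j], res$end[j])) {
        keep[j] <- FALSE
      }
    }
  }
  dplyr::arrange(res[keep, ], .data$start)
}

# Snap repeat boundaries to the columns where every chained copy agrees:
# seed runs from two adjacent copies can over- or under-shoot by chance
# flank agreement; with >= 3 copies the unanimous columns delimit the
# repeat (copies are treated as exact here; stray disagreement only stops
# the extension early, never below the 23 nt minimum).
refine_repeat <- function(seq, pos, rl, min_rep = 23L, max_rep = 47L) {
  n <- nchar(seq)
  col_equal <- function(off) {
    ch <- substring(seq, pos + off + 1L, pos + off + 1L)
    all(pos + off >= 0) && all(pos + off < n) && length(unique(ch)) == 1
  }
  # grow/shrink on the right
  while (rl < max_rep && col_equal(rl)) rl <- rl + 1L
  while (rl > min_rep && !col_equal(rl - 1L)) rl <- rl - 1L
  # grow/shrink on the left
  while (rl < max_rep && col_equal(-1L)) { pos <- pos - 1L; rl <- rl + 1L }
  while (rl > min_rep && !col_equal(0L)) { pos <- pos + 1L; rl <- rl - 1L }
  list(pos = pos, rep_len = rl)
}

consensus_string <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  paste(apply(m, 2, function(col) names(sort(table(col), decreasing = TRUE))[1]),
        collapse = "")
}

#' Extract and deduplicate spacers from detected arrays
#'
#' @param arrays output of [detect_arrays()] (rows may span genomes)
#' @return tibble with `spacer_id`, `genome_id`, `sequence`, and a
#'   `duplicate_of` column linking exact-duplicate spacers to the first
#'   occurrence (dedup is exact string identity)
#' @export
extract_spacers <- function(arrays) {
  long <- tidyr::unnest(
    dplyr::mutate(arrays, sequence = .data$spacers),
    cols = "sequence")
  long <- dplyr::select(long, "genome_id", "sequence")
  long$spacer_id <- sprintf("%s_sp%03d", long$genome_id,
                            stats::ave(seq_len(nrow(long)), long$genome_id,
                                       FUN = seq_along))
  first <- !duplicated(long$sequence)
  long$duplicate_of <- long$spacer_id[match(long$sequence, long$sequence)]
  long$duplicate_of[first] <- NA_character_
  dplyr::select(long, "spacer_id", "genome_id", "sequence", "duplicate_of")
}

# ---- protospacer matching ---------------------------------------------------

# Full-length ungapped matches of one spacer on one strand of one prophage:
# matchPattern generates candidates, package-level mismatch counting (N
# never matches) verifies them.
scan_spacer <- function(spacer, prophage_seq) {
  n <- nchar(prophage_seq)
  slen <- nchar(spacer)
  if (n < slen) return(tibble::tibble(start = integer(), strand = character(),
                                      mismatches = integer()))
  subj <- Biostrings::DNAString(prophage_seq)
  rows <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") spacer else reverse_complement(spacer)
    hits <- Biostrings::matchPattern(pat, subj,
                                     max.mismatch = MAX_MISMATCHES)
    pos <- BiocGenerics::start(hits) - 1L
    if (length(pos) == 0) next
    mm <- vapply(pos, function(s) {
      hamming_mismatches(pat, subseq0(prophage_seq, s, s + slen))
    }, integer(1))
    keep <- mm <= MAX_MISMATCHES
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        start = pos[keep], strand = strand, mismatches = mm[keep])
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(start = integer(), strand = character(),
                          mismatches = integer()))
  }
  dplyr::bind_rows(rows)
}

#' Match CRISPR spacers to prophage sequences
#'
#' Scans both strands of every prophage for full-length ungapped matches of
#' each spacer with at most 3 mismatches, scores each with
#' [spacer_bitscore()], and keeps hits reaching 44.1 bits. Both filters are
#' applied; `N` never counts as a match. Hits are annotated with the 5'TCC
#' PAM status via [check_pam()].
#'
#' @param spacers tibble with `spacer_id`, `sequence` (deduplicated
#'   upstream; see [extract_spacers()])
#' @param prophages tibble with `prophage_id`, `sequence`
#' @param max_mismatches,min_bitscore the acceptance thresholds
#' @return tibble of hits: `spacer_id`, `prophage_id`, `start`, `end`,
#'   `strand`, `mismatches`, `bitscore`, `pam_tcc`, `pam_edge`
#' @export
find_protospacers <- function(spacers, prophages,
                              max_mismatches = MAX_MISMATCHES,
                              min_bitscore = MIN_BITSCORE) {
  out <- list()
  for (i in seq_len(nrow(spacers))) {
    slen <- nchar(spacers$sequence[i])
    for (j in seq_len(nrow(prophages))) {
      hits <- scan_spacer(spacers$sequence[i], prophages$sequence[j])
      if (nrow(hits) == 0) next
      hits$spacer_id <- spacers$spacer_id[i]
      hits$prophage_id <- prophages$prophage_id[j]
      hits$end <- hits$start + slen
      hits$bitscore <- spacer_bitscore(slen, hits$mismatches)
      hits <- dplyr::filter(hits, .data$mismatches <= max_mismatches,
                            .data$bitscore >= min_bitscore)
      if (nrow(hits) == 0) next
      pam <- lapply(seq_len(nrow(hits)), function(h) {
        check_pam(hits[h, ], prophages$sequence[j])
      })
      hits$pam_tcc <- vapply(pam, `[[`, logical(1), "pam")
      hits$pam_edge <- vapply(pam, `[[`, logical(1), "edge")
      out[[length(out) + 1L]] <- hits
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(spacer_id = character(), prophage_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), mismatches = integer(),
                          bitscore = numeric(), pam_tcc = logical(),
                          pam_edge = logical()))
  }
  dplyr::select(dplyr::bind_rows(out), "spacer_id", "prophage_id", "start",
                "end", "strand", "mismatches", "bitscore", "pam_tcc",
                "pam_edge")
}

#' Check the 5'TCC protospacer-adjacent motif
#'
#' True iff the three nucleotides immediately 5' of the protospacer, read
#' on the protospacer's strand, are `TCC`. For a minus-strand hit this is
#' the reverse complement of the three forward-strand bases immediately
#' after the match. A protospacer at the sequence edge is flagged.
#'
#' @param hit one row of [find_protospacers()] output (needs `start`,
#'   `end`, `strand`)
#' @param prophage_seq the prophage sequence the hit lies on
#' @return list with `pam` (logical) and `edge` (logical)
#' @export
check_pam <- function(hit, prophage_seq) {
  n <- nchar(prophage_seq)
  if (hit$strand == "+") {
    if (hit$start < 3) return(list(pam = FALSE, edge = TRUE))
    flank <- subseq0(prophage_seq, hit$start - 3, hit$start)
    list(pam = identical(flank, "TCC"), edge = FALSE)
  } else {
    if (hit$end + 3 > n) return(list(pam = FALSE, edge = TRUE))
    flank <- reverse_complement(subseq0(prophage_seq, hit$end, hit$end + 3))
    list(pam = identical(flank, "TCC"), edge = FALSE)
  }
}

#' Host x clade spacer-targeting matrix and summaries
#'
#' Counts targeting spacers per (host genome, prophage clade), flags
#' self-targeting (a host's spacer hitting a prophage resident in that same
#' host) with its PAM status, and summarises how many hosts target 1, 2,
#' 3, ... clades and what fraction of unique spacers target any prophage.
#' PAM status does not gate the counts; it is reported separately.
#'
#' @param hits [find_protospacers()] output
#' @param spacers the spacer tibble the hits came from (`spacer_id`,
#'   `genome_id`, `sequence`, optional `duplicate_of`)
#' @param clades tibble `prophage_id` -> `clade` (see [cluster_clades()])
#' @param prophage_hosts tibble `prophage_id` -> `genome_id` of the
#'   resident host
#' @return list with `matrix` (host x clade count tibble), `self_targeting`
#'   (flagged hits), `hosts_by_n_clades`, and `unique_spacer_fraction`
#' @export
targeting_matrix <- function(hits, spacers, clades, prophage_hosts) {
  h <- dplyr::left_join(hits, clades, by = "prophage_id")
  h <- dplyr::left_join(
    h, dplyr::rename(prophage_hosts, host_of_prophage = "genome_id"),
    by = "prophage_id")
  h <- dplyr::left_join(
    h, dplyr::select(spacers, "spacer_id", spacer_genome = "genome_id"),
    by = "spacer_id")
  mat <- dplyr::count(h, .data$spacer_genome, .data$clade, name = "n_spacers")
  per_host <- dplyr::summarise(
    dplyr::group_by(mat, .data$spacer_genome),
    n_clades = dplyr::n_distinct(.data$clade), .groups = "drop")
  selfs <- dplyr::filter(h, .data$spacer_genome == .data$host_of_prophage)
  selfs <- dplyr::select(selfs, "spacer_id", "prophage_id",
                         genome_id = "spacer_genome", "pam_tcc", "pam_edge")
  n_unique <- if ("duplicate_of" %in% names(spacers)) {
    sum(is.na(spacers$duplicate_of))
  } else {
    length(unique(spacers$sequence))
  }
  targeting_unique <- length(unique(
    spacers$sequence[spacers$spacer_id %in% hits$spacer_id]))
  list(
    matrix = mat,
    self_targeting = selfs,
    hosts_by_n_clades = dplyr::count(per_host, .data$n_clades, name = "n_hosts"),
    unique_spacer_fraction = targeting_unique / n_unique)
}
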