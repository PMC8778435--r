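# Diversity-generating retroelements (TR/VR repeat pairs anchored on a
# reverse transcriptase) and tyrosine-invertase shufflons (rix-delimited Rv
# cassettes shuffled into Rc).

#' Find same-orientation repeat pairs (TR/VR candidates)
#'
#' Seeds on shared exact 20-mers between distinct positions, extends each
#' seeded diagonal ungapped in both directions, and trims to the
#' best-identity window with length in `[min_len, max_len]`. Pairs of
#' non-overlapping segments with identity >= `min_identity` are returned,
#' best (highest identity, then longest) non-redundant pairs first;
#' segments already claimed by a better pair are not reported again.
#'
#' @param sequence nucleotide string
#' @param min_len,max_len repeat length bounds (bp)
#' @param min_identity minimum Hamming identity over the trimmed window
#' @param seed_k seed length
#' @return tibble with `start1`, `end1`, `start2`, `end2`, `length`,
#'   `identity` (0-based half-open; pair 1 is the leftmost segment)
#' @export
find_repeat_pairs <- function(sequence, min_len = 100, max_len = 150,
                              min_identity = 0.90, seed_k = 20L) {
  n <- nchar(sequence)
  abort_if(n < 2 * min_len, "sequence shorter than two repeat copies")
  nk <- n - seed_k + 1L
  kmers <- substring(sequence, 1:nk, seed_k:(seed_k + nk - 1L))
  dup <- kmers[duplicated(kmers)]
  empty <- tibble::tibble(start1 = integer(), end1 = integer(),
                          start2 = integer(), end2 = integer(),
                          length = integer(), identity = numeric())
  if (length(dup) == 0) return(empty)
  # candidate diagonals: offsets between occurrences of a duplicated k-mer
  offsets <- list()
  for (km in unique(dup)) {
    pos <- which(kmers == km) - 1L
    for (a in seq_len(length(pos) - 1L)) {
      for (b in (a + 1L):length(pos)) {
        d <- pos[b] - pos[a]
        if (d >= min_len) {            # non-overlapping copies only
          offsets[[length(offsets) + 1L]] <- c(pos[a], d)
        }
      }
    }
  }
  if (length(offsets) == 0) return(empty)
  cand <- unique(do.call(rbind, offsets))
  # group seeds by diagonal; evaluate each diagonal once
  diags <- unique(cand[, 2])
  results <- list()
  for (d in diags) {
    seeds <- sort(cand[cand[, 2] == d, 1])
    # merge seeds within extension reach to avoid rescoring the same locus
    grp <- cumsum(c(1, diff(seeds) > max_len))
    for (g in unique(grp)) {
      s0 <- seeds[grp == g][1]
      win <- best_pair_window(sequence, s0, d, min_len, max_len, seed_k)
      if (!is.null(win) && win$identity >= min_identity) {
        results[[length(results) + 1L]] <- tibble::tibble(
          start1 = win$start, end1 = win$start + win$length,
          start2 = win$start + d, end2 = win$start + d + win$length,
          length = win$length, identity = win$identity)
      }
    }
  }
  if (length(results) == 0) return(empty)
  res <- dplyr::arrange(dplyr::bind_rows(results),
                        dplyr::desc(.data$identity), dplyr::desc(.data$length))
  res <- dplyr::distinct(res, .data$start1, .data$start2, .keep_all = TRUE)
  # drop pairs overlapping an already-accepted better pair
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    if (i < nrow(res)) for (j in (i + 1):nrow(res)) {
      if (!keep[j]) next
      if (intervals_overlap(res$start1[i], res$end1[i], res$start1[j], res$end1[j]) ||
          intervals_overlap(res$start2[i], res$end2[i], res$start2[j], res$end2[j])) {
        keep[j] <- FALSE
      }
    }
  }
  res[keep, ]
}

intervals_overlap <- function(a1, a2, b1, b2) a1 < b2 && b1 < a2

# Extend a seeded diagonal (copy at s0 vs s0+d) both ways, then pick the
# window with length in range maximising the blastn-style score
# (+1 match / -3 mismatch); score rewards extension while identity stays
# above 75%, so the full repeat is kept rather than a cleaner sub-window.
# NULL if nothing fits.
best_pair_window <- function(sequence, s0, d, min_len, max_len, seed_k) {
  n <- nchar(sequence)
  # available span on this diagonal around the seed
  lo <- max(0L, s0 - max_len)
  hi <- min(s0 + seed_k + max_len, n - d)
  if (hi - lo < min_len) return(NULL)
  a <- subseq0(sequence, lo, hi)
  b <- subseq0(sequence, lo + d, hi + d)
  m <- match_vector(a, b)
  len <- length(m)
  cs <- c(0, cumsum(m))
  best <- NULL
  for (w in min_len:min(max_len, len)) {
    matches <- cs[(w + 1):(len + 1)] - cs[1:(len - w + 1)]
    i <- which.max(matches)
    sc <- 4 * matches[i] - 3 * w
    # ties go to the longer window: trimming an edge segment whose score
    # is zero must not shrink the reported repeat
    if (is.null(best) || sc > best$score ||
        (sc == best$score && w > best$length)) {
      best <- list(start = lo + i - 1L, length = w,
                   identity = matches[i] / w, score = sc)
    }
  }
  best
}

#' Assemble a DGR element from repeat pairs and gene annotations
#'
#' Requires a gene whose product matches the reverse-transcriptase keyword;
#' the repeat-pair member nearer to (or inside) that gene is the template
#' repeat (TR) and the other the variable repeat (VR). The VR must fall
#' within a gene - the major-tropism-determinant candidate; any small gene
#' (< `avd_max_len`) between the TR and the mtd gene is reported as the
#' accessory variability determinant. The architecture is `TR_within_ert`
#' when the TR is nested in the RT gene, else `TR_upstream_of_ert`.
#'
#' @param sequence prophage sequence
#' @param features feature tibble relative to `sequence` (gene rows with
#'   products)
#' @param pairs output of [find_repeat_pairs()]; computed from `sequence`
#'   when omitted
#' @param rt_keyword regex identifying the reverse transcriptase product
#' @param avd_max_len maximum avd gene length
#' @return one-row tibble (`rt_gene`, `mtd_gene`, `avd_gene`, TR/VR
#'   intervals, `tr_vr_identity`, `architecture`) or NULL with a message
#'   when no qualifying pair exists
#' @export
assemble_dgr <- function(sequence, features, pairs = NULL,
                         rt_keyword = "reverse transcriptase",
                         avd_max_len = 600) {
  genes <- dplyr::filter(features, .data$kind == "gene", !is.na(.data$product))
  rt <- dplyr::filter(genes, stringr::str_detect(tolower(.data$product),
                                                 rt_keyword))
  if (nrow(rt) == 0) return(NULL)
  rt <- rt[1, ]
  if (is.null(pairs)) pairs <- find_repeat_pairs(sequence)
  if (nrow(pairs) == 0) {
    rlang::inform("reverse transcriptase present but no qualifying repeat pair")
    return(NULL)
  }
  rt_mid <- (rt$start + rt$end) / 2
  best <- NULL
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    d1 <- segment_gene_distance(p$start1, p$end1, rt)
    d2 <- segment_gene_distance(p$start2, p$end2, rt)
    if (d1 <= d2) {
      tr <- c(p$start1, p$end1); vr <- c(p$start2, p$end2)
    } else {
      tr <- c(p$start2, p$end2); vr <- c(p$start1, p$end1)
    }
    host_gene <- dplyr::filter(genes, .data$start <= vr[1], .data$end >= vr[2],
                               !stringr::str_detect(tolower(.data$product),
                                                    rt_keyword))
    if (nrow(host_gene) == 0) next
    mtd <- host_gene[1, ]
    cand <- list(tr = tr, vr = vr, identity = p$identity, mtd = mtd)
    if (is.null(best) || p$identity > best$identity) best <- cand
  }
  if (is.null(best)) {
    rlang::inform("reverse transcriptase present but no VR inside a gene")
    return(NULL)
  }
  within_ert <- best$tr[1] >= rt$start && best$tr[2] <= rt$end
  # avd: small gene between TR and mtd
  span <- range(c(best$tr, best$mtd$start, best$mtd$end))
  avd <- dplyr::filter(genes,
                       .data$start >= span[1], .data$end <= span[2],
                       .data$end - .data$start <= avd_max_len)
  tibble::tibble(
    rt_gene = rt$feature_id %||% NA_character_,
    mtd_gene = best$mtd$feature_id %||% NA_character_,
    avd_gene = if (nrow(avd) > 0) avd$feature_id[1] else NA_character_,
    tr_start = best$tr[1], tr_end = best$tr[2],
    vr_start = best$vr[1], vr_end = best$vr[2],
    tr_vr_identity = best$identity,
    architecture = if (within_ert) "TR_within_ert" else "TR_upstream_of_ert")
}

segment_gene_distance <- function(s, e, gene) {
  if (e > gene$start && gene$end > s) return(0)   # overlap
  min(abs(s - gene$end), abs(gene$start - e))
}

#' Call DGR variable sites across isolates
#'
#' A VR column is variable iff at least two distinct bases are observed
#' across the template repeat and the isolate VRs at that position
#' (`N` ignored). Offsets are 0-based within the VR. The result is
#' invariant under isolate input order.
#'
#' @param vr_sequences character vector of VR observations (>= 1), equal
#'   length
#' @param tr_reference the template repeat sequence (same length)
#' @return integer vector of variable-site offsets
#' @export
call_variable_sites <- function(vr_sequences, tr_reference) {
  abort_if(length(vr_sequences) < 1, "need at least one VR observation")
  lens <- nchar(c(vr_sequences, tr_reference))
  abort_if(length(unique(lens)) != 1,
           "VR/TR length mismatch after anchoring")
  m <- do.call(rbind, strsplit(c(tr_reference, vr_sequences), "", fixed = TRUE))
  variable <- apply(m, 2, function(col) {
    length(unique(col[col != "N"])) >= 2
  })
  which(variable) - 1L
}

#' Size of the sequence space a DGR can explore
#'
#' Each variable site can carry any of the four bases, so `n` sites span
#' `4^n` variants (exact integer arithmetic for `n <= 30`).
#'
#' @param n_sites number of variable sites
#' @return `4^n_sites`
#' @export
#' @examples
#' variant_space(10)   # > 1e6
variant_space <- function(n_sites) {
  abort_if(n_sites < 0, "`n_sites` must be >= 0")
  abort_if(n_sites > 30, "4^n exceeds exact integer arithmetic for n > 30")
  4^n_sites
}

#' Scan for shufflon crossover (rix) sites
#'
#' All exact occurrences of the motif (direct) and of its reverse
#' complement (inverted), case-insensitive, overlapping occurrences
#' allowed.
#'
#' @param sequence nucleotide string
#' @param motif the crossover motif (>= 6 nt)
#' @return tibble with `position` (0-based) and `orientation`
#'   (`direct` / `inverted`)
#' @export
find_rix_sites <- function(sequence, motif = "TTCCGTAT") {
  abort_if(nchar(motif) < 6, "motif must be at least 6 nt")
  motif <- toupper(motif)
  sequence <- toupper(sequence)
  dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(position = motif_positions(sequence, motif),
                   orientation = "direct"),
    tibble::tibble(position = motif_positions(sequence,
                                              reverse_complement(motif)),
                   orientation = "inverted")),
    .data$position)
}

#' Assemble a Rin shufflon from rix sites and gene annotations
#'
#' Requires an invertase-like recombinase gene (distinct from the
#' integrase). Rv segments are the intervals between consecutive direct rix
#' sites downstream of the recombinase; the Rc gene is the large gene after
#' the last Rv that carries at least one inverted rix downstream of its
#' stop. The Rv/Rc C-terminal homology fraction (local alignment identity
#' of each Rv 3' segment against the Rc 3' end) is reported.
#'
#' @param sequence prophage sequence
#' @param features feature tibble relative to `sequence`
#' @param rix output of [find_rix_sites()]; computed when omitted
#' @param recombinase_keyword regex identifying the invertase product
#' @param motif the crossover motif (for site width)
#' @return list with `rin_gene`, `rc_gene`, `rv_segments` (tibble),
#'   `rix_sites` (tibble), `rv_rc_homology` (per-Rv identity fractions), or
#'   NULL with a message
#' @export
assemble_shufflon <- function(sequence, features, rix = NULL,
                              recombinase_keyword = "invertase",
                              motif = "TTCCGTAT") {
  genes <- dplyr::filter(features, .data$kind == "gene", !is.na(.data$product))
  rin <- dplyr::filter(genes, stringr::str_detect(tolower(.data$product),
                                                  recombinase_keyword))
  if (is.null(rix)) rix <- find_rix_sites(sequence, motif)
  if (nrow(rin) == 0) {
    if (nrow(rix) > 0) rlang::inform("rix sites present but no recombinase gene")
    return(NULL)
  }
  rin <- rin[1, ]
  m <- nchar(motif)
  direct <- rix$position[rix$orientation == "direct" & rix$position >= rin$end]
  if (length(direct) < 2) return(NULL)
  direct <- sort(direct)
  rv <- tibble::tibble(start = direct[-length(direct)] + m,
                       end = direct[-1])
  rv <- dplyr::filter(rv, .data$end - .data$start >= 50,
                      .data$end - .data$start <= 2000)
  if (nrow(rv) == 0) return(NULL)
  last_rix <- direct[length(direct)]
  rc_cand <- dplyr::arrange(
    dplyr::filter(genes, .data$start >= last_rix,
                  .data$end - .data$start > max(rv$end - rv$start)),
    .data$start)
  rc <- NULL
  inverted <- rix$position[rix$orientation == "inverted"]
  for (i in seq_len(nrow(rc_cand))) {
    g <- rc_cand[i, ]
    if (any(inverted >= g$end & inverted <= g$end + 200)) {
      rc <- g
      break
    }
  }
  if (is.null(rc)) return(NULL)
  rc_tail <- subseq0(sequence, max(rc$start, rc$end - 200), rc$end)
  hom <- vapply(seq_len(nrow(rv)), function(i) {
    seg <- subseq0(sequence, rv$start[i], rv$end[i])
    nt_local_align(seg, rc_tail)$identity
  }, numeric(1))
  list(rin_gene = rin$feature_id, rc_gene = rc$feature_id,
       rv_segments = rv, rix_sites = rix, rv_rc_homology = hom)
}
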