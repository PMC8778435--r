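# Prophage discovery: hallmark-gene screening, boundary delineation against
# a prophage-free reference via unique-anchor chaining, and att-site
# prediction from flanking direct repeats with tRNA homology.

HALLMARK_KEYWORDS <- list(
  terminase = "terminase",
  capsid = "capsid|major head",
  portal = "portal"
)

#' Screen gene annotations for phage hallmark loci
#'
#' A candidate locus is a cluster of genes carrying at least two of the
#' three hallmark products (terminase, major capsid/head, portal protein)
#' within a 60 kb window. Matching is case-insensitive substring/regex
#' matching on the product string; the keyword list is configurable. A lone
#' integrase (or any single hallmark class) never qualifies.
#'
#' @param features features tibble (one or more genomes)
#' @param keywords named list of regexes defining the hallmark classes
#' @param window maximum span (bp) linking hallmark genes into one locus
#' @return tibble with `genome_id`, `start`, `end`, `n_hallmarks`
#' @export
screen_hallmarks <- function(features, keywords = HALLMARK_KEYWORDS,
                             window = 60000) {
  genes <- dplyr::filter(features, .data$kind == "gene",
                         !is.na(.data$product))
  if (nrow(genes) == 0) {
    return(tibble::tibble(genome_id = character(), start = integer(),
                          end = integer(), n_hallmarks = integer()))
  }
  genes$hallmark <- NA_character_
  for (k in names(keywords)) {
    hit <- stringr::str_detect(tolower(genes$product), keywords[[k]])
    genes$hallmark[hit & is.na(genes$hallmark)] <- k
  }
  marks <- dplyr::arrange(dplyr::filter(genes, !is.na(.data$hallmark)),
                          .data$genome_id, .data$start)
  if (nrow(marks) == 0) {
    return(tibble::tibble(genome_id = character(), start = integer(),
                          end = integer(), n_hallmarks = integer()))
  }
  out <- dplyr::group_modify(dplyr::group_by(marks, .data$genome_id),
                             function(df, key) {
    gap <- c(0, df$start[-1] - df$end[-nrow(df)])
    cl <- cumsum(gap > window)
    res <- dplyr::summarise(
      dplyr::group_by(df, cluster = cl),
      start = min(.data$start), end = max(.data$end),
      n_hallmarks = dplyr::n_distinct(.data$hallmark), .groups = "drop")
    dplyr::select(dplyr::filter(res, .data$n_hallmarks >= 2), -"cluster")
  })
  dplyr::ungroup(out)
}

# Unique-anchor lookup: 0-based positions of a k-mer occurring exactly once
# in the reference.
reference_anchor_index <- function(reference, k = 20L) {
  n <- nchar(reference) - k + 1L
  kmers <- substring(reference, 1:n, k:(k + n - 1L))
  uni <- !(duplicated(kmers) | duplicated(kmers, fromLast = TRUE))
  vals <- as.list((0:(n - 1L))[uni])
  names(vals) <- kmers[uni]
  env <- list2env(vals, envir = new.env(hash = TRUE, size = length(vals)))
  list(env = env, k = k)
}

# Walk outward from `from` (0-based) in direction -1/+1 until a lysogen
# k-mer anchors uniquely in the reference AND extends into a match of at
# least `min_match` bp (short spurious anchors - e.g. a spacer whose
# protospacer copy sits in the reference CRISPR array - are skipped, as a
# collinear MUM chain would skip them). Returns c(lysogen_pos, ref_pos) or
# NULL.
find_anchor <- function(lysogen, index, from, direction, reference,
                        step = 7L, min_match = 150L) {
  k <- index$k
  n <- nchar(lysogen)
  p <- from
  while (p >= 0 && p + k <= n) {
    km <- subseq0(lysogen, p, p + k)
    hit <- get0(km, envir = index$env, inherits = FALSE)
    if (!is.null(hit)) {
      total <- k +
        extend_match(lysogen, reference, p + k, hit + k, +1L,
                     cap = min_match) +
        extend_match(lysogen, reference, p, hit, -1L, cap = min_match)
      if (total >= min_match) return(c(p, hit))
    }
    p <- p + direction * step
  }
  NULL
}

# Maximal exact extension of a match seeded at lysogen pos lp / ref pos rp
# (both 0-based), towards +1 (right) or -1 (left of the given positions),
# compared block-wise; `cap` short-circuits once that many matching bases
# are confirmed.
extend_match <- function(lysogen, reference, lp, rp, direction,
                         cap = Inf, block = 4096L) {
  n1 <- nchar(lysogen); n2 <- nchar(reference)
  e <- 0L
  repeat {
    if (e >= cap) return(e)
    w <- if (direction > 0) {
      min(block, n1 - (lp + e), n2 - (rp + e))
    } else {
      min(block, lp - e, rp - e)
    }
    if (w <= 0) return(e)
    if (direction > 0) {
      a <- charToRaw(substr(lysogen, lp + e + 1L, lp + e + w))
      b <- charToRaw(substr(reference, rp + e + 1L, rp + e + w))
      neq <- which(a != b)
      if (length(neq)) return(e + neq[1] - 1L)
    } else {
      a <- charToRaw(substr(lysogen, lp - e - w + 1L, lp - e))
      b <- charToRaw(substr(reference, rp - e - w + 1L, rp - e))
      neq <- which(rev(a) != rev(b))
      if (length(neq)) return(e + neq[1] - 1L)
    }
    e <- e + w
  }
}

#' Delineate prophage boundaries against a prophage-free reference
#'
#' Anchors the lysogen to the reference with unique 20-mer exact matches on
#' both sides of a hallmark candidate locus and extends each anchor
#' maximally. The prophage is the maximal lysogen segment absent from the
#' reference that contains the candidate. The region is complete iff both
#' flanks anchor and their reference positions meet (a junction direct
#' repeat may make them overlap by up to the repeat length, so up to
#' `max_ref_gap` of overlap or gap is tolerated); a side without an anchor
#' (e.g. a contig end) leaves that terminus open.
#'
#' @param lysogen,reference single-genome tibbles (or one row each) with
#'   `genome_id` and `sequence`
#' @param candidate one row of [screen_hallmarks()] output
#' @param anchor_k anchor length (bp)
#' @param max_ref_gap tolerated reference gap/overlap between the two flank
#'   mappings for a region to be called complete
#' @param index optional prebuilt [reference_anchor_index()] of the
#'   reference, reused across candidates on the same genome
#' @return one-row tibble: `genome_id`, `start`, `end`, `complete`,
#'   `left_open`, `right_open`
#' @export
delineate_boundaries <- function(lysogen, reference, candidate,
                                 anchor_k = 20L, max_ref_gap = 200L,
                                 index = NULL) {
  lys <- lysogen$sequence[[1]]
  ref <- reference$sequence[[1]]
  idx <- index %||% reference_anchor_index(ref, k = anchor_k)
  n <- nchar(lys)
  left <- find_anchor(lys, idx, from = candidate$start, direction = -1L,
                      reference = ref)
  right <- find_anchor(lys, idx, from = candidate$end - anchor_k,
                       direction = +1L, reference = ref)
  left_open <- is.null(left)
  right_open <- is.null(right)
  if (!left_open) {
    e <- extend_match(lys, ref, left[1] + anchor_k, left[2] + anchor_k, +1L)
    start <- left[1] + anchor_k + e
    ref_left <- left[2] + anchor_k + e
  } else {
    start <- 0L
    ref_left <- NA_integer_
  }
  if (!right_open) {
    e <- extend_match(lys, ref, right[1], right[2], -1L)
    end <- right[1] - e
    ref_right <- right[2] - e
  } else {
    end <- n
    ref_right <- NA_integer_
  }
  # flank mappings overlapping in the reference (a junction repeat, or a
  # chance shared edge base) leave the interval short by the overlap;
  # retracting the left boundary by it makes the removal exact
  if (!left_open && !right_open) {
    overlap <- ref_left - ref_right
    if (overlap > 0 && overlap <= start) {
      start <- start - overlap
      ref_left <- ref_left - overlap
    }
  }
  complete <- !left_open && !right_open &&
    abs(ref_right - ref_left) <= max_ref_gap
  tibble::tibble(genome_id = lysogen$genome_id[[1]],
                 start = as.integer(start), end = as.integer(end),
                 complete = complete,
                 left_open = left_open, right_open = right_open)
}

#' Predict att sites from boundary-flanking direct repeats
#'
#' Searches 500 bp windows centred on each boundary of a complete region
#' for the longest exact direct repeat (>= `min_repeat` nt, occurring once
#' per window). When found, the region is snapped so that it is flanked by
#' the attL/attR copies (the reported interval runs from the start of attL
#' to the start of attR, i.e. it carries exactly one att copy), and the
#' attB locus is any tRNA feature whose sequence contains the core in
#' either orientation.
#'
#' @param region one-row tibble with `genome_id`, `start`, `end`
#' @param genome one-row genomes tibble for the host
#' @param features host features tibble (for tRNA lookup)
#' @param window half-window... total window size (bp) centred on each boundary
#' @param min_repeat minimum att core length
#' @return one-row tibble: `start`, `end` (snapped), `att_core`,
#'   `attb_feature_id`, `attb_isotype` (NA when no repeat qualifies)
#' @export
predict_att <- function(region, genome, features, window = 500L,
                        min_repeat = 15L) {
  seq <- genome$sequence[[1]]
  n <- nchar(seq)
  half <- window %/% 2L
  lw_start <- max(0L, region$start - half)
  rw_start <- max(0L, region$end - half)
  left_win <- subseq0(seq, lw_start, min(n, region$start + half))
  right_win <- subseq0(seq, rw_start, min(n, region$end + half))
  hit <- longest_unique_common_substring(left_win, right_win,
                                         min_len = min_repeat)
  empty <- tibble::tibble(start = region$start, end = region$end,
                          att_core = NA_character_,
                          attb_feature_id = NA_character_,
                          attb_isotype = NA_character_)
  if (is.null(hit)) return(empty)
  att_start <- lw_start + hit$pos_a           # attL start (genome coords)
  attr_start <- rw_start + hit$pos_b          # attR start
  core <- hit$s
  # self-check: the snapped region must be flanked by the direct repeat
  if (subseq0(seq, att_start, att_start + nchar(core)) != core ||
      subseq0(seq, attr_start, attr_start + nchar(core)) != core) {
    return(empty)
  }
  trnas <- dplyr::filter(features, .data$genome_id == genome$genome_id[[1]],
                         .data$kind == "tRNA")
  attb_id <- NA_character_; attb_iso <- NA_character_
  for (i in seq_len(nrow(trnas))) {
    ts <- feature_sequence(genome, trnas[i, ])
    if (grepl(core, ts, fixed = TRUE) ||
        grepl(reverse_complement(core), ts, fixed = TRUE)) {
      attb_id <- trnas$feature_id[i]
      attb_iso <- trnas$isotype[i]
      break
    }
  }
  tibble::tibble(start = att_start, end = attr_start, att_core = core,
                 attb_feature_id = attb_id, attb_isotype = attb_iso)
}

#' GC content of a genome region
#'
#' `(G+C) / (A+C+G+T)` over the region; `N` bases are excluded from the
#' denominator, and an all-N region yields `NA`.
#'
#' @param genome one-row genomes tibble
#' @param start,end 0-based half-open interval
#' @return fraction in \[0, 1\] or `NA`
#' @export
region_gc <- function(genome, start, end) {
  gc_content(subseq0(genome$sequence[[1]], start, end))
}

#' Find prophages in a cohort of genomes
#'
#' End-to-end discovery: hallmark screening, boundary delineation against
#' per-genome prophage-free references, att prediction and GC computation.
#'
#' @param genomes lysogen genomes tibble
#' @param features features tibble
#' @param references prophage-free reference genomes tibble (matched by
#'   `genome_id`)
#' @return tibble with one row per prophage region: coordinates, size,
#'   completeness, GC, att core and attB locus
#' @export
find_prophages <- function(genomes, features, references) {
  cands <- screen_hallmarks(features)
  index_cache <- new.env(parent = emptyenv())
  out <- lapply(seq_len(nrow(cands)), function(i) {
    cand <- cands[i, ]
    genome <- genomes[match(cand$genome_id, genomes$genome_id), ]
    ref <- references[match(cand$genome_id, references$genome_id), ]
    if (is.null(index_cache[[cand$genome_id]])) {
      index_cache[[cand$genome_id]] <-
        reference_anchor_index(ref$sequence[[1]])
    }
    region <- delineate_boundaries(genome, ref, cand,
                                   index = index_cache[[cand$genome_id]])
    att <- predict_att(region, genome, features)
    res <- tibble::tibble(
      genome_id = cand$genome_id,
      prophage_id = sprintf("%s_prophage_%d", cand$genome_id, i),
      start = att$start, end = att$end,
      complete = region$complete,
      att_core = att$att_core,
      attb_feature_id = att$attb_feature_id,
      attb_isotype = att$attb_isotype)
    res$size <- res$end - res$start
    res$gc <- region_gc(genome, res$start, res$end)
    res
  })
  dplyr::bind_rows(out)
}
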