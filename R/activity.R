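# Prophage-activity evidence: coverage-ratio analysis and in-silico
# excision / circularisation with attP junction reconstruction and PCR
# emulation.

#' Prophage / host read-depth ratio
#'
#' Mean depth inside the prophage interval divided by mean depth over the
#' host background. The background excludes all prophage intervals (not
#' just the one under test) so a multi-prophage host does not deflate the
#' contrast; the ratio is invariant under rescaling the whole profile.
#'
#' @param depth depth tibble (`chrom`, `pos0`, `depth`) for one genome
#' @param interval c(start, end), 0-based half-open
#' @param exclude optional tibble of all prophage intervals (`start`,
#'   `end`) to drop from the host background; defaults to `interval` only
#' @param stat `"mean"` (as reported by coverage tools) or `"median"`
#' @return the fold ratio (`NA` with a warning if host depth is zero)
#' @export
coverage_ratio <- function(depth, interval, exclude = NULL, stat = c("mean", "median")) {
  stat <- rlang::arg_match(stat)
  f <- if (stat == "mean") mean else stats::median
  abort_if(interval[1] < 0 || interval[2] > nrow(depth),
           "interval outside the depth profile")
  inside <- depth$pos0 >= interval[1] & depth$pos0 < interval[2]
  if (is.null(exclude)) {
    exclude <- tibble::tibble(start = interval[1], end = interval[2])
  }
  host <- rep(TRUE, nrow(depth))
  for (i in seq_len(nrow(exclude))) {
    host[depth$pos0 >= exclude$start[i] & depth$pos0 < exclude$end[i]] <- FALSE
  }
  host_depth <- f(depth$depth[host])
  if (is.na(host_depth) || host_depth == 0) {
    rlang::warn("host background depth is zero; ratio undefined")
    return(NA_real_)
  }
  f(depth$depth[inside]) / host_depth
}

#' Excise a prophage in silico
#'
#' Reverses integration: the host is restored as left flank + one att core
#' + right flank (the attB site), and the prophage circularises as its
#' interior plus one att core (restoring attP). The attP junction is the
#' 100 nt of the circular genome centred on the att core - the sequence a
#' junction-spanning amplicon would read. Length conservation holds
#' exactly: the lysogen carries two att copies and each product one, so
#' `len(lysogen) = len(restored_host) + len(circle)`.
#'
#' @param genome one-row genomes tibble (the lysogen)
#' @param region one-row prophage tibble with `start`, `end`, `att_core`
#'   (interval carrying exactly one att copy at its start, attR
#'   immediately after - the convention of [predict_att()] and
#'   [plant_prophage()])
#' @param junction_width width of the reported attP junction (nt)
#' @return list with `restored_host` (tibble), `circular_sequence`,
#'   `attp_junction`
#' @export
excise_prophage <- function(genome, region, junction_width = 100L) {
  abort_if(is.null(region$att_core) || is.na(region$att_core),
           "att core unknown; run predict_att() first")
  seq <- genome$sequence[[1]]
  core <- region$att_core
  c_len <- nchar(core)
  s <- region$start; e <- region$end
  abort_if(subseq0(seq, s, s + c_len) != core,
           "attL not present at the region start")
  abort_if(subseq0(seq, e, e + c_len) != core,
           "attR not present after the region end")
  circle <- subseq0(seq, s, e)
  restored <- paste0(subseq0(seq, 0, s), subseq0(seq, e, nchar(seq)))
  # junction: centre of the att core, with wrap-around on the circle
  lc <- nchar(circle)
  centre <- c_len %/% 2L
  offs <- (centre - junction_width %/% 2L + seq_len(junction_width) - 1L) %% lc
  junction <- paste(strsplit(circle, "", fixed = TRUE)[[1]][offs + 1L],
                    collapse = "")
  list(
    restored_host = tibble::tibble(genome_id = genome$genome_id[[1]],
                                   sequence = restored),
    circular_sequence = circle,
    attp_junction = junction)
}

#' In-silico PCR on a linear or circular template
#'
#' Exact primer matching: the forward primer anneals on the plus strand,
#' the reverse primer as its reverse complement on the minus strand;
#' convergent primer pairs within `max_product` bp yield a product. On
#' circular templates the search wraps across the origin.
#'
#' @param template nucleotide string
#' @param fwd,rev primer sequences (>= 15 nt)
#' @param circular is the template circular?
#' @param max_product maximum product length (bp)
#' @return character vector of product sequences (possibly empty)
#' @export
insilico_pcr <- function(template, fwd, rev, circular = FALSE,
                         max_product = 3000L) {
  abort_if(nchar(fwd) < 15 || nchar(rev) < 15, "primers must be >= 15 nt")
  n <- nchar(template)
  search_space <- if (circular) {
    paste0(template, subseq0(template, 0, min(n, max_product)))
  } else {
    template
  }
  fwd_pos <- motif_positions(search_space, toupper(fwd))
  rev_site <- reverse_complement(toupper(rev))
  rev_pos <- motif_positions(search_space, rev_site)
  if (circular) {
    fwd_pos <- fwd_pos[fwd_pos < n]          # one origin per template
  }
  products <- character(0)
  for (f in fwd_pos) {
    for (r in rev_pos) {
      pe <- r + nchar(rev_site)
      len <- pe - f
      if (len >= nchar(fwd) + nchar(rev) && len <= max_product) {
        products <- c(products, subseq0(search_space, f, pe))
      }
    }
  }
  unique(products)
}

#' Junction-PCR discrimination of prophage excision
#'
#' Designs outward-facing primers around the att junction of the planted
#' prophage (forward primer near the region end, reverse primer near the
#' region start) and runs [insilico_pcr()] on both the integrated lysogen
#' (linear) and the excised circle. Amplification from the circular form
#' only - with the product spanning the att core - is the in-silico
#' equivalent of the attP circularisation assay.
#'
#' @param genome one-row lysogen tibble
#' @param region one-row prophage tibble (`start`, `end`, `att_core`)
#' @param primer_len primer length
#' @return list with `lysogen_products`, `circle_products`,
#'   `junction_detected` (TRUE iff the circle, and only the circle,
#'   amplifies a product containing the att core)
#' @export
attp_junction_pcr <- function(genome, region, primer_len = 20L) {
  ex <- excise_prophage(genome, region)
  circle <- ex$circular_sequence
  lc <- nchar(circle)
  c_len <- nchar(region$att_core)
  # primers flank the wrap-around junction of the circle:
  # fwd reads toward the end of the interior, rev reads back from the core
  fwd <- subseq0(circle, lc - 400L, lc - 400L + primer_len)
  rev <- reverse_complement(subseq0(circle, c_len + 200L,
                                    c_len + 200L + primer_len))
  lys <- insilico_pcr(genome$sequence[[1]], fwd, rev, circular = FALSE)
  cir <- insilico_pcr(circle, fwd, rev, circular = TRUE)
  list(
    lysogen_products = lys,
    circle_products = cir,
    junction_detected = length(lys) == 0 && length(cir) > 0 &&
      any(grepl(region$att_core, cir, fixed = TRUE)))
}

#' Activity evidence table for a cohort
#'
#' Coverage fold per prophage (from a depth track) and junction-PCR
#' detection per prophage with a known att core.
#'
#' @param genomes lysogen genomes tibble
#' @param prophages prophage tibble (`prophage_id`, `genome_id`, `start`,
#'   `end`, `att_core`)
#' @param depth depth tibble covering the genomes in `prophages`
#' @return tibble with `prophage_id`, `fold`, `junction_detected`
#' @export
activity_evidence <- function(genomes, prophages, depth) {
  out <- lapply(seq_len(nrow(prophages)), function(i) {
    p <- prophages[i, ]
    d <- dplyr::filter(depth, .data$chrom == p$genome_id)
    siblings <- dplyr::filter(prophages, .data$genome_id == p$genome_id)
    fold <- if (nrow(d) > 0) {
      coverage_ratio(d, c(p$start, p$end),
                     exclude = siblings[, c("start", "end")])
    } else {
      NA_real_
    }
    jd <- if (!is.na(p$att_core)) {
      g <- genomes[match(p$genome_id, genomes$genome_id), ]
      attp_junction_pcr(g, p)$junction_detected
    } else {
      NA
    }
    tibble::tibble(prophage_id = p$prophage_id, fold = fold,
                   junction_detected = jd)
  })
  dplyr::bind_rows(out)
}
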