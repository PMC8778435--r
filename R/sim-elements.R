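# Building blocks for the synthetic cohort: GC-controlled background
# sequence, clade ancestors with planted prophage anatomy (hallmark genes,
# DGR loci, shufflons), and the exported plant_* operations that insert
# prophages and CRISPR arrays into host genomes.

HALLMARK_PRODUCTS <- c("terminase, large subunit", "portal protein",
                       "major capsid protein")

HOST_PRODUCTS <- c(
  "DNA gyrase subunit A", "DNA-directed RNA polymerase subunit beta",
  "elongation factor Tu", "30S ribosomal protein S12",
  "50S ribosomal protein L2", "ATP synthase subunit alpha",
  "chaperonin GroEL", "DNA polymerase III subunit alpha",
  "phosphoglycerate kinase", "enolase", "recombinase RecA",
  "preprotein translocase subunit SecY", "signal recognition particle protein",
  "glutamine synthetase", "aspartate aminotransferase",
  "ABC transporter ATP-binding protein", "MFS transporter",
  "two-component sensor histidine kinase", "LacI family transcriptional regulator",
  "beta-lactamase", "cardiac glycoside reductase", "catechol dehydroxylase"
)

# Random DNA at a given GC, with the shufflon crossover motif (both
# orientations) scrubbed so motif scans recover only planted sites.
random_dna <- function(n, gc = 0.5, forbid = c("TTCCGTAT", "ATACGGAA")) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
             collapse = "")
  scrub_motifs(s, forbid, allowed = integer(0), protected = integer(0), gc = gc)
}

# Remove non-planted occurrences of the given motifs by re-drawing one
# unprotected base inside each occurrence; iterates until clean.
scrub_motifs <- function(seq, motifs, allowed, protected, gc = 0.5) {
  if (length(motifs) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  for (iter in 1:50) {
    s <- paste(chars, collapse = "")
    occ <- unlist(lapply(motifs, function(m) {
      pos <- motif_positions(s, m)
      pos[!(pos %in% allowed)]
    }))
    if (length(occ) == 0) return(s)
    for (o in occ) {
      idx <- setdiff((o + 1):(o + nchar(motifs[[1]])), protected + 1L)
      if (length(idx) == 0) next
      i <- if (length(idx) == 1) idx else sample(idx, 1)
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1,
                         prob = p[match(setdiff(c("A", "C", "G", "T"), chars[i]),
                                        c("A", "C", "G", "T"))])
    }
  }
  rlang::abort("could not scrub forbidden motifs from generated sequence")
}

# Substitute `rate` of the unprotected positions to a different base.
mutate_sequence <- function(seq, rate, protected = integer(0)) {
  n <- nchar(seq)
  free <- setdiff(seq_len(n), protected + 1L)
  n_mut <- round(rate * length(free))
  if (n_mut == 0) return(seq)
  pos <- sample(free, n_mut)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[pos] <- vapply(chars[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1), USE.NAMES = FALSE)
  paste(chars, collapse = "")
}

replace_range <- function(seq, start, end, replacement) {
  stopifnot(nchar(replacement) == end - start)
  paste0(substr(seq, 1, start), replacement, substr(seq, end + 1, nchar(seq)))
}

gene_row <- function(start, end, product, strand = "+") {
  tibble::tibble(kind = "gene", start = start, end = end, strand = strand,
                 product = product, locus_tag = NA_character_,
                 isotype = NA_character_)
}

#' Write a diversity-generating retroelement into a prophage sequence
#'
#' Plants the canonical DGR anatomy near the 3' end of the supplied
#' sequence: a major tropism determinant gene (`mtd`) carrying the variable
#' repeat (VR), an accessory variability determinant (`avd`, TR-upstream
#' architecture only), the template repeat (TR), and the reverse
#' transcriptase gene. In the `"upstream"` architecture the TR lies between
#' `avd` and the RT gene; in the `"within"` architecture the TR is nested
#' inside the RT gene and the VR sits at the 5' end of `mtd`. The planted VR
#' is an exact copy of the TR; the returned variable-site offsets mark where
#' isolate-specific substitutions are introduced downstream (see
#' [generate_cohort()]), keeping TR/VR identity above 90%.
#'
#' @param prophage_seq nucleotide string (a prophage interior)
#' @param tr_length template repeat length (120-135)
#' @param n_variable_sites number of variable sites in the VR
#' @param style `"upstream"` (TR upstream of the RT gene) or `"within"`
#'   (TR inside the RT gene)
#' @return list with `sequence` (modified), `features` (gene rows, relative
#'   coordinates) and `dgr` (TR/VR intervals, variable-site offsets within
#'   VR, architecture)
#' @export
plant_dgr <- function(prophage_seq, tr_length = 130, n_variable_sites = 10,
                      style = c("upstream", "within")) {
  style <- rlang::arg_match(style)
  abort_if(tr_length < 120 || tr_length > 135, "TR length must be in [120, 135]")
  abort_if((tr_length - n_variable_sites) / tr_length <= 0.90,
           "variable sites incompatible with >90% TR/VR identity")
  L <- nchar(prophage_seq)
  abort_if(L < 8000, "prophage sequence too short for a DGR locus")
  if (style == "upstream") {
    mtd <- c(L - 6000, L - 3800)
    vr <- c(L - 4000, L - 4000 + tr_length)
    avd <- c(L - 3700, L - 3400)
    tr <- c(L - 3300, L - 3300 + tr_length)
    ert <- c(L - 3100, L - 1300)
    feats <- dplyr::bind_rows(
      gene_row(mtd[1], mtd[2], "major tropism determinant"),
      gene_row(avd[1], avd[2], "accessory variability determinant"),
      gene_row(ert[1], ert[2], "reverse transcriptase")
    )
  } else {
    ert <- c(L - 5600, L - 3600)
    tr <- c(L - 5000, L - 5000 + tr_length)
    mtd <- c(L - 3400, L - 1600)
    vr <- c(L - 3380, L - 3380 + tr_length)
    feats <- dplyr::bind_rows(
      gene_row(ert[1], ert[2], "reverse transcriptase"),
      gene_row(mtd[1], mtd[2], "major tropism determinant")
    )
  }
  tr_seq <- subseq0(prophage_seq, tr[1], tr[2])
  seq2 <- replace_range(prophage_seq, vr[1], vr[2], tr_seq)
  # sites sit in the repeat interior: an edge substitution is
  # indistinguishable from the repeat boundary under local alignment
  sites <- sort(sample(5:(tr_length - 6L), n_variable_sites))
  list(
    sequence = seq2,
    features = feats,
    dgr = list(tr = tr, vr = vr, variable_sites = sites,
               architecture = if (style == "upstream") "TR_upstream_of_ert"
                              else "TR_within_ert")
  )
}

#' Write a tyrosine-invertase (Rin) shufflon into a prophage sequence
#'
#' Plants a recombinase gene followed by `n_rv` small cassette genes (Rv),
#' each delimited by the asymmetric crossover 8-mer (`rix`) in direct
#' orientation, then a larger Rc gene carrying one inverted rix inside its
#' 3' end and one immediately downstream of its stop. The 3' segment of each
#' Rv is a diverged copy of the Rc C-terminus (the planted homology the
#' shufflon shuffles), while Rv 5' halves are unrelated, keeping pairwise
#' Rv identity low.
#'
#' @param prophage_seq nucleotide string (a prophage interior)
#' @param n_rv number of Rv cassettes (>= 1)
#' @param rix_motif crossover motif (default the asymmetric 8-mer)
#' @param at 0-based offset at which the locus starts
#' @param rv_length,rc_length cassette and Rc gene lengths
#' @param homology_divergence substitution rate applied to the Rc C-terminus
#'   copy planted at each Rv 3' end
#' @return list with `sequence`, `features`, and `shufflon` truth (rix
#'   positions/orientations, Rv segment intervals, Rin and Rc intervals)
#' @export
plant_shufflon <- function(prophage_seq, n_rv = 3, rix_motif = "TTCCGTAT",
                           at = 8200, rv_length = 250, rc_length = 1500,
                           homology_divergence = 0.30) {
  abort_if(n_rv < 1, "`n_rv` must be >= 1")
  rix_motif <- toupper(rix_motif)
  m <- nchar(rix_motif)
  rin <- c(at, at + 1100)
  cass0 <- rin[2] + 100
  period <- rv_length + m
  rix_direct <- cass0 + period * (0:n_rv)
  rv_segs <- tibble::tibble(start = rix_direct[-(n_rv + 1)] + m,
                            end = rix_direct[-1])
  rc <- c(rix_direct[n_rv + 1] + m + 60, rix_direct[n_rv + 1] + m + 60 + rc_length)
  rix_in_rc <- rc[2] - 150
  rix_after_rc <- rc[2] + 10
  L <- nchar(prophage_seq)
  abort_if(rix_after_rc + m > L, "prophage sequence too short for the shufflon")
  seq2 <- prophage_seq
  for (p in rix_direct) seq2 <- replace_range(seq2, p, p + m, rix_motif)
  rc_motif <- reverse_complement(rix_motif)
  seq2 <- replace_range(seq2, rix_in_rc, rix_in_rc + m, rc_motif)
  seq2 <- replace_range(seq2, rix_after_rc, rix_after_rc + m, rc_motif)
  # plant Rv ~ Rc C-terminal homology
  hom_len <- min(125, rv_length %/% 2)
  rc_cterm <- subseq0(seq2, rix_in_rc + m + 2, rix_in_rc + m + 2 + hom_len)
  for (i in seq_len(n_rv)) {
    seg <- mutate_sequence(rc_cterm, homology_divergence)
    seq2 <- replace_range(seq2, rv_segs$end[i] - hom_len, rv_segs$end[i], seg)
  }
  # scrub any motif copies the homology planting may have produced
  allowed <- c(rix_direct, rix_in_rc, rix_after_rc)
  allowed_rc <- c(rix_in_rc, rix_after_rc)
  prot <- unlist(lapply(allowed, function(p) p:(p + m - 1L)))
  seq2 <- scrub_motifs(seq2, c(rix_motif), allowed = rix_direct, protected = prot)
  seq2 <- scrub_motifs(seq2, c(rc_motif), allowed = allowed_rc, protected = prot)
  feats <- dplyr::bind_rows(
    gene_row(rin[1], rin[2], "tyrosine-type DNA invertase"),
    do.call(dplyr::bind_rows, lapply(seq_len(n_rv), function(i) {
      gene_row(rv_segs$start[i], rv_segs$end[i], "H-type lectin domain protein")
    })),
    gene_row(rc[1], rc[2], "receptor-binding protein")
  )
  rix_tbl <- dplyr::bind_rows(
    tibble::tibble(position = rix_direct, orientation = "direct"),
    tibble::tibble(position = c(rix_in_rc, rix_after_rc),
                   orientation = "inverted")
  )
  list(
    sequence = seq2,
    features = feats,
    shufflon = list(rix = rix_tbl, rv_segments = rv_segs,
                    rin = rin, rc = rc, motif = rix_motif)
  )
}

# A clade ancestor: prophage interior with hallmark anatomy and, per style,
# a DGR locus or a shufflon. Protected positions (att-critical regions, TR,
# VR, rix sites) are excluded from member-level mutation.
build_clade_ancestor <- function(style, interior_len, gc, cfg) {
  seq <- random_dna(interior_len, gc)
  L <- interior_len
  feats <- dplyr::bind_rows(
    gene_row(100, 1300, "tyrosine integrase"),
    gene_row(2000, 3500, "terminase, large subunit"),
    gene_row(3600, 5000, "portal protein"),
    gene_row(5100, 6400, "major capsid protein"),
    gene_row(6600, 8000, "tail tape measure protein"),
    gene_row(L - 2600, L - 2300, "holin"),
    gene_row(L - 2200, L - 1400, "endolysin, amidase"),
    gene_row(L - 1200, L - 500, "Cro/C1-type repressor")
  )
  dgr <- NULL
  shuf <- NULL
  protected <- integer(0)
  if (style %in% c("dgr_upstream", "dgr_within")) {
    pl <- plant_dgr(seq,
                    tr_length = if (style == "dgr_upstream") cfg$tr_length
                                else cfg$tr_length_within,
                    n_variable_sites = cfg$n_variable_sites,
                    style = if (style == "dgr_upstream") "upstream" else "within")
    seq <- pl$sequence
    feats <- dplyr::bind_rows(feats, pl$features)
    dgr <- pl$dgr
    protected <- c(protected, dgr$tr[1]:(dgr$tr[2] - 1L),
                   dgr$vr[1]:(dgr$vr[2] - 1L))
  }
  if (style == "shufflon") {
    pl <- plant_shufflon(seq, n_rv = cfg$n_rv, rix_motif = cfg$rix_motif)
    seq <- pl$sequence
    feats <- dplyr::bind_rows(feats, pl$features)
    shuf <- pl$shufflon
    m <- nchar(cfg$rix_motif)
    protected <- c(protected,
                   unlist(lapply(shuf$rix$position, function(p) p:(p + m - 1L))))
  }
  list(style = style, sequence = seq, features = feats, dgr = dgr,
       shufflon = shuf, protected = protected, gc = gc)
}

# Derive a related ancestor sharing roughly half of `anc`: the central block
# is replaced with fresh sequence and the shared part lightly diverged.
derive_related_ancestor <- function(anc, cfg) {
  L <- nchar(anc$sequence)
  a <- round(0.55 * L); b <- round(0.93 * L)
  mid <- random_dna(b - a, anc$gc)
  seq <- replace_range(anc$sequence, a, b, mid)
  seq <- mutate_sequence(seq, 0.02, protected = c(a:(b - 1L)))
  feats <- dplyr::filter(anc$features, .data$end <= a)
  list(style = "related", sequence = seq, features = feats, dgr = NULL,
       shufflon = NULL, protected = integer(0), gc = anc$gc)
}

# A clade member: ancestor diverged at the configured rate outside protected
# positions; DGR variable sites substituted to a non-template base so each
# isolate's VR differs from the TR at exactly those offsets.
build_member_interior <- function(anc, cfg) {
  seq <- mutate_sequence(anc$sequence, cfg$within_clade_divergence,
                         protected = anc$protected)
  if (!is.null(anc$dgr)) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    tr_chars <- chars[(anc$dgr$tr[1] + 1L):(anc$dgr$tr[2])]
    for (o in anc$dgr$variable_sites) {
      i <- anc$dgr$vr[1] + o + 1L
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), tr_chars[o + 1L]), 1)
    }
    seq <- paste(chars, collapse = "")
  }
  allowed <- if (!is.null(anc$shufflon)) anc$shufflon$rix$position else integer(0)
  m <- nchar(cfg$rix_motif)
  allowed_dir <- if (!is.null(anc$shufflon)) {
    anc$shufflon$rix$position[anc$shufflon$rix$orientation == "direct"]
  } else integer(0)
  allowed_inv <- if (!is.null(anc$shufflon)) {
    anc$shufflon$rix$position[anc$shufflon$rix$orientation == "inverted"]
  } else integer(0)
  prot <- unlist(lapply(allowed, function(p) p:(p + m - 1L)))
  seq <- scrub_motifs(seq, cfg$rix_motif, allowed = allowed_dir,
                      protected = prot)
  seq <- scrub_motifs(seq, reverse_complement(cfg$rix_motif),
                      allowed = allowed_inv, protected = prot)
  seq
}

#' Insert a prophage at a tRNA gene, duplicating the att core
#'
#' The tRNA's 3' end must end with `att_core` (the attB core). The prophage
#' interior is inserted immediately after the tRNA followed by a second copy
#' of the core, so the integrated element is flanked by attL/attR direct
#' repeats. The prophage region is recorded as the interval from the start
#' of attL to the start of attR (one att copy per region), which makes the
#' excision arithmetic exact.
#'
#' @param genomes genomes tibble
#' @param features features tibble
#' @param genome_id host genome
#' @param interior prophage interior sequence (att-free)
#' @param att_core the att core (40-55 nt)
#' @param trna_feature_id feature id of the target tRNA
#' @param prophage_id identifier for the new prophage
#' @param interior_features optional gene rows relative to the interior
#' @return list with updated `genomes`, `features`, and a one-row `prophage`
#'   truth tibble (genome coordinates)
#' @export
plant_prophage <- function(genomes, features, genome_id, interior, att_core,
                           trna_feature_id, prophage_id = "phi1",
                           interior_features = NULL) {
  abort_if(nchar(att_core) < 40 || nchar(att_core) > 55,
           "att core must be 40-55 nt")
  gi <- match(genome_id, genomes$genome_id)
  abort_if(is.na(gi), sprintf("unknown genome '%s'", genome_id))
  trna <- dplyr::filter(features, .data$genome_id == !!genome_id,
                        .data$feature_id == !!trna_feature_id)
  abort_if(nrow(trna) != 1 || trna$kind != "tRNA",
           sprintf("'%s' is not a tRNA feature of %s", trna_feature_id, genome_id))
  seq <- genomes$sequence[gi]
  trna_seq <- subseq0(seq, trna$start, trna$end)
  abort_if(!endsWith(trna_seq, att_core),
           "att core not found at the 3' end of the target tRNA")
  c_len <- nchar(att_core)
  i_len <- nchar(interior)
  ins_at <- trna$end
  new_seq <- paste0(subseq0(seq, 0, ins_at), interior, att_core,
                    subseq0(seq, ins_at, nchar(seq)))
  genomes$sequence[gi] <- new_seq
  shift <- i_len + c_len
  features <- dplyr::mutate(
    features,
    start = dplyr::if_else(.data$genome_id == !!genome_id & .data$start >= ins_at,
                           .data$start + shift, .data$start),
    end = dplyr::if_else(.data$genome_id == !!genome_id & .data$end > ins_at,
                         .data$end + shift, .data$end)
  )
  region_start <- ins_at - c_len
  region_end <- ins_at + i_len
  new_feats <- tibble::tibble(
    genome_id = genome_id,
    feature_id = c(paste0(prophage_id, "_region"),
                   paste0(prophage_id, "_attL"), paste0(prophage_id, "_attR")),
    kind = c("prophage", "repeat", "repeat"),
    start = c(region_start, region_start, region_end),
    end = c(region_end, ins_at, region_end + c_len),
    strand = "+",
    product = c(NA_character_, "attL direct repeat", "attR direct repeat"),
    locus_tag = NA_character_, isotype = NA_character_
  )
  if (!is.null(interior_features) && nrow(interior_features) > 0) {
    gene_feats <- dplyr::mutate(
      interior_features,
      genome_id = genome_id,
      feature_id = paste0(prophage_id, "_g", dplyr::row_number()),
      start = .data$start + ins_at, end = .data$end + ins_at
    )
    new_feats <- dplyr::bind_rows(new_feats, gene_feats)
  }
  features <- dplyr::bind_rows(features, new_feats)
  prophage <- tibble::tibble(
    prophage_id = prophage_id, genome_id = genome_id,
    start = region_start, end = region_end,
    att_core = att_core, attb_feature_id = trna_feature_id,
    attb_isotype = trna$isotype
  )
  list(genomes = genomes, features = features, prophage = prophage)
}

#' Insert a CRISPR repeat-spacer array into a genome
#'
#' Lays the array out as repeat-spacer-repeat-...-repeat (`n` spacers,
#' `n + 1` repeat copies) and inserts it at the given position, shifting
#' downstream features.
#'
#' @param genomes,features cohort tibbles
#' @param genome_id host genome
#' @param position 0-based insertion offset
#' @param repeat_seq the repeat (23-47 nt)
#' @param spacers character vector of spacers (>= 2, lengths 26-50)
#' @return list with updated `genomes`, `features`, and an `array` truth row
#' @export
plant_crispr_array <- function(genomes, features, genome_id, position,
                               repeat_seq, spacers) {
  abort_if(nchar(repeat_seq) < 23 || nchar(repeat_seq) > 47,
           "repeat length must be in [23, 47]")
  abort_if(length(spacers) < 2, "an array needs >= 3 repeat copies (>= 2 spacers)")
  abort_if(any(nchar(spacers) < 26 | nchar(spacers) > 50),
           "spacer lengths must be in [26, 50]")
  gi <- match(genome_id, genomes$genome_id)
  abort_if(is.na(gi), sprintf("unknown genome '%s'", genome_id))
  array_seq <- paste0(repeat_seq,
                      paste0(spacers, repeat_seq, collapse = ""))
  seq <- genomes$sequence[gi]
  abort_if(position < 0 || position > nchar(seq), "invalid insertion position")
  genomes$sequence[gi] <- paste0(subseq0(seq, 0, position), array_seq,
                                 subseq0(seq, position, nchar(seq)))
  shift <- nchar(array_seq)
  features <- dplyr::mutate(
    features,
    start = dplyr::if_else(.data$genome_id == !!genome_id & .data$start >= position,
                           .data$start + shift, .data$start),
    end = dplyr::if_else(.data$genome_id == !!genome_id & .data$end > position,
                         .data$end + shift, .data$end)
  )
  arr_feat <- tibble::tibble(
    genome_id = genome_id,
    feature_id = paste0(genome_id, "_crispr_", position),
    kind = "CRISPR_array", start = position, end = position + shift,
    strand = "+", product = NA_character_, locus_tag = NA_character_,
    isotype = NA_character_
  )
  features <- dplyr::bind_rows(features, arr_feat)
  list(genomes = genomes, features = features,
       array = tibble::tibble(genome_id = genome_id, start = position,
                              end = position + shift,
                              repeat_seq = repeat_seq,
                              n_spacers = length(spacers)))
}
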