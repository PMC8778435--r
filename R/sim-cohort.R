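# Whole-cohort synthesis: host backbones with a core/accessory/unique gene
# complement and tRNA integration targets, prophage planting per clade plan,
# CRISPR arrays whose spacers are derived from the planted prophages, and a
# machine-readable truth table. Fully deterministic given the config seed.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(prot, rate) {
  n <- nchar(prot)
  k <- round(rate * n)
  if (k == 0) return(prot)
  pos <- sample.int(n, k)
  chars <- strsplit(prot, "", fixed = TRUE)[[1]]
  chars[pos] <- vapply(chars[pos], function(a) sample(setdiff(AA20, a), 1),
                       character(1), USE.NAMES = FALSE)
  paste(chars, collapse = "")
}

codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

back_translate <- function(prot, codon_map) {
  aas <- strsplit(prot, "", fixed = TRUE)[[1]]
  codons <- vapply(aas, function(a) {
    opts <- codon_map[[a]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1), USE.NAMES = FALSE)
  paste0(paste(codons, collapse = ""), "TAA")
}

# ---- host gene complement ---------------------------------------------------

# Ancestral protein families plus a per-genome presence map giving the
# planted core/accessory/unique pangenome structure.
build_gene_plan <- function(cfg) {
  n <- cfg$n_genomes
  core <- tibble::tibble(
    og = sprintf("core_%03d", seq_len(cfg$n_core_genes)),
    protein = vapply(seq_len(cfg$n_core_genes),
                     function(i) random_protein(sample(100:300, 1)), character(1)),
    product = rep_len(HOST_PRODUCTS, cfg$n_core_genes),
    members = list(seq_len(n))
  )
  acc <- tibble::tibble(
    og = sprintf("acc_%03d", seq_len(cfg$n_accessory_genes)),
    protein = vapply(seq_len(cfg$n_accessory_genes),
                     function(i) random_protein(sample(100:300, 1)), character(1)),
    product = rep_len(rev(HOST_PRODUCTS), cfg$n_accessory_genes),
    members = lapply(seq_len(cfg$n_accessory_genes), function(i) {
      size <- sample(2:max(2, n - 1), 1)
      sort(sample.int(n, min(size, n)))
    })
  )
  uniq <- do.call(dplyr::bind_rows, lapply(seq_len(n), function(g) {
    tibble::tibble(
      og = sprintf("uniq_g%d_%02d", g, seq_len(cfg$n_unique_genes)),
      protein = vapply(seq_len(cfg$n_unique_genes),
                       function(i) random_protein(sample(100:300, 1)), character(1)),
      product = "hypothetical protein",
      members = lapply(seq_len(cfg$n_unique_genes), function(i) g)
    )
  }))
  dplyr::bind_rows(core, acc, uniq)
}

# ---- spacer plan ------------------------------------------------------------

# Which arrays exist and what each spacer targets. Targets reference
# prophages as genome/clade pairs; rows whose array genome or target
# prophage is absent from a (smaller) cohort are dropped.
default_spacer_plan <- function() {
  tibble::tribble(
    ~array_genome, ~target_genome, ~target_clade, ~mismatches, ~pam, ~strand,
    1, 1, 1, 0L, TRUE,  "+",
    1, 2, 1, 1L, FALSE, "-",
    1, 5, 2, 3L, FALSE, "+",
    1, 6, 2, 4L, FALSE, "+",
    2, 3, 1, 0L, TRUE,  "+",
    2, 10, 4, 2L, FALSE, "-",
    3, 4, 1, 1L, FALSE, "-",
    3, 8, 3, 0L, TRUE,  "+",
    4, 9, 3, 2L, FALSE, "+",
    4, 5, 5, 0L, FALSE, "-",
    5, 1, 1, 3L, TRUE,  "+",
    6, 7, 2, 1L, FALSE, "+",
    6, 10, 4, 0L, TRUE,  "+"
  )
}

# Force or suppress the 5'TCC PAM around a protospacer slot on the interior.
# Returns NULL if the edit would create a stray crossover motif nearby, so
# the caller can shift the slot.
apply_protospacer_flank <- function(interior, off, slen, strand, pam, motif) {
  set_range <- function(s, a, b, repl) replace_range(s, a, b, repl)
  if (strand == "+") {
    if (pam) interior <- set_range(interior, off - 3, off, "TCC")
    else if (subseq0(interior, off - 3, off) == "TCC")
      interior <- set_range(interior, off - 3, off, "AAC")
  } else {
    if (pam) interior <- set_range(interior, off + slen, off + slen + 3, "GGA")
    else if (subseq0(interior, off + slen, off + slen + 3) == "GGA")
      interior <- set_range(interior, off + slen, off + slen + 3, "GTT")
  }
  win <- subseq0(interior, max(0, off - 15), min(nchar(interior), off + slen + 15))
  if (length(motif_positions(win, motif)) > 0 ||
      length(motif_positions(win, reverse_complement(motif))) > 0) {
    return(NULL)
  }
  interior
}

apply_spacer_mismatches <- function(spacer, k) {
  if (k == 0) return(spacer)
  pos <- sample.int(nchar(spacer), k)
  chars <- strsplit(spacer, "", fixed = TRUE)[[1]]
  chars[pos] <- vapply(chars[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1), USE.NAMES = FALSE)
  paste(chars, collapse = "")
}

# ---- cohort generation ------------------------------------------------------

#' Generate a synthetic genome cohort with planted prophage truth
#'
#' Builds `n_genomes` host genomes, each carrying tRNA genes for the Leu,
#' Arg, Ala and Ser isotypes, a shared core gene complement plus accessory
#' and private genes, prophages planted per the default five-clade plan
#' (with attL/attR direct repeats at tRNA integration sites, one shufflon
#' clade, two DGR clades and one related clade pair), and CRISPR arrays
#' whose spacers are copied from planted prophages with controlled mismatch
#' counts and PAM placement. Byte-identical output for a given config seed.
#'
#' @param config a [sim_config()] object
#' @return a `phage_cohort`: list with `genomes` (lysogens), `references`
#'   (the same genomes without prophages), `features`, `truth` (tibbles:
#'   `prophages`, `genes`, `arrays`, `spacers`, `dgr`, `dgr_sites`,
#'   `shufflon`, `shufflon_rix`, `shufflon_rv`) and `config`
#' @export
generate_cohort <- function(config) {
  abort_if(!inherits(config, "sim_config"), "`config` must come from sim_config()")
  with_seed(config$seed, build_cohort(config))
}

build_cohort <- function(cfg) {
  n <- cfg$n_genomes
  genome_ids <- sprintf("g%02d", seq_len(n))
  plan <- default_clade_plan(n)
  if (!isTRUE(cfg$plant_prophages)) {
    plan$members <- lapply(plan$members, function(m) integer(0))
  }

  # clade ancestors (the related clade derives from the plain one)
  att_by_clade <- c("1" = CLADE1_ATT)
  ancestors <- list()
  for (i in seq_len(nrow(plan))) {
    cl <- plan$clade[i]; style <- plan$style[i]
    if (style == "related") {
      parent <- ancestors[[match("plain", plan$style)]]
      ancestors[[i]] <- derive_related_ancestor(parent, cfg)
      att_by_clade[as.character(cl)] <-
        att_by_clade[as.character(plan$clade[match("plain", plan$style)])]
    } else {
      len <- sample(cfg$prophage_size[1]:cfg$prophage_size[2], 1)
      gc <- stats::runif(1, cfg$prophage_gc[1], cfg$prophage_gc[2])
      ancestors[[i]] <- build_clade_ancestor(style, len, gc, cfg)
      if (!cl %in% as.integer(names(att_by_clade))) {
        att_by_clade[as.character(cl)] <- random_dna(43, 0.5)
      }
    }
  }

  # att core per tRNA isotype (shared clades share the isotype and core)
  att_by_isotype <- stats::setNames(
    att_by_clade[as.character(plan$clade)], plan$isotype)
  att_by_isotype <- att_by_isotype[!duplicated(names(att_by_isotype))]
  isotypes <- c("Leu", "Arg", "Ser", "Ala")
  for (iso in setdiff(isotypes, names(att_by_isotype))) {
    att_by_isotype[iso] <- random_dna(43, 0.5)
  }

  # member interiors
  members <- tidyr::unnest(
    dplyr::mutate(plan, genome = .data$members), cols = "genome")
  members <- dplyr::select(members, clade = "clade", style = "style",
                           isotype = "isotype", genome = "genome")
  members$prophage_id <- sprintf("g%02dphi%d", members$genome, members$clade)
  members$interior <- vapply(seq_len(nrow(members)), function(i) {
    anc <- ancestors[[match(members$clade[i], plan$clade)]]
    build_member_interior(anc, cfg)
  }, character(1))

  # protospacer slots and spacer derivation on the final interiors
  spacer_plan <- default_spacer_plan()
  spacer_plan <- dplyr::filter(
    spacer_plan,
    .data$array_genome <= n,
    sprintf("g%02dphi%d", .data$target_genome, .data$target_clade) %in%
      members$prophage_id
  )
  slen <- cfg$spacer_length
  slot_counter <- stats::setNames(rep(0L, nrow(members)), members$prophage_id)
  spacers <- list()
  for (i in seq_len(nrow(spacer_plan))) {
    sp <- spacer_plan[i, ]
    pid <- sprintf("g%02dphi%d", sp$target_genome, sp$target_clade)
    mi <- match(pid, members$prophage_id)
    interior <- members$interior[mi]
    repeat {
      off <- 13000L + 300L * slot_counter[[pid]]
      slot_counter[[pid]] <- slot_counter[[pid]] + 1L
      abort_if(off + slen + 3 > nchar(interior) - 7000,
               "ran out of protospacer slots")
      edited <- apply_protospacer_flank(interior, off, slen, sp$strand,
                                        sp$pam, cfg$rix_motif)
      if (!is.null(edited)) { interior <- edited; break }
    }
    members$interior[mi] <- interior
    seg <- subseq0(interior, off, off + slen)
    spacer0 <- if (sp$strand == "+") seg else reverse_complement(seg)
    spacer <- apply_spacer_mismatches(spacer0, sp$mismatches)
    att_len <- nchar(att_by_clade[[as.character(sp$target_clade)]])
    spacers[[i]] <- tibble::tibble(
      spacer_id = sprintf("sp_%02d", i),
      array_genome = sprintf("g%02d", sp$array_genome),
      sequence = spacer,
      target_prophage = pid,
      position = off + att_len,    # on the prophage region (attL + interior)
      strand = sp$strand,
      mismatches = sp$mismatches,
      pam = sp$pam
    )
  }
  spacers <- if (length(spacers)) dplyr::bind_rows(spacers) else
    tibble::tibble(spacer_id = character(), array_genome = character(),
                   sequence = character(), target_prophage = character(),
                   position = integer(), strand = character(),
                   mismatches = integer(), pam = logical())

  # per-array spacer lists: planted targeting spacers plus random filler
  array_genomes <- genome_ids[seq_len(min(6, n))]
  array_plan <- lapply(array_genomes, function(g) {
    planted <- spacers$sequence[spacers$array_genome == g]
    n_filler <- max(2L, 5L - length(planted))
    c(planted, vapply(seq_len(n_filler), function(i) random_dna(slen, 0.5),
                      character(1)))
  })
  names(array_plan) <- array_genomes
  array_repeats <- stats::setNames(
    vapply(array_genomes, function(g) random_dna(cfg$repeat_length, 0.5),
           character(1)), array_genomes)

  # gene complement
  gene_plan <- build_gene_plan(cfg)
  codon_map <- codons_by_aa()

  # backbone layout per genome
  genomes <- vector("list", n)
  feats <- vector("list", n)
  gene_truth <- list()
  for (g in seq_len(n)) {
    gid <- genome_ids[g]
    elements <- list()
    for (iso in isotypes) {
      core <- att_by_isotype[[iso]]
      pad <- random_dna(47, cfg$gc_content)
      elements[[length(elements) + 1L]] <- list(
        seq = paste0(pad, core),
        feats = tibble::tibble(kind = "tRNA", product = paste0("tRNA-", iso),
                               locus_tag = NA_character_, isotype = iso,
                               feature_id = paste0(gid, "_trna_", iso)))
    }
    here <- vapply(gene_plan$members, function(m) g %in% m, logical(1))
    genes_g <- gene_plan[here, ]
    for (j in seq_len(nrow(genes_g))) {
      prot <- if (startsWith(genes_g$og[j], "uniq")) genes_g$protein[j]
              else mutate_protein(genes_g$protein[j], 0.02)
      cds <- back_translate(prot, codon_map)
      fid <- sprintf("%s_%s", gid, genes_g$og[j])
      elements[[length(elements) + 1L]] <- list(
        seq = cds,
        feats = tibble::tibble(kind = "gene", product = genes_g$product[j],
                               locus_tag = fid, isotype = NA_character_,
                               feature_id = fid))
      gene_truth[[length(gene_truth) + 1L]] <-
        tibble::tibble(genome_id = gid, feature_id = fid, og = genes_g$og[j])
    }
    if (gid %in% array_genomes) {
      rep_seq <- array_repeats[[gid]]
      sps <- array_plan[[gid]]
      arr_seq <- paste0(rep_seq, paste0(sps, rep_seq, collapse = ""))
      elements[[length(elements) + 1L]] <- list(
        seq = arr_seq,
        feats = tibble::tibble(kind = "CRISPR_array", product = NA_character_,
                               locus_tag = NA_character_,
                               isotype = NA_character_,
                               feature_id = paste0(gid, "_crispr")))
    }
    # non-tRNA elements are shuffled; the four tRNAs are pinned at spread
    # positions (Leu/Ala/Ser/Arg at ~12.5/37.5/62.5/87.5% of the backbone)
    # so prophages co-hosted by one genome integrate > 60 kb apart and
    # their hallmark loci never merge into one candidate
    is_trna <- vapply(elements, function(e) e$feats$kind[1] == "tRNA",
                      logical(1))
    trna_elements <- elements[is_trna]
    trna_iso <- vapply(trna_elements, function(e) e$feats$isotype[1],
                       character(1))
    trna_elements <- trna_elements[match(c("Leu", "Ala", "Ser", "Arg"),
                                         trna_iso)]
    rest <- elements[!is_trna][sample.int(sum(!is_trna))]
    ranks <- pmax(1L, pmin(length(rest) + 1L,
                           round(c(0.125, 0.375, 0.625, 0.875) *
                                   (length(rest) + 4L))))
    elements <- rest
    for (t in seq_along(trna_elements)) {
      at <- min(ranks[t] + t - 1L, length(elements) + 1L)
      elements <- append(elements, trna_elements[t], after = at - 1L)
    }
    elen <- sum(vapply(elements, function(e) nchar(e$seq), numeric(1)))
    n_gap <- length(elements) + 1L
    bg_total <- cfg$genome_length - elen
    abort_if(bg_total < 1500 * n_gap,
             "genome_length too small for the configured element load")
    extra <- tabulate(sample.int(n_gap, bg_total - 1500L * n_gap,
                                 replace = TRUE), n_gap)
    gaps <- 1500L + extra
    parts <- character(0)
    frows <- list()
    pos <- 0L
    for (e in seq_along(elements)) {
      bg <- random_dna(gaps[e], cfg$gc_content)
      parts <- c(parts, bg, elements[[e]]$seq)
      pos <- pos + gaps[e]
      w <- nchar(elements[[e]]$seq)
      fr <- elements[[e]]$feats
      fr$genome_id <- gid
      fr$start <- pos
      fr$end <- pos + w
      fr$strand <- "+"
      frows[[e]] <- fr
      pos <- pos + w
    }
    parts <- c(parts, random_dna(gaps[n_gap], cfg$gc_content))
    genomes[[g]] <- paste(parts, collapse = "")
    feats[[g]] <- dplyr::bind_rows(frows)
  }
  genomes_tbl <- tibble::tibble(genome_id = genome_ids,
                                sequence = unlist(genomes))
  features_tbl <- dplyr::select(
    dplyr::bind_rows(feats),
    "genome_id", "feature_id", "kind", "start", "end", "strand",
    "product", "locus_tag", "isotype")

  references <- genomes_tbl  # snapshot before prophage insertion

  # plant prophages
  prophage_truth <- list()
  dgr_truth <- list(); dgr_sites <- list()
  shuf_truth <- list(); shuf_rix <- list(); shuf_rv <- list()
  for (i in seq_len(nrow(members))) {
    m <- members[i, ]
    gid <- sprintf("g%02d", m$genome)
    anc <- ancestors[[match(m$clade, plan$clade)]]
    att <- att_by_clade[[as.character(m$clade)]]
    # disambiguate the att direct repeats: the interior's first/last bases
    # must differ from the backbone bases flanking the two att copies, so
    # the longest flanking repeat is exactly the planted core
    trna <- dplyr::filter(features_tbl, .data$genome_id == gid,
                          .data$feature_id == paste0(gid, "_trna_", m$isotype))
    gseq <- genomes_tbl$sequence[match(gid, genomes_tbl$genome_id)]
    after_att <- substr(gseq, trna$end + 1L, trna$end + 1L)
    before_att <- substr(gseq, trna$end - nchar(att), trna$end - nchar(att))
    interior <- m$interior
    if (substr(interior, 1, 1) == after_att) {
      interior <- replace_range(interior, 0, 1,
                                setdiff(c("A", "C", "G", "T"), after_att)[1])
    }
    il <- nchar(interior)
    if (substr(interior, il, il) == before_att) {
      interior <- replace_range(interior, il - 1, il,
                                setdiff(c("A", "C", "G", "T"), before_att)[1])
    }
    members$interior[i] <- interior
    m$interior <- interior
    res <- plant_prophage(genomes_tbl, features_tbl, gid,
                          interior = m$interior, att_core = att,
                          trna_feature_id = paste0(gid, "_trna_", m$isotype),
                          prophage_id = m$prophage_id,
                          interior_features = anc$features)
    genomes_tbl <- res$genomes
    features_tbl <- res$features
    row <- res$prophage
    row$clade <- m$clade
    row$induction <- stats::runif(1, cfg$induction_range[1],
                                  cfg$induction_range[2])
    prophage_truth[[i]] <- row
    att_len <- nchar(att)
    if (!is.null(anc$dgr)) {
      d <- anc$dgr
      dgr_truth[[length(dgr_truth) + 1L]] <- tibble::tibble(
        prophage_id = m$prophage_id, architecture = d$architecture,
        tr_start = d$tr[1] + att_len, tr_end = d$tr[2] + att_len,
        vr_start = d$vr[1] + att_len, vr_end = d$vr[2] + att_len)
      dgr_sites[[length(dgr_sites) + 1L]] <- tibble::tibble(
        prophage_id = m$prophage_id, offset = d$variable_sites)
    }
    if (!is.null(anc$shufflon)) {
      s <- anc$shufflon
      shuf_truth[[length(shuf_truth) + 1L]] <- tibble::tibble(
        prophage_id = m$prophage_id,
        rin_start = s$rin[1] + att_len, rin_end = s$rin[2] + att_len,
        rc_start = s$rc[1] + att_len, rc_end = s$rc[2] + att_len)
      shuf_rix[[length(shuf_rix) + 1L]] <- tibble::tibble(
        prophage_id = m$prophage_id, position = s$rix$position + att_len,
        orientation = s$rix$orientation)
      shuf_rv[[length(shuf_rv) + 1L]] <- tibble::tibble(
        prophage_id = m$prophage_id, start = s$rv_segments$start + att_len,
        end = s$rv_segments$end + att_len)
    }
  }
  prophages <- dplyr::bind_rows(prophage_truth)
  # a later insertion upstream in the same genome shifts earlier prophages;
  # the region features track that, so truth intervals come from them
  if (nrow(prophages) > 0) {
    reg_ids <- paste0(prophages$prophage_id, "_region")
    ri <- match(reg_ids, features_tbl$feature_id)
    prophages$start <- features_tbl$start[ri]
    prophages$end <- features_tbl$end[ri]
  }
  prophages$gc <- vapply(seq_len(nrow(prophages)), function(i) {
    gc_content(subseq0(
      genomes_tbl$sequence[match(prophages$genome_id[i], genomes_tbl$genome_id)],
      prophages$start[i], prophages$end[i]))
  }, numeric(1))

  arrays <- dplyr::filter(features_tbl, .data$kind == "CRISPR_array")
  arrays <- tibble::tibble(
    genome_id = arrays$genome_id, start = arrays$start, end = arrays$end,
    repeat_seq = unname(array_repeats[arrays$genome_id]),
    n_spacers = unname(lengths(array_plan[arrays$genome_id])))

  truth <- list(
    prophages = prophages,
    genes = dplyr::bind_rows(gene_truth),
    arrays = arrays,
    spacers = spacers,
    dgr = dplyr::bind_rows(dgr_truth),
    dgr_sites = dplyr::bind_rows(dgr_sites),
    shufflon = dplyr::bind_rows(shuf_truth),
    shufflon_rix = dplyr::bind_rows(shuf_rix),
    shufflon_rv = dplyr::bind_rows(shuf_rv),
    seed = cfg$seed
  )
  structure(list(genomes = genomes_tbl, references = references,
                 features = features_tbl, truth = truth, config = cfg),
            class = "phage_cohort")
}

#' @export
print.phage_cohort <- function(x, ...) {
  cat(sprintf(
    "<phage_cohort> %d genomes (%s bp), %d prophages in %d clades, %d CRISPR arrays\n",
    nrow(x$genomes),
    format(round(mean(nchar(x$genomes$sequence))), big.mark = ","),
    nrow(x$truth$prophages), length(unique(x$truth$prophages$clade)),
    nrow(x$truth$arrays)))
  invisible(x)
}

#' Extract the planted prophage sequences of a cohort
#'
#' @param cohort a `phage_cohort`
#' @return tibble of `prophage_id`, `clade`, `sequence` (attL + interior)
#' @export
prophage_sequences <- function(cohort) {
  tr <- cohort$truth$prophages
  tibble::tibble(
    prophage_id = tr$prophage_id,
    clade = tr$clade,
    sequence = vapply(seq_len(nrow(tr)), function(i) {
      subseq0(cohort$genomes$sequence[
        match(tr$genome_id[i], cohort$genomes$genome_id)],
        tr$start[i], tr$end[i])
    }, character(1)))
}

# ---- depth simulation -------------------------------------------------------

#' Simulate per-base read depth with prophage induction
#'
#' Depth is Poisson with mean `base_depth` outside prophage regions and
#' `base_depth * induction` inside each prophage, emulating the elevated
#' copy number of induced or replicating prophages.
#'
#' @param genomes genomes tibble
#' @param prophages prophage truth tibble with `genome_id`, `start`, `end`
#'   and an `induction` column (fold change, >= 1)
#' @param base_depth mean host depth
#' @param genome_ids genomes to simulate (default: all)
#' @return tibble with `chrom`, `pos0` (0-based), `depth`
#' @export
simulate_depth <- function(genomes, prophages, base_depth = 100,
                           genome_ids = NULL) {
  abort_if(nrow(prophages) > 0 && any(prophages$induction < 1),
           "induction factors must be >= 1")
  genome_ids <- genome_ids %||% genomes$genome_id
  out <- lapply(genome_ids, function(gid) {
    len <- nchar(genomes$sequence[match(gid, genomes$genome_id)])
    lambda <- rep(base_depth, len)
    pr <- dplyr::filter(prophages, .data$genome_id == gid)
    for (i in seq_len(nrow(pr))) {
      lambda[(pr$start[i] + 1L):pr$end[i]] <- base_depth * pr$induction[i]
    }
    tibble::tibble(chrom = gid, pos0 = 0:(len - 1L),
                   depth = stats::rpois(len, lambda))
  })
  dplyr::bind_rows(out)
}

#' Read / write a BED-like depth track (chrom, pos0, depth)
#' @param path TSV path
#' @return tibble with `chrom`, `pos0`, `depth`
#' @export
read_depth_tsv <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "pos0", "depth"),
                  col_types = "cii", progress = FALSE)
}

#' @rdname read_depth_tsv
#' @param depth depth tibble
#' @export
write_depth_tsv <- function(depth, path) {
  readr::write_tsv(depth, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# ---- truth serialisation ----------------------------------------------------

#' Serialise / restore the cohort truth table as JSON
#'
#' All truth tables are flat, so the round trip is lossless.
#'
#' @param truth the `truth` element of a `phage_cohort`
#' @param path JSON path
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(x) {
    if (is.list(x) && !is.null(names(x))) tibble::as_tibble(x) else x
  })
  out$seed <- as.integer(out$seed)
  out
}
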