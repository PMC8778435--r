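# Pangenome construction: reciprocal-best-hit ortholog clustering at the
# 30% identity / 70% coverage thresholds, core/accessory/unique
# classification, gene accumulation curves, and the Heap's-law openness fit.

#' Extract per-genome proteomes from cohort features
#'
#' Translates every `gene` feature whose length is divisible by 3 and whose
#' sequence is N-free; other gene features are skipped with a warning.
#'
#' @param genomes genomes tibble
#' @param features features tibble
#' @return tibble with `genome_id`, `gene_id`, `protein`
#' @export
extract_proteomes <- function(genomes, features) {
  genes <- dplyr::filter(features, .data$kind == "gene")
  seqs <- substr(genomes$sequence[match(genes$genome_id, genomes$genome_id)],
                 genes$start + 1L, genes$end)
  minus <- genes$strand == "-"
  seqs[minus] <- vapply(seqs[minus], reverse_complement, character(1),
                        USE.NAMES = FALSE)
  ok <- nchar(seqs) %% 3 == 0 & !grepl("N", seqs, fixed = TRUE)
  if (any(!ok)) {
    rlang::warn(sprintf("skipped %d gene feature(s) not translatable",
                        sum(!ok)))
  }
  prots <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(seqs[ok]), if.fuzzy.codon = "X"))
  tibble::tibble(genome_id = genes$genome_id[ok],
                 gene_id = genes$feature_id[ok],
                 protein = sub("\\*$", "", prots))
}

#' Pairwise protein identity and coverage at the ortholog thresholds
#'
#' @inherit protein_similarity
#' @seealso [protein_similarity()]
#' @export
pairwise_protein_similarity <- function(a, b) {
  protein_similarity(a, b)
}

# Candidate cross-genome pairs sharing at least one amino-acid 5-mer; a pure
# prefilter so unrelated proteins are never aligned.
candidate_pairs <- function(proteomes, k = 5L) {
  km <- lapply(seq_len(nrow(proteomes)), function(i) {
    p <- proteomes$protein[i]
    n <- nchar(p) - k + 1L
    if (n < 1) character(0) else unique(substring(p, 1:n, k:(k + n - 1L)))
  })
  tab <- tibble::tibble(
    idx = rep.int(seq_len(nrow(proteomes)), lengths(km)),
    kmer = unlist(km))
  pairs <- dplyr::inner_join(tab, tab, by = "kmer", relationship = "many-to-many")
  pairs <- dplyr::distinct(dplyr::filter(pairs, .data$idx.x < .data$idx.y),
                           .data$idx.x, .data$idx.y)
  pairs <- dplyr::filter(pairs,
    proteomes$genome_id[.data$idx.x] != proteomes$genome_id[.data$idx.y])
  pairs
}

#' Cluster proteins into orthologous groups
#'
#' Builds a reciprocal-best-hit (RBH) graph: two proteins from different
#' genomes are linked iff their local alignment reaches `min_identity` and
#' `min_coverage` and each is the other's best qualifying hit in the
#' counterpart genome (ties broken by higher identity, then lexicographic
#' gene id). Orthologous groups are the connected components; every gene
#' belongs to exactly one OG, singletons included. The result is invariant
#' under genome and gene input order.
#'
#' @param proteomes tibble with `genome_id`, `gene_id`, `protein`
#' @param min_identity minimum alignment identity (matches / aligned columns)
#' @param min_coverage minimum aligned span over the shorter sequence
#' @return tibble with `og_id`, `genome_id`, `gene_id`, `category`
#'   (`core` / `accessory` / `unique`)
#' @export
cluster_orthologs <- function(proteomes, min_identity = 0.30,
                              min_coverage = 0.70) {
  abort_if(length(unique(proteomes$genome_id)) < 2,
           "ortholog clustering needs at least two genomes")
  empty <- setdiff(unique(proteomes$genome_id),
                   proteomes$genome_id[nzchar(proteomes$protein)])
  if (length(empty)) {
    rlang::warn(sprintf("genome(s) with empty proteome: %s",
                        paste(empty, collapse = ", ")))
  }
  proteomes <- dplyr::arrange(proteomes, .data$genome_id, .data$gene_id)
  pairs <- candidate_pairs(proteomes)
  if (nrow(pairs) > 0) {
    # one pairwiseAlignment call per subject protein (batched patterns)
    res <- lapply(split(pairs$idx.x, pairs$idx.y), function(xs) xs)
    chunks <- lapply(names(res), function(y) {
      yi <- as.integer(y)
      xs <- res[[y]]
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(proteomes$protein[xs]),
        Biostrings::AAString(proteomes$protein[yi]),
        type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1)
      cols <- nchar(as.character(Biostrings::pattern(aln)))
      len_x <- nchar(proteomes$protein[xs])
      len_y <- nchar(proteomes$protein[yi])
      span <- ifelse(len_x <= len_y,
                     Biostrings::width(Biostrings::pattern(aln)),
                     Biostrings::width(Biostrings::subject(aln)))
      tibble::tibble(idx.x = xs, idx.y = yi,
                     identity = ifelse(cols > 0,
                                       Biostrings::nmatch(aln) / cols, 0),
                     coverage = span / pmin(len_x, len_y))
    })
    pairs <- dplyr::filter(dplyr::bind_rows(chunks),
                           .data$identity >= min_identity,
                           .data$coverage >= min_coverage)
  } else {
    pairs$identity <- numeric(0)
    pairs$coverage <- numeric(0)
  }
  # best hit of each protein in each counterpart genome, then keep reciprocal
  directed <- dplyr::bind_rows(
    tibble::tibble(from = pairs$idx.x, to = pairs$idx.y,
                   identity = pairs$identity),
    tibble::tibble(from = pairs$idx.y, to = pairs$idx.x,
                   identity = pairs$identity))
  directed$to_genome <- proteomes$genome_id[directed$to]
  directed$to_gene <- proteomes$gene_id[directed$to]
  best <- dplyr::slice_head(
    dplyr::arrange(
      dplyr::group_by(directed, .data$from, .data$to_genome),
      dplyr::desc(.data$identity), .data$to_gene),
    n = 1)
  best <- dplyr::ungroup(best)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  rbh <- dplyr::filter(best, duplicated(key(.data$from, .data$to)) |
                         duplicated(key(.data$from, .data$to), fromLast = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(rbh$from), to = as.character(rbh$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(nrow(proteomes)))))
  comp <- igraph::components(g)$membership
  out <- tibble::tibble(
    genome_id = proteomes$genome_id,
    gene_id = proteomes$gene_id,
    component = comp[as.character(seq_len(nrow(proteomes)))])
  # stable OG ids: number components by their first gene id
  first_gene <- dplyr::summarise(
    dplyr::group_by(out, .data$component),
    first = min(.data$gene_id), .groups = "drop")
  first_gene <- dplyr::arrange(first_gene, .data$first)
  first_gene$og_id <- sprintf("OG%05d", seq_len(nrow(first_gene)))
  out <- dplyr::left_join(out, first_gene[, c("component", "og_id")],
                          by = "component")
  classify_orthologs(
    dplyr::select(out, "og_id", "genome_id", "gene_id"),
    n_genomes = length(unique(proteomes$genome_id)))
}

#' Classify orthologous groups as core, accessory or unique
#'
#' Core OGs span all genomes, unique OGs exactly one; the rest are
#' accessory.
#'
#' @param ogs tibble with `og_id`, `genome_id`, `gene_id`
#' @param n_genomes total number of genomes in the cohort
#' @return `ogs` with a `category` column
#' @export
classify_orthologs <- function(ogs, n_genomes) {
  span <- dplyr::summarise(dplyr::group_by(ogs, .data$og_id),
                           n_gen = dplyr::n_distinct(.data$genome_id),
                           .groups = "drop")
  span$category <- dplyr::case_when(
    span$n_gen == n_genomes ~ "core",
    span$n_gen == 1 ~ "unique",
    TRUE ~ "accessory")
  dplyr::left_join(ogs, span[, c("og_id", "category")], by = "og_id")
}

#' Summarise a pangenome
#'
#' @param ogs classified OG tibble (from [cluster_orthologs()])
#' @return one-row tibble: pan / core / accessory / unique OG counts, mean
#'   proteome size, and the core fraction of an average genome
#'   (core OGs / mean proteome size)
#' @export
pangenome_summary <- function(ogs) {
  per_cat <- table(dplyr::distinct(ogs, .data$og_id, .data$category)$category)
  get <- function(k) if (k %in% names(per_cat)) as.integer(per_cat[[k]]) else 0L
  mean_proteome <- mean(table(ogs$genome_id))
  tibble::tibble(
    pan = length(unique(ogs$og_id)),
    core = get("core"), accessory = get("accessory"), unique = get("unique"),
    mean_proteome = mean_proteome,
    core_fraction_of_average_genome = get("core") / mean_proteome)
}

#' Pan- and core-genome accumulation curves
#'
#' For each of `n_permutations` random genome orderings, the cumulative
#' pangenome (union of OGs) and core genome (intersection) are recorded at
#' every cohort size x. Pan curves are non-decreasing and core curves
#' non-increasing in x by construction.
#'
#' @param ogs classified OG tibble
#' @param n_permutations number of random genome orderings
#' @return tibble with `x`, `permutation`, `pan`, `core`
#' @export
accumulation_curves <- function(ogs, n_permutations = 100) {
  abort_if(n_permutations < 1, "`n_permutations` must be >= 1")
  genomes <- sort(unique(ogs$genome_id))
  og_ids <- sort(unique(ogs$og_id))
  m <- matrix(FALSE, nrow = length(og_ids), ncol = length(genomes),
              dimnames = list(og_ids, genomes))
  m[cbind(match(ogs$og_id, og_ids), match(ogs$genome_id, genomes))] <- TRUE
  out <- lapply(seq_len(n_permutations), function(p) {
    ord <- sample(length(genomes))
    seen <- matrixStats_rowCumany(m[, ord, drop = FALSE])
    inall <- matrixStats_rowCumall(m[, ord, drop = FALSE])
    tibble::tibble(x = seq_along(genomes), permutation = p,
                   pan = unname(colSums(seen)), core = unname(colSums(inall)))
  })
  dplyr::bind_rows(out)
}

# cumulative any/all along columns (no matrixStats dependency)
matrixStats_rowCumany <- function(m) {
  t(apply(m, 1, function(r) cumsum(r) > 0))
}
matrixStats_rowCumall <- function(m) {
  t(apply(m, 1, function(r) cumsum(r) == seq_along(r)))
}

#' Summarise accumulation curves across permutations
#'
#' @param curves output of [accumulation_curves()]
#' @return tibble with per-x mean and 2.5/97.5% quantiles of pan and core
#' @export
accumulation_summary <- function(curves) {
  dplyr::summarise(
    dplyr::group_by(curves, .data$x),
    pan_mean = mean(.data$pan),
    pan_lo = stats::quantile(.data$pan, 0.025),
    pan_hi = stats::quantile(.data$pan, 0.975),
    core_mean = mean(.data$core),
    core_lo = stats::quantile(.data$core, 0.025),
    core_hi = stats::quantile(.data$core, 0.975),
    .groups = "drop")
}
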