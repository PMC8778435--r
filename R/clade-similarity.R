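# Gegenees-style fragmented nucleotide similarity and single-linkage clade
# clustering at the >60% (within-clade) / >40% (reported relation)
# thresholds.

#' Fragmented nucleotide similarity between two sequences
#'
#' The query is tiled into fragments of `frag` bp at stride `step`; each
#' fragment is scored against the subject with blastn match/mismatch
#' weights (+1/-3) using seeded best-diagonal ungapped scoring (shared
#' 15-mer seeds select candidate diagonals; the maximal-scoring ungapped
#' segment on each is taken). Every fragment contributes: its best score is
#' normalised by its self-score (fragment length x match weight) and
#' floored at zero, and the similarity is 100 x the mean over fragments.
#' A query shorter than `frag` is scored as a single whole-sequence
#' fragment. The measure is asymmetric (tiling follows the query).
#'
#' @param query,subject nucleotide strings
#' @param frag fragment length (bp)
#' @param step tiling stride (bp)
#' @param index optional prebuilt [kmer_index()] of the subject (reused
#'   across queries by [similarity_matrix()])
#' @return similarity percentage in \[0, 100\]
#' @export
#' @examples
#' s <- strrep("ACGTTGCA", 100)
#' fragmented_similarity(s, s)
fragmented_similarity <- function(query, subject, frag = 200, step = 100,
                                  index = NULL) {
  qn <- nchar(query)
  if (is.null(index)) index <- kmer_index(subject)
  starts <- if (qn < frag) 0L else seq(0L, qn - frag, by = step)
  scores <- vapply(starts, function(s0) {
    f <- subseq0(query, s0, min(qn, s0 + frag))
    best <- fragment_best_score(f, index)
    max(0, best / (nchar(f) * BLASTN_MATCH))
  }, numeric(1))
  100 * mean(scores)
}

#' All-vs-all fragmented similarity matrix
#'
#' Computes every ordered pair (the measure is asymmetric); the diagonal is
#' 100 by construction.
#'
#' @param seqs tibble with `prophage_id` and `sequence`
#' @param frag,step see [fragmented_similarity()]
#' @return a `phage_similarity` object: list with `ids` and the percent
#'   `values` matrix (rows = query)
#' @export
similarity_matrix <- function(seqs, frag = 200, step = 100) {
  abort_if(nrow(seqs) < 1, "need at least one sequence")
  ids <- seqs$prophage_id
  n <- nrow(seqs)
  indexes <- lapply(seqs$sequence, kmer_index)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      m[i, j] <- fragmented_similarity(seqs$sequence[i], seqs$sequence[j],
                                       frag = frag, step = step,
                                       index = indexes[[j]])
    }
  }
  structure(list(ids = ids, values = m), class = "phage_similarity")
}

#' @export
print.phage_similarity <- function(x, ...) {
  cat(sprintf("<phage_similarity> %d sequences\n", length(x$ids)))
  print(round(x$values, 1))
  invisible(x)
}

#' Tidy a similarity matrix into long form
#' @param x a `phage_similarity`
#' @param ... unused
#' @return tibble with `query`, `subject`, `similarity`
#' @method tidy phage_similarity
#' @export
tidy.phage_similarity <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$values, responseName = "similarity",
                                        stringsAsFactors = FALSE))  |>
    dplyr::rename(query = "Var1", subject = "Var2")
}

#' Heatmap of a fragmented-similarity matrix
#' @param object a `phage_similarity`
#' @param ... unused
#' @return a ggplot
#' @method autoplot phage_similarity
#' @export
autoplot.phage_similarity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject, y = .data$query,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "% identity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}

#' Cluster prophages into clades from a similarity matrix
#'
#' The asymmetric matrix is symmetrised by the pairwise mean; clades are
#' the single-linkage connected components over edges above `within`
#' percent, numbered by descending size (ties by first appearance).
#' Between-clade pairs whose symmetrised similarity exceeds
#' `report_threshold` are reported as inter-clade relations rather than
#' merged.
#'
#' @param sim a `phage_similarity` object
#' @param within within-clade linkage threshold (percent)
#' @param report_threshold inter-clade relation reporting threshold
#' @return a `clade_assignment`: list with `clades` (tibble `prophage_id`,
#'   `clade`) and `relations` (tibble `clade_a`, `clade_b`,
#'   `max_similarity`)
#' @export
cluster_clades <- function(sim, within = 60, report_threshold = 40) {
  m <- (sim$values + t(sim$values)) / 2
  n <- length(sim$ids)
  g <- igraph::graph_from_adjacency_matrix(m > within, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  order_keys <- rank(-as.vector(sizes[as.character(seq_along(sizes))]),
                     ties.method = "first")
  clade <- order_keys[comp]
  clades <- tibble::tibble(prophage_id = sim$ids, clade = as.integer(clade))
  rel <- list()
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (clade[i] != clade[j] && m[i, j] > report_threshold) {
          a <- min(clade[i], clade[j]); b <- max(clade[i], clade[j])
          rel[[length(rel) + 1L]] <- tibble::tibble(
            clade_a = a, clade_b = b, similarity = m[i, j])
        }
      }
    }
  }
  relations <- if (length(rel)) {
    dplyr::summarise(dplyr::group_by(dplyr::bind_rows(rel),
                                     .data$clade_a, .data$clade_b),
                     max_similarity = max(.data$similarity), .groups = "drop")
  } else {
    tibble::tibble(clade_a = integer(), clade_b = integer(),
                   max_similarity = numeric())
  }
  structure(list(clades = clades, relations = relations,
                 within = within, report_threshold = report_threshold),
            class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  k <- length(unique(x$clades$clade))
  cat(sprintf("<clade_assignment> %d prophages in %d clades (>%g%% linkage)\n",
              nrow(x$clades), k, x$within))
  if (nrow(x$relations) > 0) {
    cat(sprintf("  inter-clade relations (> %g%%):\n", x$report_threshold))
    print(as.data.frame(x$relations))
  }
  invisible(x)
}

#' Tidy a clade assignment
#' @param x a `clade_assignment`
#' @param ... unused
#' @return the membership tibble
#' @method tidy clade_assignment
#' @export
tidy.clade_assignment <- function(x, ...) x$clades

#' Adjusted Rand index between two partitions
#'
#' Agreement between a recovered clade assignment and a reference labelling,
#' 1 for identical partitions.
#'
#' @param labels_a,labels_b label vectors over the same elements
#' @return the adjusted Rand index
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  abort_if(length(labels_a) != length(labels_b),
           "label vectors must have equal length")
  tab <- table(labels_a, labels_b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(labels_a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
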