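#' Read a multi-record nucleotide FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any character outside
#' `{A,C,G,T,N}` is rejected. Record identifiers are the first whitespace
#' token of each header and must be unique.
#'
#' @param path path to a FASTA file
#' @return a tibble with columns `genome_id` and `sequence`
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "ACGTACGT"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  abort_if(!file.exists(path), sprintf("file '%s' does not exist", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) rlang::abort(sprintf("'%s' is not valid FASTA: %s", path, conditionMessage(e)))
  )
  abort_if(length(set) == 0, sprintf("'%s' contains no FASTA records", path))
  ids <- stringr::str_split_i(names(set), "\\s+", 1)
  dup <- unique(ids[duplicated(ids)])
  abort_if(length(dup) > 0,
           sprintf("duplicate FASTA ID(s): %s", paste(dup, collapse = ", ")))
  seqs <- chartr("U", "T", toupper(as.character(set)))
  seqs <- vapply(seq_along(seqs), function(i) {
    validate_dna(seqs[[i]], what = sprintf("record '%s'", ids[[i]]))
  }, character(1))
  tibble::tibble(genome_id = ids, sequence = unname(seqs))
}

#' Write genome records to FASTA
#'
#' Round-trips with [read_fasta()]: identifiers and sequences are reproduced
#' exactly.
#'
#' @param records a tibble with columns `genome_id` and `sequence`
#' @param path output path
#' @param line_width sequence line width
#' @return `path`, invisibly
#' @export
write_fasta <- function(records, path, line_width = 70) {
  abort_if(!is.data.frame(records) || nrow(records) == 0,
           "`records` must be a non-empty data frame of genome_id/sequence")
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$genome_id
  Biostrings::writeXStringSet(set, path, width = line_width)
  invisible(path)
}

# Map a GFF3 `type` string onto the package's feature kinds.
gff_kind <- function(type) {
  dplyr::case_when(
    type %in% c("gene", "CDS") ~ "gene",
    type %in% c("tRNA", "trna") ~ "tRNA",
    type == "CRISPR" ~ "CRISPR_array",
    type == "prophage" ~ "prophage",
    type %in% c("repeat_region", "direct_repeat", "repeat") ~ "repeat",
    TRUE ~ "other"
  )
}

#' Read gene/tRNA/array features from GFF3 and attach them to genomes
#'
#' GFF 1-based closed coordinates are converted to the package-internal
#' 0-based half-open convention. `product` and `locus_tag` attributes are
#' preserved verbatim; tRNA isotypes are taken from an `isotype` attribute or
#' parsed from a `tRNA-Xxx` product.
#'
#' @param path path to a GFF3 file
#' @param genomes tibble of `genome_id`/`sequence` (from [read_fasta()])
#' @return a features tibble with columns `genome_id`, `feature_id`, `kind`,
#'   `start`, `end` (0-based half-open), `strand`, `product`, `locus_tag`,
#'   `isotype`
#' @export
read_gff <- function(path, genomes) {
  abort_if(!file.exists(path), sprintf("file '%s' does not exist", path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  abort_if(any(df$end < df$start),
           "GFF format error: feature with end < start")
  unknown <- setdiff(unique(as.character(df$seqnames)), genomes$genome_id)
  abort_if(length(unknown) > 0,
           sprintf("GFF references unknown genome(s): %s",
                   paste(unknown, collapse = ", ")))
  get_col <- function(nm) {
    if (nm %in% names(df)) as.character(df[[nm]]) else rep(NA_character_, nrow(df))
  }
  feats <- tibble::tibble(
    genome_id = as.character(df$seqnames),
    feature_id = get_col("ID"),
    kind = gff_kind(as.character(df$type)),
    start = as.integer(df$start) - 1L,
    end = as.integer(df$end),
    strand = ifelse(as.character(df$strand) == "-", "-", "+"),
    product = get_col("product"),
    locus_tag = get_col("locus_tag"),
    isotype = get_col("isotype")
  )
  feats <- dplyr::mutate(
    feats,
    isotype = dplyr::if_else(
      .data$kind == "tRNA" & is.na(.data$isotype) &
        stringr::str_detect(dplyr::coalesce(.data$product, ""), "^tRNA-"),
      stringr::str_remove(.data$product, "^tRNA-"),
      .data$isotype
    )
  )
  lens <- stats::setNames(nchar(genomes$sequence), genomes$genome_id)
  abort_if(any(feats$end > lens[feats$genome_id]),
           "GFF feature extends beyond its genome")
  feats
}

#' Write a features tibble to GFF3
#'
#' The inverse of [read_gff()]: internal 0-based half-open intervals are
#' written as 1-based closed GFF coordinates.
#'
#' @param features a features tibble (see [read_gff()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gff <- function(features, path) {
  type <- dplyr::recode(features$kind,
                        gene = "gene", tRNA = "tRNA", repeat_ = "repeat_region",
                        CRISPR_array = "CRISPR", prophage = "prophage",
                        `repeat` = "repeat_region", other = "region")
  gr <- GenomicRanges::GRanges(
    seqnames = features$genome_id,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand
  )
  gr$type <- type
  gr$ID <- features$feature_id
  gr$product <- features$product
  gr$locus_tag <- features$locus_tag
  gr$isotype <- features$isotype
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Reverse complement of a nucleotide sequence
#'
#' Standard Watson-Crick complement over `{A,C,G,T}`; `N` maps to `N`. The
#' operation is an involution: `reverse_complement(reverse_complement(s))`
#' equals `s`.
#'
#' @param seq nucleotide string over `{A,C,G,T,N}` (case-insensitive)
#' @return the reverse complement, uppercase
#' @export
#' @examples
#' reverse_complement("ACGTN")
reverse_complement <- function(seq) {
  seq <- validate_dna(seq)
  rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", seq))))
}

#' Translate a coding sequence to protein
#'
#' Standard genetic code; the first codon is translated as-is (no special
#' initiator handling). Stop codons are encoded as `*`; a single terminal
#' stop is stripped.
#'
#' @param cds nucleotide string with length divisible by 3
#' @return the protein string
#' @export
#' @examples
#' translate_cds("ATGAAATAA")
translate_cds <- function(cds) {
  cds <- validate_dna(cds, what = "CDS")
  abort_if(nchar(cds) %% 3 != 0,
           sprintf("CDS length %d is not divisible by 3", nchar(cds)))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Extract the sequence of a feature, honouring strand
#'
#' Features are stored on the forward strand; minus-strand features are
#' returned reverse-complemented.
#'
#' @param genomes genomes tibble
#' @param feature one row of a features tibble
#' @return nucleotide string
#' @export
feature_sequence <- function(genomes, feature) {
  seq <- genomes$sequence[match(feature$genome_id, genomes$genome_id)]
  abort_if(is.na(seq), sprintf("unknown genome '%s'", feature$genome_id))
  s <- subseq0(seq, feature$start, feature$end)
  if (identical(feature$strand, "-")) reverse_complement(s) else s
}

#' Extract a genome region with its features rebased to region coordinates
#'
#' @param genomes genomes tibble
#' @param features features tibble
#' @param genome_id genome to slice
#' @param start,end 0-based half-open interval
#' @return list with `sequence` and `features` (starts/ends relative to the
#'   region; only features fully inside the region are kept)
#' @export
extract_region <- function(genomes, features, genome_id, start, end) {
  seq <- genomes$sequence[match(genome_id, genomes$genome_id)]
  abort_if(is.na(seq), sprintf("unknown genome '%s'", genome_id))
  abort_if(start < 0 || end > nchar(seq) || start >= end, "invalid interval")
  feats <- dplyr::filter(features, .data$genome_id == !!genome_id,
                         .data$start >= !!start, .data$end <= !!end)
  feats <- dplyr::mutate(feats, start = .data$start - !!start,
                         end = .data$end - !!start)
  list(sequence = subseq0(seq, start, end), features = feats)
}
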