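# Independent oracle: naive all-positions, character-level Hamming scan.
oracle_protospacers <- function(spacers, prophages, max_mm = 3,
                                min_bits = 44.1) {
  rows <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers$sequence[i]
    slen <- nchar(sp)
    for (j in seq_len(nrow(prophages))) {
      seq <- prophages$sequence[j]
      n <- nchar(seq)
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") sp else reverse_complement(sp)
        pc <- strsplit(pat, "")[[1]]
        for (s in 0:(n - slen)) {
          wc <- strsplit(substr(seq, s + 1, s + slen), "")[[1]]
          mm <- sum(pc != wc | pc == "N" | wc == "N")
          bits <- spacer_bitscore(slen, mm)
          if (mm <= max_mm && bits >= min_bits) {
            rows[[length(rows) + 1L]] <- tibble::tibble(
              spacer_id = spacers$spacer_id[i],
              prophage_id = prophages$prophage_id[j],
              start = s, strand = strand, mismatches = mm)
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(spacer_id = character(), prophage_id = character(),
                          start = integer(), strand = character(),
                          mismatches = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$spacer_id,
                 .data$prophage_id, .data$start, .data$strand)
}
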