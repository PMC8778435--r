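test_that("the bit-score formula reproduces the published cutoff", {
  expect_equal(spacer_bitscore(34, 3), 44.1, tolerance = 1e-3)
  expect_gte(spacer_bitscore(34, 3), 44.1)
  expect_equal(spacer_bitscore(34, 0), 67.9, tolerance = 1e-2)
  expect_lt(spacer_bitscore(34, 4), 44.1)
  expect_equal(spacer_bitscore(34, 4), 36.2, tolerance = 0.05)
  # strictly decreasing in mismatches at fixed length
  bits <- spacer_bitscore(34, 0:8)
  expect_true(all(diff(bits) < 0))
})

test_that("planted arrays are recovered exactly", {
  co <- small_cohort()
  found <- dplyr::bind_rows(lapply(seq_len(nrow(co$genomes)), function(i) {
    detect_arrays(co$genomes[i, ])
  }))
  tr <- co$truth$arrays
  expect_equal(nrow(found), nrow(tr))
  m <- match(tr$genome_id, found$genome_id)
  expect_equal(found$start[m], tr$start)
  expect_equal(found$end[m], tr$end)
  expect_equal(found$repeat_consensus[m], tr$repeat_seq)
  expect_equal(found$n_spacers[m], tr$n_spacers)
  # planted spacers come back verbatim
  sp <- extract_spacers(found)
  expect_true(all(co$truth$spacers$sequence %in% sp$sequence))
})

test_that("array-free backgrounds and references yield nothing", {
  co <- small_cohort()
  ref_without_array <- co$references[!co$references$genome_id %in%
                                       co$truth$arrays$genome_id, ]
  if (nrow(ref_without_array) > 0) {
    expect_equal(nrow(detect_arrays(ref_without_array[1, ])), 0)
  }
  g <- tibble::tibble(genome_id = "bg", sequence = random_seq(30000, 60))
  expect_equal(nrow(detect_arrays(g)), 0)
})

test_that("two planted arrays in one genome are both found", {
  withr::with_seed(61, {
    rep_seq <- prophagr:::random_dna(29, 0.5)
    sps1 <- vapply(1:3, function(i) prophagr:::random_dna(34, 0.5), character(1))
    sps2 <- vapply(1:4, function(i) prophagr:::random_dna(34, 0.5), character(1))
    bg <- prophagr:::random_dna(60000, 0.5)
  })
  g <- tibble::tibble(genome_id = "g", sequence = bg)
  f <- tibble::tibble(genome_id = character(), feature_id = character(),
                      kind = character(), start = integer(), end = integer(),
                      strand = character(), product = character(),
                      locus_tag = character(), isotype = character())
  r1 <- plant_crispr_array(g, f, "g", 5000, rep_seq, sps1)
  r2 <- plant_crispr_array(r1$genomes, r1$features, "g", 55000,
                           withr::with_seed(62, prophagr:::random_dna(29, 0.5)),
                           sps2)
  found <- detect_arrays(r2$genomes)
  expect_equal(nrow(found), 2)
  expect_equal(sort(found$n_spacers), c(3, 4))   # 4 repeats/3 spacers etc.
})

test_that("hit filters are individually necessary at the rule boundary", {
  withr::with_seed(63, {
    proph <- prophagr:::random_dna(4000, 0.6)
  })
  target <- substr(proph, 2001, 2034)
  mut <- function(s, k) withr::with_seed(64, {
    prophagr:::apply_spacer_mismatches(s, k)
  })
  spacers <- tibble::tibble(
    spacer_id = c("m0", "m3", "m4"),
    sequence = c(target, mut(target, 3), mut(target, 4)))
  hits <- find_protospacers(spacers,
                            tibble::tibble(prophage_id = "p", sequence = proph))
  expect_setequal(hits$spacer_id, c("m0", "m3"))
  expect_equal(hits$start[hits$spacer_id == "m0"], 2000)
  expect_equal(hits$bitscore[hits$spacer_id == "m3"], 44.1,
               tolerance = 1e-3)  # retained exactly at the cutoff
  # a short spacer passes the mismatch rule but fails the bit-score rule
  short <- tibble::tibble(spacer_id = "s", sequence = substr(target, 1, 26))
  short_mut <- short
  short_mut$sequence <- mut(short$sequence, 3)   # 26 - 12 = 14 -> 27.2 bits
  expect_lt(spacer_bitscore(26, 3), 44.1)
  expect_equal(nrow(find_protospacers(short_mut,
    tibble::tibble(prophage_id = "p", sequence = proph))), 0)
})

test_that("N never counts as a match", {
  proph <- paste0(strrep("A", 50), strrep("C", 34), strrep("G", 50))
  sp <- tibble::tibble(spacer_id = "n",
                       sequence = paste0(strrep("C", 30), "NNNN"))
  hits <- find_protospacers(sp, tibble::tibble(prophage_id = "p",
                                               sequence = proph))
  expect_true(all(hits$mismatches >= 4) || nrow(hits) == 0)
})

test_that("the seeded scanner equals the brute-force oracle", {
  co <- small_cohort()
  ps <- prophage_sequences(co)
  # truncate prophages to 5 kb windows around the planted protospacer zone
  small <- ps
  small$sequence <- substr(small$sequence, 11000, 16000)
  spacers <- tibble::tibble(
    spacer_id = co$truth$spacers$spacer_id,
    sequence = co$truth$spacers$sequence)
  mine <- find_protospacers(spacers, small)
  mine <- dplyr::arrange(
    dplyr::select(mine, "spacer_id", "prophage_id", "start", "strand",
                  "mismatches"),
    .data$spacer_id, .data$prophage_id, .data$start, .data$strand)
  oracle <- oracle_protospacers(spacers, small)
  expect_equal(as.data.frame(mine), as.data.frame(oracle))
  expect_gt(nrow(mine), 0)
})

test_that("hit sets are invariant under reverse-complementing a prophage", {
  co <- small_cohort()
  ps <- prophage_sequences(co)[1, ]
  spacers <- tibble::tibble(spacer_id = co$truth$spacers$spacer_id,
                            sequence = co$truth$spacers$sequence)
  fwd <- find_protospacers(spacers, ps)
  rc <- ps
  rc$sequence <- reverse_complement(rc$sequence)
  rev <- find_protospacers(spacers, rc)
  expect_equal(nrow(fwd), nrow(rev))
  n <- nchar(ps$sequence)
  key <- function(h, flip) {
    st <- if (flip) n - h$end else h$start
    sr <- if (flip) c("+" = "-", "-" = "+")[h$strand] else h$strand
    sort(paste(h$spacer_id, st, sr, h$mismatches))
  }
  expect_equal(key(fwd, FALSE), key(rev, TRUE))
})

test_that("PAM checking respects strand and edges", {
  proph <- paste0("TCC", strrep("A", 10), "GGATTT")
  # + strand protospacer right after TCC
  hit <- tibble::tibble(start = 3, end = 13, strand = "+")
  expect_true(check_pam(hit, proph)$pam)
  hit_edge <- tibble::tibble(start = 0, end = 13, strand = "+")
  res <- check_pam(hit_edge, proph)
  expect_false(res$pam)
  expect_true(res$edge)
  # - strand: forward GGA after the match reads TCC on the minus strand
  hit_minus <- tibble::tibble(start = 3, end = 13, strand = "-")
  expect_true(check_pam(hit_minus, proph)$pam)
  hit_no <- tibble::tibble(start = 4, end = 14, strand = "+")
  expect_false(check_pam(hit_no, proph)$pam)
})

test_that("the targeting matrix counts, flags self-targets and fractions", {
  co <- small_cohort()
  ps <- prophage_sequences(co)
  arrays <- dplyr::bind_rows(lapply(
    which(co$genomes$genome_id %in% co$truth$arrays$genome_id),
    function(i) detect_arrays(co$genomes[i, ])))
  spacers <- extract_spacers(arrays)
  uniq <- spacers[is.na(spacers$duplicate_of), ]
  hits <- find_protospacers(uniq, ps)
  clades <- tibble::tibble(prophage_id = co$truth$prophages$prophage_id,
                           clade = co$truth$prophages$clade)
  hosts <- tibble::tibble(prophage_id = co$truth$prophages$prophage_id,
                          genome_id = co$truth$prophages$genome_id)
  tm <- targeting_matrix(hits, spacers, clades, hosts)
  expect_true(all(tm$matrix$n_spacers > 0))
  expect_gt(tm$unique_spacer_fraction, 0)
  expect_lte(tm$unique_spacer_fraction, 1)
  # the planted self-target (g01 spacer -> g01-resident prophage, with PAM)
  expect_true(nrow(tm$self_targeting) >= 1)
  expect_true(any(tm$self_targeting$genome_id == "g01" &
                  tm$self_targeting$pam_tcc))
  # no hits -> empty matrix
  tm0 <- targeting_matrix(hits[0, ], spacers, clades, hosts)
  expect_equal(nrow(tm0$matrix), 0)
})
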