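feature_row <- function(genome_id, id, start, end, product,
                        kind = "gene", isotype = NA_character_) {
  tibble::tibble(genome_id = genome_id, feature_id = id, kind = kind,
                 start = start, end = end, strand = "+", product = product,
                 locus_tag = NA_character_, isotype = isotype)
}

test_that("hallmark screening needs a quorum of two distinct hallmarks", {
  f <- dplyr::bind_rows(
    feature_row("g", "a", 1000, 2500, "terminase, large subunit"),
    feature_row("g", "b", 2600, 4000, "portal protein"),
    feature_row("g", "c", 90000, 91000, "tyrosine integrase"),
    feature_row("h", "d", 5000, 6000, "major capsid protein"))
  cands <- screen_hallmarks(f)
  expect_equal(nrow(cands), 1)            # lone integrase / lone capsid: no
  expect_equal(cands$genome_id, "g")
  expect_equal(cands$start, 1000)
  expect_equal(cands$end, 4000)
  expect_equal(nrow(screen_hallmarks(f[3, ])), 0)
})

test_that("two distant hallmark loci give two candidates", {
  f <- dplyr::bind_rows(
    feature_row("g", "a", 1000, 2500, "terminase, large subunit"),
    feature_row("g", "b", 2600, 4000, "major capsid protein"),
    feature_row("g", "c", 150000, 151500, "portal protein"),
    feature_row("g", "d", 152000, 153000, "terminase, large subunit"))
  expect_equal(nrow(screen_hallmarks(f)), 2)
})

test_that("boundary delineation is exact for arbitrary insertions", {
  # reference = A + B, lysogen = A + P + B  ->  recovered interval is P
  for (seed in 1:4) {
    withr::with_seed(100 + seed, {
      a <- prophagr:::random_dna(sample(2000:5000, 1), 0.5)
      b <- prophagr:::random_dna(sample(2000:5000, 1), 0.5)
      p <- prophagr:::random_dna(sample(3000:8000, 1), 0.6)
    })
    lys <- tibble::tibble(genome_id = "L", sequence = paste0(a, p, b))
    ref <- tibble::tibble(genome_id = "L", sequence = paste0(a, b))
    cand <- tibble::tibble(genome_id = "L",
                           start = nchar(a) + 500, end = nchar(a) + 1500)
    reg <- delineate_boundaries(lys, ref, cand)
    # coinciding edge bases make the junction ambiguous by a base or two;
    # the recovered segment must still be an exact representation of the
    # insertion: removing it restores the reference
    expect_lte(abs(reg$start - nchar(a)), 2)
    expect_lte(abs(reg$end - (nchar(a) + nchar(p))), 2)
    restored <- paste0(substr(lys$sequence, 1, reg$start),
                       substr(lys$sequence, reg$end + 1,
                              nchar(lys$sequence)))
    expect_identical(restored, ref$sequence)
    expect_true(reg$complete)
  }
})

test_that("a candidate at a contig end leaves that terminus open", {
  withr::with_seed(110, {
    a <- prophagr:::random_dna(4000, 0.5)
    p <- prophagr:::random_dna(6000, 0.6)
  })
  lys <- tibble::tibble(genome_id = "L", sequence = paste0(a, p))
  ref <- tibble::tibble(genome_id = "L", sequence = a)
  cand <- tibble::tibble(genome_id = "L", start = nchar(a) + 500,
                         end = nchar(a) + 1500)
  reg <- delineate_boundaries(lys, ref, cand)
  expect_false(reg$complete)
  expect_true(reg$right_open)
  expect_equal(reg$start, nchar(a))
  expect_equal(reg$end, nchar(lys$sequence))
})

test_that("att prediction finds the flanking repeat and its tRNA, either orientation", {
  core <- "CAACCCCATGGAGGTTCAAGTCCTCTCGCCCGCACCATCTGAA"
  withr::with_seed(120, {
    left <- prophagr:::random_dna(2000, 0.5)
    interior <- prophagr:::random_dna(5000, 0.6)
    right <- prophagr:::random_dna(2000, 0.5)
    trna_pad <- prophagr:::random_dna(47, 0.5)
  })
  # avoid chance collisions that would legitimately lengthen the repeat:
  # the interior must not extend the att copies on either side
  pick_diff <- function(ch) setdiff(c("A", "C", "G", "T"), ch)[1]
  substr(interior, 1, 1) <- pick_diff(substr(right, 1, 1))
  substr(interior, nchar(interior), nchar(interior)) <-
    pick_diff(substr(trna_pad, 47, 47))
  trna <- paste0(trna_pad, core)
  g <- tibble::tibble(
    genome_id = "g",
    sequence = paste0(left, trna, interior, core, right))
  trna_start <- nchar(left)
  feats <- feature_row("g", "t1", trna_start, trna_start + nchar(trna),
                       "tRNA-Leu", kind = "tRNA", isotype = "Leu")
  region <- tibble::tibble(genome_id = "g",
                           start = trna_start + nchar(trna),
                           end = trna_start + nchar(trna) + nchar(interior))
  att <- predict_att(region, g, feats)
  expect_equal(att$att_core, core)
  expect_equal(att$start, trna_start + nchar(trna) - nchar(core))
  expect_equal(att$end, region$end)
  expect_equal(att$attb_isotype, "Leu")

  # a minus-strand tRNA exposes the core as its reverse complement and
  # still gets assigned
  feats_rc <- feats
  feats_rc$strand <- "-"
  att_rc <- predict_att(region, g, feats_rc)
  expect_equal(att_rc$att_core, core)
  expect_equal(att_rc$attb_isotype, "Leu")

  # no repeat: att absent
  g2 <- tibble::tibble(genome_id = "g",
                       sequence = paste0(left, interior, right))
  region2 <- tibble::tibble(genome_id = "g", start = nchar(left),
                            end = nchar(left) + nchar(interior))
  att2 <- predict_att(region2, g2, feats[0, ])
  expect_true(is.na(att2$att_core))
})

test_that("region GC handles planted and degenerate content", {
  expect_equal(region_gc(tibble::tibble(genome_id = "g", sequence = "GGCC"),
                         0, 4), 1)
  expect_equal(region_gc(tibble::tibble(genome_id = "g", sequence = "ATAT"),
                         0, 4), 0)
  co <- small_cohort()
  tr <- co$truth$prophages
  for (i in seq_len(nrow(tr))) {
    g <- co$genomes[match(tr$genome_id[i], co$genomes$genome_id), ]
    expect_equal(region_gc(g, tr$start[i], tr$end[i]), tr$gc[i])
    expect_gt(tr$gc[i], 0.5)   # prophage GC range by construction
  }
})

test_that("the full finder recovers every planted prophage exactly", {
  co <- small_cohort()
  tr <- co$truth$prophages
  found <- find_prophages(co$genomes, co$features, co$references)
  expect_equal(nrow(found), nrow(tr))
  key <- function(d) paste(d$genome_id, round(d$start / 1000))
  m <- match(key(tr), key(found))
  expect_false(any(is.na(m)))
  expect_true(all(abs(found$start[m] - tr$start) <= 5))
  expect_true(all(abs(found$end[m] - tr$end) <= 5))
  expect_equal(found$att_core[m], tr$att_core)
  expect_equal(found$attb_isotype[m], tr$attb_isotype)
  expect_true(all(found$complete))
  # self-check invariant: reported att cores flank the region
  for (i in seq_len(nrow(found))) {
    g <- co$genomes$sequence[match(found$genome_id[i], co$genomes$genome_id)]
    core <- found$att_core[i]
    expect_equal(substr(g, found$start[i] + 1, found$start[i] + nchar(core)),
                 core)
    expect_equal(substr(g, found$end[i] + 1, found$end[i] + nchar(core)),
                 core)
  }
})
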