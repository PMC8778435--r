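test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- small_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$features, b$features)
  expect_identical(a$truth, b$truth)
})

test_that("every truth interval matches the emitted sequence", {
  co <- small_cohort()
  tr <- co$truth$prophages
  for (i in seq_len(nrow(tr))) {
    p <- tr[i, ]
    g <- co$genomes$sequence[match(p$genome_id, co$genomes$genome_id)]
    region <- substr(g, p$start + 1, p$end)
    # region carries attL at its start; attR follows immediately after
    expect_true(startsWith(region, p$att_core))
    expect_equal(substr(g, p$end + 1, p$end + nchar(p$att_core)), p$att_core)
    # the attB tRNA ends with the att core
    trna <- co$features[co$features$feature_id == p$attb_feature_id &
                        co$features$genome_id == p$genome_id, ]
    expect_true(endsWith(substr(g, trna$start + 1, trna$end), p$att_core))
  }
  # planted spacers differ from their protospacer by the configured count
  sp <- co$truth$spacers
  ps <- prophage_sequences(co)
  for (i in seq_len(nrow(sp))) {
    s <- sp[i, ]
    seq <- ps$sequence[match(s$target_prophage, ps$prophage_id)]
    seg <- substr(seq, s$position + 1, s$position + nchar(s$sequence))
    if (s$strand == "-") seg <- reverse_complement(seg)
    expect_equal(prophagr:::hamming_mismatches(s$sequence, seg), s$mismatches)
    # PAM truth: TCC immediately 5' on the protospacer strand
    g <- seq
    flank <- if (s$strand == "+") {
      substr(g, s$position - 2, s$position)
    } else {
      reverse_complement(substr(g, s$position + nchar(s$sequence) + 1,
                                s$position + nchar(s$sequence) + 3))
    }
    expect_equal(flank == "TCC", s$pam)
  }
})

test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, prophage_size = c(40000, 42000),
                          genome_length = 30000), "exceeds genome length")
  expect_error(sim_config(seed = 1, repeat_length = 50), "\\[23, 47\\]")
  expect_error(sim_config(seed = 1, n_rv = 0), "n_rv")
  expect_error(sim_config(seed = 1, tr_length = 90), "\\[120, 135\\]")
})

test_that("plant_prophage then excision restores the host exactly", {
  withr::with_seed(98, {
    left <- prophagr:::random_dna(3000, 0.6)
    pad <- prophagr:::random_dna(47, 0.6)
    core <- prophagr:::random_dna(43, 0.5)
    right <- prophagr:::random_dna(3000, 0.6)
    interior <- prophagr:::random_dna(5000, 0.6)
  })
  g <- paste0(left, pad, core, right)
  trna_start <- nchar(left)
  trna_end <- trna_start + nchar(pad) + nchar(core)
  genomes <- tibble::tibble(genome_id = "h", sequence = g)
  feats <- tibble::tibble(genome_id = "h", feature_id = "t", kind = "tRNA",
                          start = trna_start, end = trna_end, strand = "+",
                          product = "tRNA-Ala", locus_tag = NA_character_,
                          isotype = "Ala")
  res <- plant_prophage(genomes, feats, "h", interior, core, "t",
                        prophage_id = "p")
  # region carries one att copy; the tRNA feature is untouched
  expect_equal(res$prophage$start, trna_end - nchar(core))
  expect_equal(res$prophage$end, trna_end + nchar(interior))
  trna_after <- res$features[res$features$feature_id == "t", ]
  expect_equal(trna_after$start, trna_start)
  expect_equal(trna_after$end, trna_end)
  ex <- excise_prophage(res$genomes, res$prophage)
  expect_identical(ex$restored_host$sequence, g)
  expect_equal(nchar(ex$circular_sequence),
               nchar(interior) + nchar(core))
  expect_error(
    plant_prophage(genomes, feats, "h", interior, random_seq(43, 5), "t"),
    "att core not found")
})

test_that("planted DGR obeys the identity arithmetic and architectures", {
  s <- random_seq(32000, 4, gc = 0.6)
  pl0 <- withr::with_seed(1, plant_dgr(s, n_variable_sites = 0))
  tr_seq <- substr(pl0$sequence, pl0$dgr$tr[1] + 1, pl0$dgr$tr[2])
  vr_seq <- substr(pl0$sequence, pl0$dgr$vr[1] + 1, pl0$dgr$vr[2])
  expect_identical(tr_seq, vr_seq)          # no variable sites -> VR == TR

  # 10 sites on a 130 bp TR leave identity 120/130 > 90%
  expect_equal((130 - 10) / 130, 0.923, tolerance = 1e-3)
  expect_error(plant_dgr(s, tr_length = 130, n_variable_sites = 14),
               "90%")

  pl2 <- withr::with_seed(2, plant_dgr(s, tr_length = 123, style = "within"))
  ert <- pl2$features[pl2$features$product == "reverse transcriptase", ]
  expect_true(pl2$dgr$tr[1] >= ert$start && pl2$dgr$tr[2] <= ert$end)
  expect_equal(pl2$dgr$architecture, "TR_within_ert")
})

test_that("planted shufflon lays out rix sites and Rv homology", {
  s <- random_seq(32000, 5, gc = 0.6)
  pl <- withr::with_seed(3, plant_shufflon(s, n_rv = 3))
  rx <- pl$shufflon$rix
  expect_equal(sum(rx$orientation == "direct"), 4)      # n_rv + 1
  expect_equal(sum(rx$orientation == "inverted"), 2)    # in Rc + after stop
  found <- find_rix_sites(pl$sequence)
  expect_equal(found$position, sort(rx$position))
  expect_setequal(found$orientation[match(rx$position, found$position)],
                  rx$orientation)
  # background scrubbing: no motifs outside planted sites
  expect_equal(nrow(found), nrow(rx))
  # Rv genes share only limited pairwise homology
  rv <- pl$shufflon$rv_segments
  segs <- substring(pl$sequence, rv$start + 1, rv$end)
  for (i in 1:2) for (j in (i + 1):3) {
    matches <- nt_local_align(segs[i], segs[j])$matches
    expect_lt(matches / min(nchar(segs[i]), nchar(segs[j])), 0.5)
  }
})

test_that("depth simulation reflects induction factors", {
  co <- small_cohort()
  tr <- co$truth$prophages
  flat <- tr[tr$genome_id == "g02", ]
  flat$induction <- 1
  withr::with_seed(8, {
    d <- simulate_depth(co$genomes, flat, base_depth = 60,
                        genome_ids = "g02")
  })
  r <- coverage_ratio(d, c(flat$start[1], flat$end[1]),
                      exclude = flat[, c("start", "end")])
  expect_equal(r, 1, tolerance = 0.05)
  bad <- flat
  bad$induction <- 0.5
  expect_error(simulate_depth(co$genomes, bad, genome_ids = "g02"), ">= 1")
})

test_that("truth serialises to JSON and round-trips", {
  co <- small_cohort()
  tf <- withr::local_tempfile(fileext = ".json")
  write_truth(co$truth, tf)
  back <- read_truth(tf)
  for (nm in names(co$truth)) {
    a <- co$truth[[nm]]
    b <- back[[nm]]
    if (is.data.frame(a)) {
      expect_equal(as.data.frame(b), as.data.frame(a), tolerance = 1e-12,
                   ignore_attr = TRUE)
    } else {
      expect_equal(b, a, ignore_attr = TRUE)
    }
  }
})

test_that("a prophage-free cohort has an empty prophage truth map", {
  cfg <- sim_config(seed = 3, n_genomes = 3, genome_length = 60000,
                    plant_prophages = FALSE,
                    n_core_genes = 8, n_accessory_genes = 4,
                    n_unique_genes = 1)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$truth$prophages), 0)
  expect_equal(nrow(co$truth$spacers), 0)
  expect_identical(co$genomes, co$references)
})
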