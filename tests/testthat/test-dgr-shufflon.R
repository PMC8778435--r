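# Quadratic oracle for repeat-pair finding: every diagonal offset is scanned
# with a rolling-window Hamming identity (no seeding, no shortcuts).
oracle_repeat_pairs <- function(seq, min_len = 100, max_len = 150,
                                min_identity = 0.90) {
  n <- nchar(seq)
  best <- NULL
  for (d in min_len:(n - min_len)) {
    a <- substr(seq, 1, n - d)
    b <- substr(seq, d + 1, n)
    m <- prophagr:::match_vector(a, b)
    cs <- c(0, cumsum(m))
    len <- length(m)
    for (w in min_len:min(max_len, len)) {
      matches <- cs[(w + 1):(len + 1)] - cs[1:(len - w + 1)]
      i <- which.max(matches)
      sc <- 4 * matches[i] - 3 * w
      id <- matches[i] / w
      if (id >= min_identity &&
          (is.null(best) || sc > best$score ||
           (sc == best$score && w > (best$end1 - best$start1)))) {
        best <- list(start1 = i - 1L, end1 = i - 1L + w,
                     start2 = i - 1L + d, end2 = i - 1L + d + w,
                     identity = id, score = sc)
      }
    }
  }
  best
}

test_that("planted repeat pairs are found; random sequence gives none", {
  withr::with_seed(70, {
    s <- prophagr:::random_dna(5000, 0.6)
    tr <- substr(s, 1001, 1130)
  })
  planted <- paste0(substr(s, 1, 3000), tr, substr(s, 3131, 5000))
  pairs <- find_repeat_pairs(planted)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$identity, 1)              # identical duplication
  # chance edge matches may widen the window by a base or two
  expect_lte(abs(pairs$start1 - 1000), 3)
  expect_lte(abs(pairs$start2 - 3000), 3)
  expect_gte(pairs$length, 130)
  expect_lte(pairs$length, 136)

  withr::with_seed(71, {
    bg <- prophagr:::random_dna(30000, 0.5)
  })
  expect_equal(nrow(find_repeat_pairs(bg)), 0)
})

test_that("the seeded pair finder agrees with the quadratic oracle", {
  for (seed in 72:74) {
    withr::with_seed(seed, {
      s <- prophagr:::random_dna(2500, 0.6)
      tr <- substr(s, 301, 430)
      vr <- prophagr:::mutate_sequence(tr, 0.06)
    })
    planted <- paste0(substr(s, 1, 1500), vr, substr(s, 1631, 2500))
    mine <- find_repeat_pairs(planted)
    oracle <- oracle_repeat_pairs(planted)
    expect_equal(nrow(mine), 1)
    expect_equal(mine$start1, oracle$start1)
    expect_equal(mine$end1, oracle$end1)
    expect_equal(mine$start2, oracle$start2)
    expect_equal(mine$identity, oracle$identity)
  }
})

test_that("DGR assembly recovers both planted architectures", {
  co <- mid_cohort()
  tr <- co$truth
  for (i in seq_len(nrow(tr$dgr))) {
    td <- tr$dgr[i, ]
    reg <- truth_region(co, td$prophage_id)
    d <- assemble_dgr(reg$sequence, reg$features)
    expect_equal(d$architecture, td$architecture)
    expect_lte(abs(d$tr_start - td$tr_start), 5)
    expect_lte(abs(d$vr_start - td$vr_start), 5)
    expect_lte(abs(d$tr_end - td$tr_end), 5)
    expect_gt(d$tr_vr_identity, 0.90)
    expect_lte(abs((d$tr_end - d$tr_start) - (d$vr_end - d$vr_start)), 5)
    expect_false(is.na(d$rt_gene))
    expect_false(is.na(d$mtd_gene))
    if (td$architecture == "TR_upstream_of_ert") {
      expect_false(is.na(d$avd_gene))
    }
  }
  # RT gene but no repeats -> absent
  reg <- truth_region(co, tr$shufflon$prophage_id[1])  # shufflon clade: no DGR
  fake <- reg$features
  fake$product[fake$product == "holin"] <- "reverse transcriptase"
  expect_null(suppressMessages(
    assemble_dgr(reg$sequence, fake,
                 pairs = find_repeat_pairs(paste0(strrep("A", 120),
                                                  strrep("C", 120))))))
})

test_that("variable sites are called exactly and order-invariantly", {
  co <- mid_cohort()
  tr <- co$truth
  dgr_clade <- tr$dgr[tr$dgr$architecture == "TR_upstream_of_ert", ]
  getseq <- function(pid, a, b) {
    p <- tr$prophages[tr$prophages$prophage_id == pid, ]
    g <- co$genomes$sequence[match(p$genome_id, co$genomes$genome_id)]
    substr(g, p$start + a + 1, p$start + b)
  }
  vrs <- vapply(seq_len(nrow(dgr_clade)), function(i) {
    getseq(dgr_clade$prophage_id[i], dgr_clade$vr_start[i],
           dgr_clade$vr_end[i])
  }, character(1))
  trseq <- getseq(dgr_clade$prophage_id[1], dgr_clade$tr_start[1],
                  dgr_clade$tr_end[1])
  sites <- call_variable_sites(vrs, trseq)
  planted <- sort(unique(
    tr$dgr_sites$offset[tr$dgr_sites$prophage_id ==
                          dgr_clade$prophage_id[1]]))
  expect_equal(as.integer(sites), as.integer(planted))
  expect_equal(call_variable_sites(rev(vrs), trseq), sites)  # order-invariant
  # identical observations: no variable site
  expect_equal(length(call_variable_sites(c(trseq, trseq), trseq)), 0)
  # a single divergent position
  one <- trseq
  substr(one, 8, 8) <- setdiff(c("A", "C", "G", "T"),
                               substr(trseq, 8, 8))[1]
  expect_equal(call_variable_sites(one, trseq), 7L)
  expect_error(call_variable_sites(substr(trseq, 1, 50), trseq),
               "length mismatch")
})

test_that("variant space is exact integer arithmetic", {
  expect_equal(variant_space(10), 4^10)
  expect_gte(variant_space(10), 1e6)
  expect_equal(variant_space(0), 1)
  expect_equal(variant_space(1), 4)
  expect_error(variant_space(-1), ">= 0")
})

test_that("rix scanning finds both orientations and mirrors under RC", {
  expect_equal(find_rix_sites("AATTCCGTATAA")$position, 2)
  expect_equal(find_rix_sites("AATTCCGTATAA")$orientation, "direct")
  inv <- find_rix_sites("AAATACGGAAAA")
  expect_equal(inv$orientation, "inverted")
  expect_equal(inv$position, 2)
  expect_equal(nrow(find_rix_sites(random_seq(20000, 75))), 0)

  co <- mid_cohort()
  reg <- truth_region(co, co$truth$shufflon$prophage_id[1])
  fwd <- find_rix_sites(reg$sequence)
  rc <- find_rix_sites(reverse_complement(reg$sequence))
  n <- nchar(reg$sequence)
  mirrored <- tibble::tibble(
    position = sort(n - 8 - rc$position),
    orientation = rc$orientation[order(n - 8 - rc$position)])
  flip <- c(direct = "inverted", inverted = "direct")
  expect_equal(mirrored$position, fwd$position)
  expect_equal(unname(flip[mirrored$orientation]), fwd$orientation)
})

test_that("shufflon assembly recovers the planted cassette layout", {
  co <- mid_cohort()
  tr <- co$truth
  for (pid in tr$shufflon$prophage_id) {
    reg <- truth_region(co, pid)
    rix <- find_rix_sites(reg$sequence)
    truth_rix <- tr$shufflon_rix[tr$shufflon_rix$prophage_id == pid, ]
    expect_equal(rix$position, sort(as.integer(truth_rix$position)))
    sh <- assemble_shufflon(reg$sequence, reg$features, rix)
    truth_rv <- tr$shufflon_rv[tr$shufflon_rv$prophage_id == pid, ]
    expect_equal(as.integer(sh$rv_segments$start),
                 as.integer(truth_rv$start))
    expect_equal(as.integer(sh$rv_segments$end), as.integer(truth_rv$end))
    expect_false(is.na(sh$rc_gene))
    # Rv ~ Rc homology agrees with an independent aligner on the same
    # statistic (identity over aligned columns of the local alignment)
    rc_row <- tr$shufflon[tr$shufflon$prophage_id == pid, ]
    rc_tail <- substr(reg$sequence, rc_row$rc_end - 199, rc_row$rc_end)
    for (i in seq_len(nrow(truth_rv))) {
      seg <- substr(reg$sequence, truth_rv$start[i] + 1, truth_rv$end[i])
      oracle <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seg), Biostrings::DNAString(rc_tail),
        type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -3),
        gapOpening = 5, gapExtension = 2)
      oid <- Biostrings::nmatch(oracle) /
        nchar(as.character(Biostrings::pattern(oracle)))
      expect_equal(sh$rv_rc_homology[i], oid, tolerance = 0.05)
    }
  }
  # recombinase but zero rix sites -> absent
  reg <- truth_region(co, tr$shufflon$prophage_id[1])
  no_rix <- reg$features
  expect_null(assemble_shufflon(random_seq(15000, 76), no_rix))
})
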