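# Shared fixtures. The small cohort keeps per-file runtime low; the default
# cohort (10 genomes x 300 kb, the package's study conditions) is built once
# and reused by the acceptance tests. Both are cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

small_config <- function(seed = 7) {
  sim_config(seed = seed, n_genomes = 4, genome_length = 120000,
             prophage_size = c(32000, 36000),
             n_core_genes = 15, n_accessory_genes = 10, n_unique_genes = 2)
}

small_cohort <- function() {
  cached("small", function() generate_cohort(small_config()))
}

# 9 genomes so that both DGR architectures, the shufflon clade and the
# related clade are all planted, at reduced backbone size
mid_cohort <- function() {
  cached("mid", function() {
    generate_cohort(sim_config(
      seed = 11, n_genomes = 9, genome_length = 160000,
      prophage_size = c(32000, 36000),
      n_core_genes = 15, n_accessory_genes = 10, n_unique_genes = 2))
  })
}

default_cohort <- function() {
  cached("default", function() generate_cohort(sim_config(seed = 20260101)))
}

# prophage truth row + its region extraction
truth_region <- function(cohort, prophage_id) {
  p <- cohort$truth$prophages[
    cohort$truth$prophages$prophage_id == prophage_id, ]
  c(list(truth = p),
    extract_region(cohort$genomes, cohort$features, p$genome_id,
                   p$start, p$end))
}

random_seq <- function(n, seed, gc = 0.5) {
  withr::with_seed(seed, prophagr:::random_dna(n, gc))
}
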