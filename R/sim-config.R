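#' Configuration for the synthetic genome-cohort generator
#'
#' Defaults emulate, at desk scale, a high-GC gut Actinobacterium cohort
#' carrying temperate phages: 300 kb host backbones (a scaled-down stand-in
#' for ~3.3 Mb chromosomes) at GC 0.635, prophages of 32-42 kb at GC
#' 0.58-0.67 integrating at tRNA genes (Leu/Arg/Ser/Ala isotypes) with
#' 40-55 nt att cores duplicated as attL/attR direct repeats, CRISPR
#' repeat-spacer arrays whose 34-nt spacers target planted prophages with
#' controlled mismatch counts and optional 5'TCC PAMs, diversity-generating
#' retroelements (130 bp or 123 bp template repeats, >90% TR/VR identity,
#' 10 variable sites), and a tyrosine-invertase shufflon delimited by the
#' asymmetric 8-mer `TTCCGTAT`.
#'
#' @param n_genomes number of host genomes
#' @param genome_length host backbone length in bp
#' @param gc_content host background GC fraction
#' @param prophage_size length range (bp) of prophage interiors
#' @param prophage_gc GC range of prophage sequence
#' @param within_clade_divergence per-member substitution rate applied to a
#'   clade ancestor (fraction of unprotected positions)
#' @param tr_length template-repeat length for the TR-upstream architecture
#' @param tr_length_within template-repeat length for the TR-within-RT-gene
#'   architecture
#' @param n_variable_sites number of DGR variable sites in the VR
#' @param spacer_length CRISPR spacer length
#' @param repeat_length CRISPR repeat length (23-47)
#' @param n_rv number of shufflon Rv cassettes
#' @param rix_motif the shufflon crossover 8-mer
#' @param base_depth mean sequencing depth outside prophages
#' @param induction_range range of prophage/host depth ratios
#' @param n_core_genes,n_accessory_genes,n_unique_genes host gene complement:
#'   core genes present in every genome, accessory genes in a subset, unique
#'   genes private to each genome
#' @param plant_prophages set to `FALSE` for a prophage-free cohort (the
#'   truth prophage table comes back empty)
#' @param seed integer seed; mandatory, there is no silent nondeterminism
#' @return a `sim_config` list
#' @export
sim_config <- function(seed,
                       plant_prophages = TRUE,
                       n_genomes = 10,
                       genome_length = 300000,
                       gc_content = 0.635,
                       prophage_size = c(32000, 42000),
                       prophage_gc = c(0.58, 0.67),
                       within_clade_divergence = 0.02,
                       tr_length = 130,
                       tr_length_within = 123,
                       n_variable_sites = 10,
                       spacer_length = 34,
                       repeat_length = 29,
                       n_rv = 3,
                       rix_motif = "TTCCGTAT",
                       base_depth = 100,
                       induction_range = c(1.1, 5.2),
                       n_core_genes = 40,
                       n_accessory_genes = 30,
                       n_unique_genes = 5) {
  abort_if(missing(seed) || !is.numeric(seed) || length(seed) != 1,
           "`seed` is mandatory and must be a single integer")
  abort_if(diff(range(prophage_size)) < 0 || prophage_size[1] <= 0,
           "`prophage_size` must be a non-degenerate positive range")
  abort_if(prophage_size[2] >= genome_length,
           "prophage size exceeds genome length")
  abort_if(tr_length < 120 || tr_length > 135, "TR length must be in [120, 135]")
  abort_if(n_rv < 1, "`n_rv` must be >= 1")
  abort_if(repeat_length < 23 || repeat_length > 47,
           "CRISPR repeat length must be in [23, 47]")
  abort_if(spacer_length < 26 || spacer_length > 50,
           "spacer length must be in [26, 50]")
  abort_if(nchar(rix_motif) < 6, "rix motif must be at least 6 nt")
  structure(list(
    seed = as.integer(seed),
    plant_prophages = plant_prophages,
    n_genomes = n_genomes,
    genome_length = genome_length,
    gc_content = gc_content,
    prophage_size = prophage_size,
    prophage_gc = prophage_gc,
    within_clade_divergence = within_clade_divergence,
    tr_length = tr_length,
    tr_length_within = tr_length_within,
    n_variable_sites = n_variable_sites,
    spacer_length = spacer_length,
    repeat_length = repeat_length,
    n_rv = n_rv,
    rix_motif = toupper(rix_motif),
    base_depth = base_depth,
    induction_range = induction_range,
    n_core_genes = n_core_genes,
    n_accessory_genes = n_accessory_genes,
    n_unique_genes = n_unique_genes
  ), class = "sim_config")
}

# The default clade plan: five clades exercising every prophage feature the
# pipeline detects. Clade 1 carries the shufflon and integrates at tRNA-Leu
# (its att core is a documented 43-mer attP); clade 2 carries the
# TR-upstream DGR at tRNA-Arg; clade 3 the TR-within-RT DGR at tRNA-Ser;
# clade 4 is a plain prophage at tRNA-Ala; clade 5 shares half of the clade-4
# ancestor, planting one related inter-clade pair (>40% fragmented identity)
# without merging at the 60% clade threshold.
CLADE1_ATT <- "CAACCCCATGGAGGTTCAAGTCCTCTCGCCCGCACCATCTGAA"

default_clade_plan <- function(n_genomes) {
  plan <- tibble::tibble(
    clade = 1:5,
    style = c("shufflon", "dgr_upstream", "dgr_within", "plain", "related"),
    isotype = c("Leu", "Arg", "Ser", "Ala", "Ala"),
    members = list(c(1, 2, 3, 4), c(1, 5, 6, 7), c(8, 9), 10, 5)
  )
  # clades whose member genomes fall outside a smaller cohort keep their
  # ancestor (the related clade derives from the plain one) but plant nothing
  plan$members <- lapply(plan$members, function(m) m[m <= n_genomes])
  plan
}
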