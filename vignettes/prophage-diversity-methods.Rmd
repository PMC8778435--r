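---
title: "Methods: prophage discovery, diversity and activity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prophage discovery, diversity and activity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

prophagr characterises the prophage complement of a bacterial species from
genome assemblies: how the species' gene pool is structured (pangenome and
its openness), where temperate phages sit in the chromosomes and how they
integrate (att sites at tRNA genes), how diverse they are (nucleotide-level
clades), whether the hosts' CRISPR/cas arsenal sees them, what
diversification machinery they carry (diversity-generating retroelements
and invertase shufflons), and whether they are active rather than
domesticated (read-depth elevation, excision and circularisation). This
vignette explains the models and procedures behind each step, the
parameters that matter, and what the synthetic cohort used by the test
suite does and does not establish.

## The pangenome model

Predicted proteins are clustered into orthologous groups (OGs) with a
reciprocal-best-hit (RBH) graph. Two proteins from different genomes are
linked when their Smith–Waterman local alignment (BLOSUM62, gap open 11 /
extend 1) reaches **30% identity** (matches over aligned columns) and
**70% coverage** (aligned span over the shorter sequence), and each is the
other's best qualifying hit in the counterpart genome. OGs are the
connected components of this graph; every gene belongs to exactly one OG,
singletons included. Ties in best-hit selection break by higher identity,
then lexicographic gene id, which makes the partition invariant under
input order. Coverage is computed over the shorter sequence — common
ortholog-tool convention; identity/coverage thresholds are arguments if a
user calibrates differently.

OGs present in every genome are *core*, in exactly one genome *unique*,
otherwise *accessory*. Gene accumulation curves are built from full random
permutations of genome order (default 100), recording the cumulative union
(pan) and intersection (core) at each cohort size. Openness is assessed by
fitting Heap's law,

$$y = A\,x^{B} + C,$$

to the mean pan curve by nonlinear least squares (Levenberg–Marquardt,
initialised at $A = y(1)$, $B = 0.5$, $C = 0$). An exponent $0 < B < 1$
marks an open pangenome. A constant curve makes the power-law Jacobian
singular, so that degenerate case is returned in closed form
($A = 0, B = 0, C = \bar y$, closed). Non-convergence is flagged on the
returned object rather than thrown.

## Prophage discovery and att sites

Candidate loci are gene clusters carrying at least **two of three**
hallmark products — terminase, major capsid/head protein, portal protein —
within 60 kb (case-insensitive keyword matching on product strings; the
keyword list is an argument). Requiring a quorum of two tolerates a missing
annotation while excluding lone integrases.

Boundaries are delineated against a prophage-free reference genome:
unique 20-mer anchors on each side of the candidate are extended to maximal
exact matches, and the prophage is the maximal lysogen segment absent from
the reference. Anchors must extend into matches of at least 150 bp —
shorter coincidental matches (for instance a protospacer whose spacer copy
sits in the reference's own CRISPR array) are skipped, which is what
collinear match chaining achieves in whole-genome aligners. When the two
flank mappings overlap in reference coordinates — the signature of a
junction direct repeat, or simply a coinciding edge base — the left
boundary is retracted by the overlap, making removal of the interval an
exact inverse of the insertion. A flank that fails to anchor (contig end)
leaves that terminus open and the region incomplete.

att sites are predicted by searching 500 bp windows centred on each
boundary for the longest exact direct repeat (≥ 15 nt, occurring once per
window). The region is then snapped to run **from the start of attL to the
start of attR**, so it carries exactly one att copy; the attB locus is any
tRNA whose sequence contains the core in either orientation (minus-strand
tRNAs expose the reverse complement). With 500 bp windows the chance of a
spurious ≥ 15 nt repeat in background sequence is negligible. The one-copy
convention makes the excision arithmetic exact:
$\mathrm{len}(\text{lysogen}) = \mathrm{len}(\text{restored host}) +
\mathrm{len}(\text{circle})$, since the lysogen carries two att copies and
each excision product one.

## Fragmented nucleotide similarity and clades

Whole-prophage relatedness uses fragmented similarity: the query is tiled
into 200 bp fragments at 100 bp stride, each fragment is scored against
the subject with blastn match/mismatch weights (+1/−3), the score is
normalised by the fragment self-score and floored at zero, and the
similarity is 100 × the mean over *all* fragments (no fragment filtering,
matching a 0% inclusion threshold). Fragment scoring is seeded
best-diagonal ungapped scoring: shared 15-mers nominate diagonals and the
maximal-scoring ungapped segment is taken on the best few. For
substitution-divergence this equals the gapped Smith–Waterman score (a gap
costs more than three mismatches), and the test suite cross-checks the
equality against an independent gapped aligner; on indel-rich real data
the ungapped score is a lower bound, which slightly deflates similarity
but cannot merge unrelated sequences. The measure is asymmetric (tiling
follows the query), as in fragmented all-vs-all heatmap tools.

Clades are single-linkage components over the symmetrised matrix at
**> 60%**, numbered by descending size; between-clade pairs above **40%**
are reported as inter-clade relations rather than merged. Single linkage
matches a clade notion defined by pairwise whole-sequence identity;
raising the threshold can only split clades, never merge them.

## CRISPR spacers and protospacers

Arrays are detected CRT-style: a lag-correlation scan over tandem periods
49–97 bp (repeat 23–47 + spacer 26–50) seeds candidate repeats, whose
occurrences (allowing one mismatch per copy) are chained into arrays
wherever consecutive copies are separated by spacer-sized gaps; at least
three copies are required, and repeat boundaries are snapped to the
columns where all copies agree. Spacers are deduplicated by exact string
identity.

A spacer targets a protospacer when a full-length ungapped alignment has
**at most 3 mismatches** and a bit score of **at least 44.1**. The bit
score uses ungapped blastn Karlin–Altschul statistics for the +1/−3
scoring system ($\lambda = 1.374$, $K = 0.711$):

$$S = \ell - 4m, \qquad
  \text{bits} = \frac{\lambda S - \ln K}{\ln 2},$$

for spacer length $\ell$ and mismatch count $m$. At the median spacer
length of 34 nt, exactly 3 mismatches give 44.1 bits — the boundary case —
so both filters are individually active: longer spacers can pass the score
with 3 mismatches, shorter ones are score-limited. `N` never counts as a
match on either side. Matching is ungapped by design: a ≤ 3-edit
alignment of a 26–50-mer essentially never gaps under blastn-short
scoring.

The PAM check asks whether the three nucleotides immediately 5′ of the
protospacer, read on the protospacer's strand, equal `TCC` (the canonical
motif of the host's type I-C system); for a minus-strand hit this is the
reverse complement of the three forward-strand bases after the match.
Targeting counts in the host × clade matrix ignore PAM status — PAM is
reported separately and matters chiefly for interpreting self-targeting
(a host's spacer hitting a prophage resident in the same genome).

## Diversity-generating retroelements and shufflons

DGR detection starts from same-orientation repeat pairs: shared exact
20-mers seed diagonals, each diagonal is extended ungapped, and the
100–150 bp window maximising the +1/−3 score is kept if its identity is
≥ 90%. Score ties go to the longer window, so trimming an edge segment of
zero net score cannot shrink the reported repeat. Identity is computed
over the trimmed window (aligned-window identity). The element is
assembled around a reverse-transcriptase gene: the pair member nearer to
(or inside) the RT gene is the template repeat (TR), the other the
variable repeat (VR); the VR must fall within a gene — the major tropism
determinant — and a small (< 600 bp) gene between TR and mtd is reported
as avd. The TR nested inside the RT gene gives the `TR_within_ert`
architecture, otherwise `TR_upstream_of_ert`.

Variable sites across isolates: a VR column is variable when at least two
distinct bases are observed across the TR and the isolate VRs (N ignored);
offsets are 0-based within the VR and independent of isolate order. The
variant space of $n$ sites is $4^n$ — each site can carry any of the four
bases, consistent with 10 sites spanning on the order of $10^6$ variants.

Shufflon (rix) sites are exact occurrences of the asymmetric 8-mer
`TTCCGTAT` (direct) and its reverse complement (inverted); the scan is
exact by default because the crossover site is a specific motif, with no
degeneracy documented. Assembly requires an invertase-like recombinase
distinct from the integrase: Rv cassettes are the intervals between
consecutive direct rix sites downstream of the recombinase, and Rc is the
first larger gene after the last cassette with an inverted rix within
200 bp of its stop. The Rv→Rc C-terminal homology fraction is local
alignment identity of each cassette against the Rc 3′ end.

## Activity evidence

The coverage ratio is mean depth inside the prophage over mean depth in
the host background, with *all* prophage intervals excluded from the
background so a multi-prophage host does not deflate the contrast
(median available as a robust option; mean is the default because
coverage tools report averages). The ratio is invariant under rescaling
the profile, and undefined (flagged) at zero host depth.

Excision reverses integration under the one-att-copy convention and
reconstructs the attP junction as the 100 nt of the circular genome
centred on the att core — the sequence a junction-spanning amplicon would
read. In-silico PCR uses exact primer matching with convergent
orientation and a product cap of 3 kb, searching across the origin on
circular templates. Outward-facing primers around the junction therefore
amplify from the excised circle only, never from the integrated lysogen —
the in-silico analogue of the attP circularisation assay.

## The synthetic cohort: what it emulates

The generator builds a deterministic cohort (every byte reproducible from
the seed) emulating a high-GC gut Actinobacterium: by default **10
genomes of 300 kb** at GC 0.635. The backbone length is a deliberate
scale-down from the ~3.3 Mb chromosomes it stands in for; every detection
rule in the package is length-independent, and 300 kb keeps a full
pipeline run at desk scale. Each genome carries tRNA genes for the Leu,
Arg, Ala and Ser isotypes (the observed integration-target isotypes), a
shared core gene complement (40 families) plus accessory (30) and private
genes (5 per genome) built from back-translated proteins diverged 2% per
genome, and CRISPR arrays in six genomes.

Twelve prophages are planted in five clades sized 4/4/2/1/1:

* a shufflon-bearing clade integrating at tRNA-Leu, whose att core is a
  documented 43-nt attP sequence;
* a DGR clade (TR upstream of the RT gene, TR 130 bp) at tRNA-Arg;
* a DGR clade with the TR nested in the RT gene (TR 123 bp) at tRNA-Ser;
* a plain clade at tRNA-Ala;
* a related singleton sharing 62% of the plain clade's ancestry — after
  the compounded 2% member-level divergence on both sides this plants one
  inter-clade pair near 47% fragmented similarity, comfortably inside the
  (40, 60) reporting band without merging.

Prophage interiors are 32–42 kb at GC 0.58–0.67, inserted at the tRNA
with the att core duplicated as attL/attR direct repeats. Clade members
diverge from their ancestor by 2% substitutions outside protected
positions (TR, VR, rix sites), so within-clade fragmented similarity sits
near 85% and between unrelated clades near 0. DGR variable sites (10 per
element) are placed in the repeat interior — an edge substitution is
indistinguishable from the repeat boundary under local alignment — and
each isolate's VR carries a base *different* from the TR at every site,
so any isolate set determines the full site list. Spacers (34 nt) are
copied from planted prophages with controlled mismatch counts (0–3 within
the rule; one planted 4-mismatch spacer sits deliberately beyond it), a
configurable subset gets the `TCC` PAM written 5′ of the protospacer, and
one array contains a PAM-flanked self-targeting spacer. Depth profiles
are Poisson with per-prophage induction factors drawn from 1.1–5.2.

Generated background rejects the rix motif in both orientations, and the
generator disambiguates the single-base neighbourhood of att repeats and
protospacer flanks, so planted-truth recovery is exact rather than
approximate. Two caveats follow. First, what passing tests show is
recovery of *substitution-divergent, rearrangement-free* planted
structure: real genomes add indels, repeats, mobile elements, assembly
gaps and annotation noise that the cohort deliberately omits, so exact
recovery there is not implied. Second, host genes are codon-built and may
by chance contain the rix 8-mer; the motif-free guarantee applies to
prophage sequences and intergenic background, where the scan is actually
used.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; GFF's 1-based
  closed coordinates are converted at the I/O boundary only.
* Minus-strand features store forward-strand intervals and expose their
  sequence reverse-complemented on extraction.
* `N` is allowed in sequences but never counts as a match in any identity
  or mismatch computation; GC content excludes `N` from the denominator
  and an all-N region yields `NA`.
* Boundary-walk anchors: 20-mer seeds, 150 bp minimum chained match,
  completeness tolerance 200 bp of reference gap/overlap. All arguments.
* Repeat-window and fragment scoring ties resolve toward longer windows
  and earlier coordinates, for determinism.
* Queries shorter than one fragment are scored as a single whole-sequence
  fragment; a similarity matrix of one sequence is the 1×1 matrix [100].
* The Heap's fit requires ≥ 4 distinct x values; constant curves return
  the closed-form degenerate fit.

## Problem sizes used by the checks

The test suite exercises module behaviour on 4–9-genome cohorts with
120–160 kb backbones and runs the full pipeline acceptance checks on the
default 10 × 300 kb cohort; brute-force oracles (all-positions Hamming
scans, quadratic repeat search) run on ≤ 5 kb windows where exhaustive
enumeration is the point. These sizes are the package's chosen desk-scale
study conditions; all thresholds are length-independent.

## Known limitations

* Boundary delineation needs a prophage-free reference; there is no
  HMM-based de novo mode.
* Hallmark screening keys on product strings, so annotation vocabulary
  matters; the keyword lists are arguments for that reason.
* Fragment scoring is ungapped; heavily indel-diverged prophage pairs
  will score conservatively low.
* Protospacer matching is ungapped by design (documented above); gapped
  spacer matches are out of scope.
* The invertase/integrase distinction is by product keyword, not by
  profile search.
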