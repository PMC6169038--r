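---
title: "Models and methods behind metalineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metalineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalineage)
```

metalineage quantifies uncultivated microbial lineages in shotgun
metagenomes through five linked analyses: reduced-database 16S rRNA read
classification, majority-vote contig taxonomy, rRNA-masked fragment
recruitment with RPKG normalization, fragment-based ANI species
delineation, and CARD-FISH morphometrics with biomass partitioning. This
vignette explains the models, the parameters that matter, the numerical
choices that were genuinely open, and what the synthetic validation does
and does not establish.

## The alignment engine and its statistics

Every sequence comparison in the package — read screening, domain
validation, taxonomic classification, fragment recruitment, and ANI — runs
through one local-alignment engine (`local_align`, implemented in C++):
affine-gap Smith–Waterman in which a gap of length $L$ costs
$g_{open} + L\,g_{ext}$, both strands of the query are searched, and percent
identity follows the BLAST convention (identical columns over all alignment
columns, gap columns included). `N` and any non-ACGT character never match,
not even themselves — this is what makes rRNA masking absolute.

Significance uses the Karlin–Altschul form
$E = K\,m\,n\,e^{-\lambda S}$ with $m$ the query length and $n$ the total
nucleotide count of the searched database. The defaults (match $+1$,
mismatch $-2$, gap open 2, gap extend 1, $\lambda = 1.28$, $K = 0.46$) are
fixed, documented constants in the megablast style. They are a deliberate
stand-in: the analyses this package reproduces were originally run with
default BLASTN, whose exact statistical parameters depend on version and
task and are not recoverable; fixed constants make every e-value
reproducible to the bit across machines. Consequently e-values here are
internally consistent decision statistics, not BLAST-identical numbers —
all thresholds (1e-5 everywhere) act on this engine's own scale.

Two numerical choices worth knowing:

* **Tie-breaking.** When both strands score equally the forward strand
  wins; within a strand, the first best-scoring alignment *end* in
  (query, subject) scan order is taken, and the alignment start is then
  recovered by a reverse pass. Enumerating all co-optimal alignments to
  find the leftmost *start* would cost far more for no scientific gain;
  what matters is that repeated runs give identical output, which this
  rule guarantees.
* **Performance.** The score pass is computed four queries at a time over
  interleaved, independent DP chains (short queries padded with a
  never-matching code, which provably cannot alter any reported optimum).
  The engine is verified in the test suite against
  `Biostrings::pairwiseAlignment` and against an exhaustive full-matrix DP
  oracle written in plain R.

## The synthetic community generator

The generator is first-class, tested code: it defines the conditions under
which every downstream claim is checked.

* **Substitution model.** All divergence — between reference clusters,
  within clusters, sequencing error, genome mutation — is i.i.d. per-site
  substitution in which a hit site receives one of the three alternative
  bases uniformly (Jukes–Cantor-like). This is the simplest process with
  analytic oracles: two sequences independently at rate $d$ from a common
  ancestor match at a site with probability $(1-d)^2 + d^2/3$, and every
  generator test checks its realized statistic against such a closed form
  at three standard errors. Indels, chimeras, amplicon primer bias and
  quality-score models are deliberately out of scope.
* **Reference databases.** `evolve_reference_db` descends clusters from a
  shared root (default between-cluster rate 0.2, i.e. roughly 65%
  within-domain identity — comfortably separable at the 85% clustering
  threshold) and sequences from cluster ancestors (default full-length
  1500 nt). Clusters carry nested lineages (domain → phylum → class →
  cluster) so profiles can be cut at any rank.
* **Reads.** `simulate_reads` draws cluster counts from a multinomial,
  start positions uniformly on the forward strand (reverse-complement
  reads at 50% behind a flag, so strand handling is exercised without
  complicating the default), applies substitution errors, permutes read
  order, and emits a truth table whose TSV column order
  (read_id, source_id, domain, phylum, class, cluster) is fixed.
* **Cells.** `simulate_cells` samples lognormal (or normal, or fixed)
  lengths and widths per population, resampling draws that violate shape
  constraints. Lognormal is the default because measured bacterial
  cell-size distributions are right-skewed with strictly positive support.

All coordinates in the package are 0-based half-open; 1-based closed
coordinates appear only in the BLAST outfmt-6 export layer.

## Read classification

The two-stage design mirrors practice with large reference databases:
screening ten million reads against 645 thousand references is infeasible,
so a representative set built by greedy centroid clustering at 85%
identity stands in. `greedy_cluster` processes sequences in
length-descending order (ties by id); a sequence joins the first centroid
whose identity — identical columns of the best local alignment divided by
the shorter sequence's length, the UCLUST-like semantic — reaches the
threshold, else founds a new centroid. Whether the original analyses
sorted their input this way is unknowable; length-descending is the
conventional default and makes runs bit-identical.

Screening calls a read a 16S candidate when its best centroid hit has
e-value ≤ 1e-5 (score-only pass; details recovered only for candidates).
Candidates are then validated into archaeal / bacterial / eukaryotic rRNA
or non-rRNA by best hit against pooled per-domain representative sets —
an alignment-based approximation chosen over a covariance-model approach
because it is testable against the same engine and oracle machinery;
fidelity to profile-HMM validators is a non-goal. Exact archaeal/bacterial
score ties resolve alphabetically and are flagged (`tie`) in the output.

Classification against the complete database keeps the best-bit-score hit
(ties: higher identity, then lexicographic subject id) when it spans
≥ 90 columns at ≥ 80% identity; failures carry a reason, with the length
check applied before the identity check. The community profile divides by
the *prokaryotic denominator* — reads called archaeal or bacterial that
received a taxon — because the field's convention expresses abundances as
percent of total prokaryotes; eukaryotic and unclassifiable reads are
excluded. Sub-cluster percentages for the focal phylum use the same
denominator, so they sum exactly to the phylum's percentage.

Recovery behaviour under the generator's defaults: with ≥ 5000 reads,
error rate ≤ 1% and between-cluster divergence ≥ 15%, a 10% focal cluster
is recovered within three binomial standard errors (checked at 10,000
reads in the acceptance suite, ~2% of the community per cluster being the
practical floor).

## Contig taxonomy

A contig strictly longer than 5 kb ("longer than 5 kb" read literally) is
assigned to the target phylum when strictly more than half of its genes
*with hits* vote for it. Genes without any database hit are excluded from
the denominator — the source wording is ambiguous on this point, so the
choice is documented and the per-contig vote counts (`n_genes`,
`n_with_hits`, `n_target`) are returned for audit. No minimum gene count
is imposed. The decision is order-invariant and monotone in target votes;
the test suite checks it against exhaustive enumeration of every
target/non-target pattern up to 12 genes.

## Fragment recruitment and RPKG

rRNA genes are so conserved that they recruit reads from unrelated taxa;
`mask_rrna` therefore replaces annotated rRNA intervals with `N` before
recruitment, which reduces a masked region's recruitment to exactly zero
(N never matches). A read is recruited when its best alignment is at
least 50 columns, *strictly* greater than 95% identity (the printed
threshold is "> 95%", so 95.0% exactly is rejected), and e-value ≤ 1e-5 —
filters approximating species-level divergence. One best hit per read: the
statistic counts reads, not alignments.

$$\mathrm{RPKG} =
  \frac{\text{hits}}{(\text{genome length}/10^3)\,(\text{metagenome size}/10^9)}$$

Normalization uses the *full* genome length including masked bases
(masking suppresses spurious hits; the per-kilobase denominator describes
the genome, not its unmasked remainder — the choice is recorded in the
output and the mask is optional), and the metagenome size is the total
base count of the read set before any screening. RPKG is invariant under
metagenome duplication and under genome duplication with proportional
hits.

## ANI and species delineation

`ani_pair` cuts the query genome into consecutive 1020-nt fragments
(trailing remainder discarded, per the fragment-based definition), aligns
each against the other genome, and keeps fragments at ≥ 70% identity over
≥ 70% of the fragment length. The directed ANI is the mean identity of
kept fragments; the reported ANI is the arithmetic mean of the two
directions, since single values per pair are what species decisions are
made on, and it is `NA` when either direction keeps nothing. Species are
single-linkage components over pairs strictly above 95% ANI — single
linkage because the grouping semantic is "any >95% pair shares a
species"; whether the original calls used one-way or mean ANI is not
recoverable, and the mean is symmetric by construction. On the
gap-free mutation model, engine ANI at 3% divergence agrees with a direct
per-fragment Hamming oracle within 0.5 percentage points (the small
positive offset comes from local alignments legitimately trimming
mismatched fragment ends).

## Morphometrics and biomass

Biovolumes use the standard shapes of the aquatic-microbiology literature:
spheres $V = \tfrac{\pi}{6}d^3$ and rods/ovoids as cylinders with
hemispherical caps, $V = \tfrac{\pi}{4}w^2(l - w/3)$, which degenerates
continuously to the sphere at $l = w$. The upstream image-analysis
workflow that produced the motivating measurements does not publish its
exact formula, so this conventional one is the package's documented
choice; a population's printed median volume therefore need not be
reproducible from its printed mean dimensions (medians of skewed volume
distributions sit below the volume of the mean-dimension cell).

Biomass is proxied by biovolume under constant density. The focal
population's abundance share is its fraction of cell counts, its biomass
share its fraction of summed volume, and algebraically

$$\frac{\text{biomass \%}}{\text{abundance \%}}
  = \frac{\overline{V}_{focal}}{\overline{V}_{all}},$$

an identity the tests check to machine precision. A population of large
cells can thus contribute almost 20% of community biomass at 10%
abundance (ratio ≈ 2), which is exactly the worked example the acceptance
script recomputes: 100 focal spheres of diameter 0.52416 µm among 900
background spheres of 0.40 µm give ratio 2.00 and biomass 20.0%. An
allometric carbon conversion (`carbon_content`, $C = aV^b$) is provided
but off by default: partitioning claims are about biovolume shares, and a
carbon exponent would silently change the ratio. Percentiles are linear
order-statistic interpolation (R type 7), pinned for reproducibility.

## Orchestration and reproducibility

`run_pipeline` executes the stages in dependency order from one nested
configuration (R list or YAML) whose defaults are the canonical
thresholds: screen e-value 1e-5 and 1e7-read cap, classify 80%/90 bp,
contig > 5 kb, recruit 50 bp / >95% / 1e-5, ANI 1020/70%/0.7 with species
at 95%, clustering at 85%. Every stage derives its seed deterministically
from the master seed and its stage name, so disabling one stage never
shifts another's random stream; the run directory gets a manifest with
per-stage counts and md5 digests of every output, and identical
configurations produce byte-identical manifests. The package's interface
is this function surface — the natural shape for an R analysis package —
with `scripts/acceptance.R` as the reproducibility entry point.

## Problem sizes and limitations

The shipped validation runs at desk scale by design: reference databases
of a few thousand nucleotides per sequence and 12–50 sequences, read sets
of $10^2$–$10^4$ reads, genomes of 10–100 kb, and cell tables of
$10^2$–$10^3$ cells. These sizes make every oracle exhaustive and every
stochastic check statistically decisive (3-SE bounds) while keeping the
full suite in minutes. What passing them shows is that the *machinery* —
thresholds, normalizations, vote rules, estimators — does what it claims
under a known substitution process. What they cannot show is robustness
to the features the generator deliberately omits: indels and chimeric
reads, non-uniform coverage, amplicon bias, real taxonomic structure
(paralogous rRNA operons, intra-genome 16S variation), or BLAST-identical
e-values. Conclusions about real communities still require the usual
external controls; the package's contribution is that the computational
chain between inputs and numbers is fully specified, seeded, and tested.
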