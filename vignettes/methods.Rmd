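---
title: "Models and methods behind woodpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind woodpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`woodpop` packages the downstream population-genomic analyses of a small
resequencing panel — a dozen diploid birds, historical and contemporary,
mapped against a de novo assembly — together with a coalescent simulator
that generates every input the analyses consume. This vignette explains
the models, the parameters that matter, and the design decisions taken
where more than one reasonable construction existed.

## The coalescent simulator

Each locus is an independent, non-recombining realization of Hudson's
coalescent. Time runs backwards in units of 2N generations, so a pair of
lineages in a constant-size population coalesces at rate 1. Three
demographies are supported:

* **constant** — waiting time between coalescences while k lineages
  remain is exponential with rate k(k−1)/2;
* **exponential growth** at rate β (per coalescent unit): the population
  shrinks backwards in time, so the pairwise rate at time t is
  `exp(βt)`; waiting times are drawn by inverting the cumulative hazard
  in closed form;
* **two demes** of equal size with no migration, merging into one
  ancestral population at `split_depth`; lineages cannot coalesce across
  demes before the merger. Samples are split evenly, and
  `haplotypes_to_genotypes()` labels the demes "historical" and
  "contemporary" so the structure analyses can be scored against truth.

Mutations are Poisson with mean θ/2 × total branch length and fall on
branches proportionally to length, each creating a new biallelic column
(infinite sites). θ follows the ms convention: for k sequences,
`E[S] = θ a_{k−1}` and the expected average pairwise difference is θ.
Integer positions are drawn uniformly without replacement from
`1:locus_length`, which is the infinite-sites assumption expressed in
VCF coordinates; a locus whose S exceeded `locus_length` would error
rather than silently recycle positions.

The test suite checks the simulator against closed forms (E[T₂] = 1,
Watterson's E[S], E[π] = θ) and against an independent coalescent
simulator via a two-sample chi-square on folded spectra. For the
chi-square to be valid the compared counts must be near-independent, so
that comparison uses a small per-locus θ (≤ ~1 segregating site per
genealogy); with many sites per tree the shared genealogy inflates class
variance and the test would reject two perfectly matched simulators.

Per-variant depths are negative-binomial (mean 22.7×, size 5 by
default — the mean matching the sequencing regime the package targets)
contaminated with a 2% Pareto-tailed outlier mixture (scale ×5, shape
1.5). The mixture is what makes a percentile depth ceiling meaningful:
the median stays near the mean while the right tail runs an order of
magnitude higher, as collapsed repeats do in real data.

### What the generator does not emulate

Reads, mapping and genotype likelihoods are not simulated: genotypes are
exact, so filtering behaviour under genotyping error is untested here.
Z-chromosome loci are simulated as diploid in all samples (no
hemizygosity; the data regime being emulated does not state its Z
handling, and the partition machinery is what is under test).
Within-locus recombination and selection are out of scope. Passing
tests therefore demonstrate correctness of the estimators and procedures
given clean genotypes, not robustness to calling artefacts.

## Depth filtering

A variant is retained iff `min_dp ≤ DP ≤ Q`, with Q the **nearest-rank
(type-1, inverse-ECDF)** quantile of the per-variant DP distribution at
`ceiling_quantile` (default 0.90). Decisions taken:

* the interval is **closed at both ends** — the bracketed-interval
  reading of the retention rule rather than the strict-inequality
  reading of the prose describing it;
* Q is computed **once on the pre-filter distribution**, not iterated;
* nearest-rank is used because it returns an observed integer depth and
  is exactly reproducible; the suite pins it to a sorting oracle;
* DP comes from INFO/DP when every record has it, otherwise from summed
  FORMAT/DP; the choice is recorded in the filter report.

## Diversity statistics

For a partition with callable length L and a sample subset with m_v
non-missing allele copies at variant v (j_v of them alternate):

* `S` counts variants carrying both alleles among non-missing genotypes;
* `s = S/L`;
* `π = Σ_v 2 j_v (m_v − j_v) / (m_v (m_v − 1)) / L` — the mean pairwise
  difference over allele copies, with missingness reducing m_v locally
  (pairwise-complete) rather than dropping the site;
* `Θ_W = S / (a_{n−1} L)`. For nuclear genotypes n is the **haplotype
  count** 2 × (diploids in the group); for mitochondrial alignments n is
  the **number of individuals**. This convention reproduces the package's
  worked mitochondrial values exactly (0.00172 / 0.00126 / 0.00117 for
  S = 87, 44, 48 with n = 12, 5, 7 on L = 16,769 bp).

`effective_length` is a user input: variant data alone cannot tell
callable from uncallable sequence, so per-site normalization is only as
good as the L supplied.

## The folded SFS and its flattening transform

With n diploids (2n copies), `η_i` counts sites at minor-allele copy
number i ∈ 1..n; a site at exactly 50% frequency belongs to class n.
Sites with any missing genotype in the subset are skipped and counted,
not projected — hypergeometric projection is deliberately out of scope.

The transform weights are `w_i = i(2n−i)/(2n)` for i < n and `w_n = n`,
followed by renormalization to proportions. Under the standard neutral
coalescent `E[η_i] = θ(1/i + 1/(2n−i))` for i < n and `E[η_n] = θ/n`, so
every weighted class has expectation θ and the transformed spectrum is
flat at `1/n` — for the 11-diploid default, 1/11. This weight set is the
unique reading of the flattening construction consistent with that flat
line; growth demographies push ϕ₁ above it, the classic
excess-of-singletons signature of expansion. The 11-diploid default
(11 classes) is a parameter, not a constraint.

## Mitogenome statistics

Alignments are character matrices; masking removes the union of 1-based
inclusive column ranges (the package's fixture mirrors a 17,320-column
alignment with three repeat regions of 12 + 37 + 502 = 551 columns,
leaving 16,769). Columns containing a gap or IUPAC ambiguity in any
sequence are excluded from S and π (complete deletion; a heteroplasmic R
is ambiguity); p-distance uses pairwise-complete columns instead, so π
equals mean p-distance exactly only on gap-free alignments. Per-site
normalization uses the post-mask length. `Hd = n(1 − Σ p_k²)/(n − 1)`.

## Synteny assignment

Filters are **strict** (identity > 70%, reference-side length > 500 bp
for the distant preset; > 80% / > 10 kb for the close preset), while the
link-count retention is **inclusive** (≥ 500). "Unique links" are
deduplicated filtered blocks keyed by both interval pairs — one ribbon
per alignment. Overlap is measured as alignment length on the
reference, because renaming is reference-anchored. Ties in overlap break
by link count, then lexicographic reference label, making assignment
deterministic and row-order invariant; fission collisions (several query
chromosomes assigned one reference chromosome) get suffixes a, b, … by
descending overlap. Links are counted post-filter, pre-retention, per
(query, reference) pair. Segment ordering sorts query chromosomes by
(assigned reference chromosome, median reference midpoint of their
blocks).

## Structure

PCA centers each site at 2p̂ and scales by `sqrt(2p̂(1−p̂))`; monomorphic
sites and sites with > 20% missingness are dropped, and remaining
missing genotypes are **mean-imputed for PCA only** — the
identity-by-state dissimilarity uses pairwise-complete sites instead, so
a sparse pair degrades gracefully rather than silently shrinking toward
the mean. Clustering is average-linkage (UPGMA) on
`d = 1 − mean(1 − |g_a − g_b|/2)` with a fixed-height cut; the
dendrogram is exported as newick with merge heights as branch lengths.
In the recovery tests the cut is placed at the midpoint of the two
largest merge heights — the dendrogram's own gap — because a fixed
absolute height is only meaningful for a particular dataset's
dissimilarity scale.

## Numerical and degenerate-input choices

* Zero segregating sites: diversity statistics are 0, the VCF writer
  emits a header-only file, and the SFS transform errors (there is no
  spectrum to normalize).
* `Σ ϕ = 1` is exact to floating tolerance; scaling all η by a constant
  leaves ϕ unchanged.
* Seeds: all generators consume R's RNG only, so a single `set.seed()`
  makes any simulation byte-reproducible; `simulate_haplotypes()` and
  the pipeline take explicit seeds.
* Problem sizes in the test suite — 2,000 loci for spectrum flatness and
  estimator recovery (batched 20 × 100 for Monte-Carlo standard errors),
  10⁵ depths for the filter oracle, 600 blocks per synteny segment, 20
  seeds for structure recovery — were chosen so that three-standard-error
  bands are tight enough to detect real defects while each block runs in
  seconds.

## Known limitations

The simulator's clean genotypes overstate real-data performance of the
filtering stage; the SFS module offers no projection for missing data;
the synteny module assigns whole query chromosomes, so a genuinely
chimeric scaffold is forced to its majority reference chromosome; and
the pipeline's per-site normalization trusts the declared callable
lengths.
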