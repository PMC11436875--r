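---
title: "Methods: cell type-aware non-coding variant nomination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell type-aware non-coding variant nomination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncmendel)
```

## The nomination model

`ncmendel` treats non-coding variant prioritization for Mendelian cohorts
as the intersection of three independent filters, each of which discards
the overwhelming majority of a genome's variation:

* **Rarity and quality.** A causal Mendelian allele should be (nearly)
  absent from population panels. The hard filters require gnomAD *and*
  TOPMed allele frequency below `1e-3` for monoallelic (de novo/dominant)
  searches or `1e-2` for biallelic (recessive) searches, GERP > 2,
  a passing VCF FILTER, and — for every genotype an inheritance decision
  consumes — GQ > 20 with heterozygous allele balance
  `alt/(ref+alt) > 0.15`. A population AF missing from both panels is
  treated as 0: absence from the panels is itself evidence of rarity. An
  optional symmetric allele-balance check `min(AB, 1−AB) > 0.15` guards
  against reference-skewed calls.
* **Segregation.** Five per-family searches (de novo; dominant; dominant
  with incomplete penetrance; homozygous recessive; compound heterozygous)
  plus cohort-level exclusion. The de novo caller is a genotype-rule
  caller with quality gates (child het, both parents hom-ref, all three
  passing) rather than a likelihood model; this is deliberate — on
  high-coverage joint calls with the GQ/AB gates the rule table is nearly
  equivalent, and it is exactly testable against an exhaustive oracle.
  For compound hets the accessible-chromatin peak is the unit of
  heredity: the pair must lie in one disease-relevant peak, one member
  transmitted by each unaffected parent. Parental origin is inferred from
  trio genotypes when phasing is absent; sites where both parents carry
  the allele are skipped with a warning rather than guessed. Both pair
  members are gated at the biallelic AF class, the natural choice since
  the configuration is biallelic in trans.
* **Cell type.** Each disease group maps to the cranial motor neuron
  population(s) that degenerate or miswire in that phenotype; variants
  must fall in the merged accessibility peak set of those cell types.
  Overlap semantics differ by variant class: point containment for
  SNVs/indels (indels by their anchor position; a span rule is a config
  option), any-overlap for SV spans with a cohort AF < 0.005 gate, and
  ±15 bp padded insertion-point overlap for TEs with AF gates of 0.01
  (inherited) and 0 (de novo) plus a high-confidence call-label filter.

Aggregation then looks for recurrence: **multi-hit peaks** hold candidates
from ≥ 2 families under one broad mode (dominant vs recessive), after
excluding SVs > 100 kb, and **multi-hit genes** have ≥ 2 distinct linked
peaks each carrying a dominant-broad candidate.

### Coordinates

Intervals are BED-style 0-based half-open throughout; variant positions
are VCF 1-based. The conversion lives in exactly one place
(`overlap_variants()`), because silent off-by-one mixing of the two
conventions is the classic failure mode of this kind of pipeline. Merging
combines overlapping *and* book-ended intervals (`bedtools merge -d 0`
semantics), verified against `bedtools` itself in the test suite. Whether
a variant at the exact half-open right edge of a peak counts as inside is
resolved by the half-open rule: it does not.

## Supporting statistics

**Permutation enrichment.** The null randomizes *regions*, not variants: a
size-matched, mutually non-overlapping set of intervals is placed
uniformly on the unmasked genome (rejection sampling, longest-first,
chromosome chosen with probability proportional to its placeable slot
count; intervals may move across chromosomes — a per-chromosome
restriction is not imposed, matching the default behavior of
regioneR-style resampling). Enrichment is summarized as
`z = (obs − mean(null))/sd(null)` and the add-one empirical p-value
`(1 + #{null ≥ obs})/(1 + N)`, which can never be 0 and bottoms out at
`1/(N+1)` — `2.0e-4` at the default `N = 5000`. For near-saturated
genomes, longest-first rejection sampling is slightly non-uniform over
joint placements; at the densities used here (peaks cover ≪ 1% of the
assembly) the bias is negligible, and the chi-square uniformity test in
the suite confirms marginal uniformity. Individuals with > 75 filtered de
novo calls are dropped before testing as genotyping-noise outliers.

**Peak-to-gene links.** Cells are summed into `k = 100` metacell
aggregates before correlating (per-cell counts are too sparse for stable
Pearson estimates; aggregation trades resolution for variance). For every
(peak, gene) pair with peak midpoint within ±500 kb of the TSS
(strand-aware TSS; midpoint chosen as the peak's single representative
coordinate), the Pearson correlation across aggregates is tested via the
t-transform with `n − 2` degrees of freedom, and BH FDR is computed over
*all* pairs tested in the run (a global family; a per-gene family is the
other defensible reading and is not used). Retention is one-sided
(`r ≥ 0.1`, inclusive boundary by default and configurable, since both
readings of the threshold appear plausible) at `FDR < 1e-4`. Per-gene
link tabulation restricts to ±50 kb and assigns each peak to a single
gene: lowest FDR, ties broken by larger |r|, then lexicographic gene id —
the two tie-breaks are this package's own determinism choices. DORC
scores are `Σ count(cell, linked peak)/fragments(cell)`, exactly invariant
to per-cell depth rescaling.

**Cluster metrics.** Homogeneity, completeness, V-measure and per-cluster
purity are computed from the class × cluster contingency table with
natural-log entropies (`0·log 0 := 0`; h, c, V are entropy *ratios* and
hence base-invariant, but the raw entropies returned are in nats). The
degenerate branches are explicit: `h = 1` when `H(C|K) = 0` (including
single-class data), symmetrically for `c`. Purity's denominator is read
as the cluster's size `Σ_c a_ck` — the only reading bounded in
`[1/|C|, 1]`.

**Exact binomial test.** The two-sided p-value sums the null pmf over all
outcomes no more likely than the observed count. Floating-point ties at
the observed pmf are compared with a relative tolerance of `1e-7`, which
stabilizes the `≤` comparison when `n` is large and pmf values are
denormal-close. The confidence interval is exact Clopper–Pearson via beta
quantiles (Wilson available as an option); at `k = 120, n = 149` it
reproduces the two-decimal interval `[0.73, 0.87]` around the estimate
0.81. Replicates are pooled by summing counts; per-replicate p-values are
reported alongside.

**SAD Z-scores.** Raw predicted accessibility differences (summed over a
131,072 bp window about each variant, supplied externally as a TSV
contract — the predictor itself is out of scope) are standardized against
the SNV score distribution; indels are scored against the same SNV null
because indel raw scores are too few to define their own. |Z| > 2 is
flagged. The transform is exactly location/scale invariant.

## What the synthetic cohort emulates — and what it does not

The generator (`sim_config()` defaults) defines the study conditions:

* **Assembly**: 3 chromosomes × 10 Mb with the leading 10% of each
  chromosome masked. Real assemblies are never required; every coordinate
  consumer is exercised identically at this scale.
* **Cohort**: one family per (7 disease groups × 4 subgroups) = 28
  families; sporadic subgroups are trios, familial subgroups add an
  unaffected sibling and (for dominant plants) an affected parent. One
  candidate is planted per family, cycling through
  de novo/recessive/compound-het for sporadic and dominant/recessive for
  familial subgroups, so every search is exercised in every run.
* **Allele frequencies**: a mixture of a point mass at 0 (private, 30%),
  a log-uniform rare component on `[1e-4, 10^-1.5]` (50%) and a common
  component on `[0.05, 0.5]` (20%), so that the filter thresholds
  (1e-3, 5e-3, 1e-2) fall inside the spectrum and both sides of each gate
  are populated.
* **Genotypes**: founders are Hardy–Weinberg draws at the variant's
  cohort AF, children receive one allele per parent, and a per-genotype
  error rate (default 0.002, a free parameter — the real cohort's error
  model is not published) replaces calls with a random other code.
  Planted genotypes are written with deep balanced depths (GQ 60, AD
  20/20) so quality gates pass by construction.
* **Background variants** each violate at least one hard filter (low
  GERP, non-PASS FILTER, or AF ≥ 1e-2 — violations that block both AF
  classes). This makes noise-free precision/recall exactly 1 a designed
  property of the generator, which is what the planted-recovery tests
  assert.
* **Cell matrices**: negative-binomial counts (size 10, base mean 20)
  through a Gaussian copula with a lognormal per-cell depth factor
  (sdlog 0.1). Planted (peak, gene) pairs share a latent normal with the
  target correlation; copula + NB discretization attenuates the realized
  count correlation by a few percent at these means, comfortably inside
  the ±0.15 acceptance band at n ≥ 500 cells. The depth factor is kept
  small because shared depth induces spurious positive correlation among
  *all* pairs; at sdlog 0.1 the induced null correlation is ≈ 0.06,
  below the 0.1 null bound tested.

Not emulated: linkage disequilibrium, sequence content, mapping artifacts,
real peak width/GC distributions, population structure, and the CNN
predictor. Passing tests therefore demonstrate the correctness of the
*computational* pipeline on inputs with known truth, not the empirical
yield of the framework on real cohorts.

## Problem sizes and numerical choices

The test suite and acceptance script use desk-scale sizes chosen for
statistical adequacy: full pmf grids at `n ≤ 200` for the binomial
oracle, 10,000 null simulations for the type-I check, 1,000 random
pedigrees for the inheritance oracle, 50 synthetic cohorts for multi-hit
recovery, 50 null permutation runs (99 iterations each) for calibration
plus one 5,000-iteration run for the p-floor, and 1,000-cell matrices
with 100 metacells for link recovery. Ties, degenerate inputs and
zero-variance features are handled explicitly where each statistic is
defined: empty clusters are an error for purity, zero-variance features
are skipped (not errored) in link testing, `sd(null) = 0` yields a
missing z with a still-valid empirical p, and an all-zero 2×2 margin is
an error for the Fisher test while zero cells follow ordinary arithmetic
(0, ∞, or NaN odds ratios).

## Known limitations

* De novo calling ignores genotype likelihoods; borderline sites that a
  likelihood caller would rescue or reject at the same GQ are decided by
  the hard gates alone.
* X-linked and mitochondrial inheritance are not modeled.
* The incomplete-penetrance search is a per-family flag, not an inferred
  property.
* "Clear coding etiology" SV exclusion is operationalized as exon overlap
  in the gene model (config-overridable), a proxy for expert curation.
* The permutation null is not GC- or feature-matched; it answers "are
  candidates enriched in these peaks relative to placeable genome", not
  "relative to matched control elements".
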