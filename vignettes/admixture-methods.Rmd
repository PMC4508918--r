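---
title: "Methods: three-way admixture analysis and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-way admixture analysis and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(admixscan)
```

This vignette documents the models behind `admixscan`, the assumptions
they make, the parameters that matter, and the design decisions taken
where the design was genuinely open. The package analyses three-way
admixed cohorts (African, Native American, European — `AFR`/`NAM`/`EUR`
internally; reference-panel labels such as YRI/CHB/CEU are translated at
the file boundary) from two inputs: per-haplotype local-ancestry segment
calls and SNP genotypes.

## Coordinates and formats

All coordinates are 0-based half-open (BED convention). VCF `POS` and
IRanges are converted at a single boundary (`bed0_to_pos1()` /
`pos1_to_bed0()`). Segment files are six-column TSVs (individual,
haplotype 0/1, chrom, start, end, ancestry); coverage gaps are legal and
propagate into per-locus denominators, but overlapping segments on one
haplotype are rejected. Missing local-ancestry coverage is never
imputed: a haplotype without a call at a locus simply does not count
there.

## Global ancestry

**Tract aggregation.** `fractions_from_tracts()` computes per-ancestry
fractions as covered length with that ancestry over total covered
length, separately for autosomes, the X and their union. A male X
contributes one haplotype. Compartments with no coverage are absent
rather than zero-filled, so downstream pooling never divides by zero
silently.

**Allele-sharing distances and PCA.** The distance between two genomes
is the mean of `|g_i - g_j| / 2` over SNPs non-missing in both — the
fraction of allelic differences on the dosage scale, so a heterozygote
against a homozygote contributes 1/2. An alternative convention
(exact-genotype mismatch) weights heterozygous disagreements more; the
dosage scale is the standard allele-sharing behaviour and is what the
PCA consumes. The PCA centers and unit-scales the columns of the
distance matrix before decomposition (zero-variance columns are centered
only), mirroring a scaled `prcomp` of the matrix. Allele-sharing
distances are not guaranteed metric (the triangle inequality is not
asserted anywhere).

**Supervised EM.** Ancestry proportions are estimated per individual by
maximising the binomial likelihood of dosages under mixture frequencies
`mu_j = sum_k q_k f_kj`, with the reference frequencies fixed — a
deliberate substitution for unsupervised k = 3 estimation, which needs
hundreds of reference genomes and a relaxation scheme and is out of
scope. The EM update is the classical expected-ancestry-of-allele-copies
step followed by renormalisation; the log-likelihood is non-decreasing
(asserted in tests). Choices that matter:

* initialisation at (1/3, 1/3, 1/3), making runs deterministic; with
  identical frequencies across populations the likelihood is flat and
  the estimate stays at the initialisation (documented degenerate
  behaviour);
* reference frequencies clipped to `[1e-6, 1 - 1e-6]` so fixed alleles
  cannot produce infinite log-likelihoods;
* convergence on the log-likelihood increment with `tol = 1e-8`. The
  likelihood can be extremely flat along one simplex direction when two
  reference populations are similar, and a looser tolerance stops
  measurably short of the maximiser; at `1e-8` the estimates match an
  independent direct optimiser to ~1e-3;
* male X dosages enter with ploidy 1 (hemizygous binomial), which is the
  correct likelihood rather than an approximation.

## Sex-specific admixture asymmetry

For each ancestry, `delta_admix()` computes
`(F_X - F_auto) / F_total`. X chromosomes spend two thirds of their
transmission history in females, so a positive value indicates a
maternal excess of that ancestry, a negative value a paternal excess.
Cohort-level ratios pool individuals by length-weighted means *before*
taking the ratio; the mean of per-individual ratios is unstable whenever
an ancestry is nearly absent in some individuals (its `F_total`
denominator approaches zero), which is exactly the regime of minor
ancestries in admixed cohorts.

Uncertainty comes from a percentile bootstrap over individuals (default
1000 replicates, 95% interval); BCa corrections are a possible extension
but the percentile interval is the plain reading of the procedure this
package implements. Replicates in which the ancestry vanishes entirely
are redrawn (counted, capped at ten times the replicate budget). The
two-sided bootstrap tests — between two cohorts, or against zero — use
the `(k + 1) / (n_boot + 1)` small-sample correction, so reported
P-values are never below `2 / (n_boot + 1)`; with 1000 replicates the
floor is ~0.002, and far smaller published P-values for such contrasts
cannot come from a percentile bootstrap of this size. Each cohort's
resampling stream is seeded from its own (sorted) individual ids, making
the comparison invariant to argument order.

## The enrichment scan

At each locus window the cohort's chromosomes are counted by the
ancestry of the segment covering the window midpoint (half-open
containment makes a boundary exactly at the midpoint deterministic).
Midpoint assignment is exact when windows derive from the same
segmentation as the calls, and well-defined otherwise. Expected
proportions are recomputed by pooling the same counts being scanned —
internal consistency under one caller — rather than taken from
genotype-based estimates.

Two scores are reported side by side:

* `pmf` — the trinomial point probability itself, the headline score
  with its conventional threshold `alpha_p = 1e-9`. A point probability
  is not a calibrated P-value: its null distribution depends on `n`.
* `exact_tail` — the exact multinomial test with point-probability
  ordering: the sum of probabilities of all outcomes no more probable
  than the observed one. This is calibrated (conservatively, because the
  statistic is discrete) and is the score to use for inference.

Numerical choices: all pmf evaluation is in log space via `lgamma`;
`0 * log(0)` is taken as 0 so impossible categories give exactly 0; the
tail enumeration over the `(n+1)(n+2)/2` compositions treats log-pmf
values within `1e-9` as ties so that symmetric outcomes are included
with their partners; per-locus `n` may vary (missing calls), and the
enumeration is cached per distinct `n`. Loci with `n = 0` are excluded
from the Benjamini–Hochberg denominator and logged. BH is the step-up
rule implemented directly and cross-checked against `stats::p.adjust`
in the tests. Log-fold enrichments are `log2(x_k / (n p_k))`, with
`-Inf` for absent ancestries (floor it only for plotting). Adjacent
significant loci with the same enriched ancestry merge into segments
carrying the minimum score; gene annotation is half-open overlap of at
least one base. The default scan covers autosomes; X scanning is
available with the mixed-ploidy denominator (`2 n_females + n_males`)
but is kept opt-in because enrichment conventions for X loci (and
whether published locus totals include X) are not settled.

## The cohort simulator

The simulator provides ground truth for every stage. It emulates:

* **Founding.** Generation-0 founders are unadmixed per haplotype: each
  founder haplotype draws one ancestry from the founder proportions of
  the founder's sex and carries it across all chromosomes (a haplotype
  descends from one population). Drawing per haplotype rather than per
  individual guarantees all three ancestries are present even in small
  cohorts; drawing genome-wide rather than per chromosome is the
  realistic choice and makes X and autosomal founder noise cancel in the
  difference statistic.
* **Mating.** Random mating without selfing, non-overlapping
  generations, constant population size. The default depth G = 6 is a
  free parameter, not an inference target: real Latin American admixture
  is older, but tract-length decay is already realistic at G = 6 and the
  statistics under study depend on founding proportions, not G, in
  expectation.
* **Recombination.** Crossovers per meiosis are Poisson with mean
  `recomb_rate * length / 1e8` and uniform breakpoints (no hotspot map —
  the scan operates on windows, not hotspot structure). The default 1.2
  crossovers per 100 Mb approximates the human sex-averaged map. Males
  pass their single X intact to daughters and no X to sons; male X
  hemizygosity is represented as a single haplotype, so X locus counts
  are naturally `2 n_females + n_males`.
* **Genotypes.** Ancestral allele frequencies follow Balding–Nichols:
  base frequency uniform on (0.05, 0.95), population frequencies
  `Beta(p(1-F)/F, (1-p)(1-F)/F)` with default divergence F = 0.15, which
  yields mean pairwise frequency differences around 0.19 — enough for
  informative supervised estimation, comparable to continental-scale
  divergence. Haplotype alleles are Bernoulli draws conditional on the
  covering tract's ancestry; males are haploid on X.
* **Defaults as study conditions.** 60 diploid individuals, sex ratio
  1/2, founder proportions male (0.073, 0, 0.927) and female
  (0.073, 0.362, 0.565): the sex average equals the cohort-average
  ancestry of the admixed Colombian genomes this design emulates
  (7.3 / 18.1 / 74.6 %), with the maximal Native-American-maternal /
  European-paternal bias compatible with that average — historically
  defensible, since Native-American paternal founding lineages were
  essentially absent while African founding occurred on both sides. The
  genome is 22 hg19-like autosomes plus X (megabase-rounded lengths).

One master seed drives named, order-stable substreams
(`substream_seed()`), so a fixed configuration reproduces every output
file byte-for-byte.

**What the simulator does not emulate** — and hence what passing tests
do not show about real data: no linkage disequilibrium within ancestral
populations (SNPs are independent given local ancestry), no genotyping
error or missingness, no local-ancestry caller error (segments are true
tracts, whereas SupportMix-style callers smooth and miscall near
breakpoints), no selection, no mutation, no population growth or
continuous migration. Enrichment signals in simulated cohorts arise from
drift, not selection; the scan's power against *injected* composition
shifts is therefore assessed at the count level.

## Problem sizes and statistical design of the checks

The test-suite experiments are sized for a single CPU (minutes, not
hours), and several sizes are themselves statistical choices:

* Founding-proportion recovery uses cohort-mean fractions averaged over
  replicate cohorts (40 for the 0.02-band unbiasedness check, 20 for the
  0.03-band recovery check). A single cohort cannot be tested at this
  tolerance: founder-haplotype sampling alone gives the cohort mean a
  standard deviation near 0.04 at n = 60, an order set by 2n genome-wide
  founder labels, not by the genome length.
* The sign-direction experiment for ΔAdmix runs at n = 100, G = 3 with
  stronger-than-default bias (male NAM = 0, female NAM = 0.65). At
  n = 60, G = 6 the X chromosome — a single linkage unit with ~90 copies
  — accumulates enough lineage drift that even the true direction shows
  per-replicate sign errors at the ~15% level; no founder configuration
  at that size makes a 19/20 sign criterion attainable. The shallower,
  larger configuration keeps the biological signature while containing
  X drift.
* Bootstrap coverage is evaluated at G = 1, where individuals are
  nearly independent draws from the founding model. In deeper pedigrees
  individuals share lineage drift that resampling individuals cannot
  see, so the percentile interval progressively under-covers the
  founding-model parameter; the interval is then best read as describing
  the realized cohort, not the superpopulation.

## Known limitations

* The trinomial point probability (`pmf`) threshold `1e-9` is a
  convention, not a calibrated significance level; use `exact_tail` with
  BH q-values for inference.
* The exact-tail test at n = 120 chromosomes has modest power against
  moderate composition shifts: enumeration shows a two-fold excess of a
  7% ancestry reaches genome-wide BH significance only rarely. Larger
  cohorts or aggregation across adjacent loci are needed for such
  effect sizes; single-locus significance at n = 120 requires much
  stronger departures.
* Because the X is one chromosome, ΔAdmix confidence intervals in
  replicate simulated cohorts occasionally touch zero even under strong
  founding bias; direction is far more stable than interval exclusion.
* The bootstrap P-value floor (`2 / (n_boot + 1)`) bounds how small a
  reported comparison P can be.
* `read_genotypes_vcf()` records a fully missing call with ploidy 2
  (the true ploidy of a missing haploid call is unknowable from `.`),
  which only affects bookkeeping, never dosages.
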