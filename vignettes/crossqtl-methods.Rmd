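---
title: "Methods: nonparametric QTL mapping and variance decomposition in a haploid yeast cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonparametric QTL mapping and variance decomposition in a haploid yeast cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossqtl)
```

## The mapping problem

crossqtl implements the analysis chain for a cross between two haploid
*Saccharomyces cerevisiae* parents (referred to throughout as P1 and P2)
whose recombinant progeny are genotyped by sparse sequencing — read counts
for the two parental bases at a panel of SNP markers — and phenotyped by
colony patch area (mm²) on a set of solid media. The pipeline stages are:

1. **Parental SNP table.** At each genomic position, a parent's base is
   *confident* when its most frequent observed base is at least 5× more
   frequent than the runner-up (a runner-up count of zero is always
   confident when any reads are present). Positions where both parents are
   confident and differ define the marker universe. Indel positions are
   assumed excluded upstream.
2. **Progeny genotype calls.** At each marker a strain is assigned the
   parent whose base dominates its reads by the same 5× rule; anything
   less decisive is missing. The 5× rule makes single stray reads (PCR or
   sequencing error, index hopping) unable to flip a call while keeping
   modest-depth markers callable.
3. **Quality filters.** Markers are dropped when they have reads in <5% of
   strains or when the P1:P2 call ratio is more than twofold from 1:1
   (segregation distortion or paralogous alignment). Strains are dropped
   for low marker coverage, double drug-marker resistance (diploids or
   contaminants), absence of growth on rich medium, or >90% genotype
   identity with an already-retained strain (cross-contamination or
   picking the same spore twice).
4. **Ploidy screen.** Relative chromosome copy number per strain from the
   proportion of aligned reads per chromosome, with classification of
   chromosome I disomes (this cross segregates an extra chromosome I).
5. **Genome scans.** Nonparametric single-locus scans with genome-wide
   permutation thresholds, and split-population secondary scans.
6. **Phenotype statistics.** Floor-aware quantile normalization,
   broad-sense heritability, per-locus genetic variance, interaction
   ANOVA, and euploid-vs-disome group tests.

## The scan statistic

Colony areas under strong stresses are heavily non-normal — typically
bimodal with a point mass of no-growth strains — so the scan is rank
based. At each marker the Kruskal–Wallis statistic *H* is computed on
midranks of the phenotype across the two genotype classes, with the
standard tie correction `1 − Σ(t³−t)/(N³−N)`, and mapped to the LOD scale
as

> LOD = *H* / (2 ln 10),

the usual correspondence for rank-based single-QTL scans (for two groups
*H* is the tie-corrected Wilcoxon rank-sum chi-square, which is twice the
natural-log likelihood ratio under the chi-square approximation). Strains
missing either the call or the phenotype are excluded per marker
(complete-case marker regression; no imputation and no conditioning on
neighboring markers). If a marker leaves one class empty its score is
reported as 0 and flagged.

Because ranks are sufficient, the LOD profile is invariant under any
strictly monotone transform of the phenotype — the property suite checks
this explicitly.

**Significance.** Genome-wide thresholds come from permutation: the
phenotype vector is shuffled across strains while genotype rows stay
intact, preserving the inter-marker correlation structure; the genome-wide
maximum LOD is recorded per permutation and the threshold is the
`⌈(1−α)·n_perm⌉`-th order statistic (a conservative empirical quantile).
Defaults are `n_perm = 10000, α = 0.01` for primary scans and
`n_perm = 1000` with a Bonferroni-adjusted level `α/n_tests` (default
`n_tests = 12`, e.g. 6 conditions × 2 subsets) for split scans. The
permutation inner loop is compiled (Rcpp): ranks are reduced to dense
integer keys once, and each marker×permutation evaluation is a counting
pass over those keys, so no per-permutation sorting is needed. 10,000
permutations on a 412-strain × 537-marker table take on the order of a
minute on one core.

**Split scans.** A major-effect locus can mask weaker QTL in a rank-based
scan. The population is split by the allele at the primary peak (missing
calls ignored), and each subset is scanned with its own permutation
threshold. Within a subset the major locus is (nearly) fixed, so residual
association can surface.

## Phenotype statistics

**Floor-aware quantile normalization.** Under strong stresses each allele
subpopulation approximates a normal distribution with a floor: a
detection/growth limit producing a point mass of minimal areas. Plotting
positions `q = (rank − 0.5)/n` (midranks for ties) are assigned over the
whole subpopulation; the observed areas above the separation cutoff
(default 5 mm²) are regressed on `Φ⁻¹(q)`, giving the latent normal's
mean (intercept) and SD (slope); every value is then replaced by
`μ̂ + σ̂·Φ⁻¹(q)`. Rank order is preserved exactly, and floored strains
receive imputed values from the fitted tail. We replace *all* values, not
only the floored ones — this yields a coherent normal sample for the
downstream variance decomposition, and above the floor the replacement is
numerically close to the observed values anyway (the two behaviors differ
only in that residual, and the replace-all choice makes σ²ₙₛ exactly
interpretable under the fitted model).

**Broad-sense heritability.** `H² = 1 − σ²ₑ/σ²ₛ`, with σ²ₛ the variance
of the population of segregant means and σ²ₑ = σ²_w / n̄ the sampling
variance of those means. σ²_w is the pooled within-segregant variance
from a one-way random-intercept model fitted by REML (`lme4::lmer`),
using only measurements > 5 mm² from segregants with ≥ 2 such
measurements — replicate scatter at the growth floor reflects the
detection limit, not biology. A method-of-moments pooled-variance
alternative (`method = "moments"`) is provided; on balanced designs the
two agree to numerical precision. σ²ₛ is always taken over the full
population of per-strain means (normalized means for the censored
conditions), so that it is commensurable with the centered-subpopulation
variance below; applying the replicate filter to σ²ₛ as well would trim
exactly the floored strains whose variance the locus explains, and the
decomposition would no longer add up.

**Per-locus genetic variance.** The two allele subpopulations at a locus
are centered to zero mean; the variance σ²ₙₛ of the pooled centered means
is what the locus does *not* explain, so the locus accounts for
σ²ₛ − σ²ₙₛ (the conservation identity `explained + σ²ₙₛ = σ²ₛ` holds
exactly by construction). The *proportion of genetic variance explained*
divides by the genetic variance H²·σ²ₛ. Under a null locus the explained
variance can be slightly negative by sampling noise; it is reported
unclamped with a warning rather than truncated, so that averages over
replicate analyses stay unbiased. Residual genetic variance is
σ²ₙₛ − σ²ₑ.

**Interaction ANOVA.** Whether a medium additive changes the major-locus
effect beyond its rich-medium effect is tested by a two-way fixed-effects
ANOVA with interaction (allele × additive presence) on patch areas,
using Type II sums of squares (`car::Anova`). The designs here are nearly
balanced, so the SS convention is almost immaterial; Type II is the
conventional choice when the interaction is the term under test.

**Group tests.** Euploid vs chromosome I disome comparisons use the
Mann–Whitney U test with midranks: exact enumeration when both groups
have < 8 untied observations, otherwise the tie-corrected normal
approximation without continuity correction. The raw difference of group
means (mm²) is reported alongside; Bonferroni correction across
conditions is left to the caller, since the condition count is a property
of the experiment.

## The ploidy screen

For each strain, the proportion of aligned reads per chromosome is
normalized by the cross-strain median proportion for that chromosome
(valid because most strains are euploid everywhere). Chromosome I is the
exception: when a disome segregates ~1:1 the median is not a haploid
reference, so chromosome I is normalized by the cross-strain *mean*
proportion divided by 1.5 (the population mean under 1:1 segregation is
1.5× the haploid value). Each strain is finally rescaled so its median
copy number is exactly 1. Chromosome I classes: disome for values in
[1.5, 2.5], euploid for [0.5, 1.5), unresolved outside [0.5, 2.5]
(treated as sequencing artifacts). The interval endpoints overlap in
words ("between 1.5 and 2.5", "between 0.5 and 1.5"); we resolve 1.5 in
favor of disome, making the classification a monotone step function of
the copy-number estimate.

A caveat of the mean/1.5 convention: it presumes the disome actually
segregates near 1:1. In a population with *no* disomes the chromosome I
estimate would sit near 1.5 and the screen would misread it; the
convention is part of this cross's design, not a general-purpose CNV
caller.

## The synthetic cross generator

Every stage is validated against simulated crosses with known ground
truth. The generator's defaults describe the mapping population this
pipeline targets; they are fixed study conditions, not tuning knobs.

* **Genome and map.** 16 chromosomes with physical lengths close to the
  reference assembly and genetic lengths from a uniform ≈0.365 cM/kb
  (≈4,400 cM genome-wide — the conventional scale for yeast; the true map
  of this cross is unknown). ~537 markers are placed evenly per
  chromosome, allocated proportionally to physical length.
* **Meiosis.** Haldane model: crossovers are a Poisson process on the
  genetic map, so the genotype process switches parent between adjacent
  markers with probability `r(d) = (1 − e^{−2d/100})/2` at distance `d` cM.
  Individual spores are simulated, not tetrads: marker-level mapping sees
  only marginal segregation, for which spore-level simulation is
  sufficient. Chromosome I disomy is an independent Bernoulli per progeny
  (default 0.5); the extra copy is by default a non-recombinant P1
  chromosome, making disomes heterozygous wherever the resident copy is
  P2 (`disome_het = FALSE` duplicates the strain's own copy instead).
* **Sequencing.** Depth per strain×marker is negative binomial with mean
  20 and dispersion 0.5 (variance `μ + 0.5μ²` — RAD-seq coverage is
  strongly overdispersed; dispersion 0 recovers Poisson). Reads report
  the wrong parental base with probability 0.002. Chromosome I depth
  doubles in disomes, with reads split between the two copies when
  heterozygous. Whole-genome per-chromosome read totals (the ploidy
  screen's input) are emitted separately with mild dispersion (5×10⁻⁴),
  reflecting that copy-number estimation integrates over far more
  positions than the marker panel.
* **Phenotypes.** Replicate area = `max(N(floor, floor_sd²),
  μ + N(0, noise_sd²))` with `floor = 2 mm²`, `floor_sd = 0.75` —
  censoring by a noisy detection floor rather than truncation, matching
  the observed point mass of no-growth strains. μ is the condition
  baseline plus allele-matched QTL effects plus any chromosome I disome
  effect. Four replicates per strain×condition.
* **Planted genetic architecture.** Seven conditions (YPD, copper,
  rapamycin, caffeine, sodium, ethanol, SD — labels only; media
  composition is metadata). Each condition carries a major-effect locus:
  chrXV:643,999 for the YPD-family conditions and SD (effects −9, −10.5,
  −18.7, −12.4, −17 mm² on the P1 allele), chrIV:527,628 for sodium
  (−14 mm² on P2), chrIX:409,532 for ethanol, plus a rapamycin-specific
  secondary locus on chrX. A shared panel of 12 minor loci (one per
  remaining chromosome, alternating signs) supplies polygenic background
  variance; its per-condition magnitude and the replicate noise SD were
  solved so that the planted broad-sense heritabilities (0.95 / 0.97 /
  0.99 / 0.99), major-locus variance proportions (0.23 / 0.26 / 0.51 /
  ~0.47) and subpopulation mean differences are realistic for this kind
  of cross, and so that the shared background induces the strong
  YPD–copper correlation (~0.95). Chromosome I disomes carry small
  condition-specific penalties (−2.54 mm² caffeine, −1.05 mm² ethanol).
* **Randomness.** One master seed; each stage (genotypes, allele counts,
  phenotypes, parent pileups, chromosome reads) draws from a
  deterministic substream derived from it, so regenerating one stage
  never perturbs another. Identical seeds give bit-identical output.

What the generator does **not** emulate: tetrad structure (2:2 within
tetrads), crossover interference, epistasis, GC/mappability bias in
coverage, sub-chromosomal CNVs, batch/plate effects, and any
sequence-level detail (no reads, no alignment). Passing tests on
synthetic data therefore demonstrate the correctness and calibration of
the *computations* under the stated generative assumptions, not the
biological fidelity of those assumptions to any particular cross.

## Numerical choices and edge cases

* Boundaries are inclusive where the verbal rules say "at least"/"more
  than": top ≥ 5×runner-up is confident; a call ratio of exactly 2:1 is
  retained (the rule drops markers deviating *more than* twofold); a
  strain covering exactly 749 of 750 required positions is dropped.
* The 750-position strain-coverage rule counts positions with *any*
  reads, before marker filtering (the marker filters themselves need a
  full strain set to be meaningful). When the marker panel is smaller
  than the full ~5,850-position candidate scale, the pipeline scales the
  threshold proportionally (e.g. 69 of 537).
* The marker coverage rule ("reads in <5% of strains") counts strains
  with any reads, not confident calls; when a genotype table arrives
  without read counts, presence of a call is the available proxy.
* Near-duplicate removal scans strains in lexicographic order and keeps
  the first of each pair — a deterministic tie-break; which member is
  dropped is not identifiable from the data.
* Peak ties in a scan resolve to the lowest chromosome (map order), then
  position. All-tied phenotypes give LOD 0 (the tie correction would
  otherwise divide by zero). Scans run at markers only (no pseudomarker
  grid): reported peaks are named marker coordinates.
* `quantile_normalize_floored` refuses subpopulations with fewer than 10
  values above the cutoff and fits with σ̂ ≤ 0 (degenerate).
* Genome coordinates are 1-based throughout, as in pileup convention.

## Problem sizes used in validation

The test suite and the acceptance script run entirely in synthetic mode.
Planted-effect recovery uses five independent default-size crosses (412
progeny, ~537 markers) with comparisons against planted values at
3-standard-error tolerances estimated from the cross replicates.
Threshold calibration uses 300–500 independent null datasets of 100
strains × 120 markers with 400 permutations each — a scale chosen to put
the Monte-Carlo error of the false-positive rate well inside the binomial
band being asserted. Exhaustive oracle checks (the 5× caller on all count
pairs with total ≤ 12; the rank-sum statistic over all group assignments
of small value multisets) are exact, not sampled.

## Known limitations

* Single-locus scans only: no interval mapping, no multi-QTL model, no
  epistasis scan. Split-population scanning is the only conditioning
  device, as in the original analysis design.
* The heritability decomposition assumes independent replicate errors
  within strains; plate effects would inflate H².
* The ploidy screen's chromosome I convention is specific to a ~1:1
  segregating disome (see above).
* Negative explained variance is possible (and expected) for null loci;
  consumers should treat small proportions as noise around zero.
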