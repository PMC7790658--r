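---
title: "Methods: diagnostic SNP panels, admixture footprints and a two-species climate model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic SNP panels, admixture footprints and a two-species climate model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridtrace)
```

## The problem

When one newt species historically replaces another, the retreating species
can survive in *enclaves* — isolated population pockets surrounded by the
range of the competitor — and the moving hybrid zone may leave a *genomic
footprint* of introgressed neutral alleles in the advancing species.
`hybridtrace` implements the full analysis chain used to detect such
signatures from panels of species-diagnostic SNPs: marker design from
exon catalogues, diagnosticity screening, within-population tests of
Hardy–Weinberg equilibrium and linkage disequilibrium, admixture-model
inference with model selection over the number of gene pools, genotype
ordination, and a climate-based two-species distribution model used to
hindcast the species border under past climates.

Because the original field genotypes are not shipped with the package,
every stage is driven by a synthetic-data module that generates datasets
with the statistical structure the analyses assume. The generators are
first-class, tested code: their planted truths are what the test suite
measures recovery against.

## Data model

A `genotype_matrix` stores per-individual allele *dosages*: the count of
the *T. marmoratus*-diagnostic (M) allele, 0/1/2 at diploid nuclear loci
and 0/1 at the haploid mitochondrial locus, with `NA` for missing calls.
Scoring dosage as M-allele count makes downstream quantities directly
interpretable: the admixture proportion `q` is the expected fraction of M
alleles, and PCA axis 1 separates the species. Ploidy travels with the
matrix as a per-locus flag, so diploid-only statistics (Hardy–Weinberg,
admixture LD) exclude the mtDNA marker automatically. In the genotype CSV
interchange format, which has no ploidy column, loci named with an `mt`
prefix are taken as haploid; the reader accepts an explicit override.

## Synthetic study conditions

The generator defaults mirror the study design the pipeline was built
for, and they are fixed rather than tunable knobs of convenience:

* **Panel** (`sim_panel_spec()`): 60 nuclear SNPs of which 54 are
  diagnostic (parental allele-frequency differential `delta = 1`, a fixed
  difference), plus one haploid mtDNA marker fixed between species;
  2.3% of calls missing at random. The six off-target loci get a small
  differential (`delta_offtarget = 0.2`), chosen once so that they remain
  polymorphic and species-informative but sit far below the κ ≥ 0.9
  screen even with reference panels of ~240 individuals (sampling noise
  on κ at that size is ≪ 0.7, the gap to the threshold).
* **Reference panels**: 118 M and 120 P pure individuals in two reference
  populations.
* **Landscape** (`sim_landscape_spec()`): ponds with coordinates, sample
  sizes and mean admixture `q̄` — typically one mostly-M enclave
  (`q̄ ≈ 0.93`) inside a pure-P landscape of ~25–30 ponds totalling ~354
  individuals. Individual `q` is Beta-distributed around the pond mean
  (concentration 100, i.e. sd ≈ 0.025 at `q̄ = 0.93`; means of exactly 0
  or 1 are exact). An optional introgression tail imposes
  `q(d) = q0·exp(−d/λ)` with distance `d` km from the enclave; no empirical
  scale for such a tail is available in this system, so `q0` and `λ`
  are illustrative inputs, not calibrated defaults.
* **Families**: a pond may be sampled as full-sib families (two simulated
  parents per family, offspring by Mendelian segregation). This is the
  one mechanism that breaks the allele-level independence the admixture
  likelihood assumes, and it produces exactly the artefacts expected from
  sampling larvae in small water bodies: heterozygote deficit and
  admixture LD.
* **Environment** (`sim_env_spec()`): localities with a driver climate
  variable uniform on [0, 100] mm, presence labels Bernoulli with
  `p_M = 1/(1 + exp(−0.156·bio17 + 7.767))` (coefficients stored in that
  exponent convention throughout), and nuisance variables calibrated to
  target Spearman correlations with the driver by bisecting the mixing
  weight of a normal-scores transform (tolerance ±0.02; a target of
  exactly ±1 uses a pure monotone map). Default nuisance targets are
  kept below the 0.7 pruning threshold, mirroring a pruned candidate set.

What the generators deliberately do **not** emulate: genotyping batch
effects, null alleles, locus-specific missingness, linked markers,
spatially explicit drift/migration dynamics (the footprint tail is
imposed, not emerged), and spatial autocorrelation of climate at the
localities. Passing tests therefore demonstrate correctness of the
estimators under the model's own assumptions, not robustness to every
artefact of real data.

## Marker design

Exon selection follows the positional-priority scheme for avoiding UTR:
exons matched more than twice in their gene model are priority 1 (with
exactly three matches the central one is taken; with more, a seeded
uniform choice among interior exons — the "centre" of an even count > 3
is not well defined, so the random-interior rule is applied to all counts
above three), two matches are priority 2 (longest exon), single matches
priority 3 (deprioritised, not excluded: they still rank behind priority
1–2 in the composite order rather than being dropped outright). The
length filter keeps 100–400 bp inclusive, reading "minimum" and
"maximum" as attainable bounds. Ranking to the target panel of 192
removes candidates flagged for multiple similar or duplicated sequences
and sorts by priority, then e-value, percent identity, gap count, with
contig id as the final tie-break — the criteria are given by the design
procedure, the ordering among them is this package's documented choice,
made total and deterministic so that permuted inputs reproduce the panel.

## Diagnosticity

Cohen's κ is computed per allele copy: a heterozygote contributes one
allele to each column of the 2×2 allele-by-species table, a haploid locus
one allele per individual. κ = (p_o − p_e)/(1 − p_e); when both margins
are degenerate (p_e = 1) κ is defined as 1 for a diagonal table and 0
otherwise. A locus is diagnostic when κ ≥ 0.9 (boundary inclusive);
loci with any between-species frequency difference are informative. The
per-allele (rather than per-individual) scoring is a documented choice;
it weights each sampled chromosome equally.

## Population-genetic tests

* **Hardy–Weinberg**: the conditional exact test, by full enumeration of
  heterozygote counts compatible with the observed allele counts —
  biallelic loci are exactly enumerable, so no Markov chain approximation
  is needed. Two-sided p sums all configurations no more probable than
  the observed one (relative tie tolerance 1e−9 guards floating-point
  equality).
* **Genotypic LD**: a G-test on the 3×3 genotype table with a Monte Carlo
  permutation null, `p = (1 + #{G* ≥ G})/(B + 1)`; monomorphic loci give
  p = 1 by convention. Exactness and in-repo testability were preferred
  over reproducing any particular external program's MCMC internals.
* **Multiple testing**: Benjamini–Hochberg step-up, applied both within
  each population's test family and pooled, since either convention is
  defensible; the scan reports both.
* **Admixture LD**: dosages scaled to [0, 1]; `D_ij` is the pairwise
  sample covariance with pairwise deletion (appropriate at the 2.3%
  missingness regime, avoiding imputation bias), `D̄` the mean over
  pairs, with a 95% percentile bootstrap over individuals (1,000
  replicates by default). A 50/50 mix of pure gene pools gives
  `D̄ = n/(n−1)·0.25` exactly; a panmictic population's CI covers 0 at
  close to the nominal rate (percentile intervals at n of a few dozen
  individuals run slightly anti-conservative, which the tests document).

## Admixture model and model choice

The admixture likelihood — dosage `g_il ~ Binomial(c_l, Σ_k q_ik p_kl)` —
is maximised by EM with closed-form updates from expected
allele-assignment counts. This replaces Bayesian MCMC sampling of the
same model: the estimand (the ML configuration of Q and P) is the same,
the fit is deterministic per seed, and replicate random restarts play the
role of replicate chains. Convergence is declared at a log-likelihood
gain below 1e−6 (cap 500 iterations); allele frequencies are clamped to
[1e−9, 1−1e−9] to keep the likelihood finite at fixed loci. The EM
log-likelihood is asserted non-decreasing at every iteration in the test
suite. Cluster labels are arbitrary; the M-like cluster is identified as
the one with the larger mean allele frequency.

Evanno's ΔK is computed from replicate log-likelihoods per K:
`ΔK = |L(K+1) − 2L(K) + L(K−1)| / sd(L(K))` using replicate means for the
second difference. ΔK exists only for interior K; K = 1 is compared by
likelihood separately. Exactly zero replicate spread raises an error
rather than dividing by zero. Individuals are classified from the
M-cluster proportion with strict purity bounds: `q > 0.95` pure M,
`q < 0.05` pure P, boundary values admixed.

Problem sizes used in the recovery tests — 354 individuals × 54 fixed
loci for Q recovery (the planted-q RMSE bound of 0.05 sits just above
the information limit: even with known allele frequencies, 108 alleles
give a per-individual standard error near 0.04), and ten repetitions of a
two-pond, 80-individual, 30-locus landscape scanned over K = 1..5 with 10
restarts for the ΔK pipeline — were chosen as the smallest designs at
which the estimators' behaviour is cleanly measurable.

## Ordination and contours

PCA runs on column-mean-centred dosages with mean imputation of missing
calls (dropping rows would discard most individuals at 2.3% missingness
spread over 55 loci). Component signs follow a fixed rule (largest
loading entry positive) so scores are platform-reproducible. Group
summaries report componentwise mean ± sd per population. The geographic
contour surface is weight-scaled inverse-distance-squared interpolation
with population sample size as the weight — the original contouring
software's algorithm is unpublished, so IDW is declared as this package's
interpolator; it is exact at data points and bounded by the data range.

## Two-species distribution model

Candidate climate variables are pruned by UPGMA clustering on
`1 − |r_s|` cut at `|r_s| = 0.7`; each cluster is represented by the
member with the lowest mean |r_s| to variables outside the cluster (the
least redundant representative — the original analysis lists retained
variables without stating its rule). If all variables fall in one
cluster, the fallback is the lowest mean within-cluster |r_s|, ties
alphabetical. Selection is forward stepwise under the likelihood-ratio
criterion (entry p < 0.05, removal p > 0.10, ties by candidate order, a
step cap and visited-state hash guard against cycles). Logistic fits use
IRLS with explicit complete-separation detection. Fit quality is the
Mann–Whitney AUC with Hanley–McNeil standard error. Hindcasting applies
the fitted logistic to each climate reconstruction, thresholds at
`p_M > 0.5` into binary presence grids, and sums them into a cumulative
grid counting supporting models; nodata propagates through every step.

## Reproducibility

All randomness flows through explicit seeds: simulators restore the
caller's RNG state, so identical specs yield identical datasets
anywhere. The acceptance script re-derives the distribution-model
coefficient recovery from scratch at 10,000 simulated localities under a
caller-supplied seed.
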