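---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`urobiome` is an analysis chain for low-biomass shotgun metagenomic
profiles — urine being the motivating specimen type. Urine carries so
little microbial DNA that reagent and environmental contamination makes
up a visible fraction of the sequenced reads, and naive community
analyses are badly distorted by it. The package covers five stages:
mock-control-aware decontamination, community-type ("urotype")
discovery, host-factor variance decomposition, sex-differential
analysis with a random-forest classifier, and a metagenome genome-wide
association scan (mGWAS). A synthetic-cohort generator with a ground
truth object lets every stage be validated by parameter recovery.

This vignette documents the models, the tunable parameters that matter,
the numerical choices, and where the design was genuinely open, what we
chose and why. No empirical claim is made here that the test suite does
not itself compute.

## Decontamination

The three-step procedure operates on a species-level relative-abundance
table with a read-count layer, a sample sheet carrying roles
(study / mock control), 96-well plate membership, and library PCR
concentrations.

**Step 1 (cohort-wide).** A species is flagged if *any* of four
criteria holds:

* (a) its relative abundance is significantly correlated with PCR
  concentration (Spearman, p < 0.05). Contaminants enter at a roughly
  fixed mass, so their *relative* share rises as true DNA falls.
* (b) its frequency-model p-value `p_freq` is below 0.3, or it occurs
  in fewer than 4 study samples.
* (c) it is detected in the mock controls above a mean relative
  abundance of 1e-4 and is not one of the 10 expected mock species.
* (d) its cohort-summed read count is below 1,000.

`p_freq` compares, on the samples where the taxon is present and
concentration is measured (at least 5, else undefined), a contaminant
model — log10 frequency vs log10 concentration with slope fixed at −1 —
against a constant-frequency model, via the residual sum-of-squares
ratio referred to F(n−1, n−1). Small values are contaminant-like. Zeros
are excluded from the fit (log of zero is undefined); the statistic is
invariant to rescaling concentrations by a positive constant. This is a
self-contained reimplementation of the frequency idea, calibrated in
the test suite by simulation (slope −1 draws score stochastically below
slope 0 draws); we do not claim formula-level identity with any
external package.

**Step 2 (per plate).** Surviving non-expected species seen in a
plate's mock above 1e-4 are removed from that plate only.

**Step 3.** Non-bacterial taxa are dropped, each sample is renormalized
to sum 1, and the per-sample contaminated fraction (reads of flagged
taxa over total reads, computed before renormalization) is reported.
Non-bacterial removal is tracked separately and does not count toward
the contaminated fraction.

Open choices we fixed: "reads count less than 1,000" is read as the
taxon's cohort-summed count (it appears in a list of per-species
removal rules); a per-sample variant sits behind
`reads_per_sample = TRUE`. "Occurrence < 4" counts study samples only.
The Spearman criterion uses cohort-wide concentrations. Criterion (a)
defaults to the literal two-sided test; `spearman_direction =
"negative"` restricts to negative correlations. The two-sided default
has a known failure mode that our own generator exposes: once
contaminant load (proportional to 1/concentration) is mixed in,
closure forces every clean taxon's share *up* with concentration, and
the two-sided test removes clean mass. The acceptance suite therefore
runs recovery with the negative-direction variant and calibration
(false-positive rate at the nominal 5%) with the default.

The **feature filter** (prevalence > 10%, mean relative abundance >
1e-4, both strict) selects analysis features without renormalizing:
downstream distances use the retained fraction as-is, and the table is
flagged unnormalized.

## Urotyping

Distances are the square root of the Jensen–Shannon divergence with
natural logarithm — the convention of the enterotype literature — after
adding a pseudocount of 1e-10 and renormalizing; disjoint profiles sit
at sqrt(log 2) ≈ 0.8326. Clustering is PAM (BUILD initialization,
best-improvement SWAP to convergence, ties toward the lowest sample
index; cluster numbers follow ascending medoid index so results are
order-invariant up to relabeling). The number of clusters is chosen by
the Calinski–Harabasz index in its distance-only form

> W = Σ_c (1/n_c) Σ_{i<j∈c} d²,  T = (1/n) Σ_{i<j} d²,
> CH = ((T−W)/(k−1)) / (W/(n−k)),

scanned over k = 2..10 (the literature's usual range; exact bounds are a
free choice). On Euclidean-embeddable matrices this equals the centroid
form computed in full principal-coordinate space — asserted in the
tests. The result carries a `weak_structure` flag when the CH curve has no
interior peak (maximum at the smallest scanned k — on structureless
compositional clouds CH declines monotonically from k = 2) or when the
maximum is within 1.2× of the curve's median. The flag is a heuristic
for "the curve has no real peak", not an inferential threshold: a
simple max/median ratio alone does not separate blobs (≈1.2–1.3) from
genuinely clustered cohorts (≈1.3–1.5 over a 2–10 scan, because the
curve falls steeply at large k in both cases), while the position of
the maximum does.

Cluster markers use an LDA effect-size score in the LEfSe spirit but
fully specified and seed-deterministic: Kruskal–Wallis screening at
0.05 on per-million-scaled abundances; per class one-vs-rest, 30
bootstrap rounds of 2/3 per-class subsampling; per round a two-class
Fisher LDA with ridge ε = 1e-6·trace/p on the pooled covariance; the
per-feature effect is the mean of |raw mean difference| and
|discriminant-attributed difference|, and the score is its log10.
The canonical tool's subclass grid is omitted — there is no subclass
structure here. Threshold 2.0 (the field's convention, stated for the
sex analysis) is also used for urotype markers; the dominant taxon per
cluster is the rank-1 marker regardless of threshold. Welch t-tests
(BH-adjusted) confirm each dominant taxon's enrichment.

## Host factors

Univariable distance-based redundancy analysis embeds the Bray–Curtis
matrix by PCoA (positive axes only; negative eigenvalues are reported
but dropped, matching the common workflow's default rather than
applying a Cailliez correction), regresses the coordinates on one
covariate, and reports R² as the explained share of total inertia with
an ANOVA-like free permutation p-value. With a full set of group
dummies this reproduces one-factor PERMANOVA R² exactly on
Euclidean-embeddable matrices. Screening across covariates is
BH-corrected (step-up with monotonicity). Collinearity pruning is a
greedy scan in descending univariable-R² order (the source text does
not say which member of a collinear pair was dropped; keeping the
stronger factor is deterministic and defensible), dropping any
covariate with |Spearman ρ| > 0.6 against an already-kept one.
Variation partitioning reports per-category and total Ezekiel-adjusted
R², `adjR² = 1 − (1−R²)(n−1)/(n−p−1)`; no shared fractions are
computed. Urotype–phenotype correlations use binary membership
indicators (cluster probabilities are not available from PAM).

## Sex analysis

Two-class LDA effect-size screening (threshold 2.0, KW 0.05) labels
markers by the enriched sex. The classifier is a 500-tree random
forest: stratified 70/30 split, mtry = sqrt(p), unlimited depth, no
class weights — only trees and split are stated by the source; the rest
follow common defaults and are arguments. Held-out AUC uses the
Mann–Whitney rank formulation (equal to trapezoidal ROC integration, a
tested identity); importances are normalized Gini impurity decreases.
The forest is implemented in compiled code inside the package because
no forest implementation exists in the target environment; all
randomness flows through R's RNG, so a seed fixes the split, the forest
and the report byte-for-byte.

## mGWAS

Variant QC: call rate > 98%, MAF ≥ 1%, exact-test HWE p > 1e-5 (exact
conditional test, enumeration of heterozygote configurations no more
probable than observed). Genotype PCs standardize dosages by mean 2p
and sd sqrt(2p(1−p)) after mean imputation, with signs fixed by the
largest-magnitude loading.

Model routing by prevalence: > 50% → linear; (10%, 50%] → presence/
absence logistic; ≤ 10% → excluded. The source states both "over 50% →
linear" and "10–90% → presence/absence", which overlap on 50–90%; we
assign one model per taxon with the boundary at 50%, matching its
one-model-per-taxon accounting. The linear route replaces zeros with
half the taxon's minimum nonzero abundance (the usual half-minimum
pseudocount; the source is silent), takes log10 — the source's formula
says log10 while its prose says natural log; p-values are invariant to
the base — and residualizes on age, sex, BMI, read counts and 10 PCs,
exactly the two-stage procedure described, before per-variant simple
regression. The logistic route fits presence ~ dosage + covariates by
IRLS with a Firth-penalized fallback on separation (flagged in the
output). Genome-wide significance is fixed at 5e-8 with no extra
layering. G×E interaction tests Wald-test the dosage×environment
coefficient with additive dosage coding; the stratified summary
collapses genotypes to carrier classes and reports cell means with
within-class Spearman correlations.

## The synthetic cohort: what it emulates and what it does not

The generator is a stated world, fixed once:

* **Community types.** K = 5 latent clusters; each sample's cluster is
  drawn from sex-tilted priors (clusters 1 and 3 female-enriched,
  2/4/5 male-enriched, tilt 0.5). Compositions are Dirichlet with
  precision θ = 40 around cluster means: a shared lognormal
  rank-abundance backbone (sd 1.2, floored so every taxon keeps ≥0.2%
  mean share — keeping clean taxa clear of the occurrence and
  read-count removal rules, as real resident taxa are), perturbed per
  cluster by lognormal(0, 0.8) factors, with the cluster's dominant
  taxon set to a 0.30 mean share. The precision is calibrated so the
  default world has what the package's own validation assumes: five
  community types that Calinski–Harabasz model selection recovers at a
  0.30 dominant share in ≥ 90% of draws. At θ = 40 PAM already recovers
  the labels almost perfectly (ARI > 0.98) but the CH peak at k = 5 is
  shallow and k = 2–4 wins in roughly a third of draws; θ = 80 leaves a
  ~15% miss rate; θ = 120 yields a stable ~95% recovery rate (checked
  on a held-out seed block) while single draws remain visibly noisy.
  These values are within the range of Dirichlet-multinomial precisions
  fitted to real microbiome data.
* **Counts first.** Reads are multinomial at lognormal depth
  (median 50k, sd 0.4 log), so read-count-scale rules are exercisable;
  fractions are derived.
* **Sex structure.** 10 background taxa (half per sex) get a 2-fold
  Dirichlet-weight shift; phenotypes include age ~ N(29, 6),
  BMI ~ N(22, 3) and a testosterone-like hormone (male 15 ± 3,
  female 1.2 ± 0.5 nmol/L) optionally tied to a taxon's log10
  abundance.
* **Contamination.** PCR concentrations are lognormal (median 2 ng/µL,
  sd 0.7 log), drawn independently of composition; spiking adds 16
  cohort-wide and 4 plate-specific contaminant taxa whose expected read
  share is `0.08 / concentration` times lognormal noise (sd 0.5),
  capped at 0.6 — mean contaminated fraction around 5–8%, the same
  order as real low-biomass cohorts. Mock controls (two per plate)
  carry the 10 expected species equimolar plus that plate's
  contaminants at a 1% total share. Negative controls are not emitted
  by default (in the motivating study none survived library
  preparation).
* **Genetics.** Dosages are i.i.d. Binomial(2, maf) — HWE by
  construction, no linkage disequilibrium, no stratification. Planted
  effects shift log10 abundance by β per alternate allele (abundance
  mode) or tilt a presence logit (presence mode, marginal prevalence
  preserved).

What a green test does *not* establish: the generator has no taxon
co-occurrence structure beyond clusters, no batch effects other than
plate-specific contaminants, no LD (so locus-grouping behavior is
untested), no zero-inflation beyond what Dirichlet-multinomial
sampling induces, and mock composition is idealized equimolar. Results
on real data depend on properties the generator does not emulate.

## Numerical choices and degenerate inputs

Pseudocounts: 1e-10 before JSD; half-minimum before log10 in the linear
mGWAS route. All-zero samples raise errors (diversity) or are dropped
with a count (decontamination). `p_freq` guards a zero non-contaminant
residual with ε = 1e-12. PAM tie-breaks go to the lowest index; CH of a
zero-within clustering returns an `Inf` sentinel. BH is step-up with
enforced monotonicity. Logistic separation falls back to a Firth
penalty and is flagged. PERMANOVA and dbRDA p-values use the
`(1 + hits) / (1 + n_perm)` convention, so the floor is
`1/(n_perm + 1)`.

## Known limitations

Single-factor PERMANOVA only (no strata or covariate adjustment);
no UniFrac or rarefaction; no prevalence-based (negative-control)
decontamination mode; no multivariable forward-selection dbRDA or
shared variation fractions; no kinship or mixed-model association, LD
clumping, imputation, or Mendelian randomization. The LDA effect-size
score is a documented variant, not a byte-level reimplementation of
the canonical tool.
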