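# urobiome

Analysis toolkit for **low-biomass urinary shotgun metagenomics**. Urine
carries so little microbial DNA that reagent and environmental
contamination is a first-order problem, and community analyses need
contamination-aware preprocessing before any biology can be read off.
`urobiome` implements a complete analysis chain for species-level
taxonomic profiles (MetaPhlAn-style tables), a sample sheet with
mock-control/plate metadata, and genotypes in VCF:

1. **Decontamination** — a three-step procedure: cohort-wide species
   removal by OR-combined criteria (Spearman correlation of relative
   abundance with PCR concentration, p < 0.05; frequency-model
   `p.freq < 0.3` testing log10 frequency ∝ −log10 concentration, or
   occurrence in < 4 samples; detection in mock controls above 1×10⁻⁴
   mean relative abundance outside the 10 expected mock species;
   cohort-summed read count < 1,000), then per-plate removal of
   non-expected species seen in that plate's mock, then removal of
   non-bacterial taxa and renormalization, with a per-sample
   contaminated-fraction report.
2. **Community metrics** — Shannon/Simpson diversity, Bray–Curtis and
   root Jensen–Shannon distances, PCoA, one-factor and pairwise
   PERMANOVA (`P = (1 + #{F* ≥ F}) / (1 + n_perm)`).
3. **Urotyping** — PAM clustering on root-JSD distances, number of
   clusters by the Calinski–Harabasz index
   `CH = (B/(k−1)) / (W/(n−k))`, per-cluster marker ranking by a
   LEfSe-style log10 LDA effect size, dominant-taxon Welch t-tests.
4. **Host factors** — univariable Bray–Curtis dbRDA with permutation
   ANOVA, BH FDR screening, greedy Spearman collinearity pruning
   (|ρ| > 0.6), variation partitioning with Ezekiel-adjusted R²,
   feature–phenotype correlation tables.
5. **Sex analysis** — two-class LDA effect-size markers (threshold 2.0)
   and a 500-tree random-forest sex classifier (stratified 70/30 split,
   Mann–Whitney AUC, normalized Gini importances).
6. **mGWAS** — variant QC (call rate > 98%, MAF ≥ 1%, exact HWE
   p > 10⁻⁵), genotype PCs, and a dual association scan: for taxa with
   prevalence > 50%, residualized
   `log10(abundance) ~ age + sex + BMI + reads + 10 PCs` regressed
   per-variant on dosage; for prevalence in (10%, 50%], logistic
   presence/absence with the same covariates (Firth fallback on
   separation); genome-wide threshold 5×10⁻⁸; G×E interaction Wald
   tests and genotype-stratified summaries.

A **synthetic-cohort generator** (`generate_profiles`,
`spike_contaminants`, `generate_genotypes`, `plant_associations`)
produces cohorts with all the structure above plus a ground-truth
object, so every stage is validated by parameter recovery. See
`vignettes/urobiome-methods.Rmd` for the models, defaults and design
choices.

## Worked example

```r
library(urobiome)

cohort <- generate_profiles(sim_config(n_study = 300, n_plates = 4), seed = 42)
spiked <- spike_contaminants(cohort$table, cohort$sheet, cohort$truth,
                             contaminant_spec(), seed = 42)

flags <- c(
  flag_cohort_contaminants(spiked$table, spiked$sheet,
                           decontam_params(spearman_direction = "negative")),
  flag_plate_contaminants(spiked$table, spiked$sheet))
dec <- apply_decontamination(spiked$table, flags, spiked$sheet)
print(dec$report)

features <- feature_filter(dec$table)
model <- assign_urotypes(features, seed = 42)
print(model)
adjusted_rand_index(model$assignments,
                    spiked$truth$cluster_labels[names(model$assignments)])
```

prints

```
decontam_report: 34 taxa flagged, 0 non-bacterial removed, 96 retained
  contaminated fraction: mean 16.90%, median 10.55%
urotype_model: k = 5 over 300 samples
  urotype 1: n = 72 (24.0%), dominant Taxon_012
  urotype 2: n = 63 (21.0%), dominant Taxon_025
  urotype 3: n = 55 (18.3%), dominant Taxon_024
  urotype 4: n = 58 (19.3%), dominant Taxon_009
  urotype 5: n = 52 (17.3%), dominant Taxon_081
[1] 1
```

All 20 planted contaminants are among the 34 flags, along with the 10
mock-community species (zero reads in study samples, flagged by the
occurrence rule) and 4 clean taxa caught by chance-level negative
Spearman correlations — the expected cost of a 5%-level test over ~100
taxa. One of those false flags is an abundant taxon, which is why the
reported mean contaminated fraction (16.9%) overstates the generator's
planted load (7.7% in this draw): removal criteria charge the whole
read mass of every flagged taxon to contamination. The urotype model
recovers five community types, each dominated by the taxon the
generator made dominant, and the final line is the adjusted Rand index
against the generator's hidden labels — 1 means the partition was
recovered exactly up to relabeling.

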