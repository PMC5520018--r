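# transload

Transancestral case-control association and genetic-load analysis for dense
genotyping arrays, with a synthetic multi-ancestry cohort generator so the
whole pipeline runs end-to-end without access to individual-level study
data.

## The problem

Large autoimmune-disease association studies genotype cases and controls
from several ancestral groups (European, African, Hispanic/Amerindian) on
immune-locus arrays, then ask three kinds of question:

1. **Which variants are associated in each ancestry, and jointly?**
   Per-ancestry logistic regression with admixture-factor covariates and a
   genetic-model selection rule (additive primary; dominant/recessive when a
   lack-of-fit test fires), tiered significance (Tier 1 `P < 5e-8`, Tier 2
   `P < 1e-6`, Tier 3 BH-FDR `< 0.05`), and a sample-size-weighted
   inverse-normal meta-analysis across ancestries,
   `Z = Σ wᵢzᵢ / √(Σ wᵢ²)` with `zᵢ = dᵢ Φ⁻¹(1 − pᵢ/2)`, `wᵢ = √nᵢ`.

2. **What does the HLA region contribute?** Allele-dosage association,
   stepwise multi-locus models, compound risk-allele heterozygosity
   (DR3-like/DR15-like) with genotypic contrasts and dominance lack-of-fit
   tests, and neighbour-joining clustering of allele protein sequences with
   risk-unique residue identification.

3. **How does aggregate risk behave?** A genetic risk-allele load
   `GRSᵢ = Σₖ γₖ RAᵢₖ` (γₖ = training log-OR, or 1 for the unweighted count)
   evaluated on held-out samples through sliding-window odds ratios against
   the lowest-decile reference, tests for supra-additive ("cumulative hit")
   departure from linearity on the logit scale, c-statistics, and
   association with age at diagnosis.

The package implements all of this, plus SNP/sample quality control (exact
Hardy-Weinberg tests, differential missingness, LD pruning, genomic-control
λ scaled to 1,000 cases/1,000 controls), ancestry profiling of risk alleles
(frequency clustering, admixture-deviation tests) and a 0-15 biological
annotation score with CpG-site determination and eQTL proxy joins.

## Worked example

Desk-scale reproduction of four published transancestral meta-analysis rows
from their printed per-ancestry P-values, effect directions, and cohort
sizes (EA 18,264; AA 5,422; HA 3,888 — 27,574 samples in all):

```r
library(transload)
ref <- reference_study()
row <- ref$worked_rows$rs3733345
inverse_normal_meta(row)$p_combined
#> [1] 1.833655e-11     # printed value: 1.83e-11
```

Running `Rscript analysis/04_worked_examples.R` prints all four:

```
         snp p_recomputed p_reported rel_err
1  rs3733345     1.83e-11   1.83e-11 0.00200
2  rs3828069     1.76e-09   1.77e-09 0.00374
3 rs34840245     2.36e-11   2.37e-11 0.00452
4   rs223889     1.08e-08   1.08e-08 0.00328
```

All four recompute within 0.5% of the printed values (the inputs are rounded
to three significant figures, so exact equality is not expected).

The end-to-end demonstration — three simulated admixed cohorts of ~4,000
samples, 2,000 SNPs with 40 planted risk variants, a supra-additive load
term and an HLA compound-heterozygote excess — runs with

```r
art <- run_pipeline(demo_config(seed = 1))
make_report(art)$load_table
#>         mode or_point    ci_lo    ci_hi            p c_statistic
#> 1 unweighted 4.383208 3.341877 5.749019 1.289767e-26    0.705548
#> 2   weighted 3.072524 2.515324 3.753157 4.043032e-28    0.712544
```

i.e. on the held-out split, five additional risk alleles multiply the odds
of disease by ~4.4 and the load alone ranks a random case above a random
control ~71% of the time. The per-stage tables (association, meta, HLA,
load windows, deviations, annotation scores) land under the run's output
directory together with a content-hash manifest; reruns under the same seed
are bit-identical. The numbered scripts under `analysis/` walk the same
pipeline step by step and write their tables under `results/`.

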