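# geoadapt

Comparative genomics and phenotyping of laboratory-evolved bacterial
lineages, built around the analyses used to characterize *Geobacter
sulfurreducens* clones adapted to seventeen years of continuous current
generation on a graphite anode.

A clonal population evolving under one strong selective regime leaves a
recognizable signature: few SNPs against the parent but a high share of
protein-altering and loss-of-function (LOF) changes, elevated genome-wide
dN/dS, mutational hotspots, streaming deletions, faster growth on Fe(III)
oxide, and higher expression of extracellular-electron-transfer genes.
geoadapt measures every part of that signature and ships a synthetic-data
generator that plants each signal with known ground truth, so the whole
chain is testable at desk scale. It is written tidyverse-style: tibbles in,
tibbles out, pipe-friendly, with broom-style `tidy()`/`glance()` methods and
`autoplot()` for the main result types.

## What is implemented

| Stage | Functions | Core quantities |
|---|---|---|
| Synthetic evolution | `evolution_scenario()`, `generate_ancestral_genome()`, `evolve_lineage()` | planted Ts/Tv, dN/dS, LOF rate, hotspots, deletions, with a truth table |
| Variant annotation | `annotate_variants()`, `classify_variant()`, `aa_category()`, `aggregate_gene_profiles()` | codon-level effect classes, functional/LOF flags, per-gene profiles |
| Mutation statistics | `ts_tv()`, `ng_site_counts()`, `genome_dnds()`, `mutational_background()`, `detect_hotspots()`, `lof_fraction()`, `genome_reduction()`, `find_large_gaps()`, `comparison_summary()` | the full genome-wide comparison row |
| Structure comparison | `kabsch_superpose()`, `tm_score()`, `deviation_bins()`, `ss_diff()`, `segment_stats()`, `helix_content()`, `content_change()`, `heme_distance_stats()`, `compare_structures()` | RMSD, TM-score, secondary-structure and heme divergence |
| Expression | `generate_ct_table()`, `delta_delta_ct()`, `expression_contrast()` | 2^−ΔΔCt fold changes with replicate dispersion |
| Phenotype | `generate_growth_curves()`, `fit_growth_rate()`, `fold_change_rates()`, `ferrozine_fe2()`, `crystal_violet_index()` | specific growth rates k, strain-fold contrasts, assay conversions |
| Orchestration | `pipeline_config()`, `run_pipeline()`, `stat_tests()` | reproducible TSV report bundle + manifest |

The key model choices: dN/dS is Nei–Gojobori equal-pathway counting,
dN/dS = (Nd/N)/(Sd/S) with no multiple-hit correction by default; a hotspot
is a gene with ≥ 1 functional mutation and per-gene functional density ≥ 3×
the genome background; TM-score uses d0 = 1.24(L−15)^(1/3) − 1.8 Å floored
at 0.5 Å; relative expression is 2^−ΔΔCt normalized to a housekeeping gene
and a reference strain, aggregated geometrically. The methods vignette
(`vignettes/geoadapt-methods.Rmd`) covers every convention, parameter and
numerical choice in detail.

## A worked example

Simulate one evolved lineage at the published mutation regime, annotate its
variants, and assemble the genome-wide comparison row:

```r
library(geoadapt)

scn <- evolution_scenario(n_snps = 120, kappa = 2.76, omega = 0.776, seed = 42)
anc <- generate_ancestral_genome(scn)
lin <- evolve_lineage(anc, scn)
ann <- annotate_variants(anc, lin$variants)
comparison_summary(anc, lin$descendant, ann, comparison = "LT vs parent")
#>     comparison total_snps ts_tv  dnds n_functional background_density
#> 1 LT vs parent        120  2.53 0.657           71              0.526
#>   n_hotspots n_lof lof_percent
#> 1         17    11        15.5
```

At 120 SNPs a single draw scatters around the planted values (Ts/Tv 2.53 vs
the planted 2.76, dN/dS 0.66 vs 0.776) exactly as a single real lineage
would; averaged over seeds the estimators are unbiased, which the test suite
checks at 5,000 SNPs × 20 seeds to within ±10%.

Growth-rate contrast between an evolved and a parent strain (planted rates
0.224 vs 0.12 day⁻¹, 5% noise, triplicates):

```r
cv <- generate_growth_curves(c(evolved = 0.224, parent = 0.12),
                             t_grid = seq(0, 30, 1), noise_sd = 0.05,
                             replicates = 3, seed = 42)
rates <- fit_growth_rates(cv)
fold_change_rates(rates[rates$strain == "evolved", ],
                  rates[rates$strain == "parent", ])
#>   fold mean_a mean_b n_a n_b statistic  p_value        method
#> 1 1.88  0.225   0.12   3   3       182 1.26e-08 independent t
```

The evolved strain grows 1.88-fold faster — the kind of contrast the method
is built to detect (the published evolved-vs-parent fold on Fe(III) oxide is
1.8).

Structure divergence of a 407-residue model pair with 20 perturbed residues
and 11 secondary-structure changes:

```r
p <- generate_structure_pair(407, n_perturbed = 20, displacement = 2,
                             n_ss_changes = 11, n_hemes = 6,
                             heme_shift = 0.1, seed = 42)
glance(kabsch_superpose(p$a, p$b))
#>   n_aligned global_rmsd tm_score
#> 1       407       0.713    0.992
ss_diff(p$a, p$b)
#> <ss_comparison> 11/407 positions differ (2.7%)
```

A global RMSD of 0.71 Å with TM-score 0.99 says the fold is conserved while
the per-residue deviations (see `tidy()` / `autoplot()` on the fit) localize
the 20 perturbed positions; 11/407 differing secondary-structure positions
is 2.7% of residues.

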