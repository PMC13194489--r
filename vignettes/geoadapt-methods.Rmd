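---
title: "Methods: simulating and measuring adaptive divergence in electrode-grown Geobacter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring adaptive divergence in electrode-grown Geobacter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoadapt)
library(dplyr)
```

# The scientific setting

When a clonal bacterial population grows for years under one selective
regime — here, *Geobacter sulfurreducens* respiring on a poised graphite
anode — its genome accumulates a characteristic mutation signature: few total
SNPs, but a disproportionate share of protein-altering and loss-of-function
(LOF) changes, an elevated genome-wide dN/dS, streaming deletions of
dispensable regions, and mutational hotspots in genes under relaxed or
directional selection. Alongside the genomic signal, the phenotype shifts:
faster growth on Fe(III) oxide (a proxy for extracellular electron transfer
capacity), higher expression of electron-conduit genes measured by qRT-PCR,
and more surface-attached biomass. Predicted protein structures of mutated
cytochromes diverge measurably — in backbone superposition RMSD and TM-score,
in secondary-structure assignments, and in inter-heme geometry.

geoadapt implements that entire measurement chain as composable, tested R
functions, together with a synthetic-data generator that plants every one of
those signals with known ground truth. Every stage is therefore exercisable
and verifiable at desk scale, without touching the original sequencing data.

# The synthetic lineage generator

## What it emulates

`evolution_scenario()` fixes the regime; its defaults are the published
long-term-evolution signature: ~120 SNPs against the parent, a
transition/transversion count ratio (kappa) of 2.76, genome-wide dN/dS
(omega) of 0.776, and a nonsense share of coding SNPs (`lof_rate = 0.1`)
that places LOF near 14% of functional mutations. The ancestor built by
`generate_ancestral_genome()` is a bacterial-style genome: non-overlapping
CDS on both strands, ATG starts, uniform sense-codon usage (a deliberate
neutrality choice — no codon bias is assumed, so estimator tests are not
confounded by composition), and random intergenic spacers sized by
`intergenic_frac` (default 0.13, a typical coding density for a small
bacterial genome).

Gene lengths are deterministic (all genes get `mean_gene_len` codons) unless
`gene_len_jitter` is set; this keeps tiny scenarios fully predictable while
allowing realistic length variation when wanted.

## How the mutation spectrum is planted exactly

Rather than proposing random substitutions and rejecting them until the
realized spectrum looks right, `evolve_lineage()` samples directly from the
target distribution, which is equivalent in distribution but exactly
auditable:

1. `enumerate_sites()` classifies **every possible single-base change** of
   the genome — synonymous, missense, nonsense, or intergenic, and
   transition vs transversion — for all internal codons (codon 2 to n−1 of
   each CDS) and intergenic positions.
2. Target class proportions are computed so that the Nei–Gojobori estimator
   is unbiased: with N and S the genome's nonsynonymous and synonymous site
   totals and R = N/S, coding SNPs are synonymous with probability
   1/(1 + omega·R); the nonsense share is `lof_rate`; coding vs intergenic
   follows the length share of each compartment.
3. A single transition weight w is solved (by `uniroot` on a monotone
   function) so that the expected transition fraction across all classes
   equals kappa/(1 + kappa) — conditioning on effect class tilts the
   transition fraction, and this solve undoes the tilt exactly.
4. Sites are drawn without replacement within each class with weights
   (hotspot multiplier) × (w for transitions), using exponential sort keys.

Annotated start and stop codons are excluded from placement: the start codon
is constrained to an initiator and its substitutions are not ordinary
missense events, and keeping placement to sense codons 2..(n−1) makes the
planted class proportions exactly consistent with the site totals
`genome_dnds()` uses. The dN/dS site totals cover the same codons for the
same reason.

Large deletions are *chosen* before SNP placement (so no SNP falls inside
one) but *applied* to the sequence after the substitutions; they never
overlap hotspot CDS, which keeps hotspot truth interpretable. Frameshift
indels are 1-bp deletions in CDS interiors — an unambiguous LOF class.
Descendant annotation drops any gene overlapping a deletion event.

Every planted event lands in a truth table whose per-variant effect classes
are, by construction, exactly what `annotate_variants()` reports for the
same records; the test suite asserts this equality at 100%.

## Seeding

A scenario carries one integer seed; every stage (genome build, lineage
draw, structure pair, CT table, growth curves) derives its own stream from
it with a counter-based linear map, so stages are independently reproducible
and identical seeds give byte-identical outputs.

## What the generator does *not* emulate

No codon-usage bias, no recombination or population dynamics, no
selection-coefficient model beyond the omega/hotspot knobs, no read-level
sequencing error (variant tables are consumed directly). Passing recovery
tests therefore demonstrates that the *estimators* are correct and unbiased
under the stated model — not that real sequencing pipelines upstream of the
variant table are error-free.

# Variant annotation

`annotate_variants()` classifies each variant against the reference frame,
strand-aware, into exactly one of: synonymous, missense, nonsense,
start-loss, stop-loss, frameshift, in-frame indel, intergenic.
Conventions worth stating:

* Coordinates are 1-based inclusive throughout (GFF3/VCF convention); indels
  use VCF anchor style.
* At the annotated start codon, ATG/GTG/TTG are all read as initiators
  (bacterial initiator tRNA behaviour): a start codon mutated to another
  initiator is synonymous; to anything else, start-loss.
* Multi-base substitutions confined to one codon are classified jointly from
  the composite codon, not per base.
* "Functional" = any coding variant that alters the protein (missense,
  nonsense, start/stop-loss, frameshift, in-frame indel). LOF = nonsense +
  frameshift + start-loss; stop-loss is functional but **not** LOF (the
  common variant-caller convention). This choice is switch-visible in the
  outputs, since all class columns are reported per variant.
* A variant inside several overlapping CDS yields one row per locus;
  genome-wide totals deduplicate by position.

The amino-acid category scheme behind "category changes" is a six-class
chemistry partition (nonpolar-aliphatic AVLIM; aromatic FWY; polar-uncharged
STNQ; positive KRH; negative DE; special CGP). No standard for this is
universal; `aa_category()` accepts any complete replacement scheme.

# Mutation statistics

* **Ts/Tv** counts SNPs only (indels excluded); zero transversions returns a
  flagged infinite ratio rather than an error.
* **dN/dS** uses Nei–Gojobori equal-pathway site counting with no
  multiple-hit correction by default: at the divergences this package
  targets (1e-5 to 1e-3 per site) the Jukes–Cantor correction changes the
  ratio in the fourth decimal; it is available via `correction = "JC"`.
  Mutations to stop count as nonsynonymous. Zero synonymous substitutions
  gives a flagged `NA`, never a crash.
* **Background density** divides functional SNPs by total CDS length in kb
  by default. The published per-kb densities are consistent with a coding
  denominator (41 functional SNPs / 0.01229 per kb ≈ 3.34 Mb ≈ the CDS
  total of a 3.7 Mb genome), so that is the default; a genome-length
  denominator is a config switch and the choice is echoed in every output
  row.
* **Hotspots** are genes with ≥1 functional mutation whose per-gene
  functional density (per kb of gene) is at least `factor` (default 3)
  times the background. A count-based mode exists for sensitivity analysis.
  The calls are scale-invariant and monotone in added mutations, and both
  properties are tested.
* **LOF %** is reported as 100 × LOF / functional. Note that one published
  table prints 14.29% alongside 6 LOF and 41 functional SNPs — 6/42, not
  6/41; the denominator behind that figure is not recoverable, so this
  package reports the plain ratio and documents the discrepancy rather than
  reverse-engineering it.
* **Large gaps**: `find_large_gaps()` reports reference intervals ≥
  `min_gap` (default 1,000 bp — no published threshold exists, and 1 kb
  separates gene-scale loss from small indels) between non-overlapping
  alignment blocks, including terminal gaps when the reference length is
  given.

# Structure comparison

`kabsch_superpose()` is a plain SVD Kabsch solver with reflections excluded
(determinant-corrected), returning the optimal proper rotation, global RMSD,
per-residue deviations, and the TM-score with the Zhang–Skolnick
normalization d0 = 1.24(L−15)^(1/3) − 1.8 Å, floored at 0.5 Å; L defaults to
the first (reference) model's length, which makes the score asymmetric only
through that normalization. Residues are matched by index — the intended use
is two predicted models of the same mature sequence, so no alignment stage
exists. Collinear inputs make the optimal rotation non-unique and raise a
diagnostic error rather than returning an arbitrary frame. The test suite
checks optimality against 1,000 random rigid motions per instance and
cross-checks the RMSD against an independent reference implementation
(bio3d).

Secondary-structure comparison reduces 8-class DSSP letters to H/E/C
(H,G,I → H; E,B → E; rest → C) before any counting. Strand-length statistics
pair maximal runs by rank order (both sorted, truncated to the smaller
count) for a paired t-test, falling back to an unpaired Welch test — flagged
in the output — when segment counts differ; the pairing scheme behind the
published strand statistics is unstated, and rank-order pairing is the
documented default. Helix-content changes are tested on per-window
proportions (default window 50 residues). Inter-heme distances are iron–iron
Euclidean distances between index-matched hemes, consecutive pairs by
default or all pairs; deviation colour bins use cuts at 0.5 and 2 Å
(one published figure legend says "RMSD < 0 Å" for the most-similar class,
which is read as a typo for ≈ 0).

# Expression (2^−ΔΔCt)

`delta_delta_ct()` computes, per replicate, ΔCt = Ct(gene) −
Ct(housekeeping); ΔΔCt subtracts the mean reference-strain ΔCt for the same
gene and condition; the fold is 2^−ΔΔCt. Replicates aggregate on the log2
scale (geometric mean), which makes recovery of planted folds unbiased under
symmetric cycle noise and fixes the reference strain's mean fold at exactly
1. Amplification efficiency is fixed at 2 — the stated method — so no
efficiency correction is applied. Group contrasts are independent t-tests on
per-replicate log2 folds, symmetric under fold inversion.

# Phenotype

`fit_growth_rate()` estimates k as the slope of ln(value) versus time over
an automatically selected exponential window. Every contiguous span of ≥ 3
positive values is scored by the R² of its log-linear fit, and the *longest*
window within `r2_tolerance` (default 0.005) of the best R² wins. The
tolerance matters: the literal maximum-R² window is almost always a 3-point
sliver once measurement noise is comparable to per-step growth, because any
3 points fit a line nearly perfectly; differences in R² below ~0.005 carry
no information about window quality, so length breaks the tie. On noiseless
exponentials every exponential window has R² = 1 and the full span wins, so
the fit is exact to machine precision — the one contract guaranteed
regardless of policy. A slope-standard-error criterion was considered and
rejected: a flat plateau window also has a tiny slope SE, so it can beat the
exponential phase.

Simulated Fe(III)-oxide curves span 30 days sampled daily — the realistic
monitoring span for rates of 0.1–0.3 day⁻¹ — with multiplicative Gaussian
noise and an optional plateau. Rate-group contrasts
(`fold_change_rates()`) are mean-ratio folds with an independent t-test, and
refuse to compare groups carrying different time-unit tags (per-hour vs
per-day rates never mix silently). Ferrozine Fe(II) readings invert a linear
562 nm calibration with a default ×10 dilution (0.1 mL sample into 0.9 mL
HCl); the crystal-violet attachment index is A580(stain)/A600(culture).

# The pipeline

`run_pipeline()` drives all stages from one `pipeline_config()` and writes a
TSV bundle: per-lineage genome-wide summaries (one row per comparison, in
the column order of the published mutation-statistics table), a hotspot
table with the lineages carrying each hotspot, a per-gene amino-acid-change
table, a structure report, expression and growth-rate tables, and a YAML
manifest (package version, seed, every knob). Identical config + seed gives
a byte-identical bundle. No multiple-testing correction is applied anywhere
(raw p-values are reported, matching the source analyses); every statistical
test delegates to base stats routines through `stat_tests()`.

A worked end-to-end example:

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  scenario = evolution_scenario(n_snps = 120, kappa = 2.76, omega = 0.776),
  n_lineages = 5, seed = 1
)
res <- run_pipeline(cfg, "run1")
res$summary
```

# Problem sizes and what the tests show

The shipped test and verification suites use: parameter recovery on a
400-gene × 300-codon genome with 5,000 SNPs over 20 seeds (sampling error of
the mean ≈ 1%, comfortably inside the ±10% acceptance band); hotspot
detection on a 100-gene genome over 50 seeds; oracle equivalence on all nine
substitutions of 1,000 random codons; superposition optimality against
1,000 random rigid motions; and 100-seed Monte-Carlo recovery for expression
folds and growth-rate contrasts. These sizes were chosen so each property is
measured well inside its tolerance while the whole suite stays desk-scale.

Known limitations: dN/dS is a single-pair, count-based estimate (no
phylogeny, no test against 1); the structure module consumes pre-computed
coordinates and secondary-structure strings (it does not predict structure
or assign secondary structure from coordinates); expression assumes a
perfectly efficient 2× amplification; and the growth-window policy, while
robust in the regimes above, is a heuristic — the published analyses do not
state theirs, and only the noiseless-exponential contract is guaranteed.
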