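---
title: "Methods: cross-species aneuploidy dosage screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species aneuploidy dosage screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuscreen)
```

## The screening idea

Segmental trisomy models (e.g. Down-syndrome mouse lines carrying three
copies of parts of mouse chromosome 16, which is largely syntenic to human
chromosome 21) differ in which genomic segments are dosage-increased. If
some models show a phenotype — here, fasting hyperglycaemia — and others do
not, the genes *responsible* for the phenotype must lie in segments
triplicated in **every affected model and in no unaffected model**. That
region logic turns a panel of phenotype calls plus segment maps into a
candidate gene set, which is then projected to human orthologs and
intersected with disease evidence from human tissue: upregulation in
case/control expression data, and (as corroboration) CpG sites whose
methylation is negatively associated with the candidate's expression.

The funnel is:

1. **Phenotype layer** — classify each model hyper-, normo- or
   hypoglycaemic against its own control arm.
2. **Region layer** — interval algebra over dosage segments, gene
   membership, ortholog projection, then
   `intersect(affected) - union(non-affected)`.
3. **Expression layer** — keep candidates significantly *up*-regulated in
   disease.
4. **Methylation layer** — corroborate survivors that have CpG probes with
   a significant negative methylation-expression association.
5. **Annotation layer (optional)** — a user-supplied per-gene flag (e.g.
   "known mitochondrial/secretion role"). This mirrors a manual
   literature-triage step; it is deliberately never inferred by the
   package.

## Reconstructed two-group tests

Published group data usually appear as mean ± SEM with n. Every two-group
comparison in the package runs through one engine
(`two_group_test_from_summary()`) that reconstructs the unpaired t test
from those triples, using the implied SD = SEM·√n:

- `student_pooled` (default): pooled variance, df = n₁+n₂−2. The default
  because the unpaired Student t is the stated convention for parametric
  comparisons in this setting.
- `welch`: Satterthwaite df; exposed because an SEM-based reconstruction
  cannot verify the equal-variance assumption.

Applied to summaries computed from raw vectors, both reproduce
`t.test()` exactly (tested to 10+ significant figures), so per-animal
tables and printed summaries are interchangeable inputs. A Mann-Whitney
rank-sum alternative exists for raw tables only — it cannot be
reconstructed from summary statistics.

Phenotype calls use a two-sided α = 0.05 by default. The classification
threshold is not separately published for this kind of screen; 0.05
matches the lowest reported significance level and is configurable
(`alpha_phenotype`).

## Region algebra conventions

- Coordinates are 0-based half-open everywhere internally (BED
  convention); GFF3 input (1-based inclusive) is shifted at the reader.
  This keeps length arithmetic unambiguous and BED round-trips lossless.
- `normalize_segments()` merges overlapping *and bookended* intervals;
  set operations are defined per base pair and verified in the tests
  against a brute-force per-base oracle on small genomes.
- Gene containment defaults to `full`: a gene counts as dosage-increased
  only if it lies entirely inside a triplicated segment, since partial
  triplication does not guarantee a functional extra copy. `any_overlap`
  is available.
- Ortholog projection defaults to `one_to_one_only`: genes in ambiguous
  (one-to-many) links are dropped with a warning, because dosage
  reasoning is ill-defined for ambiguous orthology.
- "Non-affected" means *any* phenotype other than the affected label, so
  both normoglycaemic and hypoglycaemic models subtract their regions.
  A model carrying a human chromosome contributes human gene sets
  directly, without projection; its known deletions are encoded in the
  user-supplied segment definition.

## Expression layer

The package consumes either a normalized expression matrix (its surrogate
DE engine applies the two-group t to `log2(x+1)`; the pseudocount keeps
zero expression finite) or precomputed per-gene statistics from an
upstream engine — the latter is the expected route for real RNA-seq,
since count modelling (dispersion, normalization factors) is out of
scope. The fold-change sign convention is fixed project-wide: positive =
higher in disease. The candidate filter defaults to nominal p < 0.05 with
no multiple-testing adjustment, which is how a five-gene funnel that
counts p = 0.038 as significant must have operated; BH and Bonferroni are
one switch away (`de_procedure`).

## Methylation layer

Beta values are transformed to M-values as `M = log2(β/(1−β))` — the
standard logit2 transform, anchored by β = 0.5 ↦ 0 and β = 0.8 ↦ 2. The
printed one-line formula for this transform is typeset ambiguously
("log2 β / (1−β)"); the logit2 reading is the one that maps 0.5 to 0 and
is the field's convention, so that is what is implemented. Betas of
exactly 0 or 1 are clamped to [1e−6, 1−1e−6] at the reader boundary
(logged per cell); the transform itself rejects out-of-range input rather
than clamping silently.

Probes are excluded when their **mean** detection P across samples
exceeds 0.01, with a strict inequality (a mean of exactly 0.01 is
retained) — the strict reading of "P-value > 0.01 were excluded".

Per-site association fits OLS of M-values on the focal gene's expression.
Two analysis routes exist and the configuration records the choice:

- **marginal** (default): M ~ expression across all samples. The
  site-expression relationship is described in the source analyses as a
  correlation across all samples, and the covariate-adjusted linear model
  is specified there for the *group methylation difference*, not for this
  correlation.
- **covariate-adjusted** (`methylation_covariate_adjust = TRUE`):
  M ~ expression + batch + gender + BMI + age + islet purity + days of
  culture, categoricals expanded to indicator contrasts. Rank-deficient
  designs fail loudly, naming the collinear columns.

Negative-site flagging requires a negative slope *and* adjusted p < α;
the default adjustment is Bonferroni within the gene's probe panel (for a
16-probe panel, p < 0.05/16). Group methylation differences are reported
in percentage points of β·100 (the interpretable scale) through the same
summary-statistic test engine.

## The synthetic study generator

`default_study_config()` freezes the study conditions:

| component | value |
|---|---|
| Ts65Dn glucose | case 10.9 ± 0.9 (n = 14) vs control 8.0 ± 0.3 (n = 17) mM |
| Dp16 glucose | 12.1 ± 0.9 (n = 11) vs 9.7 ± 0.5 (n = 10) mM |
| Ts1Rhr glucose | 11.5 ± 0.4 (n = 12) vs 11.1 ± 0.6 (n = 18) mM |
| Tc1 glucose | 9.4 ± 0.5 (n = 23) vs 13.6 ± 0.6 (n = 23) mM |
| expression cohort | 77 ND vs 12 T2D, focal fold 1.53, log2 noise SD 0.5 |
| methylation cohort | 34 ND vs 15 T2D, 16 probes, 3 planted negative sites |
| planted site anchors | 51.1/57.9/42.3% control-group methylation |

Distributional choices (the published summaries state none, so these are
the generator's own, documented and pluggable):

- per-animal glucose ~ Normal(arm mean, SEM·√n);
- log2 expression ~ Normal, exponentiated to abundance — with equal
  log-scale SD in both groups the ratio of expected abundances equals the
  planted fold exactly;
- planted CpG sites: M ~ intercept + slope·expression + Normal noise
  (SD 1), slope negative and calibrated against the realized expression
  spread to a target |r| = 0.5, intercept anchored at the control-group
  percent; null sites are pure noise around fixed beta levels. Because
  expression is higher in the disease group, the negative slope also
  lowers disease-group methylation, qualitatively matching the anchored
  group differences;
- sites parameterised directly by group summaries are drawn Normal on the
  percent scale (SD = SEM·√n, clamped into (0,100)) — drawing on the M
  scale and averaging back on the beta scale would bias the group mean
  (Jensen), so the percent-scale route is used wherever the target *is* a
  printed percent;
- detection P ~ Uniform(0, 0.005) for clean probes, Uniform(0.011, 0.2)
  for contaminated ones (contamination rate 0 by default: the 16-probe
  panel emulates an already-QC-passed panel);
- HbA1c is a linear function of focal-gene expression plus noise with a
  target correlation of 0.3 — an invented default, flagged as such, since
  the source shows this relationship only graphically;
- methylation covariates (batch, gender, BMI, age, purity, culture days)
  are generated *without* planted links, so covariate adjustment on
  synthetic data costs only degrees of freedom.

What the generator does **not** emulate: count noise and library-size
effects in RNA-seq, probe-type chemistry and normalization artefacts of
Infinium arrays, correlated CpG neighbourhoods, population structure, or
any real linkage between covariates and methylation. Passing tests on
synthetic data therefore validate the *algebra and statistics* of the
screen, not its robustness to real-data artefacts.

## Replication power at the study conditions

A noteworthy property of the frozen conditions, visible in the
end-to-end tests: the weakest affected model's printed effect
(p ≈ 0.035 reconstructed) replicates at α = 0.05 in only ~58% of
simulated studies, and the joint probability that all four models
classify "correctly" *and* the expression and methylation layers pass is
roughly 0.47 per seed. The end-to-end recovery test therefore asserts
that exact recovery of the planted gene is the **modal** outcome across
seeds and that the recovery frequency matches the closed-form power
product — not that every seed recovers it. A screen that recovered its
candidate in (say) 95% of replicates at these group sizes would be
statistically implausible, and the tests would be wrong to demand it.

## Problem sizes used in the test-suite

The suite regenerates all data in code: per-bp interval oracles on
≤1,000 bp genomes; 10,000-replicate null calibrations for the phenotype
and DE engines; 400-seed family-wise error checks for the probe panel;
100-seed probe-recovery and 50-seed end-to-end censuses; 200-seed
parameter-recovery averages. These sizes give Monte-Carlo standard errors
comfortably below the asserted tolerances (2 SE bands throughout).

## Known limitations

- Copy-number states other than 3 vs 2 (monosomy, mosaicism) are not
  represented.
- Orthology is taken as input; no synteny inference is attempted.
- The surrogate DE engine is a two-group location test on transformed
  values, not a count model; for real data, supply precomputed per-gene
  statistics from a dedicated engine.
- The candidate region's gene identities in any real application depend
  entirely on the supplied segment and annotation inputs; the bundled
  60-gene genome is an illustrative synthetic layout, not a
  reconstruction of real breakpoints.
- The final literature-prioritisation step is a user-supplied boolean per
  gene, by design.
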