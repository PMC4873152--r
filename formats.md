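# File formats

All files are plain tab-separated text; `#` starts a comment line where
noted. Coordinates are 0-based half-open (BED convention) in every file
except GFF3, which is converted on read. The only missing-value token in
numeric matrices is `NA`. Decimal commas are never accepted.

## Model segments — BED3+ (`models.bed`)

One dosage-altered (3-copy) segment per line; column 4 names the model.

```
chr16	80000	1090000	Ts65Dn
```

Columns: chrom (string), start (0-based inclusive), end (0-based
exclusive), model name (optional; a file-level default may be supplied).

## Model species (`model_species.tsv`)

Header `model	species`; species is `mouse`, `human` or `mixed`.

## Gene annotation (`annotation_<species>.tsv` or GFF3)

TSV header: `gene_id	symbol	species	chrom	start	end	strand`.
`strand` is `+`, `-` or `unknown`. A GFF3 file may be supplied instead;
only `gene`-type rows are used, with 1-based inclusive coordinates shifted
to the internal convention on read, `ID`/`gene_id` as the identifier and
`Name` as the symbol.

```
gene_id	symbol	species	chrom	start	end	strand
hsa_g42	RCAN1	human	chr21	820000	830000	+
```

## Ortholog map (`orthologs.tsv`)

Two columns, no header: mouse gene id, human gene id. `#` comments
allowed. Under the default one-to-one policy, genes in ambiguous links are
dropped with a warning.

## Phenotype input (`phenotypes.tsv`)

Either per-animal rows with header `model	role	animal_id	value`
(`role` in `case`/`control`, `value` in trait units, e.g. mM glucose), or
summary rows with header `model	role	mean	sem	n`.

## Expression matrix (`expression.tsv`) and sample sheet

Matrix: header row of sample ids, first column `gene_id`, non-negative
normalized expression values. Sample sheet
(`expression_samples.tsv`): `sample_id	group	HbA1c	BMI` with `group`
in `ND`/`T2D`.

## Precomputed DE statistics

`gene_id	log2fc	p_value` (optional `p_adj`); `log2fc` positive =
higher in T2D.

## Methylation bundle

- `methylation_beta.tsv`: probe x sample beta values in [0, 1]; exact 0/1
  are clamped into `[1e-6, 1 - 1e-6]` on read with a logged count.
- `methylation_detection_p.tsv`: same shape, detection P-values in [0, 1].
- `probe_manifest.tsv`: `probe_id	gene_id	chrom	position`.
- `methylation_samples.tsv`: `sample_id	group`.
- `methylation_expression.tsv`: expression of each probed gene across the
  methylation cohort samples (first column `gene_id`).
- `covariates.tsv`: `sample_id	batch	gender	BMI	age	purity	days_culture`.

## Report output

- `evidence.tsv`: one row per candidate gene in ranked order; columns
  `gene_id, in_region, de_log2fc, de_p, de_p_adj, de_pass,
  meth_n_flagged, meth_pass, annotation_flag, n_layers_passed,
  final_pass`; p-values in scientific notation with 6 significant digits.
- `summary.json`: layer counts, phenotype calls, configuration echo,
  provenance (package version, seed, input digests).
- `screen.log`: a short, timestamp-free run log (byte-stable on rerun).

## Study truth (`truth.json`)

Written by the generator only: causal gene, planted fold and probe
slopes, contaminated probes, and the phenotype labels implied by the
configured arm parameters.
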