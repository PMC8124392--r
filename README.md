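# dubscreen

Quantitative identification of deubiquitinase (DUB) substrates from
biotin pull-down, label-free proteomics.

## The problem

Silencing a DUB raises the ubiquitination of its substrates. After a
stringent avidin capture of biotin-tagged ubiquitin conjugates, those
substrates are enriched in the DUB-silenced pull-down relative to a
control-siRNA pull-down, so substrate identification reduces to a
differential-abundance analysis of MaxQuant label-free quantification (LFQ)
intensities across triplicates. `dubscreen` is for proteomics analysts
running such screens: it takes a `proteinGroups`-style table and an
experiment design and produces differential statistics, substrate calls, QC
diagnostics and a queryable result store — with a ground-truth synthetic
generator standing in for raw mass-spectrometry data.

## The method

For each protein, with log2 LFQ intensities $x$ (silenced) and $y$
(control) after row filtering and imputation:

* **Imputation.** Missing values (LFQ = 0, i.e. below detection) in a
  sample column with observed mean $m$ and standard deviation $s$ are drawn
  from the downshifted normal $\mathcal{N}(m - 1.8\,s,\ (0.3\,s)^2)$,
  modelling expression beneath the detection limit. The imputation mask is
  retained.
* **Testing.** $\log_2 \mathrm{FC} = \bar{x} - \bar{y}$ and a two-tailed,
  pooled-variance Student's t-test with $n_x + n_y - 2$ degrees of freedom.
* **Calling.** A protein is a *putative substrate* when (1)
  $\log_2 \mathrm{FC} \ge 1$ with $p < 0.05$; (2) it has $\ge 2$ unique
  peptides; and (3) it contains no imputed value in at least one condition,
  or at most one imputed value in each. Criterion 1 alone defines the
  *initial selection*. Endogenously biotinylated carboxylases (ACACA, HLCS,
  MCCC1, PC, PCCA), ubiquitin and avidin serve as QC controls and are never
  callable; the silenced DUB itself is expected to drop and is tracked
  separately.

All thresholds are adjustable, at analysis time and again at query time
against the store. See the vignette
(`vignettes/dub-substrate-screening.Rmd`) for the full model, parameter
semantics and design decisions.

## Worked example: querying the bundled substrate table

The package ships a transcription of a published five-DUB substrate summary
(56 records for USP1, USP7, USP9X, USP11, USP42) as a store fixture:

```r
library(dubscreen)
st <- dubase_store_from_table1()
st
#> dubase_store: 5 experiment(s), 56 evidence record(s)
#> session thresholds: |log2 FC| >= 1, p < 0.05, unique peptides >= 2, direction up

query_by_dub(st, "USP7")[, c("gene_name", "log2_fc")]
#>   gene_name log2_fc
#> 1       TTK    2.33
#> 2     GABPA    1.66
#> 3     RPL29    1.61
#> 4      RNF2    1.54
#> 5     CREB1    1.44
#> 6    MARCKS    1.21

query_by_substrate(st, "RNF2")[, c("dub_name", "log2_fc")]
#>   dub_name log2_fc
#> 1     USP7    1.54
#> 2    USP42    1.11
```

Six USP7 substrates pass the default thresholds, and RNF2 — the one protein
targeted by two DUBs in this dataset — returns USP7 and USP42. Thresholds
set with `set_thresholds()` persist for the session; records from summary
tables lack p-values and unique-peptide counts and pass those filters
vacuously (each query says so in its `notice` attribute).

## Worked example: a full synthetic screen

```r
syn <- generate_synthetic(synthetic_config(seed = 42L))
res <- run_pipeline(syn$protein_groups, glygly = syn$glygly, seed = 42L)
#> input: 2042 protein groups, 6 samples
#> filter_rows: 1989 kept, removed {reverse=20, contaminant=15, only_by_site=0, no_unique_peptides=0, no_intensity=18}
#> impute: 1914 of 11934 cells imputed
#> differential: 1989 tested, 35 initial selection, 33 putative substrates
#> qc: pass
#> glygly: 43 of 81 sites kept (29 proteins)

score_recovery(res$putative_substrates$gene_name, syn$truth)
#> $sensitivity
#> [1] 0.775
#> $false_discovery_proportion
#> [1] 0.06060606
```

Of the 40 spiked substrates (+2 log2 units in the silenced condition) this
seed recovers 31, with 2 false calls — both censoring artifacts where one
condition happened to fall entirely below detection. `res` also holds the
differential table, volcano dataset, QC report, replicate-correlation
matrix, filtered GlyGly sites and a loaded store; with `out_dir=` every
table is written as CSV. `run_pipeline_config()` drives the same run from a
YAML file, which together with the exported per-stage functions is the
scripting interface of the package.

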