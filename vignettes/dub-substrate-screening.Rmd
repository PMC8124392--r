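---
title: "Calling deubiquitinase substrates from label-free pull-down proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling deubiquitinase substrates from label-free pull-down proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dubscreen)
```

## The screen

Deubiquitinating enzymes (DUBs) remove ubiquitin from their substrate
proteins. When a DUB is silenced by RNA interference, its substrates retain
more ubiquitin, so they become more abundant in a stringent pull-down of the
ubiquitinated proteome — here, an avidin capture of biotin-tagged ubiquitin
conjugates from cultured human cells. Comparing label-free quantification
(LFQ) intensities between control-siRNA and DUB-siRNA samples therefore
turns substrate identification into a differential-abundance problem: a
protein whose enrichment rises significantly upon silencing is a candidate
substrate of that DUB.

`dubscreen` implements the quantitative half of this screen, from
MaxQuant-dialect protein-group tables to a queryable substrate store. The
stages, each exposed as its own function, are:

1. **Row filtering** (`filter_rows()`): reverse-database decoys, potential
   contaminants, proteins only identified by a modification site, proteins
   with no unique peptides, and proteins never quantified are removed, each
   counted once under the first matching reason in that order.
2. **Transformation and imputation** (`log2_transform()`, `impute()`): LFQ
   intensities are log2-transformed; an LFQ of 0 means "not quantified" and
   becomes missing.
3. **Differential testing** (`compute_differential()`): per-protein log2
   fold change (silenced minus control condition means) and a two-tailed,
   equal-variance Student's t-test on the imputed matrix.
4. **Substrate calling** (`call_substrates()`): a three-criterion rule,
   below.
5. **QC and reproducibility** (`qc_report()`, `replicate_correlation()`,
   `overlap_counts()`, `pairwise_containment()`).
6. **Site-level annotation** (`filter_glygly()`, `sites_per_protein()`).
7. **Storage and querying** (`dubase_store()` and friends).

`run_pipeline()` chains stages 1–7 deterministically given a seed.

## The imputation model

LFQ missingness is left-censored: proteins drop out of the data because they
sit near or below the instrument's detection limit, not at random. Deleting
incomplete rows would discard exactly the on/off proteins a silencing screen
is most interested in, so missing values are instead *imputed from a
distribution that encodes "below detection"*. With `m` and `s` the mean and
standard deviation of the **observed** log2 intensities of a sample column,
each missing cell in that column is drawn independently from

$$\mathcal{N}\!\left(m - 1.8\,s,\ (0.3\,s)^2\right).$$

The downshift (1.8) places imputed values in the lower tail of the observed
distribution; the width (0.3) keeps them in a narrow band so they contribute
little spurious variance. Both are expressed in units of `s` — the bare
numbers only make sense as multiples of the observed spread — and both are
tunable (`width`, `downshift` arguments of `impute()`).

Two choices here were genuinely open and are surfaced as options rather than
hard-coded:

* **Per-column vs whole-matrix statistics.** `m` and `s` are computed per
  sample column by default (`mode = "per_column"`), so each sample's
  imputation respects its own depth; `mode = "whole_matrix"` pools
  everything. A column with fewer than two observed values falls back to the
  whole-matrix statistics with a warning.
* **Shared statistics across conditions.** Both conditions are imputed from
  their own columns; nothing couples them.

Draws come from a single seeded generator consumed in row-major cell order,
which makes an imputed matrix bit-reproducible across platforms for a given
seed. The imputation mask is kept alongside the values: downstream code can
always distinguish measured from modelled cells, and the replicate
correlation diagnostic (`replicate_correlation()`) deliberately excludes
imputed cells so the imputation model cannot flatter a data-quality metric.

## The three-criterion substrate call

A protein is a **putative substrate** of the silenced DUB when it

1. shows a log2 fold change (silenced/control) of at least 1 — a doubling of
   its enrichment — with a two-tailed t-test p-value below 0.05;
2. is identified by at least 2 unique peptides; and
3. has trustworthy quantification: no imputed value in at least one
   condition, or at most one imputed value in each condition
   (`imputation_rule()`).

Proteins passing criterion 1 alone form the **initial selection**; the
distinction matters because criterion 1 is purely statistical while 2 and 3
guard against identification and censoring artifacts. QC-panel proteins and
the silenced DUB itself are never callable: the DUB is *expected* to drop
(its own ubiquitinated pool shrinks when it is silenced), and the panel
proteins are controls, not candidates.

Comparison conventions: the fold-change and unique-peptide thresholds are
inclusive (`>= 1`, `>= 2`), the p-value threshold strict (`< 0.05`).
Published summary tables round fold changes to two decimals, so a displayed
value of exactly 1.00 denotes a protein that passed the threshold before
rounding; the inclusive comparison reproduces such tables from their own
printed values. Ties in the ranked output are broken by ascending p-value,
then gene name, so output order is deterministic.

No multiple-testing correction is applied by default — the screen thresholds
raw t-test p-values, and the fold-change and imputation criteria carry most
of the specificity burden. `correction = "bh"` switches category assignment
and calling to Benjamini–Hochberg adjusted p-values for users who want
FDR-controlled lists; it is strictly more conservative and clearly a
deviation from the standard workflow.

Degenerate inputs are handled explicitly rather than left to propagate:
a protein with zero pooled variance gets `t = 0, p = 1` when the condition
means agree and the smallest representable positive p (with a warning) when
they differ; `p = 0` is replaced by the smallest positive double before any
`-log10` transform.

## Quality control

The biotin pull-down brings along endogenously biotinylated carboxylases
(ACACA, HLCS, MCCC1, PC, PCCA) regardless of ubiquitination — they report on
the amount of biological material. Ubiquitin itself reports on the total
captured conjugate pool, and avidin on the resin. None should change upon
silencing one DUB, so `qc_report()` flags any panel member that meets the
significance thresholds in either direction; the report fails if one does.
The ubiquitin identifier set is configurable because the engineered
biotinylatable ubiquitin construct is not a standard database entry; the
default covers the human ubiquitin-coding genes (UBB, UBC, UBA52, RPS27A).
Panel members absent from a dataset are reported as not detected, not as
failures, and an entirely undetected panel passes vacuously with a warning.

## The substrate store

Differential results are ingested **unfiltered** — every tested protein, not
just the called ones — and user thresholds are applied only at query time.
This mirrors how a substrates database should behave: one user's "2-fold,
p < 0.05, 2 peptides" is another's "1.2-fold exploratory list", and volcano
plots must show the sub-threshold points too. The store keeps two logical
tables (`experiments` with methodological metadata, `evidence` with one row
per DUB/protein pair), enforces uniqueness of the (DUB, gene) pair within an
experiment, matches names case-insensitively, and persists session
thresholds until `set_thresholds()`/`reset_thresholds()` changes them.

Records ingested from published summary tables carry fold changes but no
p-values or peptide counts; those fields are `NA`, pass the corresponding
filters vacuously, and every query touching them attaches a notice saying
so. The bundled `dubase_table1()` fixture is exactly such a transcription
(56 records across USP1, USP7, USP9X, USP11, USP42) and powers the worked
examples in the README.

## What the synthetic generator emulates — and what it does not

Real raw mass-spectrometry data is neither small nor redistributable, so the
package validates itself on synthetic screens (`generate_synthetic()`) built
to reproduce the *statistical* structure the analysis assumes:

| feature | model | default |
|---|---|---|
| true log2 abundance | $a_i \sim \mathcal{N}(\mu_0, \sigma_0^2)$ | $\mu_0 = 26$, $\sigma_0 = 2.5$ |
| replicate noise | additive $\mathcal{N}(0, \sigma_r^2)$ per cell | $\sigma_r = 0.3$ |
| substrate effect | $+\delta$ log2 in silenced condition | $\delta = 2$, 40 proteins |
| reduced ubiquitination | $-\delta$ log2 | 10 proteins |
| detection | observed w.p. $\mathrm{logit}^{-1}((v - v_{50})/k)$ | $v_{50} = 22.5$, $k = 1.5$ |
| unique peptides | $1 + \mathrm{Poisson}(\lambda)$ | $\lambda = 6$ |
| decoys / contaminants | flagged rows | 20 / 15 |
| QC panel | effect 0, abundance $\mu_0 + 3$, always observed | 7 genes |

The logistic detection model gives dropout concentrated at low abundance —
exactly the left-censoring the downshifted-normal imputation is meant to
model — and the effect is applied on the log2 scale so a spike of 1.0 equals
the screen's 2-fold criterion. Default depth (2000 quantifiable proteins)
approximates a mid-range instrument. The generator does **not** emulate:
peptide-to-protein roll-up, shared-peptide protein grouping, correlated
(batch) noise between samples, intensity-dependent variance, ragged
replicate depth across instruments, or any spectrum-level process. Passing
recovery tests on this generator therefore demonstrates that the pipeline's
statistics behave as designed under its own assumptions — not that those
assumptions exhaust real LFQ data.

Validation uses triplicate screens of 2000 proteins averaged over 20
generator seeds, and smaller screens (100–300 proteins) for structural
properties; these sizes keep each check to seconds while leaving Monte-Carlo
error well below the margins being tested.

One behaviour of the workflow is worth knowing about and is visible in the
recovery tests: a null protein whose control replicates all happen to fall
below detection is imputed ~4 log2 units down, passes the imputation rule
(one condition fully observed), and can show a large, nominally significant
fold change. These censoring artifacts are the dominant false-positive mode
of the downshifted-imputation design — roughly 3–4 per 2000-protein screen
at the defaults — and the main reason measured false-discovery proportions
hover near, sometimes above, 10%. Symmetrically, a single imputed control
replicate inflates the pooled variance and can push a genuine substrate's
p-value past 0.05, which caps sensitivity below what the effect size alone
would suggest. Both behaviours are faithful to the workflow being
implemented, not artifacts of this implementation.

## Known limitations

* Protein groups are treated as atomic; no attempt is made to resolve shared
  peptides or isoforms beyond taking the first gene symbol.
* The t-test assumes equal variances; no moderated (empirical-Bayes)
  alternative is provided.
* GlyGly sites annotate records but are not differentially tested.
* The store is in-memory per session; persistence is via CSV export and
  re-ingest rather than a database file.
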