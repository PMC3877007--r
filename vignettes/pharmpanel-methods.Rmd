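---
title: "pharmpanel: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pharmpanel: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmpanel)
```

`pharmpanel` analyses compound screens run across panels of cancer cell
lines: it turns raw fluorescence plate data into IC50s, scores
constant-ratio drug combinations for synergy, clusters compounds by their
potency fingerprints, screens gene expression for correlates of potency,
summarises hit lists by GO Biological Process frequencies, and puts IC50s
in the context of clinical plasma exposures. This vignette explains the
models, the tunable parameters, what the synthetic-data generators do and
do not emulate, and the numerical choices made where the design was open.

## Dose-response model and IC50

Each plate experiment tests one compound against one cell line at ten
concentrations in duplicate, with six untreated control wells. Signals
are normalised as T/C = mean treated signal / mean control signal;
`fa = 1 - T/C` is the fraction of cells affected. Negative `fa`
(apparent growth stimulation) is flagged and retained, never clipped.

`fit_4pl()` fits the four-parameter logistic

$$\mathrm{TC}(D) = \mathrm{bottom} + \frac{\mathrm{top}-\mathrm{bottom}}
{1 + (D/\mathrm{ec50})^{h}}$$

by least squares on the log10-dose axis. The reported IC50 is the
**absolute** IC50 — the dose where the fitted curve crosses T/C = 0.5,
i.e. half-maximal inhibition relative to the untreated control — rather
than the relative midpoint `ec50` (kept for diagnostics). This makes
censoring well defined: if the crossing lies above the highest tested
dose the entry is censored `above_max` and written as `">X"`; a curve
whose floor sits above 0.5 never crosses at all and is likewise censored,
even though its `ec50` is finite.

Numerical choices: box constraints bottom ∈ [−0.2, 1], top ∈ [0.5, 1.5],
hill ∈ (0, 10]; a smooth quadratic penalty keeps bottom < top; a
multi-start over hill seeds {0.5, 1, 2} guards against local minima;
L-BFGS-B with `factr = 1e4`. On exact synthetic points the fit recovers
the generating parameters to ~1e-4. Independent experiments of the same
compound × line are aggregated by `aggregate_ic50()` as the arithmetic
mean of the in-range IC50s; a mixture of censored and in-range fits is
flagged `partial`, and an all-censored set stays censored at the highest
tested dose. (The aggregation policy under censoring is a package choice;
the source method description is silent.)

## Median-effect analysis and the combination index

The median-effect model, `fa/fu = (D/Dm)^m` with `fu = 1 - fa`, is
linear in log–log form; `median_effect_fit()` estimates the slope `m`
and the median-effect dose `Dm` by OLS of `log10(fa/fu)` on `log10 D`,
and reports the Pearson `r` of the plotted points as the linearity
diagnostic (cell-culture data typically achieve r > 0.90, which the
synthetic world reproduces: median r ≈ 0.98 at 10% CV noise). Points
with fa outside (0, 1) cannot be plotted; they are excluded and
recorded, preserving OLS validity — a deliberate alternative to
truncating them into range, which would bias the line.

For a pair co-diluted at a constant ratio, `combination_index()` reads
the total mixture dose producing effect `fa` from the mixture's own fit,
splits it by the ratio into component doses, and relates them to the
isoeffective monotherapy doses:

$$\mathrm{CI} = \frac{(D)_1}{(D_x)_1} + \frac{(D)_2}{(D_x)_2}
\; \left(+\; \frac{(D)_1 (D)_2}{(D_x)_1 (D_x)_2}\right)$$

the bracketed product term being added only in the mutually
*nonexclusive* variant, which therefore always exceeds the exclusive
(classic isobologram) value. CI < 1 is synergism, CI = 1 additive,
CI > 1 antagonism; the additive band is strict (ε = 0) by default and
configurable for noisy data. Because published single-CI tables rarely
state their effect level, `ci_profile()` reports a grid
{0.50, 0.75, 0.90} with fa = 0.5 as the headline.

## Potency-fingerprint clustering

`ward_cluster()` implements Ward's minimum-variance agglomeration on
Euclidean distances between compound log10-IC50 profiles, via the
Lance–Williams update on squared distances. Two choices matter:

* **log10 scale** (default): IC50s span orders of magnitude, and
  raw-scale Euclidean distances would be dominated by the most resistant
  lines. Both scales are exposed.
* **Deterministic tie-break**: among equally good merges the lowest pair
  of cluster indices wins, so the tree is reproducible for a given row
  order. The merge sequence is verified in the tests against a
  brute-force agglomerator that recomputes the total within-cluster sum
  of squared deviations at every step.

Censored entries are imputed at their bound by default (`">30"` enters
as 30 µM — a conservative lower bound on distance) or the line can be
dropped; only lines complete across all compounds are used, and missing
(untested) entries are never imputed. Trees export to Newick
(ultrametric; branch lengths are merge-height differences) and convert
to `hclust` for cutting and plotting.

## Expression–potency screen

Genes are first filtered by typical signal: mean natural-scale intensity
across lines > 500 (the floor below which summarized array intensities
are mostly noise). The mean was chosen as the filter statistic because
the floor is described as a per-gene typical level; median and max are
selectable. For each surviving gene, Pearson correlation `r` between its
expression and the compound's IC50s across lines is tested with

$$t = \frac{|r|\sqrt{n-2}}{\sqrt{1-r^2}}, \qquad p = 2\,P(T_{n-2} > t)$$

and genes with p < 0.0005 (raw, two-sided; positive and negative
correlations grouped) are reported, sorted by p. A gene with r < 0 is a
*sensitivity* gene (higher expression, lower IC50); r > 0 marks
*resistance*. The Bonferroni per-test threshold for the screened
universe (0.05/16,722 ≈ 3×10⁻⁶ for a full array) is attached as context
but deliberately not applied — the downstream GO-frequency aggregation
is robust to individual false positives, whereas Bonferroni would thin
the lists severely. Correlation is computed on natural-scale IC50s by
default (matching the screen this package models); a log10 switch shares
all code below the transform.

`term_frequencies()` then counts, for each GO-BP term, how many hit
genes carry it — once per distinct term per gene, no DAG propagation,
raw frequencies rather than enrichment statistics (that is the quantity
the histograms display); `top_k()` keeps the top 30 with alphabetical
tie-breaks.

## Pharmacokinetic context

`mass_to_molar()` converts plasma concentrations reported in ng/ml to
µM by dividing by the molecular weight (1 µg/ml ↔ 2 µM at MW 500, 3 µM
at MW 333). `exposure_coverage()` forms the per-line ratio
Cmax(µM)/IC50 and the fraction of lines whose IC50 is reached at peak
plasma concentration; censored IC50s count as *not* covered (their true
value exceeds the bound) but stay in the denominator. A transcription of
published human PK records ships as
`inst/extdata/pk_human_records.tsv`; ranges were collapsed to midpoints
and minute-scale half-lives converted to hours (noted in the file
header). Molecular weights are user-supplied configuration — the package
does no structure handling.

## The synthetic world

The generators state a world and the tests measure it; none of their
defaults were tuned against test outcomes.

* **Plates** (`gen_plate_experiment`): signals are
  `control_mean × TC(D) × lognormal(cv)`. The noise is multiplicative
  lognormal with unit mean because fluorescence plate readers show
  roughly constant CV; 10% CV and half-log dilutions are package
  choices (the modelled assay protocol does not state them). With
  `noise_cv = 0` every signal lies exactly on the model curve, which the
  tests assert bit-for-bit.
* **Combinations** (`gen_combination_dataset`): restricted to equal
  slopes `m`, where a Loewe-additive mixture is itself exactly
  median-effect with `Dm_mix = psi / (r1/Dm_A + r2/Dm_B)`. The
  interaction factor `psi` then *equals* the exclusive CI at every
  effect level — the closed-form oracle used throughout the tests.
  Unequal-slope additivity has no closed form and is out of scope.
* **Potency panels** (`gen_potency_panel`): log10-IC50 profiles built
  from shared group latents so within-/between-group population
  correlations are 0.95/0.2 by default; cutting the Ward tree at the
  group count recovers the planted membership in ≥95% of simulations.
* **Expression** (`gen_expression_panel`): background genes are
  lognormal with a configurable fraction of baselines below the
  500-signal floor; planted genes mix the standardized potency row with
  independent noise so the population |r| equals `target_abs_r`. The
  planted intensity scale defaults to mean 5000, sd 350: the truncation
  at zero then sits >14 sd away, so the realised correlation converges
  to the target (checked at 2000 lines within ±0.02) even for
  heavy-tailed potency rows — with a wider sd the truncation visibly
  attenuates |r|.

What the synthetic world does **not** emulate: probe-level microarray
data, normalization artefacts, correlated gene–gene structure, plate
positional effects, or cell-line biology. A green recovery test
establishes that the estimators invert the stated generative model at
the stated noise level — not that they reproduce any particular
published biological result, which would require the physical panel and
its expression dataset.

## Pipeline and reproducibility

`run_pipeline()` chains every stage on a configuration
(`default_config()`): each random block has its own sub-seed derived
once from the master seed, so toggling a stage off leaves the other
outputs byte-identical; no global RNG state is touched (generators save
and restore `.Random.seed`). All tables carry a header comment with the
package version and an MD5 hash of the configuration, and
`run_metadata.json` echoes the full configuration and seeds. The CLI
accepts JSON configuration files (YAML support was dropped as the
environment provides no YAML parser).

## Known limitations

* The 4PL parameterization and censoring rules of commercial plate
  software are unpublished; numerical equivalence with any particular
  vendor's IC50s cannot be asserted.
* The combination generator's equal-slope restriction means antagonism
  and synergy are modelled only through the dose-scaling factor `psi`.
* The expression screen treats matrix rows as the unit (no
  probeset-to-gene collapsing), and the permutation robustness of the
  planted-gene tests says nothing about confounding in real panels.
* `aggregate_ic50` averages on the arithmetic scale; for IC50s spanning
  decades a geometric mean is arguably better, but the modelled protocol
  states the plain mean of experiments.
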