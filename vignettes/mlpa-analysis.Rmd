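---
title: "MLPA dosage analysis with mlpaflow: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MLPA dosage analysis with mlpaflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlpaflow)
```

## The measurement and its nuisances

An MLPA reaction co-amplifies up to ~50 ligated probe pairs, each yielding
a product of unique length; a capillary run turns these into peaks whose
height (RFU) or area is roughly proportional to the copy number of the
probed locus. Two nuisance scales sit on top of that signal: a per-sample
factor (DNA input, ligation efficiency, injection) and a per-probe factor
(amplification efficiency, which also decays with product length). Writing
the data as a traces × probes matrix $Y$, the model is multiplicative and
we estimate a ratio matrix

$$x_{ij} = \frac{y_{ij}}{r_i\, c_j},$$

deliberately on the original scale rather than logs: losses and gains are
integer copy ratios (0, 0.5, 1, 1.5, 2 of the diploid level), and 0 is a
meaningful value that logs cannot carry.

All location estimates are medians. Medians over any set containing
missing cells skip them; a median over an *empty* set is a hard error with
the offending sample or probe named, never a silently propagated `NaN`.
Even-count medians are the mean of the two central values. A row or column
factor below $10^{-9}$ of the grand median aborts with an error: dividing
by a near-zero median corrupts every ratio in that row or column, and the
right response is exclusion, not a warning.

## Why not plain row/column medians

If aberrations are sparse, dividing each row by its median and each column
by its median works. It breaks exactly where MLPA is most interesting:
a tumour with more than half of its probed loci deleted has a row median
at the *deleted* level, and dividing by it inflates every ratio in the
row — unaltered loci drift toward 1.3–2 and can be miscalled as gains.
The package keeps this naive scheme available as
`naive_median_normalize()` because the contrast is the clearest regression
test of the calibration procedure: on cohorts with 11 of 12 focus probes
deleted, the calibrated pipeline keeps unaltered probes at 1.0 within a
few percent while the naive scheme shifts them above 1.1 (the test suite
computes both).

## The calibration procedure

The implemented algorithm estimates its factors from the least
contaminated part of the data and only then scales everything:

1. **Provisional row factors** $\check r_i$: each sample's median signal.
2. **Column factors** $c_j$: each probe's median across the
   row-normalised **normal** samples. Normals are diploid everywhere by
   assumption, so these columns estimate pure probe efficiency; computing
   them across tumours too would drag loss/gain columns toward their
   aberrant ratios. After this step every probe column has median exactly
   1 across the normal samples.
3–4. The kit's flagged **reference probes** (loci chosen by the kit
   vendor as unlikely to change) restricted to normal samples form the
   stability panel.
5. Steps 1–2 are re-run from scratch on that sub-matrix, so stability is
   judged free of focus-probe influence.
6. **MAD** per reference probe: the median over normal samples of
   $|x - 1|$. Note this is deviation from the *expected* ratio 1, not
   from the probe's own median — a biased-but-stable probe scores worse
   than under the classical MAD, which is what we want in a calibrator.
7. The $k$ probes with the smallest MAD become the **calibration
   probes**. Ties break by ascending probe index so runs are
   reproducible. $k$ defaults to 5; on the default synthetic panel,
   moving $k$ between 3 and 7 shifts recovered stratum means by less
   than 0.05 (tested), so the choice is not delicate. Selection needs an
   adequate normal panel: ranking 8 reference probes by MAD reliably
   flags a 3×-noisier probe with ~16 normals, while very small panels
   (2–4 normals, a realistic diagnostic batch) still calibrate well but
   rank stability noisily.
8. **Final row factors**: every sample — tumour and normal alike — is
   divided by the median of its calibration-probe values from step 2,
   pinning each row's calibration median at exactly 1.

Because step 8 rescales per row, the provisional factor $\check r_i$
cancels algebraically in the final $X$; we compute it for all rows (not
only normals) and record it in the model for audit, a uniform reading of
a step the original description leaves ambiguous. Two exactness
properties follow from the construction and are tested at $10^{-12}$:
a separable matrix $y_{ij} = a\,u_i v_j$ normalises to $X \equiv 1$, and
any per-sample rescaling of arbitrary data leaves $X$ untouched. General
per-*probe* rescalings of noisy data are absorbed only approximately —
median-based column factors are re-estimated from reweighted rows — which
is the correct behaviour for a robust estimator and worth knowing when
comparing runs.

## Quality indicators

* **Q1** = height(94 bp ligation-dependent fragment) / median height of
  the observed 64/70/76/82 bp DNA-dependent fragments. Pass is strictly
  greater than 5. Low Q1 flags failed ligation, but low-Q1 traces can
  still yield usable patterns, so the flag is advisory: `qc_report()`
  never removes a trace.
* **Q2** = median height of the first $\min(20, n)$ probe peaks by index
  (ascending product size). Below 450 RFU the trace is too weak; above
  4000 RFU the detector saturates. The bounds are read literally as
  strict ("below", "over"), so exactly 450 and exactly 4000 pass; the
  test suite sweeps every integer height and asserts the pass set is
  precisely $[450, 4000]$.
* **Q3** = median signal of the long half of the probes over the short
  half, both halves taken by probe index. For odd $n$ the middle probe
  joins the long half — long probes run lower, so this makes the check
  marginally more conservative. Pass is $\ge 0.5$.

Q1 and Q3 are ratios and scale-invariant; Q2 scales with the trace. All
three always use peak heights, whichever measure the analysis uses,
because the thresholds are height-calibrated.

## Calling and replicates

A cell is a loss when $x < 0.8$ and a gain when $x > 1.25$; both
inequalities are strict, so a value exactly at a threshold is normal.
The defaults bracket the pure-tumour expectations of 0.5 and 1.5 with
room for normal-DNA dilution (a 50% tumour gives 0.75 and 1.25); they are
configurable but must satisfy $0 < t_{loss} < 1 < t_{gain}$. Missing
cells stay missing and are counted in neither tally. Technical replicates
are combined per probe by the median — robust to one aberrant replicate
in triplicates and the midpoint for duplicates — with individual
replicate values kept for the per-sample plot. Every rendered figure
(heat map, sample plot) writes a tab-delimited twin holding the exact
numbers displayed, so downstream comparisons never parse images.

## The project store and authorization

Analyses live in a plain directory (`samples.tsv`, `kits/`, `runs/`,
`analyses/<id>/settings.json` + `results/`), replacing a GUI database
with diffable text. A settings hash (MD5 over the canonical JSON of all
non-visual settings) identifies the analysis configuration. Authorizing
an analysis freezes it: exclusions and thresholds are rejected
afterwards, while sorting and axis-scale options remain free and do not
enter the hash. Re-running an authorized analysis reproduces its result
files byte-for-byte, which the suite asserts.

## What the simulator emulates — and what it does not

`simulation_spec()` encodes the generative model: expected signal
$\text{base} \cdot s_i \cdot e_j \cdot d(\ell_j) \cdot \rho_{ij}/2$ with
lognormal per-sample scale $s_i$ (sdlog 0.2), lognormal probe efficiency
$e_j$ (sdlog 0.25), length decay $d$ of 0.8 per 100 bp (centred
mid-kit, the effect Q3 watches), and effective copy ratio
$\rho = f\,cn + (1-f)\cdot 2$ for tumour fraction $f$. Noise is
multiplicative lognormal with CV 5% (mean exactly 1), on the original
scale, matching the ratio reasoning above. Control fragments run at
250 RFU (DNA-dependent) and 2000 RFU (ligation), i.e. a healthy Q1 of
~8. Copy number 0 leaves baseline noise (SD 10 RFU) under a 20 RFU
detection limit, so homozygous deletions arrive as a mixture of
near-zero peaks and missing probes — both paths are tested. Defaults
describe the validation cohort used throughout: 8 normals + 8 tumours,
20 probes (8 reference), tumours carrying 6 single-copy losses and 4
single-copy gains at tumour fraction 1, one replicate, seed-determined
and byte-reproducible.

The simulator is honest about what it is: peaks are drawn directly, so
it cannot expose errors in electrophoresis preprocessing, size-calling
drift, pull-up/stutter artefacts, cross-kit contamination, or the
partial-degradation patterns of real FFPE DNA beyond a global scale and
length-decay knob. Passing recovery tests therefore demonstrates that
the statistical chain is correct under its stated model, not that any
particular wet-lab run is in control — that is what Q1–Q3 and the
analyst's judgement are for.

## Validation sizes

The shipped suite runs the full pipeline on 16-trace × 20-probe cohorts;
ratio recovery averages 20 seeded cohorts; the median/MAD/selection
steps are cross-checked against a loop-based brute-force oracle on 1000
random 10 × 12 matrices; MAD ranking uses 200 replications of a
16-normal panel; the Q2 window is swept over 4500 integer heights. These
sizes make the whole suite run in well under a minute while keeping the
Monte-Carlo assertions comfortably away from their bounds.

## Known limitations

* Tumour percentage and DNA index are stored as metadata but not folded
  into allelic-state inference; interpretation of diluted ratios stays
  with the analyst.
* Raw electropherograms (.fsa) are out of scope; a peak table from
  fragment-analysis software is required.
* Column factors assume the normal samples in the analysis are genuinely
  diploid at every probe; a contaminated "normal" biases the probe it
  affects.
* Reference pooling across experiments run at different times is
  deliberately unsupported (a warning fires when runs are mixed): probe
  efficiencies drift between batches.
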