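---
title: "Assessing peptide-level linearity with TMT multipoint internal calibration curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing peptide-level linearity with TMT multipoint internal calibration curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtcal)
```

## The problem

In proteome-wide relative quantification, peptide reporter signals are
compared between conditions without knowing whether each peptide responds
linearly to loaded amount, or whether its endogenous signal even lies inside
a linear response region. Targeted assays solve this with calibration
curves; whole-proteome experiments usually cannot, because external curves
ignore matrix effects and spiking isotopologue standards for every peptide
does not scale.

Multiplexing a serial dilution of a pooled digest into the same TMT
experiment as the biological samples gives *every identified peptide* an
internal, in-matrix calibration curve at essentially no extra instrument
time. `tmtcal` implements the downstream analysis: classifying each
peptide's quantitative linearity from its curve, gating endogenous
measurements to the established linear range, calibrating intensities
through the per-peptide regression lines, and quantifying proteins with or
without the nonlinear peptides.

The package starts from a peptide- or PSM-level quantification table (a
Proteome Discoverer-style export or a generic TSV); spectra processing,
search and FDR control are upstream and out of scope.

## The experimental design

The canonical layout multiplexes eleven TMT channels: two conditions in
triplicate at 25 µg each, plus a five-point serial dilution of a pooled
digest — equal parts of all biological replicates — at 0.25, 1.25, 6.25, 25
and 125 µg:

```{r design}
tmt11_calibration_design()
```

The pool is an equal mixture of both conditions, so each calibration point
carries the *mean* response of a peptide across conditions, and the 25 µg
point is the 1:1 reference against which known dilution ratios can be
checked. `read_design()` reads the same structure from a small YAML file
for other layouts; any design needs at least three calibration points with
distinct amounts.

## Reporter-ion impurity correction

Each TMT reagent carries isotopologue impurities that deposit a known
fraction of its signal −2/−1/+1/+2 Da away, i.e. into neighbouring
reporter channels. From a vendor certificate-of-analysis table
(`read_impurity_spec()`), `build_impurity_matrix()` assembles the mixing
matrix \(M\) with \(M_{ij}\) the fraction of reagent \(j\) observed in
channel \(i\): the diagonal is one minus *all* declared spills (signal
spilling outside the plex is lost, not redistributed), and off-diagonals
follow reporter-mass adjacency — in the interleaved TMT-11 channel order
(126, 127N, 127C, …) a ±1 Da spill moves *two* positions, so 126 + 1 Da
lands in 127C.

`correct_intensities()` then solves \(y = Mx\) for the true signals with
nonnegative least squares (the default). Plain inversion can return
negative intensities whenever a weak channel neighbours strong ones; NNLS
cannot, which is why it is the default, with `"inverse-clip"` available for
comparison. Missing channels are imputed as zero for the solve and restored
to missing afterwards.

## Linearity classification

For each peptide, amounts and intensities are log-transformed (base 10 by
default; the dilution series spans 2.7 decades, and classification is
base-invariant because R² is) and an ordinary least-squares line is fit to
all valid points. A peptide needs at least three valid (non-missing,
positive) calibration values to be assessed at all; below that it is
*unquantifiable*. The classifier then iterates:

1. Fit all valid points; compute R² (the squared Pearson correlation —
   identical to \(1 - SS_{res}/SS_{tot}\) for simple OLS with intercept).
2. If R² does not exceed 0.95 and more than three points remain, remove
   the lowest-concentration point and refit.
3. Stop when the fit passes or only three points remain.

The number of points remaining when the fit passes is the peptide's count
of **linear points**: 5 is a *complete* curve, 4 *nearly complete*, 3
*partial*; if even the top three points fail, the peptide is *nonlinear*
("fewer than three linear points"). Removal is always by lowest
concentration — never by largest residual — because the expected failure
mode is a background floor lifting the faint end of the curve off the
log-log line; a removed set is therefore always an ascending prefix of the
valid amounts, a property the test suite asserts.

Numerical conventions worth stating:

* the comparison is strict (R² > 0.95), and the threshold is configurable;
* a two-point fit is reported with R² = 1 but never classified;
* a perfectly flat response gets R² = 0 (the squared correlation is
  undefined at zero variance), so flat peptides land in *nonlinear* rather
  than passing as a zero-slope "line";
* *unquantifiable* (< 3 valid values) is kept distinct from *nonlinear*
  (≥ 3 valid values, no passing suffix); summaries report both the split
  and the merged view, since a donut-style summary typically merges them.

`classify_table()` applies this per record and also reports where the
missing calibration points sit; with a detection floor, missingness
concentrates mechanistically at the lowest amount. With several batches
(one quantification file per TMT mix), `cross_batch_consistency()` reports
how often peptides with complete/nearly complete curves in one batch keep
that behaviour in the others.

## Linear-range gating and calibration

A peptide's **linear range** is the interval spanned by its retained
calibration points. `assess_range()` checks each endogenous sample-channel
intensity against it. The default criterion is intensity bounds — the
log-intensity must lie inside the closed interval of the retained points'
log-intensities — because it expresses "the range established by the
curve" without passing through the fitted slope; an amount-bounds mode
(back-calculated amount inside the retained amounts) is provided because
the operational definition is genuinely open. Boundaries are inclusive: a
measurement exactly at the lowest retained point is within range.

`calibrate_intensity()` inverts the peptide's line,
\(\hat a = b^{(\log_b I - \beta_0)/\beta_1}\), reporting µg-equivalents of
the pooled digest. Near-flat lines amplify intensity noise enormously when
inverted, so calibration is refused when \(|\beta_1| < 0.1\) (the slope
floor, configurable); such peptides keep their raw intensities and are
dropped from calibrated rollups rather than mixed in on a different scale.

## Protein quantification: all vs linear-only peptides

`quantify_proteins()` summarises peptides to proteins by the per-channel
median of log2 values (intensity, or calibrated amount), compares
conditions with a Welch t test on the channel summaries, and adjusts
p-values with Benjamini–Hochberg. This deliberately simple, documented
stand-in replaces mixed-model inference engines because the package's
contribution is the *peptide selection* step, not the inference machinery;
`select_peptides()` exports the selected peptide list for any external
tool.

Selection modes:

* `all` — every quantified peptide;
* `linear_only` — peptides whose category reaches `min_category`
  (default `nearly_complete`, i.e. four or five linear points, matching the
  "complete or nearly complete" emphasis; `partial` relaxes to three) and
  whose endogenous channels lie within their linear range (`range_rule`:
  all channels by default).

`compare_selection_modes()` puts the two result sets side by side and
flags proteins that cross the significance boundary in exactly one mode —
the situation where a floor-dominated nonlinear peptide dilutes a true
change. `ratio_to_reference()` uses the dilution points themselves as
samples of known relative abundance: each protein's observed log2 ratio of
a dilution channel to the 1:1 calibration point is compared with
\(\log_2(\text{amount}/25)\), and the dispersion of the deviations is
summarised as the median absolute deviation *from the expected value*
(median |observed − expected|, capturing bias as well as spread). Ratios
are computed per protein after rollup by default, per peptide on request.
No global normalisation (e.g. channel median-centering) is applied by
default; a rollup option exists but the workflow describes none.

## The synthetic-data generator

`simulate_experiment()` emulates the structure of the deposited experiment
at desk scale. Per peptide and channel:

\[ I = c \cdot a \cdot \phi \cdot \varepsilon + f \]

with response coefficient \(c\) (units per µg), loaded amount \(a\),
fold-change factor \(\phi\) (1 for untreated; \(2^{\Delta}\) for treated
channels of a changed protein; \((1 + 2^{\Delta})/2\) for the pool
channels, which mix both conditions equally), lognormal noise
\(\varepsilon\) with CV 0.1 by default, and an additive background floor
\(f\). Intensities below the detection threshold become missing — so
missingness at the lowest dilutions *emerges* rather than being imposed.
`add_background_offset()` reproduces the constant-offset robustness
experiment (offsets such as 20, 50, 200 units added to every measured
value).

Generator defaults, chosen once as the package's study conditions:

* **Scale**: median coefficient 2000 units/µg, so the median lowest
  calibration point sits at 500 units and the offset grid 20/50/200 spans
  mild to substantial perturbations of the faint end — the grading the
  offset experiment presumes.
* **Dynamic range**: the coefficient is hierarchical, a protein-abundance
  factor (lognormal, sdlog 1.8) shared by a protein's peptides times a
  per-peptide ionisation factor (sdlog 0.9) — a roughly four-decade
  marginal dynamic range with most variance at the protein level, as in
  real proteomes. Peptides of one protein must share abundance for
  protein-level effects (a whole protein falling into the floor) to exist.
* **Noise**: multiplicative CV 0.1; the constant-offset experiments add
  only the additive term, so the multiplicative term can be zeroed for
  noiseless analyses.
* **Effects**: 20% of proteins changed by default, log2 fold-change ±1.

The generator also returns ground truth, including each peptide's
*analytically expected* linear-point count under the configured floor: with
no noise, the floor lifts the point at amount \(a\) off the log-log line by
exactly \(\log(1 + f/(ca))\), and running the deterministic classifier on
these expected signals predicts what the stochastic run should produce.

For studies of sensitivity-challenged regimes (low-input or single-cell
settings, where many peptides sit near the noise floor), the documented
**low-input scenario** lowers the median coefficient to 50 units/µg
(median 1:1 signal 1250 units) with floor/offset 200 units. The dispersion
and fold-change-recovery analyses in the acceptance suite run under this
scenario: at standard input the R² classifier demotes very few peptides —
smooth floor curvature across 2.7 decades barely dents a correlation
coefficient — so the all-peptide and linear-only selections nearly
coincide and there is nothing for the comparison to show.

What the generator does **not** emulate: co-isolation interference and ion
statistics (interference suppression is an acquisition-level property),
retention-time structure, fractionation, peptide-level missingness that is
not intensity-driven, and shared/razor peptides. Passing tests therefore
demonstrate the correctness and internal consistency of the algorithms
under a clean generative model, not performance on real spectra.

## Known limitations

* **R² is a weak curvature test.** Across a 2.7-decade dilution range a
  smoothly floor-flattened curve can retain R² > 0.95; such peptides keep
  contaminated low points in their "linear" range and their fitted slopes
  drop below one.
* **Line calibration overstretches under additive backgrounds.** Inverting
  a fitted line divides the (floor-compressed) endogenous log-ratio by the
  global slope, while the compression at the 1:1 level corresponds to the
  *local* elasticity there, which is always closer to one. Calibrated
  fold-changes of contaminated-but-classified-linear peptides therefore
  overshoot. In severe (low-input) regimes the selection step removes
  enough compressed proteins that calibrated linear-only quantification
  still beats raw all-peptide quantification; in mild regimes the raw
  pipeline on linear peptides is the safer choice — which mirrors the
  observation that direct and calibrated fold-changes are similar when
  most peptides are comfortably within range.
* The Welch-plus-BH stand-in ignores peptide-level variance structure and
  batch effects; it is calibrated under the null in simulation, but users
  wanting moderated or mixed-model inference should export the selected
  peptides to a dedicated engine.

## Problem sizes

The test and acceptance workloads use 40–150 proteins with 2–6 peptides
each (a few hundred peptides, eleven channels), 20 seeds for paired
comparisons (dispersion, fold-change recovery) and 50 seeds for null
calibration, with 1000 mixed-regime peptides for the classifier-oracle
equivalence check — sizes at which every property asserted is stable
across seeds while a full run stays in the minutes range on one CPU.

## A worked run

```{r worked}
sim <- simulate_experiment(sim_config(n_proteins = 50, seed = 7))
lin <- classify_table(sim$table)
lin
ass <- assess_table(sim$table, lin)
res_all <- quantify_proteins(sim$table, lin, ass, mode = "all")
res_lin <- quantify_proteins(sim$table, lin, ass, mode = "linear_only")
cmp <- compare_selection_modes(res_all, res_lin)
cmp$n_discrepant
ratio_to_reference(sim$table, lin, "130C")
```
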