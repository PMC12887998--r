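# tmtcal

Proteome-wide multipoint internal calibration curves for TMT
quantification: per-peptide linearity assessment, linear-range gating and
calibration, and protein quantification with or without nonlinear
peptides.

## The problem

Relative quantification in TMT proteomics compares peptide reporter-ion
intensities between conditions, usually without knowing whether each
peptide responds linearly to the amount loaded — or whether its endogenous
signal even falls inside a linear response region. Multiplexing a serial
dilution of a pooled digest (e.g. 0.25 / 1.25 / 6.25 / 25 / 125 µg on five
channels of a TMT-11 plex, alongside two conditions in triplicate at
25 µg) gives **every identified peptide its own internal calibration
curve**, acquired in the same matrix and the same run as the samples.

`tmtcal` implements the analysis downstream of the search engine:

* readers for peptide/PSM quantification tables (Proteome
  Discoverer-style exports or generic TSV) with the standard
  quantification-flag filtering, plus a YAML channel-design format;
* reporter-ion isotopic impurity correction (vendor −2/−1/+1/+2
  percentages → mixing matrix → nonnegative least-squares solve);
* the iterative linearity classifier: fit log intensity vs log amount by
  OLS; while R² ≤ 0.95, drop the lowest concentration and refit; the
  points remaining when the fit passes are the peptide's *linear points*
  (5 = complete, 4 = nearly complete, 3 = partial, otherwise nonlinear);
* linear-range gating of endogenous intensities and calibration through
  the per-peptide regression line, `amount = 10^((log10 I − b) / m)`;
* protein rollup (median of peptide log2 values per channel), Welch t
  test and Benjamini–Hochberg adjustment, under *all-peptide* vs
  *linear-only* peptide selection, with a discrepancy report between the
  two;
* a seeded synthetic-data generator for dilution-series experiments with
  additive background floors, plus the constant-offset robustness study.

## A worked example

A simulated low-input experiment (median 1:1 signal 1250 units, additive
background floor of 200 units) shows what the workflow reports:

```r
library(tmtcal)

sim <- simulate_experiment(sim_config(n_proteins = 50, coef_meanlog = log(50),
                                      background_floor = 200, seed = 7))
lin <- classify_table(sim$table)
lin
#> linearity_table: 191 peptide records (191 with >= 3 valid calibration values)
#>        complete nearly_complete         partial       nonlinear  unquantifiable
#>              58              55              62              16               0
#> complete or nearly complete: 59.2%
```

The background floor has flattened the faint end of many curves: only 59%
of peptides keep four or five linear points, and 16 peptides have no
passing three-point fit at all. Using the dilution channels as samples of
known relative abundance, restricting to linear peptides visibly tightens
protein ratios at the lowest dilution (expected log2 ratio
log2(0.25/25) = −6.64):

```r
ratio_to_reference(sim$table, lin, "129C", mode = "all")
#> ratio_dispersion [all]: 129C vs 1:1, expected log2 ratio -6.644, n=50, MAD=4.2095
ratio_to_reference(sim$table, lin, "129C", mode = "linear_only")
#> ratio_dispersion [linear_only]: 129C vs 1:1, expected log2 ratio -6.644, n=39, MAD=3.1757
```

The dispersion (median |observed − expected| over proteins) drops from
4.21 to 3.18, at the cost of 11 proteins that have no linear peptide.
`quantify_proteins()` runs the differential analysis under either peptide
selection and `compare_selection_modes()` flags proteins whose
significance verdict depends on that choice.

A thin command-line wrapper over the same functions is installed as
`exec/tmtcal` (subcommands `linearity`, `quantify`, `simulate`,
`noise-study`).

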