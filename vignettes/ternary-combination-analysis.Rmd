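---
title: "Quantifying ternary extract synergy in a co-culture inflammation assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ternary extract synergy in a co-culture inflammation assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternci)
```

## The assay and the questions it answers

An intestinal epithelial monolayer (Caco-2 / HT29-MTX-E12) sits in a
transwell above PMA-differentiated THP-1 macrophages. LPS activation of the
macrophages triggers an inflammatory cascade: the macrophages release IL-6,
TNF and PGE2 into the basolateral compartment, the stimulated epithelium
releases IL-8, MCP-1 and PGE2 apically, and the barrier — read out as
transepithelial electrical resistance (TEER) — declines. Three herbal
extracts (myrrh, coffee charcoal, chamomile flower) and their equal-parts
combination are titrated into this system.

Two questions drive the analysis. First, *how potent is each treatment on
each endpoint* — the half-maximal inhibitory concentration (IC50) for
mediator release, the half-maximal effective concentration (EC50) for TEER
recovery. Second, *does the ternary mixture beat dose additivity* — a
Chou-style combination index per endpoint.

## Normalisation

All curve fitting happens on control-anchored scales:

* **Mediators**: percent of the stimulated control, `100 · r / mean(s)`.
  Only the upper anchor is imposed; the uninflamed baseline (inactivated
  `ua` control for macrophage endpoints, unstimulated `us` for epithelial
  ones) is *not* forced to zero, because residual mediator release persists
  without stimulation.
* **TEER**: the paired per-well difference of the resistance after 48 h and
  before treatment. Internally the difference is stored as
  `after − before` (decline negative); any fixed sign convention yields the
  same normalized values because the scale is re-anchored at the stimulated
  control (0%, maximal decline) and the unstimulated control (100%, intact
  barrier).

Anchors are arithmetic means of the replicate control wells at the matched
time point, per compartment.

## The concentration–response model

Responses follow a four-parameter logistic in log10 concentration,

$$r(x) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + 10^{\,h\,(\log_{10} x - \log_{10}\mathrm{IC}_{50})}},$$

with constraints chosen per orientation:

* **Inhibition** (mediators): `top` fixed at the stimulated-control anchor
  (100 on the percent scale) — the treatment cannot exceed the untreated
  stimulated release; `bottom` free in `[0, 100]`; `h` in `(0, 10]`. The
  IC50 is the *relative* midpoint between the constrained top and fitted
  bottom, the standard convention.
* **Enhancement** (TEER): both plateaus are fixed at the scale's defined
  anchors, 0% and 100%. This is a deliberate design choice: the tested
  grids stop well short of the recovery plateau (e.g. a combination EC50 of
  80 µg/mL on a grid ending at 150 µg/mL reaches only ~65% recovery), and
  with a free upper plateau the EC50 is practically unidentified — small
  noise produces order-of-magnitude EC50 excursions. Fixing the plateau at
  the unstimulated anchor mirrors the stimulated-control upper constraint
  of the inhibition fits; the EC50 is then the concentration of
  half-maximal normalized recovery.

Fitting is Levenberg–Marquardt least squares with box bounds on well-level
residuals (all wells, not per-concentration means), restarted from five
candidate midpoints log-spaced across the data range with a hill start of 1
and keeping the best sum of squares; tolerance 1e-13 on the relative
reduction of the sum of squares, at most 1024 iterations. The 4PL is
non-convex, and the multistart makes the outcome deterministic and
insensitive to initialisation on these desk-scale problems.

The 95% confidence interval is the symmetric asymptotic interval on
log10 IC50 (standard error from the parameter covariance, t quantile at
the residual degrees of freedom), back-transformed. Working on the log
scale matches the strong right-skew such intervals show in practice; in the
zero-residual limit the interval collapses onto the point estimate, and a
singular covariance is reported as an unbounded-interval verdict rather
than a number.

### Flat curves, out-of-range estimates, activity

Three verdicts protect downstream synergy arithmetic from pseudo-curves:

* **flat** — the responses never leave the fixed plateau (all within one
  standard deviation of it), *or* the 4PL does not beat the
  constant-at-plateau "no effect" model in the extra-sum-of-squares F test
  (p ≥ 0.05). Without the F test, a 4PL fitted to pure noise can report an
  absurd half-max (e.g. 1e-4 µg/mL with a near-100% bottom) that would
  poison the combination index.
* **out_of_range** — a converged half-max more than a factor of 10 outside
  the tested concentrations; reported, but treated as not quantifiable.
* **active** — a treatment counts as active on an endpoint only if some
  concentration differs significantly from the stimulated control
  (Dunnett-adjusted p < 0.05) *and* the curve is not flat. Inactive
  treatments appear as "-" in the results table and their term is extracted
  from the combination index.

## Significance layer

TEER and PGE2 (measured at 48 h only) use one-way ANOVA; cytokine and
chemokine time courses (4, 24, 48 h) use two-way fixed-effects ANOVA
(treatment, time, interaction), with Dunnett's two-sided many-to-one
comparisons against the stimulated control within each time point on the
pooled error term. Dunnett adjusted p-values are computed by deterministic
Gauss–Legendre quadrature of the exact product-form integral of the
multivariate t (conditioning on the control mean and the pooled-sd pivot
makes the comparisons independent); the single-comparison case reproduces
the pooled t-test to near machine precision, and no Monte Carlo enters the
stars. Star thresholds are 0.05, 0.01, 0.001, 0.0001. No multiplicity
correction is applied across endpoints, matching the within-assay scope of
the original design.

A known limitation: with multiplicative (log-normal) mediator noise the
time courses are heteroscedastic across time points, while the two-way
pooled error assumes a common variance; this inflates within-time false
positives at the latest (largest-variance) time point. The flat-curve F
test absorbs the practical consequence (a noise-only series wrongly flagged
significant would otherwise enter the index).

## The combination index

For the equal-parts ternary mixture,

$$\mathrm{CI} = \frac{\mathrm{IC}_{50,\mathrm{comb}}}{\mathrm{IC}_{50,A}} +
\frac{\mathrm{IC}_{50,\mathrm{comb}}}{\mathrm{IC}_{50,B}} +
\frac{\mathrm{IC}_{50,\mathrm{comb}}}{\mathrm{IC}_{50,C}},$$

where $\mathrm{IC}_{50,\mathrm{comb}}$ is one third of the combination's
total IC50 (each component contributes one third of the mixture
concentration) and inactive components' terms are extracted. Categories
follow the Chou bands; since the quoted band edges overlap, the package
fixes a convention — synergism bands closed at the lower edge, the additive
band closed on both sides, antagonism bands closed at the upper edge:
`[0.1, 0.3)` strong synergism (++++), `[0.3, 0.7)` synergism (+++),
`[0.7, 0.85)` moderate (++), `[0.85, 0.9)` slight (+), `[0.9, 1.10]` nearly
additive (0), `(1.10, 1.20]` slight antagonism (−), `(1.20, 1.45]` moderate
(−−), `(1.45, 3.3]` antagonism (−−−), `(3.3, 10]` strong (−−−−). This
convention is consistent with both published categorisations that sit next
to an edge (0.83 → moderate synergism, 1.11 → slight antagonism). Values
outside `[0.1, 10]` map to the nearest extreme category with an
out-of-scale flag.

In pipeline mode the index uses full-precision fitted half-max values; in
replication mode (`replicate_table1()`) it uses the printed integer
IC/EC50s, because reproducing a printed table must use the table's own
inputs. Reports round the index to two decimals and the half-max values to
integers, while the JSON run report keeps full precision.

`combination_interval()` propagates fit uncertainty into the index by a
parametric bootstrap on the log10 half-max estimates (normal draws at each
fit's asymptotic standard error, percentile interval). The original
analysis reports point indices only, so this interval is an extension and
is flagged as such in the run report.

## The synthetic-data generator

`generate_assay()` emulates the study design so the whole pipeline is
testable against known truth:

* **Design**: the published concentration grids (myrrh 0.1–100, coffee
  charcoal 1–500, chamomile flower 0.1–200, combination 0.25–150 µg/mL;
  7 log-spaced points each), the control classes (s, ua, us, plus a
  budesonide positive control), cytokines/chemokines at 4, 24, 48 h with a
  rising induction fraction (0.3 / 0.7 / 1.0 — chosen as a plausible
  cytokine accumulation profile; the source reports no time-course values),
  PGE2 and TEER at 48 h.
* **Levels**: uninflamed baselines of 100 (IL-6), 150 (TNF), 200 (M-PGE2),
  120 (IL-8), 800 (MCP-1) and 50 (IEC-PGE2) pg/mL — typical ELISA working
  ranges for these mediators in such models — scaled by the published LPS
  fold-inductions (8.5, 3.3, 6.4, 12.1, 1.6, 34).
* **Curves**: treated mediator wells follow
  `ref + (s − ref)·(floor + (1 − floor)/(1 + (x/IC50)^h))` with hill 1 and
  floor 0.05 by default; true IC50/EC50 default to the published point
  estimates, with "-" cells generated flat at the stimulated level so the
  term-extraction rule is exercised. The combination curve gets its *own*
  IC50 rather than being composed by an additivity model, which keeps the
  implied true combination index a free, testable parameter.
* **Noise**: multiplicative, mean-preserving log-normal on mediator values
  (ELISA error scales with level and stays positive), default CV 0.15.
  TEER is generated as paired before/after readings around a 500 Ω
  baseline (stimulated wells decline by 30% of baseline, unstimulated rise
  by 10% — in the range reported for such co-culture monolayers); because
  differences can be negative, TEER noise is additive Gaussian on the
  after-reading with sd = CV × the anchor span, plus log-normal noise on
  the baseline.
* **Determinism**: one integer seed fixes the dataset byte-for-byte.

What passing tests on this generator do *not* show: the curves are
phenomenological Hill functions, not a cytokine network; inter-experiment
(plate-to-plate) variance, edge effects, and ELISA standard-curve error are
not modelled; real replicate structure in the source experiments is
unreported. Recovery results therefore validate the *estimator*, not the
biology.

## Numerical behaviour and problem sizes

On noise-free generator output every active IC50/EC50 and hill is recovered
to better than 1e-6 relative error across all 28 endpoint × treatment
cells, and inactive cells are flagged flat — the fits are exact where the
data are exact. Under realistic noise (CV 0.15, 3 replicates), 200
simulated experiments per cell give a median absolute log10 IC50 error
below 0.15 for well-identified cells and asymptotic interval coverage
between 90 and 98%; the test suite runs these studies at exactly those
sizes, and 1000 simulated global nulls calibrate the Dunnett familywise
error. These sizes were chosen to bound the Monte-Carlo error of each check
well below its decision margin.

Identifiability varies enormously across the design, and users should
expect it to: a cell whose fold-induction is small (MCP-1, 1.6-fold: the
percent scale spans only 100→64) or whose true half-max lies at or beyond
the grid edge (chamomile on IL-8) carries an order of magnitude more
log-IC50 variance than a well-covered steep curve. The very wide published
confidence intervals for exactly these cells (e.g. 2.1–10905 µg/mL for one
IC50 of 152) show the same effect in the original data. Consequently,
*combination indices computed from refitted noisy data inherit this
uncertainty* — at noise CV 0.05 the index for a poorly identified endpoint
can deviate from its true value by several tenths, far more than the
rounding precision of a printed table. The replication mode exists
precisely to separate the arithmetic of the index (exact, reproducible from
printed inputs) from the statistical uncertainty of curve fitting.

## Interfaces

Everything is driven from R: `read_assay_csv()` / `write_assay_csv()` for
the long plate format, `generate_assay()` for simulation,
`run_assay_analysis()` for the one-call pipeline, `replicate_table1()` for
the replication mode, and `write_results_table()` /
`write_run_report()` for persistence. The functions compose, so a shell
wrapper is a one-liner where batch use demands it.

```{r example}
sim <- make_table1_fixture(seed = 1)
res <- run_assay_analysis(sim$dataset, endpoints = c("IL6", "TEER"))
res
replicate_table1()
```
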