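---
title: "Drug sensitivity scoring for ex vivo CLL screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug sensitivity scoring for ex vivo CLL screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cllscreen)
```

## The measurement and its model

An ex vivo CLL drug-sensitivity screen exposes patient-derived cells —
pre-conditioned by co-culture with CD40L/APRIL/BAFF-expressing
fibroblasts so that spontaneous apoptosis does not confound drug effect —
to a drug library on 384-well plates, typically 94 single agents and 87
two-drug combinations, each at five ten-fold concentrations (1–10,000 nM;
0.1–1,000 nM for a few highly potent kinase inhibitors). Viability after
72 h is read as CellTiter-Glo luminescence.

Three nested models take this readout to a per-drug sensitivity scalar.

**Control anchoring.** Each plate carries vehicle (0.1% DMSO) wells
defining live signal and full-kill (100 µM benzethonium chloride) wells
defining dead signal. Percent viability is the affine rescaling

$$v = 100\,\frac{L - \mu_{pos}}{\mu_{neg} - \mu_{pos}},$$

which is invariant under any positive affine transform of the raw
luminescence (gain or offset drift of the reader cancels). Values outside
[0, 100] are deliberately preserved at this stage — they are informative
for QC — and only clipped inside scoring. Replicate wells of the same
(entry, dose) pair are averaged at normalization; the screen design here
assumes one screen per sample, so replication is within-plate only.
Controls are summarized *per plate* (each of the up-to-four plates of a
screen carries its own anchors and Z′), because plate-to-plate gain
differences are the dominant nuisance in luminescence assays. Pooling
controls across plates would be an alternative reading; per-plate is this
package's contract.

**Plate quality.** The Z′-factor
$Z' = 1 - 3(\sigma_{pos}+\sigma_{neg})/|\mu_{neg}-\mu_{pos}|$
(sample SDs, $n-1$ denominator) summarizes how well the assay window
separates live from dead given control noise. The conventional pass
threshold 0.5 is the default; failing plates are flagged, not dropped —
`run_pipeline(strict = TRUE)` turns the flag into an error.

**Concentration–response.** Viability against log10 dose is fitted with
the four-parameter logistic

$$v(x) = b + \frac{T - b}{1 + 10^{\,s\,(x - m)}}$$

with top $T$, bottom $b$, log-EC50 $m$ and Hill slope $s > 0$. Bounds
are $T \in [50, 120]$, $b \in [-10, 100]$, $s \in (0, 10]$,
$m \in [x_{lo}-2,\ x_{hi}+2]$: generous enough for partial-efficacy and
overshooting curves, tight enough to keep five-point fits identifiable.

## The drug sensitivity score

A fitted curve is reduced to a scalar by integrating *excess inhibition*
over the tested window $[x_{lo}, x_{hi}]$ (log10 nM). With inhibition
$y(x) = \mathrm{clip}(100 - v(x),\, 0,\, 100)$:

* **activity threshold** $t = 10$ inhibition points — inhibition below
  $t$ never accrues score, suppressing noise-level dips;
* **viability floor** $f = 10\%$, i.e. inhibition cap $c = 100 - f = 90$
  — the activity window on the viability axis runs from 100% down to
  10%;
* $x_1$ = first dose where $y \ge t$ (never reached → score 0, flag
  `inactive`); $x_2$ = first dose where $y \ge c$ (never → $x_{hi}$) —
  the concentration window runs from the minimum tested dose to the
  viability-10% crossing.

$$A = \int_{x_1}^{x_{hi}} \big(\min(y(x), c) - t\big)_+\,dx,\qquad
\mathrm{DSS1} = \frac{100\,A}{(100 - t)(x_{hi} - x_{lo})}.$$

DSS2 divides DSS1 by $\log_{10} d$ where $d$ is the maximal window
inhibition (capped at 100, zeroed when $d \le 10$); DSS3 multiplies DSS2
by the width factor $w = (x_{hi} - x_1)/(x_{hi} - x_{lo})$. The default
metric, **mDSS3**, is DSS3 *without* the asymptote-logarithm divisor:
$\mathrm{mDSS3} = \mathrm{DSS1}\cdot w$. All four variants stay available
through `dss_config(metric = )` because the base-DSS literature admits
more than one reading of the normalization; collapsing them silently
would hide that choice. At the default windows the attainable ceiling is
$100\,(c - t)/(100 - t) = 100\cdot 80/90 \approx 88.9$, reached by a
curve that is fully lethal at the lowest tested dose.

**Tail rule.** What happens beyond $x_2$ (the dose where viability hits
the floor) is a genuine ambiguity: one reading stops accruing area there
(`tail_rule = "truncate"`), the other counts the capped rectangle
$c - t$ out to $x_{hi}$ (`tail_rule = "cap"`), so that maximally potent
drugs score maximally. The default is `cap`; both are implemented and
tested, and differ by exactly $(c-t)(x_{hi} - x_2)$ for monotone curves.

**Flags.** `inactive` (threshold never reached, score 0);
`complete_kill_at_min` (inhibition already at the cap $c$ at the lowest
tested dose — the curve's informative part lies below the window, the
score sits at the ceiling); `poor_fit` (non-converged fit, or RMSE > 15
viability points — the score is still reported, the flag travels with
it). When inhibition at $x_{lo}$ already exceeds $t$ but not $c$, $x_1$
is set to $x_{lo}$ without a flag: the crossing is merely left-censored,
not degenerate.

## Numerical choices

**Integration is exact, not quadrature.** The integrand is piecewise
smooth: its only non-smooth points are where $v$ crosses 0, $100 - c$,
$100 - t$ or 100, and on a monotone logistic each crossing has a closed
form $x = m + \log_{10}\!\big((T-V)/(V-b)\big)/s$. The integrator splits
the window at these points and uses the closed-form logistic integral
$\int v\,dx = b\,\Delta x + (T-b)\,[x - \ln(1+10^{s(x-m)})/(s\ln 10)]$
(evaluated with a stable `log1p`-based softplus) on each smooth piece.
The test suite checks agreement with an independent 10,001-point
trapezoid oracle to 1e-4 over 100 random parameter draws, for both tail
rules.

**Fit initialization is deterministic.** Start values: top = highest
observed viability, bottom = lowest (clipped into bounds), log-EC50 = the
dose whose viability is closest to the midpoint, slope = 1. Optimization
is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with tolerances at
machine precision; a bounded L-BFGS-B least-squares pass is the fallback.
When the primary start stalls above 5 RMSE points — which happens when
the curve's transition lies at or beyond the window edge — a small
*deterministic* grid of alternative EC50/slope starts is tried and the
best SSE kept. There are no random restarts anywhere, so fits are
reproducible bit-for-bit.

**Degenerate inputs.** All-identical viability returns an exact flat
curve (top = bottom = the value; with top = bottom the slope is
irrelevant and parked at its lower bound) with `converged = TRUE`; a
flat 100% curve scores 0 with `inactive`. If both optimizers fail, the
flat curve at the mean viability is returned with `converged = FALSE`
and the score pathway flags `poor_fit`. A window with $x_{hi} = x_{lo}$
is an error.

**Ranking ties** in score tables break lexicographically by `entry_id`;
clustering leaf orders are those of `stats::hclust`, deterministic for a
given input order.

## Phospho-flow summaries

Marker medians are compared on the arcsinh-ratio scale,
$\mathrm{asinh}(\mathrm{signal}/c_f) - \mathrm{asinh}(\mathrm{ref}/c_f)$,
which is linear near zero and logarithmic for strong signals, with the
isotype/unstimulated reference mapping to exactly 0. The cofactor
defaults to 150, the common choice for conventional fluorescence
cytometry (5 is typical for mass cytometry); it is configurable because
upstream platforms differ and no single value is canonical. The package
consumes *medians* already extracted per sample and marker (gating and
barcoding deconvolution are upstream); it computes arcsinh ratios *of*
medians, the usual convention when only summary medians are exported.
Percent changes between time-points are reported as integers, rounded
half-away-from-zero — the convention that reproduces all four published
worked examples in the test suite (704, 157, 505, 120).

Heatmap matrices are clustered with Manhattan distance and Ward linkage.
Ward's criterion classically presumes squared Euclidean distances;
following the ClustVis behavior this package applies `ward.D` to the raw
Manhattan dissimilarity, which is what the field's heatmap tools do in
practice. Constant matrices and single-row/column dimensions skip
clustering with a warning and keep input order.

## What the synthetic generator emulates — and what it does not

`simulate_screen()` reproduces the *statistical* structure the analysis
assumes: true 4PL curves per entry (tops near 100, bottoms 0–10, log-EC50
uniform on [0.5, 3.5] — mostly inside the tested window, slopes 0.8–1.5),
luminescence `μ_pos + (μ_neg − μ_pos)·v/100` with multiplicative
lognormal noise (CV 5% by default, mean-1 parameterization), and
control wells drawn from normals. Default control SDs are 4% (negative)
and 1% (positive) of the assay window — full-kill wells are near the
reader floor and less dispersed — giving an expected Z′ of 0.85, inside
the ≥ 0.5 regime such screens report. Sixteen control wells per role per
plate occupy columns 23–24; treatments fill columns 1–22 row-major, up
to four plates.

`simulate_serial()` adds the longitudinal structure: additive per-entry
log-EC50 drifts model acquired resistance (positive drift at a relapse
time-point) and its reversal after treatment stop; marker medians evolve
as baseline × per-time-point multiplier with lognormal noise against a
constant reference.

The generator does **not** emulate spatial plate effects (edge
evaporation, dispensing gradients), inter-plate batch structure beyond
independent controls, non-monotone response (rescue at high dose),
drug-drug interaction surfaces (a combination is one curve, as in the
fixed-molar design), or cell-level flow distributions. Passing tests
therefore certify the *computational* pipeline — normalization algebra,
fit and score correctness, ranking behavior — not robustness to those
real-data artifacts; B-score/edge correction is explicitly out of scope.

## Problem sizes used in the checks

The test suite and acceptance script run: 100-draw oracle-agreement
sweeps on the standard 5-point window; 200-replicate parameter-recovery
simulations at 5% CV (median |Δlog-EC50| is the statistic; 0.25 the
bound); one full-scale screen (94 + 87 = 181 entries, three plates) for
the ranking and row-count checks; and an 18-entry two-time-point serial
scenario with a +1 log10 drift for the resistance delta. These sizes are
the package's reference experiment: large enough that the distributional
statistics are stable across seeds, small enough to re-run routinely.

## Known limitations

* Printed patient-level DSS values from screens of this design cannot be
  reproduced without the raw plate readouts, which are not public; the
  package validates its scoring against closed forms, oracles and
  simulations instead, and treats published magnitudes as sanity context
  only.
* The exact normalization constants of the base DSS variants differ
  between implementations in the literature; the formulas above are this
  package's contract, and the `metric`/`tail_rule` switches span the
  plausible readings rather than asserting one.
* Confidence intervals on EC50/DSS, synergy quantification
  (Bliss/Loewe/ZIP) and mixed-effects curve fitting are out of scope.
* FCS parsing, compensation and gating are upstream; the flow module
  starts from exported medians.
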