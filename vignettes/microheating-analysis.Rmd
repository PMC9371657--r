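---
title: "Methods: quantifying heat-induced Ca²⁺ release from microheating experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying heat-induced Ca2+ release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicr)
```

## The experiment and the estimand

A focused infrared laser heats the medium around cultured cells for about
two seconds; the local temperature rise ΔT decays steeply with distance from
the focus, so one field of view exposes cells to a range of ΔT values in a
single run. Cells carry a cytosolic Ca²⁺ indicator (fluo-4 or Cal-520) or an
ER-luminal one (G-CEPIA1er). A cell "responds" when the heat pulse triggers
a Ca²⁺ burst — a rapid, large rise of the cytosolic indicator — and the
quantity of interest is **ΔT_th**, the temperature rise at which half the
cells of a line respond. Comparing ΔT_th across RyR1 variants quantifies how
much more heat-sensitive the malignant-hyperthermia mutants are than wild
type.

The analysis decomposes into four stages, each exposed as ordinary
functions, with `run_pipeline()` composing them.

## Thermometry

The local ΔT is measured by the thermal quenching of the luminescent dye
Eu-TTA deposited on a cell-free dish. The quench ratio of a dye trace is

$$\Delta F/F_0 = \frac{F_\mathrm{heating} - I_\mathrm{laser}}
                      {F_\mathrm{before} - I_\mathrm{back}} - 1,$$

where $F_\mathrm{heating}$ is the intensity at the end of the heating period
(we average the final two laser-on frames for robustness to single-frame
noise), $F_\mathrm{before}$ the intensity of the frame at the pulse onset,
$I_\mathrm{laser}$ the laser-on background (what a cell-free region reads
while the beam is on, i.e. dark level plus IR scatter) and $I_\mathrm{back}$
the excitation-off background. Division by the calibrated slope (−2.7% °C⁻¹
at 24 °C base temperature, −4.1% °C⁻¹ at 36 °C) gives ΔT. Lookups at any
other base temperature fail rather than extrapolate; a user-supplied slope
table (`calibration_curve()`) can extend the set deliberately, e.g. mapping
a 23 °C muscle experiment onto the 24 °C slope.

Photobleaching is corrected by dividing out a single exponential fitted to
the pre-stimulus segment (the only window guaranteed to be uncontaminated by
heating). Because additive backgrounds do not bleach, this division is exact
only for negligible background or negligible bleaching; the package's exact
thermometry round trips are therefore stated for bleach-free sheet traces,
and the generator's default sheet bleaching rate is zero (sheet recordings
are short and dim-background).

A sheet measurement at ≥3 distances yields ΔT per distance; isotonic
regression enforces the physical requirement that ΔT not increase with
distance; per-cell ΔT is interpolated **log-log** (the field decays like an
inverse power of distance, so log ΔT is nearly linear in log r; plain
interpolation of the convex decay overestimates between knots).

## Burst metrics

All statistics are frame-wise; no smoothing anywhere. For cytosolic traces,
IR scatter (the laser-on background in excess of the dark background) is
subtracted from laser-on frames only, so on- and off-pulse frames share one
additive offset. With $F_0 = F_\mathrm{before} - I_\mathrm{back}$:

* `dfmax()` — ΔF_max/F0, the maximum of $(F - F_\mathrm{before})/F_0$ during
  the 20 s after heating initiation (closed window, half-frame tolerance at
  the edges);
* `spontaneous_dfmax()` — the same statistic for unheated cells over 10–30 s
  after the start of observation, with $F_\mathrm{before}$ at 10 s to match
  the excitation exposure of heated runs;
* `dfmin_cepia()` — ΔF_min/F0 for ER traces over 2.4–10 s after heating
  initiation, a window that starts after the pulse so the thermal-quenching
  epoch of the indicator is excluded; reported as −ΔF_min/F0 (depletion
  magnitude), on bleach-corrected traces;
* `normalize_by_store()` — divides ΔF_max/F0 by the line's resting ER Ca²⁺
  level relative to wild type, since a depleted store under-reports release.

One timing convention matters: heating effects are attributed to frames
*strictly after* the onset frame, so the frame at exactly `t_start` is the
uncontaminated `F_before` frame ("just before heating").

## Responder threshold

Spontaneous fluctuations define what counts as a response. The empirical CDF
of the unheated cells' ΔF_max/F0 values (plotting position $i/n$ at the
$i$-th sorted value) is least-squares fitted by the Gaussian CDF in its
error-function form, and the threshold is **ΔF_th = µ + 1.96σ**. The fit is
least squares on the CDF — not moment matching — so σ can differ slightly
from the sample SD; the two agree closely for near-Gaussian samples. A
heated cell is a responder iff ΔF_max/F0 > ΔF_th, strictly; a tie is a
non-responder. One pooled fluctuation model is used per line and base
temperature.

By construction this threshold lets through a small fraction of
non-bursting cells: about 2.5% from the Gaussian tail, more in practice
because the max-of-noise statistic is right-skewed and because genuine
spontaneous transients occur. This *spontaneous-response floor* is a real
feature of the classification, and it matters for the next stage.

## Dose–response and ΔT_th

Per-cell binary outcomes are fitted by maximum likelihood with

$$p(\Delta T) = g + (1 - g)\,
  \mathrm{logistic}\!\left(\frac{\Delta T - \Delta T_\mathrm{th}}{w}\right),$$

and ΔT_th is the midpoint of the heat-induced component. The floor $g$ plays
the role of a natural-response (Abbott) term in classical dose–response
work. We found a plain two-parameter logistic unacceptable here: with a
4–5% response floor it absorbs the floor into its slope and biases the
midpoint low — by more than a degree when the midpoint sits high in the
sampled range. `run_pipeline()` fixes $g$ at its directly observed value,
the fraction of unheated cells exceeding ΔF_th (the response rate at
ΔT = 0), which also removes a free parameter; standalone
`fit_dose_response()` estimates $g$ (bounded to [0, 0.2]) when it is not
supplied.

When the MLE is unavailable — complete separation, or a non-increasing fit —
the estimate falls back to isotonic regression of responder on ΔT with
linear interpolation of the 50% crossing, flagged `"isotonic"` in the
output. The 95% CI is a nonparametric bootstrap over cells (default 1,000
resamples, seeded). Binned response curves (`response_curve()`, equal-count
quantile bins of ≥8 cells) are descriptive output only; the fit uses every
cell.

Group comparisons of burst magnitudes use the two-sided Mann–Whitney U test
(`compare_groups()`): exact null distribution for small tie-free samples,
normal approximation with tie correction otherwise.

## The synthetic-data generator

The generator is first-class, tested code; its defaults encode the study
conditions the analysis is validated under.

* **Field**: $\Delta T(r,t) = aP/(r + r_0)\, g(t)$ with softening radius
  $r_0 = 15$ µm and $a$ set so that 25.6 mW gives 10 °C at 10 µm; $g(t)$ is
  first-order rise/fall with both time constants 0.05 s (the measured rise
  is faster than 100 ms). The inverse-distance form is a modelling choice —
  only measured curves are published — that reproduces steep near-source
  decay and is linear in power. `simulate_cohort()` refuses target rises the
  softened field cannot reach ($aP/r_0$); the 24 °C cohorts spanning
  [0, 20] °C therefore use 40 mW.
* **Cells**: a heat-induced burst occurs with probability
  $\mathrm{logistic}((\Delta T - \Delta T_\mathrm{th}^{true})/w)$, zero for
  unheated cells; the logistic link is the minimal smooth monotone choice
  and is shared with the estimator. Amplitudes are truncated-normal; onset
  follows the line's latency phenotype (during heating for R164C/R164L,
  after recooling otherwise at 24 °C); rise constant 0.3 s (bursts are
  faster than ~500 ms). A multiplicative SERCA-uptake dip applies during
  laser-on frames. ER traces show thermal quenching during the pulse and a
  depletion dip of Gaussian shape centred 5 s after cessation, with depth
  proportional to burst amplitude and inversely proportional to the resting
  store level.
* **Optics**: photobleaching, excitation-off background, IR scatter during
  laser-on frames, additive Gaussian noise. The indicator's temperature-
  dependent Ca²⁺ affinity (Kd 520 nM at 22 °C, 190 nM at 37 °C, interpolated
  linearly) is available as an optional saturation factor and off by
  default: the analysis operates on raw intensities.
* **Defaults not fixed by any publication**, chosen once as realistic for
  this kind of recording: frame interval 0.2 s; observation 35 s with the
  pulse at 10 s; baseline fluorescence 100 ± 10 a.u. across cells; noise SD
  1.5 a.u.; dark background 5 a.u.; scatter 3 a.u.; spontaneous transient
  rate 0.001 events/s. Line presets put the generative ΔT_th at the
  published per-line values with logistic width 1 °C; burst amplitudes,
  SERCA-dip fractions and relative store levels are set to reproduce the
  qualitative phenotypes (larger bursts and smaller dips in R164C, depleted
  stores in Y523S).
* **Reproducibility**: one master seed; per-cell substreams derived by
  counter, so growing a cohort never reshuffles earlier cells, and identical
  configurations are bitwise identical.
* **Image mode**: `render_image_stack()` draws cells as uniform disks into a
  16-bit multi-page TIFF; ROI-mean extraction reproduces the source traces
  to one quantisation step. There is no PSF or ER-geometry simulation, and
  no heat-conduction PDE — these are out of scope by design.

What passing tests on this generator do show: the formulas are implemented
exactly (round trips to 1e−6 °C on noise-free sheets), the estimator is
close to unbiased under the generative model, and the full pipeline recovers
known thresholds within ±0.5 °C at cohort sizes of a few hundred cells. What
they cannot show: robustness to structured noise (focus drift, motion,
indicator internalisation), to non-logistic true response curves, or to
temperature-field asymmetries — none of which the generator emulates.

## Numerical choices and degenerate inputs

* Window boundaries are closed with half-frame tolerance; the analysis
  windows (20 s burst, 2.4–10 s ER, 10–30 s spontaneous) are configurable.
* The bleach fit uses `nls` started from a log-linear regression; a fitted
  rate ≤ 0 returns the trace unchanged, flagged.
* The CDF fit optimises (µ, log σ) by Nelder–Mead from sample moments;
  zero-spread input yields σ = 0 with a warning and ΔF_th = µ.
* `fit_dose_response()` errors when all or no cells responded or when the
  midpoint falls outside the sampled ΔT range ("ΔT_th outside sampled
  range"); bootstrap resamples that fail are dropped from the CI.
* Cells failing the baseline precondition (F_before ≤ I_back) or with
  incomplete analysis windows are excluded and logged with machine-readable
  reason codes (`dead_baseline`, `incomplete_window`).
* Problem sizes used in the validation suite: recovery and ordering
  properties run on cohorts of 300–600 heated plus 100 unheated cells, 20
  seeded replicates; the acceptance script uses 600 heated cells per cohort.
  These sizes were chosen so the estimator's sampling error is comfortably
  inside the ±0.5 °C recovery tolerance.

## Interfaces

Traces move as long CSV tables (`cell_id, channel, time_s, intensity_au,
distance_um, laser_on`); run configurations load from YAML or JSON
(`read_run_config()`); reports write as JSON plus per-cell and per-bin CSVs,
byte-stable under a fixed seed. Role conventions in a trace set: channel
`"eutta"` marks dye-sheet ROIs, a `bg` cell-id prefix marks cell-free
background ROIs, and traces with no laser-on frames are unheated reference
cells.

## Known limitations

* The ΔT assignment assumes a radially monotone field and point-like ROIs;
  2-D temperature maps are not produced.
* Muscle (Cal-520) traces are processed by the identical ΔF_max/F0 operator
  as HEK fluo-4 traces; no statistical difference beyond parameter presets
  is modelled, since none is quantified for this experiment class.
* The fluctuation model is Gaussian although the max-statistic is mildly
  right-skewed; the dose-response floor term absorbs the resulting excess
  exceedance, but ΔF_th itself inherits the convention.
* Cross-line significance testing (many-to-one multiple comparisons) is out
  of scope; only the plain two-sample rank test is provided.
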