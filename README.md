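# hicr — heat-induced Ca²⁺ release analysis for microheating experiments

Malignant hyperthermia (MH) is driven largely by mutations in the skeletal
muscle Ca²⁺-release channel RyR1. A microscopic-heating experiment probes the
heat sensitivity of these channels directly: a focused 1455-nm IR laser
delivers a ~2-s heat pulse to cells loaded with a Ca²⁺ indicator, the local
temperature rise ΔT is read out from the thermal quenching of a luminescent
dye (Eu-TTA), and each cell either does or does not fire a Ca²⁺ burst. The
cell line's heat sensitivity is summarised by **ΔT_th**, the temperature rise
at which 50% of cells respond.

`hicr` implements the complete quantitative analysis for this class of
experiment, plus a ground-truthed synthetic-data generator, for R users
analysing single-cell fluorescence time series.

## What it computes

**Thermometry.** Dye traces are photobleach-corrected (single-exponential
fit), converted to a quench ratio

    ΔF/F0 = (F_heating − I_laser) / (F_before − I_back) − 1

and then to a temperature rise via the published quenching slopes
(−2.7% °C⁻¹ at a base temperature of 24 °C, −4.1% °C⁻¹ at 36 °C). A
dye-sheet measurement at several distances yields an isotonic radial profile
ΔT(r), interpolated to each cell's distance from the heat source.

**Burst metrics.** For cytosolic indicators (fluo-4, Cal-520), scatter from
the IR beam is subtracted from laser-on frames and the burst statistic is
ΔF_max/F0, the maximum of (F − F_before)/(F_before − I_back) during the 20 s
after heating initiation. For the ER-luminal indicator (G-CEPIA1er) the
store-depletion statistic is −ΔF_min/F0 over 2.4–10 s after heating
initiation.

**Responder threshold.** Spontaneous ΔF_max/F0 fluctuations of unheated
cells are fitted by the error-function form of the Gaussian CDF,

    F(x) = ½ [1 + erf((x − µ)/√(2σ²))],

by least squares on the empirical CDF; a cell is a responder when its
ΔF_max/F0 strictly exceeds **ΔF_th = µ + 1.96σ**.

**Dose–response.** Per-cell binary outcomes against ΔT are fitted by maximum
likelihood with a logistic curve carrying a spontaneous-response floor,
p(ΔT) = g + (1 − g)·logistic((ΔT − ΔT_th)/w); ΔT_th is the midpoint of the
heat-induced component, with a bootstrap 95% CI over cells.

**Synthetic data.** `simulate_cohort()` emulates the experiment end to end —
radially decaying ΔT field with sub-100-ms kinetics, Eu-TTA quenching, Ca²⁺
bursts whose probability is logistic in ΔT around a line-specific ΔT_th,
SERCA-uptake dips during heating, ER depletion minima ~5 s after the pulse,
photobleaching, laser scatter and noise — with full ground truth, and can
render 16-bit TIFF stacks for image-mode tests. Presets cover WT and the
Q156K, R164C, R164L and Y523S lines at 24 and 36 °C.

## Worked example

Simulate a 36 °C R164C cohort (generative ΔT_th = 1.4 °C) and run the full
analysis:

```r
library(hicr)

cfg <- sim_config(seed = 42, n_cells = 300,
                  protocol = heat_protocol(T0 = 36, laser_power = 25.6),
                  mutant = mutant_preset("R164C", 36))
cohort <- simulate_cohort(cfg, n_unheated = 100, deltaT_range = c(0, 6))
report <- run_pipeline(cohort, cfg$protocol, boot = 500, seed = 1)
print(report)
#> Microheating analysis report
#>   300 heated cells analysed (0 excluded), 100 unheated
#>   dF_th = 0.07142 (fluctuation_fit)
#> Heat-sensitivity threshold (n = 300 cells, mle)
#>   dT_th = 1.481 degC  [95% CI 1.150, 1.779]
#>   logistic width = 0.821 degC
```

The fluctuation threshold 0.071 says that an unheated cell exceeds a
relative change of 7.1% with probability ≈ 2.5%; cells above it count as
responders. The estimated ΔT_th of 1.48 °C recovers the generative 1.4 °C
within its confidence interval — this line fires Ca²⁺ bursts from a
temperature rise of little more than one degree. `plot(report$dose_response)`
draws the binned response probabilities and the fitted curve;
`summary(report$fluctuation)` and `coef(report$dose_response)` expose the
fitted parameters.

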