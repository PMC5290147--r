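---
title: "Models and methods behind the SCFS adhesion pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the SCFS adhesion pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfskit)
```

## The measurement and its statistics

In single-cell force spectroscopy a live, rounded fibroblast is bound to a
tip-less AFM cantilever, pressed onto a ligand-coated substrate to a 2 nN
setpoint, held for a defined contact time, and retracted until fully
separated. The record of cantilever force versus piezo height is the
force–distance curve; the *adhesion force* is the magnitude of its largest
downward deflection after baseline correction. Repeating this at contact
times 5, 20, 50 and 120 s for at least 10 cells per condition yields a tidy
table of (cell, condition, contact time, force) — the unit of repeated
measurement is the *cell*, each probed at every contact time.

Three quantities summarise the biology:

* **median adhesion force** per condition and contact time, compared across
  conditions with two-tailed Mann–Whitney tests;
* **adhesion strengthening**, the average of the discrete slopes
  $(F_2-F_1)/(t_2-t_1)$ over adjacent contact times of the per-time medians;
* **interaction** between two receptor classes, the deviation from an
  additive null, $\varepsilon = F_{AB} + F_0 - F_A - F_B$, evaluated on
  per-time medians: $\varepsilon<0$ means the classes compete,
  $\varepsilon>0$ that they cooperate.

Because the raw data of such assays are rarely deposited, the package ships a
generator with complete ground truth, and every processing and inference
step is validated against it.

## The generative model

**Mean kinetics.** Adhesion strengthens monotonically towards a plateau;
dot plots of real data constrain nothing beyond that. We use the simplest
three-parameter monotone model,
$$F(t) = F_{\mathrm{floor}} + F_{\max}\left(1 - e^{-t/\tau}\right),$$
with `f_floor` the nonspecific level (N), `f_max` the specific plateau (N)
and `tau` the saturation timescale (s). All three are data of the
configuration, not code. The four study presets (`study_conditions()`)
encode the reported phenotypes of integrin-reconstituted fibroblast lines: a
constant ≈0.2 nN floor for the
pan-integrin knockout; similar kinetics for the αV-only and double-positive
lines (plateau ≈1.5–1.6 nN above floor, τ = 40 s); and a β1-only line whose
120-s adhesion is about twice the double-positive line's
(`f_max` = 3.6 nN, τ = 50 s) — the competition pattern.

**Variability.** Cell-to-cell spread is a multiplicative lognormal effect
with mean 1 and relative s.d. `cell_sd_rel` (default 0.25), drawn once per
cell; within-cell scatter is additive Gaussian with s.d. `meas_sd` (default
0.15 nN), truncated at zero. The defaults reproduce dot clouds of realistic
width with an occasional strongly adhesive cell; the true variance
decomposition of the original assay is unknown, so these are labelled
assumptions, exposed as parameters, and chosen once.

**Curves.** A simulated retract segment is a detachment well ramping to
exactly $-F$ at 8 % of the travel and recovering by 35 %, optional rupture
events (a short loading ramp ending in an upward step) between 35 % and
70 %, an event-free baseline over the final 30 %, then linear drift
(`drift_slope`, N per metre of travel) and white Gaussian force noise
(`noise_sd`). Before noise, the global minimum of the curve equals exactly
$-F$; this construction oracle underlies the exact recovery tests.

**Single-molecule regime.** The single-molecule modification uses a 200 pN
setpoint, ≈100 ms contact and a 1 µm retract. With probability `p_bind` the
curve carries one rupture whose force is truncated-normal (mean 60 pN,
s.d. 15 pN, floor 20 pN) — rupture forces are not reported for the original
assay, so the distribution was chosen to sit above the detection floor and
is fully configurable. The four preset probabilities follow the measured
regimes: 0.25 (both classes active), 0.40 (β1 blocked), 0.12 (αV blocked),
0.10 (nonspecific).

**Thermal noise.** Calibration traces are i.i.d. Gaussian deflections with
the equipartition variance $k_BT/k$ (≈ 7.13·10⁻²⁰ m² at `k` = 0.06 N/m,
`T` = 310 K), optionally drifted.

**Determinism.** One master seed; per-(condition, cell, purpose) substreams
are derived by hashing a label string (`substream_seed()`), so adding a
condition to a configuration never changes the draws of existing ones, and a
fixed configuration reproduces byte-identical output.

## Curve processing rules

The vendor software used in the original assays is closed; these are this
package's explicit rules, all configurable:

* **Baseline**: ordinary least squares of force on height over the final
  30 % of retract travel (≥ 10 samples enforced), one pass rejecting
  residuals beyond 3×MAD, fitted line subtracted from the whole segment.
  Idempotent by construction.
* **Noise scale**: scaled MAD (`mad()`, i.e. MAD/0.6745) of the tail
  residuals — robust to any events accidentally in the tail.
* **Adhesion force**: $-\min$ of the corrected retract array, clipped at 0
  so pure-noise curves report 0 rather than small negatives.
* **Rupture events**: at each sample the mean force over the following 5
  samples minus the mean over the preceding 5 must exceed
  $k_\sigma \cdot \sigma$ (default $k_\sigma=5$), the preceding window mean
  must lie below $-k_\sigma\sigma$ (a loading excursion), and the largest
  single-sample jump nearby must carry at least half the windowed step —
  this sharpness condition separates genuine discontinuities from smooth
  unloading ramps and makes the detector exact on noise-free curves. Runs of
  neighbouring candidates merge into one event at the largest jump.
* **Specific binding**: ≥ 1 event *and* corrected minimum below
  $-k_\sigma\sigma$.
* **Calibration**: linear detrend, then $k = k_BT/\mathrm{var}$. The plain
  equipartition form (no spectral fit, no mode-shape correction factors) is
  exactly consistent with the generator and accurate to ~0.5 % at 10⁵
  samples.

**Detection limit.** The window statistic has s.d. $\sigma\sqrt{2/5}$, so at
$k_\sigma = 5$ a step must exceed $5\sigma$. For the single-molecule preset
we set the noise floor to 3 pN — the filtered force precision of a soft
lever at kHz bandwidth — which puts the 5σ threshold at 15 pN, below the
20 pN floor of the rupture-force distribution: every admissible rupture is
detectable, and the binding-probability estimator is unbiased (recovered
within ±0.02 at all four regimes in the acceptance suite, with a
false-positive rate far below 1 %). Cell-scale curves keep a 10 pN floor;
they need no event detection. At 10 pN single-molecule noise the smallest
ruptures would be censored and the estimator would be biased low — a
detection-limit effect worth remembering with real data.

**Binding probability** is estimated per cell (the binomial MLE), reported
as mean ± s.d. across cells with the pooled curve count as *n*. A cell with
a single curve has no within-cell s.d.; it is reported as 0 with
`sd_defined = FALSE` rather than propagating `NA`.

## Resampling inference

**Bootstrap unit.** Cells, not measurements: each cell's whole force–time
profile is resampled with replacement, preserving within-cell pairing.
"Samples of equal size" is implemented as resampling every group to the
smallest group's cell count. Whether the original analysis bootstrapped
cells or measurements, and computed slopes from medians or per-cell
trajectories, is not documented; both alternatives exist here
(`slope_difference_test(unit = "cell")`), with medians-of-cells the default.

**Slope test.** B = 100 bootstrap replicates per group (the protocol
default; configurable, with a warning below B = 20 that p-value granularity
is coarse), average slope of per-time medians per replicate, two-tailed
Wilcoxon rank-sum between the two B-length slope samples (tie-corrected
normal approximation). Both groups consume the same seeded stream, so a
group compared against itself yields identical replicates and p = 1.

**Interaction test.** Per replicate all four conditions are resampled to the
smallest cell count, ε computed per contact time from the per-time medians,
and each time point tested with a two-tailed one-sample signed-rank test of
the B bootstrap ε values against zero. Zeros are handled by Pratt's method
(they keep their ranks but contribute no sign) — base R's `wilcox.test`
drops zeros instead, which is why this test is implemented in the package —
with the normal approximation appropriate for B ≥ 20. Because it is not
documented whether the original test pooled contact times, both outputs are
reported: per-time p-values and a Holm-corrected pooled p. The per-time
`sign` is the sign of the median bootstrap ε where p < α (default 0.05),
else `"none"`.

### Anti-conservativeness of Wilcoxon-on-bootstrap

Treating B bootstrap replicates as exchangeable independent draws is not a
calibrated test. The bootstrap spread of a statistic approximates its
sampling s.d., so a rank test on B = 100 replicates resolves location shifts
of roughly 0.2 bootstrap-s.d. — and under the null the *observed* statistic
itself fluctuates by a full sampling s.d. The package's own calibration
experiments (200 simulations under exactly additive generative nulls,
10 cells per condition, in the acceptance suite) measure per-time rejection
rates around 0.8 at a nominal α = 0.05 for the interaction test, and ≈0.85
for the slope test under identical-parameter groups. The procedures are kept
because they are the field's published recipe and their *power* and *sign*
behaviour is what the headline claims rest on (negative ε detected in
essentially 100 % of competition-pattern runs; slope-ratio-2 power ≈ 100 %);
their p-values should be read as descriptive, not as calibrated error rates.
`slope_difference_test(unit = "cell")` is the calibrated alternative: a
plain rank-sum across per-cell slopes.

## Numerical choices and degenerate inputs

* Medians use R's midpoint rule for even n; exact Mann–Whitney for tie-free
  samples with both n ≤ 8 (validated against full enumeration), otherwise
  the tie-corrected normal approximation with continuity correction.
* Noise scale is floored at 10⁻¹⁶ N in the detector so noise-free synthetic
  curves remain analysable; B < 10 is an error; t₁ = t₂ in a discrete slope,
  a single time point in an average slope, empty samples, unknown or missing
  conditions, and short baseline tails all raise informative errors.
* Files are plain text with 17 significant digits: curve TSV and dataset CSV
  round trips are lossless, and write→read→write is byte-identical.

## Scope of the synthetic validation

The generator emulates the *statistical* structure of the assay, not cell
mechanics: no cortical-tension or tether (WLC) physics, no membrane-tether
force plateaus, no approach-segment indentation, no correlated (1/f) noise,
no curve-to-curve drift of cell state over a session. Passing the recovery
tests therefore shows the pipeline's rules are self-consistent and unbiased
under white noise with linear drift — not that they match any particular
vendor's closed algorithms on real traces, where tether plateaus and slow
drift are the main additional hazards. The calibration step is the plain
equipartition estimate; applying it to a real lever would additionally need
sensitivity calibration and mode-shape corrections, which are out of scope.

Problem sizes used by the validation suite — 200 simulation replicates for
the test-calibration experiments, B = 100 bootstraps, four single-molecule
batches of 20 cells × 200 curves, 10⁵-sample thermal traces — were chosen as
the smallest sizes at which the binomial/Monte-Carlo error bands are
decisively narrower than the tolerances being checked.
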