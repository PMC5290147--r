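# scfskit

Simulation and statistics for AFM-based **single-cell force spectroscopy
(SCFS)** adhesion assays, built around the early-adhesion biology of
fibronectin-binding integrins: a fibroblast attached to a calibrated
cantilever is pressed onto a ligand-coated substrate for a defined contact
time (5–120 s) and retracted; the **adhesion force** is the magnitude of the
largest downward cantilever deflection after baseline correction of the
force–distance curve. Comparing how adhesion builds up with contact time
across cell lines that express the αV-class and/or α5β1 integrin classes —
and testing whether the two classes interact — requires a small, specific
statistical toolbox, which this package provides together with a
ground-truth synthetic data generator for validating every step.

The package is aimed at biophysicists analysing SCFS adhesion kinetics and
at statisticians who want a fully reproducible, text-format pipeline for
resampling inference on per-cell repeated measures.

## What it computes

**Curve level.** Baseline correction (robust linear fit to the final 30 % of
the retract travel, one 3×MAD outlier-rejection pass), adhesion force
`F = −min(corrected retract force)`, rupture-event detection (windowed step
rule at `k·σ`, default `k = 5`), specific-binding calls for single-molecule
curves, per-cell binding probability (mean ± s.d. over cells), and
thermal-noise spring-constant calibration via equipartition,
`k = k_B T / var(deflection)`.

**Statistics level.** For each cell line, adhesion strengthening is the
*average slope* of the median adhesion force over adjacent contact times,

```
s = mean over adjacent (t1, t2) of (F2 − F1) / (t2 − t1),
```

compared between lines on `B = 100` equal-size bootstrap samples of whole
cells with a two-tailed Wilcoxon rank-sum test. The interaction between the
two integrin classes at each contact time is the deviation from an additive
null model,

```
ε = F_AB + F_0 − F_A − F_B,
```

with `ε < 0` a negative (competitive) and `ε > 0` a positive (cooperative)
interaction; `ε = 0` is tested per contact time with a two-tailed signed-rank
test on the bootstrap replicates. Median forces between conditions are
compared with two-tailed Mann–Whitney tests (exact for small tie-free
samples). Note: the bootstrap Wilcoxon procedures are the field's published
recipe and are reproduced faithfully — they are strongly anti-conservative
under the null (see the methods vignette, which quantifies this and offers a
calibrated per-cell alternative).

**Generator.** Mean adhesion per condition follows
`F(t) = F_floor + F_max (1 − exp(−t/τ))` with a lognormal per-cell effect and
Gaussian measurement noise truncated at zero; single-molecule curves carry a
rupture event with condition-specific probability `p_bind` (rupture force
truncated-normal 60 ± 15 pN, floor 20 pN); thermal-noise traces have the
equipartition variance `k_B T / k`. Everything is deterministic given one
master seed, with per-(condition, cell) substreams.

## Worked example

The `analysis/` scripts run the whole pipeline as a numbered workflow
(simulate → extract → binding probability → slopes → interaction), writing
tables under `results/`. Running them prints, for example:

```
$ Rscript analysis/01_simulate_study.R
Simulated 160 adhesion forces over 4 conditions and 24 full force-distance curves.
  pKO        median force:  0.13 nN (5 s) ->  0.22 nN (120 s)
  pKO-aV     median force:  0.47 nN (5 s) ->  1.65 nN (120 s)
  pKO-b1     median force:  0.72 nN (5 s) ->  3.98 nN (120 s)
  pKO-aV/b1  median force:  0.33 nN (5 s) ->  1.61 nN (120 s)

$ Rscript analysis/05_interaction.R
Integrin interaction test: epsilon = F[pKO-aV/b1] + F[pKO] - F[pKO-aV] - F[pKO-b1]
  100 bootstrap replicates, signed-rank vs 0, alpha = 0.05
  t =    5 s: epsilon =   -0.734 nN, p = 3.897e-18 **** (negative)
  t =   20 s: epsilon =    -1.23 nN, p = 3.897e-18 **** (negative)
  t =   50 s: epsilon =     -2.7 nN, p = 3.897e-18 **** (negative)
  t =  120 s: epsilon =     -3.8 nN, p = 3.896e-18 **** (negative)
  pooled (Holm) p = 1.559e-17
```

Read: the line expressing only α5β1 (`pKO-b1`) strengthens adhesion to about
twice the 120-s force of the double-expressing line, so the additive
expectation overshoots the observed joint effect and ε is strongly negative
at every contact time — the competition signature. The binding-probability
step recovers the four single-molecule regimes (0.25 unperturbed, 0.40 with
α5β1 blocked, 0.12 with αV blocked, 0.10 nonspecific) from simulated curve
batches through the full detection pipeline.

In code, the same analysis is three calls:

```r
library(scfskit)
ds <- simulate_adhesion_dataset(simulation_config(seed = 1))
slope_difference_test(ds[ds$condition == "pKO-aV/b1", ],
                      ds[ds$condition == "pKO-b1", ], B = 100, seed = 1)
interaction_test(ds, B = 100, seed = 1)
```

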