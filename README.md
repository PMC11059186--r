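# ebbench

Bench simulation and accuracy analysis of esophageal balloon catheters.

Esophageal balloon (EB) catheters estimate pleural pressure from the pressure
inside an air-filled balloon resting in the esophagus. The reading is only
trustworthy over a window of inflation volumes: an underfilled balloon
underestimates the surrounding pressure, an overfilled one distends the
esophageal wall and overestimates it. On a characterization bench — a balloon
mounted in an ex-vivo esophagus inside a pressure-controlled chamber — the
surrounding pressure is known exactly, so the transesophageal pressure

    TEP = P_balloon − P_box

directly measures the transmission error, and a reading is *accurate* when
|TEP| ≤ 1 cmH₂O.

`ebbench` is for engineers and physiologists characterizing such catheters.
It provides:

* a **forward simulator** of the bench — piecewise-linear TEP model
  `TEP(v, p) = −k_u·max(0, V_min(p) − v) + E_ser·max(0, v − V_ov(p))`, with
  pressure-dependent underfill/overfill thresholds, a series elastance
  `E_ser = e_b·e_es/(e_b + e_es)` of balloon and esophageal wall, two-segment
  balloon-alone curves (residual volume `V_res`, elastance `e_b`), saturating
  occlusion-test transmission `r(v) = 1 − exp(−(v − v_dead)/τ)`, and Gaussian
  measurement noise — so every analysis stage is testable without recordings;
* **accuracy-volume analysis**: per-sweep `V_accuracy-min`, `V_accuracy-max`
  and `V_working = V_accuracy-max − V_accuracy-min` at the 0 ± 1 cmH₂O band,
  per-catheter summaries, accuracy at manufacturer-recommended volumes;
* **elastance characterization**: residual volume by change-point (hinge)
  detection, elastance by least squares, the 40-cmH₂O volume;
* a surrogate **positive-pressure occlusion test (PPOT)**: four stepped
  chamber increments to 10 cmH₂O, the ΔPes/ΔPbox ratio, 0.1-mL volume
  titration into the 0.8–1.2 band, and the post-titration fixed-volume
  accuracy sweep (9 pressures × 3 replicates = 27 TEP values per catheter);
* **nonparametric statistics**: Kruskal–Wallis with Bonferroni-corrected
  pairwise rank-sum post-hoc tests, Fisher exact tests on accuracy counts,
  and median/IQR/mean ± SD summaries.

Seven catheter fixtures ship in `inst/extdata/catheters.json`; published
bench medians seed the parameters where they exist (e.g. Cooper elastance
15.7 cmH₂O/mL, residual volume 0.5 mL), and invented values are flagged
`synthetic_parameters`.

## Worked example

```r
library(ebbench)
sc <- default_study_config(seed = 42)
cath <- sc$catheters[["Cooper"]]

# one chamber sweep at +10 cmH2O and its accuracy-volume range
sw <- simulate_chamber_sweep(cath, sc$esophagus, p_box = 10, sc$bench, seed = 42)
accuracy_volume_range(sw)
#> # A tibble: 1 × 8
#>   catheter p_box_cmH2O replicate v_accuracy_min v_accuracy_max v_working
#> 1 Cooper            10         1              0              1         1

# occlusion-test volume titration from an empty balloon
titrate_volume(cath, sc$esophagus, start_volume = 0, sc$bench, seed = 42)
#> <ppot_result> Cooper: 0.00 -> 0.50 mL in 5 adjustment(s); ratio 0.877 (converged)

# balloon-alone curve characterization
fit_pv_curve(simulate_elastance_sweep(cath, sc$bench, seed = 42))
#> # A tibble: 1 × 7
#>   catheter replicate v_res_hat elastance_hat v40_hat fit_rss n_linear_points
#> 1 Cooper           1       0.5          15.7     3.5  0.0365               5
```

The sweep at +10 cmH₂O reads accurately from 0 to 1 mL (a 1-mL working
volume); the titration inflates the empty balloon by five 0.1-mL steps until
88% of a chamber swing reaches the balloon; and the curve fit recovers the
generative residual volume (0.5 mL) and elastance (15.7 cmH₂O/mL) of this
stiff polyethylene balloon, which reaches 40 cmH₂O by 3.5 mL.

## The study workflow

The full seven-catheter study is organized as numbered drivers over the
package functions, writing plain CSV/JSON tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # 189 chamber sweeps + 21 balloon curves
Rscript analysis/02_accuracy.R    # accuracy-volume ranges and summaries
Rscript analysis/03_elastance.R   # residual volume / elastance / V_40 fits
Rscript analysis/04_ppot.R        # titration + post-titration accuracy
Rscript analysis/05_stats.R       # Kruskal-Wallis, post-hoc, Fisher exact
```

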