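---
title: "Bench characterization of esophageal balloon catheters: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bench characterization of esophageal balloon catheters: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebbench)
```

## The measurement problem

Esophageal balloon (EB) catheters estimate pleural pressure from the pressure
inside an air-filled balloon resting in the esophagus. The reading is only
trustworthy over a window of inflation volumes: an underfilled balloon is
decoupled from its surroundings and underestimates the surrounding pressure,
while an overfilled balloon distends the esophageal wall and reads its own
recoil on top of the surrounding pressure. On a bench, a balloon mounted in an
ex-vivo esophagus inside a pressure-controlled chamber makes the surrounding
("pleural") pressure known exactly, so the transesophageal pressure

$$\mathrm{TEP} = P_\mathrm{balloon} - P_\mathrm{box}$$

directly measures the transmission error; a reading is called accurate when
$|\mathrm{TEP}| \le 1\ \mathrm{cmH_2O}$ (a closed interval: "0 ± 1" reads as
including its endpoints).

`ebbench` simulates that bench and implements the analysis stages used to
characterize catheters on it. Everything downstream of the simulator —
accuracy banding, elastance fitting, occlusion-test titration, group
statistics — operates on plain tables and works identically on recorded data
with the same columns.

## The forward model

The simulator's noise-free TEP at inflation volume $v$ and chamber pressure
$p$ is piecewise linear:

$$\mathrm{TEP}(v, p) = -k_u \max(0, V_{\min}(p) - v)
  + E_{ser}\max(0, v - V_{ov}(p))$$

with an underfill threshold $V_{\min}(p) = v_{u0} + c_u \max(0, p)$, an
overfill threshold $V_{ov}(p) = \max(V_{\min}(p),\ v_{o0} + c_o\, p)$, and the
series elastance $E_{ser} = e_b e_{es} / (e_b + e_{es})$ of balloon and
esophageal wall. This is the minimal shape that reproduces the asymmetry
observed on real benches: positive chamber pressures raise the volume needed
to couple the balloon (underestimation at low volumes), negative chamber
pressures lower the volume at which the wall is engaged (overestimation at
high volumes), and in between lies a plateau where TEP is exactly zero. The
model is monotone non-decreasing in $v$ at fixed $p$, so the set of in-band
volumes is always contiguous.

Balloon-alone inflation follows a two-segment curve: pressure stays at zero
until the residual volume $V_{res}$ is taken up unfurling the balloon, then
rises with slope $e_b$ (the balloon elastance) until the sweep stops at
40 cmH2O. Occlusion-test transmission follows a saturating law
$r(v) = 1 - e^{-\max(0, v - v_\mathrm{dead})/\tau}$, monotone in volume and
bounded below 1, so the 0.8–1.2 target band is approached from below and a
titration that can reach 0.8 always terminates.

All recorded pressures carry additive i.i.d. Gaussian noise with a default
standard deviation of 0.1 cmH2O. Bench transducers of the class modeled here
resolve 0.01 cmH2O, so 0.1 cmH2O is a deliberately conservative noise floor
that also stands in for small mounting and temperature disturbances.

### Default study conditions

The bundled configuration mirrors the bench protocol: chamber pressures −20
to +20 cmH2O in 5-cmH2O increments (9 levels), 0.5-mL inflation steps from
0 mL until the noise-free balloon pressure reaches 30 cmH2O (capped and
flagged at 10 mL when unreachable, as at strongly negative chamber
pressures), three replicates per cell, seven catheter models: 189 chamber
experiments in all, and 21 balloon-alone curves. The balloon-alone sweep
stops when the *recorded* pressure reaches 40 cmH2O — the operator watches
the display — which guarantees the terminal step of every stored curve
satisfies the stop criterion even when noise straddles the threshold.

Fixture parameters for the seven catheter models seed the published bench
medians where those exist (Cooper: elastance 15.7 cmH2O/mL, residual volume
0.5 mL; Aspisafe NG: 1.9 cmH2O/mL, 9.0 mL; Aspisafe NG+ 2.1, Nutrivent 2.9
and Marquat 2.2 cmH2O/mL); the remaining generative parameters — thresholds,
gains, transmission constants, and everything for the two SmartCath models —
are synthetic, chosen to place each catheter's accuracy plateau near its
published mean accuracy-volume range, and are flagged as synthetic in
`inst/extdata/catheters.json`. The esophageal wall elastance defaults to
4 cmH2O/mL, a mid-range value for passive ex-vivo esophagi; it only enters
through the series combination $E_{ser}$, which is dominated by the softer of
the two elastances.

## Analysis stages

### Accuracy-volume ranges

For one sweep, `accuracy_volume_range()` reports the smallest
(`v_accuracy_min`) and largest (`v_accuracy_max`) in-band volumes, their
difference `v_working` (only when at least two in-band volumes exist — a
single in-band step gives a degenerate range and no working volume), and the
in-band count. The extremes deliberately ignore interior out-of-band
excursions (possible under noise); such sweeps are flagged `has_gaps` for
audit rather than split. `v_accuracy_min` may be 0 mL: a narrow esophagus or
negative chamber pressure can make any added volume unnecessary.
Per-catheter summaries pool across chamber pressures and replicates. No
interpolation between grid volumes is attempted; ranges are reported at the
0.5-mL resolution actually swept.

### Elastance characterization

Residual volume is the breakpoint of a hinge model — a constant level up to
the breakpoint and a straight line emanating continuously from it — fit by
least squares with the breakpoint searched over the measured volume grid.
The continuity constraint matters: with an unconstrained second line, the
breakpoints at the true residual volume and one grid step below it fit
noise-free data equally well, because the measurement at the residual volume
lies on both limbs; the hinge makes the minimum unique. The flat level is
estimated rather than pinned at zero, tolerating transducer offset drift.
Remaining exact ties break toward the smaller volume, and a curve that never
rises more than $3\sigma$ above its flat level is rejected as having no
linear region. Elastance is then the ordinary least-squares slope over the
points above the breakpoint, excluding points at or above the 40-cmH2O cap
where the physical sweep stops; `find_v40()` reports the first recorded
crossing. Deflation limbs and hysteresis are out of scope — the bench
inflates only.

### Occlusion-test titration

`simulate_ppot()` applies four quasi-static chamber increments of 2.5, 5.0,
7.5 and 10.0 cmH2O (the bench protocol specifies four increments to
10 cmH2O; equal spacing is the natural reading). `delta_ratio()` reduces the
four excursions to the total-excursion ratio at the largest increment — the
most robust single number, insensitive to the small-increment steps where
noise is proportionally largest. `titrate_volume()` starts from the
catheter's mean `v_accuracy_min`, adds 0.1 mL while the ratio is below 0.8
and removes 0.1 mL above 1.2 (floored at 0), and stops in band, after 100
tests, or when a volume is revisited three times (an oscillation guard;
under the monotone saturating transmission law the walk is single-crossing
and the guard never fires in practice). The low-ratio ⇒ inflate direction
follows from the monotone transmission model. The post-titration sweep holds
the titrated volume fixed and visits the nine chamber pressures in
randomized order per replicate, three replicates, giving 27 TEP values per
catheter.

### Statistics

Descriptive summaries report mean ± SD (sample, $n-1$), median and type-7
linearly interpolated quartiles; a singleton's SD is reported as 0 with a
flag so summary tables never abort. Between-catheter comparisons use the
tie-corrected Kruskal–Wallis H with a $\chi^2_{k-1}$ reference (the all-tied
degenerate case is defined as $H = 0$), followed — only when the global test
is significant at 0.05 — by two-sided Mann–Whitney rank-sum tests over all
$k(k-1)/2$ pairs with Bonferroni correction (Dunn's rank-based post-hoc is a
documented alternative, not implemented). Accuracy proportions are compared
with Fisher's exact test: full conditional enumeration for tables with total
count ≤ 200, a seeded Monte-Carlo p-value (10⁵ permutations) beyond that.
These are standard procedures and are delegated to R's `stats` machinery;
the package's tests verify them against hand-enumerated ranks and full
hypergeometric enumeration written from first principles.

## What the simulator does and does not show

The generator emulates the structural features the analyses depend on — the
plateau-bounded accuracy window moving with chamber pressure, two-segment
balloon curves, saturating occlusion-test transmission, measurement noise —
so passing tests demonstrate that the analysis stages recover known
generative truth under realistic noise. It does not emulate tidal
ventilation or cardiac oscillations, active smooth-muscle tone of the
esophageal wall, balloon hysteresis, or drift between replicates; agreement
on simulated data therefore validates the *procedures*, not any particular
catheter's physical parameters, which on a real bench must come from the
recordings themselves.

## Numerical choices

* Band endpoints inclusive; percentages rounded half-up to one decimal
  (`round()`'s banker's rounding would turn 62.96 into 63.0 *and* 12.45 into
  12.4 depending on parity; summary tables use the decimal convention).
* Chamber sweeps stop on the noise-free crossing of 30 cmH2O (the stop is a
  protocol event, not a recorded quantity); balloon-alone sweeps stop on the
  recorded crossing of 40 cmH2O (the stop is read off the display, and the
  stored curve must contain its terminal crossing).
* Titration: band [0.8, 1.2], step 0.1 mL, `max_iter` 100, three-visit
  oscillation guard; all invented safeguards beyond the stated protocol.
* Determinism: every simulator entry point takes a seed; a grid run consumes
  the RNG in a fixed loop order, so identical config + seed reproduce
  byte-identical tables. With `noise_sd = 0` results are seed-independent.
* Problem sizes in the test suite: the full default grid (189 sweeps) for
  bookkeeping checks, 100 noisy curves per catheter for parameter recovery,
  200 seeded titrations per catheter for convergence, and 10,000 null
  datasets (3 groups × 9) for the rank test's size — all chosen to keep the
  whole suite in the tens of seconds while leaving Monte-Carlo error well
  below the tolerances asserted.

## Known limitations

Quasi-static only; single balloon per catheter (gastric lumens and
sequential-inflation features of dual-balloon models are not modeled);
the transmission ratio saturates below 1, so ratios above 1.2 — possible in
vivo with cardiac artifacts — arise here only through noise; and the
esophagus is a single lumped elastance with no axial position dependence.
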