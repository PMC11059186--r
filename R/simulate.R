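#' Underfill and overfill volume thresholds
#'
#' The forward model places an accuracy plateau between two volume thresholds
#' that move with chamber pressure: positive chamber pressure raises the
#' volume needed to couple the balloon to the chamber (underfilling), while
#' negative chamber pressure lowers the volume at which the balloon starts to
#' distend the esophageal wall (overfilling).
#'
#' @param p_box Chamber pressure (cmH2O); vectorized.
#' @param cath A [catheter_spec()].
#' @return Threshold volume(s) in mL.
#' @export
v_underfill_threshold <- function(p_box, cath) {
  cath$v_u0 + cath$c_u * pmax(0, p_box)
}

#' @rdname v_underfill_threshold
#' @export
v_overfill_threshold <- function(p_box, cath) {
  pmax(v_underfill_threshold(p_box, cath), cath$v_o0 + cath$c_o * p_box)
}

#' Series elastance of balloon and esophageal wall
#'
#' Once the balloon is overfilled it distends the esophageal wall; the excess
#' pressure per mL of overfilling is the series combination
#' \eqn{E_{ser} = e_b e_{es} / (e_b + e_{es})}.
#'
#' @param cath A [catheter_spec()].
#' @param eso An [esophagus_spec()].
#' @return Elastance in cmH2O/mL.
#' @export
series_elastance <- function(cath, eso) {
  cath$e_b * eso$e_es / (cath$e_b + eso$e_es)
}

#' Noise-free transesophageal pressure model
#'
#' Piecewise-linear forward model of the true TEP at inflation volume `v` and
#' chamber pressure `p_box`:
#' \deqn{TEP(v, p) = -k_u \max(0, V_{min}(p) - v) + E_{ser} \max(0, v - V_{ov}(p))}
#' Below the underfill threshold the balloon underestimates (TEP < 0, worst at
#' positive chamber pressure); above the overfill threshold it overestimates
#' (TEP > 0, reached earliest at negative chamber pressure); on the plateau in
#' between TEP is exactly 0.
#'
#' @param v Inflation volume(s), mL (>= 0); vectorized.
#' @param p_box Chamber pressure, cmH2O (scalar).
#' @param cath A [catheter_spec()].
#' @param eso An [esophagus_spec()].
#' @return True TEP(s), cmH2O.
#' @export
tep_model <- function(v, p_box, cath, eso) {
  stopifnot(is.numeric(v), is.numeric(p_box), length(p_box) == 1L)
  if (any(v < 0)) stop("inflation volume must be >= 0", call. = FALSE)
  v_min <- v_underfill_threshold(p_box, cath)
  v_ov <- v_overfill_threshold(p_box, cath)
  -cath$k_u * pmax(0, v_min - v) + series_elastance(cath, eso) * pmax(0, v - v_ov)
}

#' Chamber-to-balloon transmission ratio
#'
#' Fraction of a chamber pressure swing transmitted to the balloon lumen
#' during an occlusion-test maneuver:
#' \eqn{r(v) = 1 - e^{-\max(0, v - v_{dead})/\tau}}. Monotone non-decreasing
#' in volume and saturating below 1.
#'
#' @param v Inflation volume(s), mL; vectorized.
#' @param cath A [catheter_spec()].
#' @return Ratio(s) in [0, 1).
#' @export
transmission_ratio <- function(v, cath) {
  1 - exp(-pmax(0, v - cath$v_dead) / cath$tau)
}

#' Simulate a balloon-alone inflation sweep
#'
#' Inflates the balloon outside the chamber in `volume_step` increments from
#' 0 mL, recording internal pressure, until the first volume whose recorded
#' pressure reaches `p_cap` (default 40 cmH2O) — the operator stops on the
#' displayed reading, so the terminal recorded step always satisfies the
#' stop criterion. The true curve is flat at 0 up to the residual volume
#' `v_res`, then rises with slope `e_b`; recorded pressures carry additive
#' Gaussian noise.
#'
#' @param cath A [catheter_spec()].
#' @param cfg A [bench_config()] (`volume_step`, `noise_sd` are used).
#' @param replicate_id Integer replicate label stored in the output.
#' @param seed Optional integer; when given, seeds the RNG for this sweep.
#' @return A tibble with columns `catheter`, `replicate`, `volume_mL`,
#'   `pressure_cmH2O`.
#' @export
simulate_elastance_sweep <- function(cath, cfg = bench_config(),
                                     replicate_id = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # guard volume: noise-free pressure 12 sd above the cap, so the measured
  # crossing has happened long before with any realistic noise level
  guard_p <- cath$p_cap + 12 * cfg$noise_sd
  n_guard <- ceiling((cath$v_res + guard_p / cath$e_b) / cfg$volume_step)
  v <- seq(0, n_guard * cfg$volume_step, by = cfg$volume_step)
  p_true <- cath$e_b * pmax(0, v - cath$v_res)
  p_meas <- p_true + stats::rnorm(length(v), sd = cfg$noise_sd)
  stop_at <- which(p_meas >= cath$p_cap)[1L]
  if (is.na(stop_at)) stop_at <- length(v)
  v <- v[seq_len(stop_at)]
  p_meas <- p_meas[seq_len(stop_at)]
  tibble::tibble(catheter = cath$name,
                 replicate = as.integer(replicate_id),
                 volume_mL = v,
                 pressure_cmH2O = p_meas)
}

#' Simulate a chamber sweep at one chamber pressure
#'
#' Inflates the balloon inside the pressurized chamber in `volume_step`
#' increments from 0 mL, recording balloon pressure and TEP, until the first
#' volume whose noise-free balloon pressure reaches `p_stop_chamber`. Sweeps
#' whose stop criterion is unreachable within `max_volume` are truncated there
#' and flagged (attribute `truncated`). At least one step is always emitted.
#'
#' @param cath A [catheter_spec()].
#' @param eso An [esophagus_spec()].
#' @param p_box Chamber pressure for this sweep, cmH2O.
#' @param cfg A [bench_config()].
#' @param replicate_id Integer replicate label.
#' @param seed Optional integer RNG seed for this sweep.
#' @return A tibble with columns `catheter`, `p_box_cmH2O`, `replicate`,
#'   `volume_mL`, `p_balloon_cmH2O`, `tep_cmH2O`, `truncated`. TEP is
#'   recorded balloon pressure minus chamber pressure, so noise propagates
#'   into both recorded pressures consistently.
#' @export
simulate_chamber_sweep <- function(cath, eso, p_box, cfg = bench_config(),
                                   replicate_id = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- seq(0, cfg$max_volume, by = cfg$volume_step)
  p_true <- p_box + tep_model(v, p_box, cath, eso)
  stop_at <- which(p_true >= cfg$p_stop_chamber)[1L]
  truncated <- is.na(stop_at)
  if (truncated) stop_at <- length(v)
  idx <- seq_len(max(1L, stop_at))
  p_meas <- p_true[idx] + stats::rnorm(length(idx), sd = cfg$noise_sd)
  out <- tibble::tibble(catheter = cath$name,
                        p_box_cmH2O = p_box,
                        replicate = as.integer(replicate_id),
                        volume_mL = v[idx],
                        p_balloon_cmH2O = p_meas,
                        tep_cmH2O = p_meas - p_box,
                        truncated = truncated)
  attr(out, "truncated") <- truncated
  out
}

#' Simulate one positive-pressure occlusion test
#'
#' Applies four quasi-static chamber pressure increments (2.5, 5.0, 7.5,
#' 10.0 cmH2O) at a fixed balloon volume and records the balloon pressure
#' excursion at each, with transmission governed by [transmission_ratio()].
#'
#' @param cath A [catheter_spec()].
#' @param eso An [esophagus_spec()] (carried for interface symmetry; the
#'   quasi-static excursion is governed by the transmission ratio alone).
#' @param v Balloon inflation volume, mL (>= 0).
#' @param cfg A [bench_config()] (`noise_sd` is used).
#' @param seed Optional integer RNG seed.
#' @return A tibble with columns `delta_p_box_cmH2O`, `delta_p_es_cmH2O`.
#' @export
simulate_ppot <- function(cath, eso, v, cfg = bench_config(), seed = NULL) {
  stopifnot(is.numeric(v), length(v) == 1L)
  if (v < 0) stop("inflation volume must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dp_box <- c(2.5, 5.0, 7.5, 10.0)
  r <- transmission_ratio(v, cath)
  dp_es <- r * dp_box + stats::rnorm(length(dp_box), sd = cfg$noise_sd)
  tibble::tibble(delta_p_box_cmH2O = dp_box, delta_p_es_cmH2O = dp_es)
}

#' Run the full chamber-sweep study grid
#'
#' One chamber sweep per catheter x chamber-pressure level x replicate, in
#' deterministic order (catheters in list order, then pressure levels, then
#' replicates), reproducible from the top-level seed. The default grid of 7
#' catheters, 9 levels and 3 replicates yields 189 sweeps.
#'
#' @param catheters Non-empty list of [catheter_spec()] objects.
#' @param eso An [esophagus_spec()].
#' @param cfg A [bench_config()].
#' @param seed Integer seed for the whole grid.
#' @return A tibble of stacked [simulate_chamber_sweep()] rows.
#' @export
run_study_grid <- function(catheters, eso, cfg = bench_config(), seed = 1L) {
  if (length(catheters) == 0L) stop("need at least one catheter", call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (cath in catheters)
    for (p_box in cfg$p_box_levels)
      for (rep_id in seq_len(cfg$replicates))
        rows[[length(rows) + 1L]] <-
          simulate_chamber_sweep(cath, eso, p_box, cfg, replicate_id = rep_id)
  do.call(rbind, rows)
}

#' Run the balloon-alone elastance phase
#'
#' One inflation sweep per catheter x replicate (default 3 samples per model,
#' so 21 curves for the bundled seven catheters).
#'
#' @inheritParams run_study_grid
#' @return A tibble of stacked [simulate_elastance_sweep()] rows.
#' @export
run_elastance_grid <- function(catheters, cfg = bench_config(), seed = 1L) {
  if (length(catheters) == 0L) stop("need at least one catheter", call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (cath in catheters)
    for (rep_id in seq_len(cfg$replicates))
      rows[[length(rows) + 1L]] <-
        simulate_elastance_sweep(cath, cfg, replicate_id = rep_id)
  do.call(rbind, rows)
}
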