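#' Residual volume by two-segment change-point fit
#'
#' The balloon-alone curve is flat (pressure ~ 0) while the balloon unfurls,
#' then rises linearly. The residual volume is estimated by fitting a hinge
#' model — a constant level up to a breakpoint, a straight line emanating
#' continuously from it — with the breakpoint searched over the measured
#' volume grid, minimizing the total residual sum of squares; remaining exact
#' ties are broken toward the smaller volume. The flat level is estimated
#' jointly rather than fixed at 0, tolerating transducer offset drift. The
#' continuity constraint makes the minimum unique at the true breakpoint on
#' noise-free data (an unconstrained second segment would fit the breakpoint
#' and the grid point below it equally well, since the point at the residual
#' volume lies on both limbs).
#'
#' @param curve A tibble with columns `volume_mL`, `pressure_cmH2O` (one
#'   balloon-alone sweep, >= 3 steps).
#' @param noise_sd Measurement-noise scale used for the degenerate-curve
#'   guard: if the curve never rises more than `3 * noise_sd` above the flat
#'   level, there is no linear region and an error is raised.
#' @return A list with `v_res_hat` (mL), `flat_level` (cmH2O), `rss`
#'   (cmH2O^2).
#' @export
detect_residual_volume <- function(curve, noise_sd = 0.1) {
  stopifnot(all(c("volume_mL", "pressure_cmH2O") %in% names(curve)))
  v <- curve$volume_mL
  p <- curve$pressure_cmH2O
  n <- length(v)
  if (n < 3L) stop("need at least 3 steps", call. = FALSE)
  # candidate breakpoints leave >= 2 points on the rising limb
  best <- NULL
  for (j in seq_len(n - 2L)) {
    fit <- stats::lm.fit(cbind(1, pmax(0, v - v[j])), p)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(v_res_hat = v[j], flat_level = unname(fit$coefficients[1L]),
                   rss = rss)
  }
  if (max(p) - best$flat_level <= 3 * noise_sd)
    stop("no linear region: curve never rises above the flat segment",
         call. = FALSE)
  best
}

#' Balloon elastance by least squares over the linear limb
#'
#' Ordinary least-squares slope of pressure on volume over the points above
#' the estimated residual volume, excluding points at or above `p_cap` where
#' the physical sweep stops.
#'
#' @param curve A balloon-alone sweep tibble (`volume_mL`, `pressure_cmH2O`).
#' @param v_res_hat Estimated residual volume, mL.
#' @param p_cap Sweep stop pressure, cmH2O (default 40).
#' @return Elastance estimate, cmH2O/mL.
#' @export
fit_elastance <- function(curve, v_res_hat, p_cap = 40) {
  sel <- curve$volume_mL > v_res_hat & curve$pressure_cmH2O < p_cap
  if (sum(sel) < 2L)
    stop("need at least 2 points in the linear region", call. = FALSE)
  v <- curve$volume_mL[sel]
  p <- curve$pressure_cmH2O[sel]
  sum((v - mean(v)) * (p - mean(p))) / sum((v - mean(v))^2)
}

#' Volume at which internal pressure reaches the cap
#'
#' @param curve A balloon-alone sweep tibble.
#' @param p_cap Threshold pressure, cmH2O (default 40).
#' @return Smallest measured volume whose pressure is `>= p_cap`, mL.
#' @export
find_v40 <- function(curve, p_cap = 40) {
  hit <- which(curve$pressure_cmH2O >= p_cap)
  if (length(hit) == 0L)
    stop("truncated sweep: no step reaches ", p_cap, " cmH2O", call. = FALSE)
  curve$volume_mL[min(hit)]
}

#' Characterize one balloon-alone curve
#'
#' Runs residual-volume detection, elastance fit and the pressure-cap volume
#' on one sweep.
#'
#' @param curve A balloon-alone sweep tibble; may carry `catheter` and
#'   `replicate` columns which are propagated.
#' @param p_cap Sweep stop pressure, cmH2O.
#' @param noise_sd Noise scale for the change-point degenerate guard.
#' @return A one-row tibble: `catheter`, `replicate`, `v_res_hat`,
#'   `elastance_hat`, `v40_hat`, `fit_rss`, `n_linear_points`.
#' @export
fit_pv_curve <- function(curve, p_cap = 40, noise_sd = 0.1) {
  cp <- detect_residual_volume(curve, noise_sd = noise_sd)
  e_hat <- fit_elastance(curve, cp$v_res_hat, p_cap = p_cap)
  tibble::tibble(
    catheter = if ("catheter" %in% names(curve)) curve$catheter[1L] else NA_character_,
    replicate = if ("replicate" %in% names(curve)) curve$replicate[1L] else NA_integer_,
    v_res_hat = cp$v_res_hat,
    elastance_hat = e_hat,
    v40_hat = find_v40(curve, p_cap),
    fit_rss = cp$rss,
    n_linear_points = sum(curve$volume_mL > cp$v_res_hat &
                            curve$pressure_cmH2O < p_cap)
  )
}

#' Characterize every curve of an elastance phase
#'
#' @param pv Long tibble of curves as produced by [run_elastance_grid()].
#' @param p_cap,noise_sd Passed to [fit_pv_curve()].
#' @return One row per (catheter, replicate) curve.
#' @export
fit_pv_curves <- function(pv, p_cap = 40, noise_sd = 0.1) {
  key <- interaction(pv$catheter, pv$replicate, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(pv)), key),
                               function(i) fit_pv_curve(pv[i, ], p_cap, noise_sd)))
  out[order(match(out$catheter, unique(pv$catheter)), out$replicate), ]
}
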