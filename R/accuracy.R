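#' Transesophageal pressure
#'
#' TEP is the balloon internal pressure minus the surrounding chamber
#' pressure; 0 means perfect transmission.
#'
#' @param p_balloon Balloon pressure(s), cmH2O.
#' @param p_box Chamber pressure(s), cmH2O.
#' @return TEP(s), cmH2O.
#' @export
compute_tep <- function(p_balloon, p_box) p_balloon - p_box

#' Is a TEP reading inside the accuracy band?
#'
#' @param tep TEP value(s), cmH2O.
#' @param band An [accuracy_band()].
#' @return Logical vector.
#' @export
is_accurate <- function(tep, band = accuracy_band()) {
  if (band$inclusive) abs(tep) <= band$half_width else abs(tep) < band$half_width
}

#' Working volume of accuracy
#'
#' Difference between the maximal and minimal in-band inflation volumes.
#'
#' @param v_min,v_max Minimal and maximal volumes of accuracy, mL
#'   (`v_min <= v_max`).
#' @return `v_max - v_min`, mL.
#' @export
working_volume <- function(v_min, v_max) {
  if (any(v_max < v_min, na.rm = TRUE))
    stop("v_max must be >= v_min", call. = FALSE)
  v_max - v_min
}

# round() is banker's rounding; summary tables use decimal half-up.
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Accuracy rate of a set of TEP readings
#'
#' @param teps Non-empty numeric vector of TEP readings, cmH2O.
#' @param band An [accuracy_band()].
#' @return A list with `n_in_band`, `n_total`, and `percent`
#'   (100 * n_in_band / n_total, half-up rounded to one decimal).
#' @export
accuracy_rate <- function(teps, band = accuracy_band()) {
  if (length(teps) == 0L) stop("need at least one TEP value", call. = FALSE)
  n_in <- sum(is_accurate(teps, band))
  list(n_in_band = n_in, n_total = length(teps),
       percent = accuracy_percent(n_in, length(teps)))
}

#' @rdname accuracy_rate
#' @param n_in_band,n_total Counts of in-band and total readings.
#' @export
accuracy_percent <- function(n_in_band, n_total) {
  stopifnot(n_total >= 1, n_in_band >= 0, n_in_band <= n_total)
  round_half_up(100 * n_in_band / n_total, 1)
}

#' Accuracy-volume range of one chamber sweep
#'
#' Extracts the minimal (`v_accuracy_min`) and maximal (`v_accuracy_max`)
#' inflation volumes whose TEP falls inside the accuracy band. Interior
#' out-of-band gaps between the two extremes are ignored for the range but
#' flagged (`has_gaps`) for audit. The working volume `v_working` is
#' `v_accuracy_max - v_accuracy_min`, reported only when at least two
#' in-band volumes exist; with no in-band step both extremes are `NA` and
#' `n_in_band` is 0.
#'
#' @param sweep A tibble with columns `volume_mL` and `tep_cmH2O` (one sweep,
#'   as produced by [simulate_chamber_sweep()]).
#' @param band An [accuracy_band()].
#' @return A one-row tibble: `v_accuracy_min`, `v_accuracy_max`, `v_working`,
#'   `n_in_band`, `has_gaps`, plus any of `catheter`, `p_box_cmH2O`,
#'   `replicate` present in the input.
#' @export
accuracy_volume_range <- function(sweep, band = accuracy_band()) {
  stopifnot(nrow(sweep) >= 1L,
            all(c("volume_mL", "tep_cmH2O") %in% names(sweep)))
  ok <- is_accurate(sweep$tep_cmH2O, band)
  n_in <- sum(ok)
  if (n_in == 0L) {
    v_min <- v_max <- v_work <- NA_real_
    has_gaps <- FALSE
  } else {
    v_in <- sweep$volume_mL[ok]
    v_min <- min(v_in)
    v_max <- max(v_in)
    v_work <- if (n_in >= 2L) working_volume(v_min, v_max) else NA_real_
    span <- sweep$volume_mL >= v_min & sweep$volume_mL <= v_max
    has_gaps <- any(span & !ok)
  }
  keys <- intersect(c("catheter", "p_box_cmH2O", "replicate"), names(sweep))
  out <- tibble::as_tibble(sweep[1L, keys, drop = FALSE])
  out$v_accuracy_min <- v_min
  out$v_accuracy_max <- v_max
  out$v_working <- v_work
  out$n_in_band <- n_in
  out$has_gaps <- has_gaps
  out
}

#' Accuracy-volume ranges for every sweep in a study dataset
#'
#' Applies [accuracy_volume_range()] per (catheter, chamber pressure,
#' replicate) group.
#'
#' @param sweeps Long tibble of sweeps as produced by [run_study_grid()].
#' @param band An [accuracy_band()].
#' @return One row per sweep.
#' @export
accuracy_ranges <- function(sweeps, band = accuracy_band()) {
  key <- interaction(sweeps$catheter, sweeps$p_box_cmH2O, sweeps$replicate,
                     drop = TRUE)
  parts <- lapply(split(seq_len(nrow(sweeps)), key),
                  function(i) accuracy_volume_range(sweeps[i, ], band))
  out <- do.call(rbind, parts)
  out[order(match(out$catheter, unique(sweeps$catheter)),
            out$p_box_cmH2O, out$replicate), ]
}

#' Per-catheter accuracy at manufacturer-recommended volumes
#'
#' Restricts every sweep to the steps whose inflation volume lies within the
#' catheter's recommended range and computes the accuracy rate over those
#' steps. Catheters without a stated range are skipped (row kept, flagged).
#'
#' @param sweeps Long tibble of sweeps as produced by [run_study_grid()].
#' @param catheters Named list of [catheter_spec()] objects covering every
#'   catheter present in `sweeps`.
#' @param band An [accuracy_band()].
#' @return A tibble with one row per catheter: `catheter`, `n_in_band`,
#'   `n_total`, `percent`, `skipped` (no stated range), `empty` (range stated
#'   but no steps fall inside it).
#' @export
recommended_volume_accuracy <- function(sweeps, catheters,
                                        band = accuracy_band()) {
  rows <- lapply(catheters, function(cath) {
    base <- tibble::tibble(catheter = cath$name, n_in_band = NA_integer_,
                           n_total = NA_integer_, percent = NA_real_,
                           skipped = FALSE, empty = FALSE)
    if (is.na(cath$recommended_min) || is.na(cath$recommended_max)) {
      message("no recommended inflation range stated for ", cath$name,
              "; skipped")
      base$skipped <- TRUE
      return(base)
    }
    sel <- sweeps$catheter == cath$name &
      sweeps$volume_mL >= cath$recommended_min &
      sweeps$volume_mL <= cath$recommended_max
    if (!any(sel)) {
      base$n_in_band <- 0L; base$n_total <- 0L; base$empty <- TRUE
      return(base)
    }
    r <- accuracy_rate(sweeps$tep_cmH2O[sel], band)
    base$n_in_band <- r$n_in_band
    base$n_total <- r$n_total
    base$percent <- r$percent
    base
  })
  do.call(rbind, rows)
}

#' Per-catheter descriptive summary of accuracy volumes
#'
#' Pools every sweep of a catheter (across chamber pressures and replicates)
#' and reports mean +/- SD and median (Q1-Q3) of `v_accuracy_min`,
#' `v_accuracy_max` and `v_working`, mirroring the layout of a per-catheter
#' inflation-volume summary table. Missing ranges (sweeps with no in-band
#' step) are dropped per statistic.
#'
#' @param ranges Output of [accuracy_ranges()].
#' @return A tibble, one row per catheter; for each of the three volumes the
#'   columns `<v>_mean`, `<v>_sd`, `<v>_median`, `<v>_q1`, `<v>_q3`.
#' @export
table2_summary <- function(ranges) {
  stat_cols <- c("v_accuracy_min", "v_accuracy_max", "v_working")
  rows <- lapply(split(ranges, factor(ranges$catheter,
                                      levels = unique(ranges$catheter))),
                 function(d) {
    out <- tibble::tibble(catheter = d$catheter[1L])
    for (col in stat_cols) {
      vals <- d[[col]][!is.na(d[[col]])]
      s <- if (length(vals)) summarize_values(vals) else
        list(mean = NA_real_, sd = NA_real_, median = NA_real_,
             q1 = NA_real_, q3 = NA_real_)
      out[[paste0(col, "_mean")]] <- s$mean
      out[[paste0(col, "_sd")]] <- s$sd
      out[[paste0(col, "_median")]] <- s$median
      out[[paste0(col, "_q1")]] <- s$q1
      out[[paste0(col, "_q3")]] <- s$q3
    }
    out
  })
  do.call(rbind, rows)
}
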