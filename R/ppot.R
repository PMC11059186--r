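#' Occlusion-test pressure-transmission ratio
#'
#' Ratio of the balloon pressure excursion to the chamber pressure excursion.
#' Aggregation uses the largest applied increment (the total excursion), the
#' most robust single number when four stepped increments are available.
#'
#' @param excursions A tibble with columns `delta_p_box_cmH2O`,
#'   `delta_p_es_cmH2O`, as produced by [simulate_ppot()]. At least one
#'   excursion with nonzero chamber increment is required.
#' @return Dimensionless ratio.
#' @export
delta_ratio <- function(excursions) {
  stopifnot(all(c("delta_p_box_cmH2O", "delta_p_es_cmH2O") %in% names(excursions)))
  ok <- excursions$delta_p_box_cmH2O != 0
  if (!any(ok)) stop("all chamber increments are zero", call. = FALSE)
  i <- which.max(abs(excursions$delta_p_box_cmH2O))
  excursions$delta_p_es_cmH2O[i] / excursions$delta_p_box_cmH2O[i]
}

#' Titrate balloon volume into the transmission-ratio band
#'
#' Iterates occlusion tests, adjusting the inflation volume in `step_mL`
#' increments until the excursion ratio falls inside `ratio_band`
#' (default 0.8-1.2): a low ratio means an underfilled balloon, so the volume
#' is increased; a high ratio decreases it (floored at 0). Stops when in band,
#' after `max_iter` occlusion tests, or when the same volume has been visited
#' three times (oscillation guard).
#'
#' @param cath A [catheter_spec()].
#' @param eso An [esophagus_spec()].
#' @param start_volume Starting inflation volume, mL (>= 0); the bench
#'   protocol starts at the catheter's mean minimal volume of accuracy from
#'   the characterization phase.
#' @param cfg A [bench_config()] (`noise_sd` is used).
#' @param seed Optional integer RNG seed for the whole titration.
#' @param ratio_band Length-2 numeric target band (default `c(0.8, 1.2)`).
#' @param step_mL Adjustment increment, mL (default 0.1).
#' @param max_iter Maximum number of occlusion tests (default 100).
#' @return A list of class `ppot_result`: `catheter_name`, `start_volume`,
#'   `final_volume`, `final_ratio`, `n_adjustments`, `converged`,
#'   `oscillated`, `excursions` (tibble from the final occlusion test).
#' @export
titrate_volume <- function(cath, eso, start_volume, cfg = bench_config(),
                           seed = NULL, ratio_band = c(0.8, 1.2),
                           step_mL = 0.1, max_iter = 100L) {
  stopifnot(is.numeric(start_volume), length(start_volume) == 1L,
            start_volume >= 0, length(ratio_band) == 2L,
            ratio_band[1] <= ratio_band[2], step_mL > 0)
  if (!is.null(seed)) set.seed(seed)
  v <- start_volume
  visits <- integer(0)
  n_adj <- 0L
  converged <- FALSE
  oscillated <- FALSE
  ratio <- NA_real_
  exc <- NULL
  for (iter in seq_len(max_iter)) {
    key <- sprintf("%.6f", v)
    visits[key] <- if (is.na(visits[key])) 1L else visits[key] + 1L
    if (visits[key] >= 3L) { oscillated <- TRUE; break }
    exc <- simulate_ppot(cath, eso, v, cfg)
    ratio <- delta_ratio(exc)
    if (ratio >= ratio_band[1] && ratio <= ratio_band[2]) {
      converged <- TRUE
      break
    }
    v <- if (ratio < ratio_band[1]) v + step_mL else max(0, v - step_mL)
    n_adj <- n_adj + 1L
  }
  structure(list(catheter_name = cath$name,
                 start_volume = start_volume,
                 final_volume = v,
                 final_ratio = ratio,
                 n_adjustments = n_adj,
                 converged = converged,
                 oscillated = oscillated,
                 excursions = exc),
            class = "ppot_result")
}

#' @export
print.ppot_result <- function(x, ...) {
  cat(sprintf(
    "<ppot_result> %s: %.2f -> %.2f mL in %d adjustment(s); ratio %.3f (%s)\n",
    x$catheter_name, x$start_volume, x$final_volume, x$n_adjustments,
    x$final_ratio,
    if (x$converged) "converged" else if (x$oscillated) "oscillated" else "not converged"))
  invisible(x)
}

#' Fixed-volume accuracy sweep after titration
#'
#' With the titrated inflation volume held fixed, visits every chamber
#' pressure level in randomized order per replicate (the bench applies
#' randomized increments or decrements) and records TEP: 9 levels x 3
#' replicates = 27 values per catheter under the default configuration.
#'
#' @param cath A [catheter_spec()].
#' @param eso An [esophagus_spec()].
#' @param volume Fixed inflation volume, mL.
#' @param cfg A [bench_config()].
#' @param seed Optional integer RNG seed.
#' @return A tibble with one row per measurement: `catheter`, `replicate`,
#'   `visit_order`, `p_box_cmH2O`, `tep_cmH2O`.
#' @export
post_titration_sweep <- function(cath, eso, volume, cfg = bench_config(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (rep_id in seq_len(cfg$replicates)) {
    ord <- sample.int(length(cfg$p_box_levels))
    p_seq <- cfg$p_box_levels[ord]
    tep <- vapply(p_seq, function(p) tep_model(volume, p, cath, eso), numeric(1))
    tep <- tep + stats::rnorm(length(tep), sd = cfg$noise_sd)
    rows[[rep_id]] <- tibble::tibble(catheter = cath$name,
                                     replicate = rep_id,
                                     visit_order = seq_along(p_seq),
                                     p_box_cmH2O = p_seq,
                                     tep_cmH2O = tep)
  }
  do.call(rbind, rows)
}

#' Summarize post-titration TEP accuracy per catheter
#'
#' Accuracy counts and descriptive statistics of the fixed-volume TEP values,
#' one row per catheter (in-band count out of the per-catheter total, percent,
#' mean +/- SD, median, Q1, Q3).
#'
#' @param teps Long tibble from [post_titration_sweep()] (possibly several
#'   catheters stacked).
#' @param band An [accuracy_band()].
#' @return A tibble, one row per catheter.
#' @export
table3_summary <- function(teps, band = accuracy_band()) {
  rows <- lapply(split(teps, factor(teps$catheter, levels = unique(teps$catheter))),
                 function(d) {
    r <- accuracy_rate(d$tep_cmH2O, band)
    s <- summarize_values(d$tep_cmH2O)
    tibble::tibble(catheter = d$catheter[1L],
                   n_in_band = r$n_in_band, n_total = r$n_total,
                   percent = r$percent,
                   tep_mean = s$mean, tep_sd = s$sd,
                   tep_median = s$median, tep_q1 = s$q1, tep_q3 = s$q3)
  })
  do.call(rbind, rows)
}

#' Run the whole occlusion-test phase
#'
#' For every catheter: titrate the volume starting from its mean minimal
#' volume of accuracy, then run the fixed-volume accuracy sweep. Catheters
#' whose titration fails to converge are flagged, not dropped.
#'
#' @param catheters Named list of [catheter_spec()] objects.
#' @param eso An [esophagus_spec()].
#' @param start_volumes Named numeric vector of starting volumes (mL), one per
#'   catheter name; typically mean `v_accuracy_min` per catheter from
#'   [accuracy_ranges()]. Missing or `NA` entries start at 0.
#' @param cfg A [bench_config()].
#' @param seed Integer seed for the phase.
#' @return A list: `titrations` (list of `ppot_result`), `teps` (long tibble),
#'   `summary` (tibble from [table3_summary()] with a `converged` column).
#' @export
run_ppot_phase <- function(catheters, eso, start_volumes,
                           cfg = bench_config(), seed = 1L) {
  set.seed(seed)
  titr <- list()
  teps <- list()
  for (cath in catheters) {
    sv <- start_volumes[[cath$name]]
    if (is.null(sv) || is.na(sv)) sv <- 0
    res <- titrate_volume(cath, eso, sv, cfg)
    titr[[cath$name]] <- res
    teps[[cath$name]] <- post_titration_sweep(cath, eso, res$final_volume, cfg)
  }
  teps <- do.call(rbind, teps)
  summ <- table3_summary(teps)
  summ$converged <- unname(vapply(summ$catheter,
                                  function(nm) titr[[nm]]$converged,
                                  logical(1)))
  list(titrations = titr, teps = teps, summary = summ)
}
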