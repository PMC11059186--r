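#' Catheter specification
#'
#' Generative parameters of one esophageal-balloon (EB) catheter model, used
#' both to drive the bench simulator and to carry manufacturer metadata.
#' Volumes are in mL, pressures in cmH2O, elastances in cmH2O/mL.
#'
#' @param name Text label, unique within a study.
#' @param v_res Residual volume: inflation volume consumed unfurling the
#'   balloon before internal pressure rises linearly (mL, >= 0).
#' @param e_b Balloon elastance: slope of the linear limb of the balloon-alone
#'   pressure-volume curve (cmH2O/mL, > 0).
#' @param v_dead Transmission dead volume below which chamber pressure swings
#'   do not reach the balloon lumen (mL, >= 0).
#' @param tau Volume constant of the transmission ratio
#'   \eqn{r(v) = 1 - e^{-(v - v_{dead})/\tau}} (mL, > 0).
#' @param v_u0,c_u Underfill threshold \eqn{V_{min}(p) = v_{u0} + c_u \max(0, p)}:
#'   intercept (mL) and slope (mL per cmH2O, >= 0).
#' @param k_u Underestimation gain: cmH2O of negative transesophageal pressure
#'   per mL of underfilling (>= 0).
#' @param v_o0,c_o Overfill threshold \eqn{V_{ov}(p) = \max(V_{min}(p), v_{o0} + c_o p)}:
#'   intercept (mL) and slope (mL per cmH2O, >= 0). A negative chamber
#'   pressure lowers the threshold, so large volumes overestimate there.
#' @param recommended_min,recommended_max Manufacturer recommended inflation
#'   range (mL); `NA` when the manufacturer states none.
#' @param p_cap Pressure at which a balloon-alone inflation sweep stops
#'   (cmH2O, default 40).
#'
#' @return An object of class `catheter_spec`.
#' @export
catheter_spec <- function(name, v_res, e_b, v_dead, tau,
                          v_u0, c_u, k_u, v_o0, c_o,
                          recommended_min = NA_real_,
                          recommended_max = NA_real_,
                          p_cap = 40) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  num1 <- function(x, nm) {
    if (length(x) == 1L && is.na(x)) return(NA_real_)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  spec <- list(
    name = name,
    v_res = num1(v_res, "v_res"), e_b = num1(e_b, "e_b"),
    v_dead = num1(v_dead, "v_dead"), tau = num1(tau, "tau"),
    v_u0 = num1(v_u0, "v_u0"), c_u = num1(c_u, "c_u"),
    k_u = num1(k_u, "k_u"),
    v_o0 = num1(v_o0, "v_o0"), c_o = num1(c_o, "c_o"),
    recommended_min = num1(recommended_min, "recommended_min"),
    recommended_max = num1(recommended_max, "recommended_max"),
    p_cap = num1(p_cap, "p_cap")
  )
  if (spec$v_res < 0) stop("v_res must be >= 0", call. = FALSE)
  if (spec$e_b <= 0) stop("e_b must be > 0", call. = FALSE)
  if (spec$v_dead < 0) stop("v_dead must be >= 0", call. = FALSE)
  if (spec$tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (spec$v_u0 < 0 || spec$v_o0 < 0) stop("thresholds must be >= 0", call. = FALSE)
  if (spec$c_u < 0 || spec$c_o < 0) stop("threshold slopes must be >= 0", call. = FALSE)
  if (spec$k_u < 0) stop("k_u must be >= 0", call. = FALSE)
  if (spec$v_o0 < spec$v_u0) stop("v_o0 must be >= v_u0", call. = FALSE)
  if (!is.na(spec$recommended_min) && !is.na(spec$recommended_max) &&
      spec$recommended_max < spec$recommended_min)
    stop("recommended_max must be >= recommended_min", call. = FALSE)
  structure(spec, class = "catheter_spec")
}

#' @export
print.catheter_spec <- function(x, ...) {
  rec <- if (is.na(x$recommended_min)) "none stated" else
    sprintf("%.1f-%.1f mL", x$recommended_min, x$recommended_max)
  cat(sprintf(
    "<catheter_spec> %s\n  V_res %.2f mL, elastance %.2f cmH2O/mL, recommended range: %s\n",
    x$name, x$v_res, x$e_b, rec))
  invisible(x)
}

#' Esophagus specification
#'
#' Mechanical and bookkeeping parameters of the ex-vivo esophagus mounted in
#' the pressure chamber.
#'
#' @param e_es Esophageal wall elastance (cmH2O/mL, > 0). Acts in series with
#'   the balloon elastance when the balloon distends the wall.
#' @param storage_days,temperature_c Reporting metadata only (cold-storage
#'   duration in days, bath temperature in Celsius); no mechanical effect.
#'
#' @return An object of class `esophagus_spec`.
#' @export
esophagus_spec <- function(e_es, storage_days = NA_real_, temperature_c = NA_real_) {
  stopifnot(is.numeric(e_es), length(e_es) == 1L, is.finite(e_es))
  if (e_es <= 0) stop("e_es must be > 0", call. = FALSE)
  structure(list(e_es = as.numeric(e_es),
                 storage_days = as.numeric(storage_days),
                 temperature_c = as.numeric(temperature_c)),
            class = "esophagus_spec")
}

#' Bench configuration
#'
#' Protocol parameters of the bench: the chamber-pressure levels, inflation
#' step, stop criteria and the measurement-noise level.
#'
#' @param p_box_levels Ordered chamber pressures (cmH2O); default -20 to +20
#'   in 5-cmH2O increments (9 levels). Must be strictly monotone.
#' @param volume_step Inflation increment per step (mL, > 0; default 0.5).
#' @param p_stop_chamber Chamber sweeps stop at the first volume whose
#'   noise-free balloon pressure reaches this value (cmH2O; default 30).
#' @param max_volume Guard against unreachable stop criteria: a chamber sweep
#'   is truncated (and flagged) at this volume (mL; default 10).
#' @param noise_sd Gaussian measurement noise on recorded pressures (cmH2O;
#'   default 0.1).
#' @param replicates Replicates per experimental cell (>= 1; default 3).
#'
#' @return An object of class `bench_config`.
#' @export
bench_config <- function(p_box_levels = seq(-20, 20, by = 5),
                         volume_step = 0.5,
                         p_stop_chamber = 30,
                         max_volume = 10,
                         noise_sd = 0.1,
                         replicates = 3) {
  stopifnot(is.numeric(p_box_levels), length(p_box_levels) >= 1L)
  if (length(p_box_levels) > 1L) {
    d <- diff(p_box_levels)
    if (!(all(d > 0) || all(d < 0)))
      stop("p_box_levels must be strictly monotone", call. = FALSE)
  }
  if (!is.numeric(volume_step) || volume_step <= 0)
    stop("volume_step must be > 0", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.numeric(replicates) || replicates < 1 || replicates != round(replicates))
    stop("replicates must be an integer >= 1", call. = FALSE)
  if (!is.numeric(max_volume) || max_volume <= 0)
    stop("max_volume must be > 0", call. = FALSE)
  structure(list(p_box_levels = as.numeric(p_box_levels),
                 volume_step = as.numeric(volume_step),
                 p_stop_chamber = as.numeric(p_stop_chamber),
                 max_volume = as.numeric(max_volume),
                 noise_sd = as.numeric(noise_sd),
                 replicates = as.integer(replicates)),
            class = "bench_config")
}

#' Transesophageal-pressure accuracy band
#'
#' A TEP reading is accurate when it falls within 0 +/- `half_width` cmH2O.
#' Endpoints are inclusive by default, reading "0 +/- 1 cmH2O" as a closed
#' interval.
#'
#' @param half_width Half-width of the band (cmH2O, > 0; default 1).
#' @param inclusive Whether the band endpoints count as accurate (default TRUE).
#' @return An object of class `accuracy_band`.
#' @export
accuracy_band <- function(half_width = 1, inclusive = TRUE) {
  stopifnot(is.numeric(half_width), length(half_width) == 1L, half_width > 0,
            is.logical(inclusive), length(inclusive) == 1L)
  structure(list(half_width = as.numeric(half_width), inclusive = inclusive),
            class = "accuracy_band")
}

#' Bundled catheter fixtures
#'
#' Reads the bundled set of seven catheter models. Residual volumes and
#' elastances of the named commercial models follow published bench medians
#' (e.g. Cooper elastance 15.7 cmH2O/mL, residual volume 0.5 mL; Aspisafe NG
#' 1.9 cmH2O/mL and 9.0 mL); parameters not publicly printed are synthetic and
#' flagged as such in the JSON.
#'
#' @param path Optional path to a catheter JSON file; defaults to the bundled
#'   fixture.
#' @return A named list of [catheter_spec()] objects.
#' @export
default_catheters <- function(path = system.file("extdata", "catheters.json",
                                                 package = "ebbench")) {
  read_catheters(path)
}

#' Read catheter specifications from JSON
#'
#' @param path Path to a JSON array of catheter objects; field names match the
#'   arguments of [catheter_spec()]. Unknown fields are rejected by name.
#' @return A named list of [catheter_spec()] objects.
#' @export
read_catheters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  specs <- lapply(raw, function(rec) {
    rec$synthetic_parameters <- NULL  # provenance note, not a model parameter
    known <- names(formals(catheter_spec))
    extra <- setdiff(names(rec), known)
    if (length(extra))
      stop("unknown catheter field(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    rec[c("recommended_min", "recommended_max")] <-
      lapply(rec[c("recommended_min", "recommended_max")],
             function(x) if (is.null(x)) NA_real_ else x)
    do.call(catheter_spec, rec)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs)))
    stop("catheter names must be unique", call. = FALSE)
  specs
}
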