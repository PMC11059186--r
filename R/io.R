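#' Read a study configuration from JSON
#'
#' A study configuration bundles the bench protocol, the catheter set and the
#' esophagus under the top-level keys `bench`, `catheters`, `esophagus` (plus
#' an optional `seed`). Unknown keys at any level are rejected by name.
#'
#' @param path Path to a JSON configuration file.
#' @return A list of class `study_config`: `bench` ([bench_config()]),
#'   `catheters` (named list of [catheter_spec()]), `esophagus`
#'   ([esophagus_spec()]), `seed` (integer or `NA`).
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  known <- c("bench", "catheters", "esophagus", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  check_fields <- function(rec, fn, what) {
    extra <- setdiff(names(rec), names(formals(fn)))
    if (length(extra))
      stop("unknown ", what, " field(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    rec
  }
  bench <- raw$bench %||% list()
  if (!is.null(bench$p_box_levels)) bench$p_box_levels <- unlist(bench$p_box_levels)
  bench <- do.call(bench_config, check_fields(bench, bench_config, "bench"))
  eso <- do.call(esophagus_spec,
                 check_fields(raw$esophagus %||% list(e_es = 4),
                              esophagus_spec, "esophagus"))
  caths <- if (is.null(raw$catheters)) default_catheters() else {
    specs <- lapply(raw$catheters, function(rec) {
      rec$synthetic_parameters <- NULL
      rec[c("recommended_min", "recommended_max")] <-
        lapply(rec[c("recommended_min", "recommended_max")],
               function(x) if (is.null(x)) NA_real_ else x)
      do.call(catheter_spec, check_fields(rec, catheter_spec, "catheter"))
    })
    names(specs) <- vapply(specs, `[[`, character(1), "name")
    if (anyDuplicated(names(specs)))
      stop("catheter names must be unique", call. = FALSE)
    specs
  }
  structure(list(bench = bench, catheters = caths, esophagus = eso,
                 seed = if (is.null(raw$seed)) NA_integer_ else
                   as.integer(raw$seed)),
            class = "study_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default study configuration
#'
#' The bundled seven-catheter study: default bench protocol (chamber
#' pressures -20 to +20 cmH2O in 5-cmH2O steps, 0.5-mL inflation increments,
#' 3 replicates, 0.1-cmH2O measurement noise) and an esophageal wall
#' elastance of 4 cmH2O/mL.
#'
#' @param seed Integer seed stored in the configuration.
#' @return A `study_config` list.
#' @export
default_study_config <- function(seed = 1L) {
  structure(list(bench = bench_config(),
                 catheters = default_catheters(),
                 esophagus = esophagus_spec(e_es = 4, storage_days = 19,
                                            temperature_c = 37),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Write and read sweep tables
#'
#' Long-format CSV round trip for chamber sweeps
#' (`catheter,p_box_cmH2O,replicate,volume_mL,p_balloon_cmH2O,tep_cmH2O,truncated`)
#' and balloon-alone curves
#' (`catheter,replicate,volume_mL,pressure_cmH2O`). Comma-separated, UTF-8,
#' `.` decimal, header row mandatory; units are encoded in the column names.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `read_*` return tibbles; `write_*` return `path` invisibly.
#' @export
write_sweeps_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweeps_csv
#' @export
read_sweeps_csv <- function(path) {
  need <- c("catheter", "p_box_cmH2O", "replicate", "volume_mL",
            "p_balloon_cmH2O", "tep_cmH2O")
  read_checked_csv(path, need)
}

#' @rdname write_sweeps_csv
#' @export
write_pv_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweeps_csv
#' @export
read_pv_csv <- function(path) {
  read_checked_csv(path, c("catheter", "replicate", "volume_mL",
                           "pressure_cmH2O"))
}

read_checked_csv <- function(path, need) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  tibble::as_tibble(x)
}

#' Provenance record for a simulated dataset
#'
#' Seed, configuration digest and record counts, sufficient to regenerate a
#' dataset bit-identically and audit any downstream report.
#'
#' @param config A `study_config`.
#' @param seed Integer seed actually used.
#' @param counts Named list/vector of per-stage record counts.
#' @param path Optional path; when given the record is also written as JSON.
#' @return The provenance list, invisibly when written.
#' @export
provenance_record <- function(config, seed, counts = list(), path = NULL) {
  cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  rec <- list(seed = as.integer(seed),
              config_sha = digest_string(as.character(cfg_json)),
              counts = counts,
              timestamp = format(Sys.time(), tz = "UTC",
                                 format = "%Y-%m-%dT%H:%M:%SZ"))
  if (!is.null(path)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rec))
  }
  rec
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

# Small FNV-1a content digest; enough to detect config drift in provenance
# logs without an external hashing dependency.
digest_string <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("fnv1a-%08x", as.integer(h))
}
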