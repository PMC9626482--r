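#' Sweep the lowest-cluster dose-rate centroid over voltage and frequency
#'
#' For every (voltage, frequency) cell at fixed flow, runs extract -> cluster
#' -> summarise on the supplied dose-damage database and records the centroid
#' of the lowest dose-rate cluster. Cells where every database point is
#' unreachable are `NA` (undefined, never zero-filled). Default grid follows
#' the study: frequencies 0.5 to 4 kHz in 0.25 kHz steps at 7, 8 and 9 kV.
#'
#' @param predictor a `damage_predictor`.
#' @param db dose-damage database (one radiation type, typically).
#' @param voltages,frequencies sweep grids (kV, kHz).
#' @param flow fixed feed-gas flow, slm.
#' @param k clusters per cell (default 4).
#' @param restarts,seed passed to [kmeans_1d()].
#' @param ... inversion settings forwarded to [extract_dose_rates()].
#' @return object of class `sweep_grid`: list with `centroid`, a
#'   |voltages| x |frequencies| matrix of lowest-cluster centroids (Gy/s),
#'   `min_rate`, the matching matrix of minimum retained member rates in the
#'   lowest cluster, plus the axes.
#' @export
parameter_sweep <- function(predictor, db, voltages = c(7, 8, 9),
                            frequencies = seq(0.5, 4, by = 0.25), flow = 2,
                            k = 4L, restarts = 10L, seed = 1L, ...) {
  if (!length(voltages) || !length(frequencies)) {
    stop_bad("empty sweep grid", "invalid_parameter")
  }
  if (!nrow(db)) stop_bad("empty database for sweep", "invalid_parameter")
  centroid <- matrix(NA_real_, length(voltages), length(frequencies),
                     dimnames = list(paste0(voltages, "kV"),
                                     paste0(frequencies, "kHz")))
  min_rate <- centroid
  for (i in seq_along(voltages)) {
    for (j in seq_along(frequencies)) {
      est <- extract_dose_rates(predictor, voltage = voltages[i],
                                frequency = frequencies[j], flow = flow,
                                db = db, ...)
      ok <- which(est$reachable)
      if (length(ok) < k) next            # undefined cell
      cl <- cluster_dose_rates(est, k = k, restarts = restarts,
                               seed = stage_seed(seed, sprintf("cell_%d_%d", i, j)))
      low <- cl$summary[cl$summary$label == 1, ]
      centroid[i, j] <- low$centroid_Gy_per_s
      min_rate[i, j] <- min(unlist(low$retained))
    }
  }
  structure(list(centroid = centroid, min_rate = min_rate,
                 voltages = voltages, frequencies = frequencies, flow = flow,
                 k = k),
            class = "sweep_grid")
}

#' Relative deviation of swept dose rates from a reference rate
#'
#' Cellwise |estimate - reference| / reference; undefined (NA) cells
#' propagate.
#'
#' @param sweep a `sweep_grid` from [parameter_sweep()] (or a numeric matrix).
#' @param reference reference dose rate, Gy/s (> 0).
#' @return matrix of dimensionless deviations.
#' @export
relative_deviation_grid <- function(sweep, reference) {
  if (!is.numeric(reference) || length(reference) != 1 || reference <= 0) {
    stop_bad("'reference' must be a single rate > 0", "invalid_parameter")
  }
  est <- if (inherits(sweep, "sweep_grid")) sweep$centroid else sweep
  abs(est - reference) / reference
}

#' Reference dose rates per radiation type
#'
#' Reads a JSON map of radiation type to reference dose rate (Gy/s). Entries
#' may carry `"placeholder": true`; placeholder-derived comparisons are
#' labelled as such downstream. The packaged
#' `extdata/reference_rates_synthetic.json` ships clearly-labelled arbitrary
#' placeholders — the study's literature table is not public.
#'
#' @param path JSON file; default the packaged synthetic placeholders.
#' @return data.frame with `radiation_type`, `rate_Gy_per_s`, `placeholder`.
#' @export
read_reference_rates <- function(path = system.file(
  "extdata", "reference_rates_synthetic.json", package = "plasmadose")) {
  raw <- jsonlite::read_json(path)
  raw <- raw[vapply(raw, function(e) is.list(e) && !is.null(e$rate_Gy_per_s),
                    TRUE)]
  rows <- lapply(names(raw), function(ty) {
    e <- raw[[ty]]
    data.frame(radiation_type = ty, rate_Gy_per_s = as.numeric(e$rate_Gy_per_s),
               placeholder = isTRUE(e$placeholder))
  })
  out <- do.call(rbind, rows)
  if (any(out$rate_Gy_per_s <= 0)) stop_bad("reference rates must be > 0",
                                            "configuration_error")
  out
}

#' Measured LTP dose rates from traditional dosimeters
#'
#' The two laboratory measurements at 8 kV, 1 kHz, 2 slm that bracket the
#' modelled estimates: the Fricke chemical dosimeter (0.76 Gy/s) and the
#' alanine/EPR dosimeter (0.01 Gy/s). Consumed as comparison constants only.
#'
#' @return named numeric vector of rates, Gy/s.
#' @export
measured_ltp_rates <- function() {
  raw <- jsonlite::read_json(system.file("extdata", "measured_ltp_rates.json",
                                         package = "plasmadose"))
  raw <- raw[vapply(raw, is.list, TRUE)]
  vapply(raw, function(e) as.numeric(e$rate_Gy_per_s), 0)
}

#' Per-type comparison summary against reference dose rates
#'
#' For each radiation type with a sweep: the minimum and mean relative
#' deviation over defined cells, and the ratio of the minimum estimated rate
#' within the lowest cluster across the sweep to the reference rate. Types
#' whose sweep has no defined cell are excluded with a warning (the study
#' likewise excluded some radiation types).
#'
#' @param sweeps named list of `sweep_grid` objects, one per radiation type.
#' @param references data.frame from [read_reference_rates()].
#' @return data.frame with one row per comparable type: `radiation_type`,
#'   `min_rel_dev`, `avg_rel_dev`, `min_rate_Gy_per_s`, `reference_Gy_per_s`,
#'   `ratio_min_to_reference`, `placeholder`.
#' @export
comparison_summary <- function(sweeps, references) {
  rows <- lapply(names(sweeps), function(ty) {
    ref <- references[references$radiation_type == ty, ]
    if (!nrow(ref)) {
      warning(sprintf("no reference rate for '%s'; excluded", ty), call. = FALSE)
      return(NULL)
    }
    sw <- sweeps[[ty]]
    dev <- relative_deviation_grid(sw, ref$rate_Gy_per_s)
    if (all(is.na(dev))) {
      warning(sprintf("all sweep cells undefined for '%s'; excluded", ty),
              call. = FALSE)
      return(NULL)
    }
    mn_rate <- min(sw$min_rate, na.rm = TRUE)
    data.frame(radiation_type = ty,
               min_rel_dev = min(dev, na.rm = TRUE),
               avg_rel_dev = mean(dev, na.rm = TRUE),
               min_rate_Gy_per_s = mn_rate,
               reference_Gy_per_s = ref$rate_Gy_per_s,
               ratio_min_to_reference = mn_rate / ref$rate_Gy_per_s,
               placeholder = ref$placeholder)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a sweep grid (or deviation matrix) as CSV
#'
#' Rows are voltages, columns frequencies; the header row/column carry units.
#'
#' @param m matrix with the sweep dimnames, or a `sweep_grid`.
#' @param path output path.
#' @export
write_sweep_csv <- function(m, path) {
  if (inherits(m, "sweep_grid")) m <- m$centroid
  df <- data.frame(voltage = rownames(m), m, check.names = FALSE)
  write_csv_lf(df, path)
}
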