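#' Kinetics configuration for the synthetic ground truth
#'
#' Parameterizes the saturating-exponential damage kinetics used as synthetic
#' ground truth: \deqn{D(V, f, Q, t) = d_{max} (1 - e^{-k t}),\quad
#' k = k_0 (V/V_0)^{\alpha_V} (f/f_0)^{\alpha_f} (Q/Q_0)^{\alpha_Q}.}
#' The form is linear in time at short exposures and saturates later, which is
#' the qualitative shape of plasma-induced DNA damage accumulation; the rate
#' constant grows with applied voltage and pulse frequency.
#'
#' @param k0 base rate constant (1/s) at the reference operating point.
#' @param ref_voltage,ref_frequency,ref_flow reference point (kV, kHz, slm).
#' @param alpha_v,alpha_f,alpha_q power-law exponents on voltage, frequency
#'   and feed-gas flow.
#' @param d_max saturation damage level, percent (0 < d_max <= 100).
#' @param noise_sd additive Gaussian noise standard deviation, percent.
#' @param seed integer seed used when the config drives data generation.
#' @return an object of class `kinetics_config`.
#' @export
kinetics_config <- function(k0 = 0.02, ref_voltage = 8, ref_frequency = 1,
                            ref_flow = 2, alpha_v = 2, alpha_f = 1,
                            alpha_q = 0.5, d_max = 100, noise_sd = 2,
                            seed = 1L) {
  check_finite_positive(k0, "k0")
  check_finite_positive(ref_voltage, "ref_voltage")
  check_finite_positive(ref_frequency, "ref_frequency")
  check_finite_positive(ref_flow, "ref_flow")
  if (!is.finite(d_max) || d_max <= 0 || d_max > 100) {
    stop_bad("'d_max' must lie in (0, 100]", "invalid_parameter")
  }
  check_finite_nonneg(noise_sd, "noise_sd")
  structure(list(k0 = k0, ref_voltage = ref_voltage,
                 ref_frequency = ref_frequency, ref_flow = ref_flow,
                 alpha_v = alpha_v, alpha_f = alpha_f, alpha_q = alpha_q,
                 d_max = d_max, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "kinetics_config")
}

kinetic_rate <- function(voltage, frequency, flow, kinetics) {
  kinetics$k0 *
    (voltage   / kinetics$ref_voltage)   ^ kinetics$alpha_v *
    (frequency / kinetics$ref_frequency) ^ kinetics$alpha_f *
    (flow      / kinetics$ref_flow)      ^ kinetics$alpha_q
}

#' Noise-free synthetic DNA damage at an operating point
#'
#' Evaluates the ground-truth kinetics. Vectorized over all four process
#' parameters (recycled to a common length).
#'
#' @param voltage applied voltage, kV (> 0).
#' @param frequency pulse frequency, kHz (> 0).
#' @param flow feed-gas flow, slm (> 0).
#' @param time irradiation time, s (>= 0).
#' @param kinetics a [kinetics_config()].
#' @return percent DNA damage in [0, d_max]; strictly increasing in `time`.
#' @export
true_damage <- function(voltage, frequency, flow, time,
                        kinetics = kinetics_config()) {
  check_finite_positive(voltage, "voltage")
  check_finite_positive(frequency, "frequency")
  check_finite_positive(flow, "flow")
  check_finite_nonneg(time, "time")
  k <- kinetic_rate(voltage, frequency, flow, kinetics)
  kinetics$d_max * (1 - exp(-k * time))
}

#' Generate a synthetic design-of-experiments (DoE) damage table
#'
#' Builds the full factorial of the supplied factor levels, replicated, and
#' evaluates the ground-truth kinetics plus additive Gaussian noise truncated
#' to [0, 100] percent. Records at irradiation times below a typical
#' short-time cutoff form the minority stratum that downstream oversampling
#' targets.
#'
#' Default levels: V in {7..11} kV, f in {0.5, 1, 2, 3, 4} kHz, Q in {1, 2, 3}
#' slm, t in {5, 10, 20, 30, 40, 60} s, three replicates.
#'
#' @param levels named list with numeric vectors `voltage`, `frequency`,
#'   `flow`, `time` (at least one level each).
#' @param kinetics a [kinetics_config()]; `noise_sd` and `d_max` are taken
#'   from it.
#' @param replicates replicate count per factorial cell (>= 1).
#' @param seed integer seed; identical seed gives an identical table.
#' @return data.frame with columns `voltage_kV`, `frequency_kHz`, `flow_slm`,
#'   `time_s`, `damage_pct`.
#' @export
generate_doe_dataset <- function(levels = default_doe_levels(),
                                 kinetics = kinetics_config(),
                                 replicates = 3L,
                                 seed = kinetics$seed) {
  need <- c("voltage", "frequency", "flow", "time")
  if (!all(need %in% names(levels)) ||
      any(vapply(levels[need], length, 1L) == 0)) {
    stop_bad("'levels' needs non-empty voltage/frequency/flow/time vectors",
             "configuration_error")
  }
  if (replicates < 1) stop_bad("'replicates' must be >= 1", "configuration_error")
  grid <- expand.grid(voltage = levels$voltage, frequency = levels$frequency,
                      flow = levels$flow, time = levels$time,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[rep(seq_len(nrow(grid)), each = replicates), , drop = FALSE]
  mu <- true_damage(grid$voltage, grid$frequency, grid$flow, grid$time, kinetics)
  damage <- with_seed(seed, mu + rnorm(length(mu), 0, kinetics$noise_sd))
  damage <- pmin(100, pmax(0, damage))
  data.frame(voltage_kV = grid$voltage, frequency_kHz = grid$frequency,
             flow_slm = grid$flow, time_s = grid$time, damage_pct = damage,
             row.names = NULL)
}

#' @rdname generate_doe_dataset
#' @export
default_doe_levels <- function() {
  list(voltage = c(7, 8, 9, 10, 11), frequency = c(0.5, 1, 2, 3, 4),
       flow = c(1, 2, 3), time = c(5, 10, 20, 30, 40, 60))
}

#' Configuration of the synthetic dose vs. DNA-damage literature database
#'
#' Each radiation type gets a number of simulated "studies". A study draws its
#' damage-per-Gy sensitivity beta (percent/Gy) from a log-normal mixture,
#' emulating between-study heterogeneity (different DNA substrates, buffers,
#' assays); well-separated mixture components seed distinct dose-rate clusters
#' downstream. Within a study, damage follows the saturating curve
#' `cap * (1 - exp(-beta * dose / cap))` over a (log-spaced) dose grid.
#'
#' Component medians default to 0.2, 1, 5 and 25 percent/Gy — an
#' orders-of-magnitude spread of the kind literature compilations show — with
#' small log-scale spread so components stay identifiable. All defaults are
#' placeholders for the unpublished literature compilation.
#'
#' @param types character vector of radiation types.
#' @param n_studies simulated studies per type.
#' @param beta_meanlog,beta_sdlog,beta_weights log-normal mixture parameters
#'   (weights must sum to 1).
#' @param dose_min,dose_max,dose_points dose grid per study, Gy (min < max).
#' @param log_spaced logical; log-spaced dose grid.
#' @param cap saturation cap, percent.
#' @param noise_sd additive damage noise, percent.
#' @param seed integer seed.
#' @return an object of class `literature_db_config`.
#' @export
literature_db_config <- function(types = c("gamma", "xray", "proton", "ion"),
                                 n_studies = 8L,
                                 beta_meanlog = log(c(0.2, 1, 5, 25)),
                                 beta_sdlog = rep(0.15, 4),
                                 beta_weights = rep(0.25, 4),
                                 dose_min = 1, dose_max = 1000,
                                 dose_points = 12L, log_spaced = TRUE,
                                 cap = 100, noise_sd = 0,
                                 seed = 1L) {
  ok_types <- c("gamma", "xray", "proton", "ion", "alpha", "electron", "uv")
  if (!all(types %in% ok_types)) {
    stop_bad(sprintf("unknown radiation type(s): %s",
                     paste(setdiff(types, ok_types), collapse = ", ")),
             "configuration_error")
  }
  if (dose_min <= 0 || dose_max <= dose_min) {
    stop_bad("dose grid needs 0 < dose_min < dose_max", "configuration_error")
  }
  if (abs(sum(beta_weights) - 1) > 1e-8 || any(beta_weights < 0)) {
    stop_bad("'beta_weights' must be non-negative and sum to 1",
             "configuration_error")
  }
  stopifnot(length(beta_meanlog) == length(beta_sdlog),
            length(beta_meanlog) == length(beta_weights))
  structure(list(types = types, n_studies = as.integer(n_studies),
                 beta_meanlog = beta_meanlog, beta_sdlog = beta_sdlog,
                 beta_weights = beta_weights, dose_min = dose_min,
                 dose_max = dose_max, dose_points = as.integer(dose_points),
                 log_spaced = isTRUE(log_spaced), cap = cap,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "literature_db_config")
}

#' Generate a synthetic dose vs. DNA-damage literature database
#'
#' @param config a [literature_db_config()].
#' @return data.frame with columns `radiation_type`, `study_id`, `dose_Gy`,
#'   `damage_pct`, plus a provenance column `component` recording which
#'   sensitivity-mixture component generated each study (used by tests; not
#'   part of the CSV schema).
#' @export
generate_literature_db <- function(config = literature_db_config()) {
  stopifnot(inherits(config, "literature_db_config"))
  doses <- if (config$log_spaced) {
    exp(seq(log(config$dose_min), log(config$dose_max),
            length.out = config$dose_points))
  } else {
    seq(config$dose_min, config$dose_max, length.out = config$dose_points)
  }
  with_seed(config$seed, {
    rows <- lapply(config$types, function(ty) {
      comp <- sample.int(length(config$beta_weights), config$n_studies,
                         replace = TRUE, prob = config$beta_weights)
      beta <- exp(rnorm(config$n_studies, config$beta_meanlog[comp],
                        config$beta_sdlog[comp]))
      do.call(rbind, lapply(seq_len(config$n_studies), function(s) {
        damage <- config$cap * (1 - exp(-beta[s] * doses / config$cap))
        if (config$noise_sd > 0) {
          damage <- pmin(100, pmax(0, damage + rnorm(length(doses), 0, config$noise_sd)))
        }
        data.frame(radiation_type = ty, study_id = s, dose_Gy = doses,
                   damage_pct = damage, component = comp[s])
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Read/write the CSV schemas used by the framework
#'
#' DoE tables use columns `voltage_kV,frequency_kHz,flow_slm,time_s,damage_pct`;
#' dose-damage databases use `radiation_type,study_id,dose_Gy,damage_pct`.
#' Files are UTF-8 with LF line endings and a decimal point.
#'
#' @param x data.frame in the respective schema.
#' @param path file path.
#' @return `read_*` return data.frames; `write_*` return `path` invisibly.
#' @export
write_doe_csv <- function(x, path) {
  cols <- c("voltage_kV", "frequency_kHz", "flow_slm", "time_s", "damage_pct")
  stopifnot(all(cols %in% names(x)))
  write_csv_lf(x[cols], path)
}

#' @rdname write_doe_csv
#' @export
read_doe_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("voltage_kV", "frequency_kHz", "flow_slm", "time_s",
                  "damage_pct") %in% names(x)))
  x
}

#' @rdname write_doe_csv
#' @export
write_dose_db_csv <- function(x, path) {
  cols <- c("radiation_type", "study_id", "dose_Gy", "damage_pct")
  stopifnot(all(cols %in% names(x)))
  write_csv_lf(x[cols], path)
}

#' @rdname write_doe_csv
#' @export
read_dose_db_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("radiation_type", "study_id", "dose_Gy", "damage_pct")
                %in% names(x)))
  x
}

write_csv_lf <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}
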