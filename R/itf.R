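#' Irradiation-time-finder query
#'
#' @param voltage,frequency,flow fixed process parameters (kV, kHz, slm).
#' @param target_damage target percent DNA damage in [0, 100].
#' @param t_min,t_max time search domain, s (0 <= t_min < t_max). Default
#'   [0.5, 120] s.
#' @param tolerance damage tolerance, percent (> 0); default 0.1.
#' @param n_bracket coarse bracketing grid size; default 256.
#' @param t_resolution bisection stopping resolution, s; default 1e-3.
#' @return object of class `itf_query`.
#' @export
itf_query <- function(voltage, frequency, flow, target_damage,
                      t_min = 0.5, t_max = 120, tolerance = 0.1,
                      n_bracket = 256L, t_resolution = 1e-3) {
  check_finite_positive(voltage, "voltage")
  check_finite_positive(frequency, "frequency")
  check_finite_positive(flow, "flow")
  if (t_min < 0 || t_min >= t_max) stop_bad("need 0 <= t_min < t_max", "invalid_parameter")
  if (tolerance <= 0) stop_bad("'tolerance' must be > 0", "invalid_parameter")
  if (any(target_damage < 0 | target_damage > 100)) {
    stop_bad("'target_damage' must be in [0, 100]", "invalid_parameter")
  }
  structure(list(voltage = voltage, frequency = frequency, flow = flow,
                 target_damage = target_damage, t_min = t_min, t_max = t_max,
                 tolerance = tolerance, n_bracket = as.integer(n_bracket),
                 t_resolution = t_resolution),
            class = "itf_query")
}

itf_newdata <- function(query, times) {
  data.frame(voltage_kV = query$voltage, frequency_kHz = query$frequency,
             flow_slm = query$flow, time_s = times)
}

#' Find the irradiation time producing a target extent of DNA damage
#'
#' Inverts a fitted damage predictor at fixed (voltage, frequency, flow):
#' returns the smallest time in the query domain at which the predicted
#' damage crosses the target, found by coarse grid bracketing (default 256
#' points) followed by bisection to the time resolution (default 1e-3 s). The
#' smallest-crossing rule resolves plateaus and residual non-monotonicity
#' deterministically; a detected non-monotonicity raises a warning but the
#' smallest crossing is still returned.
#'
#' Unreachable targets are signalled with distinct statuses: `below_range`
#' when the target lies more than `tolerance` below the curve at `t_min`
#' (inverting would need a shorter exposure than the domain allows) and
#' `above_range` when it exceeds the curve's maximum by more than `tolerance`.
#'
#' @param predictor a `damage_predictor`.
#' @param query an [itf_query()] (scalar target).
#' @return list with `t_irr` (s, or NA), `status` one of "ok", "below_range",
#'   "above_range", `achieved` (predicted damage at t_irr) and `monotone`
#'   (FALSE when a decrease was seen while bracketing).
#' @export
find_irradiation_time <- function(predictor, query) {
  stopifnot(inherits(query, "itf_query"), length(query$target_damage) == 1)
  res <- find_irradiation_times(predictor, query, query$target_damage)
  lapply(res, `[[`, 1)
}

#' Batch inversion sharing one bracketing grid
#'
#' Vectorised version of [find_irradiation_time()] for many targets at the
#' same (voltage, frequency, flow): the coarse grid is evaluated once and the
#' bisection iterations run on all targets simultaneously.
#'
#' @param predictor a `damage_predictor`.
#' @param query an [itf_query()] (its `target_damage` is ignored here).
#' @param targets numeric vector of target damages, percent.
#' @return list of vectors `t_irr`, `status`, `achieved`, `monotone`, each of
#'   length `length(targets)`.
#' @export
find_irradiation_times <- function(predictor, query, targets) {
  tg <- seq(query$t_min, query$t_max, length.out = query$n_bracket)
  fg <- predict_damage(predictor, itf_newdata(query, tg))
  monotone_curve <- !is.unsorted(fg, strictly = FALSE)
  if (!monotone_curve) {
    warning("predictor is not monotone on the bracketing grid; ",
            "returning smallest crossings", call. = FALSE)
  }
  m <- length(targets)
  t_irr <- rep(NA_real_, m)
  status <- character(m)
  achieved <- rep(NA_real_, m)
  run_max <- cummax(fg)

  below <- targets < fg[1] - query$tolerance
  above <- targets > max(fg) + query$tolerance
  status[below] <- "below_range"
  status[above] <- "above_range"
  todo <- which(!below & !above)

  if (length(todo)) {
    # immediate hits at t_min; otherwise first coarse interval whose running
    # max reaches the target (smallest crossing)
    at_min <- todo[targets[todo] <= fg[1]]
    t_irr[at_min] <- query$t_min
    rest <- setdiff(todo, at_min)
    if (length(rest)) {
      hi_idx <- vapply(targets[rest],
                       function(y) which(run_max >= y)[1], 1L)
      # targets within tolerance above the curve maximum never cross; take
      # the earliest point attaining the maximum
      capped <- is.na(hi_idx)
      if (any(capped)) {
        i_max <- which(fg >= max(fg))[1]
        t_irr[rest[capped]] <- tg[i_max]
        rest <- rest[!capped]; hi_idx <- hi_idx[!capped]
      }
    }
    if (length(rest)) {
      lo <- tg[hi_idx - 1]; hi <- tg[hi_idx]
      lo_cur <- lo; hi_cur <- hi
      while (max(hi_cur - lo_cur) > query$t_resolution) {
        mid <- (lo_cur + hi_cur) / 2
        fm <- predict_damage(predictor, itf_newdata(query, mid))
        up <- fm >= targets[rest]
        hi_cur[up] <- mid[up]
        lo_cur[!up] <- mid[!up]
      }
      # the upper end of the final bracket: first time at/above the crossing,
      # mirroring a dense ascending scan
      t_irr[rest] <- hi_cur
    }
    achieved[todo] <- predict_damage(predictor, itf_newdata(query, t_irr[todo]))
    # round-trip check: solutions outside tolerance are unreachable after all
    off <- todo[abs(achieved[todo] - targets[todo]) > query$tolerance]
    if (length(off)) {
      status[off] <- ifelse(achieved[off] < targets[off],
                            "above_range", "below_range")
      t_irr[off] <- NA_real_; achieved[off] <- NA_real_
    }
    status[setdiff(todo, off)] <- "ok"
  }
  list(t_irr = t_irr, status = status, achieved = achieved,
       monotone = rep(monotone_curve, m))
}
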