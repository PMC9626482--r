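#' Damage-predictor contract
#'
#' Every fitted model in the package is a `damage_predictor`: an object whose
#' [predict_damage()] method maps process parameters (voltage kV, frequency
#' kHz, flow slm, irradiation time s) to percent DNA damage, clipped to the
#' physical range [0, 100]. Clipping happens at the prediction boundary only;
#' training losses see the raw network output so gradients are unaffected.
#'
#' @param object a `damage_predictor`.
#' @param newdata data.frame with columns `voltage_kV`, `frequency_kHz`,
#'   `flow_slm`, `time_s` (the DoE schema, target column optional).
#' @param ... unused.
#' @return numeric vector of percent damage in [0, 100].
#' @export
predict_damage <- function(object, newdata, ...) UseMethod("predict_damage")

feature_matrix <- function(newdata) {
  cols <- c("voltage_kV", "frequency_kHz", "flow_slm", "time_s")
  if (!all(cols %in% names(newdata))) {
    stop_bad(paste("newdata must have columns", paste(cols, collapse = ", ")),
             "invalid_parameter")
  }
  m <- as.matrix(newdata[cols])
  if (any(!is.finite(m))) stop_bad("non-finite process parameters", "invalid_parameter")
  storage.mode(m) <- "double"
  m
}

clip01 <- function(x) pmin(100, pmax(0, x))

#' Wrap a plain function as a damage predictor
#'
#' Useful for tests and for exposing the synthetic ground truth to the
#' inversion and dose-rate machinery.
#'
#' @param fn function(voltage, frequency, flow, time) returning percent damage.
#' @param clip clip predictions to [0, 100]? Default TRUE.
#' @return a `damage_predictor`.
#' @export
as_damage_predictor <- function(fn, clip = TRUE) {
  stopifnot(is.function(fn))
  structure(list(fn = fn, clip = clip),
            class = c("function_predictor", "damage_predictor"))
}

#' @export
predict_damage.function_predictor <- function(object, newdata, ...) {
  m <- feature_matrix(newdata)
  out <- object$fn(m[, 1], m[, 2], m[, 3], m[, 4])
  if (object$clip) clip01(out) else out
}

#' Ground-truth predictor for a kinetics configuration
#'
#' @param kinetics a [kinetics_config()].
#' @return a `damage_predictor` evaluating the noise-free kinetics.
#' @export
true_damage_predictor <- function(kinetics = kinetics_config()) {
  as_damage_predictor(function(v, f, q, t) true_damage(v, f, q, t, kinetics))
}
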