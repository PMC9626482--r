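# internal validation / RNG helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(msg, class) {
  stop(structure(class = c(class, "plasmadose_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_finite_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_bad(sprintf("'%s' must be finite and > 0", name), "invalid_parameter")
  }
  invisible(x)
}

check_finite_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop_bad(sprintf("'%s' must be finite and >= 0", name), "invalid_parameter")
  }
  invisible(x)
}

#' Derive a per-stage seed from a global seed
#'
#' Stage names are hashed to 32-bit integers and mixed with the global seed so
#' that each pipeline stage is independently reproducible. The rule is a fixed
#' multiply-and-fold over the UTF-8 bytes of the stage name, reduced modulo
#' 2^31 - 1 (R integers are 32-bit signed).
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed in [1, 2^31 - 2].
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  s <- (as.numeric(seed) * 1000003 + h * 2654435) %% 2147483646
  as.integer(s) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
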