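## Internal helpers: typed conditions, unit constants, RNG hygiene.

# 1 mmHg = 133.322 Pa; 1 mmHg.s/mL = 133.322e6 Pa.s/m^3
PA_PER_MMHG <- 133.322
MMHG_S_ML_PER_PA_S_M3 <- 7.5006e-9   # 1 Pa.s/m3 in mmHg.s/mL
ML_MMHG_PER_M3_PA <- 1 / 7.5006e-9   # 1 m3/Pa in mL/mmHg

#' Signal a typed cbpkit error
#'
#' All estimator and solver failures raise classed conditions (never silent
#' NaN), so dataset-level evaluation can count failures per subject.
#'
#' @param message error message.
#' @param class condition subclass, e.g. "cbpkit_error_fit_failed".
#' @param ... fields attached to the condition (e.g. best incumbent of a fit).
#' @noRd
cbp_stop <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "cbpkit_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Run code with a private, restored RNG state
#'
#' Used by the optimizer multi-start so fits are reproducible and do not
#' disturb the caller's random stream.
#' @noRd
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# linear recurrence y[k] = x[k] + a * y[k-1], y[0] = y0; returns y[1..n]
recursive_filter <- function(x, a, y0 = 0) {
  as.numeric(stats::filter(x, a, method = "recursive", init = y0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
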