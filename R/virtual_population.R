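#' Cardiovascular parameter specification for the virtual population
#'
#' Mean and spread of the six cardiovascular parameters that define a virtual
#' subject. Each parameter takes five factorial levels
#' \code{mu + c(-1, -0.5, 0, 0.5, 1) * sigma}, so the grid standard deviation
#' is \code{sigma * sqrt(0.5)}.
#'
#' The defaults describe a sample of healthy adults: heart rate 68.8 +/- 16.0
#' beats/min and stroke volume 88.4 +/- 17.3 mL (grid SDs 11.3 and 12.2),
#' total resistance 0.51 +/- 0.12 mmHg.s/mL, total compliance 1.3 +/- 0.4
#' mL/mmHg, characteristic impedance 0.0255 +/- 0.01 mmHg.s/mL (about 5\% of
#' the resistance scale), and outflow pressure 32.3 +/- 8 mmHg (about half the
#' diastolic pressure). All values are configuration defaults and can be
#' overridden per parameter.
#'
#' @param HR,SV,R_T,C_T,Z_0,P_out two-element numeric vectors
#'   \code{c(mu, sigma)}; units beats/min, mL, mmHg.s/mL, mL/mmHg,
#'   mmHg.s/mL, mmHg.
#' @return an object of class \code{cv_parameter_spec}.
#' @export
cv_parameter_spec <- function(HR = c(68.8, 16.0),
                              SV = c(88.4, 17.3),
                              R_T = c(0.51, 0.12),
                              C_T = c(1.3, 0.4),
                              Z_0 = c(0.0255, 0.01),
                              P_out = c(32.3, 8)) {
  spec <- list(HR = HR, SV = SV, R_T = R_T, C_T = C_T, Z_0 = Z_0,
               P_out = P_out)
  for (nm in names(spec)) {
    v <- spec[[nm]]
    if (length(v) != 2L || !all(is.finite(v)))
      cbp_stop(sprintf("parameter %s needs c(mu, sigma)", nm),
               "cbpkit_error_spec")
    if (v[2L] < 0)
      cbp_stop(sprintf("parameter %s has negative sigma", nm),
               "cbpkit_error_spec")
    if (v[1L] < 0 || (nm != "Z_0" && v[1L] <= 0))
      cbp_stop(sprintf("parameter %s has non-positive mean", nm),
               "cbpkit_error_spec")
  }
  structure(spec, class = "cv_parameter_spec")
}

grid_levels <- function(mu_sigma) {
  mu_sigma[1L] + c(-1, -0.5, 0, 0.5, 1) * mu_sigma[2L]
}

#' Factorial parameter grid of virtual subjects
#'
#' Full Cartesian product of the five levels of each of the six parameters
#' (5^6 = 15,625 combinations by default), in deterministic order: the first
#' listed parameter varies fastest.
#'
#' @param spec a \code{\link{cv_parameter_spec}}.
#' @param dedupe drop duplicated rows (relevant when some \code{sigma} is 0).
#' @return data.frame with columns \code{id, HR, SV, R_T, C_T, Z_0, P_out}.
#' @export
build_grid <- function(spec = cv_parameter_spec(), dedupe = FALSE) {
  levels <- lapply(spec, grid_levels)
  for (nm in names(levels)) {
    bad <- if (nm == "Z_0") any(levels[[nm]] < 0) else any(levels[[nm]] <= 0)
    if (bad)
      cbp_stop(sprintf("grid values for %s are not positive", nm),
               "cbpkit_error_spec")
  }
  g <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE)
  if (dedupe) g <- unique(g)
  rownames(g) <- NULL
  cbind(id = seq_len(nrow(g)), g)
}

#' Generate a parameterized aortic flow wave
#'
#' Synthetic single-cycle aortic root flow: a skewed half-sine ejection phase
#' \code{Q(t) = Q_max * sin(pi * (t/LVET)^asymmetry)^m} for
#' \code{t in [0, LVET]} and zero flow in diastole. \code{Q_max} is scaled so
#' the integral of the wave equals the stroke volume exactly (to the
#' trapezoidal quadrature used throughout). The ejection time is tied to the
#' cycle length as \code{LVET = k_lvet * T}.
#'
#' @param HR heart rate in beats/min (30--200).
#' @param SV stroke volume in mL (10--200).
#' @param dt sampling interval (s); default 1 kHz sampling.
#' @param k_lvet systolic fraction of the cycle, \code{LVET = k_lvet * T}.
#' @param m sine exponent (waveform peakedness).
#' @param asymmetry late-systolic skew exponent (1 = symmetric half-sine).
#' @return list with \code{q_in} (a flow \code{\link{uniform_wave}}) and
#'   \code{LVET} (s).
#' @export
generate_flow_wave <- function(HR, SV, dt = 1e-3, k_lvet = 0.293, m = 1,
                               asymmetry = 1) {
  if (!is.finite(HR) || HR < 30 || HR > 200)
    cbp_stop("HR must be in [30, 200] beats/min", "cbpkit_error_physiology")
  if (!is.finite(SV) || SV < 10 || SV > 200)
    cbp_stop("SV must be in [10, 200] mL", "cbpkit_error_physiology")
  period <- 60 / HR
  lvet <- k_lvet * period
  if (lvet >= period)
    cbp_stop("LVET must be shorter than the cardiac cycle",
             "cbpkit_error_physiology")
  n <- max(round(period / dt), 32L)
  dt_used <- period / n
  t <- (0:(n - 1L)) * dt_used
  s <- t / lvet
  base <- ifelse(t < lvet, sin(pi * pmin(s, 1)^asymmetry)^m, 0)
  total <- sum(base) * dt_used     # periodic trapezoid = plain sum here
  if (total <= 0)
    cbp_stop("degenerate flow wave", "cbpkit_error_physiology")
  q <- uniform_wave(base * SV / total, dt_used, t0 = 0, kind = "flow")
  list(q_in = q, LVET = lvet)
}

default_exclusion_bounds <- function() {
  list(cSBP_max = 220, cDBP_min = 44, cPP_min = 18, cPP_max = 109)
}

#' Flag virtual subjects outside physiological pressure bounds
#'
#' A subject is excluded when its simulated central pressure violates any
#' bound: cSBP > 220 mmHg, cDBP < 44 mmHg, cPP < 18 mmHg or cPP > 109 mmHg
#' (strict inequalities; subjects exactly on a bound are retained). Bounds are
#' configurable.
#'
#' @param truth data.frame containing \code{cSBP}, \code{cDBP}, \code{cPP}
#'   columns (e.g. the \code{truth} table of a generated dataset).
#' @param bounds named list overriding the default bounds.
#' @return the data.frame with logical \code{excluded} and character
#'   \code{reason} columns replaced/added.
#' @export
apply_exclusions <- function(truth, bounds = default_exclusion_bounds()) {
  b <- utils::modifyList(default_exclusion_bounds(), bounds)
  reasons <- character(nrow(truth))
  add <- function(cur, flag, label) ifelse(flag, paste0(cur, ifelse(nzchar(cur), "+", ""), label), cur)
  f1 <- truth$cSBP > b$cSBP_max
  f2 <- truth$cDBP < b$cDBP_min
  f3 <- truth$cPP < b$cPP_min
  f4 <- truth$cPP > b$cPP_max
  reasons <- add(reasons, f1, "cSBP")
  reasons <- add(reasons, f2, "cDBP")
  reasons <- add(reasons, f3, "cPP_low")
  reasons <- add(reasons, f4, "cPP_high")
  truth$excluded <- f1 | f2 | f3 | f4
  truth$reason <- ifelse(truth$excluded, reasons, "")
  truth
}

#' Generate the 0-D virtual-subject dataset
#'
#' For every point of the factorial grid: build the aortic flow wave from
#' (HR, SV), simulate the central pressure wave as the periodic three-element
#' Windkessel solution for the subject's true (R_T, C_T, Z_0, P_out), record
#' cycle statistics and apply the physiological exclusion bounds. The whole
#' procedure is deterministic.
#'
#' @param spec a \code{\link{cv_parameter_spec}}.
#' @param dt sampling interval (s).
#' @param k_lvet,m,asymmetry flow-wave shape settings
#'   (see \code{\link{generate_flow_wave}}).
#' @param bounds exclusion bounds (see \code{\link{apply_exclusions}}).
#' @param limit generate only the first \code{limit} grid points.
#' @param dedupe drop duplicated grid rows before simulating.
#' @param keep_waves "none" (default; waves are regenerated on demand by
#'   \code{\link{subject_waves}}), "pressure", or "both".
#' @return object of class \code{cbp_dataset}: list with \code{truth}
#'   (data.frame of parameters, cycle statistics, exclusion flags),
#'   \code{settings}, \code{spec}, \code{manifest}, and (optionally)
#'   \code{waves}.
#' @export
generate_dataset <- function(spec = cv_parameter_spec(), dt = 1e-3,
                             k_lvet = 0.293, m = 1, asymmetry = 1,
                             bounds = default_exclusion_bounds(),
                             limit = NULL, dedupe = FALSE,
                             keep_waves = c("none", "pressure", "both")) {
  keep_waves <- match.arg(keep_waves)
  grid <- build_grid(spec, dedupe = dedupe)
  if (!is.null(limit)) grid <- grid[seq_len(min(limit, nrow(grid))), , drop = FALSE]
  n <- nrow(grid)
  lvet <- numeric(n)
  cDBP <- numeric(n); cSBP <- numeric(n); cMBP <- numeric(n)
  q_mean <- numeric(n); q_max <- numeric(n)
  ok <- rep(TRUE, n); fail_msg <- character(n)
  waves <- if (keep_waves == "none") NULL else vector("list", n)
  settings <- list(dt = dt, k_lvet = k_lvet, m = m, asymmetry = asymmetry,
                   bounds = bounds, model = "3wk")
  for (i in seq_len(n)) {
    res <- tryCatch({
      fw <- generate_flow_wave(grid$HR[i], grid$SV[i], dt = dt,
                               k_lvet = k_lvet, m = m, asymmetry = asymmetry)
      pw <- solve_3wk(fw$q_in,
                      wk_params(grid$R_T[i], grid$C_T[i], grid$Z_0[i],
                                grid$P_out[i]))
      list(fw = fw, pw = pw)
    }, cbpkit_error = function(e) e)
    if (inherits(res, "error")) {
      ok[i] <- FALSE; fail_msg[i] <- conditionMessage(res)
      lvet[i] <- NA; cDBP[i] <- NA; cSBP[i] <- NA; cMBP[i] <- NA
      q_mean[i] <- NA; q_max[i] <- NA
      next
    }
    lvet[i] <- res$fw$LVET
    ps <- wave_stats(res$pw); qs <- wave_stats(res$fw$q_in)
    cDBP[i] <- ps$DBP; cSBP[i] <- ps$SBP; cMBP[i] <- ps$MBP
    q_mean[i] <- qs$Q_mean; q_max[i] <- qs$Q_max
    if (keep_waves == "pressure") waves[[i]] <- list(cbp = res$pw)
    if (keep_waves == "both") waves[[i]] <- list(q_in = res$fw$q_in, cbp = res$pw)
  }
  truth <- cbind(grid,
                 data.frame(LVET = lvet, cDBP = cDBP, cSBP = cSBP,
                            cMBP = cMBP, cPP = cSBP - cDBP,
                            Q_mean = q_mean, Q_max = q_max,
                            valid = ok, fail_reason = fail_msg))
  truth <- apply_exclusions(truth, bounds)
  truth$excluded[!ok] <- TRUE
  manifest <- list(
    package = "cbpkit",
    version = as.character(utils::packageVersion("cbpkit")),
    spec = lapply(unclass(spec), as.numeric),
    settings = settings[c("dt", "k_lvet", "m", "asymmetry", "model")],
    bounds = bounds,
    counts = list(n_total = n, n_invalid = sum(!ok),
                  n_excluded = sum(truth$excluded),
                  n_retained = sum(!truth$excluded))
  )
  structure(list(truth = truth, spec = spec, settings = settings,
                 manifest = manifest, waves = waves),
            class = "cbp_dataset")
}

#' @export
print.cbp_dataset <- function(x, ...) {
  cts <- x$manifest$counts
  cat(sprintf("<cbp_dataset> %d virtual subjects (%d retained, %d excluded, %d invalid)\n",
              cts$n_total, cts$n_retained, cts$n_excluded, cts$n_invalid))
  cat(sprintf("  3-Wk model, dt = %g s, k_lvet = %g\n",
              x$settings$dt, x$settings$k_lvet))
  invisible(x)
}

#' Waves of one virtual subject
#'
#' Returns the subject's flow and central pressure waves, regenerating them
#' deterministically from the stored parameters when the dataset was built
#' with \code{keep_waves = "none"}.
#'
#' @param ds a \code{cbp_dataset}.
#' @param i row index into \code{ds$truth}.
#' @return list with \code{q_in}, \code{cbp} (\code{\link{uniform_wave}}s) and
#'   \code{LVET}.
#' @export
subject_waves <- function(ds, i) {
  tr <- ds$truth[i, ]
  if (!isTRUE(tr$valid))
    cbp_stop(sprintf("subject %d failed generation: %s", tr$id, tr$fail_reason),
             "cbpkit_error_invalid_subject")
  st <- ds$settings
  have <- if (!is.null(ds$waves)) ds$waves[[i]] else NULL
  q <- have$q_in
  p <- have$cbp
  if (is.null(q))
    q <- generate_flow_wave(tr$HR, tr$SV, dt = st$dt, k_lvet = st$k_lvet,
                            m = st$m, asymmetry = st$asymmetry)$q_in
  if (is.null(p))
    p <- solve_3wk(q, wk_params(tr$R_T, tr$C_T, tr$Z_0, tr$P_out))
  list(q_in = q, cbp = p, LVET = tr$LVET)
}
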