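#' Mean percentage error and its spread
#'
#' Per-item percentage error is \code{100 * (est - ref) / ref}; MPE is the
#' mean and \code{sigma} the sample standard deviation (n-1 denominator) of
#' those percentage errors.
#'
#' @param est,ref paired numeric vectors; \code{ref} must be nonzero.
#' @return list with \code{MPE} and \code{sigma} (percent).
#' @export
mpe_sigma <- function(est, ref) {
  if (length(est) != length(ref))
    cbp_stop("est and ref must have equal length", "cbpkit_error_invalid_input")
  if (any(ref == 0))
    cbp_stop("ref contains zero values", "cbpkit_error_invalid_input")
  pe <- 100 * (est - ref) / ref
  list(MPE = mean(pe), sigma = if (length(pe) > 1L) stats::sd(pe) else NA_real_)
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are \code{est - ref}; the bias is their mean and the limits of
#' agreement are bias +/- 1.96 standard deviations.
#'
#' @param est,ref paired numeric vectors (length >= 2).
#' @return list with \code{bias}, \code{loa_low}, \code{loa_high}.
#' @export
bland_altman <- function(est, ref) {
  if (length(est) != length(ref) || length(est) < 2L)
    cbp_stop("need at least 2 paired values", "cbpkit_error_invalid_input")
  d <- est - ref
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Bland-Altman plot
#'
#' @param est,ref paired numeric vectors.
#' @param ... passed to \code{plot}.
#' @return the \code{\link{bland_altman}} summary, invisibly.
#' @export
bland_altman_plot <- function(est, ref, ...) {
  ba <- bland_altman(est, ref)
  m <- (est + ref) / 2
  graphics::plot(m, est - ref, xlab = "Mean of estimate and reference",
                 ylab = "Difference (est - ref)", ...)
  graphics::abline(h = c(ba$bias, ba$loa_low, ba$loa_high), lty = c(1, 2, 2))
  invisible(ba)
}

#' Root-mean-square error between two pressure waves
#'
#' The waves are aligned by their systolic foot, resampled onto a common
#' 1 kHz grid spanning the shorter period, and compared sample by sample.
#'
#' @param est,ref pressure \code{\link{uniform_wave}}s whose periods agree
#'   within 10\%.
#' @return RMSE in mmHg.
#' @export
rmse_waves <- function(est, ref) {
  assert_wave(est, "pressure"); assert_wave(ref, "pressure")
  if (abs(est$period - ref$period) > 0.1 * max(est$period, ref$period))
    cbp_stop("wave periods differ by more than 10%",
             "cbpkit_error_incomparable_waves")
  align <- function(w) {
    foot <- tryCatch(detect_foot(w), cbpkit_error = function(e) w$t0)
    shift <- round(((foot - w$t0) %% w$period) / w$dt)
    v <- w$values
    if (shift > 0) v <- c(v[(shift + 1L):length(v)], v[seq_len(shift)])
    uniform_wave(v, w$dt, t0 = 0, kind = "pressure")
  }
  a <- resample_wave(align(est), 1e-3)
  b <- resample_wave(align(ref), 1e-3)
  n <- min(length(a$values), length(b$values))
  sqrt(mean((a$values[seq_len(n)] - b$values[seq_len(n)])^2))
}

#' Coefficient of determination of paired values
#'
#' Squared Pearson correlation.
#'
#' @param est,ref paired numeric vectors with nonzero variance.
#' @return R^2 in [0, 1].
#' @export
r_squared <- function(est, ref) {
  if (length(est) != length(ref) || length(est) < 2L)
    cbp_stop("need at least 2 paired values", "cbpkit_error_invalid_input")
  if (stats::var(est) == 0 || stats::var(ref) == 0)
    cbp_stop("zero variance in input", "cbpkit_error_invalid_input")
  stats::cor(est, ref)^2
}

# map a method code to the CV parameter it estimates
method_parameter <- function(code) {
  switch(substr(code, 1, 2),
         LV = "LVET", OP = "P_out", AR = "R_T", AC = "C_T", PV = "PWV",
         Z1 = "Z_0", Z2 = "Z_0", Z3 = "Z_0", Z4 = "Z_0", Z5 = "Z_0",
         Z6 = "Z_0",
         cbp_stop(sprintf("unknown method code %s", code),
                  "cbpkit_error_configuration"))
}

# run one estimation method on one subject, with truth-valued dependencies
run_method_on_subject <- function(code, ds, i, waves = NULL) {
  tr <- ds$truth[i, ]
  w <- waves %||% subject_waves(ds, i)
  inp <- estimator_input(p_wave = w$cbp, q_wave = w$q_in)
  par <- method_parameter(code)
  est <- switch(par,
    LVET = estimate_lvet(inp, code),
    P_out = estimate_pout(inp, code, lvet = tr$LVET),
    R_T = estimate_rt(inp, code, P_out = tr$P_out),
    C_T = estimate_ct(inp, code, R_T = tr$R_T, P_out = tr$P_out,
                      Z_0 = if (code %in% c("AC1", "AC2", "AC3", "AC4")) tr$Z_0 else NULL,
                      lvet = tr$LVET),
    Z_0 = estimate_z0(inp, code, R_T = tr$R_T, P_out = tr$P_out),
    cbp_stop(sprintf("method %s is not evaluable on the lumped dataset", code),
             "cbpkit_error_configuration"))
  est$value
}

#' Evaluate estimation methods over a virtual-subject dataset
#'
#' Applies each method to every retained subject, comparing estimates with
#' the subject's generating (true) parameter value. Dependencies a method
#' needs but does not itself estimate (LVET for the diastolic windows, P_out
#' for resistance, R_T and P_out for compliance) are taken from the truth,
#' mirroring validation against known reference values. Estimator failures
#' are counted per method, never silently dropped.
#'
#' @param ds a \code{cbp_dataset} from \code{\link{generate_dataset}}.
#' @param methods character vector of method codes (e.g. \code{c("AR1",
#'   "OP1", "AC2")}).
#' @param ids subject row indices to use; defaults to all retained subjects.
#' @return data.frame of class \code{error_report}: one row per method with
#'   \code{parameter}, \code{n}, \code{n_failed}, \code{MPE}, \code{sigma},
#'   \code{bias}, \code{loa_low}, \code{loa_high}, \code{r2}.
#' @export
evaluate_dataset <- function(ds, methods, ids = NULL) {
  if (is.null(ids)) ids <- which(!ds$truth$excluded)
  if (length(ids) == 0L)
    cbp_stop("no retained subjects to evaluate", "cbpkit_error_invalid_input")
  est_mat <- matrix(NA_real_, nrow = length(ids), ncol = length(methods),
                    dimnames = list(NULL, methods))
  for (k in seq_along(ids)) {
    w <- subject_waves(ds, ids[k])
    for (code in methods) {
      est_mat[k, code] <- tryCatch(
        run_method_on_subject(code, ds, ids[k], waves = w),
        cbpkit_error = function(e) NA_real_)
    }
  }
  rows <- lapply(methods, function(code) {
    par <- method_parameter(code)
    ref_all <- ds$truth[[if (par == "LVET") "LVET" else par]][ids]
    est <- est_mat[, code]
    okk <- is.finite(est)
    if (sum(okk) >= 2L) {
      ms <- mpe_sigma(est[okk], ref_all[okk])
      ba <- bland_altman(est[okk], ref_all[okk])
      r2 <- tryCatch(r_squared(est[okk], ref_all[okk]),
                     cbpkit_error = function(e) NA_real_)
    } else {
      ms <- list(MPE = NA_real_, sigma = NA_real_)
      ba <- list(bias = NA_real_, loa_low = NA_real_, loa_high = NA_real_)
      r2 <- NA_real_
    }
    data.frame(method = code, parameter = par, n = sum(okk),
               n_failed = sum(!okk), MPE = ms$MPE, sigma = ms$sigma,
               bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
               r2 = r2)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("error_report", "data.frame")
  out
}

#' Evaluate a full cBP estimation algorithm over a dataset
#'
#' Runs the two-stage pipeline (scenario-specific method selection, CV
#' parameter estimation, forward Windkessel simulation) on each subject and
#' compares the estimated central pressures with the generating ones:
#' cDBP/cSBP error summaries (mean +/- SD, in mmHg) and the mean waveform
#' RMSE.
#'
#' @param ds a \code{cbp_dataset}.
#' @param scenario "carotid+" or "carotid-".
#' @param model "3wk" or "2wk".
#' @param profile method-selection profile ("1D" default, as in the pipeline).
#' @param selection optional explicit \code{\link{select_methods}} result
#'   (overrides \code{profile}).
#' @param ids subject row indices; defaults to all retained subjects.
#' @return list with per-subject data.frame \code{errors} and a \code{summary}
#'   data.frame (cDBP/cSBP bias and SD, mean RMSE, n, n_failed).
#' @export
evaluate_cbp_algorithm <- function(ds, scenario = c("carotid+", "carotid-"),
                                   model = c("3wk", "2wk"), profile = "1D",
                                   selection = NULL, ids = NULL) {
  scenario <- match.arg(scenario); model <- match.arg(model)
  if (is.null(ids)) ids <- which(!ds$truth$excluded)
  if (is.null(selection)) selection <- select_methods(scenario, profile)
  res <- lapply(ids, function(i) {
    tr <- ds$truth[i, ]
    out <- tryCatch({
      w <- subject_waves(ds, i)
      inp <- if (scenario == "carotid+")
        estimator_input(p_wave = w$cbp, q_wave = w$q_in)
      else
        estimator_input(DBP = tr$cDBP, SBP = tr$cSBP, q_wave = w$q_in)
      cb <- run_cbp_pipeline(inp, scenario, model, selection = selection)
      data.frame(id = tr$id, e_cDBP = cb$cDBP - tr$cDBP,
                 e_cSBP = cb$cSBP - tr$cSBP,
                 rmse = rmse_waves(cb$wave, w$cbp), failed = FALSE)
    }, cbpkit_error = function(e)
      data.frame(id = tr$id, e_cDBP = NA_real_, e_cSBP = NA_real_,
                 rmse = NA_real_, failed = TRUE))
    out
  })
  errors <- do.call(rbind, res)
  okk <- !errors$failed
  summary <- data.frame(
    scenario = scenario, model = model, n = sum(okk),
    n_failed = sum(!okk),
    cDBP_bias = mean(errors$e_cDBP[okk]), cDBP_sd = stats::sd(errors$e_cDBP[okk]),
    cSBP_bias = mean(errors$e_cSBP[okk]), cSBP_sd = stats::sd(errors$e_cSBP[okk]),
    rmse_mean = mean(errors$rmse[okk]), rmse_sd = stats::sd(errors$rmse[okk]))
  list(errors = errors, summary = summary)
}
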