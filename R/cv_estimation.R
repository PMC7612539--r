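#' Bundle of measurements available to the estimators
#'
#' Collects everything an estimation method might need: an aortic (or
#' peripheral) pressure wave, scalar cuff pressures, the aortic root flow
#' wave, a distal (descending-aorta) flow wave, a carotid--femoral pressure
#' pair with its path length, aortic geometry, and blood density. Individual
#' estimators validate their own requirements.
#'
#' @param p_wave pressure \code{\link{uniform_wave}} (optional).
#' @param DBP,SBP scalar diastolic/systolic pressure in mmHg (optional; filled
#'   from \code{p_wave} when absent).
#' @param q_wave aortic root flow \code{\link{uniform_wave}}.
#' @param q_distal descending-aorta flow wave (optional).
#' @param p_pair list of two pressure waves, proximal then distal (optional).
#' @param dx path length between the waves of \code{p_pair} or between
#'   \code{q_wave} and \code{q_distal}, in metres.
#' @param A aortic root cross-sectional area in m^2 (optional).
#' @param rho blood density in kg/m^3.
#' @return list of class \code{estimator_input}.
#' @export
estimator_input <- function(p_wave = NULL, DBP = NULL, SBP = NULL,
                            q_wave = NULL, q_distal = NULL, p_pair = NULL,
                            dx = NULL, A = NULL, rho = 1060) {
  if (is.null(p_wave) && (is.null(DBP) || is.null(SBP)) && is.null(p_pair))
    cbp_stop("at least one pressure source (wave, DBP+SBP, or pair) is required",
             "cbpkit_error_invalid_input")
  if (!is.null(dx) && dx <= 0)
    cbp_stop("dx must be positive", "cbpkit_error_invalid_input")
  if (rho <= 0) cbp_stop("rho must be positive", "cbpkit_error_invalid_input")
  if (!is.null(p_wave)) {
    st <- wave_stats(p_wave)
    DBP <- DBP %||% st$DBP
    SBP <- SBP %||% st$SBP
  }
  structure(list(p_wave = p_wave, DBP = DBP, SBP = SBP, q_wave = q_wave,
                 q_distal = q_distal, p_pair = p_pair, dx = dx, A = A,
                 rho = rho),
            class = "estimator_input")
}

cv_estimate <- function(value, method, diagnostics = list(),
                        positive = TRUE) {
  if (!is.finite(value) || (positive && value <= 0))
    cbp_stop(sprintf("method %s produced a nonphysical value (%g)", method,
                     value), "cbpkit_error_nonphysical")
  structure(list(value = value, method = method, diagnostics = diagnostics),
            class = "cv_estimate")
}

#' @export
print.cv_estimate <- function(x, ...) {
  cat(sprintf("<cv_estimate> %s = %.6g\n", x$method, x$value))
  invisible(x)
}

need <- function(x, what, method) {
  if (is.null(x))
    cbp_stop(sprintf("method %s requires %s", method, what),
             "cbpkit_error_inapplicable_method")
  x
}

# interpolated pressure value at absolute time t (periodic)
wave_at <- function(w, t) {
  n <- length(w$values)
  tt <- w$t0 + (0:n) * w$dt
  vv <- c(w$values, w$values[1L])
  tl <- w$t0 + ((t - w$t0) %% w$period)
  stats::approx(tt, vv, xout = tl)$y
}

#' Three-parameter exponential fit of the diastolic pressure decay
#'
#' Fits \code{P(t) = P_out + (P_1 - P_out) * exp(-(t - t_1)/tau)} over
#' \code{[t_start, t_end]} by variable projection: for each candidate
#' \code{tau} the remaining parameters are linear and solved exactly, and the
#' profiled residual is minimized over \code{log(tau)} with
#' \code{\link[stats]{optimize}}. Deterministic; no starting values needed.
#'
#' @param p pressure \code{\link{uniform_wave}}.
#' @param t_start,t_end fit window in absolute time (s); \code{t_end} defaults
#'   to the end of the cycle.
#' @param tau_range search range for the decay constant (s).
#' @return list with \code{P_out}, \code{P_1}, \code{tau}, \code{rmse},
#'   \code{n} (samples used) and the window.
#' @export
fit_diastolic_decay <- function(p, t_start, t_end = NULL,
                                tau_range = c(0.01, 30)) {
  assert_wave(p, "pressure")
  t <- wave_times(p)
  t_end <- t_end %||% (p$t0 + p$period)
  idx <- which(t >= t_start - 1e-12 & t <= t_end + 1e-12)
  if (length(idx) < 5L)
    cbp_stop("fewer than 5 samples in the diastolic fit window",
             "cbpkit_error_fit_failed")
  tt <- t[idx] - t[idx[1L]]
  y <- p$values[idx]
  rss_of <- function(ltau) {
    e <- exp(-tt / exp(ltau))
    fit <- stats::lm.fit(cbind(1, e), y)
    sum(fit$residuals^2)
  }
  opt <- stats::optimize(rss_of, log(tau_range), tol = 1e-10)
  tau <- exp(opt$minimum)
  e <- exp(-tt / tau)
  fit <- stats::lm.fit(cbind(1, e), y)
  P_out <- fit$coefficients[1L]
  B <- fit$coefficients[2L]
  if (!is.finite(P_out) || !is.finite(B) || B <= 0)
    cbp_stop("diastolic decay fit is not a positive decaying exponential",
             "cbpkit_error_fit_failed")
  if (P_out < 0)
    cbp_stop("diastolic decay fit gave a negative outflow pressure",
             "cbpkit_error_fit_failed")
  list(P_out = unname(P_out), P_1 = unname(P_out + B), tau = tau,
       rmse = sqrt(mean(fit$residuals^2)), n = length(idx),
       window = c(t[idx[1L]], t[idx[length(idx)]]))
}

#' Estimate left ventricular ejection time (methods LV1--LV4)
#'
#' \describe{
#'   \item{LV1}{dicrotic notch time minus pressure foot; inapplicable when the
#'     wave has no notch (e.g. lumped-model pressures with a monotone
#'     diastolic decay).}
#'   \item{LV2}{time of the global minimum of dP/dt after the systolic peak,
#'     minus the pressure foot.}
#'   \item{LV3}{the literal fraction 0.37 T of the cycle duration
#'     (\code{weissler_sqrt = TRUE} uses 0.37 sqrt(T) instead).}
#'   \item{LV4}{flow-derived ejection window: from the flow foot to the first
#'     time after peak flow at which the flow drops below
#'     \code{q_th * Q_max}, or the first local minimum, whichever is earlier.}
#' }
#'
#' @param input an \code{\link{estimator_input}}.
#' @param method one of "LV1", "LV2", "LV3", "LV4".
#' @param q_th relative flow threshold for LV4.
#' @param weissler_sqrt use 0.37*sqrt(T) for LV3.
#' @return a \code{cv_estimate} (seconds).
#' @export
estimate_lvet <- function(input, method = c("LV4", "LV1", "LV2", "LV3"),
                          q_th = 0.02, weissler_sqrt = FALSE) {
  method <- match.arg(method)
  if (method %in% c("LV1", "LV2")) {
    p <- need(input$p_wave, "a pressure wave", method)
    foot <- detect_foot(p)
    if (method == "LV1") {
      notch <- detect_dicrotic_notch(p)
      if (is.na(notch))
        cbp_stop("LV1 requires a dicrotic notch, none found",
                 "cbpkit_error_inapplicable_method")
      return(cv_estimate(notch - foot, "LV1", list(foot = foot, notch = notch)))
    }
    d <- central_diff(p$values, p$dt)
    i_peak <- which.max(p$values)
    after <- seq(i_peak, length(d))
    i_min <- after[which.min(d[after])]
    t_min <- p$t0 + (i_min - 1L) * p$dt
    return(cv_estimate(t_min - foot, "LV2", list(foot = foot, t_dpdt_min = t_min)))
  }
  if (method == "LV3") {
    w <- input$p_wave %||% input$q_wave
    period <- need(w, "a wave for the cycle duration", "LV3")$period
    val <- if (weissler_sqrt) 0.37 * sqrt(period) else 0.37 * period
    return(cv_estimate(val, "LV3", list(period = period)))
  }
  q <- need(input$q_wave, "a flow wave", "LV4")
  foot <- detect_foot(q)
  v <- q$values
  n <- length(v)
  i_max <- which.max(v)
  thr <- q_th * v[i_max]
  t_th <- NA_real_
  for (j in seq(i_max + 1L, n)) {
    if (v[j] <= thr) {
      # sub-sample crossing time by linear interpolation
      frac <- if (v[j - 1L] > v[j]) (v[j - 1L] - thr) / (v[j - 1L] - v[j]) else 1
      t_th <- q$t0 + (j - 2L + frac) * q$dt
      break
    }
  }
  t_lm <- NA_real_
  for (j in seq(i_max + 1L, n - 1L)) {
    if (v[j] < v[j - 1L] && v[j] <= v[j + 1L]) {
      t_lm <- q$t0 + (j - 1L) * q$dt
      break
    }
  }
  t_end <- suppressWarnings(min(t_th, t_lm, na.rm = TRUE))
  if (!is.finite(t_end))
    cbp_stop("LV4 found no end-of-ejection landmark",
             "cbpkit_error_landmark_not_found")
  cv_estimate(t_end - foot, "LV4", list(foot = foot, t_end = t_end))
}

#' Estimate the outflow pressure (methods OP1--OP4)
#'
#' OP1 fits the three-parameter exponential decay over diastole from
#' \code{LVET + 0.02 s} to the end of the cycle and returns its asymptote;
#' OP2 uses the final two-thirds of diastole; OP3 and OP4 are the fixed
#' fractions 0.5 DBP and 0.7 DBP.
#'
#' The pressure wave is assumed to start at the systolic foot (as all
#' generated waves do), so the diastolic window is measured from the start of
#' the cycle.
#'
#' @param input an \code{\link{estimator_input}}.
#' @param method one of "OP1", "OP2", "OP3", "OP4".
#' @param lvet left ventricular ejection time (s); required for OP1/OP2.
#' @return a \code{cv_estimate} (mmHg).
#' @export
estimate_pout <- function(input, method = c("OP1", "OP2", "OP3", "OP4"),
                          lvet = NULL) {
  method <- match.arg(method)
  if (method %in% c("OP3", "OP4")) {
    DBP <- need(input$DBP, "DBP", method)
    frac <- if (method == "OP3") 0.5 else 0.7
    return(cv_estimate(frac * DBP, method, list(DBP = DBP)))
  }
  p <- need(input$p_wave, "a pressure wave", method)
  lvet <- need(lvet, "an LVET estimate", method)
  t_end <- p$t0 + p$period
  t_start <- if (method == "OP1") p$t0 + lvet + 0.02
             else p$t0 + lvet + (p$period - lvet) / 3
  fit <- fit_diastolic_decay(p, t_start, t_end)
  cv_estimate(fit$P_out, method, fit)
}

#' Estimate total arterial resistance (methods AR1, AR2)
#'
#' AR1 = (MBP - P_out) / Q_mean with MBP from the pressure wave;
#' AR2 = (DBP + 0.4 PP - P_out) / Q_mean using only cuff scalars.
#'
#' @param input an \code{\link{estimator_input}} (AR1 needs \code{p_wave},
#'   AR2 needs DBP and SBP; both need \code{q_wave}).
#' @param method "AR1" or "AR2".
#' @param P_out outflow pressure (mmHg).
#' @return a \code{cv_estimate} (mmHg.s/mL).
#' @export
estimate_rt <- function(input, method = c("AR1", "AR2"), P_out) {
  method <- match.arg(method)
  q <- need(input$q_wave, "a flow wave", method)
  q_mean <- wave_stats(q)$Q_mean
  if (q_mean <= 0)
    cbp_stop("mean flow must be positive", "cbpkit_error_nonphysical")
  num <- if (method == "AR1") {
    p <- need(input$p_wave, "a pressure wave", "AR1")
    wave_stats(p)$MBP - P_out
  } else {
    DBP <- need(input$DBP, "DBP", "AR2"); SBP <- need(input$SBP, "SBP", "AR2")
    DBP + 0.4 * (SBP - DBP) - P_out
  }
  if (num <= 0)
    cbp_stop(sprintf("%s numerator (pressure drop) is not positive", method),
             "cbpkit_error_nonphysical")
  cv_estimate(num / q_mean, method, list(Q_mean = q_mean))
}

#' Estimate total arterial compliance (methods AC1--AC9)
#'
#' Diastolic-decay methods (AC1--AC3) recover the time constant tau of the
#' pressure decay and return \code{tau / R_T} (or \code{tau / (R_T - Z_0)}
#' when \code{Z_0} is supplied): AC1 from two diastolic samples, AC2 from the
#' exponential fit over the OP1 window, AC3 over the OP2 window. AC4 is the
#' area method, AC5 the two-area method (a 2x2 linear system from integrating
#' the two-element model over systole and diastole). AC6 and AC7 root-find the
#' compliance at which the periodic two-element model reproduces the measured
#' DBP or PP. AC8 = SV/PP. AC9 takes the compliance of the optimized
#' three-element fit (\code{\link{fit_3wk_optimized}}).
#'
#' @param input an \code{\link{estimator_input}}.
#' @param method one of "AC1".."AC9".
#' @param R_T total resistance (required by AC1--AC7, AC9).
#' @param P_out outflow pressure (required by AC1--AC7, AC9).
#' @param Z_0 characteristic impedance; when supplied, decay methods divide
#'   tau by \code{R_T - Z_0} instead of \code{R_T}.
#' @param lvet LVET (s), needed by the window-based methods.
#' @param c_range bracketing interval for the AC6/AC7 root search (mL/mmHg).
#' @return a \code{cv_estimate} (mL/mmHg).
#' @export
estimate_ct <- function(input, method = sprintf("AC%d", 1:9), R_T = NULL,
                        P_out = NULL, Z_0 = NULL, lvet = NULL,
                        c_range = c(0.05, 10)) {
  method <- match.arg(method)
  r_eff <- function() {
    r <- need(R_T, "R_T", method)
    if (!is.null(Z_0)) r - Z_0 else r
  }
  if (method == "AC8") {
    q <- need(input$q_wave, "a flow wave", "AC8")
    sv <- wave_stats(q)$SV
    DBP <- need(input$DBP, "DBP", "AC8"); SBP <- need(input$SBP, "SBP", "AC8")
    pp <- SBP - DBP
    if (pp <= 0) cbp_stop("pulse pressure must be positive",
                          "cbpkit_error_nonphysical")
    return(cv_estimate(sv / pp, "AC8", list(SV = sv, PP = pp)))
  }
  if (method == "AC9") {
    p <- need(input$p_wave, "a pressure wave", "AC9")
    q <- need(input$q_wave, "a flow wave", "AC9")
    fit <- fit_3wk_optimized(p, q, need(R_T, "R_T", "AC9"),
                             need(P_out, "P_out", "AC9"))
    return(cv_estimate(fit$C_T, "AC9",
                       list(Z_0 = fit$Z_0, rmse = fit$rmse)))
  }
  if (method %in% c("AC6", "AC7")) {
    q <- need(input$q_wave, "a flow wave", method)
    R_T <- need(R_T, "R_T", method); P_out <- need(P_out, "P_out", method)
    target <- if (method == "AC6") need(input$DBP, "DBP", "AC6")
              else need(input$SBP, "SBP", "AC7") - need(input$DBP, "DBP", "AC7")
    fn <- function(ct) {
      st <- wave_stats(solve_2wk(q, wk_params(R_T, ct, 0, P_out)))
      (if (method == "AC6") st$DBP else st$PP) - target
    }
    flo <- fn(c_range[1L]); fhi <- fn(c_range[2L])
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
      cbp_stop(sprintf("%s target not bracketed in C_T range [%g, %g]",
                       method, c_range[1L], c_range[2L]),
               "cbpkit_error_fit_failed")
    root <- stats::uniroot(fn, c_range, tol = 1e-8)
    return(cv_estimate(root$root, method, list(target = target)))
  }
  # pressure-wave based methods AC1-AC5
  p <- need(input$p_wave, "a pressure wave", method)
  lvet <- need(lvet, "an LVET estimate", method)
  P_out <- need(P_out, "P_out", method)
  t1 <- p$t0 + lvet + 0.05
  t2 <- p$t0 + p$period - p$dt
  if (method == "AC1") {
    y1 <- wave_at(p, t1) - P_out; y2 <- wave_at(p, t2) - P_out
    if (y1 <= 0 || y2 <= 0)
      cbp_stop("AC1 needs positive decaying pressure above P_out",
               "cbpkit_error_fit_failed")
    ratio <- y1 / y2
    if (ratio <= 1)
      cbp_stop("AC1 log ratio is not positive (no diastolic decay)",
               "cbpkit_error_fit_failed")
    tau <- (t2 - t1) / log(ratio)
    return(cv_estimate(tau / r_eff(), "AC1", list(tau = tau)))
  }
  if (method %in% c("AC2", "AC3")) {
    t_start <- if (method == "AC2") p$t0 + lvet + 0.02
               else p$t0 + lvet + (p$period - lvet) / 3
    fit <- fit_diastolic_decay(p, t_start)
    return(cv_estimate(fit$tau / r_eff(), method, fit))
  }
  if (method == "AC4") {
    t <- wave_times(p)
    idx <- which(t >= t1 - 1e-12 & t <= t2 + 1e-12)
    if (length(idx) < 5L)
      cbp_stop("AC4 window has fewer than 5 samples", "cbpkit_error_fit_failed")
    y <- p$values[idx] - P_out
    area <- sum((y[-1L] + y[-length(y)]) / 2) * p$dt
    drop <- wave_at(p, t1) - wave_at(p, t2)
    if (drop <= 0)
      cbp_stop("AC4 pressure drop over diastole is not positive",
               "cbpkit_error_fit_failed")
    tau <- area / drop
    return(cv_estimate(tau / r_eff(), "AC4", list(tau = tau)))
  }
  # AC5 two-area method
  q <- need(input$q_wave, "a flow wave", "AC5")
  if (length(q$values) != length(p$values))
    q <- resample_wave(q, p$dt)
  t <- wave_times(p)
  sys_idx <- which(t <= p$t0 + lvet)
  dia_idx <- which(t >= p$t0 + lvet)
  row_for <- function(idx) {
    y <- p$values[idx] - P_out
    qq <- q$values[idx]
    c(dP = p$values[idx[length(idx)]] - p$values[idx[1L]],
      intP = sum((y[-1L] + y[-length(y)]) / 2) * p$dt,
      intQ = sum((qq[-1L] + qq[-length(qq)]) / 2) * q$dt)
  }
  r1 <- row_for(sys_idx); r2 <- row_for(dia_idx)
  Amat <- rbind(c(r1[["dP"]], r1[["intP"]]), c(r2[["dP"]], r2[["intP"]]))
  bvec <- c(r1[["intQ"]], r2[["intQ"]])
  if (abs(det(Amat)) < 1e-14)
    cbp_stop("AC5 linear system is singular", "cbpkit_error_fit_failed")
  sol <- solve(Amat, bvec)
  cv_estimate(sol[1L], "AC5", list(inv_R = sol[2L]))
}

#' Estimate pulse wave velocity (methods PV1--PV5)
#'
#' PV1/PV2: foot-to-foot transit time between two flow (PV1) or pressure
#' (PV2) waves over a known path length. PV3/PV4: least-squares transit time,
#' the shift minimizing the squared mismatch of the two upstrokes, refined to
#' sub-sample resolution by parabolic interpolation. PV5: "sum of squares"
#' water-hammer method \code{PWV = (1/rho) sqrt(sum(dP^2)/sum(dU^2))} from a
#' co-located pressure wave and flow velocity \code{U = Q/A}.
#'
#' @param input an \code{\link{estimator_input}}; PV1/PV3 need \code{q_wave},
#'   \code{q_distal} and \code{dx}; PV2/PV4 need \code{p_pair} and \code{dx};
#'   PV5 needs \code{p_wave}, \code{q_wave}, \code{A} and \code{rho}.
#' @param method one of "PV1".."PV5".
#' @return a \code{cv_estimate} (m/s).
#' @export
estimate_pwv <- function(input, method = sprintf("PV%d", 1:5)) {
  method <- match.arg(method)
  if (method == "PV5") {
    p <- need(input$p_wave, "a pressure wave", "PV5")
    q <- need(input$q_wave, "a flow wave", "PV5")
    A <- need(input$A, "the aortic root area A", "PV5")
    if (length(q$values) != length(p$values)) q <- resample_wave(q, p$dt)
    dP <- diff(p$values) * PA_PER_MMHG
    dU <- diff(q$values * 1e-6 / A)
    if (sum(dU^2) <= 0)
      cbp_stop("PV5: flow velocity has zero variation", "cbpkit_error_nonphysical")
    return(cv_estimate(sqrt(sum(dP^2) / sum(dU^2)) / input$rho, "PV5",
                       list(A = A)))
  }
  dx <- need(input$dx, "the path length dx", method)
  if (method %in% c("PV1", "PV3")) {
    prox <- need(input$q_wave, "the proximal flow wave", method)
    dist <- need(input$q_distal, "the distal flow wave", method)
  } else {
    pair <- need(input$p_pair, "a pressure wave pair", method)
    prox <- pair[[1L]]; dist <- pair[[2L]]
  }
  if (method %in% c("PV1", "PV2")) {
    tt <- detect_foot(dist) - detect_foot(prox)
    if (tt <= 0)
      cbp_stop("transit time must be positive", "cbpkit_error_nonphysical")
    return(cv_estimate(dx / tt, method, list(transit_time = tt)))
  }
  # least-squares transit time over the proximal upstroke window
  if (abs(dist$dt - prox$dt) > 1e-12) dist <- resample_wave(dist, prox$dt)
  foot_i <- max(1L, 1L + round((detect_foot(prox) - prox$t0) / prox$dt))
  peak_i <- which.max(prox$values)
  if (peak_i <= foot_i)
    cbp_stop("proximal upstroke window is empty", "cbpkit_error_landmark_not_found")
  win <- foot_i:peak_i
  t_win <- prox$t0 + (win - 1L) * prox$dt
  s_grid <- seq(0, 0.5 * prox$period, by = prox$dt)
  sse <- vapply(s_grid, function(s)
    sum((prox$values[win] - wave_at(dist, t_win + s))^2), numeric(1))
  i_best <- which.min(sse)
  s_star <- s_grid[i_best]
  if (i_best > 1L && i_best < length(s_grid)) {   # parabolic refinement
    y1 <- sse[i_best - 1L]; y2 <- sse[i_best]; y3 <- sse[i_best + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom > 0) s_star <- s_star + 0.5 * prox$dt * (y1 - y3) / denom
  }
  if (s_star <= 0)
    cbp_stop("least-squares transit time is not positive",
             "cbpkit_error_nonphysical")
  cv_estimate(dx / s_star, method, list(transit_time = s_star))
}

#' Estimate aortic characteristic impedance (methods Z1--Z6)
#'
#' Z1 averages the input-impedance modulus \code{|P_k / Q_k|} over
#' intermediate harmonics (default 4--10). Z2 is the PQ-loop slope: the
#' least-squares slope of pressure against flow over early systole (from the
#' flow foot until the flow first reaches 95\% of its peak). Z3 = 0.05 R_T.
#' Z4 = (MBP - DBP)/Q_max. Z5 is the water-hammer form rho PWV / A, converted
#' to mmHg.s/mL. Z6 takes the impedance of the optimized three-element fit.
#'
#' @param input an \code{\link{estimator_input}}.
#' @param method one of "Z1".."Z6".
#' @param R_T total resistance (Z3).
#' @param PWV pulse wave velocity in m/s (Z5).
#' @param P_out outflow pressure (Z6).
#' @param harmonic_range integer harmonics used by Z1.
#' @param MBP mean pressure override for Z4; defaults to the wave mean when a
#'   pressure wave is present, else the cuff surrogate DBP + 0.4 PP.
#' @return a \code{cv_estimate} (mmHg.s/mL).
#' @export
estimate_z0 <- function(input, method = sprintf("Z%d", 1:6), R_T = NULL,
                        PWV = NULL, P_out = NULL, harmonic_range = 4:10,
                        MBP = NULL) {
  method <- match.arg(method)
  if (method == "Z3")
    return(cv_estimate(0.05 * need(R_T, "R_T", "Z3"), "Z3", list(R_T = R_T)))
  if (method == "Z5") {
    A <- need(input$A, "the aortic root area A", "Z5")
    PWV <- need(PWV, "a PWV estimate", "Z5")
    z_si <- input$rho * PWV / A
    return(cv_estimate(z_si * MMHG_S_ML_PER_PA_S_M3, "Z5",
                       list(z_pa_s_m3 = z_si)))
  }
  if (method == "Z4") {
    q <- need(input$q_wave, "a flow wave", "Z4")
    DBP <- need(input$DBP, "DBP", "Z4")
    if (is.null(MBP)) {
      MBP <- if (!is.null(input$p_wave)) wave_stats(input$p_wave)$MBP
             else DBP + 0.4 * (need(input$SBP, "SBP", "Z4") - DBP)
    }
    qmax <- wave_stats(q)$Q_max
    if (qmax <= 0) cbp_stop("Q_max must be positive", "cbpkit_error_nonphysical")
    return(cv_estimate((MBP - DBP) / qmax, "Z4", list(MBP = MBP)))
  }
  p <- need(input$p_wave, "a pressure wave", method)
  q <- need(input$q_wave, "a flow wave", method)
  if (method == "Z6") {
    fit <- fit_3wk_optimized(p, q, need(R_T, "R_T", "Z6"),
                             need(P_out, "P_out", "Z6"))
    return(cv_estimate(fit$Z_0, "Z6", list(C_T = fit$C_T, rmse = fit$rmse)))
  }
  if (length(q$values) != length(p$values)) q <- resample_wave(q, p$dt)
  if (method == "Z1") {
    kmax <- max(harmonic_range)
    hp <- wave_harmonics(p, kmax)
    hq <- wave_harmonics(q, kmax)
    q0 <- Mod(hq[1L])
    keep <- harmonic_range[Mod(hq[harmonic_range + 1L]) > 1e-9 * q0]
    if (length(keep) == 0L)
      cbp_stop("all selected harmonics have negligible flow content",
               "cbpkit_error_fit_failed")
    z <- Mod(hp[keep + 1L] / hq[keep + 1L])
    return(cv_estimate(mean(z), "Z1",
                       list(harmonics = keep, moduli = z)))
  }
  # Z2: PQ-loop slope over early systole
  foot_i <- max(1L, 1L + round((detect_foot(q) - q$t0) / q$dt))
  qmax <- max(q$values)
  i95 <- which(q$values >= 0.95 * qmax)[1L]
  if (is.na(i95) || i95 - foot_i + 1L < 5L)
    cbp_stop("fewer than 5 samples in the early-systolic PQ window",
             "cbpkit_error_fit_failed")
  win <- foot_i:i95
  slope <- stats::cov(q$values[win], p$values[win]) / stats::var(q$values[win])
  cv_estimate(slope, "Z2", list(window = range(win)))
}
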