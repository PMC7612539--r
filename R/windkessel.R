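#' Windkessel parameter set
#'
#' Lumped-parameter description of the systemic arterial tree: total
#' resistance \code{R_T}, total compliance \code{C_T}, proximal characteristic
#' impedance \code{Z_0} (zero for the two-element model) and the asymptotic
#' outflow pressure \code{P_out}. The distal resistance is
#' \code{R = R_T - Z_0}.
#'
#' Units: resistance and impedance in mmHg.s/mL, compliance in mL/mmHg,
#' pressure in mmHg.
#'
#' @param R_T total arterial resistance (> 0).
#' @param C_T total arterial compliance (> 0).
#' @param Z_0 characteristic impedance (0 <= Z_0 < R_T).
#' @param P_out outflow pressure (>= 0).
#' @return an object of class \code{wk_params}.
#' @export
wk_params <- function(R_T, C_T, Z_0 = 0, P_out = 0) {
  if (!is.finite(R_T) || R_T <= 0)
    cbp_stop("R_T must be positive", "cbpkit_error_invalid_params")
  if (!is.finite(C_T) || C_T <= 0)
    cbp_stop("C_T must be positive", "cbpkit_error_invalid_params")
  if (!is.finite(Z_0) || Z_0 < 0 || Z_0 >= R_T)
    cbp_stop("Z_0 must satisfy 0 <= Z_0 < R_T", "cbpkit_error_invalid_params")
  if (!is.finite(P_out) || P_out < 0)
    cbp_stop("P_out must be non-negative", "cbpkit_error_invalid_params")
  structure(list(R_T = R_T, C_T = C_T, Z_0 = Z_0, P_out = P_out,
                 R = R_T - Z_0),
            class = "wk_params")
}

#' @export
print.wk_params <- function(x, ...) {
  cat(sprintf("<wk_params> R_T = %.4g mmHg.s/mL, C_T = %.4g mL/mmHg, Z_0 = %.4g, P_out = %.4g mmHg\n",
              x$R_T, x$C_T, x$Z_0, x$P_out))
  invisible(x)
}

#' Solver settings for the Windkessel forward models
#'
#' @param mode "periodic" (default) returns the unique cycle with
#'   \code{P(0) = P(T)}, obtained in closed form from the linearity of the
#'   model; "transient" integrates cycle by cycle from \code{P_0}.
#' @param P_0 initial pressure for transient mode (mmHg); defaults to
#'   \code{P_out}.
#' @param tol convergence tolerance on the cycle-start pressure for transient
#'   mode (mmHg).
#' @param max_cycles maximum number of transient cycles.
#' @return a list of class \code{wk_settings}.
#' @export
wk_settings <- function(mode = c("periodic", "transient"), P_0 = NULL,
                        tol = 1e-6, max_cycles = 200L) {
  mode <- match.arg(mode)
  if (tol <= 0) cbp_stop("tol must be positive", "cbpkit_error_invalid_params")
  if (max_cycles < 1) cbp_stop("max_cycles must be >= 1", "cbpkit_error_invalid_params")
  structure(list(mode = mode, P_0 = P_0, tol = tol,
                 max_cycles = as.integer(max_cycles)),
            class = "wk_settings")
}

# Shared integrator for both Windkessel models.
#
# Substituting y = P - P_out - Z_0*Q turns the governing equation into
# dy/dt = -y/tau + Q/C_T with tau = (R_T - Z_0)*C_T, which is advanced with an
# exponential integrator (trapezoid rule on the exponentially weighted
# forcing). The decay factor is assembled inside the step so nothing
# overflows for small tau. The step is a linear recurrence
# y[k+1] = a*y[k] + x[k], evaluated at C speed via stats::filter.
solve_wk_core <- function(q, params, settings) {
  assert_wave(q, "flow")
  Qv <- q$values
  n <- length(Qv)
  dt <- q$dt
  tau <- params$R * params$C_T
  if (!is.finite(tau) || tau <= 0)
    cbp_stop("(R_T - Z_0) * C_T must be positive", "cbpkit_error_invalid_params")
  a <- exp(-dt / tau)
  Qnext <- Qv[c(2:n, 1L)]                       # periodic closure
  x <- (dt / (2 * params$C_T)) * (a * Qv + Qnext)
  z <- recursive_filter(x, a, y0 = 0)           # particular solution, y0 = 0

  if (settings$mode == "periodic") {
    an <- a^n
    y0 <- z[n] / (1 - an)
    if (!is.finite(y0))
      cbp_stop("periodic solve failed (tau too large relative to T?)",
               "cbpkit_error_solver")
  } else {
    P0 <- settings$P_0 %||% params$P_out
    y0 <- P0 - params$P_out - params$Z_0 * Qv[1L]
    an <- a^n
    converged <- FALSE
    for (cyc in seq_len(settings$max_cycles)) {
      y0_next <- z[n] + an * y0
      if (abs(y0_next - y0) < settings$tol) { converged <- TRUE; y0 <- y0_next; break }
      y0 <- y0_next
    }
    if (!converged)
      cbp_stop(sprintf("transient solve did not converge in %d cycles",
                       settings$max_cycles), "cbpkit_error_solver")
  }

  y <- c(y0, z[seq_len(n - 1L)] + a^(seq_len(n - 1L)) * y0)
  P <- params$P_out + params$Z_0 * Qv + y
  uniform_wave(P, dt, t0 = q$t0, kind = "pressure")
}

#' Two-element Windkessel pressure solution
#'
#' Solves \code{dP/dt + (P - P_out)/(R_T C_T) = Q_in/C_T} for the pressure
#' wave driven by one cycle of aortic inflow, by the integrating-factor
#' (exponential) method. In periodic mode the unique initial value with
#' \code{P(0) = P(T)} is found in closed form.
#'
#' @param q inflow wave (\code{\link{uniform_wave}}, kind "flow").
#' @param params \code{\link{wk_params}}; \code{Z_0} is ignored (treated as 0).
#' @param settings \code{\link{wk_settings}}.
#' @return pressure \code{uniform_wave} on the same grid as \code{q}.
#' @export
solve_2wk <- function(q, params, settings = wk_settings()) {
  p2 <- wk_params(R_T = params$R_T, C_T = params$C_T, Z_0 = 0,
                  P_out = params$P_out)
  solve_wk_core(q, p2, settings)
}

#' Three-element Windkessel pressure solution
#'
#' Solves \code{dP/dt + (P - P_out)/(R C_T) = Z_0 dQ/dt + R_T Q/(R C_T)} with
#' \code{R = R_T - Z_0}. The \code{Z_0 dQ/dt} term is handled analytically
#' through the substitution \code{y = P - P_out - Z_0 Q}, so no numerical
#' differentiation of the flow is needed. With \code{Z_0 = 0} the solution
#' reduces exactly to the two-element model.
#'
#' @inheritParams solve_2wk
#' @param params \code{\link{wk_params}} with \code{0 <= Z_0 < R_T}.
#' @return pressure \code{uniform_wave} on the same grid as \code{q}.
#' @export
solve_3wk <- function(q, params, settings = wk_settings()) {
  solve_wk_core(q, params, settings)
}

#' Diastolic pressure-decay time constant
#'
#' With zero inflow the Windkessel pressure decays as
#' \code{exp(-t/tau)} toward \code{P_out}, with
#' \code{tau = (R_T - Z_0) * C_T} (three-element; \code{R_T * C_T} for the
#' two-element model, where \code{Z_0 = 0}).
#'
#' @param params \code{\link{wk_params}}.
#' @return tau in seconds.
#' @export
diastolic_decay_constant <- function(params) {
  (params$R_T - params$Z_0) * params$C_T
}

#' Fixed-step Runge-Kutta reference integration of the Windkessel equations
#'
#' Classic 4th-order Runge-Kutta applied directly to the governing pressure
#' ODE, intended as an independent numerical cross-check of the closed-form
#' solvers. The flow (and, for the three-element model, its derivative) is
#' supplied as a function of time so the oracle does not share the solvers'
#' sampled-convolution code path. For this scalar linear ODE the RK4 step
#' reduces to a linear recurrence whose coefficients are formed from the
#' forcing at \code{t}, \code{t + h/2} and \code{t + h}; the recurrence is
#' evaluated exactly, so the result is the classic RK4 trajectory to machine
#' precision.
#'
#' @param qfun vectorized function of time returning inflow (mL/s).
#' @param params \code{\link{wk_params}}.
#' @param period cycle duration T (s).
#' @param dt step size (s); the actual step divides T exactly.
#' @param dqfun vectorized derivative of \code{qfun} (required when
#'   \code{Z_0 > 0}).
#' @param periodic if TRUE (default) the periodic cycle is returned, using two
#'   integrations to identify the linear one-cycle map and its fixed point;
#'   otherwise a single cycle from \code{P_0}.
#' @param P_0 initial pressure for the non-periodic case.
#' @return pressure \code{uniform_wave} sampled at the step size.
#' @export
solve_wk_rk4 <- function(qfun, params, period, dt = 1e-5, dqfun = NULL,
                         periodic = TRUE, P_0 = NULL) {
  if (params$Z_0 > 0 && is.null(dqfun))
    cbp_stop("dqfun is required when Z_0 > 0", "cbpkit_error_invalid_params")
  n <- max(round(period / dt), 32L)
  h <- period / n
  cc <- 1 / (params$R * params$C_T)
  tt <- (0:(2L * n)) * (h / 2)
  g <- params$P_out * cc + params$R_T * qfun(tt) * cc
  if (params$Z_0 > 0) g <- g + params$Z_0 * dqfun(tt)
  idx0 <- 2L * (0:(n - 1L)) + 1L
  g0 <- g[idx0]; gh <- g[idx0 + 1L]; g1 <- g[idx0 + 2L]
  b <- cc * h
  A <- 1 - b + b^2 / 2 - b^3 / 6 + b^4 / 24
  B <- (h / 6) * ((1 - b + b^2 / 2 - b^3 / 4) * g0 + (4 - 2 * b + b^2 / 2) * gh + g1)
  run <- function(P0) c(P0, recursive_filter(B, A, y0 = P0))
  if (periodic) {
    r0 <- run(0); r1 <- run(1)
    Afull <- r1[n + 1L] - r0[n + 1L]       # numerically identified cycle map slope
    P0 <- r0[n + 1L] / (1 - Afull)
    P <- run(P0)[seq_len(n)]
    out <- uniform_wave(P, h, t0 = 0, kind = "pressure")
  } else {
    P0 <- P_0 %||% params$P_out
    traj <- run(P0)
    out <- uniform_wave(traj[seq_len(n)], h, t0 = 0, kind = "pressure")
    attr(out, "P_end") <- traj[n + 1L]   # pressure at t = T
  }
  out
}

#' Optimized three-element Windkessel fit
#'
#' Estimates \code{Z_0} and \code{C_T} by least squares: the pair minimizing
#' the RMSE between a measured pressure wave and the periodic three-element
#' solution driven by the measured flow wave, with \code{R_T} and \code{P_out}
#' held fixed. This is the basis of the AC9 (compliance) and Z6 (impedance)
#' estimation methods.
#'
#' The search is a bounded derivative-free Nelder-Mead run in a logit-
#' transformed parameterization (\code{Z_0} in \code{(1e-4, 0.5) * R_T},
#' \code{C_T} in \code{(0.05, 10)} mL/mmHg), from \code{n_starts} starting
#' points: one heuristic (\code{Z_0 = 0.05 R_T}, \code{C_T = SV/PP}) and the
#' rest drawn with an internal fixed-seed generator so fits are reproducible
#' and leave the caller's RNG untouched. The best run is polished with a
#' restarted Nelder-Mead.
#'
#' @param p measured pressure \code{\link{uniform_wave}}.
#' @param q flow \code{\link{uniform_wave}}; resampled onto the pressure grid
#'   when the grids differ (periods must agree within 1\%).
#' @param R_T,P_out fixed total resistance and outflow pressure (from AR1/OP1
#'   or known truth).
#' @param n_starts number of multi-start points (>= 1; default 4).
#' @param seed seed for the internal start-point generator.
#' @return an object of class \code{wk3_fit} with components \code{Z_0},
#'   \code{C_T}, \code{R_T}, \code{P_out}, \code{rmse}, the fitted pressure
#'   wave and the inputs. Supports \code{coef}, \code{print}, \code{fitted},
#'   \code{residuals} and \code{plot}.
#' @export
fit_3wk_optimized <- function(p, q, R_T, P_out, n_starts = 4L, seed = 20200241) {
  assert_wave(p, "pressure"); assert_wave(q, "flow")
  if (abs(p$period - q$period) > 0.01 * p$period)
    cbp_stop("pressure and flow periods differ by more than 1%",
             "cbpkit_error_incomparable_waves")
  if (length(q$values) != length(p$values) || abs(q$dt - p$dt) > 1e-12) {
    q <- resample_wave(q, p$dt)
    if (length(q$values) != length(p$values))
      q$values <- stats::approx(seq(0, 1, length.out = length(q$values) + 1L),
                                c(q$values, q$values[1L]),
                                xout = seq(0, 1, length.out = length(p$values) + 1L)[seq_len(length(p$values))])$y
  }
  lo <- c(1e-4 * R_T, 0.05)
  hi <- c(0.5 * R_T, 10)
  to_theta <- function(x) stats::qlogis((x - lo) / (hi - lo))
  from_theta <- function(th) lo + (hi - lo) * stats::plogis(th)
  pv <- p$values
  obj <- function(th) {
    x <- from_theta(th)
    pr <- try(solve_wk_core(q, wk_params(R_T, x[2L], x[1L], P_out),
                            wk_settings("periodic")), silent = TRUE)
    if (inherits(pr, "try-error")) return(1e6)
    sqrt(mean((pr$values - pv)^2))
  }
  st <- wave_stats(p)
  sv <- wave_stats(q)$SV
  c0 <- if (st$PP > 0) sv / st$PP else 1.3
  start1 <- pmin(pmax(c(0.05 * R_T, c0), lo * 1.05), hi * 0.95)
  starts <- list(to_theta(start1))
  if (n_starts > 1L) {
    extra <- with_local_seed(seed, {
      lapply(seq_len(n_starts - 1L), function(i)
        to_theta(lo + (hi - lo) * stats::runif(2, 0.05, 0.95)))
    })
    starts <- c(starts, extra)
  }
  best <- NULL
  n_fail <- 0L
  for (s in starts) {
    res <- try(stats::optim(s, obj, method = "Nelder-Mead",
                            control = list(reltol = 1e-12, maxit = 1000)),
               silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res$value)) {
      n_fail <- n_fail + 1L
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    cbp_stop("all optimizer starts failed", "cbpkit_error_fit_failed",
             incumbent = NULL)
  # polish: restart Nelder-Mead from the incumbent
  pol <- try(stats::optim(best$par, obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-14, maxit = 1000)),
             silent = TRUE)
  if (!inherits(pol, "try-error") && is.finite(pol$value) && pol$value <= best$value)
    best <- pol
  x <- from_theta(best$par)
  fit_wave <- solve_wk_core(q, wk_params(R_T, x[2L], x[1L], P_out),
                            wk_settings("periodic"))
  structure(list(Z_0 = x[1L], C_T = x[2L], R_T = R_T, P_out = P_out,
                 rmse = best$value, fitted_wave = fit_wave,
                 pressure = p, flow = q, n_starts = length(starts),
                 n_failed_starts = n_fail),
            class = "wk3_fit")
}

#' @export
print.wk3_fit <- function(x, ...) {
  cat(sprintf("<wk3_fit> Z_0 = %.5g mmHg.s/mL, C_T = %.5g mL/mmHg (R_T = %.4g, P_out = %.4g fixed)\n",
              x$Z_0, x$C_T, x$R_T, x$P_out))
  cat(sprintf("  waveform RMSE = %.4g mmHg over %d samples\n",
              x$rmse, length(x$pressure$values)))
  invisible(x)
}

#' @export
coef.wk3_fit <- function(object, ...) {
  c(Z_0 = object$Z_0, C_T = object$C_T)
}

#' @export
fitted.wk3_fit <- function(object, ...) object$fitted_wave$values

#' @export
residuals.wk3_fit <- function(object, ...) {
  object$pressure$values - object$fitted_wave$values
}

#' @export
plot.wk3_fit <- function(x, ...) {
  t <- wave_times(x$pressure)
  graphics::plot(t, x$pressure$values, type = "l", xlab = "Time (s)",
                 ylab = "Pressure (mmHg)", ...)
  graphics::lines(t, x$fitted_wave$values, lty = 2, col = 2)
  graphics::legend("topright", c("measured", "3-Wk fit"), lty = 1:2,
                   col = 1:2, bty = "n")
  invisible(x)
}
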