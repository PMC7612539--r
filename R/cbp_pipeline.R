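## Two-stage central blood pressure estimation: method selection, CV
## parameter estimation in dependency order, and forward Windkessel
## simulation; plus outlet-parameter construction for 1-D solver coupling.

# methods that require a full peripheral pressure wave
PRESSURE_WAVE_METHODS <- c("LV1", "LV2", "OP1", "OP2", "AR1",
                           sprintf("AC%d", 1:5), "AC9", "PV5",
                           "Z1", "Z2", "Z6")

#' Select CV parameter estimation methods for a clinical scenario
#'
#' Returns the per-parameter method codes found optimal for each scenario and
#' validation profile. Defaults use the physiologically richer 1-D profile:
#' carotid+ (peripheral pressure wave available) uses LV4, OP1, AR1, AC9,
#' PV1, Z2; carotid- (only cuff DBP/SBP) uses LV4, OP3, AR2, AC8, PV1, Z4.
#' The lumped-model (0D) profile swaps the compliance and impedance choices
#' for AC2/Z6 (carotid+) and AC7/Z3 (carotid-), and has no PWV method (a
#' lumped model has no wave propagation).
#'
#' @param scenario "carotid+" or "carotid-".
#' @param profile "1D" (default) or "0D".
#' @param overrides named list of method codes to override, e.g.
#'   \code{list(C_T = "AC2")}; overrides incompatible with the scenario (a
#'   wave-based method under carotid-) raise a configuration error.
#' @return named character vector of class \code{method_selection} with
#'   entries LVET, P_out, R_T, C_T, PWV, Z_0.
#' @export
select_methods <- function(scenario = c("carotid+", "carotid-"),
                           profile = c("1D", "0D"), overrides = NULL) {
  scenario <- match.arg(scenario)
  profile <- match.arg(profile)
  sel <- if (profile == "1D") {
    if (scenario == "carotid+")
      c(LVET = "LV4", P_out = "OP1", R_T = "AR1", C_T = "AC9", PWV = "PV1",
        Z_0 = "Z2")
    else
      c(LVET = "LV4", P_out = "OP3", R_T = "AR2", C_T = "AC8", PWV = "PV1",
        Z_0 = "Z4")
  } else {
    if (scenario == "carotid+")
      c(LVET = "LV4", P_out = "OP1", R_T = "AR1", C_T = "AC2", PWV = NA,
        Z_0 = "Z6")
    else
      c(LVET = "LV4", P_out = "OP3", R_T = "AR2", C_T = "AC7", PWV = NA,
        Z_0 = "Z3")
  }
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(sel))
    if (length(bad))
      cbp_stop(sprintf("unknown parameter(s) in overrides: %s",
                       paste(bad, collapse = ", ")),
               "cbpkit_error_configuration")
    sel[names(overrides)] <- unlist(overrides)
  }
  if (scenario == "carotid-") {
    wavey <- sel[sel %in% PRESSURE_WAVE_METHODS & !is.na(sel)]
    if (length(wavey))
      cbp_stop(sprintf("method(s) %s need a pressure wave, unavailable under carotid-",
                       paste(wavey, collapse = ", ")),
               "cbpkit_error_configuration")
  }
  structure(sel, class = "method_selection", scenario = scenario,
            profile = profile)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    cbp_stop(sprintf("CV estimation failed at stage %s: %s", stage,
                     conditionMessage(e)),
             "cbpkit_error_pipeline", stage = stage, parent = e)
  })
}

#' Estimate all CV parameters for a subject (pipeline stage 1)
#'
#' Runs the selected estimators in dependency order
#' LVET -> P_out -> R_T -> C_T -> (PWV) -> Z_0, feeding each result into the
#' later stages. Any estimator failure aborts with an error naming the stage.
#'
#' @param input an \code{\link{estimator_input}}.
#' @param selection a \code{\link{select_methods}} result.
#' @param q_th LV4 flow threshold.
#' @return list of class \code{cv_param_estimates}: numeric \code{values}
#'   (LVET, P_out, R_T, C_T, Z_0, and PWV when computed) plus the individual
#'   \code{cv_estimate} objects under \code{details}.
#' @export
estimate_cv_params <- function(input, selection, q_th = 0.02) {
  det <- list()
  det$LVET <- pipeline_stage("LVET",
    estimate_lvet(input, selection[["LVET"]], q_th = q_th))
  det$P_out <- pipeline_stage("P_out",
    estimate_pout(input, selection[["P_out"]], lvet = det$LVET$value))
  det$R_T <- pipeline_stage("R_T",
    estimate_rt(input, selection[["R_T"]], P_out = det$P_out$value))
  det$C_T <- pipeline_stage("C_T",
    estimate_ct(input, selection[["C_T"]], R_T = det$R_T$value,
                P_out = det$P_out$value, lvet = det$LVET$value))
  pwv_code <- selection[["PWV"]]
  if (!is.na(pwv_code) && (!is.null(input$q_distal) || !is.null(input$p_pair))) {
    det$PWV <- pipeline_stage("PWV", estimate_pwv(input, pwv_code))
  }
  det$Z_0 <- pipeline_stage("Z_0",
    estimate_z0(input, selection[["Z_0"]], R_T = det$R_T$value,
                P_out = det$P_out$value,
                PWV = if (!is.null(det$PWV)) det$PWV$value else NULL))
  values <- vapply(det, function(d) d$value, numeric(1))
  structure(list(values = values, details = det, selection = selection),
            class = "cv_param_estimates")
}

#' @export
print.cv_param_estimates <- function(x, ...) {
  cat("<cv_param_estimates>\n")
  for (nm in names(x$values))
    cat(sprintf("  %-6s = %-10.5g (%s)\n", nm, x$values[[nm]],
                x$details[[nm]]$method))
  invisible(x)
}

#' Simulate the central blood pressure wave (pipeline stage 2)
#'
#' Periodic two- or three-element Windkessel solution driven by the measured
#' aortic flow wave, using estimated (or known) CV parameters.
#'
#' @param q_in aortic root flow \code{\link{uniform_wave}}.
#' @param params a \code{\link{wk_params}}, a \code{cv_param_estimates}, or a
#'   named list/vector with R_T, C_T, Z_0, P_out.
#' @param model "3wk" (default) or "2wk".
#' @return object of class \code{cbp_estimate}: the simulated \code{wave} plus
#'   derived cDBP/cSBP/cMBP/cPP, the parameters and model label. Supports
#'   \code{print}, \code{summary}, \code{coef} and \code{plot}.
#' @export
estimate_cbp <- function(q_in, params, model = c("3wk", "2wk")) {
  model <- match.arg(model)
  if (inherits(params, "cv_param_estimates")) params <- as.list(params$values)
  if (!inherits(params, "wk_params")) {
    params <- as.list(params)
    params <- wk_params(R_T = params$R_T, C_T = params$C_T,
                        Z_0 = params$Z_0 %||% 0, P_out = params$P_out)
  }
  wave <- if (model == "3wk") solve_3wk(q_in, params)
          else solve_2wk(q_in, params)
  st <- wave_stats(wave)
  structure(list(wave = wave, q_in = q_in, params = params, model = model,
                 cDBP = st$DBP, cSBP = st$SBP, cMBP = st$MBP, cPP = st$PP),
            class = "cbp_estimate")
}

#' @export
print.cbp_estimate <- function(x, ...) {
  cat(sprintf("<cbp_estimate> %s model: cDBP %.1f, cSBP %.1f, cMBP %.1f, cPP %.1f mmHg\n",
              x$model, x$cDBP, x$cSBP, x$cMBP, x$cPP))
  invisible(x)
}

#' @export
summary.cbp_estimate <- function(object, ...) {
  cat(sprintf("Central blood pressure estimate (%s Windkessel model)\n",
              object$model))
  cat(sprintf("  cDBP %.1f mmHg, cSBP %.1f mmHg, cMBP %.1f mmHg, cPP %.1f mmHg\n",
              object$cDBP, object$cSBP, object$cMBP, object$cPP))
  cat(sprintf("  parameters: R_T %.4g mmHg.s/mL, C_T %.4g mL/mmHg, Z_0 %.4g, P_out %.4g mmHg\n",
              object$params$R_T, object$params$C_T, object$params$Z_0,
              object$params$P_out))
  invisible(object)
}

#' @export
coef.cbp_estimate <- function(object, ...) {
  with(object$params, c(R_T = R_T, C_T = C_T, Z_0 = Z_0, P_out = P_out))
}

#' @export
plot.cbp_estimate <- function(x, ...) {
  plot(x$wave, main = sprintf("Estimated cBP (%s)", x$model), ...)
  invisible(x)
}

#' Full two-stage cBP estimation pipeline
#'
#' Convenience wrapper: select methods for the scenario, estimate the CV
#' parameters in dependency order, then simulate the central pressure wave.
#'
#' @param input an \code{\link{estimator_input}} containing at least the flow
#'   wave and a pressure source matching the scenario.
#' @param scenario "carotid+" or "carotid-".
#' @param model "3wk" or "2wk".
#' @param profile method-selection profile, "1D" or "0D".
#' @param selection optional explicit \code{\link{select_methods}} result.
#' @return a \code{cbp_estimate} with the stage-1 estimates attached as
#'   \code{$cv_params}.
#' @export
run_cbp_pipeline <- function(input, scenario = c("carotid+", "carotid-"),
                             model = c("3wk", "2wk"), profile = c("1D", "0D"),
                             selection = NULL) {
  scenario <- match.arg(scenario); model <- match.arg(model)
  profile <- match.arg(profile)
  if (is.null(selection)) selection <- select_methods(scenario, profile)
  est <- estimate_cv_params(input, selection)
  out <- estimate_cbp(need(input$q_wave, "a flow wave", "pipeline"),
                      est, model = model)
  out$cv_params <- est
  out
}

#' Outlet Windkessel parameters for a 1-D arterial network model
#'
#' Builds the three-element Windkessel parameters coupled to each terminal
#' segment of a 1-D thoracic-aorta model. Per outlet j:
#' \code{Z0_Wk = rho PWV / A_out} (water hammer, converted to mmHg.s/mL);
#' the outflow distribution \code{OD_j} is \code{Q_mean_j / Q_mean_in} when
#' outlet flows are measured, otherwise the flow deficit
#' \code{Q_mean_in - Q_mean_out} is split across the supra-aortic outlets in
#' proportion to their areas; \code{R_Wk = R_T / OD - Z0_Wk}; and
#' \code{C_Wk = (C_T - C_T_art) R_T / R_Wk}, where \code{C_T_art} is the
#' summed compliance of the 1-D segments,
#' \code{sum(A_mean * L / (rho PWV^2))}.
#'
#' @param Q_in ascending-aorta flow: a flow \code{\link{uniform_wave}} or the
#'   scalar mean flow (mL/s).
#' @param Q_out descending-aorta flow wave or scalar mean (mL/s).
#' @param outlets data.frame of supra-aortic outlets with columns
#'   \code{name}, \code{A_out} (m^2) and optionally \code{Q_mean} (mL/s).
#' @param R_T,C_T,P_out lumped parameters of the whole systemic tree
#'   (mmHg.s/mL, mL/mmHg, mmHg).
#' @param PWV aortic pulse wave velocity (m/s).
#' @param segments data.frame of 1-D segments with columns \code{A_mean}
#'   (m^2) and \code{L} (m).
#' @param rho blood density (kg/m^3).
#' @return object of class \code{outlet_params}: data.frame of per-outlet
#'   \code{Z0_Wk}, \code{R_Wk}, \code{C_Wk} (canonical units) and \code{OD},
#'   with \code{C_T_art} (mL/mmHg) and the inputs attached as attributes.
#' @export
build_1d_outlet_params <- function(Q_in, Q_out, outlets, R_T, C_T, P_out,
                                   PWV, segments, rho = 1060) {
  qbar <- function(x) if (is_wave(x)) wave_stats(x)$Q_mean else as.numeric(x)
  qin <- qbar(Q_in); qout <- qbar(Q_out)
  if (any(outlets$A_out <= 0) || sum(outlets$A_out) <= 0)
    cbp_stop("outlet areas must be positive", "cbpkit_error_invalid_input")
  if (is.null(outlets$Q_mean)) {
    if (qin <= qout)
      cbp_stop("area-based outflow distribution needs Q_mean_in > Q_mean_out",
               "cbpkit_error_invalid_input")
    q_outlet <- (qin - qout) * outlets$A_out / sum(outlets$A_out)
  } else {
    q_outlet <- outlets$Q_mean
  }
  od <- q_outlet / qin
  if (any(od <= 0))
    cbp_stop("outflow distribution has a zero/negative share",
             "cbpkit_error_invalid_input")
  if (sum(od) > 1 + 1e-9)
    cbp_stop("outflow distribution shares exceed the inflow",
             "cbpkit_error_invalid_input")
  z0 <- rho * PWV / outlets$A_out * MMHG_S_ML_PER_PA_S_M3
  r_wk <- R_T / od - z0
  if (any(r_wk <= 0))
    cbp_stop("an outlet resistance is not positive (Z0 exceeds R_T/OD)",
             "cbpkit_error_nonphysical")
  ct_art <- sum(segments$A_mean * segments$L / (rho * PWV^2)) * ML_MMHG_PER_M3_PA
  if (ct_art >= C_T)
    cbp_stop(sprintf("1-D segment compliance (%.3g mL/mmHg) is not below C_T (%.3g)",
                     ct_art, C_T), "cbpkit_error_nonphysical")
  c_wk <- (C_T - ct_art) * R_T / r_wk
  out <- data.frame(name = outlets$name %||% paste0("outlet", seq_along(od)),
                    A_out = outlets$A_out, Q_mean = q_outlet, OD = od,
                    Z0_Wk = z0, R_Wk = r_wk, C_Wk = c_wk)
  structure(out, class = c("outlet_params", "data.frame"),
            C_T_art = ct_art, R_T = R_T, C_T = C_T, P_out = P_out,
            PWV = PWV, rho = rho)
}
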