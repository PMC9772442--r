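#' Closed-form concentration predictions
#'
#' Evaluates the joint one-compartment parent-metabolite model in closed
#' form.  Amounts follow the linear chain depot -> VEN central -> ODV
#' central: a fraction `fp` of the absorbed dose is converted pre-systemically
#' and enters the ODV compartment directly; the remainder enters the VEN
#' compartment and is converted at rate `kp = cl_f / v_f`; ODV is eliminated
#' at `km = clm_f / vm_f`.  Concentrations are amount / volume scaled by 1000
#' (mg/L to ng/ml).  Contributions from all administered doses are
#' superposed; steady-state trains use per-exponential accumulation factors
#' `1 / (1 - exp(-lambda * tau))`.  Nearly equal rate constants (within a
#' relative 1e-4) are evaluated through confluent limit forms so the profile
#' is continuous through the `ka = kp` degeneracy.
#'
#' @param params a [structural_params()] object.
#' @param regimen a [pk_regimen()] (or single [dose_event()]).
#' @param times observation times (h); times before the first dose predict 0.
#' @param analyte `"VEN"` or `"ODV"`, recycled across `times` if scalar.
#' @return Numeric vector of concentrations (ng/ml).
#' @examples
#' p <- default_structural_params()
#' reg <- pk_regimen(dose_event(0, 50))
#' predict_conc(p, reg, c(1, 2, 6), "VEN")
#' @export
predict_conc <- function(params, regimen, times, analyte = "VEN") {
  stopifnot(inherits(params, "structural_params"))
  code <- .analyte_code(analyte, length(times))
  cpp_pred(.param_vec(params), .regimen_matrix(regimen),
           as.numeric(times), code)
}

.analyte_code <- function(analyte, n) {
  if (is.character(analyte)) {
    a <- match(analyte, c("VEN", "ODV")) - 1L
    if (any(is.na(a))) stop("analyte must be 'VEN' or 'ODV'", call. = FALSE)
  } else a <- as.integer(analyte)
  if (length(a) == 1L) a <- rep(a, n)
  if (length(a) != n) stop("analyte length must match times", call. = FALSE)
  a
}

#' @rdname predict_conc
#' @export
conc_parent <- function(params, regimen, times) {
  predict_conc(params, regimen, times, "VEN")
}

#' @rdname predict_conc
#' @export
conc_metabolite <- function(params, regimen, times) {
  predict_conc(params, regimen, times, "ODV")
}

#' Compartment amounts by numerical integration
#'
#' Integrates the model ODEs
#' \deqn{dA_0/dt = -k_a A_0,\quad
#'       dA_1/dt = (1 - f_p) k_a A_0 - k_p A_1,\quad
#'       dA_2/dt = f_p k_a A_0 + k_p A_1 - k_m A_2}
#' with doses added to the depot as events, plus the cumulative eliminated
#' metabolite amount for mass-balance checks.  Serves as the numerical
#' oracle for the closed-form predictor; steady-state event records are not
#' supported here.
#'
#' @inheritParams predict_conc
#' @param rtol,atol integrator tolerances passed to [deSolve::lsoda()].
#' @return A data frame with columns `time`, `depot`, `ven`, `odv`,
#'   `eliminated` (all mg).
#' @export
amounts_ode <- function(params, regimen, times, rtol = 1e-10, atol = 1e-10) {
  stopifnot(inherits(params, "structural_params"))
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and nonnegative", call. = FALSE)
  doses <- .expand_doses(regimen)
  kk <- derived_rates(params)
  ka <- params$ka; fp <- params$fp
  kp <- kk[["kp"]]; km <- kk[["km"]]
  rhs <- function(t, y, parms) {
    list(c(-ka * y[1],
           (1 - fp) * ka * y[1] - kp * y[2],
           fp * ka * y[1] + kp * y[2] - km * y[3],
           km * y[3]))
  }
  ev <- data.frame(var = "A0", time = doses$time, value = doses$amt,
                   method = "add")
  tout <- sort(unique(c(0, doses$time, times)))
  if (length(tout) < 2 || max(tout) == 0) tout <- c(tout, max(tout) + 1)
  sol <- deSolve::lsoda(c(A0 = 0, A1 = 0, A2 = 0, A3 = 0), tout, rhs, NULL,
                        rtol = rtol, atol = atol,
                        events = list(data = ev))
  if (attr(sol, "istate")[1] < 0)
    stop("numerical error: ODE integrator failed (istate ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  idx <- match(times, sol[, "time"])
  out <- data.frame(time = times, depot = sol[idx, "A0"],
                    ven = sol[idx, "A1"], odv = sol[idx, "A2"],
                    eliminated = sol[idx, "A3"])
  # the integrator reports the pre-event state at dose times; report
  # post-dose so an output exactly at a dose time includes that dose
  for (k in seq_len(nrow(doses)))
    out$depot <- out$depot +
      ifelse(abs(out$time - doses$time[k]) < 1e-12, doses$amt[k], 0)
  out
}

#' Steady-state concentration for a repeated oral regimen
#'
#' Concentration `t_after_dose` hours after a maintenance dose once the
#' regimen `dose` every `tau` hours has reached steady state.
#'
#' @param params a [structural_params()] object.
#' @param dose maintenance dose (mg).
#' @param tau interdose interval (h).
#' @param t_after_dose time after the last dose (h).
#' @param analyte `"VEN"` or `"ODV"`.
#' @return Concentration (ng/ml).
#' @export
steady_state_conc <- function(params, dose, tau, t_after_dose,
                              analyte = c("VEN", "ODV")) {
  analyte <- match.arg(analyte)
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive", call. = FALSE)
  reg <- pk_regimen(dose_event(0, dose, interdose_interval = tau,
                               steady_state = TRUE))
  predict_conc(params, reg, t_after_dose, analyte)
}
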