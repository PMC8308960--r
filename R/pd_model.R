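# Pharmacodynamics: donor-cell growth/kill driven by tubulin-bound drug.

#' EC50 of the kill function at a given exposure time
#'
#' Drug potency changes with exposure duration; the EC50 of the kill Hill
#' function declines from its time-zero value at rate `gamma_EC50`, either
#' exponentially (default; always positive) or linearly with a positive
#' floor.
#'
#' @param t time, h (non-negative; vectorized).
#' @param pd a [pd_parameters()] object.
#' @return EC50 at `t`, nM.
#' @export
#' @examples
#' pd <- pd_parameters(EC50_initial = 100, gamma_EC50 = log(2) / 24)
#' ec50_at_time(24, pd)  # half the initial value
ec50_at_time <- function(t, pd) {
  if (any(t < 0)) stop("t must be >= 0")
  if (pd$ec50_form == "exponential") {
    pd$EC50_initial * exp(-pd$gamma_EC50 * t)
  } else {
    pmax(pd$EC50_initial - pd$gamma_EC50 * t, pd$ec50_floor)
  }
}

#' Percent cytotoxicity relative to an untreated control
#'
#' @param N_treated treated-well cell count (or any proportional signal).
#' @param N_control untreated control count, must be positive.
#' @return Cytotoxicity, percent: `100 * (1 - N_treated / N_control)`.
#'   Negative values (treated growing faster than control) are reported
#'   as-is.
#' @export
#' @examples
#' cytotoxicity_percent(0.42, 1)  # 58 percent
cytotoxicity_percent <- function(N_treated, N_control) {
  if (any(N_control <= 0)) stop("N_control must be > 0")
  100 * (1 - N_treated / N_control)
}

#' Simulate coupled PK and donor-cell cytotoxicity
#'
#' Solves the cellular PK model, then drives the growth/kill ODE
#' `dN/dt = (k_g - k_kill * C_tub^n / (EC50(t)^n + C_tub^n)) * N` with the
#' interpolated tubulin-bound drug concentration (one-way coupling; the cell
#' count in the PK model is held at `N0`). Cytotoxicity is reported against
#' an exponentially growing untreated control, as in an SRB assay normalized
#' to parallel control wells.
#'
#' @inheritParams simulate_pk
#' @param pd a [pd_parameters()] object.
#' @return A list of class `ptx_pkpd` with elements `timecourse` (the
#'   `ptx_timecourse`), `pd` (data frame: `time_h`, `N`, `N_control`,
#'   `cytotoxicity_percent`) and the call metadata.
#' @export
#' @examples
#' sim <- simulate_pkpd(model_parameters(), pd_parameters(), 1000, 24)
#' tail(sim$pd, 1)$cytotoxicity_percent
simulate_pkpd <- function(params, pd, dose_nM, duration_h,
                          inhib = inhibition_settings(),
                          reltol = 1e-8, abstol = 1e-10, dt_out = 0.1) {
  tc <- simulate_pk(params, dose_nM, duration_h, inhib,
                    reltol = reltol, abstol = abstol, dt_out = dt_out)
  # the cell-count equation rides along the same (one-way coupled) system
  y0 <- c(A_medium = dose_nM * 1000 * params$V_medium, A_exo = 0,
          A_cell_free = 0, A_tubulin = 0, A_ves = 0, N = params$N0)
  sol <- deSolve::lsoda(y = y0, times = tc$time_h, func = "qp_derivs",
                        dllname = "exoflux", initfunc = "qp_initmod",
                        parms = .rhs_parms(params, inhib$alpha, inhib$beta,
                                           pd),
                        rtol = reltol, atol = c(rep(abstol, 5), 1e-2))
  if (attr(sol, "istate")[1] < 0) stop("PD integration failed")
  N <- sol[, "N"]
  N_control <- params$N0 * exp(pd$k_g * tc$time_h)
  out <- list(timecourse = tc,
              pd = data.frame(time_h = tc$time_h, N = N,
                              N_control = N_control,
                              cytotoxicity_percent =
                                cytotoxicity_percent(N, N_control)),
              dose_nM = dose_nM, inhib = inhib)
  class(out) <- "ptx_pkpd"
  out
}

#' @export
print.ptx_pkpd <- function(x, ...) {
  last <- x$pd[nrow(x$pd), ]
  cat(sprintf("PK/PD simulation: dose %.4g nM, %.4g h, arm %s\n",
              x$dose_nM, last$time_h, x$inhib$label))
  cat(sprintf("  final cytotoxicity %.3g%% (N = %.4g vs control %.4g)\n",
              last$cytotoxicity_percent, last$N, last$N_control))
  invisible(x)
}

#' Final-time cytotoxicity for a treatment condition
#'
#' Convenience wrapper returning the percent cytotoxicity at the end of a
#' simulated treatment.
#'
#' @inheritParams simulate_pkpd
#' @return Cytotoxicity at `duration_h`, percent.
#' @export
simulate_cytotoxicity <- function(params, pd, dose_nM, duration_h,
                                  inhib = inhibition_settings(), ...) {
  if (dose_nM == 0) return(0)
  sim <- simulate_pkpd(params, pd, dose_nM, duration_h, inhib, ...)
  sim$pd$cytotoxicity_percent[nrow(sim$pd)]
}
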