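# Cellular PK of exosome-mediated drug efflux.
#
# State vector (amounts, pmol):
#   A_medium    non-exosomal drug in medium (free + macromolecule-bound,
#               split instantaneously by fu_medium)
#   A_exo       drug in extracellular exosomes
#   A_cell_free free intracellular drug
#   A_tubulin   tubulin-bound intracellular drug
#   A_ves       drug in pre-exosome intracellular vesicles
#
# Concentrations are nM = pmol / (1000 * V[L]).

.state_names <- c("A_medium", "A_exo", "A_cell_free", "A_tubulin", "A_ves")

.entity_names <- c("PTX_medium_free", "PTX_exo", "PTX_cell_free",
                   "PTX_tubulin", "PTX_ves", "PTX_donor_lysate")

.conc_nM <- function(A_pmol, V_L) A_pmol / (1000 * V_L)

#' Time derivatives of the cellular PK state
#'
#' Right-hand side of the cellular PK model. Drug enters and leaves the cell
#' by passive diffusion along the free-drug gradient, is pumped out by a
#' saturable P-glycoprotein term, binds reversibly to a saturable tubulin
#' pool, is sorted (first order) from the free and tubulin-bound pools into
#' pre-exosome vesicles, leaves the cell by first-order exosome release, and
#' re-enters by saturable receptor-mediated exosome internalization. The
#' sorting flux is scaled by `(1 - alpha)` and the release flux by
#' `(1 - beta)`. The system is closed: the derivatives sum to zero.
#'
#' @param state named numeric vector of the five amounts (pmol), in the order
#'   `A_medium`, `A_exo`, `A_cell_free`, `A_tubulin`, `A_ves`.
#' @param t time, h (the system is autonomous; `t` is accepted for solver
#'   compatibility).
#' @param params a [model_parameters()] object.
#' @param inhib an [inhibition_settings()] object.
#' @return Named numeric vector of time derivatives, pmol/h.
#' @export
#' @examples
#' p <- model_parameters()
#' d <- ptx_derivatives(c(A_medium = 2000, A_exo = 0, A_cell_free = 0,
#'                        A_tubulin = 0, A_ves = 0), 0, p, inhibition_settings())
#' sum(d)  # closed system: 0
ptx_derivatives <- function(state, t = 0, params, inhib = inhibition_settings()) {
  if (length(state) != 5) stop("state must have 5 components")
  if (any(!is.finite(state))) stop("non-finite state component")
  if (any(state < -1e-9)) stop("negative state component")
  names(state) <- .state_names
  d <- .ptx_rhs(t, state, list(p = params, alpha = inhib$alpha,
                               beta = inhib$beta))[[1]]
  names(d) <- .state_names
  d
}

# parameter vector for the compiled RHS (see src/qp_rhs.c)
.rhs_parms <- function(p, alpha, beta, pd = NULL) {
  c(p$D_fd, p$Jmax_pgp, p$Kd_pgp, p$k_tubulin_on, p$k_tubulin_off,
    p$B_tubulin_max, p$k_formation_free, p$k_formation_tubulin,
    p$k_release, p$Jmax_inter_exo, p$Kd_inter_exo, p$fu_medium,
    p$V_medium, p$v_cell, p$N0, alpha, beta,
    as.numeric(p$reuptake_to == "cytosol"),
    as.numeric(p$alpha_targets == "both"),
    as.numeric(!is.null(pd)),
    if (is.null(pd)) rep(0, 7)
    else c(pd$k_kill, pd$EC50_initial, pd$gamma_EC50, pd$n_hill, pd$k_g,
           as.numeric(pd$ec50_form == "exponential"), pd$ec50_floor))
}

# deSolve-style RHS in R; reference implementation used by
# ptx_derivatives() and kept as the oracle the compiled core is tested
# against. parms = list(p = model_parameters, alpha, beta)
.ptx_rhs <- function(t, y, parms) {
  p <- parms$p
  alpha <- parms$alpha
  beta <- parms$beta
  V_cells <- p$N0 * p$v_cell
  ncell6 <- p$N0 / 1e6

  C_mf <- p$fu_medium * .conc_nM(y[1], p$V_medium)  # free drug in medium, nM
  C_exo <- .conc_nM(y[2], p$V_medium)
  C_cf <- .conc_nM(y[3], V_cells)
  C_tub <- .conc_nM(y[4], V_cells)

  J_diff <- p$D_fd * 1000 * V_cells * (C_mf - C_cf)          # medium -> cell
  J_pgp <- p$Jmax_pgp * ncell6 * C_cf / (p$Kd_pgp + C_cf)    # cell -> medium
  J_on <- p$k_tubulin_on * C_cf * (p$B_tubulin_max - C_tub) * 1000 * V_cells
  J_off <- p$k_tubulin_off * y[4]
  sort_free <- p$k_formation_free * y[3]
  sort_tub <- p$k_formation_tubulin * y[4]
  if (p$alpha_targets == "both") {
    sort_free <- (1 - alpha) * sort_free
    sort_tub <- (1 - alpha) * sort_tub
  } else {
    sort_free <- (1 - alpha) * sort_free
  }
  J_rel <- (1 - beta) * p$k_release * y[5]                   # ves -> exo
  J_up <- p$Jmax_inter_exo * ncell6 * C_exo / (p$Kd_inter_exo + C_exo)

  dM <- -J_diff + J_pgp
  dE <- J_rel - J_up
  dF <- J_diff - J_pgp - J_on + J_off - sort_free
  dT <- J_on - J_off - sort_tub
  dV <- sort_free + sort_tub - J_rel
  if (p$reuptake_to == "cytosol") dF <- dF + J_up else dV <- dV + J_up
  list(c(dM, dE, dF, dT, dV))
}

#' Simulate the cellular PK time course
#'
#' Integrates the model from an all-drug-in-medium initial condition (the
#' experimental design: drug is added to the culture medium at time zero at
#' concentration `dose_nM`, all intracellular and exosomal pools empty) with
#' a stiff-capable adaptive solver (`deSolve::lsoda`).
#'
#' @param params a [model_parameters()] object.
#' @param dose_nM initial total drug concentration in medium, nM.
#' @param duration_h treatment duration, h.
#' @param inhib an [inhibition_settings()] object.
#' @param reltol,abstol solver tolerances (abstol in pmol).
#' @param dt_out output grid spacing, h.
#' @return A `ptx_timecourse`: a data frame with the time grid (`time_h`),
#'   the five amounts (pmol) and the derived concentration series
#'   `PTX_medium_free`, `PTX_exo`, `PTX_cell_free`, `PTX_tubulin`, `PTX_ves`
#'   and `PTX_donor_lysate` (all nM; the lysate series is the sum of the
#'   three intracellular entities), with dose, arm and parameter metadata in
#'   attributes.
#' @export
#' @examples
#' tc <- simulate_pk(model_parameters(), dose_nM = 1000, duration_h = 48)
#' auc(tc, "PTX_exo", 0, 48)
simulate_pk <- function(params, dose_nM, duration_h,
                        inhib = inhibition_settings(),
                        reltol = 1e-8, abstol = 1e-10, dt_out = 0.1) {
  if (!is.finite(dose_nM) || dose_nM < 0) stop("dose_nM must be >= 0")
  if (duration_h <= 0) stop("duration_h must be > 0")
  y0 <- c(A_medium = dose_nM * 1000 * params$V_medium, A_exo = 0,
          A_cell_free = 0, A_tubulin = 0, A_ves = 0)
  times <- unique(c(seq(0, duration_h, by = dt_out), duration_h))
  sol <- deSolve::lsoda(y = y0, times = times, func = "qp_derivs",
                        dllname = "exoflux", initfunc = "qp_initmod",
                        parms = .rhs_parms(params, inhib$alpha, inhib$beta),
                        rtol = reltol, atol = abstol)
  if (attr(sol, "istate")[1] < 0)
    stop("PK integration failed at t = ", max(sol[, "time"]), " h")
  tc <- as.data.frame(sol)
  names(tc)[1] <- "time_h"
  # numerical negatives at the solver tolerance are clipped
  tc[.state_names] <- lapply(tc[.state_names], function(a) pmax(a, 0))
  V_cells <- params$N0 * params$v_cell
  tc$PTX_medium_free <- params$fu_medium * .conc_nM(tc$A_medium, params$V_medium)
  tc$PTX_exo <- .conc_nM(tc$A_exo, params$V_medium)
  tc$PTX_cell_free <- .conc_nM(tc$A_cell_free, V_cells)
  tc$PTX_tubulin <- .conc_nM(tc$A_tubulin, V_cells)
  tc$PTX_ves <- .conc_nM(tc$A_ves, V_cells)
  tc$PTX_donor_lysate <- tc$PTX_cell_free + tc$PTX_tubulin + tc$PTX_ves
  structure(tc,
            class = c("ptx_timecourse", "data.frame"),
            dose_nM = dose_nM, inhib = inhib, params = params)
}

#' @export
print.ptx_timecourse <- function(x, ...) {
  inhib <- attr(x, "inhib")
  cat(sprintf("PK time course: dose %.4g nM, %.4g h, arm %s (alpha %.2g, beta %.2g)\n",
              attr(x, "dose_nM"), max(x$time_h), inhib$label, inhib$alpha,
              inhib$beta))
  tail1 <- x[nrow(x), ]
  cat(sprintf("  at %.4g h: [PTX_exo] %.4g nM, [PTX_cell,free] %.4g nM, [PTX_tubulin] %.4g uM, [PTX_ves] %.4g uM\n",
              tail1$time_h, tail1$PTX_exo, tail1$PTX_cell_free,
              tail1$PTX_tubulin / 1000, tail1$PTX_ves / 1000))
  invisible(x)
}

#' Total cell-lysate drug concentration
#'
#' The experimentally measurable lysate concentration is the sum of the three
#' intracellular entities (free, tubulin-bound, vesicle-associated drug),
#' interpolated linearly on the solver grid.
#'
#' @param tc a `ptx_timecourse` from [simulate_pk()].
#' @param t time, h; must lie within the simulated range.
#' @return Lysate concentration, nM.
#' @export
lysate_concentration <- function(tc, t) {
  if (any(t < min(tc$time_h) - 1e-9) || any(t > max(tc$time_h) + 1e-9))
    stop("t outside the simulated time range")
  stats::approx(tc$time_h, tc$PTX_donor_lysate, xout = t, rule = 2)$y
}

#' Interpolate an entity concentration at arbitrary times
#'
#' @param tc a `ptx_timecourse`.
#' @param entity one of `"PTX_medium_free"`, `"PTX_exo"`, `"PTX_cell_free"`,
#'   `"PTX_tubulin"`, `"PTX_ves"`, `"PTX_donor_lysate"`.
#' @param t times, h, within the simulated range.
#' @return Concentrations, nM.
#' @export
entity_concentration <- function(tc, entity, t) {
  if (!entity %in% .entity_names)
    stop("unknown entity '", entity, "'; expected one of: ",
         paste(.entity_names, collapse = ", "))
  if (any(t < min(tc$time_h) - 1e-9) || any(t > max(tc$time_h) + 1e-9))
    stop("t outside the simulated time range")
  stats::approx(tc$time_h, tc[[entity]], xout = t, rule = 2)$y
}

#' Area under an entity concentration-time curve
#'
#' Trapezoidal integral of a named entity series on the solver grid.
#'
#' @inheritParams entity_concentration
#' @param t0,t1 integration limits, h, with `t0 < t1`, inside the grid.
#' @return AUC in nM h.
#' @export
auc <- function(tc, entity, t0 = 0, t1 = max(tc$time_h)) {
  if (!entity %in% .entity_names)
    stop("unknown entity '", entity, "'")
  if (t0 >= t1) stop("t0 must be < t1")
  if (t0 < min(tc$time_h) - 1e-9 || t1 > max(tc$time_h) + 1e-9)
    stop("integration limits outside the simulated range")
  tt <- tc$time_h
  yy <- tc[[entity]]
  keep <- tt > t0 & tt < t1
  tt2 <- c(t0, tt[keep], t1)
  yy2 <- c(stats::approx(tt, yy, t0)$y, yy[keep], stats::approx(tt, yy, t1)$y)
  sum(diff(tt2) * (utils::head(yy2, -1) + utils::tail(yy2, -1)) / 2)
}

#' Export a time course as a tidy table
#'
#' One row per (time, entity) with both the amount and the derived
#' concentration, plus the dose/arm metadata, ready for CSV export.
#'
#' @param tc a `ptx_timecourse`.
#' @param path optional CSV path; when given the table is also written.
#' @return A data frame with columns `time_h`, `entity`, `amount_pmol`,
#'   `conc`, `conc_unit`, `dose_nM`, `arm`, `alpha`, `beta`.
#' @export
timecourse_table <- function(tc, path = NULL) {
  p <- attr(tc, "params")
  inhib <- attr(tc, "inhib")
  V_cells <- p$N0 * p$v_cell
  amount_of <- list(
    PTX_medium_free = p$fu_medium * tc$A_medium,
    PTX_exo = tc$A_exo,
    PTX_cell_free = tc$A_cell_free,
    PTX_tubulin = tc$A_tubulin,
    PTX_ves = tc$A_ves,
    PTX_donor_lysate = tc$A_cell_free + tc$A_tubulin + tc$A_ves)
  out <- do.call(rbind, lapply(.entity_names, function(e)
    data.frame(time_h = tc$time_h, entity = e,
               amount_pmol = amount_of[[e]], conc = tc[[e]],
               conc_unit = "nM", dose_nM = attr(tc, "dose_nM"),
               arm = inhib$label, alpha = inhib$alpha, beta = inhib$beta)))
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
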