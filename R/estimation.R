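# Weighted least-squares estimation of the inhibition fractions alpha/beta.

#' Construct an observed PK/PD dataset
#'
#' Validates and classes a tidy table of observations. Each record is one
#' condition mean: an observable (`PTX_exo`, `PTX_donor_lysate`, both nM, or
#' `Cyto_donor`, percent), the medium dose (nM), the treatment time (h), the
#' arm (`PTX`, `OME+PTX`, `GW+PTX`), the mean `value`, its `sem` and the
#' number of replicates `n`, plus a `role` flag separating model-building
#' from validation data.
#'
#' @param data a data frame with columns `observable`, `dose_nM`, `time_h`,
#'   `arm`, `value`, `sem`, `n`, `role`.
#' @return The validated data frame with class `observed_dataset`.
#' @export
observed_dataset <- function(data) {
  req <- c("observable", "dose_nM", "time_h", "arm", "value", "sem", "n",
           "role")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(data$observable %in% c("PTX_exo", "PTX_donor_lysate", "Cyto_donor")))
    stop("unknown observable")
  if (!all(data$arm %in% c("PTX", "OME+PTX", "GW+PTX")))
    stop("arm must be one of PTX, OME+PTX, GW+PTX")
  if (any(data$sem < 0)) stop("sem must be >= 0")
  if (any(data$n < 1)) stop("n must be >= 1")
  if (!all(data$role %in% c("model_building", "validation")))
    stop("role must be model_building or validation")
  class(data) <- c("observed_dataset", "data.frame")
  data
}

#' Read/write observed datasets as CSV
#' @param path CSV file path.
#' @param data an `observed_dataset`.
#' @return `read_observed_dataset()` returns an `observed_dataset`.
#' @export
read_observed_dataset <- function(path) {
  observed_dataset(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_observed_dataset
#' @export
write_observed_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

# One compiled sparse-output solve: states (and cell count when pd is
# given) at exactly the requested times.
.solve_at <- function(params, dose, inhib, times, pd = NULL,
                      reltol = 1e-6, abstol = 1e-9) {
  y0 <- c(A_medium = dose * 1000 * params$V_medium, A_exo = 0,
          A_cell_free = 0, A_tubulin = 0, A_ves = 0)
  atol <- rep(abstol, 5)
  if (!is.null(pd)) { y0 <- c(y0, N = params$N0); atol <- c(atol, 1e-2) }
  sol <- deSolve::lsoda(y = y0, times = unique(c(0, times)),
                        func = "qp_derivs", dllname = "exoflux",
                        initfunc = "qp_initmod",
                        parms = .rhs_parms(params, inhib$alpha, inhib$beta,
                                           pd),
                        rtol = reltol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failed (dose ", dose, " nM, arm ", inhib$label, ")")
  sol[match(times, sol[, "time"]), , drop = FALSE]
}

# Model predictions for every record of a dataset under per-arm (alpha, beta).
# inhib_by_arm: named list, e.g. list(`OME+PTX` = inhibition_settings(...)).
# The PTX arm always runs uninhibited. One sparse-output solve per
# (arm, dose, observable kind), read at the record times.
predict_records <- function(records, params, pd, inhib_by_arm,
                            reltol = 1e-6, abstol = 1e-9) {
  inhib_of <- function(arm) {
    if (arm == "PTX") inhibition_settings(0, 0, "PTX")
    else if (!is.null(inhib_by_arm[[arm]])) inhib_by_arm[[arm]]
    else stop("no inhibition settings supplied for arm ", arm)
  }
  yhat <- numeric(nrow(records))
  V_cells <- params$N0 * params$v_cell
  pk_idx <- records$observable %in% c("PTX_exo", "PTX_donor_lysate")
  if (any(pk_idx)) {
    grp <- unique(records[pk_idx, c("arm", "dose_nM")])
    for (i in seq_len(nrow(grp))) {
      sel <- pk_idx & records$arm == grp$arm[i] &
        records$dose_nM == grp$dose_nM[i]
      tt <- sort(unique(records$time_h[sel]))
      sol <- .solve_at(params, grp$dose_nM[i], inhib_of(grp$arm[i]), tt,
                       reltol = reltol, abstol = abstol)
      exo <- sol[, "A_exo"] / (1000 * params$V_medium)
      lys <- (sol[, "A_cell_free"] + sol[, "A_tubulin"] + sol[, "A_ves"]) /
        (1000 * V_cells)
      for (j in which(sel)) {
        row <- match(records$time_h[j], tt)
        yhat[j] <- if (records$observable[j] == "PTX_exo") exo[row]
                   else lys[row]
      }
    }
  }
  pd_idx <- records$observable == "Cyto_donor"
  if (any(pd_idx)) {
    grp <- unique(records[pd_idx, c("arm", "dose_nM")])
    for (i in seq_len(nrow(grp))) {
      sel <- pd_idx & records$arm == grp$arm[i] &
        records$dose_nM == grp$dose_nM[i]
      if (grp$dose_nM[i] == 0) { yhat[sel] <- 0; next }
      tt <- sort(unique(records$time_h[sel]))
      sol <- .solve_at(params, grp$dose_nM[i], inhib_of(grp$arm[i]), tt,
                       pd = pd, reltol = reltol, abstol = abstol)
      cyto <- cytotoxicity_percent(sol[, "N"],
                                   params$N0 * exp(pd$k_g * sol[, "time"]))
      yhat[sel] <- cyto[match(records$time_h[sel], tt)]
    }
  }
  yhat
}

#' Weighted residual sum of squares for a candidate (alpha, beta) vector
#'
#' Objective of the inhibition fit: the model is simulated at every record's
#' (dose, time, arm) and the weighted squared residuals are summed.
#' Observables span three orders of magnitude across the PK and PD records,
#' so the default weighting is proportional-error, `w = 1/yhat^2`
#' (recomputed at the candidate), which makes each residual a relative
#' deviation; `1/sem^2` weighting is available when measured dispersions
#' should drive the fit.
#'
#' @param candidate named numeric vector of inhibition fractions. For a
#'   single inhibitor arm use `c(alpha = , beta = )`; for both arms use
#'   `c(alpha_OME = , beta_OME = , alpha_GW = , beta_GW = )`.
#' @param datasets an [observed_dataset()] (model-building records are used).
#' @param params a [model_parameters()] object.
#' @param pd a [pd_parameters()] object.
#' @param weighting `"proportional"` (default) or `"sem"`.
#' @return The weighted residual sum of squares (scalar).
#' @export
weighted_ssr <- function(candidate, datasets, params, pd,
                         weighting = c("proportional", "sem")) {
  r <- .weighted_residuals(candidate, datasets, params, pd,
                           match.arg(weighting))
  sum(r^2)
}

.candidate_inhib <- function(candidate) {
  nm <- names(candidate)
  if (all(c("alpha", "beta") %in% nm)) {
    list(`OME+PTX` = inhibition_settings(candidate[["alpha"]],
                                         candidate[["beta"]], "OME"),
         `GW+PTX` = inhibition_settings(candidate[["alpha"]],
                                        candidate[["beta"]], "GW"))
  } else {
    out <- list()
    if ("alpha_OME" %in% nm)
      out$`OME+PTX` <- inhibition_settings(candidate[["alpha_OME"]],
                                           candidate[["beta_OME"]], "OME")
    if ("alpha_GW" %in% nm)
      out$`GW+PTX` <- inhibition_settings(candidate[["alpha_GW"]],
                                          candidate[["beta_GW"]], "GW")
    if (!length(out)) stop("candidate must name alpha/beta parameters")
    out
  }
}

.weighted_residuals <- function(candidate, datasets, params, pd, weighting) {
  recs <- datasets[datasets$role == "model_building", , drop = FALSE]
  if (!nrow(recs)) stop("no model-building records")
  yhat <- predict_records(recs, params, pd, .candidate_inhib(candidate))
  if (weighting == "proportional") {
    denom <- pmax(abs(yhat), 1e-6)
    (recs$value - yhat) / denom
  } else {
    if (any(recs$sem <= 0)) stop("sem weighting requires positive sem")
    (recs$value - yhat) / recs$sem
  }
}

#' Fit the inhibition fractions by weighted least squares
#'
#' Estimates alpha (sorting inhibition) and beta (release inhibition) for
#' each inhibitor arm present in the model-building data, holding all other
#' model parameters fixed. The fractions are logit-transformed during
#' optimization to enforce the \[0, 1\] bounds, the weighted least-squares
#' problem is solved by Levenberg-Marquardt from multiple Latin-hypercube
#' starting points, and standard errors come from the Gauss-Newton
#' approximation (inverse weighted Jacobian cross-product) at the optimum,
#' propagated through the logit transform by the delta method.
#'
#' @inheritParams weighted_ssr
#' @param multistart number of Latin-hypercube starts (>= 1).
#' @param seed integer seed making the starts (and hence the fit)
#'   deterministic.
#' @param model which inhibition model to fit: `"full"` (alpha and beta per
#'   arm), or the nested reductions `"alpha_only"` / `"beta_only"` with the
#'   other fraction fixed at 0 (for BIC model selection).
#' @param reltol solver tolerance used inside the objective; the default
#'   resolves the smooth concentration and kill trajectories well below the
#'   measurement noise.
#' @return An object of class `ptx_fit`: list with `estimates`, `se`,
#'   `wrss`, `n_obs`, `n_params`, `bic`, `converged`, `starts`
#'   (per-start log), `seed`.
#' @export
fit_inhibition <- function(datasets, params, pd, multistart = 16,
                           seed = 1, weighting = c("proportional", "sem"),
                           model = c("full", "alpha_only", "beta_only"),
                           reltol = 1e-8) {
  weighting <- match.arg(weighting)
  model <- match.arg(model)
  if (multistart < 1) stop("multistart must be >= 1")
  recs <- datasets[datasets$role == "model_building", , drop = FALSE]
  arms <- intersect(c("OME+PTX", "GW+PTX"), unique(recs$arm))
  if (!length(arms)) stop("no inhibitor arm in the model-building data")
  free <- switch(model, full = c("alpha", "beta"), alpha_only = "alpha",
                 beta_only = "beta")
  suffix <- c(`OME+PTX` = "OME", `GW+PTX` = "GW")[arms]
  par_names <- as.vector(t(outer(free, suffix, paste, sep = "_")))
  k <- length(par_names)
  n_obs <- nrow(recs)
  if (n_obs <= k)
    stop("need more observations (", n_obs, ") than parameters (", k, ")")
  if (weighting == "sem" && any(recs$sem <= 0))
    stop("sem weighting requires positive sem")

  # the uninhibited arm never changes with the candidate: predict it once
  fixed_idx <- recs$arm == "PTX"
  yhat_fixed <- if (any(fixed_idx))
    predict_records(recs[fixed_idx, , drop = FALSE], params, pd, list(),
                    reltol = reltol)
  inhib_from <- function(cand) {
    out <- list()
    for (arm in arms) {
      sfx <- suffix[[arm]]
      a <- if (paste0("alpha_", sfx) %in% names(cand))
        cand[[paste0("alpha_", sfx)]] else 0
      b <- if (paste0("beta_", sfx) %in% names(cand))
        cand[[paste0("beta_", sfx)]] else 0
      out[[arm]] <- inhibition_settings(a, b, sfx)
    }
    out
  }
  # work on the logit scale; residuals as in weighted_ssr
  res_fn <- function(lpar) {
    cand <- stats::plogis(lpar)
    names(cand) <- par_names
    yhat <- numeric(n_obs)
    if (any(fixed_idx)) yhat[fixed_idx] <- yhat_fixed
    yhat[!fixed_idx] <- predict_records(recs[!fixed_idx, , drop = FALSE],
                                        params, pd, inhib_from(cand),
                                        reltol = reltol)
    if (weighting == "proportional")
      (recs$value - yhat) / pmax(abs(yhat), 1e-6)
    else (recs$value - yhat) / recs$sem
  }

  set.seed(seed)
  starts <- stats::qlogis(pmin(pmax(lhs::randomLHS(multistart, k), 0.02), 0.98))
  log <- vector("list", multistart)
  best <- NULL
  for (i in seq_len(multistart)) {
    # epsfcn sets the finite-difference step well above the ODE-solver
    # interpolation noise; with machine-epsilon steps the LM Jacobian is
    # dominated by that noise and the optimizer stalls
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(starts[i, ], fn = res_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100, epsfcn = 1e-6))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      log[[i]] <- list(start = stats::plogis(starts[i, ]), error = conditionMessage(fit))
      next
    }
    log[[i]] <- list(start = stats::plogis(starts[i, ]),
                     wrss = fit$deviance, info = fit$info)
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed; see per-start log")

  est <- stats::plogis(best$par)
  names(est) <- par_names
  # Gauss-Newton covariance on the logit scale from a central-difference
  # Jacobian with a step wide enough to average over solver-grid noise,
  # delta-method back-transform to the fraction scale
  h <- 0.05
  J <- matrix(0, n_obs, k)
  for (j in seq_len(k)) {
    up <- best$par; up[j] <- up[j] + h
    dn <- best$par; dn[j] <- dn[j] - h
    J[, j] <- (res_fn(up) - res_fn(dn)) / (2 * h)
  }
  sigma2 <- best$deviance / (n_obs - k)
  cov_l <- tryCatch(solve(crossprod(J)) * sigma2, error = function(e)
    matrix(NA_real_, k, k))
  grad <- est * (1 - est)  # d plogis / d x
  se <- sqrt(pmax(diag(cov_l), 0)) * grad
  names(se) <- par_names

  out <- list(estimates = est, se = se, wrss = best$deviance,
              n_obs = n_obs, n_params = k,
              bic = bic(best$deviance, n_obs, k),
              converged = best$info %in% 1:4,
              weighting = weighting, starts = log, seed = seed)
  class(out) <- "ptx_fit"
  out
}

#' @export
print.ptx_fit <- function(x, ...) {
  cat("Inhibition-fraction fit (weighted least squares,",
      x$weighting, "weights)\n")
  for (i in seq_along(x$estimates))
    cat(sprintf("  %-10s %.3f +/- %.3f\n", names(x$estimates)[i],
                x$estimates[i], x$se[i]))
  cat(sprintf("  weighted RSS %.4g on %d records (%d parameters), BIC %.2f\n",
              x$wrss, x$n_obs, x$n_params, x$bic))
  if (!x$converged) cat("  WARNING: best start did not converge cleanly\n")
  invisible(x)
}

#' Bayesian information criterion for a weighted least-squares fit
#'
#' `n_obs * log(wrss / n_obs) + n_params * log(n_obs)`, the Gaussian
#' profile-likelihood form used for model selection among nested inhibition
#' models.
#'
#' @param rss_weighted weighted residual sum of squares (> 0).
#' @param n_obs number of observations (> `n_params`).
#' @param n_params number of fitted parameters (>= 1).
#' @return The BIC value; `-Inf` with a warning when `rss_weighted` is 0.
#' @export
#' @examples
#' bic(10, 20, 2)  # 20*log(0.5) + 2*log(20)
bic <- function(rss_weighted, n_obs, n_params) {
  if (n_params < 1) stop("n_params must be >= 1")
  if (n_obs <= n_params) stop("n_obs must exceed n_params")
  if (rss_weighted < 0) stop("rss_weighted must be >= 0")
  if (rss_weighted == 0) {
    warning("zero residual sum of squares; BIC is -Inf")
    return(-Inf)
  }
  n_obs * log(rss_weighted / n_obs) + n_params * log(n_obs)
}

#' Validate a fitted model against held-out data
#'
#' Simulates every validation record at the fitted inhibition fractions and
#' reports the relative deviation `|simulated - observed| / observed`. The
#' summary passes when every retained record deviates by at most `tol`
#' (default 30%). Records whose observed value is zero are excluded with a
#' warning; records below `min_effect` (cytotoxicity too small for the assay
#' to resolve against control variability) are excluded from the gate; and a
#' record whose absolute deviation is within `sem_mult` standard errors of
#' the observed mean is accepted as agreeing within sampling noise.
#'
#' @param fit a `ptx_fit` from [fit_inhibition()].
#' @param validation an [observed_dataset()] with `role == "validation"`.
#' @inheritParams weighted_ssr
#' @param tol relative-deviation threshold (default 0.30).
#' @param min_effect smallest observed cytotoxicity (percent) entering the
#'   gate; smaller observations are reported but not gated.
#' @param sem_mult sampling-noise allowance in SEM multiples (0 disables).
#' @return A list of class `ptx_validation`: `records` (with `yhat`,
#'   `rel_dev`, `gated`, `ok`), `pass`, `max_dev`, `tol`.
#' @export
validate_against <- function(fit, validation, params, pd, tol = 0.30,
                             min_effect = 10, sem_mult = 2) {
  recs <- validation[validation$role == "validation", , drop = FALSE]
  if (!nrow(recs)) stop("no validation records")
  est <- fit$estimates
  inhib <- list()
  if ("alpha_OME" %in% names(est))
    inhib$`OME+PTX` <- inhibition_settings(est[["alpha_OME"]],
                                           est[["beta_OME"]], "OME")
  if ("alpha_GW" %in% names(est))
    inhib$`GW+PTX` <- inhibition_settings(est[["alpha_GW"]],
                                          est[["beta_GW"]], "GW")
  recs$yhat <- predict_records(recs, params, pd, inhib)
  zero <- recs$value == 0
  if (any(zero)) {
    warning(sum(zero), " record(s) with observed value 0 excluded")
  }
  recs$rel_dev <- ifelse(zero, NA_real_,
                         abs(recs$yhat - recs$value) / abs(recs$value))
  small <- recs$observable == "Cyto_donor" & abs(recs$value) < min_effect
  recs$gated <- !zero & !small
  within_sem <- sem_mult > 0 & recs$sem > 0 &
    abs(recs$yhat - recs$value) <= sem_mult * recs$sem
  recs$ok <- !recs$gated | recs$rel_dev <= tol | within_sem
  out <- list(records = recs,
              pass = all(recs$ok),
              max_dev = suppressWarnings(max(recs$rel_dev[recs$gated],
                                             na.rm = TRUE)),
              tol = tol)
  class(out) <- "ptx_validation"
  out
}

#' @export
print.ptx_validation <- function(x, ...) {
  n <- sum(x$records$gated)
  cat(sprintf("Hold-out validation: %d gated records, max relative deviation %.3g (tol %.2g) -> %s\n",
              n, x$max_dev, x$tol, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Serialize a fit result to a structured-text report
#'
#' @param fit a `ptx_fit`.
#' @param path destination file (YAML).
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  yaml::write_yaml(list(
    estimates = as.list(fit$estimates), se = as.list(fit$se),
    wrss = fit$wrss, n_obs = fit$n_obs, n_params = fit$n_params,
    bic = fit$bic, converged = fit$converged, weighting = fit$weighting,
    seed = fit$seed,
    starts = lapply(fit$starts, function(s)
      lapply(s, function(v) if (is.numeric(v)) as.list(round(v, 6)) else v))),
    path)
  invisible(path)
}
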