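# Curve-shift and uncertainty-envelope (UE) drug-interactivity analysis.
#
# The envelope construction follows the published decision rule (combination
# curve inside the band = additivity, left of it = synergy, right of it =
# antagonism) with a documented surrogate for the band itself: Loewe-additive
# unit summation plus a nonparametric bootstrap quantile band built from the
# single-agent concentration-effect data (means and dispersions).

#' Construct a cytotoxicity concentration-effect curve
#'
#' @param data data frame with columns `dose_nM`, `duration_h`, `arm`,
#'   `cytotoxicity_percent` and optionally `sem`, `n_replicates`.
#' @param provenance `"simulated"`, `"observed"` or `"synthetic"`.
#' @return The data frame with class `cytotoxicity_curve`.
#' @export
cytotoxicity_curve <- function(data, provenance = "simulated") {
  req <- c("dose_nM", "duration_h", "arm", "cytotoxicity_percent")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(data$cytotoxicity_percent > 100 + 1e-9))
    stop("cytotoxicity cannot exceed 100%")
  if (any(data$dose_nM < 0)) stop("doses must be >= 0")
  attr(data, "provenance") <- provenance
  class(data) <- c("cytotoxicity_curve", "data.frame")
  data
}

#' Fit a Hill concentration-effect function
#'
#' Least-squares fit of `E(C) = E_obs_max * C^h / (EC50^h + C^h)` to a
#' single-agent (or combination) cytotoxicity curve. Agents whose maximal
#' observed effect stays below `inactive_below` (default 5%) are handled by
#' the inactive-single-agent convention: `E_obs_max` is set to 1% and `EC50`
#' to 100 uM (1e5 nM) with unit slope, so that an inactive partner still has
#' defined concentration units in the envelope analysis.
#'
#' @param curve a [cytotoxicity_curve()] (one arm, one duration).
#' @param inactive_below effect ceiling (percent) triggering the
#'   inactive-agent convention.
#' @return An object of class `hill_fit`: `E_obs_max` (%), `EC50_hill`
#'   (dose units), `h`, `covariance` (3x3, NA for the convention),
#'   `inactive` flag.
#' @export
#' @examples
#' d <- data.frame(dose_nM = c(1, 3, 10, 30, 100), duration_h = 96,
#'                 arm = "PTX",
#'                 cytotoxicity_percent = 80 * c(1, 3, 10, 30, 100)^1.5 /
#'                   (10^1.5 + c(1, 3, 10, 30, 100)^1.5))
#' fit_hill(cytotoxicity_curve(d))
fit_hill <- function(curve, inactive_below = 5) {
  dat <- curve[curve$dose_nM > 0, , drop = FALSE]
  if (max(dat$cytotoxicity_percent) < inactive_below) {
    out <- list(E_obs_max = 1, EC50_hill = 1e5, h = 1,
                covariance = matrix(NA_real_, 3, 3), inactive = TRUE,
                data = dat)
    class(out) <- "hill_fit"
    return(out)
  }
  if (length(unique(dat$dose_nM)) < 4)
    stop("need >= 4 distinct positive doses")
  emax0 <- min(max(dat$cytotoxicity_percent) * 1.05, 100)
  ec0 <- stats::approx(dat$cytotoxicity_percent, dat$dose_nM,
                       xout = emax0 / 2, rule = 2, ties = mean)$y
  res_fn <- function(p) {
    emax <- p[1]; lec <- p[2]; h <- exp(p[3])
    pred <- emax * dat$dose_nM^h / (exp(lec)^h + dat$dose_nM^h)
    dat$cytotoxicity_percent - pred
  }
  fit <- minpack.lm::nls.lm(c(emax0, log(ec0), log(1)), fn = res_fn,
                            lower = c(1e-3, log(min(dat$dose_nM) / 100),
                                      log(0.05)),
                            upper = c(100, log(max(dat$dose_nM) * 100),
                                      log(20)),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$deviance / stats::var(dat$cytotoxicity_percent) /
      nrow(dat) > 0.9 && max(dat$cytotoxicity_percent) < inactive_below * 2)
    stop("flat/non-monotone data; consider the inactive-agent convention")
  p <- fit$par
  if (p[1] < inactive_below) {
    # the fitted maximum is below the activity floor: apply the convention
    out <- list(E_obs_max = 1, EC50_hill = 1e5, h = 1,
                covariance = matrix(NA_real_, 3, 3), inactive = TRUE,
                data = dat)
    class(out) <- "hill_fit"
    return(out)
  }
  sigma2 <- fit$deviance / max(nrow(dat) - 3, 1)
  cov_t <- tryCatch(solve(fit$hessian) * sigma2,
                    error = function(e) matrix(NA_real_, 3, 3))
  # delta method from (emax, log ec50, log h) to natural scale
  grad <- diag(c(1, exp(p[2]), exp(p[3])))
  covariance <- grad %*% cov_t %*% t(grad)
  out <- list(E_obs_max = p[1], EC50_hill = exp(p[2]), h = exp(p[3]),
              covariance = covariance, inactive = FALSE, data = dat)
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$inactive)
    cat("Hill fit: inactive agent (convention: E_obs_max = 1%, EC50 = 100 uM)\n")
  else
    cat(sprintf("Hill fit: E_obs_max %.3g%%, EC50 %.4g, slope %.3g\n",
                x$E_obs_max, x$EC50_hill, x$h))
  invisible(x)
}

#' Evaluate a fitted Hill curve
#' @param hill a `hill_fit`.
#' @param dose doses (same units as the fitted data).
#' @return Predicted effect, percent.
#' @export
hill_effect <- function(hill, dose) {
  hill$E_obs_max * dose^hill$h / (hill$EC50_hill^hill$h + dose^hill$h)
}

#' Concentration reaching a given absolute effect level
#'
#' Inverts the fitted Hill curve at an absolute effect level (default 5%
#' cytotoxicity, the EC_5% axis unit of the curve-shift plot). For an
#' inactive agent the level is unreachable and the conventional EC50
#' (100 uM) is returned as the unit.
#'
#' @param hill a `hill_fit`.
#' @param level_percent absolute effect level, percent.
#' @return Concentration in the fitted dose units.
#' @export
ec_level <- function(hill, level_percent = 5) {
  if (hill$inactive) return(hill$EC50_hill)
  if (level_percent >= hill$E_obs_max)
    stop("effect level ", level_percent, "% unreachable (E_obs_max = ",
         signif(hill$E_obs_max, 3), "%) and no inactive-agent convention")
  hill$EC50_hill * (level_percent / (hill$E_obs_max - level_percent))^(1 / hill$h)
}

#' Express doses in EC_5% units
#'
#' Divides doses by the concentration at which the fitted single-agent curve
#' reaches `level_percent` absolute effect, the normalization that puts
#' agents with very different potencies on one concentration axis.
#'
#' @param dose doses in the fitted units.
#' @inheritParams ec_level
#' @return Doses in EC units.
#' @export
#' @examples
#' # a dose equal to the EC_5% concentration is 1 unit by definition
to_ec_units <- function(dose, hill, level_percent = 5) {
  dose / ec_level(hill, level_percent)
}

# Loewe-additive total units to reach effect `e` along the fixed-partner
# design: agent 1 (varied) + agent 2 at fixed dose c2. The additive
# combination reaching e satisfies c1/EC_e1 + c2/EC_e2 = 1; inactive or
# out-of-range partners contribute no effect (EC_e2 = Inf) but still add
# their concentration in units. Returns NA where e is unreachable.
loewe_total_units <- function(e, hill1, hill2, c2, level_percent = 5) {
  u2 <- if (c2 > 0) to_ec_units(c2, hill2, level_percent) else 0
  sapply(e, function(ei) {
    if (!hill1$inactive && ei < hill1$E_obs_max) {
      ece1 <- hill1$EC50_hill *
        (ei / (hill1$E_obs_max - ei))^(1 / hill1$h)
    } else return(NA_real_)
    frac2 <- if (!hill2$inactive && ei < hill2$E_obs_max && c2 > 0) {
      ece2 <- hill2$EC50_hill * (ei / (hill2$E_obs_max - ei))^(1 / hill2$h)
      min(c2 / ece2, 1)
    } else 0
    c1 <- ece1 * (1 - frac2)
    to_ec_units(c1, hill1, level_percent) + u2
  })
}

#' Build the additivity uncertainty envelope
#'
#' For every effect level on a grid, the Loewe-additive total concentration
#' (in EC_5% units) needed by the combination of the single agents is
#' computed on bootstrap resamples of the single-agent data: each resample
#' perturbs the per-dose means by their standard errors, refits the Hill
#' curves, and recomputes the additive curve. The band is the pair of
#' `alpha_level/2` and `1 - alpha_level/2` quantiles across resamples; with
#' zero-variance input it collapses onto the additive curve.
#'
#' @param single_curves list of two [cytotoxicity_curve()] objects; the
#'   first is the varied agent (drug), the second the fixed-concentration
#'   partner (inhibitor).
#' @param partner_dose fixed partner concentration (same units as its
#'   curve).
#' @param n_boot number of bootstrap resamples (>= 200 recommended).
#' @param alpha_level significance level of the band (default 0.05).
#' @param seed integer seed; the band is deterministic given the seed.
#' @param effect_grid effect levels (percent) at which the band is
#'   evaluated; default 1% steps from 1 to 99.
#' @param level_percent EC unit level (default 5%).
#' @param include_combo_noise widen the band by the sampling noise of a
#'   combination curve measured with the same assay design, estimated by a
#'   second, independent resample of the varied single agent (default
#'   `TRUE`). Without it the band covers only the additive curve itself and
#'   systematically under-covers noisy combination curves.
#' @return An object of class `envelope_band`: data frame `band` with
#'   `effect`, `additive`, `lower`, `upper` (total units), plus the fitted
#'   single-agent `hill` fits and metadata.
#' @export
build_envelope <- function(single_curves, partner_dose, n_boot = 500,
                           alpha_level = 0.05, seed = 1,
                           effect_grid = seq(1, 99, by = 1),
                           level_percent = 5, include_combo_noise = TRUE) {
  if (length(single_curves) != 2) stop("need exactly two single-agent curves")
  if (n_boot < 2) stop("n_boot must be >= 2")
  h1 <- fit_hill(single_curves[[1]])
  h2 <- fit_hill(single_curves[[2]])
  central <- loewe_total_units(effect_grid, h1, h2, partner_dose,
                               level_percent)
  has_sem <- vapply(single_curves, function(cu)
    "sem" %in% names(cu) && all(is.finite(cu$sem)), logical(1))
  if (!all(has_sem))
    stop("envelope resampling requires 'sem' (and 'n_replicates') columns")
  set.seed(seed)
  resample_fit <- function(cu) {
    pert <- cu
    pert$cytotoxicity_percent <- pmin(
      cu$cytotoxicity_percent + stats::rnorm(nrow(cu), 0, cu$sem), 100)
    tryCatch(fit_hill(cytotoxicity_curve(pert, "synthetic")),
             error = function(e) NULL)
  }
  # central single-agent units, for the combination-noise term
  u1_central <- if (include_combo_noise)
    vapply(effect_grid, function(e) {
      if (h1$inactive || e >= h1$E_obs_max) return(NA_real_)
      to_ec_units(h1$EC50_hill * (e / (h1$E_obs_max - e))^(1 / h1$h), h1,
                  level_percent)
    }, numeric(1))
  boot <- matrix(NA_real_, n_boot, length(effect_grid))
  for (b in seq_len(n_boot)) {
    fits <- list(resample_fit(single_curves[[1]]),
                 resample_fit(single_curves[[2]]))
    if (any(vapply(fits, is.null, logical(1)))) next
    u <- loewe_total_units(effect_grid, fits[[1]], fits[[2]],
                           partner_dose, level_percent)
    if (include_combo_noise) {
      # a combination curve is measured with the same design and noise as
      # the varied single agent: inject that sampling error via an
      # independent resample
      f2 <- resample_fit(single_curves[[1]])
      if (is.null(f2)) next
      u2 <- vapply(effect_grid, function(e) {
        if (f2$inactive || e >= f2$E_obs_max) return(NA_real_)
        to_ec_units(f2$EC50_hill * (e / (f2$E_obs_max - e))^(1 / f2$h), h1,
                    level_percent)
      }, numeric(1))
      u <- u + (u2 - u1_central)
    }
    boot[b, ] <- u
  }
  qs <- apply(boot, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 2) c(NA_real_, NA_real_)
    else stats::quantile(col, c(alpha_level / 2, 1 - alpha_level / 2),
                         names = FALSE)
  })
  out <- list(band = data.frame(effect = effect_grid, additive = central,
                                lower = qs[1, ], upper = qs[2, ]),
              hill = list(h1, h2), partner_dose = partner_dose,
              alpha_level = alpha_level, level_percent = level_percent,
              n_boot = n_boot, seed = seed)
  class(out) <- "envelope_band"
  out
}

#' @export
print.envelope_band <- function(x, ...) {
  ok <- is.finite(x$band$lower)
  cat(sprintf("Uncertainty envelope: %d effect levels (%d defined), %d bootstrap resamples, %g%% band\n",
              nrow(x$band), sum(ok), x$n_boot, 100 * (1 - x$alpha_level)))
  invisible(x)
}

# Observed combination total units at each effect level: invert the fitted
# combination Hill curve (varied-agent dose) and add the fixed partner units.
combo_units_at <- function(e, combo_hill, partner_units, level_units) {
  sapply(e, function(ei) {
    if (combo_hill$inactive || ei >= combo_hill$E_obs_max) return(NA_real_)
    c1 <- combo_hill$EC50_hill *
      (ei / (combo_hill$E_obs_max - ei))^(1 / combo_hill$h)
    c1 / level_units + partner_units
  })
}

#' Classify a combination against the uncertainty envelope
#'
#' The observed combination concentration-effect curve is expressed in
#' summed EC_5% units and compared with the envelope at every effect level
#' where both are defined: left of the lower bound is synergy, right of the
#' upper bound antagonism, inside is additivity. The overall call is the
#' majority over levels; per-level calls are retained.
#'
#' @param combo a [cytotoxicity_curve()] of the combination arm (doses of
#'   the varied agent; the fixed partner dose is taken from the band).
#' @param band an `envelope_band` from [build_envelope()].
#' @return An object of class `interactivity_call`: `classification`
#'   (`"synergy"`, `"additivity"`, `"antagonism"` or `"indeterminate"`),
#'   `per_level` data frame, and the combination `hill` fit.
#' @export
classify <- function(combo, band) {
  ch <- fit_hill(combo)
  h1 <- band$hill[[1]]
  ec5_1 <- ec_level(h1, band$level_percent)
  partner_units <- if (band$partner_dose > 0)
    to_ec_units(band$partner_dose, band$hill[[2]], band$level_percent) else 0
  eff <- band$band$effect
  obs <- combo_units_at(eff, ch, partner_units, ec5_1)
  ok <- is.finite(obs) & is.finite(band$band$lower) &
    is.finite(band$band$upper)
  if (!any(ok)) {
    out <- list(classification = "indeterminate",
                per_level = data.frame(), hill = ch)
    class(out) <- "interactivity_call"
    return(out)
  }
  call_at <- ifelse(obs < band$band$lower, "synergy",
                    ifelse(obs > band$band$upper, "antagonism", "additivity"))
  per <- data.frame(effect = eff[ok], observed_units = obs[ok],
                    lower = band$band$lower[ok], upper = band$band$upper[ok],
                    call = call_at[ok])
  tab <- table(per$call)
  out <- list(classification = names(tab)[which.max(tab)],
              per_level = per, hill = ch)
  class(out) <- "interactivity_call"
  out
}

#' @export
print.interactivity_call <- function(x, ...) {
  cat("Interactivity call:", x$classification, "\n")
  if (nrow(x$per_level)) {
    tab <- table(x$per_level$call)
    cat("  per-level calls:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extent of drug interactivity (EI)
#'
#' EI is the ratio of the observed combination total concentration (in
#' summed EC_5% units) to the additivity-predicted total concentration at a
#' fixed effect level, by default 50% of the combination's maximal observed
#' effect. EI < 1 indicates synergy and `1/EI` is the fold-synergy; EI = 1
#' on a perfectly additive combination.
#'
#' @param combo a [cytotoxicity_curve()] of the combination.
#' @param band an `envelope_band` (supplies the single-agent fits and the
#'   additive curve).
#' @param effect_level effect level, percent; `NULL` (default) uses 50% of
#'   the combination `E_obs_max`.
#' @return A list of class `ei_result`: `EI`, `fold_interaction`,
#'   `effect_level`, `attainable`. When the combination does not reach the
#'   requested level, `attainable` is `FALSE` and `EI` is `NA` (the
#'   short-duration case in which 50% cytotoxicity is never observed).
#' @export
extent_of_interactivity <- function(combo, band, effect_level = NULL) {
  ch <- fit_hill(combo)
  if (is.null(effect_level)) effect_level <- ch$E_obs_max / 2
  if (ch$inactive || effect_level >= ch$E_obs_max) {
    out <- list(EI = NA_real_, fold_interaction = NA_real_,
                effect_level = effect_level, attainable = FALSE)
    class(out) <- "ei_result"
    return(out)
  }
  h1 <- band$hill[[1]]
  ec5_1 <- ec_level(h1, band$level_percent)
  partner_units <- if (band$partner_dose > 0)
    to_ec_units(band$partner_dose, band$hill[[2]], band$level_percent) else 0
  obs <- combo_units_at(effect_level, ch, partner_units, ec5_1)
  add <- loewe_total_units(effect_level, h1, band$hill[[2]],
                           band$partner_dose, band$level_percent)
  if (!is.finite(add) || !is.finite(obs)) {
    out <- list(EI = NA_real_, fold_interaction = NA_real_,
                effect_level = effect_level, attainable = FALSE)
    class(out) <- "ei_result"
    return(out)
  }
  out <- list(EI = obs / add, fold_interaction = add / obs,
              effect_level = effect_level, attainable = TRUE)
  class(out) <- "ei_result"
  out
}

#' @export
print.ei_result <- function(x, ...) {
  if (!x$attainable)
    cat(sprintf("EI not attainable at %.3g%% effect (combination does not reach it)\n",
                x$effect_level))
  else
    cat(sprintf("EI = %.3g at %.3g%% effect (%.2g-fold %s)\n", x$EI,
                x$effect_level, x$fold_interaction,
                if (x$EI < 1) "synergy" else "antagonism"))
  invisible(x)
}
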