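# Model-based simulation studies: dose sweeps, inhibition grids, exosomal
# AUC tables, entity-entity regressions.

.sweep_units <- c(PTX_ves = "uM", PTX_tubulin = "uM", PTX_donor_lysate = "uM",
                  PTX_cell_free = "nM", PTX_exo = "nM")
.sweep_entities <- names(.sweep_units)

.sweep_row <- function(tc, t, dose, inhib, provenance) {
  conc <- vapply(.sweep_entities, function(e)
    entity_concentration(tc, e, t), numeric(1))
  conc <- ifelse(.sweep_units[.sweep_entities] == "uM", conc / 1000, conc)
  data.frame(dose_nM = dose, alpha = inhib$alpha, beta = inhib$beta,
             arm = inhib$label, time_h = t, entity = .sweep_entities,
             concentration = unname(conc),
             unit = unname(.sweep_units[.sweep_entities]),
             parameter_provenance = provenance,
             row.names = NULL)
}

#' Concentration sweep of all drug entities over a dose grid
#'
#' Simulates the model across a (log-spaced) dose grid for each arm and
#' tabulates the five entity concentrations at the evaluation time: the
#' concentration-dependence study of the intracellular pools that cannot be
#' measured directly.
#'
#' @param params a [model_parameters()] object.
#' @param doses dose grid, nM; default 25 log-spaced points per decade over
#'   0.01-1000 nM.
#' @param arms named list of [inhibition_settings()] (default: no-inhibitor
#'   arm only).
#' @param t evaluation time, h (default 48).
#' @return A `sweep_table` data frame: one row per (dose, arm, entity) with
#'   columns `dose_nM`, `alpha`, `beta`, `arm`, `time_h`, `entity`,
#'   `concentration`, `unit` (uM for the vesicle/tubulin/lysate pools, nM
#'   for free cytosolic and exosomal drug).
#' @export
sweep_concentration <- function(params,
                                doses = 10^seq(-2, 3, by = 1 / 25),
                                arms = list(inhibition_settings(0, 0, "PTX")),
                                t = 48) {
  rows <- list()
  for (inhib in arms) {
    for (dose in doses) {
      tc <- simulate_pk(params, dose, t, inhib, reltol = 1e-8,
                        abstol = 1e-12, dt_out = 0.25)
      rows[[length(rows) + 1]] <- .sweep_row(tc, t, dose, inhib, params$provenance)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Inhibition-grid sweep at a fixed dose
#'
#' Varies the sorting-inhibition fraction alpha over a grid with beta = 0,
#' and the release-inhibition fraction beta with alpha = 0 (no, medium and
#' high inhibition by default), at a fixed dose and time: the perturbation
#' study contrasting inhibition of vesicle formation with inhibition of
#' exosome release.
#'
#' @inheritParams sweep_concentration
#' @param dose dose, nM (default 1000).
#' @param alpha_grid,beta_grid inhibition fractions (defaults 0, 0.5, 0.9).
#' @return A `sweep_table` as in [sweep_concentration()]; alpha rows carry
#'   `arm = "alpha_sweep"`, beta rows `arm = "beta_sweep"`, and the shared
#'   uninhibited baseline appears in both.
#' @export
sweep_inhibition <- function(params, dose = 1000, t = 48,
                             alpha_grid = c(0, 0.5, 0.9),
                             beta_grid = c(0, 0.5, 0.9)) {
  if (any(alpha_grid < 0 | alpha_grid > 1) ||
      any(beta_grid < 0 | beta_grid > 1))
    stop("grids must lie within [0, 1]")
  rows <- list()
  for (a in alpha_grid) {
    inhib <- inhibition_settings(a, 0, "alpha_sweep")
    tc <- simulate_pk(params, dose, t, inhib, reltol = 1e-8, abstol = 1e-10,
                      dt_out = 0.25)
    rows[[length(rows) + 1]] <- .sweep_row(tc, t, dose, inhib, params$provenance)
  }
  for (b in beta_grid) {
    inhib <- inhibition_settings(0, b, "beta_sweep")
    tc <- simulate_pk(params, dose, t, inhib, reltol = 1e-8, abstol = 1e-10,
                      dt_out = 0.25)
    rows[[length(rows) + 1]] <- .sweep_row(tc, t, dose, inhib, params$provenance)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Exosomal drug AUC table over a dose set
#'
#' Area under the exosomal drug concentration-time curve from 0 to `T_h`
#' for each dose, in nM h.
#'
#' @inheritParams sweep_concentration
#' @param doses doses, nM.
#' @param T_h upper integration limit, h.
#' @return Data frame with `dose_nM` and `auc_nM_h`.
#' @export
exo_auc_table <- function(params, doses = c(0.01, 0.1, 1, 10, 100, 1000),
                          T_h = 48) {
  auc_v <- vapply(doses, function(dose) {
    if (dose == 0) return(0)
    tc <- simulate_pk(params, dose, T_h, reltol = 1e-8, abstol = 1e-12,
                      dt_out = 0.1)
    auc(tc, "PTX_exo", 0, T_h)
  }, numeric(1))
  data.frame(dose_nM = doses, auc_nM_h = auc_v)
}

#' Regressions of exosomal drug on the intracellular entities
#'
#' Ordinary least squares of the exosomal drug concentration against each
#' intracellular entity across the doses of a sweep, per arm. The
#' tubulin-bound relationship is additionally checked for a biphasic shape:
#' a two-segment (broken-line) fit is compared with the single line and the
#' relationship is flagged biphasic when the segmented fit reduces the
#' residual sum of squares by more than `biphasic_gain`.
#'
#' @param sweep a `sweep_table` from [sweep_concentration()] containing the
#'   `PTX_exo` entity.
#' @param predictors intracellular entities to regress on.
#' @param biphasic_gain fractional RSS improvement declaring a biphasic fit.
#' @return Data frame with `arm`, `entity`, `slope`, `intercept`, `r2`,
#'   `biphasic`. A constant predictor yields `NA` r2.
#' @export
entity_regressions <- function(sweep,
                               predictors = c("PTX_ves", "PTX_cell_free",
                                              "PTX_tubulin",
                                              "PTX_donor_lysate"),
                               biphasic_gain = 0.2) {
  rows <- list()
  for (arm in unique(sweep$arm)) {
    sub <- sweep[sweep$arm == arm, ]
    wide <- stats::reshape(
      sub[, c("dose_nM", "entity", "concentration")],
      idvar = "dose_nM", timevar = "entity", direction = "wide")
    names(wide) <- sub("^concentration\\.", "", names(wide))
    if (nrow(wide) < 3) stop("need >= 3 doses per arm")
    y <- wide$PTX_exo
    for (ent in predictors) {
      x <- wide[[ent]]
      if (stats::sd(x) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          arm = arm, entity = ent, slope = NA_real_, intercept = NA_real_,
          r2 = NA_real_, biphasic = NA)
        next
      }
      fit <- stats::lm(y ~ x)
      r2 <- summary(fit)$r.squared
      rows[[length(rows) + 1]] <- data.frame(
        arm = arm, entity = ent, slope = stats::coef(fit)[2],
        intercept = stats::coef(fit)[1], r2 = r2,
        biphasic = .is_biphasic(x, y, sum(stats::resid(fit)^2),
                                biphasic_gain))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Two-segment least squares with breakpoint scanned over interior points;
# TRUE when the best segmented fit improves RSS by > gain relative to the
# single line.
.is_biphasic <- function(x, y, rss1, gain) {
  if (length(x) < 6 || rss1 <= 0) return(FALSE)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  best <- Inf
  for (k in 3:(length(x) - 3)) {
    brk <- x[k]
    z <- pmax(x - brk, 0)
    rss <- sum(stats::resid(stats::lm(y ~ x + z))^2)
    if (rss < best) best <- rss
  }
  (rss1 - best) / rss1 > gain
}

#' Export a sweep table to CSV
#' @param sweep a `sweep_table`.
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE)
  invisible(path)
}
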