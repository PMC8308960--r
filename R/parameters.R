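#' Cellular pharmacokinetic model parameters
#'
#' Container for every rate constant, capacity and compartment-geometry value
#' of the cellular PK model of exosome-mediated drug efflux. Amounts are
#' carried internally in pmol and concentrations in nM (1 nM = 1000 pmol/L);
#' rate constants are per hour.
#'
#' The default values are the calibrated MCF7 set shipped with the package
#' (provenance flag `"calibrated"`): passive diffusion and tubulin-binding
#' kinetics at literature magnitudes, and the sorting/release/re-uptake
#' constants calibrated (see `scripts/calibrate.R`) so that the untreated
#' baseline at 1000 nM medium drug, 48 h reproduces the reference subcellular
#' distribution (vesicle pool 46 uM, free cytosolic drug 139 nM, exosomal
#' drug 21 nM). MCF7 cells express little P-glycoprotein, so `Jmax_pgp = 0`
#' by default.
#'
#' @param D_fd passive-diffusion rate constant across the cell membrane, 1/h,
#'   applied to the medium-to-cell free-drug concentration gradient scaled by
#'   total cell volume.
#' @param Jmax_pgp maximum P-glycoprotein-mediated efflux rate, pmol/h per
#'   1e6 cells. Zero for MCF7.
#' @param Kd_pgp P-glycoprotein dissociation constant, nM.
#' @param k_tubulin_on drug-tubulin association rate constant, 1/(nM h).
#' @param k_tubulin_off drug-tubulin dissociation rate constant, 1/h.
#' @param B_tubulin_max maximum tubulin binding capacity, nM (intracellular).
#' @param k_formation_free first-order sorting rate of free intracellular drug
#'   into pre-exosome vesicles, 1/h.
#' @param k_formation_tubulin first-order sorting rate of tubulin-bound drug
#'   into pre-exosome vesicles, 1/h.
#' @param k_release first-order exosome release rate constant, 1/h.
#' @param Jmax_inter_exo maximum receptor-mediated exosome re-internalization
#'   rate, pmol/h per 1e6 cells.
#' @param Kd_inter_exo half-saturation constant of exosome re-internalization,
#'   nM (exosomal drug concentration in medium).
#' @param fu_medium unbound fraction of non-exosomal drug in medium, in (0, 1].
#' @param V_medium medium volume, L.
#' @param v_cell single-cell volume, L.
#' @param N0 initial cell count.
#' @param reuptake_to compartment receiving re-internalized exosomal drug:
#'   `"cytosol"` (default; endocytosed cargo is returned to the free
#'   intracellular pool) or `"vesicle"`.
#' @param alpha_targets which sorting routes the sorting-inhibition fraction
#'   alpha acts on: `"both"` (default) or `"free"` only.
#' @param provenance provenance label for the numeric values:
#'   `"calibrated"` (the shipped set) or `"published"` for values
#'   transcribed from a published table.
#'
#' @return An object of class `model_parameters` (a named list).
#' @seealso [pd_parameters()], [inhibition_settings()], [simulate_pk()]
#' @export
#' @examples
#' p <- model_parameters()
#' p$Jmax_pgp  # 0 for MCF7
model_parameters <- function(D_fd = 5000,
                             Jmax_pgp = 0,
                             Kd_pgp = 1000,
                             k_tubulin_on = 0.12406,
                             k_tubulin_off = 0.6203,
                             B_tubulin_max = 30010,
                             k_formation_free = 271.3,
                             k_formation_tubulin = 0.3056,
                             k_release = 0.9811,
                             Jmax_inter_exo = 266.5,
                             Kd_inter_exo = 38.23,
                             fu_medium = 0.1568,
                             V_medium = 2e-3,
                             v_cell = 2e-12,
                             N0 = 1e6,
                             reuptake_to = c("cytosol", "vesicle"),
                             alpha_targets = c("both", "free"),
                             provenance = "calibrated") {
  p <- list(D_fd = D_fd, Jmax_pgp = Jmax_pgp, Kd_pgp = Kd_pgp,
            k_tubulin_on = k_tubulin_on, k_tubulin_off = k_tubulin_off,
            B_tubulin_max = B_tubulin_max,
            k_formation_free = k_formation_free,
            k_formation_tubulin = k_formation_tubulin,
            k_release = k_release,
            Jmax_inter_exo = Jmax_inter_exo, Kd_inter_exo = Kd_inter_exo,
            fu_medium = fu_medium, V_medium = V_medium, v_cell = v_cell,
            N0 = N0,
            reuptake_to = match.arg(reuptake_to),
            alpha_targets = match.arg(alpha_targets),
            provenance = provenance)
  class(p) <- "model_parameters"
  validate_model_parameters(p)
  p
}

validate_model_parameters <- function(p) {
  num <- c("D_fd", "Jmax_pgp", "Kd_pgp", "k_tubulin_on", "k_tubulin_off",
           "B_tubulin_max", "k_formation_free", "k_formation_tubulin",
           "k_release", "Jmax_inter_exo", "Kd_inter_exo", "fu_medium",
           "V_medium", "v_cell", "N0")
  vals <- unlist(p[num])
  if (any(!is.finite(vals)))
    stop("non-finite model parameter: ",
         paste(num[!is.finite(vals)], collapse = ", "))
  if (any(vals < 0))
    stop("negative model parameter: ", paste(num[vals < 0], collapse = ", "))
  if (p$fu_medium <= 0 || p$fu_medium > 1)
    stop("fu_medium must be in (0, 1]")
  if (p$N0 <= 0) stop("N0 must be positive")
  if (p$V_medium <= 0 || p$v_cell <= 0) stop("volumes must be positive")
  invisible(p)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Cellular PK model parameters (", x$provenance, ")\n", sep = "")
  cat(sprintf("  diffusion D_fd = %.4g /h, fu_medium = %.3g\n",
              x$D_fd, x$fu_medium))
  cat(sprintf("  Pgp: Jmax = %.4g pmol/h/1e6 cells (Kd = %.4g nM)\n",
              x$Jmax_pgp, x$Kd_pgp))
  cat(sprintf("  tubulin: k_on = %.4g /(nM h), k_off = %.4g /h, Bmax = %.4g nM\n",
              x$k_tubulin_on, x$k_tubulin_off, x$B_tubulin_max))
  cat(sprintf("  sorting: k_formation_free = %.4g /h, k_formation_tubulin = %.4g /h (alpha on %s)\n",
              x$k_formation_free, x$k_formation_tubulin, x$alpha_targets))
  cat(sprintf("  release k_release = %.4g /h; re-uptake Jmax = %.4g (Kd = %.4g nM) -> %s\n",
              x$k_release, x$Jmax_inter_exo, x$Kd_inter_exo, x$reuptake_to))
  cat(sprintf("  geometry: V_medium = %.3g L, v_cell = %.3g L, N0 = %.3g cells\n",
              x$V_medium, x$v_cell, x$N0))
  invisible(x)
}

#' Pharmacodynamic (growth/kill) model parameters
#'
#' Parameters of the donor-cell growth and drug-induced kill model. The kill
#' rate is a Hill function of the tubulin-bound drug concentration with a
#' time-varying EC50; drug potency increases with exposure time
#' (`gamma_EC50 > 0` shrinks the EC50).
#'
#' @param k_kill maximal kill rate constant, 1/h.
#' @param EC50_initial tubulin-bound drug concentration giving half-maximal
#'   kill at time zero, nM.
#' @param gamma_EC50 rate of EC50 change per unit time, 1/h.
#' @param n_hill Hill exponent of the kill function, dimensionless.
#' @param k_g exponential cell growth rate constant, 1/h.
#' @param ec50_form functional form of EC50(t): `"exponential"` (default,
#'   `EC50_initial * exp(-gamma_EC50 * t)`, always positive) or `"linear"`
#'   (`EC50_initial - gamma_EC50 * t`, floored at `ec50_floor`).
#' @param ec50_floor positive floor applied under the linear form, nM.
#'
#' @return An object of class `pd_parameters`.
#' @export
#' @examples
#' pd_parameters(gamma_EC50 = 0)$EC50_initial
pd_parameters <- function(k_kill = 0.045,
                          EC50_initial = 60000,
                          gamma_EC50 = 0.018,
                          n_hill = 1.5,
                          k_g = 0.02,
                          ec50_form = c("exponential", "linear"),
                          ec50_floor = 1) {
  pd <- list(k_kill = k_kill, EC50_initial = EC50_initial,
             gamma_EC50 = gamma_EC50, n_hill = n_hill, k_g = k_g,
             ec50_form = match.arg(ec50_form), ec50_floor = ec50_floor)
  class(pd) <- "pd_parameters"
  validate_pd_parameters(pd)
  pd
}

validate_pd_parameters <- function(pd) {
  num <- c("k_kill", "EC50_initial", "gamma_EC50", "n_hill", "k_g",
           "ec50_floor")
  vals <- unlist(pd[num])
  if (any(!is.finite(vals))) stop("non-finite PD parameter")
  if (pd$k_kill < 0 || pd$EC50_initial <= 0 || pd$k_g < 0)
    stop("k_kill, k_g must be >= 0 and EC50_initial > 0")
  if (pd$n_hill <= 0) stop("n_hill must be > 0")
  if (pd$ec50_floor <= 0) stop("ec50_floor must be > 0")
  invisible(pd)
}

#' @export
print.pd_parameters <- function(x, ...) {
  cat("PD (growth/kill) parameters\n")
  cat(sprintf("  k_kill = %.4g /h, EC50(0) = %.4g nM (%s decline, gamma = %.4g /h)\n",
              x$k_kill, x$EC50_initial, x$ec50_form, x$gamma_EC50))
  cat(sprintf("  Hill n = %.3g, growth k_g = %.4g /h\n", x$n_hill, x$k_g))
  invisible(x)
}

#' Inhibition settings for exosome sorting and release
#'
#' The two perturbation handles of the model: `alpha` is the fractional
#' inhibition of sorting drug into pre-exosome vesicles and `beta` the
#' fractional inhibition of release of drug-loaded exosomes. Both are
#' fractions in \[0, 1\]; 0 means no inhibition and 1 a complete block.
#'
#' @param alpha sorting-inhibition fraction in \[0, 1\].
#' @param beta release-inhibition fraction in \[0, 1\].
#' @param label arm name (e.g. `"none"`, `"OME"`, `"GW"`).
#' @return An object of class `inhibition_settings`.
#' @export
#' @examples
#' inhibition_settings(0.61, 0.38, "OME")
inhibition_settings <- function(alpha = 0, beta = 0, label = "none") {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be in [0, 1]")
  if (!is.finite(beta) || beta < 0 || beta > 1)
    stop("beta must be in [0, 1]")
  structure(list(alpha = alpha, beta = beta, label = as.character(label)),
            class = "inhibition_settings")
}

#' @export
print.inhibition_settings <- function(x, ...) {
  cat(sprintf("Inhibition [%s]: alpha = %.3g (sorting), beta = %.3g (release)\n",
              x$label, x$alpha, x$beta))
  invisible(x)
}

#' Read and write parameter configuration files
#'
#' Parameter sets round-trip through a structured-text (YAML) config in which
#' each entry is the parameter symbol mapped to `value` and `unit`. Unknown
#' keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path file path of the YAML configuration.
#' @param params a `model_parameters` object (for writing).
#' @param pd an optional `pd_parameters` object stored under `pd:`.
#' @return `read_parameter_config()` returns a list with elements `params`
#'   and (when present in the file) `pd`; `write_parameter_config()` returns
#'   `path` invisibly.
#' @examples
#' cfg <- read_parameter_config(system.file("extdata", "mcf7_calibrated.yaml",
#'                                          package = "exoflux"))
#' cfg$params$provenance
#' @export
write_parameter_config <- function(params, path, pd = NULL) {
  units <- .parameter_units()
  num <- intersect(names(units), names(params))
  cfg <- list(model = lapply(num, function(k)
    list(value = params[[k]], unit = units[[k]])))
  names(cfg$model) <- num
  cfg$model$reuptake_to <- params$reuptake_to
  cfg$model$alpha_targets <- params$alpha_targets
  cfg$model$provenance <- params$provenance
  if (!is.null(pd)) {
    pdu <- .pd_units()
    pk <- intersect(names(pdu), names(pd))
    cfg$pd <- lapply(pk, function(k) list(value = pd[[k]], unit = pdu[[k]]))
    names(cfg$pd) <- pk
    cfg$pd$ec50_form <- pd$ec50_form
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_parameter_config
#' @export
read_parameter_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model)) stop("config has no 'model' section")
  take <- function(section, extra_chr) {
    vals <- list()
    for (k in names(section)) {
      if (k %in% extra_chr) vals[[k]] <- section[[k]]
      else vals[[k]] <- section[[k]]$value
    }
    vals
  }
  margs <- take(cfg$model, c("reuptake_to", "alpha_targets", "provenance"))
  unknown <- setdiff(names(margs), names(formals(model_parameters)))
  if (length(unknown))
    stop("unknown model parameter in config: ", paste(unknown, collapse = ", "))
  out <- list(params = do.call(model_parameters, margs))
  if (!is.null(cfg$pd)) {
    pargs <- take(cfg$pd, "ec50_form")
    unknown <- setdiff(names(pargs), names(formals(pd_parameters)))
    if (length(unknown))
      stop("unknown pd parameter in config: ", paste(unknown, collapse = ", "))
    out$pd <- do.call(pd_parameters, pargs)
  }
  out
}

.parameter_units <- function() {
  list(D_fd = "1/h", Jmax_pgp = "pmol/h per 1e6 cells", Kd_pgp = "nM",
       k_tubulin_on = "1/(nM h)", k_tubulin_off = "1/h",
       B_tubulin_max = "nM", k_formation_free = "1/h",
       k_formation_tubulin = "1/h", k_release = "1/h",
       Jmax_inter_exo = "pmol/h per 1e6 cells", Kd_inter_exo = "nM",
       fu_medium = "fraction", V_medium = "L", v_cell = "L", N0 = "cells")
}

.pd_units <- function() {
  list(k_kill = "1/h", EC50_initial = "nM", gamma_EC50 = "1/h",
       n_hill = "dimensionless", k_g = "1/h", ec50_floor = "nM")
}
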