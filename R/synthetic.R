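# Seeded synthetic-data generators emulating the study design, so the
# estimation and interactivity stages are testable without laboratory data.

#' The default study design
#'
#' PK sampling at 300 and 1000 nM medium drug, 8 and 24 h; donor-cell
#' cytotoxicity over a log-spaced 0.1-1000 nM dose grid at 12, 24, 48, 72
#' and 96 h; arms without and with each exosome inhibitor; replicated as in
#' the reference assays (PK: 3 experiments with triplicates; cytotoxicity:
#' 4 experiments with duplicates). Model-building data are the PK records
#' plus the 12/48 h cytotoxicity; the remaining durations are held out for
#' validation.
#'
#' @param pk_doses PK doses, nM.
#' @param pk_times PK sampling times, h.
#' @param pd_doses cytotoxicity dose grid, nM.
#' @param pd_times cytotoxicity durations, h.
#' @param building_times durations assigned to the model-building role.
#' @param arms treatment arms.
#' @param pk_experiments,pk_replicates PK assay replication: independent
#'   experiments and technical replicates per experiment (3 x 3, as in the
#'   drug-level tables).
#' @param pd_experiments,pd_replicates cytotoxicity assay replication
#'   (4 experiments x duplicates, as in the dose-response figures).
#' @return A list of class `study_design`.
#' @export
study_design <- function(pk_doses = c(300, 1000),
                         pk_times = c(8, 24),
                         pd_doses = c(0.1, 0.5, 1, 5, 10, 50, 100, 300, 1000),
                         pd_times = c(12, 24, 48, 72, 96),
                         building_times = c(12, 48),
                         arms = c("PTX", "OME+PTX", "GW+PTX"),
                         pk_experiments = 3, pk_replicates = 3,
                         pd_experiments = 4, pd_replicates = 2) {
  if (any(pk_doses <= 0) || any(pd_doses <= 0)) stop("doses must be > 0")
  if (any(pk_times <= 0) || any(pd_times <= 0)) stop("times must be > 0")
  if (min(pk_experiments, pk_replicates, pd_experiments, pd_replicates) < 1)
    stop("replicates must be >= 1")
  out <- list(pk_doses = pk_doses, pk_times = pk_times, pd_doses = pd_doses,
              pd_times = pd_times, building_times = building_times,
              arms = arms, pk_experiments = pk_experiments,
              pk_replicates = pk_replicates, pd_experiments = pd_experiments,
              pd_replicates = pd_replicates)
  class(out) <- "study_design"
  out
}

#' Measurement noise model
#'
#' Multiplicative (lognormal or truncated-normal) noise for concentration
#' observables; the coefficient of variation applies per replicate.
#'
#' @param cv coefficient of variation (>= 0).
#' @param distribution `"lognormal"` (default) or `"truncated-normal"`.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(cv = 0.15, distribution = c("lognormal",
                                                    "truncated-normal")) {
  if (cv < 0) stop("cv must be >= 0")
  structure(list(cv = cv, distribution = match.arg(distribution)),
            class = "noise_model")
}

# n multiplicative noise factors with unit mean and the requested CV
.noise_factors <- function(n, noise) {
  if (noise$cv == 0) return(rep(1, n))
  if (noise$distribution == "lognormal") {
    sdlog <- sqrt(log(1 + noise$cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    f <- stats::rnorm(n, 1, noise$cv)
    pmax(f, 0)
  }
}

#' Default true inhibition settings per arm
#'
#' The fitted point estimates of the reference analysis, used as the truth
#' of the synthetic study: OME inhibits sorting by 0.61 and release by 0.38;
#' GW inhibits sorting by 0.33 and release by 0.47.
#' @return Named list of [inhibition_settings()].
#' @export
default_true_inhibition <- function() {
  list(`PTX` = inhibition_settings(0, 0, "PTX"),
       `OME+PTX` = inhibition_settings(0.61, 0.38, "OME"),
       `GW+PTX` = inhibition_settings(0.33, 0.47, "GW"))
}

#' Generate a synthetic PK dataset
#'
#' Simulates exosomal and cell-lysate drug concentrations for every
#' (dose, time, arm) of the design, draws noisy replicates
#' (experiments x duplicates) around the model prediction, and records the
#' replicate mean, SEM and count per condition, in the same layout as the
#' laboratory LC-MS/MS measurements. All records carry the
#' `model_building` role.
#'
#' @param params a [model_parameters()] object.
#' @param true_inhib named list of [inhibition_settings()] per arm.
#' @param design a [study_design()].
#' @param noise a [noise_model()].
#' @param seed integer seed; generation is a pure function of
#'   (inputs, seed).
#' @return An [observed_dataset()] with observables `PTX_exo` and
#'   `PTX_donor_lysate`.
#' @export
generate_pk_dataset <- function(params, true_inhib = default_true_inhibition(),
                                design = study_design(),
                                noise = noise_model(), seed = 1) {
  set.seed(seed)
  n_rep <- design$pk_experiments * design$pk_replicates
  rows <- list()
  for (arm in design$arms) {
    inhib <- true_inhib[[arm]]
    if (is.null(inhib)) stop("no true inhibition for arm ", arm)
    for (dose in design$pk_doses) {
      tc <- simulate_pk(params, dose, max(design$pk_times), inhib,
                        reltol = 1e-8, abstol = 1e-10, dt_out = 0.25)
      for (tt in design$pk_times) {
        for (obs in c("PTX_exo", "PTX_donor_lysate")) {
          truth <- entity_concentration(tc, obs, tt)
          reps <- truth * .noise_factors(n_rep, noise)
          rows[[length(rows) + 1]] <- data.frame(
            observable = obs, dose_nM = dose, time_h = tt, arm = arm,
            value = mean(reps),
            sem = stats::sd(reps) / sqrt(n_rep), n = n_rep,
            role = "model_building")
        }
      }
    }
  }
  observed_dataset(do.call(rbind, rows))
}

#' Generate a synthetic cytotoxicity (PD) dataset
#'
#' Simulates donor-cell cytotoxicity for every (dose, duration, arm), adds
#' additive Gaussian noise on the percent scale (truncated at 100%) per
#' replicate, and splits the records into model-building (the design's
#' `building_times`) and validation (all other durations) roles.
#'
#' @inheritParams generate_pk_dataset
#' @param pd a [pd_parameters()] object.
#' @param sd_percent additive noise standard deviation, percentage points.
#' @return A list: `dataset` (an [observed_dataset()] of `Cyto_donor`
#'   records) and `curves` (a [cytotoxicity_curve()] of the same means, for
#'   the interactivity analysis).
#' @export
generate_pd_dataset <- function(params, pd,
                                true_inhib = default_true_inhibition(),
                                design = study_design(), sd_percent = 5,
                                seed = 1) {
  set.seed(seed + 1)
  n_rep <- design$pd_experiments * design$pd_replicates
  rows <- list()
  for (arm in design$arms) {
    inhib <- true_inhib[[arm]]
    if (is.null(inhib)) stop("no true inhibition for arm ", arm)
    for (dose in design$pd_doses) {
      sim <- simulate_pkpd(params, pd, dose, max(design$pd_times), inhib,
                           reltol = 1e-8, abstol = 1e-10, dt_out = 0.25)
      cy <- stats::approxfun(sim$pd$time_h, sim$pd$cytotoxicity_percent,
                             rule = 2)
      for (tt in design$pd_times) {
        truth <- cy(tt)
        reps <- pmin(truth + stats::rnorm(n_rep, 0, sd_percent), 100)
        rows[[length(rows) + 1]] <- data.frame(
          observable = "Cyto_donor", dose_nM = dose, time_h = tt, arm = arm,
          value = mean(reps), sem = stats::sd(reps) / sqrt(n_rep), n = n_rep,
          role = if (tt %in% design$building_times) "model_building"
                 else "validation")
      }
    }
  }
  ds <- observed_dataset(do.call(rbind, rows))
  curves <- cytotoxicity_curve(
    data.frame(dose_nM = ds$dose_nM, duration_h = ds$time_h, arm = ds$arm,
               cytotoxicity_percent = ds$value, sem = ds$sem,
               n_replicates = ds$n),
    provenance = "synthetic")
  list(dataset = ds, curves = curves)
}

#' Generate a Loewe-additive combination curve
#'
#' The additivity null for envelope validation: combination effects are
#' computed under exact Loewe additivity from the fitted single-agent Hill
#' curves (varied agent + fixed partner), then noised. With zero noise and a
#' zero partner dose the single-agent curve is reproduced and the EI of the
#' output is exactly 1.
#'
#' @param single_hills list of two `hill_fit` objects (varied agent,
#'   partner).
#' @param doses varied-agent doses, nM.
#' @param partner_dose fixed partner concentration.
#' @param duration_h duration label for the output curve.
#' @param sd_percent additive noise SD, percentage points.
#' @param n_rep replicates per dose.
#' @param seed integer seed.
#' @return A [cytotoxicity_curve()] with `sem` and `n_replicates`.
#' @export
generate_additive_combo <- function(single_hills, doses, partner_dose,
                                    duration_h = 96, sd_percent = 0,
                                    n_rep = 6, seed = 1) {
  set.seed(seed + 2)
  h1 <- single_hills[[1]]; h2 <- single_hills[[2]]
  eff <- vapply(doses, function(d)
    .loewe_effect(d, partner_dose, h1, h2), numeric(1))
  rows <- lapply(seq_along(doses), function(i) {
    reps <- pmin(eff[i] + stats::rnorm(n_rep, 0, sd_percent), 100)
    data.frame(dose_nM = doses[i], duration_h = duration_h, arm = "combo",
               cytotoxicity_percent = mean(reps),
               sem = if (sd_percent > 0) stats::sd(reps) / sqrt(n_rep) else 0,
               n_replicates = n_rep)
  })
  cytotoxicity_curve(do.call(rbind, rows), provenance = "synthetic")
}

# Effect of the Loewe-additive combination (c1 varied agent, c2 partner):
# the effect e solving c1/EC_e1 + c2/EC_e2 = 1. Monotone in e, solved by
# bisection; capped below the smaller of the reachable maxima.
.loewe_effect <- function(c1, c2, h1, h2) {
  if (c1 <= 0 && c2 <= 0) return(0)
  index <- function(e) {
    s <- 0
    if (!h1$inactive && e < h1$E_obs_max && c1 > 0)
      s <- s + c1 / (h1$EC50_hill * (e / (h1$E_obs_max - e))^(1 / h1$h))
    if (!h2$inactive && e < h2$E_obs_max && c2 > 0)
      s <- s + c2 / (h2$EC50_hill * (e / (h2$E_obs_max - e))^(1 / h2$h))
    s
  }
  emax <- max(if (!h1$inactive) h1$E_obs_max else 0,
              if (!h2$inactive) h2$E_obs_max else 0)
  if (emax <= 0) return(0)
  lo <- 1e-9; hi <- emax * (1 - 1e-9)
  if (index(hi) > 1) return(hi)  # beyond the curve: cap at the maximum
  if (index(lo) < 1) return(0)   # below any measurable effect
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (index(mid) >= 1) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Write a synthetic-study manifest
#'
#' Records the seed, design, noise and true parameters of a generated
#' dataset so any synthetic study is reproducible from its manifest.
#'
#' @param path YAML destination.
#' @param seed integer seed used.
#' @param design a [study_design()].
#' @param noise a [noise_model()] (or NULL).
#' @param true_inhib named list of [inhibition_settings()].
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, design, noise = NULL,
                           true_inhib = default_true_inhibition()) {
  yaml::write_yaml(list(
    seed = seed,
    design = unclass(design),
    noise = if (!is.null(noise)) unclass(noise),
    true_inhibition = lapply(true_inhib, function(x)
      list(alpha = x$alpha, beta = x$beta, label = x$label))), path)
  invisible(path)
}
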