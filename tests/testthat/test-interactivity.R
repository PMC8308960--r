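test_that("exact Hill data are recovered to high precision", {
  cu <- hill_curve(emax = 80, ec50 = 10, h = 1.5)
  fit <- fit_hill(cu)
  expect_equal(fit$E_obs_max, 80, tolerance = 1e-6)
  expect_equal(fit$EC50_hill, 10, tolerance = 1e-6)
  expect_equal(fit$h, 1.5, tolerance = 1e-6)
  expect_error(fit_hill(hill_curve(doses = c(1, 10, 100))), ">= 4")
})

test_that("inactive single agents take the stated convention", {
  flat <- cytotoxicity_curve(data.frame(
    dose_nM = c(3, 9, 29, 90, 300) * 1000, duration_h = 96, arm = "OME",
    cytotoxicity_percent = c(0.5, 1.2, 0.8, 1.5, 2.1), sem = 0.5,
    n_replicates = 8), "synthetic")
  fit <- fit_hill(flat)
  expect_true(fit$inactive)
  expect_equal(fit$E_obs_max, 1)
  expect_equal(fit$EC50_hill, 1e5)  # 100 uM in nM
  # the conventional EC50 serves as the concentration unit
  expect_equal(ec_level(fit, 5), 1e5)
})

test_that("EC-unit conversion is definitional", {
  cu <- hill_curve(emax = 80, ec50 = 10, h = 1.5)
  fit <- fit_hill(cu)
  ec5 <- ec_level(fit, 5)
  expect_equal(to_ec_units(ec5, fit), 1)
  expect_equal(to_ec_units(0, fit), 0)
  expect_equal(to_ec_units(2 * ec5, fit), 2)
  # a curve with EC5% of 1.16 maps 2.32 to 2 units
  scaled <- hill_curve(emax = 87, ec50 = 1.16 * (5 / 82)^(-1 / 1.2), h = 1.2)
  f2 <- fit_hill(scaled)
  expect_equal(to_ec_units(2.32, f2), 2, tolerance = 1e-3)
  expect_error(ec_level(fit, 90), "unreachable")
})

test_that("bootstrap and analytic Hill uncertainties agree in scale", {
  set.seed(42)
  doses <- c(0.5, 1, 2, 5, 10, 20, 50, 100, 300)
  truth <- 80 * doses^1.5 / (10^1.5 + doses^1.5)
  noisy <- truth + rnorm(length(doses), 0, 2)
  cu <- cytotoxicity_curve(data.frame(
    dose_nM = doses, duration_h = 96, arm = "PTX",
    cytotoxicity_percent = noisy, sem = 2, n_replicates = 8), "synthetic")
  fit <- fit_hill(cu)
  boots <- replicate(400, {
    pert <- cu
    pert$cytotoxicity_percent <- noisy + rnorm(length(doses), 0, 2)
    f <- fit_hill(pert)
    c(f$E_obs_max, f$EC50_hill, f$h)
  })
  se_boot <- apply(boots, 1, sd)
  se_analytic <- sqrt(diag(fit$covariance))
  for (i in 1:3)
    expect_lt(abs(se_analytic[i] / se_boot[i] - 1), 0.2)
})

test_that("zero-variance single agents collapse the envelope onto additivity", {
  ptx <- hill_curve(emax = 85, ec50 = 15, h = 1.4, sem = 0)
  ome <- cytotoxicity_curve(data.frame(
    dose_nM = c(3, 9, 29, 90, 300) * 1000, duration_h = 96, arm = "OME",
    cytotoxicity_percent = rep(1, 5), sem = 0, n_replicates = 8),
    "synthetic")
  band <- build_envelope(list(ptx, ome), partner_dose = 29000, n_boot = 50,
                         seed = 1)
  ok <- is.finite(band$band$lower)
  expect_true(any(ok))
  expect_equal(band$band$lower[ok], band$band$additive[ok], tolerance = 1e-8)
  expect_equal(band$band$upper[ok], band$band$additive[ok], tolerance = 1e-8)
})

test_that("envelopes are reproducible bit-for-bit given the seed", {
  ptx <- hill_curve(emax = 85, ec50 = 15, h = 1.4, sem = 1.5)
  ome <- cytotoxicity_curve(data.frame(
    dose_nM = c(3, 9, 29, 90, 300) * 1000, duration_h = 96, arm = "OME",
    cytotoxicity_percent = rep(1, 5), sem = 0.5, n_replicates = 8),
    "synthetic")
  b1 <- build_envelope(list(ptx, ome), 29000, n_boot = 80, seed = 7)
  b2 <- build_envelope(list(ptx, ome), 29000, n_boot = 80, seed = 7)
  expect_identical(b1$band, b2$band)
  # band width grows with the injected single-agent dispersion
  wider <- hill_curve(emax = 85, ec50 = 15, h = 1.4, sem = 4)
  b3 <- build_envelope(list(wider, ome), 29000, n_boot = 80, seed = 7)
  w1 <- stats::median(b1$band$upper - b1$band$lower, na.rm = TRUE)
  w3 <- stats::median(b3$band$upper - b3$band$lower, na.rm = TRUE)
  expect_gt(w3, w1)
})

test_that("additive combinations classify as additivity, shifted ones as synergy", {
  ptx <- hill_curve(emax = 85, ec50 = 15, h = 1.4, sem = 1)
  ome <- cytotoxicity_curve(data.frame(
    dose_nM = c(3, 9, 29, 90, 300) * 1000, duration_h = 96, arm = "OME",
    cytotoxicity_percent = rep(1, 5), sem = 0.5, n_replicates = 8),
    "synthetic")
  h1 <- fit_hill(ptx); h2 <- fit_hill(ome)
  band <- build_envelope(list(ptx, ome), 29000, n_boot = 200, seed = 3)
  # combination exactly on the additive surface
  combo_add <- generate_additive_combo(list(h1, h2),
                                       doses = c(1, 2, 5, 10, 20, 50, 100),
                                       partner_dose = 29000, sd_percent = 0)
  expect_equal(classify(combo_add, band)$classification, "additivity")
  ei_add <- extent_of_interactivity(combo_add, band)
  expect_equal(ei_add$EI, 1, tolerance = 1e-3)
  # threefold leftward shift with a tight band
  combo_syn <- combo_add
  combo_syn$dose_nM <- combo_syn$dose_nM / 3
  cl <- classify(combo_syn, band)
  expect_equal(cl$classification, "synergy")
  ei <- extent_of_interactivity(combo_syn, band)
  expect_lt(ei$EI, 1)
  expect_equal(ei$fold_interaction, 1 / ei$EI, tolerance = 1e-12)
  # classification and EI agree in direction
  expect_true(ei$EI < 1 && cl$classification == "synergy")
})

test_that("an EI of 0.31 corresponds to roughly threefold synergy", {
  # definitional fixture for the fold-interaction scale: a combination
  # needing 0.31x the additive concentration at the reference effect is a
  # ~3.2-fold synergy (1/0.31)
  expect_equal(1 / 0.31, 3.2, tolerance = 0.01)
  ptx <- hill_curve(emax = 85, ec50 = 15, h = 1.4, sem = 1)
  ome <- cytotoxicity_curve(data.frame(
    dose_nM = c(3, 9, 29, 90, 300) * 1000, duration_h = 96, arm = "OME",
    cytotoxicity_percent = rep(1, 5), sem = 0.5, n_replicates = 8),
    "synthetic")
  # no fixed partner: the unit offset is zero and the shift is exactly EI
  band <- build_envelope(list(ptx, ome), partner_dose = 0, n_boot = 100,
                         seed = 3)
  combo <- generate_additive_combo(list(fit_hill(ptx), fit_hill(ome)),
                                   doses = c(1, 2, 5, 10, 20, 50, 100),
                                   partner_dose = 0, sd_percent = 0)
  combo$dose_nM <- combo$dose_nM * 0.31
  ei <- extent_of_interactivity(combo, band)
  expect_equal(ei$EI, 0.31, tolerance = 1e-3)
  expect_equal(ei$fold_interaction, 1 / 0.31, tolerance = 1e-3)
})

test_that("EI is invariant to rescaling an agent's dose axis", {
  ptx <- hill_curve(emax = 85, ec50 = 15, h = 1.4, sem = 1)
  ome <- cytotoxicity_curve(data.frame(
    dose_nM = c(3, 9, 29, 90, 300) * 1000, duration_h = 96, arm = "OME",
    cytotoxicity_percent = rep(1, 5), sem = 0.5, n_replicates = 8),
    "synthetic")
  band <- build_envelope(list(ptx, ome), 29000, n_boot = 100, seed = 3)
  combo <- generate_additive_combo(list(fit_hill(ptx), fit_hill(ome)),
                                   doses = c(1, 2, 5, 10, 20, 50), 29000,
                                   sd_percent = 0)
  combo$dose_nM <- combo$dose_nM / 2
  ei1 <- extent_of_interactivity(combo, band)$EI
  # express the drug in different units (x 1000) everywhere: doses and curve
  ptx2 <- ptx; ptx2$dose_nM <- ptx2$dose_nM * 1000
  band2 <- build_envelope(list(ptx2, ome), 29000, n_boot = 100, seed = 3)
  combo2 <- combo; combo2$dose_nM <- combo2$dose_nM * 1000
  ei2 <- extent_of_interactivity(combo2, band2)$EI
  expect_equal(ei1, ei2, tolerance = 1e-6)
})

test_that("unreachable effect levels yield the not-attainable sentinel", {
  # a weak, short-treatment-like curve never reaches 50% effect
  weak <- hill_curve(emax = 30, ec50 = 20, h = 1.3, sem = 1)
  ome <- cytotoxicity_curve(data.frame(
    dose_nM = c(3, 9, 29, 90, 300) * 1000, duration_h = 12, arm = "OME",
    cytotoxicity_percent = rep(1, 5), sem = 0.5, n_replicates = 8),
    "synthetic")
  band <- build_envelope(list(weak, ome), 29000, n_boot = 50, seed = 2)
  combo <- generate_additive_combo(list(fit_hill(weak), fit_hill(ome)),
                                   doses = c(1, 5, 20, 100), 29000,
                                   sd_percent = 0)
  ei <- extent_of_interactivity(combo, band, effect_level = 50)
  expect_false(ei$attainable)
  expect_true(is.na(ei$EI))
})
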