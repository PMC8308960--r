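test_that("observed datasets validate their schema", {
  good <- data.frame(observable = "PTX_exo", dose_nM = 300, time_h = 8,
                     arm = "PTX", value = 5, sem = 0.5, n = 9,
                     role = "model_building")
  expect_s3_class(observed_dataset(good), "observed_dataset")
  expect_error(observed_dataset(good[, -1]), "missing columns")
  bad <- good; bad$arm <- "XXX"
  expect_error(observed_dataset(bad), "arm")
  bad <- good; bad$sem <- -1
  expect_error(observed_dataset(bad), "sem")
  # CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_observed_dataset(observed_dataset(good), path)
  expect_equal(as.data.frame(read_observed_dataset(path)),
               as.data.frame(observed_dataset(good)))
})

test_that("weighted SSR is zero on self-consistent data and obeys arithmetic", {
  p <- toy_params()
  pd <- toy_pd()
  des <- small_design()
  pk <- generate_pk_dataset(p, design = des, noise = noise_model(0), seed = 1)
  truth <- c(alpha_OME = 0.61, beta_OME = 0.38)
  expect_lt(weighted_ssr(truth, pk, p, pd), 1e-6)
  # single hand-made record: w = 1, y = 2, yhat = 5 -> 9
  one <- observed_dataset(data.frame(
    observable = "PTX_exo", dose_nM = 300, time_h = 8, arm = "OME+PTX",
    value = 2, sem = 1, n = 3, role = "model_building"))
  cand <- c(alpha_OME = 0.2, beta_OME = 0.2)
  yhat <- predict_records(one, p, pd,
                          list(`OME+PTX` = inhibition_settings(0.2, 0.2)))
  one$value <- yhat + 3  # residual exactly 3 under unit (sem) weights
  expect_equal(weighted_ssr(cand, one, p, pd, weighting = "sem"), 9)
})

test_that("the optimizer beats a coarse grid search everywhere", {
  p <- toy_params()
  pd <- toy_pd()
  des <- small_design()
  pk <- generate_pk_dataset(p, design = des, seed = 11)
  fit <- fit_inhibition(pk, p, pd, multistart = 4, seed = 2,
                        weighting = "sem")
  grid <- expand.grid(alpha = seq(0.025, 0.975, length.out = 21),
                      beta = seq(0.025, 0.975, length.out = 21))
  gvals <- mapply(function(a, b)
    weighted_ssr(c(alpha_OME = a, beta_OME = b), pk, p, pd,
                 weighting = "sem"),
    grid$alpha, grid$beta)
  expect_lte(fit$wrss, min(gvals) + 1e-6)
})

test_that("noise-free synthetic data recover the generating fractions", {
  p <- model_parameters()
  pd <- pd_parameters()
  des <- study_design(arms = c("PTX", "OME+PTX"))
  pk <- generate_pk_dataset(p, design = des, noise = noise_model(0), seed = 1)
  pdd <- generate_pd_dataset(p, pd, design = des, sd_percent = 0, seed = 1)
  ds <- observed_dataset(rbind(
    pk, pdd$dataset[pdd$dataset$role == "model_building", ]))
  fit <- fit_inhibition(ds, p, pd, multistart = 4, seed = 2)
  expect_equal(unname(fit$estimates[["alpha_OME"]]), 0.61, tolerance = 2e-3)
  expect_equal(unname(fit$estimates[["beta_OME"]]), 0.38, tolerance = 2e-2)
})

test_that("bic matches its closed form and guards its domain", {
  expect_equal(bic(20, 20, 2), 2 * log(20))  # rss = n: the log term drops
  expect_equal(bic(10, 20, 2), 20 * log(0.5) + 2 * log(20))
  expect_equal(bic(10, 20, 2), -7.8714, tolerance = 1e-4)
  expect_warning(b0 <- bic(0, 10, 1), "-Inf")
  expect_identical(b0, -Inf)
  expect_error(bic(1, 2, 2), "exceed")
})

test_that("fit is invariant to record order and weight rescaling", {
  p <- toy_params()
  pd <- toy_pd()
  des <- small_design()
  pk <- generate_pk_dataset(p, design = des, seed = 5)
  fit1 <- fit_inhibition(pk, p, pd, multistart = 2, seed = 9,
                         weighting = "sem")
  shuf <- pk[sample(nrow(pk)), ]
  fit2 <- fit_inhibition(observed_dataset(shuf), p, pd, multistart = 2,
                         seed = 9, weighting = "sem")
  expect_equal(fit1$estimates, fit2$estimates, tolerance = 1e-6)
  # rescaling every sem by one factor shifts wrss but not the optimum
  scaled <- pk; scaled$sem <- scaled$sem * 3
  fit3 <- fit_inhibition(observed_dataset(scaled), p, pd, multistart = 2,
                         seed = 9, weighting = "sem")
  expect_equal(fit1$estimates, fit3$estimates, tolerance = 1e-5)
  expect_equal(fit3$wrss, fit1$wrss / 9, tolerance = 1e-4)
})

test_that("validation gate flags constructed violations and passes truth", {
  p <- model_parameters()
  pd <- pd_parameters()
  des <- study_design(arms = c("PTX", "OME+PTX"))
  pk <- generate_pk_dataset(p, design = des, noise = noise_model(0), seed = 1)
  pdd <- generate_pd_dataset(p, pd, design = des, sd_percent = 0, seed = 1)
  ds <- observed_dataset(rbind(
    pk, pdd$dataset[pdd$dataset$role == "model_building", ]))
  fit <- fit_inhibition(ds, p, pd, multistart = 2, seed = 2)
  val <- pdd$dataset[pdd$dataset$role == "validation", ]
  v <- validate_against(fit, observed_dataset(val), p, pd)
  expect_true(v$pass)
  expect_lt(v$max_dev, 0.05)  # noise-free data equal model predictions
  # inflating one sizable record breaks the gate and is flagged
  val2 <- val
  big <- which(val2$value > 30)[1]
  val2$value[big] <- val2$value[big] * 2
  v2 <- validate_against(fit, observed_dataset(val2), p, pd)
  expect_false(v2$pass)
  expect_false(v2$records$ok[big])
  # zero observations are excluded with a warning
  val3 <- val
  val3$value[1] <- 0
  expect_warning(validate_against(fit, observed_dataset(val3), p, pd),
                 "excluded")
})

test_that("wald intervals are calibrated across synthetic replicates", {
  p <- model_parameters()
  pd <- pd_parameters()
  des <- study_design(arms = c("PTX", "OME+PTX"))
  n_rep <- 200
  est <- matrix(NA_real_, n_rep, 4)
  for (s in seq_len(n_rep)) {
    pk <- generate_pk_dataset(p, design = des, seed = 5000 + s)
    pdd <- generate_pd_dataset(p, pd, design = des, seed = 5000 + s)
    ds <- observed_dataset(rbind(
      pk, pdd$dataset[pdd$dataset$role == "model_building", ]))
    fit <- fit_inhibition(ds, p, pd, multistart = 3, seed = 3,
                          weighting = "sem")
    est[s, ] <- c(fit$estimates, fit$se)
  }
  tq <- stats::qt(0.975, 52 - 2)
  cov_a <- mean(abs(est[, 1] - 0.61) <= tq * est[, 3])
  cov_b <- mean(abs(est[, 2] - 0.38) <= tq * est[, 4])
  expect_gte(cov_a, 0.90); expect_lte(cov_a, 0.99)
  expect_gte(cov_b, 0.90); expect_lte(cov_b, 0.99)
})
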