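# Inverse prediction and delta-method error propagation.

test_that("noiseless inversion is exact with zero sd", {
  cal <- oracle_calibration()
  cal$residual_sd <- 0; cal$var_background <- 0
  cal$var_sensitivity <- 0; cal$cov_bg_sens <- 0
  inv <- invert_intensity(cal, 60)
  expect_equal(inv$dilution_estimate, 0.5)
  expect_equal(inv$sd, 0)
})

test_that("the delta-method sd matches its closed form and the MC oracle", {
  cal <- oracle_calibration()
  inv <- invert_intensity(cal, 60, m = 1)
  expect_equal(inv$dilution_estimate, 0.5)
  # (sigma^2 + var_b + r^2 var_s + 2 r cov) / s^2 = 14.25e-4
  expect_equal(inv$sd, sqrt(14.25) / 100, tolerance = 1e-12)
  expect_equal(inv$sd, 0.037749, tolerance = 1e-4)
  mc <- mc_sd_r(10, 100, 4, 25, -5, 3, 60, m = 1)
  expect_equal(inv$sd, mc, tolerance = 0.02)

  # two pooled replicates shrink only the sample-intensity term
  inv2 <- invert_intensity(cal, mean(c(55, 65)), m = 2)
  expect_equal(inv2$dilution_estimate, 0.5)
  expect_equal(inv2$sd, sqrt(9.75) / 100, tolerance = 1e-12)  # 0.031225
  mc2 <- mc_sd_r(10, 100, 4, 25, -5, 3, 60, m = 2)
  expect_equal(inv2$sd, mc2, tolerance = 0.02)
})

test_that("concentrations scale the inversion by C0, linearly", {
  cal <- oracle_calibration(c0 = 200)
  sv <- one_channel_survey(60)
  est <- quantify(sv, cal)
  expect_equal(est$concentration, 100)
  expect_equal(est$sd, 200 * sqrt(14.25) / 100, tolerance = 1e-12) # 7.5498
  expect_equal(est$flag, "ok")

  cal2 <- oracle_calibration(c0 = 400)
  est2 <- quantify(sv, cal2)
  expect_identical(est2$concentration, 2 * est$concentration)
  expect_identical(est2$sd, 2 * est$sd)
})

test_that("flags follow the sign and extrapolation rules", {
  cal <- oracle_calibration()
  est <- quantify(one_channel_survey(c(5, 60, 150)), cal)
  expect_equal(est$flag,
               c("below_background", "ok", "extrapolated_above_standard"))
  expect_lt(est$concentration[1], 0)       # reported unclamped
  expect_gt(est$dilution_estimate[3], 1)
  # invariant: below_background iff concentration < 0
  expect_identical(est$flag == "below_background", est$concentration < 0)
})

test_that("non-positive-sensitivity channels are refused", {
  cal <- oracle_calibration()
  cal$sensitivity <- -100
  cal$flag <- "non_positive_sensitivity"
  expect_error(invert_intensity(cal, 60), class = "compcal_value_error")
  est <- quantify(one_channel_survey(60), cal)
  expect_identical(est$flag, "non_positive_sensitivity")
  expect_true(is.na(est$concentration))
})

test_that("a channel without a calibration is a keyed error", {
  cal <- oracle_calibration()
  sv <- survey_intensities(tibble::tibble(
    sample_id = "s1", role = "assay", `27Al` = 60, `63Cu` = 40
  ))
  err <- expect_error(quantify(sv, cal), class = "compcal_value_error")
  expect_match(conditionMessage(err), "63Cu")
})

test_that("pooled quantification averages intensities first", {
  cal <- oracle_calibration(c0 = 200)
  # pooling one sample reduces to per-sample quantification
  one <- one_channel_survey(60)
  expect_equal(
    quantify_pooled(one, cal)[c("dilution_estimate", "concentration", "sd")],
    quantify(one, cal)[c("dilution_estimate", "concentration", "sd")]
  )
  # the worked two-replicate case: c = 100, sd = 6.2450
  two <- one_channel_survey(c(55, 65))
  pooled <- quantify_pooled(two, cal)
  expect_equal(pooled$concentration, 100)
  expect_equal(pooled$m, 2L)
  expect_equal(pooled$sd, 200 * sqrt(9.75) / 100, tolerance = 1e-12) # 6.2450
  mc <- mc_sd_r(10, 100, 4, 25, -5, 3, 60, m = 2)
  expect_equal(pooled$sd, 200 * mc, tolerance = 0.02)
  # linearity: mean of per-sample concentrations equals the pooled one
  per <- quantify(two, cal)
  expect_equal(mean(per$concentration), pooled$concentration,
               tolerance = 1e-12)
  # and the pooled sd is smaller
  expect_lt(pooled$sd, per$sd[1])
})

test_that("noiseless end-to-end quantification recovers the truth", {
  truth <- simulate_design(n_elements = 9, seed = 12, noise_rel = 0)
  survey <- simulate_survey(truth, seed = 13)
  calib <- fit_calibrations(survey, truth$design)
  est <- quantify(split_survey(survey, truth$design)$assay, calib)
  joined <- dplyr::inner_join(tibble::as_tibble(est), truth$assay,
                              by = c("sample_id", "element"))
  scale <- pmax(abs(joined$conc_true),
                truth$design$mixture$c0[match(joined$element,
                                              truth$design$mixture$element)])
  expect_lt(max(abs(joined$concentration - joined$conc_true) / scale), 1e-9)
  expect_lt(max(abs(est$sd)), 1e-6)
})

test_that("quantifying the undiluted mixture itself returns r = 1, c = C0", {
  truth <- simulate_design(n_elements = 5, seed = 14, noise_rel = 0)
  survey <- simulate_survey(truth, seed = 15)
  calib <- fit_calibrations(survey, truth$design)
  # re-present the d = 1 calibration sample as an assay sample
  top_id <- truth$design$dilutions$sample_id[truth$design$dilutions$dilution == 1]
  top <- tibble::as_tibble(survey)[survey$sample_id == top_id, ]
  top$role <- "assay"
  top <- survey_intensities(top[c("sample_id", "role", calib$channel)])
  est <- quantify(top, calib)
  expect_equal(est$dilution_estimate, rep(1, 5), tolerance = 1e-12)
  expect_equal(est$concentration, calib$c0, tolerance = 1e-12)
})

test_that("delta-method sd tracks the MC oracle within 10% when well-conditioned", {
  set.seed(40)
  for (i in 1:10) {
    d <- c(1, 0.5, 0.1, 0.01, 0)
    b <- runif(1, 100, 1000); s <- 10^runif(1, 3.5, 5)
    sigma <- 0.01 * s
    fit <- fit_element_calibration(d, b + s * d + rnorm(5, 0, sigma))
    intensity <- b + s * runif(1, 0.3, 0.9)
    inv <- invert_intensity(fit, intensity)
    cv <- inv$sd / inv$dilution_estimate
    rel_s <- sqrt(fit$var_sensitivity) / fit$sensitivity
    if (cv < 0.05 && rel_s < 0.05) {
      mc <- mc_sd_r(fit$background, fit$sensitivity, fit$var_background,
                    fit$var_sensitivity, fit$cov_bg_sens, fit$residual_sd,
                    intensity, n_draws = 2e5, seed = 100 + i)
      expect_equal(inv$sd, mc, tolerance = 0.1)
    }
  }
})

test_that("a negative propagated variance is clamped to zero with a warning", {
  cal <- oracle_calibration()
  # a covariance beyond the Cauchy-Schwarz bound (e.g. a corrupted
  # calibration file) drives the bracket negative near r = -cov/var_s
  cal$residual_sd <- 0; cal$var_background <- 0.01
  cal$var_sensitivity <- 4; cal$cov_bg_sens <- -0.21
  expect_warning(inv <- invert_intensity(cal, cal$background + 5.25), "clamped")
  expect_equal(inv$sd, 0)
})
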