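# The per-channel OLS calibration: closed forms, oracle equivalence,
# vectorization, and the sampling distribution of the estimates.

test_that("an exact line is recovered with zero residual SD", {
  fit <- fit_element_calibration(c(0, 0.5, 1), c(10, 60, 110))
  expect_equal(fit$background, 10)
  expect_equal(fit$sensitivity, 100)
  expect_equal(fit$residual_sd, 0)
  expect_equal(fit$var_background, 0)
  expect_equal(fit$var_sensitivity, 0)
})

test_that("the noisy three-point fit matches the hand-checked closed form", {
  fit <- fit_element_calibration(c(0, 0.5, 1), c(0, 40, 100))
  expect_equal(fit$background, -10 / 3, tolerance = 1e-12)
  expect_equal(fit$sensitivity, 100, tolerance = 1e-12)
  expect_equal(fit$residual_sd^2, 200 / 3, tolerance = 1e-12)  # 66.667
  expect_equal(fit$residual_sd, 8.16497, tolerance = 1e-5)
})

test_that("degenerate and undersized designs are refused", {
  expect_error(fit_element_calibration(c(0.2, 0.2, 0.2), c(1, 2, 3)),
               class = "compcal_design_error")
  expect_error(fit_element_calibration(c(0, 1), c(1, 2)),
               class = "compcal_design_error")
  # ties in d are fine as long as two levels exist
  expect_silent(fit_element_calibration(c(0, 0, 1), c(1, 2, 3)))
})

test_that("estimates and (co)variances agree with the lm() oracle", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    d <- round(runif(n), 3)
    if (length(unique(d)) < 2) d[1] <- d[1] + 0.5
    intensity <- 50 + 300 * d + rnorm(n, 0, 5)
    fit <- fit_element_calibration(d, intensity)
    ref <- lm(intensity ~ d)
    vc <- vcov(ref)
    expect_equal(fit$background, unname(coef(ref)[1]), tolerance = 1e-9)
    expect_equal(fit$sensitivity, unname(coef(ref)[2]), tolerance = 1e-9)
    expect_equal(fit$residual_sd, summary(ref)$sigma, tolerance = 1e-9)
    expect_equal(fit$var_background, vc[1, 1], tolerance = 1e-9)
    expect_equal(fit$var_sensitivity, vc[2, 2], tolerance = 1e-9)
    expect_equal(fit$cov_bg_sens, vc[1, 2], tolerance = 1e-9)
  }
})

test_that("covariance inequality |cov| <= sqrt(var_b * var_s) always holds", {
  set.seed(7)
  for (i in 1:20) {
    d <- runif(6)
    fit <- fit_element_calibration(d, 10 + 100 * d + rnorm(6))
    expect_lte(abs(fit$cov_bg_sens),
               sqrt(fit$var_background * fit$var_sensitivity) + 1e-12)
  }
})

test_that("vectorized fit is bit-identical to the per-channel loop", {
  truth <- simulate_design(n_elements = 9, seed = 2)
  survey <- simulate_survey(truth, seed = 3)
  vec <- tidy(fit_calibrations(survey, truth$design, vectorized = TRUE))
  loop <- tidy(fit_calibrations(survey, truth$design, vectorized = FALSE))
  expect_identical(as.data.frame(vec), as.data.frame(loop[names(vec)]))
})

test_that("channels absent from the mixture are dropped by the split", {
  design <- toy_design()
  sv <- survey_intensities(tibble::tibble(
    sample_id = c(sprintf("cal_%d", 1:5), "s1", "s2"),
    role = rep(c("calibration", "assay"), c(5, 2)),
    `27Al` = runif(7, 10, 100), `63Cu` = runif(7, 10, 100),
    `40Ca` = runif(7, 10, 100)   # not in the mixture
  ))
  parts <- split_survey(sv, design)
  expect_equal(dim(parts$calibration), c(5L, 2L + 2L))
  expect_equal(dim(parts$assay), c(2L, 2L + 2L))
  expect_false("40Ca" %in% survey_channels(parts$calibration))
  expect_false("40Ca" %in% survey_channels(parts$assay))
  # a calibration sample without a declared dilution factor is an error
  sv2 <- sv
  sv2$sample_id[1] <- "cal_unknown"
  expect_error(split_survey(sv2, design), class = "compcal_design_error")
})

test_that("a survey with zero assay samples still calibrates", {
  truth <- simulate_design(n_elements = 3, seed = 4)
  survey <- simulate_survey(truth, seed = 5)
  cal_only <- survey[survey$role == "calibration", ]
  class(cal_only) <- c("cc_survey", class(cal_only))
  parts <- split_survey(cal_only, truth$design)
  expect_equal(nrow(parts$assay), 0L)
  fit <- fit_calibrations(cal_only, truth$design)
  expect_equal(nrow(fit), 3L)
})

test_that("permuting calibration rows leaves the estimates unchanged", {
  truth <- simulate_design(n_elements = 5, seed = 6)
  survey <- simulate_survey(truth, seed = 7)
  fit1 <- tidy(fit_calibrations(survey, truth$design))
  perm <- survey[c(5, 3, 1, 2, 4, 6:nrow(survey)), ]
  class(perm) <- c("cc_survey", class(perm))
  fit2 <- tidy(fit_calibrations(perm, truth$design))
  for (col in c("background", "sensitivity", "residual_sd", "var_background",
                "var_sensitivity", "cov_bg_sens")) {
    expect_equal(fit1[[col]], fit2[[col]], tolerance = 1e-12)
  }
})

test_that("rescaling intensities by k rescales b, s, sigma by k", {
  d <- c(1, 0.5, 0.1, 0.01, 0)
  set.seed(8)
  intensity <- 20 + 500 * d + rnorm(5, 0, 3)
  f1 <- fit_element_calibration(d, intensity)
  f2 <- fit_element_calibration(d, 4 * intensity)   # power of two: exact
  expect_identical(f2$background, 4 * f1$background)
  expect_identical(f2$sensitivity, 4 * f1$sensitivity)
  expect_identical(f2$residual_sd, 4 * f1$residual_sd)
  f3 <- fit_element_calibration(d, 3.7 * intensity)
  expect_equal(f3$sensitivity, 3.7 * f1$sensitivity, tolerance = 1e-12)
  expect_equal(f3$residual_sd, 3.7 * f1$residual_sd, tolerance = 1e-12)
})

test_that("parameter recovery is unbiased and intervals cover at the exact t rate", {
  # At the 5-point design the standardized errors (b_hat - b)/sqrt(var_b)
  # and (s_hat - s)/sqrt(var_s) are exactly t with n-2 = 3 df, so nominal
  # +/-1.96 intervals cover 2*pt(1.96, 3) - 1 = 85.5%; check both the
  # unbiasedness and that exact rate, and that a long design reaches the
  # normal-regime 95%.
  d5 <- c(1, 0.5, 0.1, 0.01, 0)
  b_true <- 50; s_true <- 1000; sigma <- 10
  n_rep <- 2000
  set.seed(20)
  hit_b <- hit_s <- logical(n_rep)
  err_s <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    fit <- fit_element_calibration(d5, b_true + s_true * d5 + rnorm(5, 0, sigma))
    err_s[i] <- fit$sensitivity - s_true
    hit_b[i] <- abs(fit$background - b_true) <= 1.96 * sqrt(fit$var_background)
    hit_s[i] <- abs(fit$sensitivity - s_true) <= 1.96 * sqrt(fit$var_sensitivity)
  }
  expect_lt(abs(mean(err_s)), 3 * sigma / sqrt(sum((d5 - mean(d5))^2)) / sqrt(n_rep) * 3)
  t_rate <- 2 * pt(1.96, 3) - 1
  expect_lt(abs(mean(hit_b) - t_rate), 0.025)
  expect_lt(abs(mean(hit_s) - t_rate), 0.025)

  # 30-point design: df = 28, nominal 1.96 intervals approach the normal
  # 95% rate (exact rate 2*pt(1.96, 28) - 1 = 94.0%)
  d30 <- rep(d5, 6)
  set.seed(21)
  hit30 <- vapply(seq_len(n_rep), function(i) {
    fit <- fit_element_calibration(d30, b_true + s_true * d30 + rnorm(30, 0, sigma))
    abs(fit$sensitivity - s_true) <= 1.96 * sqrt(fit$var_sensitivity)
  }, TRUE)
  expect_lt(abs(mean(hit30) - (2 * pt(1.96, 28) - 1)), 0.025)
})

test_that("bias of b and s vanishes as noise goes to zero", {
  d <- c(1, 0.5, 0.1, 0.01, 0)
  for (sigma in c(1, 1e-3, 1e-6)) {
    set.seed(31)
    fits <- replicate(200, {
      f <- fit_element_calibration(d, 40 + 800 * d + rnorm(5, 0, sigma))
      c(f$background, f$sensitivity)
    })
    expect_lt(abs(mean(fits[1, ]) - 40), 4 * sigma)
    expect_lt(abs(mean(fits[2, ]) - 800), 8 * sigma)
  }
})
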