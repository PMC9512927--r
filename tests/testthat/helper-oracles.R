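# Independent oracles and small fixture builders shared across test files.

# Monte-Carlo propagation oracle for the inverse prediction r = (I - b)/s:
# draws (b, s) from the bivariate normal implied by the reported
# (co)variances, the sample intensity independently with SD sigma/sqrt(m),
# and returns the SD of the resulting r draws. Independent of the
# delta-method code path under test.
mc_sd_r <- function(b, s, var_b, var_s, cov_bs, sigma, intensity, m = 1,
                    n_draws = 1e6, seed = 42) {
  set.seed(seed)
  z1 <- rnorm(n_draws)
  z2 <- rnorm(n_draws)
  if (var_b > 0) {
    b_d <- b + sqrt(var_b) * z1
    s_d <- s + (cov_bs / sqrt(var_b)) * z1 +
      sqrt(max(var_s - cov_bs^2 / var_b, 0)) * z2
  } else {
    b_d <- rep(b, n_draws)
    s_d <- s + sqrt(var_s) * z2
  }
  i_d <- intensity + rnorm(n_draws, 0, sigma / sqrt(m))
  stats::sd((i_d - b_d) / s_d)
}

# The worked calibration used across quantification tests (matches a
# hand-checked OLS fit: b = 10, s = 100, sigma = 3, var_b = 4, var_s = 25,
# cov_bs = -5).
oracle_calibration <- function(c0 = 200) {
  structure(
    tibble::tibble(
      channel = "27Al", element = "Al", primary = TRUE,
      background = 10, sensitivity = 100, residual_sd = 3,
      var_background = 4, var_sensitivity = 25, cov_bg_sens = -5,
      n_points = 5L, flag = "ok", c0 = c0
    ),
    class = c("cc_calibration", class(tibble::tibble()))
  )
}

# Minimal survey with one 27Al channel and the given assay intensities.
one_channel_survey <- function(intensities, ids = NULL) {
  ids <- ids %||% sprintf("assay_%d", seq_along(intensities))
  survey_intensities(tibble::tibble(
    sample_id = ids, role = "assay", `27Al` = intensities
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny three-element design built by hand, for io and screening tests.
toy_design <- function() {
  calibration_design(
    mixture = tibble::tibble(element = c("Al", "Cu", "Zn"), c0 = c(200, 100, 50)),
    dilutions = tibble::tibble(
      sample_id = sprintf("cal_%d", 1:5),
      dilution = c(1, 0.5, 0.1, 0.01, 0)
    ),
    channels = tibble::tibble(
      channel = c("27Al", "63Cu", "64Zn"),
      element = c("Al", "Cu", "Zn"),
      primary = TRUE
    )
  )
}
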