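# Per-channel calibration of intensity against dilution factor.
#
# Model, for one mass channel: I = b + s*d + eps, eps ~ (0, sigma^2) i.i.d.
# across calibration samples; sigma is channel-specific but does not depend
# on the dilution factor. Because the independent variable is the dilution
# factor of the whole mixture rather than each element's concentration, the
# same design vector d serves every channel and the ordinary-least-squares
# closed forms can be evaluated for all channels in one vectorized pass.

#' Split a survey into calibration and assay parts
#'
#' Separates the survey rows by role and drops every mass channel that is
#' not mapped to an element of the main mixture (elements absent from the
#' external standards cannot be calibrated).
#'
#' @param survey A `cc_survey` tibble.
#' @param design A `cc_design`.
#' @return A list with `cc_survey` elements `calibration` and `assay`, both
#'   restricted to the retained channels.
#' @export
split_survey <- function(survey, design) {
  stopifnot(inherits(survey, "cc_survey"), inherits(design, "cc_design"))
  keep_map <- design$channels[design$channels$element %in% design$mixture$element, ]
  keep <- intersect(survey_channels(survey), keep_map$channel)
  cal_ids <- survey$sample_id[survey$role == "calibration"]
  undeclared <- setdiff(cal_ids, design$dilutions$sample_id)
  if (length(undeclared) > 0L) {
    cc_abort(
      sprintf("calibration sample(s) with no declared dilution factor: %s",
              paste(undeclared, collapse = ", ")),
      class = "design_error"
    )
  }
  pick <- function(rows) {
    out <- tibble::as_tibble(survey)[rows, c("sample_id", "role", keep)]
    class(out) <- c("cc_survey", class(out))
    out
  }
  list(
    calibration = pick(survey$role == "calibration"),
    assay = pick(survey$role == "assay")
  )
}

# The residual-variance estimator is isolated here so the denominator
# convention (unbiased n-2) can be swapped in one place.
residual_variance <- function(rss, n) rss / (n - 2)

#' Fit the calibration line for one mass channel
#'
#' Ordinary least squares of intensity on dilution factor,
#' `I = b + s*d + eps`, returning the background (intercept), sensitivity
#' (slope), the estimated error SD of intensity measurements, and the
#' parameter (co)variances needed for downstream error propagation:
#' `var_s = sigma^2/S_dd`, `var_b = sigma^2*(1/n + dbar^2/S_dd)`,
#' `cov_bs = -sigma^2*dbar/S_dd`, with `sigma^2 = RSS/(n-2)`.
#'
#' @param d Dilution factors of the calibration samples.
#' @param intensity Measured intensities (cps), same length as `d`.
#' @return A one-row tibble with columns `background`, `sensitivity`,
#'   `residual_sd`, `var_background`, `var_sensitivity`, `cov_bg_sens`,
#'   `n_points` and `flag` (`"ok"` or `"non_positive_sensitivity"`).
#' @examples
#' fit_element_calibration(c(0, 0.5, 1), c(10, 60, 110))
#' @export
fit_element_calibration <- function(d, intensity) {
  n <- length(d)
  if (n != length(intensity)) {
    cc_abort("dilution and intensity vectors differ in length", class = "design_error")
  }
  if (n < 3L) {
    cc_abort("at least 3 calibration points are required", class = "design_error")
  }
  if (length(unique(d)) < 2L) {
    cc_abort("degenerate design: all dilution factors identical", class = "design_error")
  }
  # sums divided by n (not mean(): its two-pass correction would make the
  # looped and vectorized paths differ in the last bit)
  dbar <- sum(d) / n
  sdd <- sum((d - dbar)^2)
  s <- sum((d - dbar) * intensity) / sdd
  b <- sum(intensity) / n - s * dbar
  rss <- sum((intensity - (b + s * d))^2)
  sigma2 <- residual_variance(rss, n)
  tibble::tibble(
    background = b,
    sensitivity = s,
    residual_sd = sqrt(sigma2),
    var_background = sigma2 * (1 / n + dbar^2 / sdd),
    var_sensitivity = sigma2 / sdd,
    cov_bg_sens = -sigma2 * dbar / sdd,
    n_points = n,
    flag = if (s > 0) "ok" else "non_positive_sensitivity"
  )
}

#' Calibrate every retained mass channel
#'
#' Splits the survey, then fits the intensity-versus-dilution line for all
#' retained channels. Because the design vector is shared across channels,
#' the default path evaluates the closed forms for the whole intensity
#' matrix at once; `vectorized = FALSE` loops channel by channel through
#' [fit_element_calibration()] and yields bit-identical results.
#'
#' @param survey A `cc_survey` (full table; split internally), or the
#'   calibration part returned by [split_survey()].
#' @param design A `cc_design`.
#' @param vectorized Use the single-pass matrix evaluation (default) or the
#'   per-channel loop.
#' @return A tibble of class `cc_calibration`, one row per channel, with
#'   the columns of [fit_element_calibration()] plus `channel`, `element`
#'   and `c0`. The calibration intensities are kept in attribute `data`
#'   for plotting.
#' @export
fit_calibrations <- function(survey, design, vectorized = TRUE) {
  stopifnot(inherits(survey, "cc_survey"), inherits(design, "cc_design"))
  cal <- split_survey(survey, design)$calibration
  if (nrow(cal) == 0L) {
    cc_abort("survey contains no calibration-role samples", class = "design_error")
  }
  chans <- survey_channels(cal)
  if (length(chans) == 0L) {
    cc_abort("no survey channel maps to an element of the mixture",
             class = "design_error")
  }
  d <- design$dilutions$dilution[match(cal$sample_id, design$dilutions$sample_id)]
  n <- length(d)
  if (n < 3L) {
    cc_abort("at least 3 calibration points are required", class = "design_error")
  }
  if (length(unique(d)) < 2L) {
    cc_abort("degenerate design: all dilution factors identical", class = "design_error")
  }
  intens <- as.matrix(tibble::as_tibble(cal)[chans])
  if (vectorized) {
    dbar <- sum(d) / n
    sdd <- sum((d - dbar)^2)
    s <- colSums((d - dbar) * intens) / sdd
    b <- colSums(intens) / n - s * dbar
    rss <- colSums((intens - (rep(1, n) %o% b + d %o% s))^2)
    sigma2 <- residual_variance(rss, n)
    fits <- tibble::tibble(
      channel = chans,
      background = unname(b),
      sensitivity = unname(s),
      residual_sd = sqrt(unname(sigma2)),
      var_background = unname(sigma2) * (1 / n + dbar^2 / sdd),
      var_sensitivity = unname(sigma2) / sdd,
      cov_bg_sens = -unname(sigma2) * dbar / sdd,
      n_points = n,
      flag = ifelse(s > 0, "ok", "non_positive_sensitivity")
    )
  } else {
    fits <- purrr::map_dfr(chans, function(ch) {
      fit <- tryCatch(
        fit_element_calibration(d, intens[, ch]),
        error = function(e) {
          cc_abort(sprintf("channel %s: %s", ch, conditionMessage(e)),
                   class = "design_error")
        }
      )
      tibble::add_column(fit, channel = ch, .before = 1L)
    })
  }
  meta <- dplyr::left_join(design$channels, design$mixture, by = "element")
  out <- dplyr::inner_join(fits, meta, by = "channel")
  out <- dplyr::relocate(out, "channel", "element", "primary")
  cal_long <- tidyr::pivot_longer(
    tibble::as_tibble(cal)[c("sample_id", chans)],
    -"sample_id", names_to = "channel", values_to = "intensity"
  )
  cal_long$dilution <- d[match(cal_long$sample_id, cal$sample_id)]
  attr(out, "data") <- cal_long
  class(out) <- c("cc_calibration", class(out))
  out
}

#' Write a Calibration File
#'
#' One CSV row per channel with the fitted parameters, their (co)variances,
#' the number of calibration points and the mixture concentration `c0`.
#' Values round trip through [read_calibration_file()] at full double
#' precision.
#'
#' @param calibrations A `cc_calibration` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_file <- function(calibrations, path) {
  if (nrow(calibrations) == 0L) {
    cc_abort("refusing to write an empty calibration set", class = "value_error")
  }
  readr::write_csv(full_precision(tibble::as_tibble(calibrations)), path)
  invisible(path)
}

calibration_file_cols <- c(
  "channel", "element", "background", "sensitivity", "residual_sd",
  "var_background", "var_sensitivity", "cov_bg_sens", "n_points", "c0"
)

#' Read a Calibration File
#'
#' @param path Path to a CSV written by [write_calibration_file()].
#' @return A `cc_calibration` tibble (without the plotting data attribute).
#' @export
read_calibration_file <- function(path) {
  if (!file.exists(path)) {
    cc_abort(sprintf("no such file: %s", path), class = "io_error")
  }
  x <- read_csv_precise(path)
  miss <- setdiff(calibration_file_cols, names(x))
  if (length(miss) > 0L) {
    cc_abort(sprintf("calibration file missing column(s): %s",
                     paste(miss, collapse = ", ")),
             class = "format_error")
  }
  x$n_points <- as.integer(x$n_points)
  if (!"primary" %in% names(x)) x$primary <- TRUE
  if (!"flag" %in% names(x)) {
    x$flag <- ifelse(x$sensitivity > 0, "ok", "non_positive_sensitivity")
  }
  class(x) <- c("cc_calibration", class(x))
  x
}

#' @method tidy cc_calibration
#' @export
tidy.cc_calibration <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "data") <- NULL
  out
}

#' @method glance cc_calibration
#' @export
glance.cc_calibration <- function(x, ...) {
  tibble::tibble(
    n_channels = nrow(x),
    n_points = max(x$n_points),
    n_flagged = sum(x$flag != "ok"),
    median_rel_sd_sensitivity =
      stats::median(sqrt(x$var_sensitivity) / abs(x$sensitivity))
  )
}

#' Plot fitted calibration lines
#'
#' Calibration points and the fitted line per mass channel, facetted.
#' Available when the object was produced by [fit_calibrations()] (the
#' points are carried in the `data` attribute).
#'
#' @param object A `cc_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cc_calibration
#' @export
autoplot.cc_calibration <- function(object, ...) {
  pts <- attr(object, "data")
  if (is.null(pts)) {
    cc_abort("no calibration points attached; refit with fit_calibrations()",
             class = "value_error")
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$dilution, y = .data$intensity)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(
      data = tibble::as_tibble(object),
      ggplot2::aes(intercept = .data$background, slope = .data$sensitivity),
      colour = "steelblue"
    ) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "dilution factor", y = "intensity (cps)")
}
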