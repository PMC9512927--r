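# Inverse prediction: from a measured intensity back through the fitted
# calibration line to a dilution-factor estimate, then to a concentration.
#
# r = (I - b)/s is the sample's dilution factor with respect to the main
# calibration standard mixture; c = r * C0 converts to concentration. The
# standard deviation is first-order (delta-method) propagation treating the
# sample intensity and the parameter estimates (b, s) as independent:
#   sd_r^2 = (sigma^2/m + var_b + r^2*var_s + 2*r*cov_bs) / s^2
# where m intensities were averaged into I.

#' Invert a fitted calibration for one intensity
#'
#' @param calibration A one-row `cc_calibration` (or any list/row carrying
#'   `background`, `sensitivity`, `residual_sd`, `var_background`,
#'   `var_sensitivity`, `cov_bg_sens`, `flag`).
#' @param intensity Measured (or replicate-averaged) intensity, cps.
#' @param m Number of intensity replicates averaged into `intensity`.
#' @return A list with `dilution_estimate` and `sd`; if sampling noise
#'   makes the propagated variance negative it is clamped to zero with a
#'   warning.
#' @examples
#' cal <- fit_element_calibration(c(0, 0.5, 1), c(10, 60, 110))
#' invert_intensity(cal, 60)
#' @export
invert_intensity <- function(calibration, intensity, m = 1L) {
  if (!is.null(calibration$flag) &&
      any(calibration$flag == "non_positive_sensitivity")) {
    cc_abort("channel flagged non_positive_sensitivity; refusing to invert",
             class = "value_error")
  }
  if (any(calibration$sensitivity == 0)) {
    cc_abort("zero sensitivity; calibration cannot be inverted", class = "value_error")
  }
  if (m < 1L) cc_abort("replicate count m must be >= 1", class = "value_error")
  r <- (intensity - calibration$background) / calibration$sensitivity
  bracket <- calibration$residual_sd^2 / m + calibration$var_background +
    r^2 * calibration$var_sensitivity + 2 * r * calibration$cov_bg_sens
  if (any(bracket < 0)) {
    warning("negative propagated variance clamped to zero", call. = FALSE)
    bracket <- pmax(bracket, 0)
  }
  list(dilution_estimate = r, sd = sqrt(bracket) / abs(calibration$sensitivity))
}

quantify_flags <- function(r, conc, s_flag) {
  dplyr::case_when(
    s_flag != "ok" ~ "non_positive_sensitivity",
    conc < 0 ~ "below_background",
    r > 1 ~ "extrapolated_above_standard",
    TRUE ~ "ok"
  )
}

#' Quantify assay samples
#'
#' Estimates, for every assay sample and every calibrated channel, the
#' dilution factor of the analyte with respect to the main mixture and the
#' concentration `c = r * C0` with its propagated standard deviation.
#' Estimates with `r > 1` extrapolate above the undiluted standard and are
#' flagged but reported (such estimates remain usable); intensities below
#' the fitted background yield negative concentrations, flagged
#' `below_background` and reported unclamped so that downstream averaging
#' stays unbiased. Channels with non-positive fitted sensitivity are
#' refused: their rows carry `NA` estimates and the
#' `non_positive_sensitivity` flag.
#'
#' @param survey A `cc_survey` holding the samples to quantify (assay-role
#'   rows; calibration-role rows are ignored), restricted or not to
#'   calibrated channels.
#' @param calibrations A `cc_calibration` tibble.
#' @param m Replicate count behind each stored intensity (default 1).
#' @return A tibble of class `cc_estimates`, one row per
#'   (sample, calibrated channel): `sample_id`, `channel`, `element`,
#'   `primary`, `dilution_estimate`, `concentration` (ug/L), `sd` (ug/L),
#'   `m`, `flag`.
#' @export
quantify <- function(survey, calibrations, m = 1L) {
  stopifnot(inherits(survey, "cc_survey"), inherits(calibrations, "cc_calibration"))
  assay <- tibble::as_tibble(survey)[survey$role == "assay", ]
  chans <- intersect(survey_channels(survey), calibrations$channel)
  missing <- setdiff(survey_channels(survey), calibrations$channel)
  if (length(missing) > 0L) {
    cc_abort(
      sprintf("no calibration for channel(s): %s", paste(missing, collapse = ", ")),
      class = "value_error"
    )
  }
  if (length(chans) == 0L) {
    cc_abort("no survey channel has a calibration", class = "value_error")
  }
  long <- tidyr::pivot_longer(
    assay[c("sample_id", chans)], -"sample_id",
    names_to = "channel", values_to = "intensity"
  )
  cal <- tibble::as_tibble(calibrations)
  attr(cal, "data") <- NULL
  long <- dplyr::left_join(long, cal, by = "channel")
  ok <- long$flag == "ok"
  r <- sd_r <- rep(NA_real_, nrow(long))
  if (any(ok)) {
    inv <- invert_intensity(
      list(
        background = long$background[ok], sensitivity = long$sensitivity[ok],
        residual_sd = long$residual_sd[ok],
        var_background = long$var_background[ok],
        var_sensitivity = long$var_sensitivity[ok],
        cov_bg_sens = long$cov_bg_sens[ok], flag = "ok"
      ),
      long$intensity[ok], m = m
    )
    r[ok] <- inv$dilution_estimate
    sd_r[ok] <- inv$sd
  }
  out <- tibble::tibble(
    sample_id = long$sample_id,
    channel = long$channel,
    element = long$element,
    primary = long$primary,
    dilution_estimate = r,
    concentration = r * long$c0,
    sd = sd_r * long$c0,
    m = as.integer(m),
    flag = quantify_flags(r, r * long$c0, long$flag)
  )
  class(out) <- c("cc_estimates", class(out))
  out
}

#' Quantify from pooled intensities
#'
#' Averages the intensities of a set of samples channel by channel first,
#' then inverts the calibration once with `m` equal to the pool size. For
#' the linear model this equals the average of the per-sample
#' concentrations, but the standard deviation is the correct, smaller one
#' (the sample-intensity noise enters as `sigma^2/m`).
#'
#' @param survey A `cc_survey`; all its assay-role rows are pooled.
#' @param calibrations A `cc_calibration`.
#' @param id Sample id given to the pooled estimate (default
#'   `"pooled"`).
#' @return A `cc_estimates` tibble, one row per calibrated channel.
#' @export
quantify_pooled <- function(survey, calibrations, id = "pooled") {
  stopifnot(inherits(survey, "cc_survey"))
  assay <- tibble::as_tibble(survey)[survey$role == "assay", ]
  if (nrow(assay) == 0L) {
    cc_abort("no assay samples to pool", class = "value_error")
  }
  chans <- intersect(survey_channels(survey), calibrations$channel)
  pooled <- tibble::as_tibble(c(
    list(sample_id = id, role = "assay"),
    lapply(assay[chans], mean)
  ))
  class(pooled) <- c("cc_survey", class(pooled))
  quantify(pooled, calibrations, m = nrow(assay))
}

#' Write a Concentrations File
#'
#' Long-format CSV with one row per (sample, channel) estimate.
#'
#' @param estimates A `cc_estimates` tibble.
#' @param path Output path.
#' @param unit `"ppb"` (ug/L, the internal unit) or `"ppm"` (mg/L);
#'   concentrations and sds are scaled on write.
#' @return `path`, invisibly.
#' @export
write_concentrations_file <- function(estimates, path, unit = c("ppb", "ppm")) {
  unit <- match.arg(unit)
  x <- tibble::as_tibble(estimates)
  if (unit == "ppm") {
    x$concentration <- x$concentration / 1000
    x$sd <- x$sd / 1000
  }
  x$unit <- unit
  readr::write_csv(full_precision(x), path)
  invisible(path)
}

#' Read a Concentrations File
#'
#' @param path Path to a CSV written by [write_concentrations_file()].
#' @return A `cc_estimates` tibble in ug/L (ppm files are scaled back).
#' @export
read_concentrations_file <- function(path) {
  if (!file.exists(path)) {
    cc_abort(sprintf("no such file: %s", path), class = "io_error")
  }
  x <- read_csv_precise(path)
  need <- c("sample_id", "element", "concentration", "sd", "flag")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    cc_abort(sprintf("concentrations file missing column(s): %s",
                     paste(miss, collapse = ", ")),
             class = "format_error")
  }
  if ("m" %in% names(x)) x$m <- as.integer(x$m)
  if ("unit" %in% names(x) && any(x$unit == "ppm")) {
    ppm <- x$unit == "ppm"
    x$concentration[ppm] <- x$concentration[ppm] * 1000
    x$sd[ppm] <- x$sd[ppm] * 1000
    x$unit <- "ppb"
  }
  class(x) <- c("cc_estimates", class(x))
  x
}

#' Plot concentration estimates
#'
#' Point-and-error-bar display of primary-channel estimates per element.
#'
#' @param object A `cc_estimates` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cc_estimates
#' @export
autoplot.cc_estimates <- function(object, ...) {
  x <- tibble::as_tibble(object)
  if ("primary" %in% names(x)) x <- x[is.na(x$primary) | x$primary, ]
  ggplot2::ggplot(
    x, ggplot2::aes(x = .data$sample_id, y = .data$concentration)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$concentration - .data$sd,
                   ymax = .data$concentration + .data$sd),
      linewidth = 0.3, size = 0.3
    ) +
    ggplot2::facet_wrap(~element, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "concentration (µg/L)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
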