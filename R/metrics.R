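# Leachate time-series summaries and the XRF normalization arithmetic.
#
# These operate on long concentration tables (element, condition columns,
# timestamp, concentration, sd) such as a Concentrations File joined with
# sample metadata.

#' Time-averaged concentrations from pooled intensities
#'
#' Averages the survey intensities of each sample group first and inverts
#' the calibration once per group (the averages are computed directly from
#' the Survey Intensities and only then translated via the calibration
#' curves), which for the linear model equals averaging per-sample
#' concentrations but with the correct pooled standard deviation.
#'
#' @param survey A `cc_survey` of assay samples.
#' @param calibrations A `cc_calibration`.
#' @param meta Data frame with `sample_id` plus grouping columns.
#' @param ... Grouping columns in `meta` (tidy-select, e.g.
#'   `treatment, water_type`).
#' @return A `cc_estimates` tibble, one row per (group, channel), with the
#'   grouping columns prepended and `sample_id` a collapsed group label.
#' @export
time_averaged <- function(survey, calibrations, meta, ...) {
  stopifnot(inherits(survey, "cc_survey"))
  meta <- tibble::as_tibble(meta)
  keys <- dplyr::distinct(dplyr::select(meta, ...))
  if (ncol(keys) == 0L) {
    cc_abort("supply at least one grouping column", class = "value_error")
  }
  out <- purrr::pmap_dfr(keys, function(...) {
    key <- tibble::tibble(...)
    ids <- dplyr::semi_join(meta, key, by = names(key))$sample_id
    sub <- tibble::as_tibble(survey)[survey$sample_id %in% ids & survey$role == "assay", ]
    if (nrow(sub) == 0L) return(NULL)
    class(sub) <- c("cc_survey", class(sub))
    est <- quantify_pooled(sub, calibrations,
                           id = paste(unlist(key), collapse = "/"))
    dplyr::bind_cols(key[rep(1L, nrow(est)), , drop = FALSE], est)
  })
  class(out) <- c("cc_estimates", class(out))
  out
}

#' Concentration change between last and first measurements
#'
#' For each group (element and condition), the absolute time-dependent
#' variation `delta = c_last - c_first`, with
#' `sd = sqrt(sd_last^2 + sd_first^2)` (measurements assumed independent).
#'
#' @param data Long tibble with columns `timestamp`, `concentration`, `sd`
#'   plus grouping columns.
#' @param ... Grouping columns (tidy-select), e.g. `element, treatment`.
#' @return A tibble with one row per group: `delta`, `sd`, `t_first`,
#'   `t_last`.
#' @export
delta_last_first <- function(data, ...) {
  x <- dplyr::arrange(tibble::as_tibble(data), .data$timestamp)
  out <- dplyr::summarise(
    x,
    n_points = dplyr::n(),
    t_first = dplyr::first(.data$timestamp),
    t_last = dplyr::last(.data$timestamp),
    delta = dplyr::last(.data$concentration) - dplyr::first(.data$concentration),
    sd = sqrt(dplyr::last(.data$sd)^2 + dplyr::first(.data$sd)^2),
    .by = c(...)
  )
  if (any(out$n_points < 2L)) {
    cc_abort("a series needs at least 2 time points for a last-minus-first change",
             class = "value_error")
  }
  dplyr::select(out, -"n_points")
}

#' Relative deviation between two treatment series
#'
#' Per timestamp, `(c_bs - c_ba)/c_ba` with first-order propagated sd
#' (series independent); positive values mean the biostimulated
#' concentration exceeds the bioaugmented one. Series are compared on the
#' intersection of their timestamps; non-shared timestamps are dropped
#' with a warning. Timestamps where the denominator is not positive give
#' `NA` with flag `"undefined_denominator"`.
#'
#' @param bs,ba Tibbles with columns `element`, `timestamp`,
#'   `concentration`, `sd`.
#' @return A tibble with `element`, `timestamp`, `rel_dev`, `sd`, `flag`.
#' @export
relative_deviation <- function(bs, ba) {
  bs <- tibble::as_tibble(bs)
  ba <- tibble::as_tibble(ba)
  key <- c("element", "timestamp")
  joined <- dplyr::inner_join(
    dplyr::rename(bs[c(key, "concentration", "sd")],
                  c_bs = "concentration", sd_bs = "sd"),
    dplyr::rename(ba[c(key, "concentration", "sd")],
                  c_ba = "concentration", sd_ba = "sd"),
    by = key
  )
  if (nrow(joined) == 0L) {
    cc_abort("the two series share no (element, timestamp) keys",
             class = "value_error")
  }
  dropped <- nrow(bs) + nrow(ba) - 2L * nrow(joined)
  if (dropped > 0L) {
    warning(sprintf("%d non-shared (element, timestamp) rows dropped", dropped),
            call. = FALSE)
  }
  ok <- joined$c_ba > 0
  rel <- ifelse(ok, (joined$c_bs - joined$c_ba) / joined$c_ba, NA_real_)
  # delta method: var = (sd_bs/c_ba)^2 + (c_bs*sd_ba/c_ba^2)^2
  sd <- ifelse(
    ok,
    sqrt((joined$sd_bs / joined$c_ba)^2 +
           (joined$c_bs * joined$sd_ba / joined$c_ba^2)^2),
    NA_real_
  )
  tibble::tibble(
    element = joined$element,
    timestamp = joined$timestamp,
    rel_dev = rel,
    sd = sd,
    flag = ifelse(ok, "ok", "undefined_denominator")
  )
}

#' Normalize an abundance series to its last measurement
#'
#' Used for XRF relative abundances when the first measurement is below
#' the detection limit: each value is divided by the last, so the final
#' value is exactly 1.
#'
#' @param x Numeric vector ordered in time.
#' @return `x / x[length(x)]`.
#' @examples
#' normalize_to_last(c(2, 3, 4))
#' @export
normalize_to_last <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  last <- x[length(x)]
  if (!is.finite(last) || last <= 0) {
    cc_abort("last measurement must be > 0 to normalize", class = "value_error")
  }
  x / last
}

#' Normalize XRF abundance tables to the last measurement
#'
#' @param data Tibble with columns `element`, `timestamp`, `abundance`.
#' @return The input with an added `rel_abundance` column, normalized per
#'   element.
#' @export
xrf_normalize <- function(data) {
  x <- dplyr::arrange(tibble::as_tibble(data), .data$element, .data$timestamp)
  dplyr::mutate(x, rel_abundance = normalize_to_last(.data$abundance),
                .by = "element")
}

#' Plot concentration time series
#'
#' @param data Long tibble with `element`, `timestamp`, `concentration`,
#'   `sd` and optionally condition columns mapped via `colour`.
#' @param colour Optional column (tidy-select) mapped to colour.
#' @return A ggplot object.
#' @export
plot_series <- function(data, colour = NULL) {
  p <- ggplot2::ggplot(
    tibble::as_tibble(data),
    ggplot2::aes(x = .data$timestamp, y = .data$concentration,
                 colour = {{ colour }})
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$concentration - .data$sd,
                   ymax = .data$concentration + .data$sd),
      size = 0.3
    ) +
    ggplot2::facet_wrap(~element, scales = "free_y") +
    ggplot2::labs(x = "timestamp", y = "concentration (µg/L)")
  p
}
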