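# The external-standard specification: composition of the main calibration
# standard mixture, the dilution series prepared from it, and the mapping
# from mass channels to elements.

#' Construct a calibration design
#'
#' @param mixture Tibble/data frame with columns `element` and `c0`
#'   (concentration of the element in the undiluted main mixture, ug/L).
#' @param dilutions Tibble with columns `sample_id` and `dilution`
#'   (dilution factor d in `[0, 1]`; d = 1 is the undiluted mixture, d = 0
#'   a blank).
#' @param channels Tibble with columns `channel`, `element` and logical
#'   `primary` (exactly one primary channel per quantified element).
#' @return A list of class `cc_design` with elements `mixture`, `dilutions`
#'   and `channels`.
#' @export
calibration_design <- function(mixture, dilutions, channels) {
  mixture <- tibble::as_tibble(mixture)
  dilutions <- tibble::as_tibble(dilutions)
  channels <- tibble::as_tibble(channels)
  stopifnot(
    all(c("element", "c0") %in% names(mixture)),
    all(c("sample_id", "dilution") %in% names(dilutions)),
    all(c("channel", "element", "primary") %in% names(channels))
  )
  if (any(!is.finite(mixture$c0) | mixture$c0 <= 0)) {
    cc_abort("every mixture concentration C0 must be > 0", class = "config_error")
  }
  if (anyDuplicated(mixture$element)) {
    cc_abort("duplicate element in mixture composition", class = "config_error")
  }
  d <- dilutions$dilution
  if (any(!is.finite(d) | d < 0 | d > 1)) {
    cc_abort("dilution factors must lie in [0, 1]", class = "design_error")
  }
  if (length(unique(d)) < 3L) {
    cc_abort("calibration design needs at least 3 distinct dilution factors",
             class = "design_error")
  }
  parse_channels(channels$channel)
  prim <- channels[channels$primary, ]
  missing_el <- setdiff(prim$element, mixture$element)
  if (length(missing_el) > 0L) {
    cc_abort(
      sprintf("primary channel declared for element(s) absent from the mixture: %s",
              paste(missing_el, collapse = ", ")),
      class = "config_error"
    )
  }
  if (anyDuplicated(prim$element)) {
    cc_abort("more than one primary channel for an element", class = "config_error")
  }
  structure(
    list(mixture = mixture, dilutions = dilutions, channels = channels),
    class = "cc_design"
  )
}

#' Read a standards configuration
#'
#' Parses the YAML description of the external standards: the main-mixture
#' composition (either a direct `c0` in ug/L, or a CRM `stock`
#' concentration with the `dilution` of that stock into the mixture, so
#' that `c0 = stock * dilution`), the dilution series of calibration
#' samples, the mass-channel-to-element map, and the designated primary
#' channel per element.
#'
#' @param path Path to the YAML file with keys `mixture`, `dilution_series`,
#'   `channel_map` and `primary_channels`.
#' @return A `cc_design` object.
#' @export
read_standards_config <- function(path) {
  if (!file.exists(path)) {
    cc_abort(sprintf("no such file: %s", path), class = "io_error")
  }
  cfg <- yaml::read_yaml(path)
  need <- c("mixture", "dilution_series", "channel_map", "primary_channels")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0L) {
    cc_abort(sprintf("standards config missing key(s): %s",
                     paste(miss, collapse = ", ")),
             class = "config_error")
  }
  mixture <- purrr::map_dfr(cfg$mixture, function(entry) {
    c0 <- if (!is.null(entry$c0)) {
      as.numeric(entry$c0)
    } else if (!is.null(entry$stock) && !is.null(entry$dilution)) {
      as.numeric(entry$stock) * as.numeric(entry$dilution)
    } else {
      cc_abort(
        sprintf("mixture entry for %s needs either `c0` or `stock` + `dilution`",
                entry$element %||% "<unnamed>"),
        class = "config_error"
      )
    }
    tibble::tibble(element = as.character(entry$element), c0 = c0)
  })
  dilutions <- tibble::tibble(
    sample_id = names(cfg$dilution_series),
    dilution = as.numeric(unlist(cfg$dilution_series))
  )
  channels <- tibble::tibble(
    channel = names(cfg$channel_map),
    element = as.character(unlist(cfg$channel_map))
  )
  prim <- tibble::tibble(
    element = names(cfg$primary_channels),
    channel = as.character(unlist(cfg$primary_channels))
  )
  bad <- setdiff(prim$channel, channels$channel)
  if (length(bad) > 0L) {
    cc_abort(sprintf("primary channel(s) not in channel_map: %s",
                     paste(bad, collapse = ", ")),
             class = "config_error")
  }
  channels$primary <- channels$channel %in% prim$channel
  calibration_design(mixture, dilutions, channels)
}

#' Write a standards configuration
#'
#' Serializes a `cc_design` to the YAML layout read by
#' [read_standards_config()].
#'
#' @param design A `cc_design` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_standards_config <- function(design, path) {
  stopifnot(inherits(design, "cc_design"))
  prim <- design$channels[design$channels$primary, ]
  cfg <- list(
    mixture = purrr::pmap(design$mixture, function(element, c0) {
      list(element = element, c0 = c0)
    }),
    dilution_series = stats::setNames(
      as.list(design$dilutions$dilution), design$dilutions$sample_id
    ),
    channel_map = stats::setNames(
      as.list(design$channels$element), design$channels$channel
    ),
    primary_channels = stats::setNames(as.list(prim$channel), prim$element)
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @export
print.cc_design <- function(x, ...) {
  cat(sprintf(
    "<Calibration design: %d elements, %d calibration samples (%d dilution levels), %d channels>\n",
    nrow(x$mixture), nrow(x$dilutions), length(unique(x$dilutions$dilution)),
    nrow(x$channels)
  ))
  invisible(x)
}
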