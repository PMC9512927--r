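# Survey Intensities: the wide per-sample, per-mass-channel intensity table
# exported after a preliminary scanning-mode sweep.

#' Construct and validate a survey-intensity table
#'
#' A survey-intensity table is a tibble with one row per sample: a
#' `sample_id` column, a `role` column (`"calibration"` or `"assay"`), and
#' one numeric column per mass channel (labels like `"27Al"`). Intensities
#' are counts per second and must be finite and non-negative.
#'
#' @param x A data frame with columns `sample_id`, `role` and one numeric
#'   column per mass channel.
#' @return A validated tibble of class `cc_survey`.
#' @export
survey_intensities <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("sample_id", "role") %in% names(x))) {
    cc_abort("survey table needs `sample_id` and `role` columns",
             class = "format_error")
  }
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) {
    cc_abort(
      sprintf("duplicate sample id(s): %s",
              paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", ")),
      class = "format_error"
    )
  }
  if (!all(x$role %in% c("calibration", "assay"))) {
    cc_abort("every sample role must be \"calibration\" or \"assay\"",
             class = "format_error")
  }
  chans <- survey_channels(x)
  if (length(chans) == 0L) {
    cc_abort("survey table has no mass-channel columns", class = "format_error")
  }
  if (anyDuplicated(chans)) {
    cc_abort(
      sprintf("duplicate mass channel(s): %s",
              paste(unique(chans[duplicated(chans)]), collapse = ", ")),
      class = "format_error"
    )
  }
  parse_channels(chans)  # validates the label grammar
  for (ch in chans) {
    v <- x[[ch]]
    if (!is.numeric(v)) {
      cc_abort(sprintf("channel %s is not numeric", ch), class = "value_error")
    }
    bad <- !is.finite(v) | v < 0
    if (any(bad)) {
      i <- which(bad)[1L]
      cc_abort(
        sprintf("invalid intensity at sample %s, channel %s: %s",
                x$sample_id[i], ch, format(v[i])),
        class = "value_error"
      )
    }
  }
  class(x) <- c("cc_survey", class(x))
  x
}

#' Read a Survey Intensities file
#'
#' Reads the wide CSV exported from a survey scan (first column sample id,
#' remaining header fields mass-channel labels) and assigns each sample a
#' role by matching its id against glob patterns.
#'
#' @param path Path to the CSV file.
#' @param role_rule Glob pattern(s); sample ids matching any pattern get
#'   role `"calibration"`, all others `"assay"`. Default `"cal_*"`.
#' @param overrides Optional named character vector of explicit roles,
#'   `c(sample_id = "calibration")`, taking precedence over `role_rule`.
#' @param sample_col Name or index of the sample-id column (vendor exports
#'   vary); default the first column.
#' @return A tibble of class `cc_survey`; row and channel order follow the
#'   file.
#' @export
read_survey_intensities <- function(path, role_rule = "cal_*",
                                    overrides = NULL, sample_col = 1L) {
  if (!file.exists(path)) {
    cc_abort(sprintf("no such file: %s", path), class = "io_error")
  }
  raw <- read_csv_precise(path)
  nm <- names(raw)
  if (anyDuplicated(nm)) {
    cc_abort(
      sprintf("duplicate column header(s): %s",
              paste(unique(nm[duplicated(nm)]), collapse = ", ")),
      class = "format_error"
    )
  }
  id_col <- if (is.numeric(sample_col)) nm[sample_col] else sample_col
  ids <- as.character(raw[[id_col]])
  body <- raw[setdiff(nm, id_col)]
  role <- ifelse(
    Reduce(`|`, lapply(utils::glob2rx(role_rule), grepl, x = ids)),
    "calibration", "assay"
  )
  if (!is.null(overrides)) {
    hit <- match(names(overrides), ids)
    role[hit[!is.na(hit)]] <- overrides[!is.na(hit)]
  }
  survey_intensities(
    tibble::tibble(sample_id = ids, role = role, !!!body)
  )
}

#' Write a Survey Intensities file
#'
#' Writes the wide CSV form read back by [read_survey_intensities()]; the
#' `role` column is dropped (roles are reassigned on read). Values round
#' trip at full double precision.
#'
#' @param survey A `cc_survey` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey_intensities <- function(survey, path) {
  stopifnot(inherits(survey, "cc_survey"))
  readr::write_csv(full_precision(dplyr::select(tibble::as_tibble(survey), -"role")), path)
  invisible(path)
}

#' @export
print.cc_survey <- function(x, ...) {
  chans <- survey_channels(x)
  cat(sprintf(
    "<Survey Intensities: %d samples (%d calibration, %d assay) x %d mass channels>\n",
    nrow(x), sum(x$role == "calibration"), sum(x$role == "assay"), length(chans)
  ))
  NextMethod()
}
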