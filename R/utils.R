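# Internal helpers.

cc_abort <- function(message, class, ...) {
  rlang::abort(message, class = paste0("compcal_", class), ...)
}

#' Mass-channel columns of a survey table
#'
#' @param survey A `cc_survey` tibble.
#' @return Character vector of channel labels, in column order (everything
#'   except `sample_id` and `role`).
#' @export
survey_channels <- function(survey) {
  setdiff(names(survey), c("sample_id", "role"))
}

`%||%` <- rlang::`%||%`

# Format double columns with 17 significant digits so CSV round trips are
# bit-exact (the default shortest-representation writer keeps only 15).
full_precision <- function(df) {
  df[] <- lapply(df, function(v) if (is.double(v)) sprintf("%.17g", v) else v)
  df
}

# Read a CSV with exact double parsing: the fast vroom parser can be off in
# the last bit, so parse everything as character and convert through R's
# correctly-rounded strtod.
read_csv_precise <- function(path) {
  x <- readr::read_csv(path, progress = FALSE, name_repair = "minimal",
                       col_types = readr::cols(.default = readr::col_character()))
  x[] <- lapply(x, function(v) {
    out <- utils::type.convert(v, as.is = TRUE)
    if (is.integer(out)) out <- as.double(out)  # columns stay double
    out
  })
  x
}
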