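# Downstream screening: cross-checking element panels between runs,
# significance filtering of trace-level estimates, and validation against
# the precise peak-hopping quantification.

#' Cross-check element panels between two runs
#'
#' Two measurement runs (e.g. the two growth-medium experiments) may use
#' external standards with different element panels; only elements present
#' in both standards are comparable, the rest are excluded.
#'
#' @param panel_a,panel_b Character vectors of element symbols.
#' @return A tibble with columns `element`, `in_a`, `in_b` and `decision`
#'   (`"kept"` for the intersection, `"excluded_not_common"` otherwise).
#'   The kept elements are also available as attribute `common`.
#' @examples
#' cross_check_elements(c("Al", "Cu", "Zn", "Fe"), c("Al", "Cu", "Mg"))
#' @export
cross_check_elements <- function(panel_a, panel_b) {
  all_el <- union(panel_a, panel_b)
  out <- tibble::tibble(
    element = all_el,
    in_a = all_el %in% panel_a,
    in_b = all_el %in% panel_b,
    decision = ifelse(all_el %in% panel_a & all_el %in% panel_b,
                      "kept", "excluded_not_common")
  )
  attr(out, "common") <- out$element[out$decision == "kept"]
  out
}

#' Significance filter for element estimates
#'
#' An element whose estimated standard deviation is in the range of its
#' estimated concentration carries no usable quantitative signal and is
#' excluded. Operationally: summarise the per-sample primary-channel
#' estimates of a run per element (median by default) and exclude when
#' `sd >= rho * |c|` or `c <= 0`.
#'
#' @param estimates A `cc_estimates` tibble (one run).
#' @param rho Threshold ratio, default 1.
#' @param summarise Function collapsing per-sample values to a run-level
#'   value; default [stats::median()].
#' @return A tibble with columns `element`, `concentration`, `sd`
#'   (run-level summaries) and `decision`
#'   (`"kept"` or `"excluded_insignificant"`).
#' @export
significance_filter <- function(estimates, rho = 1, summarise = stats::median) {
  stopifnot(rho > 0)
  x <- tibble::as_tibble(estimates)
  if ("primary" %in% names(x)) x <- x[is.na(x$primary) | x$primary, ]
  x <- x[is.finite(x$concentration) & is.finite(x$sd), ]
  out <- dplyr::summarise(
    x,
    concentration = summarise(.data$concentration),
    sd = summarise(.data$sd),
    .by = "element"
  )
  out$decision <- ifelse(
    out$sd >= rho * abs(out$concentration) | out$concentration <= 0,
    "excluded_insignificant", "kept"
  )
  out
}

#' Compare compressed-calibration and peak-hopping concentrations
#'
#' For every (sample, element) present in both tables, the difference
#' between the two methods' concentrations is divided by the
#' compressed-calibration standard deviation; agreement is declared when
#' `|z|` is within the critical value `k` (default three standard
#' deviations).
#'
#' @param cc A `cc_estimates` tibble (primary channels are used).
#' @param ph Peak-hopping concentrations: a data frame with columns
#'   `sample_id`, `element`, `concentration` (same unit as `cc`).
#' @param k Critical value, default 3.
#' @return A tibble with one row per matching (sample, element):
#'   `z = (c_cc - c_ph)/sd_cc` and logical `pass`. A zero `sd_cc` with
#'   unequal concentrations yields an infinite `z` and a fail. The
#'   per-element maximum `|z|` is attached as attribute `summary`.
#' @export
compare_methods <- function(cc, ph, k = 3) {
  stopifnot(k > 0)
  x <- tibble::as_tibble(cc)
  if ("primary" %in% names(x)) x <- x[is.na(x$primary) | x$primary, ]
  ph <- tibble::as_tibble(ph)
  joined <- dplyr::inner_join(
    x[c("sample_id", "element", "concentration", "sd")],
    dplyr::rename(ph[c("sample_id", "element", "concentration")],
                  concentration_ph = "concentration"),
    by = c("sample_id", "element")
  )
  if (nrow(joined) == 0L) {
    cc_abort("no matching (sample, element) keys between the two methods",
             class = "value_error")
  }
  diff <- joined$concentration - joined$concentration_ph
  z <- ifelse(joined$sd > 0, diff / joined$sd,
              ifelse(diff == 0, 0, Inf * sign(diff)))
  out <- tibble::tibble(
    sample_id = joined$sample_id,
    element = joined$element,
    concentration_cc = joined$concentration,
    sd_cc = joined$sd,
    concentration_ph = joined$concentration_ph,
    z = z,
    pass = is.finite(z) & abs(z) <= k
  )
  attr(out, "summary") <- dplyr::summarise(
    out, max_abs_z = max(abs(.data$z)), all_pass = all(.data$pass),
    .by = "element"
  )
  out
}

#' Build a screening report for two runs
#'
#' Chains the statistical-analysis pipeline: panel cross-check between the
#' two runs' standards, run-wise significance filtering of the estimates,
#' and (optionally) the three-standard-deviation comparison against
#' peak-hopping concentrations for the surviving elements.
#'
#' @param estimates_a,estimates_b `cc_estimates` for the two runs.
#' @param ph Optional peak-hopping table (see [compare_methods()]).
#' @param rho,k Thresholds passed through.
#' @return A list of class `cc_screening` with elements `decisions`
#'   (element, decision, with cross-check losses taking precedence over
#'   insignificance), `z_scores` (or `NULL`).
#' @export
screening_report <- function(estimates_a, estimates_b, ph = NULL,
                             rho = 1, k = 3) {
  cross <- cross_check_elements(unique(estimates_a$element),
                                unique(estimates_b$element))
  common <- attr(cross, "common")
  sig_a <- significance_filter(estimates_a, rho = rho)
  sig_b <- significance_filter(estimates_b, rho = rho)
  decisions <- cross[c("element", "decision")]
  insig <- union(
    sig_a$element[sig_a$decision != "kept"],
    sig_b$element[sig_b$decision != "kept"]
  )
  sel <- decisions$decision == "kept" & decisions$element %in% insig
  decisions$decision[sel] <- "excluded_insignificant"
  kept <- decisions$element[decisions$decision == "kept"]
  z <- NULL
  if (!is.null(ph)) {
    both <- rbind(tibble::as_tibble(estimates_a), tibble::as_tibble(estimates_b))
    both <- both[both$element %in% kept, ]
    z <- compare_methods(both, ph, k = k)
  }
  structure(list(decisions = decisions, z_scores = z, rho = rho, k = k),
            class = "cc_screening")
}

#' @export
print.cc_screening <- function(x, ...) {
  tab <- table(x$decisions$decision)
  cat("<Screening report>\n")
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  if (!is.null(x$z_scores)) {
    cat(sprintf("  cross-method: %d/%d pairs within %.1f sd\n",
                sum(x$z_scores$pass), nrow(x$z_scores), x$k))
  }
  invisible(x)
}

#' Read peak-hopping concentrations
#'
#' @param path Long-format CSV with columns `sample_id`, `element`,
#'   `concentration`.
#' @return A tibble.
#' @export
read_peak_hopping <- function(path) {
  if (!file.exists(path)) {
    cc_abort(sprintf("no such file: %s", path), class = "io_error")
  }
  x <- read_csv_precise(path)
  miss <- setdiff(c("sample_id", "element", "concentration"), names(x))
  if (length(miss) > 0L) {
    cc_abort(sprintf("peak-hopping file missing column(s): %s",
                     paste(miss, collapse = ", ")),
             class = "format_error")
  }
  x
}
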