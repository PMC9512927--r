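# Synthetic survey-scan generator with known ground truth.
#
# Emulates the structure of a column bioleaching study: one measurement run
# per growth medium, treatments BS (biostimulation) and BA (bioaugmentation),
# effluent and pore-water samples at 5 timestamps, plus an external-standard
# dilution series measured in the same run. Intensities follow
# I = b* + s*·r + eps with channel-specific Gaussian noise of SD sigma*,
# independent of the dilution factor.

# Default element panel: the interfering components retained in the study
# plus trace elements detected near their standard deviations.
cc_default_panel <- c("Mg", "Si", "Al", "K", "Mn", "Fe", "Cu", "Zn", "Se",
                      "Li", "Co", "Cd", "Sr", "Ba", "Ni", "Cr", "V", "Ga",
                      "Rb", "Y")

primary_mass <- function(element) {
  # first listed stable mass, except where ICP-MS practice prefers another
  pref <- c(K = 39, Fe = 56, Se = 78, Ca = 44, Cr = 52, Cd = 111)
  if (element %in% names(pref)) return(pref[[element]])
  isotope_masses[[element]][1L]
}

# Deterministic per-channel substream seed: adding a channel never perturbs
# the draws of existing channels.
channel_seed <- function(seed, j) {
  ((seed %% 100000L) * 10007 + j * 7919) %% 2147483647
}

#' Simulate a calibration design with ground truth
#'
#' Builds an external-standard design (mixture composition, dilution
#' series, channel map) together with the ground truth needed to score
#' every downstream stage: true background, sensitivity and noise SD per
#' channel, and a true dilution-equivalent `r*` for every
#' (assay sample, element) over the study layout
#' (treatment BS/BA x water type effluent/pore x 5 timestamps). The panel
#' always contains one element at near-zero true concentration (to
#' exercise the significance filter) and one whose concentration exceeds
#' the undiluted standard (`r* > 1`, exercising the extrapolation flag).
#'
#' @param n_elements Number of elements (default 9, the size of the
#'   retained interfering-component panel: Mg, Si, Al, K, Mn, Fe, Cu, Zn,
#'   Se).
#' @param dilution_levels Dilution factors of the calibration series;
#'   default `c(1, 0.5, 0.1, 0.01, 0)` — a main calibration sample and a
#'   set of subsequent dilutions, with a blank.
#' @param seed Integer seed; identical seeds give identical designs.
#' @param elements Optional explicit element panel (overrides
#'   `n_elements`).
#' @param noise_rel True noise SD as a fraction of true sensitivity
#'   (default 0.01, survey-scan counting noise at high count rates).
#' @param medium Label stored in the sample metadata (default `"R2Ab"`).
#' @return A list of class `cc_truth`: `design` (a `cc_design`),
#'   `channels` (tibble: channel, element, b_true, s_true, sigma_true),
#'   `assay` (tibble: sample_id, treatment, water_type, timestamp,
#'   element, r_true, conc_true), `meta` (per-sample metadata), `seed`.
#' @export
simulate_design <- function(n_elements = 9, dilution_levels = c(1, 0.5, 0.1, 0.01, 0),
                            seed = 1L, elements = NULL, noise_rel = 0.01,
                            medium = "R2Ab") {
  if (is.null(elements)) {
    if (n_elements < 1 || n_elements > length(cc_default_panel)) {
      cc_abort(sprintf("n_elements must be in [1, %d]", length(cc_default_panel)),
               class = "value_error")
    }
    elements <- cc_default_panel[seq_len(n_elements)]
  }
  if (length(unique(dilution_levels)) < 3L) {
    cc_abort("need at least 3 distinct dilution levels", class = "design_error")
  }
  set.seed(seed)
  p <- length(elements)
  channels <- vapply(elements, function(e) paste0(primary_mass(e), e), "")
  c0 <- round(stats::runif(p, 50, 500), 1)            # ug/L in the mixture
  s_true <- 10^stats::runif(p, 3.5, 5)                # cps per unit d
  # blank-borne background: 5-25% of the full-standard response, well above
  # the noise SD so zero-flooring of blanks stays a rare event
  b_true <- s_true * stats::runif(p, 0.05, 0.25)
  sigma_true <- noise_rel * s_true

  treatments <- c("BS", "BA")
  waters <- c("effluent", "pore")
  timestamps <- 1:5
  meta <- tidyr::expand_grid(
    treatment = treatments, water_type = waters, timestamp = timestamps
  )
  meta$medium <- medium
  meta$sample_id <- sprintf("%s_%s_%s_t%d", medium, meta$treatment,
                            substr(meta$water_type, 1, 3), meta$timestamp)

  # Per-element smooth time profiles: base level, exponential trend, and
  # condition multipliers. Element 1 is a blank-level trace (near zero);
  # element 2 exceeds the undiluted standard at late timestamps.
  base <- stats::runif(p, 0.05, 0.9)
  trend <- stats::runif(p, -0.3, 0.3)
  base[1L] <- 0
  if (p >= 2L) {
    base[2L] <- 1.1
    trend[2L] <- 0.2
  }
  cond_mult <- function(treatment, water) {
    1 + 0.3 * (treatment == "BS") + 0.2 * (water == "pore")
  }
  assay <- tidyr::expand_grid(sample_id = meta$sample_id, element = elements)
  assay <- dplyr::left_join(assay, meta, by = "sample_id")
  idx <- match(assay$element, elements)
  assay$r_true <- base[idx] *
    exp(trend[idx] * (assay$timestamp - 1) / 4) *
    cond_mult(assay$treatment, assay$water_type)
  assay$conc_true <- assay$r_true * c0[idx]
  assay <- assay[c("sample_id", "treatment", "water_type", "timestamp",
                   "element", "r_true", "conc_true")]

  design <- calibration_design(
    mixture = tibble::tibble(element = elements, c0 = c0),
    dilutions = tibble::tibble(
      sample_id = sprintf("cal_%02d", seq_along(dilution_levels)),
      dilution = dilution_levels
    ),
    channels = tibble::tibble(channel = unname(channels), element = elements,
                              primary = TRUE)
  )
  structure(
    list(
      design = design,
      channels = tibble::tibble(channel = unname(channels), element = elements,
                                b_true = b_true, s_true = s_true,
                                sigma_true = sigma_true),
      assay = assay,
      meta = meta[c("sample_id", "medium", "treatment", "water_type", "timestamp")],
      seed = seed
    ),
    class = "cc_truth"
  )
}

#' Simulate a Survey Intensities table from ground truth
#'
#' Calibration rows use the design's dilution factors as `r`; assay rows
#' use the per-sample true dilution equivalents. Noise is Gaussian with
#' the channel's true SD, i.i.d. across samples; draws use one
#' deterministic substream per channel, so adding channels never perturbs
#' existing ones. Negative noisy intensities are floored at zero (counts
#' are physical); the number of floored values is attached as attribute
#' `n_floored`.
#'
#' @param truth A `cc_truth` from [simulate_design()].
#' @param seed Integer seed for the noise (independent of the design
#'   seed).
#' @return A `cc_survey` tibble: calibration rows first, then assay rows.
#' @export
simulate_survey <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "cc_truth"))
  ch <- truth$channels
  d <- truth$design$dilutions
  r_assay <- tidyr::pivot_wider(
    truth$assay[c("sample_id", "element", "r_true")],
    names_from = "element", values_from = "r_true"
  )
  sample_ids <- c(d$sample_id, r_assay$sample_id)
  role <- rep(c("calibration", "assay"), c(nrow(d), nrow(r_assay)))
  n <- length(sample_ids)
  n_floored <- 0L
  cols <- vector("list", nrow(ch))
  names(cols) <- ch$channel
  for (j in seq_len(nrow(ch))) {
    r <- c(d$dilution, r_assay[[ch$element[j]]])
    set.seed(channel_seed(seed, j))
    eps <- if (ch$sigma_true[j] > 0) stats::rnorm(n, 0, ch$sigma_true[j]) else numeric(n)
    intensity <- ch$b_true[j] + ch$s_true[j] * r + eps
    n_floored <- n_floored + sum(intensity < 0)
    cols[[j]] <- pmax(intensity, 0)
  }
  out <- survey_intensities(
    tibble::tibble(sample_id = sample_ids, role = role, !!!cols)
  )
  attr(out, "n_floored") <- n_floored
  out
}

#' Write a complete synthetic dataset
#'
#' Emits the Survey Intensities CSV, the standards YAML, a sample-metadata
#' CSV and a ground-truth CSV into a directory, so the command-line
#' pipeline can run on generated data unchanged.
#'
#' @param truth A `cc_truth`.
#' @param survey The matching `cc_survey`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(truth, survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_survey_intensities(survey, file.path(dir, "survey.csv"))
  write_standards_config(truth$design, file.path(dir, "standards.yml"))
  readr::write_csv(truth$meta, file.path(dir, "meta.csv"))
  readr::write_csv(truth$assay, file.path(dir, "truth.csv"))
  invisible(dir)
}
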