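# Mass-channel labels and the embedded isotope table.

# Stable (or primordial) mass numbers for elements routinely measured by
# ICP-MS; used to sanity-check channel labels such as "27Al".
isotope_masses <- list(
  Li = c(6, 7), Be = 9, B = c(10, 11), Na = 23, Mg = 24:26, Al = 27,
  Si = 28:30, P = 31, S = c(32:34, 36), K = c(39, 40, 41),
  Ca = c(40, 42, 43, 44, 46, 48), Sc = 45, Ti = 46:50, V = c(50, 51),
  Cr = c(50, 52, 53, 54), Mn = 55, Fe = c(54, 56, 57, 58), Co = 59,
  Ni = c(58, 60, 61, 62, 64), Cu = c(63, 65), Zn = c(64, 66, 67, 68, 70),
  Ga = c(69, 71), Ge = c(70, 72, 73, 74, 76), As = 75,
  Se = c(74, 76, 77, 78, 80, 82), Rb = c(85, 87),
  Sr = c(84, 86, 87, 88), Y = 89, Zr = c(90, 91, 92, 94, 96),
  Nb = 93, Mo = c(92, 94, 95, 96, 97, 98, 100), Ag = c(107, 109),
  Cd = c(106, 108, 110, 111, 112, 113, 114, 116),
  Sn = c(112, 114:120, 122, 124), Sb = c(121, 123),
  Ba = c(130, 132, 134:138), La = c(138, 139), Ce = c(136, 138, 140, 142),
  W = c(180, 182, 183, 184, 186), Pb = c(204, 206, 207, 208),
  Th = 232, U = c(234, 235, 238)
)

#' Parse mass-channel labels
#'
#' Mass channels follow the grammar `<mass number><element symbol>`, e.g.
#' `"27Al"` or `"63Cu"`. The element symbol must be a known IUPAC symbol;
#' a mass number not listed among the element's stable isotopes raises a
#' warning (it may still be a valid instrument channel, e.g. a polyatomic
#' proxy) rather than an error.
#'
#' @param channels Character vector of channel labels.
#' @return A tibble with columns `channel`, `mass` (integer) and `element`.
#' @examples
#' parse_channels(c("27Al", "63Cu"))
#' @export
parse_channels <- function(channels) {
  stopifnot(is.character(channels))
  m <- regmatches(channels, regexec("^([0-9]{1,3})([A-Z][a-z]?)$", channels))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    cc_abort(
      sprintf(
        "malformed mass-channel label(s): %s (expected e.g. \"27Al\")",
        paste(channels[bad], collapse = ", ")
      ),
      class = "format_error"
    )
  }
  mass <- as.integer(vapply(m, `[`, "", 2L))
  element <- vapply(m, `[`, "", 3L)
  unknown <- !element %in% names(isotope_masses)
  if (any(unknown)) {
    cc_abort(
      sprintf(
        "unknown element symbol in channel(s): %s",
        paste(channels[unknown], collapse = ", ")
      ),
      class = "format_error"
    )
  }
  plausible <- mapply(function(e, a) a %in% isotope_masses[[e]], element, mass)
  if (any(!plausible)) {
    warning(
      sprintf(
        "mass number not a stable isotope of its element: %s",
        paste(channels[!plausible], collapse = ", ")
      ),
      call. = FALSE
    )
  }
  tibble::tibble(channel = channels, mass = mass, element = element)
}
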