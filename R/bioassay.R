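# Deterministic assay arithmetic: extinction coefficients, Beer-Lambert
# concentrations, percent inhibition.

#' Molar extinction coefficient at 280 nm
#'
#' Sum of the chromophore contributions: tryptophan 5690, tyrosine 1280 and
#' cystine (disulfide) 120 M^-1 cm^-1. Cystines default to the
#' fully-oxidized count, `floor(nCys / 2)`.
#'
#' @param sequence peptide sequence.
#' @param n_cystines number of disulfide bonds (default fully oxidized).
#' @param eps_trp,eps_tyr,eps_cystine per-chromophore coefficients.
#' @return extinction coefficient in M^-1 cm^-1.
#' @examples
#' extinction_coefficient("NRVGVCLFVGKPCWSDADCPSGCYCKPLPLIDAGYCGFL")  # 8610
#' @export
extinction_coefficient <- function(sequence, n_cystines = NULL,
                                   eps_trp = 5690, eps_tyr = 1280,
                                   eps_cystine = 120) {
  comp <- aa_composition(sequence)
  if (is.null(n_cystines)) n_cystines <- comp[["C"]] %/% 2L
  if (n_cystines > comp[["C"]] %/% 2L)
    stop("n_cystines exceeds floor(nCys/2)")
  comp[["W"]] * eps_trp + comp[["Y"]] * eps_tyr + n_cystines * eps_cystine
}

#' Molar concentration from A280 (Beer-Lambert)
#'
#' @param a280 absorbance at 280 nm.
#' @param epsilon extinction coefficient (M^-1 cm^-1).
#' @param path_cm optical path length in cm.
#' @return concentration in mol/L.
#' @export
molar_concentration <- function(a280, epsilon, path_cm = 1) {
  if (any(epsilon <= 0)) stop("epsilon must be positive")
  if (any(path_cm <= 0)) stop("path length must be positive")
  a280 / (epsilon * path_cm)
}

#' Percent inhibition relative to total enzyme activity
#'
#' `100 * (1 - (signal - background) / (negative_control - background))`,
#' where the negative control is the uninhibited enzyme. Values outside
#' 0-100 (activation, noise) are clamped with a flag rather than rejected.
#'
#' @param signal,negative_control,background readings in consistent units
#'   (vectorized over `signal`).
#' @param clamp clamp to the 0-100 range.
#' @return numeric vector of percentages with attribute `clamped`
#'   (logical vector).
#' @examples
#' percent_inhibition(50, 100, 0)  # 50
#' @export
percent_inhibition <- function(signal, negative_control, background = 0,
                               clamp = TRUE) {
  if (any(negative_control == background))
    stop("degenerate controls: negative control equals background")
  p <- 100 * (1 - (signal - background) / (negative_control - background))
  clamped <- p < 0 | p > 100
  if (clamp) p <- pmin(pmax(p, 0), 100)
  attr(p, "clamped") <- clamped
  p
}
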