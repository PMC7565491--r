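# Monoisotopic constants (IUPAC/Unimod), 5+ decimals. Residue masses are the
# in-chain values (free amino acid minus water); average masses unsupported.

.MASS_H2O    <- 18.0105646
.MASS_PROTON <- 1.0072765
.MASS_H      <- 1.0078250
.MASS_CAM    <- 57.0214637  # carbamidomethyl, +C2H3NO on Cys thiol

.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.AA_CODES <- names(.AA_MONO)

.seq_chars <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single character string")
  if (nchar(sequence) == 0L) return(character(0))
  strsplit(toupper(sequence), "")[[1]]
}

.check_alphabet <- function(chars, context = "sequence") {
  bad <- setdiff(unique(chars), .AA_CODES)
  if (length(bad))
    stop(sprintf("non-standard residue code(s) in %s: %s",
                 context, paste(bad, collapse = ", ")))
  invisible(chars)
}

#' Monoisotopic residue mass
#'
#' Returns the in-chain (residue, not free amino acid) monoisotopic mass of
#' one-letter amino acid codes. Only the 20 standard residues are accepted;
#' note that Leu and Ile are isobaric and Lys exceeds Gln by only 0.0364 Da,
#' the two ambiguities that drive the enzymatic resolution step of the
#' de novo workflow.
#'
#' @param code character vector of one-letter residue codes.
#' @return numeric vector of masses in Da.
#' @examples
#' residue_mass("G")
#' residue_mass("K") - residue_mass("Q")
#' @export
residue_mass <- function(code) {
  code <- toupper(as.character(code))
  .check_alphabet(code, "residue code")
  unname(.AA_MONO[code])
}

#' Construct a peptide with modifications and disulfides
#'
#' A peptide is a residue string plus per-position modifications and a
#' disulfide count. Native cystine-knot peptides are assumed fully oxidized,
#' so `n_disulfides` defaults to `floor(nCys / 2)`; pass `n_disulfides = 0`
#' for free-thiol or reduced species. `cam = TRUE` is a shortcut that places
#' a carbamidomethyl (+57.02146 Da) on every Cys and sets disulfides to 0,
#' the state of peptides after reduction/alkylation.
#'
#' @param sequence single character string of one-letter codes.
#' @param modifications `NULL` or a data.frame with columns `position`,
#'   `name`, `delta_mass`.
#' @param n_disulfides number of disulfide bonds, or `NULL` for the
#'   fully-oxidized default.
#' @param cam logical; carbamidomethylate all cysteines (implies 0 disulfides
#'   unless overridden).
#' @return an object of class `crp_peptide`.
#' @examples
#' peptide("VCLFVGK", cam = TRUE)
#' @export
peptide <- function(sequence, modifications = NULL, n_disulfides = NULL,
                    cam = FALSE) {
  chars <- .seq_chars(sequence)
  .check_alphabet(chars)
  n_cys <- sum(chars == "C")
  if (cam) {
    cam_mods <- if (n_cys)
      data.frame(position = which(chars == "C"), name = "carbamidomethyl",
                 delta_mass = .MASS_CAM)
    else
      data.frame(position = integer(0), name = character(0),
                 delta_mass = numeric(0))
    modifications <- rbind(modifications, cam_mods)
    if (is.null(n_disulfides)) n_disulfides <- 0L
  }
  if (is.null(n_disulfides)) n_disulfides <- n_cys %/% 2L
  if (n_disulfides < 0 || n_disulfides > n_cys %/% 2L)
    stop("n_disulfides must lie in [0, floor(nCys/2)]")
  if (!is.null(modifications) && nrow(modifications)) {
    if (any(modifications$position < 1 | modifications$position > length(chars)))
      stop("modification position outside sequence")
  }
  structure(list(sequence = paste(chars, collapse = ""),
                 modifications = modifications,
                 n_disulfides = as.integer(n_disulfides)),
            class = "crp_peptide")
}

#' @export
print.crp_peptide <- function(x, ...) {
  m <- peptide_mass(x)
  nmod <- if (is.null(x$modifications)) 0L else nrow(x$modifications)
  cat(sprintf("crp_peptide: %s\n  %d aa, %d modification(s), %d disulfide(s), M %.4f, [M+H]+ %.4f\n",
              x$sequence, nchar(x$sequence), nmod, x$n_disulfides,
              m[["M"]], m[["MH"]]))
  invisible(x)
}

.as_peptide <- function(x, ...) {
  if (inherits(x, "crp_peptide")) x else peptide(x, ...)
}

#' Monoisotopic peptide mass
#'
#' Computes the neutral monoisotopic mass `M` and the singly protonated
#' `[M+H]+` of a peptide: the sum of residue masses plus one water, plus all
#' modification deltas, minus two hydrogens per disulfide bond. Free
#' amine/free acid termini are assumed (the linear-peptide convention).
#'
#' @param x a `crp_peptide`, or a character sequence forwarded to
#'   [peptide()].
#' @param ... passed to [peptide()] when `x` is a character string.
#' @return named numeric vector with elements `M` and `MH` (Da).
#' @examples
#' peptide_mass("VCLFVGK", cam = TRUE)["MH"]  # 822.45, the tryptic N-terminal
#' @export
peptide_mass <- function(x, ...) {
  p <- .as_peptide(x, ...)
  chars <- .seq_chars(p$sequence)
  m <- sum(.AA_MONO[chars]) + .MASS_H2O
  if (!is.null(p$modifications) && nrow(p$modifications))
    m <- m + sum(p$modifications$delta_mass)
  m <- m - p$n_disulfides * 2 * .MASS_H
  c(M = m, MH = m + .MASS_PROTON)
}

#' Mass shift from reduction and carbamidomethylation
#'
#' Reduction of each disulfide adds two hydrogens; alkylation with
#' iodoacetamide adds +57.02146 Da to every cysteine. For a fully oxidized
#' peptide with six cysteines in three disulfides the shift is 348.2 Da, the
#' fingerprint used to count cysteines in intact-mass spectra.
#'
#' @param n_cys number of cysteine residues.
#' @param n_disulfides number of disulfide bonds reduced.
#' @return shift in Da.
#' @examples
#' reduction_alkylation_shift(6, 3)  # ~348.2
#' @export
reduction_alkylation_shift <- function(n_cys, n_disulfides) {
  if (any(n_cys < 0) || any(n_disulfides < 0))
    stop("counts must be non-negative")
  if (any(n_cys < 2 * n_disulfides))
    stop("n_cys must be at least 2 * n_disulfides")
  n_disulfides * 2 * .MASS_H + n_cys * .MASS_CAM
}

#' Amino-acid composition
#'
#' Counts each of the 20 standard residues in a sequence, the comparison
#' surface for hydrolysis-based amino acid analysis.
#'
#' @param sequence single character string.
#' @return named integer vector over the 20 standard codes.
#' @export
aa_composition <- function(sequence) {
  chars <- .seq_chars(sequence)
  .check_alphabet(chars)
  tab <- table(factor(chars, levels = .AA_CODES))
  stats::setNames(as.integer(tab), .AA_CODES)
}
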