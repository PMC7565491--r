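# Seeded generators for every input class the pipeline consumes: CRP
# sequences on the knottin-like template, precursor-bearing nucleotide
# backgrounds, MALDI peak-list pairs, and b/y fragment spectra. All
# generators are pure functions of their arguments plus the seed; peak
# intensities are log-normal, mimicking the MALDI dynamic range.

.NON_CYS <- setdiff(.AA_CODES, "C")

#' Generate synthetic cysteine-rich peptides
#'
#' Draws `n` six-cysteine sequences on a loop-length template, with the P1
#' residue (second position of loop 1) set by policy: `"aromatic"` (F/Y/W,
#' the antimicrobial-branch signature), `"basic"` (R/K, the
#' trypsin-inhibitor signature) or `"random"`. With `base` given, sequences
#' are point mutants of `base` at `mutation_rate` per non-Cys position,
#' preserving the cysteine scaffold and the P1 policy -- useful for
#' planting divergent families.
#'
#' @param n number of sequences.
#' @param loops integer vector of the five inter-Cys loop lengths.
#' @param prefix_range,suffix_range `c(min, max)` flank lengths.
#' @param p1_policy `"aromatic"`, `"basic"` or `"random"`.
#' @param base optional template sequence to mutate instead of sampling.
#' @param mutation_rate per-position substitution probability when `base`
#'   is given.
#' @param seed RNG seed (identical seeds give identical output).
#' @return named character vector of sequences.
#' @export
gen_crp <- function(n, loops = c(6, 5, 3, 1, 10), prefix_range = c(1, 5),
                    suffix_range = c(0, 3),
                    p1_policy = c("aromatic", "basic", "random"),
                    base = NULL, mutation_rate = 0.1, seed = NULL) {
  p1_policy <- match.arg(p1_policy)
  if (any(loops < 0) || prefix_range[1] > prefix_range[2] ||
      suffix_range[1] > suffix_range[2])
    stop("inconsistent template bounds")
  if (loops[1] < 2 && p1_policy != "random")
    stop("loop 1 must hold a P1 residue (length >= 2)")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(stats::setNames(character(0), character(0)))
  p1_pool <- switch(p1_policy, aromatic = c("F", "Y", "W"),
                    basic = c("R", "K"), random = .NON_CYS)
  draw <- function(k) paste(sample(.NON_CYS, k, replace = TRUE),
                            collapse = "")
  out <- character(n)
  for (i in seq_len(n)) {
    if (is.null(base)) {
      pre <- draw(sample(prefix_range[1]:prefix_range[2], 1))
      suf <- draw(sample(suffix_range[1]:suffix_range[2], 1))
      lps <- vapply(loops, draw, character(1))
    } else {
      pat <- loop_pattern(base)
      chars <- .seq_chars(base)
      mut <- runif(length(chars)) < mutation_rate & chars != "C"
      chars[mut] <- vapply(which(mut), function(j)
        sample(setdiff(.NON_CYS, chars[j]), 1), character(1))
      pre <- paste(chars[seq_len(pat$prefix_len)], collapse = "")
      suf <- if (pat$suffix_len)
        paste(chars[(length(chars) - pat$suffix_len + 1):length(chars)],
              collapse = "") else ""
      lps <- vapply(seq_along(pat$loops), function(k) {
        a <- pat$cys_pos[k] + 1L; b <- pat$cys_pos[k + 1L] - 1L
        if (b < a) "" else paste(chars[a:b], collapse = "")
      }, character(1))
    }
    if (p1_policy != "random") {
      p1 <- sample(p1_pool, 1)
      substr(lps[1], 2, 2) <- p1
    }
    out[i] <- paste0(pre, paste0("C", lps, collapse = ""), "C", suf)
  }
  stats::setNames(out, sprintf("syn%03d", seq_len(n)))
}

.CODONS <- local({
  bases <- c("T", "C", "A", "G")
  # standard-table order: third base fastest, first base slowest
  eg <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                    stringsAsFactors = FALSE)
  codons <- paste0(eg$b1, eg$b2, eg$b3)
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  split(codons, aa)
})

#' Reverse-translate a peptide with random synonymous codons
#'
#' @param aa peptide sequence.
#' @param seed RNG seed.
#' @return nucleotide string, length `3 * nchar(aa)`.
#' @export
reverse_translate <- function(aa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- .seq_chars(aa)
  .check_alphabet(chars)
  paste(vapply(chars, function(a) {
    pool <- .CODONS[[a]]
    pool[sample.int(length(pool), 1)]
  }, character(1)), collapse = "")
}

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Plant CRP coding segments in a random nucleotide background
#'
#' Reverse-translates each peptide with uniformly sampled synonymous
#' codons and embeds it at a random, non-overlapping position on a random
#' strand of a uniform-random ACGT background. The truth table records
#' where and how each precursor was planted.
#'
#' @param crps named character vector of peptide sequences.
#' @param background_length total background length in nt.
#' @param seed RNG seed.
#' @param source_id name of the generated sequence.
#' @return list with `genome` (named character vector of length 1) and
#'   `truth` (data.frame: `name`, `peptide`, `nt_start`, `nt_end` 1-based
#'   inclusive forward-strand coordinates, `strand`, `frame`).
#' @export
gen_precursor_genome <- function(crps, background_length = 50000,
                                 seed = NULL, source_id = "synthetic_genome") {
  if (!is.null(seed)) set.seed(seed)
  inserts <- vapply(crps, function(a) reverse_translate(a), character(1))
  if (sum(nchar(inserts)) > background_length)
    stop("background too short for the requested inserts")
  genome <- sample(c("A", "C", "G", "T"), background_length, replace = TRUE)
  taken <- rep(FALSE, background_length)
  truth <- list()
  for (i in seq_along(inserts)) {
    ins <- inserts[[i]]
    strand <- sample(c("+", "-"), 1)
    placed_nt <- if (strand == "+") ins else .revcomp(ins)
    w <- nchar(placed_nt)
    ok_start <- NULL
    for (try in 1:200) {
      s <- sample.int(background_length - w + 1L, 1)
      if (!any(taken[s:(s + w - 1L)])) { ok_start <- s; break }
    }
    if (is.null(ok_start))
      stop("could not place insert ", i, ": background overcrowded")
    genome[ok_start:(ok_start + w - 1L)] <- strsplit(placed_nt, "")[[1]]
    taken[ok_start:(ok_start + w - 1L)] <- TRUE
    e <- ok_start + w - 1L
    frame <- if (strand == "+") ((ok_start - 1L) %% 3L) + 1L
             else -((( background_length - e) %% 3L) + 1L)
    truth[[i]] <- data.frame(
      name = names(crps)[i] %||% paste0("crp", i), peptide = crps[[i]],
      nt_start = ok_start, nt_end = e, strand = strand, frame = frame)
  }
  list(genome = stats::setNames(paste(genome, collapse = ""), source_id),
       truth = do.call(rbind, truth))
}

.lognorm_intensity <- function(n) stats::rlnorm(n, meanlog = 6, sdlog = 1)

#' Simulate paired native/alkylated MALDI peak lists
#'
#' One native peak at the theoretical native `[M+H]+` (all cysteines
#' oxidized) and one alkylated peak at the reduced/carbamidomethylated mass,
#' each with independent Gaussian calibration jitter, plus uniform decoy
#' peaks in both spectra. Intensities are log-normal.
#'
#' @param peptides named character vector of sequences.
#' @param jitter_sd calibration jitter SD in Da.
#' @param n_decoys decoy peaks added to each list.
#' @param mz_range decoy m/z range.
#' @param seed RNG seed.
#' @return list with `native` and `alkylated` peak data.frames and `truth`
#'   (name, native_mh, alkylated_mh, n_cys).
#' @export
sim_peaklists <- function(peptides, jitter_sd = 0.05, n_decoys = 0,
                          mz_range = c(3000, 4600), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(peptides)
  nat <- alk <- ncys <- numeric(n)
  for (i in seq_len(n)) {
    p <- peptides[[i]]
    ncys[i] <- aa_composition(p)[["C"]]
    nat[i] <- peptide_mass(peptide(p))[["MH"]]
    alk[i] <- nat[i] + reduction_alkylation_shift(ncys[i], ncys[i] %/% 2L)
  }
  mk <- function(mhs) {
    mz <- c(mhs + stats::rnorm(length(mhs), 0, jitter_sd),
            stats::runif(n_decoys, mz_range[1], mz_range[2]))
    .as_peaklist(data.frame(mz = mz,
                            intensity = .lognorm_intensity(length(mz))))
  }
  nm <- names(peptides) %||% sprintf("pep%d", seq_len(n))
  list(native = mk(nat), alkylated = mk(alk),
       truth = data.frame(name = nm, native_mh = nat, alkylated_mh = alk,
                          n_cys = as.integer(ncys)))
}

#' Simulate an MS/MS fragment spectrum
#'
#' Generates the singly charged b/y ladder of a (by default
#' carbamidomethylated) fragment peptide, drops each ion independently with
#' probability `dropout`, jitters surviving ions, and adds uniform decoy
#' peaks. The precursor is set to the theoretical `[M+H]+`.
#'
#' @param sequence fragment peptide sequence.
#' @param cam carbamidomethylate cysteines.
#' @param jitter_sd fragment jitter SD in Da.
#' @param dropout per-ion dropout probability in `[0, 1]`.
#' @param n_decoys decoy peaks added.
#' @param seed RNG seed.
#' @return an [msms_spectrum()].
#' @export
sim_msms <- function(sequence, cam = TRUE, jitter_sd = 0.01, dropout = 0.1,
                     n_decoys = 5, seed = NULL) {
  if (dropout < 0 || dropout > 1) stop("dropout must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p <- peptide(sequence, cam = cam)
  mh <- peptide_mass(p)[["MH"]]
  ions <- unlist(ion_series(p))
  keep <- stats::runif(length(ions)) >= dropout
  mz <- ions[keep] + stats::rnorm(sum(keep), 0, jitter_sd)
  mz <- c(mz, stats::runif(n_decoys, 100, max(mh - 50, 150)))
  if (!length(mz))
    return(msms_spectrum(mh, numeric(0), numeric(0)))
  msms_spectrum(mh, mz, .lognorm_intensity(length(mz)))
}
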