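# File formats: FASTA (via Biostrings, wrapped at 60 columns), two-column
# peak-list TSV with '#' comments, and the MGF dialect used for singly
# charged MALDI MS/MS spectra (BEGIN IONS / PEPMASS / optional CHARGE /
# END IONS). Machine outputs carry a '# crpkit <version>' header where the
# format allows comments; coordinates in reports are 1-based inclusive.

.crpkit_header <- function() {
  ver <- tryCatch(as.character(utils::packageVersion("crpkit")),
                  error = function(e) "dev")
  sprintf("# crpkit %s", ver)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @param type `"AA"` or `"DNA"`.
#' @return named character vector of sequences (description kept after the
#'   first whitespace is dropped from the names).
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  out <- stats::setNames(as.character(set),
                         sub("\\s.*$", "", names(set)))
  out
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @param width line wrap (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60) {
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a two-column peak list
#'
#' Whitespace- or tab-separated `m/z  intensity` pairs, one peak per line,
#' `#` comments ignored.
#'
#' @param path input file.
#' @return data.frame with columns `mz`, `intensity`, sorted by `mz`.
#' @export
read_peaklist <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = FALSE, comment.char = "#",
                      col.names = c("mz", "intensity"),
                      colClasses = "numeric"),
    error = function(e) stop("malformed peak list '", path, "': ",
                             conditionMessage(e)))
  .as_peaklist(df)
}

#' Write a two-column peak list
#'
#' @param peaks data.frame with `mz`, `intensity` (or numeric m/z vector).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  peaks <- .as_peaklist(peaks)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(.crpkit_header(), "# mz\tintensity"), con)
  writeLines(sprintf("%.5f\t%.6g", peaks$mz, peaks$intensity), con)
  invisible(path)
}

#' Read MS/MS spectra from MGF
#'
#' Parses the Mascot generic format dialect used here: `BEGIN IONS`,
#' `TITLE=`, `PEPMASS=` (required; taken as the singly protonated
#' precursor), optional `CHARGE=`, peak lines `m/z intensity`, `END IONS`.
#'
#' @param path MGF file.
#' @return named list of [msms_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L; n <- length(lines); block <- 0L
  while (i <= n) {
    ln <- trimws(lines[i])
    if (ln == "BEGIN IONS") {
      block <- block + 1L
      title <- paste0("spectrum", block)
      pepmass <- NA_real_
      mz <- numeric(0); inten <- numeric(0)
      i <- i + 1L
      repeat {
        if (i > n) stop("MGF block ", block, " ('", title,
                        "') not closed by END IONS")
        ln <- trimws(lines[i])
        if (ln == "END IONS") break
        if (grepl("^TITLE=", ln)) title <- sub("^TITLE=", "", ln)
        else if (grepl("^PEPMASS=", ln))
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln),
                                         "\\s+")[[1]][1])
        else if (grepl("^[A-Z]+=", ln)) NULL  # CHARGE etc.: ignored (1+)
        else if (nzchar(ln) && !startsWith(ln, "#")) {
          fields <- as.numeric(strsplit(ln, "\\s+")[[1]])
          mz <- c(mz, fields[1])
          inten <- c(inten, if (length(fields) > 1) fields[2] else 1)
        }
        i <- i + 1L
      }
      if (is.na(pepmass))
        stop("MGF block ", block, " ('", title, "') has no PEPMASS")
      out[[title]] <- msms_spectrum(pepmass, mz, inten)
    }
    i <- i + 1L
  }
  out
}

#' Write MS/MS spectra to MGF
#'
#' @param spectra a named list of [msms_spectrum()] objects (or one).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "msms_spectrum")) spectra <- list(spectrum1 = spectra)
  if (is.null(names(spectra)))
    names(spectra) <- paste0("spectrum", seq_along(spectra))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.crpkit_header(), con)
  for (nm in names(spectra)) {
    s <- spectra[[nm]]
    writeLines(c("BEGIN IONS", paste0("TITLE=", nm),
                 sprintf("PEPMASS=%.5f", s$precursor_mh), "CHARGE=1+"), con)
    writeLines(sprintf("%.5f %.6g", s$peaks$mz, s$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}
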