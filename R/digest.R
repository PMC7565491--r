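# In-silico complete and partial proteolysis.
#
# The trypsin preset has the proline block OFF: the observed digest
# fragments of the citcol family (e.g. the 822.4 Da N-terminal tryptic
# peptide) require cleavage at Lys-Pro junctions, which the classical
# "no cleavage before Pro" rule would forbid. Pass block_before_proline =
# TRUE to restore the classical rule.

.ENZYMES <- list(
  trypsin      = list(cleave_after = c("K", "R"), block_before_proline = FALSE),
  chymotrypsin = list(cleave_after = c("F", "Y", "W", "L"),
                      block_before_proline = FALSE),
  "glu-c"      = list(cleave_after = "E", block_before_proline = FALSE)
)

#' Protease cleavage rule
#'
#' Returns a cleavage rule: the residue set cut after, and whether a
#' following proline blocks cleavage. Presets: `trypsin` (K/R),
#' `chymotrypsin` (F/Y/W/L, high-specificity plus Leu), `glu-c` (E only,
#' the ammonium-bicarbonate buffer specificity).
#'
#' @param name preset name, or any label when `cleave_after` is supplied.
#' @param cleave_after optional custom residue set, overriding the preset.
#' @param block_before_proline logical; suppress cleavage when the next
#'   residue is proline.
#' @return object of class `crp_enzyme`.
#' @examples
#' enzyme("trypsin")
#' enzyme("trypsin", block_before_proline = TRUE)  # classical K/R rule
#' @export
enzyme <- function(name, cleave_after = NULL, block_before_proline = NULL) {
  if (inherits(name, "crp_enzyme")) return(name)
  name <- tolower(name)
  preset <- .ENZYMES[[name]]
  if (is.null(preset) && is.null(cleave_after))
    stop("unknown enzyme '", name, "'; supply cleave_after for a custom rule")
  structure(list(
    name = name,
    cleave_after = toupper(cleave_after %||% preset$cleave_after),
    block_before_proline =
      block_before_proline %||% (preset$block_before_proline %||% FALSE)
  ), class = "crp_enzyme")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.crp_enzyme <- function(x, ...) {
  cat(sprintf("crp_enzyme %s: cleaves after {%s}%s\n", x$name,
              paste(x$cleave_after, collapse = ","),
              if (x$block_before_proline) ", blocked before P" else ""))
  invisible(x)
}

#' Cleavage sites of an enzyme on a sequence
#'
#' Positions `i` (1-based) such that the enzyme cuts between residues `i`
#' and `i + 1`. The last residue is never a site.
#'
#' @param sequence peptide sequence.
#' @param enz a `crp_enzyme` or preset name.
#' @return integer vector of cut positions (possibly empty).
#' @export
cleavage_sites <- function(sequence, enz) {
  enz <- enzyme(enz)
  chars <- .seq_chars(sequence)
  n <- length(chars)
  if (n < 2) return(integer(0))
  idx <- which(chars[-n] %in% enz$cleave_after)
  if (enz$block_before_proline && length(idx))
    idx <- idx[chars[idx + 1] != "P"]
  idx
}

.fragment_frame <- function(sequence, bounds, sites, cam, parent_id) {
  # bounds: matrix of (start, end) 1-based inclusive
  if (!nrow(bounds))
    return(data.frame(parent_id = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      missed_cleavages = integer(0), mh = numeric(0),
                      low_mass = logical(0)))
  seqs <- substring(sequence, bounds[, 1], bounds[, 2])
  missed <- vapply(seq_len(nrow(bounds)), function(i)
    sum(sites > bounds[i, 1] - 1 & sites < bounds[i, 2]), integer(1))
  mh <- vapply(seqs, function(s)
    peptide_mass(peptide(s, cam = cam))[["MH"]], numeric(1))
  out <- data.frame(parent_id = parent_id, start = bounds[, 1],
                    end = bounds[, 2], sequence = seqs,
                    missed_cleavages = missed, mh = unname(mh),
                    low_mass = unname(mh) < 500)
  rownames(out) <- NULL
  out[order(out$start, out$end), ]
}

#' Complete in-silico digestion
#'
#' All fragments bounded by consecutive cleavage sites or termini with at
#' most `max_missed` internal (missed) sites. Fragments with zero missed
#' cleavages tile the parent exactly. Theoretical `[M+H]+` is computed on
#' the carbamidomethylated sequence by default (`cam = TRUE`), matching the
#' reduced/alkylated state in which digests are run; fragments below the
#' 500 Da MALDI matrix region are retained but flagged `low_mass`.
#'
#' @param sequence parent peptide sequence.
#' @param enz enzyme (see [enzyme()]).
#' @param max_missed maximum missed cleavages.
#' @param cam carbamidomethylate cysteines for the theoretical mass.
#' @param parent_id label recorded in the output.
#' @return data.frame with columns `parent_id`, `start`, `end` (1-based,
#'   inclusive), `sequence`, `missed_cleavages`, `mh`, `low_mass`.
#' @examples
#' digest_complete("VCLFVGKPCWSDADCPSGCYCKPLPLIDAGYCGFL", "trypsin")
#' @export
digest_complete <- function(sequence, enz, max_missed = 0, cam = TRUE,
                            parent_id = NA_character_) {
  if (max_missed < 0) stop("max_missed must be non-negative")
  enz <- enzyme(enz)
  chars <- .seq_chars(sequence)
  sites <- cleavage_sites(sequence, enz)
  edges <- c(0L, sites, length(chars))  # fragment boundaries
  bounds <- list()
  for (i in seq_len(length(edges) - 1L)) {
    for (j in (i + 1L):min(length(edges), i + 1L + max_missed)) {
      bounds[[length(bounds) + 1L]] <- c(edges[i] + 1L, edges[j])
    }
  }
  .fragment_frame(paste(chars, collapse = ""),
                  do.call(rbind, bounds), sites, cam, parent_id)
}

#' Partial in-silico digestion
#'
#' Every substring whose boundaries are both cleavage sites or parent
#' termini, with any number of missed cleavages -- the fragment population
#' of an incomplete digest. Equivalent to [digest_complete()] with
#' `max_missed` equal to the number of sites.
#'
#' @inheritParams digest_complete
#' @return data.frame as in [digest_complete()].
#' @export
digest_partial <- function(sequence, enz, cam = TRUE,
                           parent_id = NA_character_) {
  n_sites <- length(cleavage_sites(sequence, enzyme(enz)))
  digest_complete(sequence, enz, max_missed = n_sites, cam = cam,
                  parent_id = parent_id)
}
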