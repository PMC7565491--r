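# Six-frame translation of nucleotide data and motif/alignment retrieval of
# CRP-like segments. A local, self-contained stand-in for a blastp/tblastn
# search over user-supplied FASTA: E-values use the ungapped Karlin-Altschul
# constants for BLOSUM62 (lambda ~0.318, K ~0.13) and are adequate for
# thresholding, not calibrated against NCBI's gapped statistics.

.KA_LAMBDA <- 0.318
.KA_K <- 0.13

#' Six-frame translation
#'
#' Translates a nucleotide sequence in the three forward frames (+1..+3)
#' and the three frames of its reverse complement (-1..-3) with the
#' standard genetic code. Stop codons are retained as `*` (no ORF
#' filtering); `N`-containing codons translate to `X`.
#'
#' @param nt named character vector of nucleotide sequences (alphabet
#'   ACGTN), or a `Biostrings::DNAStringSet`.
#' @return data.frame with columns `source_id`, `frame` (+1..+3, -1..-3),
#'   `offset` (nt skipped at the reading start, 0..2), `protein`.
#' @examples
#' six_frame_translate(c(x = "ATGGGC"))
#' @export
six_frame_translate <- function(nt) {
  if (methods::is(nt, "DNAStringSet")) {
    ids <- names(nt) %||% paste0("seq", seq_along(nt))
    nt <- stats::setNames(as.character(nt), ids)
  }
  if (is.null(names(nt))) names(nt) <- paste0("seq", seq_along(nt))
  out <- list()
  for (id in names(nt)) {
    s <- toupper(nt[[id]])
    bad <- setdiff(unique(strsplit(s, "")[[1]]), c("A", "C", "G", "T", "N"))
    if (length(bad))
      stop("non-ACGTN character(s) in ", id, ": ", paste(bad, collapse = ","))
    fwd <- Biostrings::DNAString(s)
    rev <- Biostrings::reverseComplement(fwd)
    L <- nchar(s)
    for (f in 1:3) {
      for (strand in c(1, -1)) {
        src <- if (strand == 1) fwd else rev
        naa <- (L - (f - 1)) %/% 3
        prot <- if (naa == 0) "" else as.character(Biostrings::translate(
          Biostrings::subseq(src, start = f, width = 3 * naa),
          if.fuzzy.codon = "X"))
        out[[length(out) + 1L]] <- data.frame(
          source_id = id, frame = strand * f, offset = f - 1L,
          protein = prot)
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$source_id, -sign(res$frame), abs(res$frame)),
             c("source_id", "frame", "offset", "protein")]
  rownames(res) <- NULL
  res
}

#' Cysteine-spacing template
#'
#' Loop-length bounds for the motif scan. The default captures the squash
#' CRP family: up to 5 residues of prefix, loops exactly 6, 5, 3, 1, then
#' 5-12 residues in loop 5 (the loop that separates the antimicrobial from
#' the trypsin-inhibitor branch), up to 3 residues of suffix.
#'
#' @param prefix,suffix length ranges `c(min, max)`.
#' @param loops list of 5 loop-length ranges (scalars mean exact length).
#' @return list of bounds used by [scan_motif()].
#' @export
crp_template <- function(prefix = c(0, 5),
                         loops = list(6, 5, 3, 1, c(5, 12)),
                         suffix = c(0, 3)) {
  norm <- function(x) if (length(x) == 1) c(x, x) else as.numeric(x[1:2])
  loops <- lapply(loops, norm)
  if (any(vapply(loops, function(b) b[1] > b[2], logical(1))))
    stop("inconsistent loop bounds")
  list(prefix = norm(prefix), loops = loops, suffix = norm(suffix))
}

#' Scan a protein for cysteine-spacing motif candidates
#'
#' Finds every window of six consecutive cysteines whose five inter-Cys
#' spacings satisfy the template bounds, has no stop codon or non-Cys
#' violation inside, and whose prefix/suffix (cysteine-free, up to the
#' template maxima) can be attached. Overlapping candidates are all
#' reported.
#'
#' @param protein a protein sequence (may contain `*` stops and `X`).
#' @param template from [crp_template()].
#' @return data.frame with columns `start`, `end` (1-based, inclusive,
#'   protein coordinates of the reported segment), `cys_start`, `cys_end`
#'   (coordinates of Cys I and Cys VI), `segment`.
#' @export
scan_motif <- function(protein, template = crp_template()) {
  chars <- if (nchar(protein)) strsplit(toupper(protein), "")[[1]]
           else character(0)
  empty <- data.frame(start = integer(0), end = integer(0),
                      cys_start = integer(0), cys_end = integer(0),
                      segment = character(0))
  cys <- which(chars == "C")
  if (length(cys) < 6) return(empty)
  # stop codons and untranslatable X both disqualify a precursor segment
  stops <- which(chars == "*" | chars == "X")
  out <- list()
  for (i in seq_len(length(cys) - 5L)) {
    w <- cys[i:(i + 5L)]
    gaps <- diff(w) - 1L
    ok <- all(vapply(1:5, function(k) {
      b <- template$loops[[k]]
      gaps[k] >= b[1] && gaps[k] <= b[2]
    }, logical(1)))
    if (!ok) next
    if (any(stops > w[1] & stops < w[6])) next
    # cysteine-free, stop-free flanks up to the template maxima
    lim_l <- max(c(0L, cys[cys < w[1]], stops[stops < w[1]]))
    pre <- min(template$prefix[2], w[1] - 1L - lim_l)
    lim_r <- min(c(length(chars) + 1L, cys[cys > w[6]], stops[stops > w[6]]))
    suf <- min(template$suffix[2], lim_r - w[6] - 1L)
    if (pre < template$prefix[1] || suf < template$suffix[1]) next
    s <- w[1] - pre; e <- w[6] + suf
    out[[length(out) + 1L]] <- data.frame(
      start = s, end = e, cys_start = w[1], cys_end = w[6],
      segment = paste(chars[s:e], collapse = ""))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score and filter candidate segments against CRP queries
#'
#' Smith-Waterman local alignment (BLOSUM62, affine 10/0.5) of each
#' candidate against every query; the best query score is converted to an
#' E-value estimate with ungapped Karlin-Altschul statistics,
#' `E = K * m * n * exp(-lambda * S)`, where `m` is the query length and
#' `n` the database size in residues. Hits passing the cutoff are returned
#' sorted by ascending E-value.
#'
#' @param queries named character vector of query peptide sequences.
#' @param candidates data.frame with a `segment` column (as produced by
#'   [scan_motif()]), or a character vector of segments.
#' @param evalue_cutoff significance threshold (default 0.001; the looser
#'   screening cutoff used in database searches is 0.1).
#' @param db_size database size in residues; defaults to the summed
#'   candidate lengths.
#' @return the candidate rows augmented with `best_query`, `sw_score`,
#'   `evalue_est`, filtered and sorted.
#' @export
rank_hits <- function(queries, candidates, evalue_cutoff = 0.001,
                      db_size = NULL) {
  if (!length(queries)) stop("at least one query is required")
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  if (is.character(candidates)) candidates <- data.frame(segment = candidates)
  empty <- cbind(candidates[0, , drop = FALSE],
                 data.frame(best_query = character(0), sw_score = numeric(0),
                            evalue_est = numeric(0)))
  if (!nrow(candidates)) return(empty)
  segs <- chartr("*X", "GG", toupper(candidates$segment))
  # X/* cannot occur inside reported motif segments; chartr guards direct use
  if (is.null(db_size)) db_size <- sum(nchar(segs))
  mat <- .blosum62()
  best_score <- rep(-Inf, length(segs))
  best_query <- rep(NA_character_, length(segs))
  best_m <- rep(NA_integer_, length(segs))
  for (qn in names(queries)) {
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(segs), Biostrings::AAString(queries[[qn]]),
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
      type = "local", scoreOnly = TRUE)
    upd <- sc > best_score
    best_score[upd] <- sc[upd]
    best_query[upd] <- qn
    best_m[upd] <- nchar(queries[[qn]])
  }
  ev <- .KA_K * best_m * db_size * exp(-.KA_LAMBDA * best_score)
  keep <- which(ev <= evalue_cutoff)
  if (!length(keep)) return(empty)
  out <- cbind(candidates[keep, , drop = FALSE],
               data.frame(best_query = best_query[keep],
                          sw_score = best_score[keep],
                          evalue_est = ev[keep]))
  out <- out[order(out$evalue_est), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# protein-span -> nucleotide coordinates on the forward strand of the source
.prot_to_nt <- function(frame, seq_len_nt, ps, pe) {
  f <- abs(frame)
  if (frame > 0) c(start = (f - 1) + 3 * (ps - 1) + 1, end = (f - 1) + 3 * pe)
  else c(start = seq_len_nt - (f - 1) - 3 * pe + 1,
         end = seq_len_nt - (f - 1) - 3 * (ps - 1))
}

#' Mine nucleotide sequences for CRP-like precursors
#'
#' The full retrieval pipeline: six-frame translation, cysteine-spacing
#' motif scan, Smith-Waterman ranking against the queries, and mapping of
#' hits back to forward-strand nucleotide coordinates.
#'
#' @param nt named character vector of nucleotide sequences.
#' @param queries named character vector of CRP query peptides.
#' @param template from [crp_template()].
#' @param evalue_cutoff significance threshold.
#' @return data.frame of hits: `source_id`, `frame`, `prot_start`,
#'   `prot_end`, `nt_start`, `nt_end`, `segment`, `best_query`, `sw_score`,
#'   `evalue_est`, plus the loop pattern string.
#' @export
mine_sequences <- function(nt, queries, template = crp_template(),
                           evalue_cutoff = 0.001) {
  tr <- six_frame_translate(nt)
  cands <- list()
  for (i in seq_len(nrow(tr))) {
    hits <- scan_motif(tr$protein[i], template)
    if (!nrow(hits)) next
    hits$source_id <- tr$source_id[i]
    hits$frame <- tr$frame[i]
    hits$.src_len <- nchar(nt[[tr$source_id[i]]])
    cands[[length(cands) + 1L]] <- hits
  }
  empty <- data.frame(source_id = character(0), frame = integer(0),
                      prot_start = integer(0), prot_end = integer(0),
                      nt_start = integer(0), nt_end = integer(0),
                      segment = character(0), best_query = character(0),
                      sw_score = numeric(0), evalue_est = numeric(0),
                      cys_pattern = character(0))
  if (!length(cands)) return(empty)
  cands <- do.call(rbind, cands)
  db_size <- sum(nchar(tr$protein))
  ranked <- rank_hits(queries, cands, evalue_cutoff, db_size = db_size)
  if (!nrow(ranked)) return(empty)
  coords <- t(vapply(seq_len(nrow(ranked)), function(i)
    .prot_to_nt(ranked$frame[i], ranked$.src_len[i],
                ranked$start[i], ranked$end[i]), numeric(2)))
  pat <- vapply(ranked$segment, function(s) {
    p <- loop_pattern(s)
    sprintf("X%d-%s-X%d", p$prefix_len,
            paste0("CX", p$loops, collapse = ""), p$suffix_len)
  }, character(1))
  out <- data.frame(source_id = ranked$source_id, frame = ranked$frame,
                    prot_start = ranked$start, prot_end = ranked$end,
                    nt_start = as.integer(coords[, "start"]),
                    nt_end = as.integer(coords[, "end"]),
                    segment = ranked$segment,
                    best_query = ranked$best_query,
                    sw_score = ranked$sw_score,
                    evalue_est = ranked$evalue_est,
                    cys_pattern = unname(pat))
  rownames(out) <- NULL
  out
}
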