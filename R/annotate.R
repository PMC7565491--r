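# Cysteine-loop architecture, P1 classification, EMBOSS-Needle-style
# pairwise similarity, frequency-logo matrices and neighbor-joining trees.

#' Cysteine loop decomposition
#'
#' Splits a sequence at its cysteines into a prefix, inter-cysteine loops
#' and a suffix. The citcol family follows the knottin-like template
#' `X(1-5) C X6 C X5 C X3 C X1 C X10 C X(0-3)`; loop 5 (between Cys V and
#' Cys VI) is the discriminating feature between the antimicrobial and
#' trypsin-inhibitor branches of the squash CRP family.
#'
#' @param sequence peptide sequence with at least two cysteines.
#' @return object of class `cys_pattern`: `prefix_len`, `loops` (integer
#'   vector of inter-Cys residue counts), `suffix_len`, `cys_pos` (1-based
#'   positions), `n_cys`.
#' @examples
#' loop_pattern("NRVGVCLFVGKPCWSDADCPSGCYCKPLPLIDAGYCGFL")$loops
#' @export
loop_pattern <- function(sequence) {
  chars <- .seq_chars(sequence)
  .check_alphabet(chars)
  cys <- which(chars == "C")
  if (length(cys) < 2) stop("loop decomposition needs at least 2 cysteines")
  structure(list(prefix_len = cys[1] - 1L,
                 loops = as.integer(diff(cys) - 1L),
                 suffix_len = length(chars) - cys[length(cys)],
                 cys_pos = cys,
                 n_cys = length(cys),
                 sequence = paste(chars, collapse = "")),
            class = "cys_pattern")
}

#' @export
print.cys_pattern <- function(x, ...) {
  cat(sprintf("cys_pattern: X%d %s X%d  (%d Cys)\n", x$prefix_len,
              paste(sprintf("C X%d", x$loops), collapse = " "),
              x$suffix_len, x$n_cys))
  invisible(x)
}

#' Classify a CRP by its P1 residue
#'
#' In canonical squash protease inhibitors the P1 residue -- the residue
#' N-terminal to the scissile bond -- sits at the second position of loop 1
#' (between Cys I and Cys II). A basic residue (Arg/Lys) there confers
#' trypsin inhibition; the citcol-type peptides carry Phe instead and fall
#' on the antimicrobial branch. The loop offset of the P1 position is an
#' inference from the aligned examples and is configurable.
#'
#' @param sequence peptide sequence.
#' @param p1_offset position of P1 within loop 1 (default 2).
#' @return list with `p1_residue`, `label`
#'   (`"trypsin_inhibitor_like"` or `"antimicrobial_like"`), `basis`.
#' @examples
#' classify_p1("NRVGVCLFVGKPCWSDADCPSGCYCKPLPLIDAGYCGFL")$label
#' @export
classify_p1 <- function(sequence, p1_offset = 2) {
  pat <- loop_pattern(sequence)
  if (pat$loops[1] < p1_offset)
    stop("loop 1 too short to contain a P1 residue at offset ", p1_offset)
  chars <- .seq_chars(pat$sequence)
  p1 <- chars[pat$cys_pos[1] + p1_offset]
  list(p1_residue = p1,
       label = if (p1 %in% c("R", "K")) "trypsin_inhibitor_like"
               else "antimicrobial_like",
       basis = sprintf("P1 = loop-1 position %d", p1_offset))
}

#' Putative cystine-knot connectivity
#'
#' For a six-cysteine peptide, returns the inhibitor-cystine-knot pairing
#' C I-IV, C II-V, C III-VI (the third disulfide threading the ring formed
#' by the first two), with the residue indices attached. This is a
#' homology-based prediction, not an experimental determination.
#'
#' @param x a sequence or a `cys_pattern`.
#' @return data.frame with columns `cys_a`, `cys_b` (ordinals) and
#'   `pos_a`, `pos_b` (residue indices).
#' @export
putative_connectivity <- function(x) {
  pat <- if (inherits(x, "cys_pattern")) x else loop_pattern(x)
  if (pat$n_cys != 6)
    stop("knot connectivity is defined here only for 6-cysteine peptides")
  a <- 1:3; b <- 4:6
  data.frame(cys_a = a, cys_b = b,
             pos_a = pat$cys_pos[a], pos_b = pat$cys_pos[b])
}

# BLOSUM62 from Biostrings, loaded lazily once
.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Global pairwise alignment with EMBOSS Needle conventions
#'
#' Optimal global alignment under affine gap penalties with unpenalized end
#' gaps (BLOSUM62, gap open 10, gap extend 0.5 by default), reported over
#' the full alignment length including end gaps: identity is the percentage
#' of identical pairs, similarity the percentage of pairs with a positive
#' substitution score, gaps the percentage of gapped columns.
#'
#' @param a,b sequences (standard residues only).
#' @param gap_open,gap_extend affine gap parameters.
#' @return object of class `needle_alignment`: `aligned_a`, `aligned_b`,
#'   `score`, `length`, `identity_pct`, `similarity_pct`, `gaps_pct`,
#'   `n_identity`, `n_similarity`.
#' @examples
#' aln <- needle_align("NRVGVCLFVGKPCWSDADCPSGCYCKPLPLIDAGYCGFL",
#'                     "QRACPRILKKCRRDSDCPGECICKENGYCG")
#' aln$similarity_pct  # 43.6
#' @export
needle_align <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  ca <- .seq_chars(a); cb <- .seq_chars(b)
  if (!length(ca) || !length(cb)) stop("sequences must be non-empty")
  .check_alphabet(ca, "sequence a"); .check_alphabet(cb, "sequence b")
  a <- paste(ca, collapse = ""); b <- paste(cb, collapse = "")
  mat <- .blosum62()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "overlap")
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  sp <- Biostrings::start(Biostrings::pattern(aln))
  ep <- Biostrings::end(Biostrings::pattern(aln))
  ss <- Biostrings::start(Biostrings::subject(aln))
  es <- Biostrings::end(Biostrings::subject(aln))
  lead_a <- substr(a, 1, sp - 1); lead_b <- substr(b, 1, ss - 1)
  tail_a <- substr(a, ep + 1, nchar(a)); tail_b <- substr(b, es + 1, nchar(b))
  npl <- max(nchar(lead_a), nchar(lead_b))
  npr <- max(nchar(tail_a), nchar(tail_b))
  padl <- function(s, n) paste0(strrep("-", n - nchar(s)), s)
  padr <- function(s, n) paste0(s, strrep("-", n - nchar(s)))
  fa <- paste0(padl(lead_a, npl), pa, padr(tail_a, npr))
  fb <- paste0(padl(lead_b, npl), pb, padr(tail_b, npr))
  va <- strsplit(fa, "")[[1]]; vb <- strsplit(fb, "")[[1]]
  n <- length(va)
  both <- va != "-" & vb != "-"
  n_id <- sum(va == vb & both)
  n_sim <- sum(mat[cbind(va[both], vb[both])] > 0)
  structure(list(aligned_a = fa, aligned_b = fb,
                 score = Biostrings::score(aln), length = n,
                 identity_pct = round(100 * n_id / n, 1),
                 similarity_pct = round(100 * n_sim / n, 1),
                 gaps_pct = round(100 * sum(!both) / n, 1),
                 n_identity = n_id, n_similarity = n_sim),
            class = "needle_alignment")
}

#' @export
print.needle_alignment <- function(x, ...) {
  cat(sprintf("%s\n%s\nlength %d | identity %.1f%% | similarity %.1f%% | gaps %.1f%% | score %.1f\n",
              x$aligned_a, x$aligned_b, x$length, x$identity_pct,
              x$similarity_pct, x$gaps_pct, x$score))
  invisible(x)
}

#' Substitutions between two aligned sequences
#'
#' Counts columns where both sequences have (different) residues, i.e.
#' substitutions outside any gapped columns.
#'
#' @param aln a `needle_alignment`.
#' @return integer count.
#' @export
count_substitutions <- function(aln) {
  va <- strsplit(aln$aligned_a, "")[[1]]
  vb <- strsplit(aln$aligned_b, "")[[1]]
  sum(va != "-" & vb != "-" & va != vb)
}

#' Position-wise residue frequency matrix
#'
#' For a set of equal-length (gapped) sequences, the frequency of each
#' residue (plus the gap symbol) at every column -- the matrix behind a
#' sequence logo. Each column sums to one.
#'
#' @param aligned character vector of equal-length gapped sequences.
#' @return numeric matrix, rows = residues and `-`, columns = positions.
#' @export
frequency_matrix <- function(aligned) {
  if (!length(aligned)) stop("no sequences")
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1)
    stop("aligned sequences must have equal (gapped) lengths")
  chars <- do.call(rbind, strsplit(toupper(aligned), ""))
  lv <- c(.AA_CODES, "-")
  bad <- setdiff(unique(as.vector(chars)), lv)
  if (length(bad)) stop("unexpected symbols: ", paste(bad, collapse = ", "))
  out <- apply(chars, 2, function(col)
    table(factor(col, levels = lv)) / length(col))
  rownames(out) <- lv
  colnames(out) <- seq_len(ncol(out))
  out
}

#' Pairwise identity distances
#'
#' `1 - identity fraction` from [needle_align()] for every sequence pair.
#'
#' @param sequences named character vector.
#' @param ... passed to [needle_align()].
#' @return a `dist` object.
#' @export
identity_distances <- function(sequences, ...) {
  n <- length(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- needle_align(sequences[[i]], sequences[[j]], ...)
      d[i, j] <- d[j, i] <- 1 - aln$identity_pct / 100
    }
  }
  stats::as.dist(d)
}

#' Neighbor-joining tree from pairwise identity
#'
#' Builds an unrooted neighbor-joining tree on `1 - identity` distances
#' (negative branch lengths clamped to zero). A desk-scale stand-in for a
#' full maximum-likelihood phylogeny, adequate for recovering the
#' two-branch structure (antimicrobial vs trypsin-inhibitor) of the squash
#' CRP family.
#'
#' @param sequences named character vector (at least 3).
#' @param ... passed to [needle_align()].
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(sequences, ...) {
  if (length(sequences) < 3) stop("a tree needs at least 3 sequences")
  tr <- ape::nj(identity_distances(sequences, ...))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
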