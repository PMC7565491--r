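# End-to-end de novo workflow used by the round-trip tests: pick a covering
# set of digest fragments, simulate their spectra, interpret, assemble with
# candidate alternatives, resolve isobars enzymatically and settle the rest
# against the (measured) amino-acid composition.

# fragments an analyst would submit to MS/MS: above the matrix region,
# sequence-able length, not more than 3 missed cleavages; greedy covering
# set preferring long fragments
select_covering_fragments <- function(truth) {
  pool <- rbind(cbind(digest_partial(truth, "trypsin"), enzyme = "trypsin"),
                cbind(digest_partial(truth, "chymotrypsin"),
                      enzyme = "chymotrypsin"))
  pool <- pool[pool$mh >= 500 & nchar(pool$sequence) >= 5 &
                 nchar(pool$sequence) <= 28 & pool$missed_cleavages <= 3, ]
  pool <- pool[order(-(pool$end - pool$start)), ]
  covered <- rep(FALSE, nchar(truth)); keep <- integer(0)
  for (i in seq_len(nrow(pool))) {
    span <- pool$start[i]:pool$end[i]
    if (any(!covered[span])) { keep <- c(keep, i); covered[span] <- TRUE }
  }
  pool[keep, , drop = FALSE]
}

# full round trip for one peptide; returns the resolved consensus (or NA)
denovo_round_trip <- function(truth, seed, dropout = 0, jitter_sd = 0.01,
                              n_decoys = 5) {
  set.seed(seed)
  intact <- peptide_mass(peptide(truth))[["MH"]] + rnorm(1, 0, 0.05)
  fr <- select_covering_fragments(truth)
  cands <- list()
  for (i in seq_len(nrow(fr))) {
    sp <- sim_msms(fr$sequence[i], jitter_sd = jitter_sd, dropout = dropout,
                   n_decoys = n_decoys, seed = seed * 1000 + i)
    cc <- tryCatch(interpret_spectrum(sp, tol = 0.05),
                   error = function(e) list())
    if (length(cc))
      cands[[length(cands) + 1L]] <- list(candidates = cc,
                                          enzyme = fr$enzyme[i])
  }
  if (!length(cands)) return(NA_character_)
  worst <- function(cs)
    which.min(vapply(cs, function(f) f$candidates[[1]]$score, numeric(1)))
  comp <- aa_composition(truth)  # the amino-acid analysis measurement
  asm <- NULL; tries <- 0
  while (is.null(asm) && length(cands) >= 1 && tries < 3) {
    asm <- tryCatch(assemble_fragments(cands, intact_mh = intact,
                                       mass_tol = 0.7, composition = comp),
                    error = function(e) NULL)
    if (is.null(asm)) {
      if (length(cands) > 1) cands <- cands[-worst(cands)] else tries <- 3
      tries <- tries + 1
    }
  }
  if (is.null(asm)) return(NA_character_)
  tr <- digest_complete(truth, "trypsin")$mh
  ch <- digest_complete(truth, "chymotrypsin")$mh
  pk <- list(trypsin = tr + rnorm(length(tr), 0, 0.05),
             chymotrypsin = ch + rnorm(length(ch), 0, 0.05))
  res <- NULL
  for (alt in asm$candidates) {
    r <- resolve_isobaric(alt, pk, tol = 0.3)
    r <- resolve_by_composition(r, comp)
    if (is.null(res)) res <- r
    if (!any(r$flags$kq | r$flags$ji) &&
        identical(aa_composition(r$consensus), comp)) { res <- r; break }
  }
  res$consensus
}
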