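test_that("six-frame translation follows the standard code and strands", {
  tr <- six_frame_translate(c(x = "ATGGGC"))
  expect_identical(nrow(tr), 6L)
  expect_identical(tr$protein[tr$frame == 1], "MG")
  # reverse frames read the reverse complement
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGGGC")))
  tr_rc <- six_frame_translate(c(y = rc))
  expect_identical(tr$protein[tr$frame == -1], tr_rc$protein[tr_rc$frame == 1])
  # floor arithmetic on short input
  t5 <- six_frame_translate(c(z = "ATGCA"))
  expect_identical(nchar(t5$protein[t5$frame == 3]), 1L)
  # fuzzy codons become X, other characters are rejected
  expect_true(grepl("X", six_frame_translate(c(n = "ATGNNN"))$protein[1]))
  expect_error(six_frame_translate(c(bad = "ATGU")), "non-ACGTN")
})

test_that("the motif scan finds planted segments and nothing else", {
  c8 <- citcol[["citcol-8"]]
  set.seed(61)
  bg <- paste(sample(setdiff(strsplit("ADEFGHIKLMNPQRSTVWY", "")[[1]], "C"),
                     200, TRUE), collapse = "")
  prot <- paste0(substr(bg, 1, 100), c8, substr(bg, 101, 200))
  hits <- scan_motif(prot)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$segment, c8)
  # cysteine-free proteins yield nothing
  expect_identical(nrow(scan_motif(bg)), 0L)
  # the C. melo homolog satisfies the default template
  expect_identical(scan_motif(cmelo_homolog)$segment, cmelo_homolog)
  # stop codons disqualify a segment
  broken <- sub("SDADC", "SD*DC", c8)
  expect_identical(nrow(scan_motif(broken)), 0L)
  expect_error(crp_template(loops = list(6, 5, 3, 1, c(12, 5))),
               "inconsistent")
})

test_that("hit ranking is score-monotone and significance-filtered", {
  c8 <- citcol[["citcol-8"]]
  cands <- c(c8, cmelo_homolog, reference_crps[["Q07A30"]])
  hits <- rank_hits(c(citcol8 = c8), cands, evalue_cutoff = 10)
  # self-match first, E-value decreasing with score
  expect_identical(hits$segment[1], c8)
  expect_true(all(diff(hits$sw_score) <= 0))
  expect_true(all(diff(hits$evalue_est) >= 0))
  expect_identical(nrow(rank_hits(c(q = c8), character(0))), 0L)
})

test_that("shuffled decoys produce no significant hits", {
  c8 <- citcol[["citcol-8"]]
  set.seed(71)
  chars <- strsplit(c8, "")[[1]]
  decoys <- vapply(1:1000, function(i)
    paste(sample(chars), collapse = ""), character(1))
  hits <- rank_hits(c(citcol8 = c8), decoys, evalue_cutoff = 0.001)
  # composition-preserving shuffles of a 6-Cys peptide are a conservative
  # null, and the ungapped Karlin-Altschul constants understate gapped
  # E-values slightly: a single borderline decoy (E ~ 6e-4) survives
  expect_lte(nrow(hits), 1L)
})

test_that("planted precursors are mined back at their recorded coordinates", {
  c8 <- citcol[["citcol-8"]]
  crps <- gen_crp(5, base = c8, mutation_rate = 0.12, seed = 11)
  g <- gen_precursor_genome(crps, background_length = 50000, seed = 12)
  hits <- mine_sequences(g$genome, c(citcol8 = c8), evalue_cutoff = 0.001)
  expect_identical(nrow(hits), 5L)
  found <- vapply(seq_len(nrow(g$truth)), function(i)
    any(hits$nt_start == g$truth$nt_start[i] &
          hits$nt_end == g$truth$nt_end[i] &
          hits$segment == g$truth$peptide[i]), logical(1))
  expect_true(all(found))
  # an empty genome region yields no hits at the significance cutoff
  g0 <- gen_precursor_genome(character(0), background_length = 20000,
                             seed = 13)
  expect_identical(nrow(mine_sequences(g0$genome, c(citcol8 = c8))), 0L)
})

test_that("genome generation is a pure function of its seed", {
  crps <- gen_crp(3, seed = 81)
  a <- gen_precursor_genome(crps, 10000, seed = 82)
  b <- gen_precursor_genome(crps, 10000, seed = 82)
  expect_identical(a, b)
  # translation round trip: the planted strand re-translates to the peptide
  for (i in seq_len(nrow(a$truth))) {
    nt <- substr(a$genome[[1]], a$truth$nt_start[i], a$truth$nt_end[i])
    if (a$truth$strand[i] == "-")
      nt <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(nt)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
    expect_identical(aa, unname(a$truth$peptide[i]))
  }
})
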