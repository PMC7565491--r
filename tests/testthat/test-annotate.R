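test_that("cysteine loop decomposition matches the knottin template", {
  p8 <- loop_pattern(citcol[["citcol-8"]])
  expect_identical(p8$prefix_len, 5L)
  expect_identical(p8$loops, c(6L, 5L, 3L, 1L, 10L))
  expect_identical(p8$suffix_len, 3L)
  m3 <- loop_pattern(reference_crps[["P82410"]])  # MCoTI-III
  expect_identical(m3$prefix_len, 3L)
  expect_identical(m3$loops, c(6L, 5L, 3L, 1L, 5L))
  expect_identical(m3$suffix_len, 1L)
  cc <- loop_pattern("CC")
  expect_identical(cc$prefix_len, 0L)
  expect_identical(cc$loops, 0L)
  expect_identical(cc$suffix_len, 0L)
  expect_error(loop_pattern("ACDEF"), "cysteine")
})

test_that("loop decomposition is a bijection on cysteine positions", {
  set.seed(41)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:200) {
    s <- paste(sample(aas, sample(6:40, 1), TRUE), collapse = "")
    if (sum(strsplit(s, "")[[1]] == "C") < 2) next
    p <- loop_pattern(s)
    rebuilt <- c(p$prefix_len,
                 unlist(lapply(p$loops, function(l) c(0, l))), 0,
                 p$suffix_len)
    # reconstruct cysteine positions from the decomposition
    pos <- p$prefix_len + cumsum(c(1, p$loops + 1))
    expect_identical(as.integer(pos), p$cys_pos)
    expect_identical(p$prefix_len + p$n_cys + sum(p$loops) + p$suffix_len,
                     nchar(s))
  }
})

test_that("the P1 residue of loop 1 separates the two functional branches", {
  for (s in citcol) {
    cl <- classify_p1(s)
    expect_identical(cl$p1_residue, "F")
    expect_identical(cl$label, "antimicrobial_like")
  }
  m <- classify_p1(reference_crps[["P82410"]])
  expect_identical(m$p1_residue, "R")
  expect_identical(m$label, "trypsin_inhibitor_like")
  expect_error(classify_p1("CACAACAACAAC"), "loop 1")
})

test_that("six-cysteine peptides get the I-IV / II-V / III-VI knot pairing", {
  con <- putative_connectivity(citcol[["citcol-2"]])
  expect_identical(con$cys_a, 1:3)
  expect_identical(con$cys_b, 4:6)
  expect_identical(con$pos_a, c(2L, 9L, 15L))
  expect_identical(con$pos_b, c(19L, 21L, 32L))
  toy <- putative_connectivity("CACACACACAC")
  expect_identical(toy$cys_a, 1:3)
  expect_error(putative_connectivity("CACAC"), "6-cysteine")
})

test_that("Needle-style alignment reproduces the published similarities", {
  c8 <- citcol[["citcol-8"]]
  self <- needle_align(c8, c8)
  expect_equal(self$identity_pct, 100)
  expect_equal(self$gaps_pct, 0)
  for (id in names(reference_crps)) {
    aln <- needle_align(c8, reference_crps[[id]])
    expect_equal(aln$similarity_pct, reference_similarity[[id]],
                 info = id)
  }
  expect_error(needle_align(c8, "ABZ"), "non-standard")
})

test_that("alignment scores and similarity are symmetric in their arguments", {
  set.seed(51)
  picks <- sample(names(reference_crps), 3)
  for (id in picks) {
    ab <- needle_align(citcol[["citcol-8"]], reference_crps[[id]])
    ba <- needle_align(reference_crps[[id]], citcol[["citcol-8"]])
    expect_equal(ab$score, ba$score)
    expect_equal(ab$similarity_pct, ba$similarity_pct)
    expect_equal(ab$identity_pct, ba$identity_pct)
  }
})

test_that("frequency matrices sum to one per column and flag conservation", {
  one <- frequency_matrix("ACDG")
  expect_true(all(colSums(one) == 1))
  expect_true(all(apply(one, 2, max) == 1))
  half <- frequency_matrix(c("A", "A", "G", "G", "A", "A", "G", "G"))
  expect_equal(half["A", 1], 0.5)
  expect_equal(half["G", 1], 0.5)
  expect_error(frequency_matrix(c("AC", "ACD")), "equal")
  # Table-style right-alignment of the citcol family: the shared 35-residue
  # core is fully conserved except the two S/Y positions and position 14/18
  pad <- vapply(citcol, function(s)
    paste0(strrep("-", 39 - nchar(s)), s), character(1))
  fm <- frequency_matrix(pad)
  core <- fm[, 5:39]
  n_variable <- sum(apply(core, 2, max) < 1)
  expect_identical(n_variable, 3L)
})

test_that("neighbor joining separates planted families concordant with P1", {
  c8 <- citcol[["citcol-8"]]
  fam_a <- gen_crp(5, base = c8, mutation_rate = 0.08,
                   p1_policy = "aromatic", seed = 21)
  fam_b <- gen_crp(5, base = reference_crps[["P82410"]],
                   mutation_rate = 0.08, p1_policy = "basic", seed = 22)
  names(fam_a) <- paste0("amp", 1:5)
  names(fam_b) <- paste0("ti", 1:5)
  tr <- nj_tree(c(fam_a, fam_b))
  expect_s3_class(tr, "phylo")
  expect_identical(sort(tr$tip.label), sort(c(names(fam_a), names(fam_b))))
  expect_true(all(tr$edge.length >= 0))
  expect_true(ape::is.monophyletic(tr, names(fam_a)))
  expect_true(ape::is.monophyletic(tr, names(fam_b)))
  # tree bipartition agrees with the P1 classification
  labs <- vapply(c(fam_a, fam_b), function(s) classify_p1(s)$label,
                 character(1))
  expect_true(all(labs[names(fam_a)] == "antimicrobial_like"))
  expect_true(all(labs[names(fam_b)] == "trypsin_inhibitor_like"))
  # the citcol family is monophyletic against the MCoTI outgroup
  tr2 <- nj_tree(c(citcol, MCoTI_III = reference_crps[["P82410"]]))
  expect_true(ape::is.monophyletic(tr2, names(citcol)))
  expect_error(nj_tree(citcol[1:2]), "3 sequences")
})
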