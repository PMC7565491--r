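test_that("b/y series follow the fragment-ion arithmetic", {
  s <- ion_series("AG")
  expect_equal(s$b[1], 72.0444, tolerance = 1e-3)
  expect_equal(s$y[1], 76.0393, tolerance = 1e-3)
  expect_equal(ion_series(peptide("VCLFVGK", cam = TRUE))$y[[1]], 147.1128,
               tolerance = 1e-3)
  expect_error(ion_series("A"), "at least 2")
  # complementarity: b_i + y_(n-i) = M + 2 protons, for random peptides
  set.seed(31)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:10) {
    sq <- paste(sample(aas, sample(4:15, 1), TRUE), collapse = "")
    p <- peptide(sq, n_disulfides = 0)
    io <- ion_series(p)
    n <- nchar(sq)
    expect_equal(io$b + rev(io$y),
                 rep(peptide_mass(p)[["M"]] + 2 * 1.0072765, n - 1),
                 tolerance = 1e-6)
  }
})

test_that("complete ladders are read back with the J ambiguity code", {
  sp <- sim_msms("VCLFVGK", jitter_sd = 0, dropout = 0, n_decoys = 0,
                 seed = 1)
  cc <- interpret_spectrum(sp, tol = 0.05)
  expect_gt(length(cc), 0)
  top <- cc[[1]]
  expect_identical(top$sequence, "VCJFVGK")
  expect_equal(top$coverage, 1)
  expect_true(top$flags$ji[3])
  expect_true(top$flags$kq[7])  # terminal K is K/Q-ambiguous at 0.05 Da
  # empty spectrum
  expect_identical(interpret_spectrum(msms_spectrum(800, numeric(0))),
                   list())
})

test_that("a deleted b-ion is recovered through the complementary y-ion", {
  io <- ion_series(peptide("VCLFVGK", cam = TRUE))
  mh <- peptide_mass(peptide("VCLFVGK", cam = TRUE))[["MH"]]
  mz <- c(io$b[-3], io$y)  # drop b3, keep all y
  cc <- interpret_spectrum(msms_spectrum(mh, mz), tol = 0.05)
  expect_identical(cc[[1]]$sequence, "VCJFVGK")
  expect_equal(cc[[1]]$coverage, 1)  # y4 complements the lost b3
})

test_that("interpretation is invariant to intensity scaling and inert noise", {
  io <- ion_series(peptide("PWDKCTDAF", cam = TRUE))
  mh <- peptide_mass(peptide("PWDKCTDAF", cam = TRUE))[["MH"]]
  mz <- c(io$b, io$y)
  base <- interpret_spectrum(msms_spectrum(mh, mz, rep(1, length(mz))))
  scaled <- interpret_spectrum(msms_spectrum(mh, mz, rep(250, length(mz))))
  expect_identical(sapply(base, `[[`, "sequence"),
                   sapply(scaled, `[[`, "sequence"))
  # noise peaks that chain with nothing do not change the top read
  noisy <- interpret_spectrum(
    msms_spectrum(mh, c(mz, c(233.3337, 477.7779, 801.1113))))
  expect_identical(noisy[[1]]$sequence, base[[1]]$sequence)
})

test_that("fragment assembly reconstructs the parent from two digests", {
  c2 <- citcol[["citcol-2"]]
  frags <- data.frame(
    sequence = c("VCLFVGK", "PCWSDADCPSGCYCK", "PLPLIDAGYCGFL",
                 "VGKPCWSDADCPSGCY", "CKPLPLIDAGYCGFL"),
    enzyme = c("trypsin", "trypsin", "trypsin",
               "chymotrypsin", "chymotrypsin"))
  asm <- assemble_fragments(frags, intact_mh = 3734.1, mass_tol = 0.7)
  expect_identical(asm$consensus, c2)
  expect_false(asm$ambiguous)
  # a single full-length fragment assembles to itself
  solo <- assemble_fragments(data.frame(sequence = c2, enzyme = "trypsin"),
                             intact_mh = 3734.1)
  expect_identical(solo$consensus, c2)
  # contradictory overlaps cannot be placed
  expect_error(
    assemble_fragments(data.frame(sequence = c("AKAAAG", "AKACCG"),
                                  enzyme = "trypsin"),
                       intact_mh = 700),
    "conflict|mass")
})

test_that("disjoint fragments yield both orderings, flagged ambiguous", {
  # two tryptic fragments with no overlap: order is underdetermined
  frags <- data.frame(sequence = c("AGAK", "VMFK"), enzyme = "trypsin")
  mh <- peptide_mass(peptide("AGAKVMFK", n_disulfides = 0))[["MH"]]
  asm <- assemble_fragments(frags, intact_mh = mh, mass_tol = 0.2)
  expect_true(asm$ambiguous)
  expect_setequal(asm$sequences, c("AGAKVMFK", "VMFKAGAK"))
})

test_that("Lys/Gln and Leu/Ile resolve from complete-digest evidence", {
  c2 <- citcol[["citcol-2"]]
  frags <- list(
    list(sequence = "VCJFVGK", enzyme = "trypsin"),
    list(sequence = "PCWSDADCPSGCYCK", enzyme = "trypsin"),
    list(sequence = "PJPJJDAGYCGFJ", enzyme = "trypsin"),
    list(sequence = "VGKPCWSDADCPSGCY", enzyme = "chymotrypsin"))
  asm <- assemble_fragments(frags, intact_mh = 3734.1, mass_tol = 0.7)
  expect_identical(norm_isobaric(asm$consensus), norm_isobaric(c2))
  pk <- list(trypsin = digest_complete(c2, "trypsin")$mh,
             chymotrypsin = digest_complete(c2, "chymotrypsin")$mh)
  res <- resolve_isobaric(asm, pk, tol = 0.3)
  # I27 stays Ile: no chymotryptic boundary after it is supported
  expect_identical(substr(res$consensus, 27, 27), "I")
  # internal leucines are set by their observed boundary fragments
  expect_identical(substr(res$consensus, 24, 26), "LPL")
  # the C-terminal residue is cleavage-blind and waits for composition
  expect_true(res$flags$ji[35])
  res <- resolve_by_composition(res, aa_composition(c2))
  expect_identical(res$consensus, c2)
  # an assembly without flags passes through unchanged
  plain <- assemble_fragments(data.frame(sequence = "AGAK", enzyme = "trypsin"),
                              intact_mh = peptide_mass(peptide("AGAK"))[["MH"]])
  expect_identical(resolve_isobaric(plain, pk)$consensus, "AGAK")
})

test_that("noisy 7-mer spectra are mostly read back correctly", {
  # Monte-Carlo at 20% per-ion dropout, calibration jitter and decoy peaks
  # (seeds fixed; expectations are the computed recovery of this
  # interpreter, whose irreducible losses are forward/reverse ladder
  # symmetry and dipeptide transposition ties)
  set.seed(99)
  aas <- setdiff(strsplit("GASPVTCLNDQKEMHFRYW", "")[[1]], "C")
  top1 <- 0; top5 <- 0; n <- 60
  for (i in 1:n) {
    s <- paste(sample(aas, 7, replace = TRUE), collapse = "")
    sp <- sim_msms(s, jitter_sd = 0.01, dropout = 0.2, n_decoys = 5,
                   seed = 1000 + i)
    cc <- tryCatch(interpret_spectrum(sp, tol = 0.05),
                   error = function(e) list())
    seqs <- vapply(cc, function(x) norm_isobaric(x$sequence), character(1))
    if (length(seqs) && seqs[1] == norm_isobaric(s)) top1 <- top1 + 1
    if (norm_isobaric(s) %in% utils::head(seqs, 5)) top5 <- top5 + 1
  }
  expect_gte(top1 / n, 0.70)
  expect_gte(top5 / n, 0.85)
})
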