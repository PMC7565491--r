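test_that("residue masses follow the standard monoisotopic table", {
  expect_equal(residue_mass("G"), 57.02146)
  expect_equal(residue_mass("W"), 186.07931)
  # the isobaric pairs that drive the enzymatic-resolution workflow
  expect_equal(residue_mass("L"), residue_mass("I"))
  expect_equal(residue_mass("K") - residue_mass("Q"), 0.03638,
               tolerance = 1e-6)
  expect_error(residue_mass("B"), "non-standard")
  expect_error(residue_mass("Z"), "non-standard")
})

test_that("peptide masses are additive over residues, water, mods, disulfides", {
  # water + proton only
  expect_equal(unname(peptide_mass(peptide("", n_disulfides = 0))[["MH"]]),
               19.01784, tolerance = 1e-4)
  # carbamidomethylated tryptic fragment, oracle value
  expect_equal(peptide_mass(peptide("VCLFVGK", cam = TRUE))[["MH"]],
               822.4542, tolerance = 1e-3)
  # native fully-oxidized citcol-2 (3 disulfides by default)
  p <- peptide(citcol[["citcol-2"]])
  expect_identical(p$n_disulfides, 3L)
  expect_equal(peptide_mass(p)[["MH"]], 3734.6319, tolerance = 1e-3)
  # additivity: M(A++B) = M(A) + M(B) - water, over random unmodified pairs
  set.seed(11)
  aas <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "C")
  for (i in 1:20) {
    a <- paste(sample(aas, sample(3:10, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(3:10, 1), TRUE), collapse = "")
    expect_equal(
      peptide_mass(peptide(paste0(a, b), n_disulfides = 0))[["M"]],
      peptide_mass(peptide(a, n_disulfides = 0))[["M"]] +
        peptide_mass(peptide(b, n_disulfides = 0))[["M"]] - 18.01056,
      tolerance = 1e-5)
  }
  expect_error(peptide("VCLFVGK", n_disulfides = 2), "n_disulfides")
})

test_that("reduction/alkylation shift is 58.029 Da per oxidized cysteine", {
  expect_equal(reduction_alkylation_shift(6, 3), 348.18, tolerance = 0.01)
  expect_equal(reduction_alkylation_shift(0, 0), 0)
  # constant per-cysteine shift whatever the count
  for (n in seq(2, 20, by = 2))
    expect_equal(reduction_alkylation_shift(n, n / 2) / n, 58.0293,
                 tolerance = 1e-4)
  expect_error(reduction_alkylation_shift(-1, 0), "non-negative")
  expect_error(reduction_alkylation_shift(2, 2), "at least")
})

test_that("observed intact citcol masses sit near theory (calibration spread)", {
  # printed values are observed with instrument error; the spread reaches
  # ~0.75 Da on the heaviest peptides
  theor <- vapply(citcol, function(s) peptide_mass(peptide(s))[["MH"]],
                  numeric(1))
  expect_true(all(abs(theor - citcol_observed_mh) <= 0.75))
})

test_that("amino-acid composition counts residues", {
  comp8 <- aa_composition(citcol[["citcol-8"]])
  expect_identical(comp8[["C"]], 6L)
  expect_identical(comp8[["W"]], 1L)
  expect_identical(comp8[["Y"]], 2L)
  expect_identical(sum(comp8), nchar(citcol[["citcol-8"]]))
  expect_true(all(aa_composition("") == 0L))
  # citcol-2 differs from citcol-1 by a single S -> Y substitution
  d <- aa_composition(citcol[["citcol-2"]]) - aa_composition(citcol[["citcol-1"]])
  expect_identical(d[["Y"]], 1L)
  expect_identical(d[["S"]], -1L)
  expect_identical(sum(d != 0L), 2L)
})
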