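test_that("cleavage sites honour specificity and the proline-block flag", {
  c2 <- citcol[["citcol-2"]]
  # both citcol-2 lysines precede proline: only the relaxed rule cuts there
  expect_identical(cleavage_sites(c2, "trypsin"), c(7L, 22L))
  expect_identical(
    cleavage_sites(c2, enzyme("trypsin", block_before_proline = TRUE)),
    integer(0))
  expect_identical(cleavage_sites("AAAA", "trypsin"), integer(0))
  expect_identical(cleavage_sites("AAAA", "chymotrypsin"), integer(0))
  expect_identical(cleavage_sites("AEAEA", "glu-c"), c(2L, 4L))
  # the last residue is never a site
  expect_identical(cleavage_sites("AK", "trypsin"), integer(0))
  expect_error(enzyme("pepsin"), "unknown enzyme")
})

test_that("complete digestion tiles the parent and respects missed cleavages", {
  c2 <- citcol[["citcol-2"]]
  d0 <- digest_complete(c2, "trypsin", max_missed = 0)
  expect_setequal(d0$sequence,
                  c("VCLFVGK", "PCWSDADCPSGCYCK", "PLPLIDAGYCGFL"))
  expect_identical(paste(d0$sequence[order(d0$start)], collapse = ""), c2)
  expect_true(all(d0$missed_cleavages == 0L))
  d1 <- digest_complete(c2, "trypsin", max_missed = 1)
  expect_setequal(setdiff(d1$sequence, d0$sequence),
                  c("VCLFVGKPCWSDADCPSGCYCK",
                    "PCWSDADCPSGCYCKPLPLIDAGYCGFL"))
  # no-site sequence: the whole parent, 0 missed
  dn <- digest_complete("AAAA", "trypsin")
  expect_identical(dn$sequence, "AAAA")
  expect_identical(dn$missed_cleavages, 0L)
})

test_that("partial digestion enumerates all site-bounded substrings", {
  c2 <- citcol[["citcol-2"]]
  pt <- digest_partial(c2, "trypsin")
  # n sites -> choose(n + 2, 2) fragments
  n <- length(cleavage_sites(c2, "trypsin"))
  expect_identical(nrow(pt), as.integer(choose(n + 2, 2)))
  expect_true("PCWSDADCPSGCYCKPLPLIDAGYCGFL" %in% pt$sequence)
  pc <- digest_partial(c2, "chymotrypsin")
  expect_true(all(c("CKPLPLIDAGY", "CKPLPLIDAGYCGFL",
                    "VGKPCWSDADCPSGCY") %in% pc$sequence))
  expect_identical(digest_partial("W", "chymotrypsin")$sequence, "W")
  # union-closure: merging adjacent partial fragments stays in the set
  key <- paste(pt$start, pt$end)
  for (i in seq_len(nrow(pt))) {
    adjacent <- which(pt$start == pt$end[i] + 1L)
    for (j in adjacent)
      expect_true(paste(pt$start[i], pt$end[j]) %in% key)
  }
})

test_that("theoretical fragment masses match the observed digest signals", {
  c2 <- citcol[["citcol-2"]]
  frags <- rbind(cbind(digest_partial(c2, "trypsin"), enzyme = "trypsin"),
                 cbind(digest_partial(c2, "chymotrypsin"),
                       enzyme = "chymotrypsin"))
  for (i in seq_len(nrow(observed_fragments))) {
    row <- observed_fragments[i, ]
    hit <- frags[frags$sequence == row$sequence & frags$enzyme == row$enzyme, ]
    expect_identical(nrow(hit), 1L)
    # reflector-mode signals sit within 0.2 Da of theory (most within 0.1)
    expect_lt(abs(hit$mh - row$observed_mh), 0.2)
  }
  # fragment masses are consistent with the core mass arithmetic
  d0 <- digest_complete(c2, "trypsin")
  expect_equal(d0$mh[d0$sequence == "VCLFVGK"],
               peptide_mass(peptide("VCLFVGK", cam = TRUE))[["MH"]])
  # sub-500 Da fragments are kept but flagged below the matrix region
  df <- digest_partial("AKAK", "trypsin")
  expect_true(all(df$low_mass))
})
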