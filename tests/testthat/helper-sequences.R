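# Published citcol peptide sequences and the reference CRPs they are
# compared against, plus frozen monoisotopic expectations computed with an
# independent mass oracle (pyteomics standard residue table).

citcol <- c(
  `citcol-1` = "VCLFVGKPCWSDADCPSGCSCKPLPLIDAGYCGFL",
  `citcol-2` = "VCLFVGKPCWSDADCPSGCYCKPLPLIDAGYCGFL",
  `citcol-3` = "VGVCLFVGKPCWSDADCPSGCSCKPLPLIDAGYCGFL",
  `citcol-4` = "VGVCLFVGKPCWSDADCPSGCYCKPLPLIDAGYCGFL",
  `citcol-5` = "RVGVCLFVGKPCWSDADCPSGCYCKPLPLIDAGYCGFL",
  `citcol-6` = "NRVGVCLFVGKPCWSDADCPSGCSCKPLPLIDAGYCGFL",
  `citcol-7` = "NRVGVCLFVGKPCKSDANCPSGCYCKPLPLIDAGYCGFL",
  `citcol-8` = "NRVGVCLFVGKPCWSDADCPSGCYCKPLPLIDAGYCGFL")

# observed [M+H]+ of the purified native peptides
citcol_observed_mh <- c(3658.1, 3734.1, 3814.4, 3890.2, 4046.9, 4084.1,
                        4101.2, 4160.3)

# reference cysteine-rich peptides (UniProt) used for similarity analysis,
# with the published EMBOSS-Needle percent similarity to citcol-8
reference_crps <- c(
  P82410 = "QRACPRILKKCRRDSDCPGECICKENGYCG",        # MCoTI-III
  P01075 = "HADPICNKPCKTHDDCSGAWFCQACWNSARTCGPY",
  P81418 = "AGCIKNGGRCNASAGPPYCCSSYCFQIAGQSYGVCKNR",
  P84781 = "EDKCSPSGAICSGFGPPEQCCSGACVPHPILRIFVCQ",
  P80403 = "CIPKWNRCGPKMDGVPCCEPYTCTSDYYGNCS",
  Q5I2B2 = "AGECVQGRCPSGMCCSQFGYCGRGPKYCGR",
  Q07A30 = "TYSCGGHIDCKDFCKSEGYRGFKCTPKKTCTCFH")
reference_similarity <- c(P82410 = 43.6, P01075 = 38.5, P81418 = 31.7,
                          P84781 = 29.5, P80403 = 27.3, Q5I2B2 = 26.7,
                          Q07A30 = 20.0)

# translated-genome homolog of citcol-8 (Cucumis melo chromosome 7)
cmelo_homolog <- "RLGVCLLVGKPCMSDADCPSGCYCKPVPLLDIGYCGFL"

# frozen monoisotopic [M+H]+ values (independent oracle)
frozen_mh <- c(
  citcol2_native       = 3734.6319,  # 3 disulfides
  citcol8_native       = 4160.8658,
  VCLFVGK_cam          = 822.4542,
  PLPLIDAGYCGFL_cam    = 1435.7290,
  CKPLPLIDAGY_cam      = 1246.6500,
  CKPLPLIDAGYCGFL_cam  = 1723.8546,
  VGKPCWSDADCPSGCY_cam = 1858.7193,
  PCWSDADCPSGCYCKPLPLIDAGYCGFL_cam = 3279.3712,
  PCWSDADCPSGCYCK_cam  = 1862.6601)

# observed partial-digest fragment masses of citcol-2
observed_fragments <- data.frame(
  sequence = c("VCLFVGK", "PLPLIDAGYCGFL", "CKPLPLIDAGY", "CKPLPLIDAGYCGFL",
               "VGKPCWSDADCPSGCY", "PCWSDADCPSGCYCKPLPLIDAGYCGFL"),
  enzyme = c("trypsin", "trypsin", "chymotrypsin", "chymotrypsin",
             "chymotrypsin", "trypsin"),
  observed_mh = c(822.4, 1435.7, 1246.6, 1723.8, 1858.6, 3279.2))

# collapse the isobaric codes a spectrum alone cannot separate
norm_isobaric <- function(s) gsub("Q", "K", chartr("IJ", "LL", s))
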