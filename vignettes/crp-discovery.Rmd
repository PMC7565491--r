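---
title: "Discovering cysteine-rich peptides with crpkit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cysteine-rich peptides with crpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpkit)
```

# The scientific problem

Plants of the squash family (Cucurbitaceae) produce small peptides
stabilized by three disulfide bonds, often arranged as an inhibitor cystine
knot (ICK): the disulfide C~I~–C~IV~ and C~II~–C~V~ form a ring that the
third bond, C~III~–C~VI~, threads. Some of these peptides are potent
trypsin inhibitors; close relatives with the same cysteine scaffold are
antimicrobial instead. crpkit implements the complete computational
workflow for discovering and characterizing such peptides from MALDI-TOF
mass spectrometry and sequence data:

1. **Cysteine counting by alkylation mass shift.** Reduction of a
   disulfide adds two hydrogens (2 × 1.00783 Da); carbamidomethylation of
   each liberated thiol by iodoacetamide adds 57.02146 Da. A fully
   oxidized peptide therefore shifts by 58.029 Da *per cysteine*, so a
   Δ348.2 Da shift between the native and the reduced/alkylated spectrum
   identifies six cysteines and three disulfides
   (`pair_peaks()`, `count_cys_from_shift()`).
2. **In-silico digestion** with trypsin, chymotrypsin, or Glu-C, complete
   (tiling, bounded missed cleavages) or partial (every site-bounded
   substring) — `digest_complete()`, `digest_partial()`.
3. **De novo sequencing**: theoretical singly-charged b/y series
   (`ion_series()`), ladder interpretation of MS/MS spectra
   (`interpret_spectrum()`), assembly of overlapping digest fragments into
   the full-length sequence (`assemble_fragments()`), and enzymatic plus
   composition-based resolution of the isobaric residue pairs
   (`resolve_isobaric()`, `resolve_by_composition()`).
4. **Annotation**: cysteine-loop decomposition (`loop_pattern()`),
   putative knot connectivity (`putative_connectivity()`), and functional
   classification from the P1 residue (`classify_p1()`).
5. **Similarity and phylogeny**: EMBOSS-Needle-convention global alignment
   (`needle_align()`), frequency-logo matrices (`frequency_matrix()`), and
   neighbor-joining trees (`nj_tree()`).
6. **Mining** of six-frame-translated nucleotide data for homologous
   precursors (`six_frame_translate()`, `scan_motif()`, `rank_hits()`,
   `mine_sequences()`).
7. **Assay arithmetic**: extinction coefficients, Beer–Lambert
   concentrations and percent inhibition (`extinction_coefficient()`,
   `molar_concentration()`, `percent_inhibition()`).

Seeded simulators (`gen_crp()`, `sim_peaklists()`, `sim_msms()`,
`gen_precursor_genome()`) generate every input class the pipeline
consumes, so the whole chain is testable without instrument data or
database downloads.

# Mass model

All masses are monoisotopic, from the standard residue table at five
decimals; average masses are unsupported because reflector-mode MALDI data
are monoisotopic. Peptides are linear with free termini:

$$M = \sum_i m_{r_i} + 18.01056 + \sum_j \Delta_j - n_{SS}\cdot 2\cdot 1.00783,
\qquad [M+H]^+ = M + 1.00728 .$$

Native cystine-knot peptides default to the fully oxidized state
($n_{SS} = \lfloor n_{Cys}/2\rfloor$); `cam = TRUE` models the
reduced/carbamidomethylated state used for digestion and MS/MS.

Two residue pairs are indistinguishable by fragment mass at MALDI-TOF/TOF
accuracy: Leu/Ile (identical) and Lys/Gln (Δ0.0364 Da, below realistic
fragment tolerances). crpkit reports `J` for Leu/Ile, and keeps Lys/Gln as
the nearest-mass letter with a per-position flag.

```{r}
peptide_mass(peptide("VCLFVGK", cam = TRUE))[["MH"]]
reduction_alkylation_shift(n_cys = 6, n_disulfides = 3)
```

# Digestion rules

The presets are trypsin (after K/R), chymotrypsin (after F/Y/W/L, the
high-specificity set plus Leu), and Glu-C (after E only, the
ammonium-bicarbonate specificity). Two deliberate choices:

* **The trypsin proline block is off by default.** The observed citcol
  digest fragments (e.g. the 822.4 Da N-terminal peptide) require cleavage
  at Lys–Pro junctions, which the classical "no cleavage before Pro" rule
  forbids. `enzyme("trypsin", block_before_proline = TRUE)` restores the
  classical rule.
* Fragments below 500 Da are retained but flagged `low_mass`: they fall in
  the MALDI matrix region and would not be observed.

Coordinates are 1-based inclusive throughout, the R convention.

# The de novo interpreter

`interpret_spectrum()` works in *prefix space*: every peak is considered
both as a b-ion and as the complement of a y-ion
($b_i = [M+H]^+ + 1.00728 - y_{n-i}$), readings closer than half the
tolerance are merged into nodes, and residue-mass gaps between nodes form
a DAG walked by a beam dynamic program (default beam 50 partial ladders
per node). The ranking score is

$$\text{score} = \#\text{supported} - \#\text{inserted} -
  \sum_e \left(\frac{\max(0, |r_e| - 0.3\,\tau)}{\tau/5}\right)^2$$

where $r_e$ is the mass residual of edge $e$ and $\tau$ the fragment
tolerance (default 0.05 Da). The deadband leaves honest calibration jitter
unpenalized while coincidental matches near the tolerance edge forfeit
several support points; scores are quantized to half-points for ranking so
that parsimony (coverage, then intensity, then lexicographic order)
decides near-ties. Two structural rules matter:

* **Complement exclusion**: a physical ladder consumes each peak in one
  ion role, so a path may not visit both a node and its complement. This
  bars "hybrid" readings that double-count the two series. Near
  mass-palindromic peptides legitimately violate it, so an exclusion-free
  fallback pass runs when no complete ladder survives.
* **Bridges**: one missing ladder position may be crossed by a dipeptide
  gap; inside the single-residue mass range a bridge is only offered when
  it fits clearly better than any single residue (exact isobars such as
  Gly+Gly versus Asn must read as one residue).

Limits that no mass-only interpreter can cross: the forward and reversed
reading of a symmetric peak set are exactly equivalent; the two orders of
a bridged dipeptide are equivalent; and compositional near-isobars
(Gly+Glu vs Trp at Δ0.015 Da, Gly+Val vs Arg at Δ0.011 Da) can be cheaper
than the true reading in unlucky jitter realizations. These are resolved
downstream, not in the spectrum.

# Assembly and isobar resolution

`assemble_fragments()` searches placements of fragment candidates (each
fragment may bring its ranked candidate list, letting the assembler pick
among interpretations) such that overlaps agree ambiguity-aware, every
fragment starts at the peptide N-terminus or right after a cleavage
residue of its own enzyme, and — the package's own extension — *ends* in a
cleavage residue or at the peptide C-terminus. The C-side rule is what
rejects mirrored readings, whose reversal preserves mass and overlaps but
not protease specificity. Surviving consensi must match the measured
intact native mass (default tolerance 0.7 Da, absorbing the calibration
offset between linear-mode intact masses and reflector-mode fragments)
and, when supplied, the measured amino-acid composition (isobar-aware:
the Leu/Ile and Lys/Gln pools are counted jointly).

`resolve_isobaric()` then uses enzyme specificity: a flagged Lys/Gln
position is Lys iff the complete tryptic digest of the hypothesized
sequence has *both* cleavage products of that boundary matched by observed
peaks; Leu/Ile is decided the same way from chymotrypsin. A first
left-to-right sweep uses the N-terminal product only (downstream sites are
uncommitted), then two-sided refinement sweeps run to a fixpoint.
Requiring both products removes chance collisions of a single fragment
mass. The peptide's C-terminal residue has no cleavage products at all and
is left to `resolve_by_composition()` — mirroring the role that hydrolysis
amino-acid analysis plays in the wet-lab workflow.

```{r}
c2 <- "VCLFVGKPCWSDADCPSGCYCKPLPLIDAGYCGFL"  # citcol-2
frags <- data.frame(
  sequence = c("VCLFVGK", "PCWSDADCPSGCYCK", "PLPLIDAGYCGFL",
               "VGKPCWSDADCPSGCY", "CKPLPLIDAGYCGFL"),
  enzyme = c("trypsin", "trypsin", "trypsin",
             "chymotrypsin", "chymotrypsin"))
asm <- assemble_fragments(frags, intact_mh = 3734.1)
asm$consensus
```

# Annotation and classification

The citcol-type scaffold is `X(1-5) C X6 C X5 C X3 C X1 C X10 C X(0-3)`;
the trypsin-inhibitor branch shares loops 1–4 but has a short loop 5
(e.g. 5 residues in MCoTI-III). The P1 residue — the residue N-terminal to
the scissile bond of a canonical inhibitor — sits at the second position
of loop 1; this offset is an inference from the aligned examples
(Phe in the citcol loop `LFVGKP`, Arg/Lys in squash inhibitors) and is
configurable. Arg/Lys at P1 predicts trypsin inhibition; anything else is
labelled antimicrobial-like.

```{r}
classify_p1("NRVGVCLFVGKPCWSDADCPSGCYCKPLPLIDAGYCGFL")[c("p1_residue", "label")]
```

`needle_align()` wraps an overlap (free-end-gap) global alignment with
BLOSUM62 and affine gaps 10/0.5, and reports EMBOSS-Needle-style
statistics over the full padded alignment: identity, similarity
(positive-scoring pairs), and gaps, each as a percentage of the alignment
length including end gaps. These conventions reproduce published
similarity percentages exactly. The phylogeny module deliberately uses
neighbor joining on `1 - identity` distances rather than maximum
likelihood: at desk scale the question is the two-branch split
(antimicrobial vs trypsin-inhibitor), which NJ recovers on planted
families with ≥40% inter-family divergence; bootstrap support and ML
branch lengths are out of scope.

# Mining

Nucleotide data are translated in all six frames (stops retained; fuzzy
codons as `X`), scanned for six-cysteine windows whose spacings satisfy
the loop template (default loops 6, 5, 3, 1, 5–12 — wide enough in loop 5
for both branches), with stop- and `X`-free flanks. Candidates are scored
by Smith–Waterman local alignment against the queries and thresholded on
an E-value estimated with *ungapped* Karlin–Altschul constants for
BLOSUM62 (λ ≈ 0.318, K ≈ 0.13), scaled by query length and database size.
This is an approximation — applied to gapped scores it understates E
slightly, so against a conservative composition-preserving shuffle null
of a 6-cysteine query an occasional borderline decoy (E ≈ 6×10⁻⁴) can
slip under the 0.001 cutoff — adequate for thresholding on user-supplied
FASTA but not calibrated against NCBI's gapped statistics. Motif
filtering before scoring keeps random nucleotide background at zero hits
in practice.

# The simulators and what they do (not) show

The generators emulate the study conditions: six-cysteine peptides on the
knottin-like loop template with the P1 policy of either branch;
native/alkylated MALDI peak lists with Gaussian calibration jitter
(default σ 0.05 Da), log-normal intensities and uniform decoy peaks;
MS/MS spectra as complete b/y ladders with per-ion dropout (default 0.1),
fragment jitter (default σ 0.01 Da) and decoys; and uniform-random ACGT
backgrounds with precursors reverse-translated through uniformly sampled
synonymous codons. They do **not** model isotope envelopes, multiply
charged ions, intensity structure along the ladder, codon bias, or
nonspecific proteolysis — so passing round trips demonstrate the
correctness of the inference chain under the stated noise, not
instrument-grade performance on real spectra.

Measured behaviour at the package's chosen problem sizes (all seeded, all
computed by the test suite):

* **Full-ladder round trip** — generate CRPs, simulate partial digests
  and complete b/y spectra (jitter 0.01 Da, 5 decoys), interpret,
  assemble, resolve: 57/60 (95.0%) exact sequence recovery at the
  suite's problem size, 188/200 (94.0%) at a larger one. Failures are
  deep isobaric coincidences (compositional near-isobars combined with
  symmetric peak subsets).
* **Noisy 7-mers** — at 20% per-ion dropout the top-1 exact-read rate is
  about 75% (85%+ within the top five candidates); the irreducible losses
  are the forward/reverse ladder symmetry and bridged-dipeptide order
  ties. In the full pipeline these are rescued by overlap assembly, which
  is why the workflow digests with two enzymes rather than sequencing
  single spectra.
* **At the default 10% dropout** the end-to-end recovery is ~84%: missing
  ladder positions in *multiple* overlapping fragments cannot always be
  reconciled. The wet-lab countermeasure — acquiring more spectra — has no
  equivalent inside a fixed simulation.

# Numerical choices

* Pairing tolerance 0.3 Da (observed alkylation-shift spread ±0.2 Da);
  fragment tolerance 0.05 Da (below it the Lys/Gln gap would pretend to be
  resolvable by mass, which MALDI-TOF/TOF cannot do); intact-mass check
  0.7 Da; boundary-evidence matching 0.3 Da.
* Observed intact masses of the published peptide family sit up to
  ~0.75 Da below theory while reflector-mode fragment masses agree within
  0.06–0.17 Da; the package treats intact values as observed with
  calibration error and never forces equality tighter than that spread.
* Alignment tie-breaks follow the underlying dynamic program
  deterministically; generator RNG is R's default, seeded per call, and
  identical seeds give byte-identical outputs.

# Known limitations

* Direction (forward vs reversed) of a single spectrum is undecidable
  from masses alone; assembly context or protease specificity is needed.
* E-values are screening estimates, not NCBI-calibrated.
* Disulfide connectivity is a homology-based prediction
  (C I–IV, II–V, III–VI), not determined from data.
* The P1 offset within loop 1 is an inference from aligned examples,
  exposed as a parameter.
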