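# crpkit

Discovery and characterization of plant cysteine-rich peptides (CRPs)
from mass spectrometry and sequence data.

Squash-family (Cucurbitaceae) plants produce ~3.5–4.5 kDa peptides held
together by three disulfide bonds, frequently in the inhibitor cystine
knot (ICK) topology C<sub>I</sub>–C<sub>IV</sub>,
C<sub>II</sub>–C<sub>V</sub>, C<sub>III</sub>–C<sub>VI</sub>. Whether such
a peptide inhibits trypsin or acts as an antimicrobial is encoded in small
sequence features — above all the P1 residue at the second position of
loop 1 (Arg/Lys → trypsin inhibitor; Phe and others → antimicrobial-like).
crpkit implements the full desk workflow for finding and sequencing these
peptides:

* **Cysteine counting** from the reduction + carbamidomethylation mass
  shift between native and alkylated MALDI peak lists
  (58.029 Da per oxidized cysteine): `pair_peaks()`,
  `count_cys_from_shift()`.
* **In-silico digestion** (trypsin / chymotrypsin / Glu-C, complete or
  partial, missed cleavages, Lys–Pro cleavage on by default as the
  observed fragments require): `digest_complete()`, `digest_partial()`.
* **De novo sequencing** from b/y-ion ladders: `ion_series()`,
  `interpret_spectrum()`, `assemble_fragments()`, with enzymatic
  resolution of Leu/Ile and Lys/Gln (`resolve_isobaric()`) and
  composition-based confirmation (`resolve_by_composition()`).
* **Annotation**: cysteine-loop decomposition (`loop_pattern()`), knot
  connectivity prediction (`putative_connectivity()`), P1 classification
  (`classify_p1()`).
* **Similarity and trees**: EMBOSS-Needle-convention global alignment
  (`needle_align()`), frequency-logo matrices, neighbor-joining trees.
* **Genome/transcriptome mining**: six-frame translation, cysteine-spacing
  motif scan, Smith–Waterman ranking with Karlin–Altschul E-value
  estimates: `mine_sequences()`.
* **Assay arithmetic**: extinction coefficients, Beer–Lambert
  concentrations, percent inhibition.
* **Seeded simulators** for peak lists, fragment spectra, CRP sequences
  and precursor-bearing genomes: `gen_crp()`, `sim_peaklists()`,
  `sim_msms()`, `gen_precursor_genome()`.

The model at the core is plain monoisotopic mass arithmetic,
M = Σ residues + H₂O + Σ mods − n<sub>SS</sub>·2H, combined with a beam
dynamic program over the spectrum graph (peaks read as b-ions and as
y-complements) and protease-aware overlap assembly. The methods vignette
(`vignettes/crp-discovery.Rmd`) describes the scoring, the boundary rules
and every tunable default.

## Worked example

Count cysteines from an observed native/alkylated peak pair, then
reconstruct a peptide from its digest spectra:

```r
library(crpkit)

pair_peaks(3734.2, 4082.3, tol = 0.3)
#>   native_mz alkylated_mz delta n_cys   residual primary
#> 1    3734.2       4082.3 348.1     6 -0.0757322    TRUE
```

A shift of 348.1 Da is six cysteines (6 × 58.029 = 348.18), i.e. three
disulfides. Digesting the corresponding purified peptide and assembling
the fragment sequences recovered from its MS/MS spectra:

```r
frags <- data.frame(
  sequence = c("VCLFVGK", "PCWSDADCPSGCYCK", "PLPLIDAGYCGFL",
               "VGKPCWSDADCPSGCY", "CKPLPLIDAGYCGFL"),
  enzyme   = c("trypsin", "trypsin", "trypsin",
               "chymotrypsin", "chymotrypsin"))
asm <- assemble_fragments(frags, intact_mh = 3734.1)
asm$consensus
#> [1] "VCLFVGKPCWSDADCPSGCYCKPLPLIDAGYCGFL"

classify_p1(asm$consensus)[c("p1_residue", "label")]
#> $p1_residue
#> [1] "F"
#>
#> $label
#> [1] "antimicrobial_like"

needle_align(read_fasta(system.file("extdata", "citcol.fasta",
                                    package = "crpkit"))[["citcol-8"]],
             "QRACPRILKKCRRDSDCPGECICKENGYCG")$similarity_pct
#> [1] 43.6
```

The peptide carries the citcol-type loop pattern with Phe at P1 — an
antimicrobial-branch CRP, 43.6% similar to the trypsin inhibitor
MCoTI-III.

A command-line front end is included at `exec/crpkit`:

```sh
exec/crpkit annotate --fasta inst/extdata/citcol.fasta
exec/crpkit mine --genome genome.fasta --queries inst/extdata/citcol.fasta --evalue 0.001
```

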