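---
title: "Models and methods behind tailscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tailscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailscreen)
```

# Scope

Cargo selection into clathrin-coated vesicles is driven by short linear
motifs in the cytoplasmic tails of membrane proteins. Three signals are
well characterised — YXX&#934; (&#934; a bulky hydrophobic residue, bound
by the &#956;2 subunit of AP-2), the acidic dileucine [D/E]XXXL[L/I]
(bound mainly by &#963;2), and FXNPXY (bound by PTB-domain alternative
adaptors) — and a fourth, YXXX&#934;N, has been proposed on the basis of a
random-tail reporter screen. `tailscreen` implements the computational
layer around that style of experiment: motif definition and scanning, tail
extraction by membrane topology, a presence/co-occurrence census, and
simulators for the two wet-lab stages (random-tail library construction
and the two-colour FACS internalization screen), plus seeded synthetic
data generators so the whole pipeline is testable end to end with no
external inputs.

# The motif grammar

Patterns are ordered position specs, written as whitespace-separated
tokens: an exact residue (`Y`), a wildcard (`x`), a bracketed alternative
set (`[DE]`), or a named residue class (`{Phi}`), with an optional
C-terminal anchor `@C<=k`. The built-in registry is:

```{r}
sapply(builtin_motifs(), format_pattern)
```

Design choices that needed a decision:

* **&#934; = {L, I, M, F, V}.** The field's conventional "bulky
  hydrophobic" set. Both experimentally observed YXXX&#934;N instances use
  L (the RYR reporter tail) and I (CTLA-4's YFIPIN), which are members
  under any reasonable reading. The class is configurable through
  `residue_class()` / `compile_pattern(classes = ...)`, because the exact
  membership of &#934; is nowhere enumerated authoritatively.
* **Anchor semantics.** "Within three residues of the C-terminus" is read
  literally: the number of residues *strictly after* the final matched
  position must be at most 3, so `...DXXLL`, `...DXXLLx`, `...DXXLLxx`
  and `...DXXLLxxx` all qualify.
* **KKXX.** Modelled with the standard dibasic ER-retrieval convention:
  lysines pinned at the &#8722;4 and &#8722;3 positions (pattern
  `K K x x @C<=0`). A looser KXKXX-style placement would be a different
  (configurable) pattern; the strict convention is the default.
* **Overlaps and copies.** `scan_tail()` reports every matching window,
  including overlapping ones; presence-level statistics use `has_motif()`
  ("at least one copy"), so copy number can never inflate a census.
* **Coordinates** are 1-based, inclusive, N&#8594;C everywhere, matching
  the residue-numbering style used for mutagenesis (Y2, L6, N7 of the RYR
  tail).
* **Unknown residues** (X, B, Z, U, J, O) match wildcards only — they can
  never satisfy an exact residue, a set, or a class. Scanning is
  case-insensitive.

The scanner is deliberately simple (vectorised window filtering per
position spec); its correctness is anchored by a test-suite oracle that
re-checks every window with explicit loops, over a thousand random tails
for all six built-in motifs.

# Tails from topology

A `membrane_protein_record` carries one transmembrane domain (TMD) with
1-based inclusive coordinates and a topology flag. Type I proteins expose
their C-terminus to the cytosol, so the tail is everything after the TMD;
type II proteins expose their N-terminus, and the tail is everything
before the TMD, kept in stored N&#8594;C orientation. Census defaults
restrict to type I tails (the published co-occurrence table was computed
over type I proteins); type II and combined scans are available through
`extract_tails(topology = ...)`. No minimum tail length is imposed — a
tail shorter than a pattern simply cannot match.

# The census and what it can and cannot reproduce

`run_census()` computes, per motif, the number of tails with at least one
copy, and for each motif pair the number of tails carrying both; the
diagonal of the pair matrix repeats the single counts. Conditional
overlaps (`overlap_fraction()`), any-of overlaps (`any_of_overlap()`) and
the fraction of tails free of the classical signals
(`no_signal_fraction()`) are derived views.

The published census figures (1266 type I tails, 649 without classical
signals, 60 YXXX&#934;N tails, 143 YXX&#934;/dileucine dual-motif tails,
and so on) were computed over a proteome snapshot from a
membrane-protein-localisation database that is no longer obtainable, so
those absolute numbers are *not* reproduction targets. What is reproduced
and tested is the table's semantics: at-least-one-copy counting, symmetry,
diagonal and bound invariants, and exact agreement between census counts
and realized motif truth on synthetic proteomes. YXXX&#934;N and YXX&#934;
are counted independently even where instances share a tyrosine, since
they are distinct signals mechanistically.

# Library construction model

The wet protocol: yeast genomic DNA is digested with Sau3AI (cuts
`^GATC`, leaving a BamHI-compatible 5&#8242; overhang), 50–100 bp
fragments are gel purified and ligated into the BamHI site of a reporter
plasmid whose empty cytoplasmic tail is KRLKRRRI-PISTFHDDR (the dash is
the insertion point). The simulator makes these choices:

* **Single-strand bookkeeping.** A fragment's sequence carries its
  leading GATC exactly once. Concatenating a digest therefore
  reconstructs the source (tested as an identity on random genomes), and
  splicing `upstream + insert + downstream` never double-counts junction
  nucleotides: the right-hand GATC at each junction is contributed by the
  downstream piece. In reverse orientation the duplex flips, so the
  insert's top strand becomes `GATC + revcomp(core)`.
* **Terminal fragments** of a linear molecule lack an overhang on their
  outer end and are refused ligation; on circular molecules every
  fragment is ligatable.
* **Size selection** uses inclusive bounds, [50, 100] bp, the literal
  reading of "50–100 bp".
* **The vector DNA.** Only the empty-vector peptide and the position of
  the BamHI site are published, not the plasmid sequence, so the package
  ships one concrete coding sequence (configurable in
  `vector_context()`), designed so that (i) the religated empty vector
  translates exactly to `KRLKRRRIPISTFHDDR`, and (ii) the BamHI `GGATCC`
  spans the I8–P9 codons, which makes the `ATC` inside every insert's
  leading `GATC` code the invariant isoleucine 8. Consequently every
  construct's tail begins `KRLKRRRI`, and every in-frame, stop-free
  construct ends `...IPISTFHDDR` — consistent with the observation that
  the vector-encoded IPI and DDR residues can contribute to an insert's
  internalization signal. Frame bookkeeping: with the 20-nt upstream arm,
  an insert of length *n* leaves the vector C-terminus in frame iff *n*
  &#8801; 0 (mod 3).
* **Stops and frameshifts.** Translation runs codon-by-codon from the
  vector frame; an in-insert or frameshift-induced stop truncates the
  peptide and sets `truncated_by_stop`. Complete digestion is assumed
  (no partial-digest fragments containing internal GATC).
* **Clone statistics.** Identity is the insert-encoded peptide. Expected
  amino-acid frequencies come from translating the eligible fragment pool
  in the ligation frame (i.e. from the pool's codon usage), and the
  goodness of fit is Pearson's chi-square over residues with non-zero
  expectation (df = 19 when all twenty are expected).

# Screen model

Per cell, with construct relative rate $r \in (0,1]$:

$$E \sim \mathrm{LogNormal}(0, \sigma_E),\qquad
  f = 1 - e^{-k_0\, r\, d(E)\, t},\qquad
  d(E) = \min\!\left(1, \tfrac{2s}{s+E}\right)$$

$$\text{green} = E\,[f + (1-q)(1-f)]\,\varepsilon_g,\qquad
  \text{red} = E\,(1-f)\,\varepsilon_r$$

where $t$ is the 40-minute uptake window, $q$ the quench efficiency,
$\varepsilon$ multiplicative log-normal measurement noise, and $d(E)$ a
continuous damping factor that halves the uptake rate as expression rises
well above the saturation scale $s$ ("efficiency decreases with
expression, due to saturation of the machinery"). This is a
one-compartment uptake model with no recycling over the window — the
simplest model consistent with a single uptake interval.

Defaults and their reasoning:

| parameter | default | why |
|---|---|---|
| reference rate constant $k_0$ | 0.05 min&#8315;&#185; | a rate-1 construct internalizes ~86% of label in 40 min |
| quench efficiency $q$ | 0.9 | only "never 100%" is published; 0.9 leaves a visible unquenched floor |
| expression dispersion $\sigma_E$ | 0.6 (log scale) | broad transient-transfection-like spread |
| measurement noise | 0.2 (log scale) | moderate channel noise |
| saturation scale $s$ | 5 (in units of median expression) | damping only well above typical expression |

The relative-rate rules mirror the measured designer-construct ladder:
canonical YXX&#934; and acidic dileucine at 1; the 4-spacer dileucine at
0.9 ("nearly as efficiently"); FXNPXY, YXXX&#934;N and 2-/5-spacer
dileucines at 0.5 ("about half"); a bare LL/LI weak (0.25); a proline at
&#8722;1 of the dileucine at least doubles, a downstream DD pair about
doubles, multiplicatively, capped at 1. None of these are fitted values —
they encode the published qualitative ladder and are all configurable in
`uptake_model()`.

Gating follows the sorting strategy: an expression window (5th–50th
percentile of total signal by default, selecting "equal, and relatively
low" surface expression) and percentile ratio gates (top decile = plus,
bottom decile = minus). Recovery abstracts the cell-based PCR step: a
construct is recovered in a gate when at least `min_cells` (default 3) of
its cells land there, which suppresses single-cell stragglers the way
sequencing depth does in practice. Precision/recall are computed against
the planted truth labels.

# Synthetic data

* **Proteomes.** Defaults emulate the scale and shape of the real tail
  database: fraction of type I records 0.264 (1266 of 4794 single-pass
  proteins), log-normal tail lengths (median 35 aa, log-SD 0.8, clamped
  to [1, 500]), average-proteome residue frequencies as background, a
  21-residue hydrophobic TMD, and log-normal ectodomain lengths. By
  default no motifs are planted; planting rates are raised explicitly in
  recovery experiments. **Truth is defined post hoc by scanning** the
  generated tails rather than by the planting plan, because incidental
  motifs inevitably arise in background sequence; this makes downstream
  recovery tests exact. Anchored motifs are planted only at
  anchor-respecting positions, and a tail too short for a chosen motif is
  re-drawn (bounded retries). Note that two motifs planted into the same
  short tail can overwrite one another — truth, being post hoc, remains
  correct regardless.
* **Genomes.** An alternation of GATC sites and GATC-free gaps with
  geometric gap lengths (default mean 75 bp, which centres fragment
  lengths on the gel window), gap sequence drawn codon-wise from a
  configurable codon-usage table (uniform by default; gap segments that
  would contain an incidental GATC are re-drawn so spacing stays under
  the spacing model's control). A property worth knowing: under a
  geometric spacing model the achievable yield in the inclusive 50–100 bp
  window is capped near 27% for *any* spacing parameter
  ($\max_q (q^{46}-q^{97}) \approx 0.269$), and the test suite checks the
  realized yield against this analytic value, not against a larger
  aspiration.
* **Fixtures.** The designer tails are assembled by their published
  construction rule (eight residues between common P and V anchors; YAAL,
  EAAALL, FANPAY representing the three classical classes). The five
  library-derived tails were published only as a figure image, so
  `fixtures()` ships *synthetic reconstructions*: every residue fixed by
  the mutagenesis record is honoured (insert start triplets; DQD/ILS/PIL
  for PIA; RHN/TPL and the vector IPI/DDR involvement for PNT;
  LES/QLD and the C-terminal WF for WPK; RYRRSLNHK for RYR; the YQSI
  YXX&#934; for STS), alanine fills unconstrained positions, and the
  reconstructions reproduce the published scan outcome — exactly one of
  the five tails carries a classical motif. They are flagged
  `reconstructed = TRUE` and must not be mistaken for the original
  inserts.

# Numerical and testing choices

Problem sizes in the shipped tests were chosen to keep the full suite
around a minute on one CPU while leaving comfortable statistical margins:
1000 random tails for scanner/oracle equivalence, 5000 synthetic proteins
for frequency recovery (binomial 3-SE bounds), 12–20 thousand simulated
cells for stochastic-ordering and precision checks. The screen-precision
threshold (&#8805; 0.9 at 200 constructs, 10% signal-bearing, 20,000
cells) was fixed from a pilot run before freezing the test. All
generators and simulators take explicit integer seeds, save and restore
the caller's RNG state, and are bit-reproducible under a fixed seed.

# Known limitations

* The scanner is exact-pattern only: no position-weight matrices, no
  affinity prediction, no structural modelling of adaptor recognition.
* The library simulator does not model partial digestion, ligation bias,
  or transformation bottlenecks; both insert orientations are equally
  likely and religated empty vector is excluded from sampled libraries.
* The screen model has no recycling, no compensation/optics modelling,
  and no dead-cell artefacts; its parameters are explicitly configuration,
  not measured claims.
* Synthetic proteomes are i.i.d. background with planted signals; they do
  not reproduce homology structure, composition biases near the membrane,
  or real tail-length anatomy. Passing recovery tests therefore shows the
  census machinery is correct, not that any biological frequency estimate
  is accurate.
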