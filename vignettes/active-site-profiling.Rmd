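---
title: "Active-site profiling for ACS substrate-specificity prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-site profiling for ACS substrate-specificity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acsprofiler)
```

## The model

Members of the acyl-adenylate (ACS) superfamily share a conserved fold and a
conserved adenylation chemistry but diverge heavily in sequence, and their
substrate choice — acetate, medium/long-chain fatty acids, coumarate,
luciferin, amino acids — is decided by a small number of binding-pocket
residues. `acsprofiler` operationalises this as two complementary
classifiers over six subfamilies (AcCS, MCS, LCS, 4CL, Luciferase, NRPS):

* a **position-specific scoring matrix (PSSM)** over the residues a query
  carries at the specificity-determining residue (SDR) positions of a
  structural template, and
* a **whole-sequence profile HMM** per subfamily.

Both assign a query to the best-scoring subfamily. Their disagreement is
informative: a sequence whose whole-sequence model points at one subfamily
while its active-site profile points at another is a candidate for anomalous
substrate specificity.

### SDR derivation

SDRs are derived from a ligand-bound template structure as all residues with
at least one heavy (non-hydrogen) atom within a cutoff of the substrate's
C&beta; atom. At 6 Å this yields 12 positions on the shipped template; three
border positions that sit just outside the cutoff (residues 239, 278, 299 in
template numbering) are appended manually, giving the 15-position set used
by the PSSM-15 protocol. Widening the cutoff to 10 Å yields 44 positions
(PSSM-44), accommodating subfamilies with larger substrates. The heavy-atom
convention is a deliberate choice: it is the most common reading of
"residues within d Å" and is insensitive to missing hydrogens in crystal
structures. `derive_sdr_positions()` is monotone in the cutoff and agrees
with a brute-force all-pairs distance scan by construction of its tests.

### Active-site profiles and the PSSM

A query's active-site profile (ASP) is obtained by global alignment to the
template sequence (Needleman–Wunsch, BLOSUM62, gap open 10, gap extension
0.5, terminal gaps free) and reading the query symbol aligned to each SDR
column; a gap at an SDR column yields `-`, which is a first-class symbol.
Per subfamily, scores are

$$ s(a, p) = \log\!\frac{\mathrm{Freq}(a, p)}{0.05} $$

over the 21-symbol alphabet (20 amino acids + gap), where 0.05 is the
uniform background probability. A symbol never observed at a position
receives a fixed floor score of $-3.00$. Two consequences of taking the
floor literally: no pseudocounts are used, and a symbol with small nonzero
frequency may legitimately score *below* $-3.00$ (e.g. frequency 0.001);
the floor substitutes only for $\log 0$. The logarithm base is not fixed by
the scoring scheme's definition; the package defaults to the natural
logarithm (`log10` selectable) — the classification argmax is base-invariant.
Ties (within $10^{-9}$) are flagged and broken alphabetically so runs are
deterministic.

### The profile HMM

The whole-sequence classifier is a Krogh-style profile HMM authored in this
package (match/insert/delete states; no HMMER dependency, and no
HMMER-format bridge). Columns of the subfamily alignment with at most 50%
gaps become match states. Emissions and transitions are Laplace-smoothed
counts (`pseudocount_weight`, default 1; 0 gives maximum-likelihood point
masses, useful for analytic tests). Insert emissions equal the uniform
background (0.05), so inserted residues cost only their transitions. Scores
are log-odds in nats against a same-length i.i.d. background — matching the
PSSM background, so the two protocols are comparable — computed by Viterbi
(default) or forward; forward is always at least Viterbi, and equals a
brute-force sum over complete state paths on small models (both are test
invariants). Ambiguous residues (`X`) emit as background in the HMM and
score at the floor in the PSSM.

### Benchmarking

Accuracy is evaluated by a stratified random split (default 70% training),
profile training on the training side only, and one-vs-rest confusion
statistics per subfamily on the held-out side: $Sn = TP/(TP+FN)$,
$Sp = TN/(TN+FP)$. Division by zero yields `NA`, never a silent 0. The
split ratio is configurable because the original evaluation protocol for
this family of methods does not pin it down; 0.7 is a conventional choice.

## The synthetic data generator

Neither the curated ACS sequence collection nor the crystal structures are
redistributable, so the package generates data with the statistical
structure the method assumes. Two objects are involved.

**The synthetic template** (`template_structure()`, labelled synthetic
everywhere) is a deterministic 430-residue backbone + C&beta; model with a
phenylalanine substrate and an AMP cofactor. The pocket is engineered so
that exactly 12 residues fall within 6 Å of the substrate C&beta;, the three
manually curated positions sit just outside 6 Å, and 44 residues fall within
10 Å — the counts the real adenylation-domain template produces. It stands
in for a reference structure this package cannot ship; its geometry is
designed, not crystallographic, so distances carry no physical meaning
beyond the cutoff classes.

**The sequence generator** (`generate_dataset()`) draws, per subfamily, a
hidden ancestral sequence and a hidden 15-residue SDR signature
(pairwise-distinct across subfamilies at every position). Its defaults are
the study conditions for all tests: 6 subfamilies x 75 sequences, lengths
within 300–750 aa, SDR conservation 0.9, within-subfamily background
identity 0.4, cross-subfamily identity ~0.22. Members are i.i.d. per-site
mutations of the ancestor; a conserved "superfamily core" (short motif
blocks shared by all subfamilies, including ±3 flanks around each SDR
position, retained at rate 0.95) plays the role of the real superfamily's
conserved motifs, anchors the template alignment, and produces the
configured cross-subfamily identity; the free-site retention rate is solved
numerically from the within-identity target. Indels are Poisson-placed
(rate 1.5 per sequence, lengths 1–4) away from SDR columns, and random
terminal extensions spread lengths across the allowed band. Anomalous
records (fraction configurable, 0 by default) combine the whole-sequence
background of one subfamily with the SDR signature of another and are
labelled by the signature — the synthetic analogue of luciferase-homologous
enzymes that experimentally act as long-chain ligases.

What the generator does **not** emulate: phylogenetic correlation between
sequences (no tree-based evolution), site-rate heterogeneity, realistic
indel hotspots outside the alignment core, or compositional bias. Passing
benchmarks on this data therefore demonstrates correctness of the protocol
and its implementation under the method's own assumptions — not expected
accuracy on real proteomes, where alignability to the template and SDR
conservation are both weaker.

## Numerical and design choices

* **Alignment conventions.** Gap of length $L$ costs
  $\mathrm{open} + L\cdot\mathrm{ext}$; terminal gaps are free by default
  (the convention of the classic global-alignment tools whose percentage
  outputs this package mirrors). Percent identity and percent similarity
  (substitution-score-positive pairs) use the full alignment length,
  terminal gap columns included. The aligner is verified against exhaustive
  enumeration of all global alignments on short sequences.
* **Guide trees.** `progressive_msa()` is intentionally minimal: UPGMA
  (`hclust`, average linkage) on a self-score-normalised NW score distance
  computed by a score-only DP, then profile–profile merges under
  sum-of-pairs BLOSUM62. It is meant for fixture-scale training sets (tens
  of sequences); production users can supply an external MSA via
  `read_alignment()`.
* **Superposition.** Kabsch via SVD with reflection correction;
  cross-checked against an independent least-squares fit and against direct
  numerical minimisation over rotations. Template-to-target position mapping
  requires at least 20 aligned C&alpha; pairs and maps each SDR to the
  nearest target C&alpha; within 8 Å after superposition, reporting
  unmapped positions rather than guessing.
* **Degenerate inputs.** Empty sequences, ragged alignments, duplicate ids,
  absent ligands/reference atoms, single-member subfamilies under
  stratification, and mixed SDR sets all raise errors naming the offender;
  unknown residue characters are mapped to `X` with a warning.
* **Determinism.** Every stochastic step (generation, splitting) takes an
  explicit seed and restores the caller's RNG state; same-seed runs are
  byte-identical, which the test suite asserts on FASTA, profile-store and
  benchmark outputs.
* **Problem sizes.** The shipped tests and the acceptance script run the
  full default study size (450 sequences, 70/30 split, both protocols, plus
  a second run with 5% anomalous records); oracle-based property tests use
  reduced alphabets and short sequences where enumeration is exact.

## Known limitations

* The ASP route assumes the query aligns to the single structural template
  well enough to place SDR columns; for real sequences below ~15–20%
  identity to the template this is the dominant error source, and the
  44-position variant inherits it.
* The profile HMM is global (no local/glocal modes, no E-values); scores
  are comparable across same-library models but not calibrated
  probabilities.
* `progressive_msa()` does not refine (no iterative realignment), so very
  gappy fixture alignments can shift match-column choices in the HMM;
  supplying a curated MSA is supported and preferred at scale.
* The consensus profile's conservation categories use literal thresholds
  (>80% high, <50% low, boundaries mid); percentages are computed with gaps
  in the denominator, so heavily gapped positions read as low-conserved by
  design.
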