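---
title: "Methods: evaluating head-to-tail cyclic peptide binders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating head-to-tail cyclic peptide binders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycbinder)
```

## The problem

Head-to-tail cyclic peptides have no backbone termini: residue adjacency is
circular. That breaks two assumptions baked into standard protein–peptide
modelling machinery. First, structure predictors encode residue order through
a relative positional encoding, the integer offset matrix
$o(i,j) = \mathrm{residue\_index}_i - \mathrm{residue\_index}_j$; on a ring
that difference should wrap, so position 1 and position $L$ are neighbours.
Second, when comparing a designed cyclic peptide against a native linear
peptide there is no canonical residue 1: any rotation of the ring labels
describes the same molecule, so naive position-by-position RMSD is
ill-defined. `cycbinder` implements the machinery around both problems — the
complex offset matrix, a cyclic-permutation-aware windowed RMSD, the
confidence / interface-energy triage of candidate designs, and the gapped
alignments used for sequence logos — for workflows in which a deep-learning
predictor proposes protein–cyclic-peptide complexes and designed binder
sequences for a protein–protein interaction target.

## The cyclic complex offset

`build_residue_index()` assigns each residue of a multi-chain complex an
integer index: 0-based within the first chain, increasing by one per residue,
with the first residue of each later chain starting `chain_break` above the
last index of the previous chain. The break (default 50, the conventional
value for complex prediction) makes inter-chain index differences large
enough that the predictor treats the chains as separate molecules. A 20+10
complex therefore indexes the protein 0..19 and the peptide 69..78.

`build_complex_offset()` starts from the default complex offset — the plain
difference matrix of those indices — and replaces the intra-chain block of
each designated cyclic chain with the cyclic offset
$$o_c(i,j) = \arg\min_{v \in \{i-j,\; i-j-L,\; i-j+L\}} |v|,$$
whose magnitude never exceeds $\lfloor L/2 \rfloor$. Cross-chain blocks and
non-cyclic chains keep the default differences, so the target protein remains
linearly encoded while the peptide block wraps.

Numerical conventions worth stating:

* **Tie-break.** For even $L$ the two candidates at $|i-j| = L/2$ tie in
  magnitude; both matrix cells get the positive value $+L/2$. Any fixed
  convention works for a predictor; ours is chosen for reproducibility, and
  it is the one place where the matrix is not antisymmetric.
* **No clipping.** Offsets are emitted unclipped; clipping to a predictor's
  relative-position window (e.g. ±32) is the consumer's job, since the
  encoding input — not the clip — is what changes for cyclic peptides.
* **Positions are 1-based in this package's API** (the R convention); the
  `residue_index` *values* are 0-based because they are predictor inputs,
  not R indices.

## Windowed RMSD of a cyclic design against a linear native peptide

Whole-complex accuracy is reported by `peptide_rmsd()` in two modes:
superpose on the protein Cα atoms and read the in-place peptide Cα RMSD
(placement error in the binding frame), or superpose on the peptide itself
and read the fitted RMSD (conformational accuracy regardless of placement).
Fitting can only reduce RMSD, so the peptide-aligned value never exceeds the
protein-aligned one. Superposition is plain all-Cα Kabsch (centroid
subtraction, SVD, reflection-corrected rotation); no outlier-rejection
cycles are applied, so values may differ slightly from viewers that trim
outliers.

For designed sequences, which need not match the native sequence or length,
`rmsd_best()` implements the windowed comparison: after protein-frame
superposition, every native window of width $W$ (sliding without wraparound,
$L_\mathrm{native} - W + 1$ of them) is compared against every design window
(sliding one residue at a time and wrapping head-to-tail, $L_\mathrm{design}$
of them for a cyclic design). Each comparison is an in-place Cα RMSD — no
refitting per window, because the question is where the design sits in the
native binding frame. The minimum over all pairs is RMSD$_\mathrm{best}$;
for a 13-residue native against a 13-residue cyclic design at $W = 6$ that
is $(13-5) \times 13 = 104$ evaluations. The defaults are $W = 6$ for cyclic
designs and $W = 10$ for linear ones; a native shorter than $W$ shrinks $W$
to its length. Exact ties between window pairs are broken to the smallest
native start, then the smallest design start — arbitrary, but deterministic.
Residue correspondence between native and predicted proteins is positional
after chain mapping, guarded by a strict length check; sequence-alignment
based correspondence is deliberately out of scope.

## Triage of designed binders

Candidate designs are filtered on two axes. Confidence: the mean per-residue
pLDDT over the peptide region of the predicted complex must be strictly
above the threshold (70 by default; 90 for stricter selections). Energetics:
the interface score is the Rosetta InterfaceAnalyzer binding energy
normalised by buried interface area, $\mathrm{dG\_separated} /
\mathrm{dSASA} \times 100$, which removes the advantage large interfaces
have on raw binding energy; a design passes when its normalised score is
strictly below the native complex's, or — when no design beats the native —
below zero (the fallback rule). Among passing designs the selection is the
argmin of either RMSD$_\mathrm{best}$ (most native-like pose) or the
normalised score (best energetics), with ties broken by design id so runs
are reproducible. Records with non-positive dSASA are flagged and excluded:
their normalised score is undefined. This package only consumes
InterfaceAnalyzer score tables; running Rosetta (minimisation,
`-pack_separated`, etc.) is upstream.

## Logo preparation

For each surviving design, the letters of its best window — taken cyclically
from the design sequence — are placed at the native positions that window
matched; all other native positions become `'-'`. Only the $W$ windowed
letters contribute: flanking design residues are *not* projected onto
adjacent native positions, which keeps each row's support exactly equal to
the window the RMSD justified. Per column the gap-excluded letter
frequencies, the occupancy (fraction of rows contributing a letter — the
"letter width" of a rendered logo), and the information content
$R = \log_2 20 - H$ are computed, where $H$ is the Shannon entropy of the
frequencies; a fully conserved gap-free column scores $\log_2 20 \approx
4.32$ bits, a uniform column 0. No small-sample entropy correction is
applied (renderers such as WebLogo apply one by default), trading a small
systematic difference for exactness and testability. Rows are thresholded on
RMSD$_\mathrm{best}$ before counting; rendering itself is delegated to
external tools via the gapped FASTA writer.

## The synthetic generator

All tests run on synthetic complexes with known ground truth, generated by
`make_complex_pair()`: a helical protein Cα trace (2.3 Å radius, 1.5 Å
rise, 100°/residue) and a peptide ring of $L$ points on a circle sized so
every adjacent pair — including the ring-closing one — is exactly 3.8 Å
apart, in a seeded random orientation. The "predicted" partner is the native
with an optional rigid peptide displacement followed by isotropic Gaussian
noise; `noise_sigma` is the root-mean-square 3D displacement per Cα
(per-coordinate sd $\sigma/\sqrt{3}$). The truth record retains the exact
noise and displacement, so every downstream metric can be recomputed
independently of the code under test. `make_score_fixtures()` similarly
plants a known triage outcome: a unique winner under both selectors, or a
fallback scenario in which no design beats the native but a known subset is
below zero.

What the generator does *not* emulate: real backbone dihedrals, side chains,
sequence-dependent geometry, energetic realism, or predictor-correlated
error structure. Passing tests therefore demonstrate the correctness of the
bookkeeping and numerics — window enumeration, superposition, wraparound,
filters, information content — not predictive accuracy on real complexes,
which depends on the upstream predictor.

Problem sizes used throughout the tests — 20-residue proteins, 13-residue
peptides, 50-seed Monte-Carlo sweeps, 100-fixture oracle comparisons — keep
the whole suite in the tens of seconds while exercising every code path;
the 13-residue peptide matches the standard design length for cyclic binder
studies.

## Degenerate inputs and edge cases

Superposition requires at least three non-collinear point pairs; fewer, or
collinear sets, raise a degeneracy error rather than returning an arbitrary
rotation. Missing residues in a PDB become `'X'` in the sequence (as do
nonstandard residue names); a residue lacking a Cα atom carries `NA`
coordinates and is listed in the parse report, and Cα-based operations use
only coordinate-bearing residues. Alternate locations keep the first altloc
by label; only the first MODEL is read. Empty triage passing sets return an
explicit empty result. A logo built from zero surviving rows is an explicit
empty logo object.

## Known limitations

* Cα only, everywhere: full-backbone or all-atom RMSD is out of scope, so
  values are not directly comparable to all-atom numbers.
* The even-$L$ tie convention in the cyclic offset is a documented choice
  and may differ from other implementations at exactly that cell.
* Whether a published "aligned with peptide" RMSD fits on Cα only or all
  atoms varies between tools; this package fits on Cα.
* The windowed alignment places only windowed letters; an alternative
  reading that rotates the whole design sequence into native coordinates
  would fill flanking positions too, and would produce denser logos.
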