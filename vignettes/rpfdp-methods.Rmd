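---
title: "Methods: model-versus-data NMR validation with rpfdp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-versus-data NMR validation with rpfdp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the scoring
model and its assumptions, the tunable parameters, what the synthetic
benchmark does and does not establish, and the design choices made where
the method definition left room.

## 1. The scoring model

A protein model is compared against two primary NMR observables without
ever deriving restraints.

**Nodes.** Every proton listed in the assignment table becomes a node,
after grouping degenerate protons into pseudoatom *sites*: methyls (3
protons), prochiral methylene and sidechain NH2 pairs that share one shift
or carry NMR-STAR ambiguity code 2 (2 protons), symmetric Phe/Tyr ring
positions (2), and Leu/Val isopropyl pairs with a single shared assignment
(6).  Protons absent from the assignment table do not participate on
either side — the data define the node universe.

**Model side (graph G).** Sites are connected when their *summation
distance* is at most `d_max`:
$$ d_\mathrm{sum} = \Big(\sum_{i\in a}\sum_{j\in b}
   \langle r_{ij}^{-6}\rangle\Big)^{-1/6} $$
with $\langle\cdot\rangle$ the mean across ensemble conformers.  This is
the NOE-equivalent effective distance under the assumption of uniform
relaxation.  The summation runs over member pairs first and the ensemble
average is applied per pair term *before* the $-1/6$ power; the method
definition does not fix this order, so it is declared here (tests probe
sensitivity at small M — differences are far below score resolution).

**Data side (graph G_ANOE).** Each NOESY cross peak is expanded into every
candidate site pair whose ¹H shifts match the two proton dimensions within
`tol_h` and, for ¹³C/¹⁵N-edited spectra, whose attached heavy-atom shift
matches the edited dimension within `tol_c`/`tol_n`.  By convention the
edited dimension is attached to the acquisition-dimension proton.  Peaks
whose two ¹H positions coincide within `tol_h` are excluded as diagonal
artifacts; peaks with no candidate at all are excluded from the counts and
reported as "unmatched" (they indicate assignment-table incompleteness,
not model error).

**Classification and scores.** A peak is TP if *any* of its candidates is
an edge of G, FN otherwise; a model edge listed by no peak is FP.  Recall
R = TP/(TP+FN).  Precision is weighted by $d^{-6}$ over TP/FP edges,
which stops the many near-cutoff weak pairs from dominating and makes the
score insensitive to the exact `d_max`.  F is the harmonic mean, and
$$ \mathrm{DP} = \frac{F - F(G_\mathrm{free})}
                      {F(G_\mathrm{ideal}) - F(G_\mathrm{free})}. $$
True negatives are counted and reported but consumed by no score.
Only precision carries the $d^{-6}$ weighting; recall is a plain peak
count.  That asymmetry is deliberate: weighting is described for the
precision metric, and recall's numerator/denominator are peaks, which
carry no model distance.

**Bounds.** $F(G_\mathrm{ideal})$ assumes recall 1 and precision equal to
the *completeness* of the local network: the $d^{-6}$-weighted fraction of
geminal and vicinal (2–3 bond) proton pairs with a supporting peak.  Local
pair weights are taken from the model being scored; local geometry is
essentially fixed by covalent structure, so this introduces no material
model dependence.  $F(G_\mathrm{free})$ is the mean single-conformer F of
M freely rotating chains: fixed ideal covalent geometry, all backbone and
sidechain torsions uniform on $(-180°, 180°]$ (proline φ pinned at −65°).
The original chain reference is not reproduced in the method description,
so this simulated estimator is this package's own construction; it is
seeded and deterministic.

**Per-residue maps.** An FN peak distributes 1/(number of candidates) to
both residues of each candidate pair; an FP edge adds 1 to each of its two
residues.  The method's published per-residue maps do not define
attribution under ambiguity; the fractional rule above keeps the total
mass per peak equal to one.

## 2. Parameters

| parameter | default | units | notes |
|---|---|---|---|
| `d_max` | 5.0 | Å | NOE detection ceiling; 7.0 recommended for perdeuterated samples |
| `tol_h` | 0.03 | ppm | ¹H match tolerance; the method definition states none, this is common practice; tests use 0 on exact synthetic data |
| `tol_c`, `tol_n` | 0.4 | ppm | heavy-atom match tolerances |
| `f_free_m` | 200 | chains | Monte-Carlo size of the F(G_free) estimate; doubling M moves F_free by < 0.02 on the benchmark |
| clash floor | 0.5 | Å | interproton distances below 0.5 Å are floored with a warning instead of failing, so physically unreasonable models still score (they earn their low DP through unsupported short pairs) |
| Q denominator | factor 2 | — | `sqrt(2 Da² (4+3Rh²)/5)`, the convention of the standard SVD fitting servers; the printed equation is typographically ambiguous on this factor, so it is switchable (`denom_factor2 = FALSE`) and logged |
| RDC weights | 1 | — | Q is invariant under uniform weight scaling (weights are normalized by their mean) |

RDC couplings of different vector types (N–Hᴺ, Cᵅ–Hᵅ, Cᵅ–C′, C′–N) are
scaled to the N–Hᴺ frame by γ_aγ_b/r³ ratios from
`inst/extdata/dipolar_constants.tsv`; fitting a single type reproduces the
conventional per-type Q exactly.

## 3. The synthetic benchmark: what it emulates, what it does not

`synth_config(n_residues = 40, seed = 17)` defines the standard fixture:

* **Structure**: a procedurally built helix–turn–helix with a short
  extended C-terminal tail, built from ideal torsions with greedy χ
  rotamer selection until no non-covalent heavy-atom pair is closer than
  1.8 Å.  The tile sequence guarantees Val, Leu, Ile, Phe, Tyr and Gly, so
  methyl, prochiral, isopropyl and ring pseudoatom paths are all
  exercised.  The design decision to pack two helices (rather than a
  helix against a lone strand) is deliberate: a strand cannot be made to
  pack by ideal dihedrals alone, and packed helices supply the long-range
  NOEs that make DP informative.
* **Shifts**: per-(residue, atom) random-coil means from
  `inst/extdata/random_coil_shifts.tsv`, plus a deterministic, seeded
  per-group *structural dispersion* (`shift_dispersion`, 0.15 ppm ¹H, 8×
  for heavy nuclei) and optional measurement jitter (`shift_jitter`,
  default 0).  The dispersion is part of the stated world: with bare
  tabulated means every same-type proton in the chain is exactly
  degenerate, the candidate union becomes implausibly dense, and precision
  stops responding to model error.  Real tables are dispersed by the fold.
  Exchange-broadened protons (hydroxyls, sulfhydryls, Lys/Arg terminal NH,
  His ring NH, the N-terminal amine) are unassigned, as in practice.
* **Peaks**: one cross peak per true short site pair, positions exactly at
  the assigned shifts (± jitter), intensity ∝ d⁻⁶, with seeded dropout and
  uniform-random artifact peaks as configured.  2D and ¹³C/¹⁵N-edited 3D
  variants.
* **Decoys**: torsion-space perturbations of the truth, rescaled
  iteratively to a target backbone RMSD, with draws rejected (up to 12
  tries) if any non-covalent heavy pair comes below 1.5 Å — real models at
  moderate RMSD do not interpenetrate, and the torsion rebuild has no
  steric term of its own.  Local covalent geometry is ideal at every
  level, as in real predictions.  A freely rotating chain decoy is
  appended as the fold-less reference.
* **RDCs**: forward-calculated from a stated (Da, Rh, orientation) tensor
  with seeded Gaussian noise.

A green benchmark establishes that the implementation is self-consistent
and responds to model error in the right direction with roughly the right
calibration (DP > 0.6 within 2 Å RMSD; random coil ≈ 0).  It does *not*
establish performance on real spectra: no peak overlap or lineshape
effects, no chemical-shift referencing errors, no spin diffusion or
relaxation-dependent intensities, no water/exchange artifacts, and decoys
drawn from one family of torsion perturbations rather than the diversity
of real prediction errors.

## 4. Numerical choices and degenerate inputs

* The random-coil null, DP ≈ 0, is asserted on the *mean* single-conformer
  DP of an independent 150-chain sample: a single chain conformer has DP
  s.d. ≈ 0.3 (compactness of uniform-torsion chains varies widely), so the
  distributional mean is the meaningful quantity.
* Hydrogen placement is a built-in ideal-geometry builder (no external
  program): sp³/sp² completion by vector sums, rotors staggered, N-terminal
  amine represented by one proton.  Missing heavy frames or collinear
  frames skip the affected protons with named warnings rather than
  failing, because prediction models with broken geometry must still
  score.
* Altloc resolution keeps the highest occupancy, ties to "A".  PDB v2
  hydrogen names are normalized to IUPAC/BMRB on input.
* Candidate ordering in contact lists: ascending summed shift mismatch,
  ties lexicographic by site label — stable under rewrite.
* Empty usable peak sets raise a typed error (recall is undefined);
  rank-deficient RDC design matrices report their condition number.

## 5. Known limitations

* No stereospecific-assignment bookkeeping beyond ambiguity code 2; codes
  above 2 are treated as 1.
* Only standard amino acids; nucleic acids and modified residues are
  rejected by the topology layer.
* The freely-rotating-chain estimator ignores excluded volume; it slightly
  overestimates chain compactness and hence F(G_free), which cancels in DP
  comparisons but is not a literal Flory model.
* Reproduction of deposited-ensemble Q scores (the downloaded-data
  benchmark) depends on restraint-file completeness and per-type scaling
  conventions of the original fitting server and is intentionally outside
  the test suite.
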