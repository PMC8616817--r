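# rpfdp — NOESY-based RPF-DP structure quality scores and RDC Q factors

`rpfdp` validates protein 3D structure models directly against
**unassigned NMR data**: NOESY peak lists plus a chemical-shift assignment
table, and residual dipolar couplings (RDCs).  It is aimed at NMR
spectroscopists and structure-prediction assessors who want an NMR
"R-factor" for a model — experimental structure, predicted model or
crystal structure — without first deriving distance restraints.

## The scores

**RPF-DP.**  Let *G* be the graph whose nodes are all assigned protons
(degenerate groups — methyls, unresolved prochiral pairs, symmetric
aromatic ring positions — collapse to pseudoatom sites) and whose edges
connect sites whose *r⁻⁶ summation distance* in the model,

> d_sum = ( Σᵢ Σⱼ ⟨r_ij⁻⁶⟩ )^(−1/6),

is at most d_NOE_max (default 5 Å; ⟨·⟩ averages over ensemble conformers).
Let *G_ANOE* be the graph of **all shift-compatible assignments** of every
NOESY cross peak under the match tolerances.  Then

- a peak is a **true positive** if at least one of its candidate pairs is
  an edge of *G*, a **false negative** if none is;
- a model edge unsupported by any peak is a **false positive**;
- **recall** R = TP/(TP+FN); **precision** P_w = Σ_TP d⁻⁶ / (Σ_TP d⁻⁶ +
  Σ_FP d⁻⁶) (the d⁻⁶ weighting curbs the many weak long-range pairs);
- **F** = harmonic mean of R and P_w;
- **DP** = (F − F(G_free)) / (F(G_ideal) − F(G_free)),

where F(G_free) is the F-measure expected for a freely rotating polypeptide
chain (Monte-Carlo estimate, seeded) and F(G_ideal) takes recall 1 and
precision equal to the completeness of the local (2–3 bond) proton-pair
network.  A random coil therefore scores DP ≈ 0, and a model as good as the
data allow scores DP = 1.  Accurate structures typically have DP > 0.6 per
conformer; ensemble-averaged DP runs ~10–15% higher.

**RDC Q.**  The five-parameter Saupe alignment tensor is fitted to observed
couplings by SVD; Q = rms(W·(D_obs − D_calc)) / sqrt(2·Da²·(4+3Rh²)/5).
Q < 0.2 indicates adequate agreement.  Mixed coupling types are scaled to
the N–Hᴺ frame via a shipped gyromagnetic/bond-length constants table.

**Ambiguous contact lists.**  The same shift matching, without coordinates,
exports every candidate assignment of every peak as a ranked TSV — the
data-assisted-prediction input format.

## Worked example

Everything below is generated in code — no downloads.  The synthetic
benchmark builds a 40-residue helix-turn-helix toy fold, assigns
random-coil-based shifts, and emits one NOESY peak per true short contact:

```r
library(rpfdp)
cfg    <- synth_config(n_residues = 40, seed = 17)
truth  <- make_structure(cfg)           # all-atom conformer, protonated
shifts <- make_shifts(truth, cfg)       # 499 assigned nuclei
peaks  <- make_noesy(truth, shifts, cfg)

rs <- score_rpf(truth, shifts, peaks, tol = match_tolerance(0, 0, 0),
                d_max = 5, seed = 17)
rs$conformer[[1]]
#> RPF-DP result [conformer_1]
#>   TP 1824  FP 0  FN 0  TN 19314 (unmatched 0, diagonal 0)
#>   R = 1.000  P(w) = 1.000  F = 1.000
#>   F_free = 0.384  F_ideal = 1.000  DP = 1.000
```

The generating structure explains every peak (R = 1), every short model
distance is observed (P_w = 1), and DP = 1 because F reaches the
data-completeness ceiling.  A freely rotating chain decoy scored on the
same data gives DP ≈ 0, and torsion-noise decoys at 0.5/1/2/4 Å backbone
RMSD give median DP 0.98 / 0.96 / 0.93 / 0.88 — DP degrades with model
error.

RDCs close the loop the same way:

```r
rdc <- make_rdcs(truth, da = 12, rh = 0.3, noise = 0, seed = 17)
fit_tensor(truth, rdc)
#> <alignment tensor: Da = 12.000 Hz, Rh = 0.300, rms dev = 0.000 Hz>
q_score(truth, rdc)$q        # 0 (exact back-calculation)
```

## Command line

```sh
rpf synth    --out bench/ --seed 17 --nres 40        # write a benchmark set
rpf score    --model m.pdb --shifts s.str --peaks p.list \
             --dmax 5.0 --tolh 0.03 --json report.json --addh
rpf rdc      --model m.pdb --rdc r.tsv
rpf contacts --shifts s.tsv --peaks p.tsv --out contacts.tsv
rpf report   --json report.json
```

Exit codes: 0 success, 2 usage error, 3 data error.  Readers accept PDB
(multi-MODEL), NMR-STAR v3 shift loops, XEASY `.peaks`, Sparky `.list` and
an in-house TSV; hydrogens are added at ideal geometry with `--addh` when a
model lacks them.

Contact-list columns (stable order): `peak_id`, `dim_positions`
(comma-joined ppm), `candidate_rank` (by summed shift mismatch, ties
lexicographic), `atom_a`, `atom_b` (`chain.resno.resname.name`, pseudoatom
names like `QB`, `QD1`, `QQG`).

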