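---
title: "Torsion-space analysis and comparison of nucleic-acid structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsion-space analysis and comparison of nucleic-acid structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsionspace)
```

## The angular picture of a nucleic-acid structure

A polynucleotide backbone is a chain of rotatable bonds. Instead of
Cartesian coordinates, each residue can be summarized by a small set of
angles:

* **Backbone torsions** `alpha`–`zeta`: the six dihedral angles along
  O3'(i−1)–P–O5'–C5'–C4'–C3'–O3'–P(i+1). They capture backbone
  conformation independently of position and orientation.
* **Glycosidic torsion** `chi` (O4'–C1'–N9–C4 for purines,
  O4'–C1'–N1–C2 for pyrimidines): the base orientation about the
  sugar–base bond. We classify `chi` in (−90°, 90°] as *syn* and the rest
  as *anti*, the textbook window; left-handed Z-form duplexes show the
  characteristic alternation of syn purines and anti pyrimidines.
* **Ring torsions** `nu0`–`nu4` of the five-membered sugar, collapsed
  into the **pseudorotation phase**
  `P = atan2((nu4 + nu1) − (nu3 + nu0), 2 nu2 (sin 36° + sin 72°))`,
  reported in [0°, 360°). Each 18°-wide sector of `P` carries a standard
  envelope/twist name; `P = 0°` is the C2'-exo–C3'-endo twist, `P = 90°`
  O4'-endo, `P = 270°` O4'-exo. The two-argument arctangent is essential:
  half the wheel has `nu2 ≤ 0`, where a plain arctangent would be off by
  180°.
* **Pseudo-torsions** `eta`, `theta` (over P and C4' of adjacent
  residues) and `eta_prime`, `theta_prime` (over P and C1'): a
  coarse-grained two-angles-per-residue backbone descriptor, analogous to
  phi/psi maps for proteins.

All of this is computed by `calc_torsions()` from a flat atom table
produced by `read_structure()`/`parse_structure()` (PDB or PDBx/mmCIF,
multi-model, modified residues included). Angles whose atom quadruple
crosses a chain break or touches a missing atom are `NA`, never imputed:
`alpha`, `eta`, `eta_prime` are undefined at a 5' terminus, `epsilon`,
`zeta`, `theta`, `theta_prime` at a 3' terminus.

## Comparing structures in torsion space

Angular differences are always taken on the circle (the minimum arc):
`delta(a, b) = min(|a − b| mod 360, 360 − |a − b| mod 360)`, in
[0°, 180°]. A set `D` of such differences is aggregated by the **mean of
circular quantities**:

`MCQ(D) = atan2(sum sin d, sum cos d)`

which stays in [0°, 180°] and respects periodicity. The package computes
it at three scopes: per residue (`per_residue_mcq()`), globally over the
pooled differences of all paired residues (`global_mcq()` — pooling, not
averaging per-residue values), and over contiguous segments
(`lcs_ta()`). Residues of target and model are paired by the longest
common subsequence of their one-letter sequences (`pair_residues()`),
case-insensitively so that modified residues mapped to lowercase parent
letters pair with their parents; among co-optimal alignments the
leftmost-in-target, then leftmost-in-model traceback is returned.

**LCS-TA** reports the longest run of consecutively paired residues
(consecutive in *both* chains) whose pooled MCQ stays at or below a
threshold (default 15°), together with its position and achieved MCQ.

### Why LCS-TA scans all window lengths

A natural accelerated search would binary-search the segment length,
testing each length with a sliding window. That presumes feasibility is
monotone in length, which is false for circular means: with per-residue
differences {10°, 170°, 10°} and threshold 30°, the full window of three
pools to 27.9° (passes), no window of two passes, and the single residue
10° passes again. `lcs_ta()` therefore evaluates every window exactly,
longest first, using incremental sine/cosine prefix sums (O(1) per
window, O(n²) windows worst case — negligible at chain scale). Ties at
equal length go to the smaller MCQ, then the leftmost target position.
Windows whose residues contribute no defined difference cannot certify
anything and never pass.

### What the MCQ can hide

Because the MCQ averages, one corrupted residue is diluted by good ones:
seven 90° differences among sixty-three zeros pool to 6.3°. Antipodal
differences even cancel (sin 180° = 0). Per-residue values, the severity
bands ([0,15), [15,30), [30,60), [60,180] degrees — the heatmap colours),
coverage fractions and LCS-TA exist precisely to expose what a single
global number can mask.

## Ensemble analysis

`mcq_dissimilarity()` builds the symmetric model-by-model matrix of
global MCQ values. Three standard views are layered on top:

* `mds_embed()`: classical (Torgerson–Gower) scaling — double-centering
  of squared dissimilarities, eigendecomposition, axes scaled by the
  square root of the eigenvalues. Angular dissimilarities are not exactly
  Euclidean, so negative eigenvalues appear and are clamped to zero; the
  embedding's orientation and signs are arbitrary, which is why all
  fidelity checks compare distance matrices, never raw coordinates.
* `k_medoids()`: cluster centres are actual models, found on the
  dissimilarity matrix directly. For any realistic ensemble size
  (`choose(n, k)` up to 10⁴, e.g. ten models at any k) the medoid set is
  the exact enumeration optimum, deterministically, ties broken by the
  lexicographically smallest index set. Larger problems fall back to the
  classic PAM search — deterministic greedy BUILD, then best-improvement
  SWAP passes — optionally with seeded random restarts. The exact path
  exists because BUILD+SWAP is a local search: on a few percent of random
  non-metric matrices it stops above the global optimum, and at ensemble
  scale there is no reason to accept that.
* `mcq_dendrogram()`: average-linkage (UPGMA) agglomeration via
  `stats::hclust`, exported to Newick with `as_newick()`.

## The synthetic chain builder

`build_chain()` turns a `torsion_prescription()` — per-residue targets
for `alpha`–`zeta`, `chi`, and the pucker (`P`, amplitude `tau_max`) —
into full-atom coordinates, placing atoms sequentially by
natural-extension (NeRF) so that every prescribed backbone and
glycosidic torsion is realized exactly under a bundled table of ideal
bond lengths and angles. The ring torsions follow the cosine pucker
model `nu_j = tau_max · cos(P + 144°(j − 2))`.

A closed five-ring has nine internal degrees of freedom, so five fixed
bond lengths plus five exact torsions over-determine it by one: a small
closure residual is unavoidable. The ring solver (damped Gauss–Newton on
O4', C1', C2' with bond lengths restrained, ring angles free, and two
weak exocyclic restraints pinning the rigid rotation about C3'–C4')
distributes that residual so the recomputed pseudorotation phase stays
within 1° of the prescription (individual `nu` within 2.5°); otherwise
the build fails naming the residue. Identical prescriptions give
bit-identical coordinates. `perturb_chain()` rebuilds with selected
angles shifted — the basis of the constant-shift identity used in
testing: shifting all compared angles by `c` makes every MCQ exactly
`c`.

What the generator emulates: idealized, geometrically self-consistent
chains with arbitrary prescribed torsions, including Z-form-like
syn/anti alternation. What it does not: experimental bond-length and
bond-angle variation, sterics, base pairing, solvent, or disorder. Tests
passing on these fixtures validate the angular mathematics and the I/O
paths; they say nothing about force-field realism, which the package
does not model.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `break_cutoff` | 2.5 Å | O3'–P distance defining a chain break (~1.6 Å covalent bond plus slack); inter-residue angles are never computed across a break |
| `angles` | `alpha`…`zeta`, `chi` | angle kinds entering MCQ sums; ring and pseudo-torsions are opt-in, the derived `P` never enters |
| `lcs_threshold` | 15° | inclusive MCQ bound for the LCS-TA segment |
| severity bands | 15/30/60° | heatmap bins for per-residue MCQ |
| `bin_width` | 15° | histogram bin width, must divide 360 |
| syn window | (−90°, 90°] | glycosidic classification boundary |
| altloc rule | — | highest occupancy wins, ties to the lexicographically smallest altloc |

## Numerical choices and degenerate inputs

Every circular aggregation (`MCQ`, circular means, `P`) uses the
two-argument arctangent, so no quadrant is ever lost. Degenerate
geometry — collinear atoms, coincident centres, flat rings — yields `NA`
rather than an error, so one bad residue never aborts a run; `n_terms`
is carried alongside every MCQ so sparse comparisons are visible.
Undefined values render as blank fields in the CSV reports, which print
two decimals and are byte-identical across repeated runs of the same
configuration.

Test problem sizes are chosen to exercise the mathematics at full
strength while keeping the suite quick: 100 random ten-residue chains
(plus 20 rigid motions each) for round-trip checks, 200 random paired
instances up to length 30 against the exhaustive LCS-TA oracle, 50
random matrices against exhaustive medoid search, and the complete 1°
grid (129,600 pairs) for the circular difference.

## Known limitations

* Global MCQ can mask localized errors (see above); report per-residue
  tables alongside it.
* MDS of angular data is a visualization aid, not an isometry; stress is
  unavoidable when eigenvalues go negative.
* Secondary-structure context (helix vs loop weighting, base-pair
  annotation from 3D) is out of scope; a dot-bracket string, if you have
  one, is metadata the package does not interpret.
* The builder's bases are minimal rigid fragments sufficient for
  classification and `chi`; it is a fixture generator, not a modeling
  tool.
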