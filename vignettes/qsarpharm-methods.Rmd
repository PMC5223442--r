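---
title: "Methods: grid-field 3D-QSAR and pharmacophore screening in qsarpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid-field 3D-QSAR and pharmacophore screening in qsarpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarpharm)
```

# The workflow

`qsarpharm` implements a ligand-based discovery pipeline for congeneric
series — sets of compounds sharing a scaffold and differing by substituents.
The chain is: rigid template alignment of all structures into one frame;
Gasteiger–Marsili partial charges; steric and electrostatic probe energies on
a rectangular grid (molecular field analysis, the CoMFA idiom); stepwise
partial-least-squares regression of pIC50 on those grid energies with full
internal, external, and response-scrambling validation; common-pharmacophore
hypothesis generation from the active compounds; k-of-n library screening
against the selected hypothesis; and enrichment statistics (EF, GH, ROC/AUC)
for the screen.

# Alignment and culling

Every structure is superposed onto a reference via the Kabsch algorithm on a
shared substructure. Templates are element-labelled connectivity patterns
(plain-element SMILES or explicit atom correspondences) matched by VF2
subgraph isomorphism on the heavy-atom graph; bond orders are deliberately
not constrained, since congeneric scaffolds are conserved at the
connectivity level while drawn bond orders (e.g. Kekulé choices) vary.
Compounds whose minimised template RMSD exceeds a cutoff are culled before
field computation — a high residual means the compound cannot adopt the
common binding orientation, so its fields would not be comparable. The
cutoff defaults to 2.0 Å and is inclusive at the boundary; field-based QSAR
practice rarely reports the exact value used, so it is exposed as a
parameter rather than hard-coded.

# Charges and fields

Partial charges come from the iterative partial equalisation of orbital
electronegativity (PEOE): electronegativity is the quadratic
`chi = a + b q + c q^2` per element/hybridisation, and each iteration
transfers `(chi_j - chi_i) / chi_plus(donor) * 0.5^k` electrons along every
bond. Six iterations converge far below the 1e-3 e tolerance at which the
charge-sum invariant is enforced. The implementation reproduces the openbabel
PEOE charges to 4 decimals on identical topologies (cross-checked in the
test suite).

Field descriptors are probe interaction energies at every grid point:

* steric: Lennard-Jones 6–12 with an sp3-carbon probe (radius 1.70 Å, well
  depth 0.1094 kcal/mol), mixing `rmin = r_probe + r_atom`,
  `eps = sqrt(eps_probe * eps_atom)`;
* electrostatic: Coulomb `332.06 q_i q_probe / (D r)` with unit probe charge
  and dielectric 1.0.

Both are clamped to ±30 kcal/mol (the standard CoMFA truncation; otherwise
points inside atoms dominate the column variance), and a grid point within
1e-6 Å of a nucleus reports the positive clamp rather than a singularity.
The grid spans the union bounding box of the aligned series plus a 4 Å
margin at 2.0 Å spacing. Descriptor labels are `S_k`/`E_k` with
`k = ix + nx*(iy + ny*iz)` (0-based flattened grid index), so every label
decodes back to a coordinate. Columns whose population variance over the
training rows falls below 1.0 kcal²/mol² are removed: such "static" points
feel the conserved scaffold only and cannot explain activity differences.
Hydrophobic fields are not computed — the regression operates on the E and S
classes — but the field-class architecture leaves that as an extension
point.

# The QSAR model

`qsar()` is the central fitting function. Descriptor selection is
stepwise-forward: at each step the candidate column maximising the
leave-one-out q² of the refitted model joins the model, stopping at
`max_terms` (default 4) or when the best gain drops below 0.001. Ties break
to the lower column index, so fits are deterministic. Greedy forward search
against a spatially smooth, strongly collinear descriptor field is not
guaranteed to find the globally optimal subset; on noise-free synthetic
series it recovers the planted support (and r² = 1) in most runs, and with
realistic noise it lands on the planted columns or their immediate grid
neighbours, which carry essentially the same spatial information.

The regression itself is NIPALS PLS on mean-centred data. Columns are not
scaled to unit variance because all descriptors share units (kcal/mol) and
their variance ordering is chemically meaningful. The number of latent
variables is chosen to maximise LOO q², capped at `min(5, n selected)`. At
full rank the PLS solution equals ordinary least squares, which gives the
implementation a free exactness check (asserted to 1e-8 in the tests) and a
fast leave-one-out path through the hat matrix (`e_i / (1 - h_ii)`),
asserted against brute-force refits to 1e-10. A leave-one-out fold whose
refit degenerates falls back to the fold training mean and says so.

Validation reports:

* r² and q² with standard errors taken as the RMSE of the fitted and LOO
  residuals (reported QSAR "se" values are rarely given a formula; RMSE is
  the only self-consistent reading since both are in pIC50 units);
* external pred_r², computed against the *test-set* mean — a deliberate
  asymmetry with q², which uses the training mean;
* the regression F statistic `(r2/k)/((1-r2)/(n-k-1))` with `n` and `k`
  always explicit, since an F value is uninterpretable without them;
* signed contribution percentages
  `sign(coef) * 100 * |coef * sd(x)| / sum |coef * sd(x)|`, whose absolute
  values sum to exactly 100;
* a seeded Y-randomization test: the response is permuted (default 100
  times), the model refit on the same columns, and the true q² summarised
  as `z = (h - mu)/sigma` against the permuted distribution, with the best
  random r²/q² reported alongside.

Published field equations can be loaded with `qsar_model()` (labels,
coefficients, intercept) and evaluated with `predict()`; prediction is a
plain affine map and errors by name on any missing descriptor.

# Pharmacophores

Feature perception uses a small, documented rule table over six kinds:
acceptor (N/O not positively charged, lone-pair direction opposite the mean
bond vector), donor (one feature per O–H/N–H bond, located on the heavy atom,
pointing along X→H), positively ionizable (formally cationic N), negatively
ionizable (carboxylate-style groups at the oxygen centroid, other anions
individually), aromatic rings (5/6-rings that are either flagged aromatic or
all-sp2, centroid position, ring-normal direction), and hydrophobic groups
(connected non-aromatic carbon/halogen clusters with no polar neighbour, at
the cluster centroid).

Hypothesis enumeration considers every 4–5-feature combination of every
active as a candidate reference and keeps those whose intersite distance
matrix is reproducible (within 2.0 Å per pair) by kind-compatible features
of every other active. Scoring follows the site/vector/volume/selectivity
decomposition:

* site score `max(0, 1 - rmsd/1.2)` on the superposed site points;
* vector score: mean cosine between corresponding direction vectors
  (ring normals compare by |cos| since a normal's sign is arbitrary); with no
  vector-bearing pairs the score is 1 by convention, logged;
* volume score: Tanimoto of van der Waals volumes by seeded Monte-Carlo
  integration (20,000 points by default; the identity case is exact because
  both sphere sets coincide);
* selectivity: `-log10` of the fraction of a reference decoy set matching
  the hypothesis, floored at 0, with a half-count continuity correction when
  no decoy matches;
* survival `S = W_site S_site + W_vec S_vec + W_vol S_vol + W_sel S_sel`,
  all weights defaulting to 1. The printed form of this equation in the
  screening literature carries additional energy/activity terms that are
  never given definitions or weights; they exist here as hooks with weight
  0. `survival_inactive` subtracts the mean match score over known
  inactives.

Screening follows the two-pass contract: pass 1 records kind- and
distance-compatible site assignments (≥ `must_match` of the sites, default
4 of 5) to a match file; pass 2 superposes each recorded match and scores
`fitness = site + vector + volume` (≤ 3), retaining hits at fitness ≥ 1.0.
The assignment search is exhaustive over site subsets and injective feature
mappings with distance pruning — molecules carry few features, so brute
force is both exact and fast, and the suite cross-checks it against an
independent enumeration.

# Screening statistics

From `D, A, Ht, Ha` the package derives TP/FN/FP/TN, sensitivity and
specificity, the enrichment factor `EF = (Ha D)/(Ht A)` and goodness-of-hit
`GH = (Ha(3A+Ht))/(4HtA) * (1 - (Ht-Ha)/(D-A))`. GH stays in [0, 1] for any
consistent counts (property-tested over random tuples) and equals 1 exactly
at perfect retrieval. ROC curves sweep thresholds over every distinct score
(an active-scores-only sweep is available as an option, mirroring the manual
construction some screening papers use); tied scores enter as blocks, making
the trapezoidal AUC identical to the normalised Mann–Whitney U statistic,
which the tests assert to machine precision. Reported yield percentages are
always recomputed from the counts rather than copied from any source table,
because published tables sometimes carry internally inconsistent rounded
percentages.

# The synthetic data generator

Real hydroxamate series and vendor screening databases cannot be bundled, so
the generator builds the study conditions from scratch:

* **Series**: a di-aryl cyclopropane hydroxamic acid chemotype — a
  cyclopropane core bearing two phenyl rings and a C(=O)N(H)OH arm — with
  substituents drawn from {H, F, Cl, Br, CH3, OH, OCH3, NH2} at three ring
  positions. Geometry is assembled from idealised bond lengths and angles
  directly in a common frame (alignment is then exact by construction and
  verified, not assumed). The default series size is 44 compounds, matching
  a culled congeneric set; activities are planted as
  `pIC50 = 6.5 + sum(coef_j x_j) + N(0, 0.15)` over three descriptor
  columns — two steric, one electrostatic, mirroring the class mix of
  published field equations — chosen among high-variance columns at least
  three grid cells apart, with contribution shares 50/30/20 and signs
  (+, +, −), scaled so the noise-free activity spread is about 0.7 pIC50
  units (range roughly 5–8). The planted truth is returned alongside the
  data so tests never re-derive it.
* **Library**: actives embed a planted 5-site ADDRR hypothesis (one
  acceptor, two donors, two aromatic rings) as feature-bearing fragments
  (formaldehyde, methanol, benzene) placed at the site coordinates with
  Gaussian jitter (default 0.3 Å); decoys carry 1–3 fragments at random
  positions, constrained so their implied feature kinds can never cover
  four hypothesis sites. The default 100 actives + 900 decoys is a
  desk-scale stand-in for the ~82,000-compound databases screened in
  practice.

What the generator does *not* emulate: conformational flexibility (one
conformer per molecule), tautomers/protonation states, realistic decoy
chemistry (decoys are abstract fragment assemblies rather than drug-like
molecules), and any relationship between library actives and the QSAR
series' chemistry. Passing tests therefore demonstrate that the statistical
machinery recovers planted structure under controlled noise — not that the
pipeline would rank a real vendor library correctly.

# Numerical choices and degenerate inputs

* Train/test split: training size is `round-half-up(n * 0.85)`; the split
  warns when the test activity range extends beyond the training range
  (external validation is only interpolative inside it).
* A single-compound activity vector reports sd = 0 rather than NA.
* Tie-breaks everywhere are deterministic: lowest column index (selection),
  lowest atom-index tuple (template matches), id order (hit lists and
  hypothesis selection).
* Monte-Carlo volume integration and Y-randomization take explicit seeds;
  two runs of the pipeline with the same configuration produce
  byte-identical model artifacts (asserted in the suite).
* Model YAML is written at 15 significant digits so save/load round-trips
  at 1e-9.
* Screening a library that shares no feature kinds with the hypothesis
  warns and returns an empty hit list instead of erroring.
* In the screening arm, hits are carried into the model frame by their
  pharmacophore alignment before descriptor evaluation; predicted
  activities are only chemically meaningful when the hypothesis was built
  in the same frame as the QSAR grid (as `run_qsar`/`run_screen` arrange by
  construction), and are reported as a ranking aid otherwise.

# Problem sizes in the test suite

The suite exercises the study-scale conditions directly: series of 44
compounds (37/7 split) for recovery and randomization checks over 10 seeds,
1,000-molecule libraries over 10 seeds for enrichment, 1,000 draws of
200+200 scores for the AUC null, and 10,000 random count tuples for the
EF/GH identities. These sizes keep the full suite under a few minutes on a
single core while leaving every statistical conclusion at its stated
replication level.

# Known limitations

* Greedy forward selection is a heuristic; with strongly collinear grids it
  may return a proxy column one cell away from the planted truth (the
  recovery tests accept grid-neighbour hits for exactly this reason).
* Template matching ignores bond orders and SMARTS logic beyond element
  connectivity.
* Feature perception is rule-table chemistry, not a full aromaticity or
  pKa model; exotic heterocycles and tautomer-dependent features will be
  mis-assigned.
* One conformer per molecule throughout: conformational search is out of
  scope, so screening recall on flexible molecules is underestimated.
* EF/GH/AUC are computed from whatever hit list the screen produces; no
  correction for library composition bias is attempted.
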