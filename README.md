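# qsarpharm

Grid-field 3D-QSAR and pharmacophore screening for congeneric ligand
series, in R.

## What problem this solves

Medicinal chemistry programs routinely face a congeneric series — tens of
compounds sharing a scaffold, differing by substituents, each with a
measured potency (pIC50) — and a large untested library to mine for new
actives. `qsarpharm` implements the classic ligand-based answer end to end:

1. **Molecular field analysis (CoMFA-style 3D-QSAR).** All structures are
   rigidly aligned on their common template (Kabsch superposition over an
   element-graph substructure match), high-RMSD outliers are culled, and
   steric (Lennard-Jones) plus electrostatic (Coulomb, Gasteiger–Marsili
   charges, dielectric 1) probe energies are evaluated on a 3D grid around
   the series. Grid energies become the regression descriptors
   `S_k`, `E_k`.
2. **Stepwise PLS regression with full validation.** Descriptors enter by
   greedy forward selection on leave-one-out q²; the final NIPALS PLS model

   `pIC50 = b1·(descriptor 1) + … + bk·(descriptor k) + b0`

   is reported with r², q² (LOO, training-mean convention), external
   pred_r² (test-mean convention), standard errors, the regression
   F statistic, signed contribution percentages, and a seeded
   Y-randomization Z-score.
3. **Common pharmacophore hypotheses.** Features (acceptor, donor,
   hydrophobe, ± ionizable, aromatic ring) are perceived from documented
   rules; all 4–5-site arrangements common to the actives are enumerated
   and ranked by survival score
   `S = W_site·S_site + W_vec·S_vec + W_vol·S_vol + W_sel·S_sel`.
4. **Virtual screening and its statistics.** Libraries are screened with a
   k-of-n (default 4-of-5) site match and fitness
   `site + vector + volume` (threshold 1.0); hits feed confusion counts and
   the screening-quality metrics
   `EF = (Ha·D)/(Ht·A)`,
   `GH = (Ha·(3A+Ht))/(4·Ht·A) · (1 − (Ht−Ha)/(D−A))`,
   sensitivity/specificity and ROC/AUC (tie handling identical to the
   Mann–Whitney U statistic).

A synthetic-data module generates congeneric series with planted
field-linear activities and actives/decoys libraries with a planted
pharmacophore, so every stage is testable without proprietary data.

## Worked example

```r
library(qsarpharm)

# a 44-compound synthetic hydroxamate-like series with planted activity
gen   <- generate_series(n_molecules = 44, noise_sd = 0.15, seed = 7)
split <- split_train_test(gen$activities, train_fraction = 0.85, seed = 7)
X     <- drop_invariant_columns(gen$descriptors, variance_cutoff = 1.0,
                                train_ids = split$train$molecule_id)
fit <- qsar(X[split$train$molecule_id, ],
            setNames(split$train$pIC50, split$train$molecule_id),
            x_test = X[split$test$molecule_id, ],
            y_test = setNames(split$test$pIC50, split$test$molecule_id),
            n_perm = 100, seed = 7)
summary(fit)
```

```
Grid-field 3D-QSAR model (PLS, 3 latent variables)
  pIC50 = +0.028198 (S_584) +0.018287 (S_592) -0.0098148 (E_470) -0.005405 (S_675) +6.4764
  n = 37, k = 4: r2 0.9212 (se 0.1380), q2 0.8991 (se 0.1561), F 93.5021
  external: pred_r2 0.9735 (se 0.0818)
  Contribution (%):
    S_584     +50.478
    S_592     +25.609
    E_470     -16.853
    S_675      -7.060
Y-randomization (100 permutations): true q2 0.8991, permuted mu -0.1824 sd 0.1232
  Z = 8.781   best random r2 0.4133   best random q2 0.1165
```

The planted truth for this seed was `S_584 S_569 E_458`: the fit recovers
the dominant steric descriptor exactly and the other two as immediate grid
neighbours (`S_592` sits one cell from `S_569`, `E_470` one cell from
`E_458`), with a q² of 0.90 against a scrambled-response mean of −0.18
(Z ≈ 8.8) — i.e. the model reads genuine field structure, not noise.

Screening a planted 1,000-molecule library against its 5-site ADDRR
hypothesis:

```r
lib <- generate_screening_library(seed = 7)   # 100 actives + 900 decoys
res <- screen_library(lib$library, lib$hypothesis)  # 4-of-5, fitness >= 1
cnt <- confusion_counts(res$id[res$hit], lib$active_ids, res$id)
enrichment_factor(cnt)   # 10.0  (= D/A, perfect retrieval here)
gh_score(cnt)            # 1.000
```

`run_qsar()` / `run_screen()` orchestrate the same chain behind a single
configuration list (YAML-compatible, see `pipeline_config()`), writing
aligned structures, descriptor tables, model/validation YAML, hit lists and
ROC points to an output directory; `inst/cli/qsarpharm.R` is a thin shell
wrapper over them.

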