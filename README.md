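# liabprof

Ligand-based off-target **liability profiling** for small molecules, as an R
package. Drug candidates bind, on average, half a dozen proteins besides
their intended target, and those off-target hits — hERG block, muscarinic
antagonism, COX inhibition — are a leading cause of clinical failure.
`liabprof` implements the full first-tier screening workflow at desk scale:

1. **Curation** — raw structure–activity records (SMILES + IC50/EC50/Ki/Kd)
   are filtered (human-only, censored values out), standardized (salt
   stripping, neutralization, nitro/N-oxide/azide normalization,
   canonicalization) and collapsed to one compound per structure with the
   **median** pACTIVITY = −log10(molar activity); 1 µM ↔ 6.0.
2. **Featurization** — 2059 features per compound: 11 physicochemical
   descriptors + radius-6 extended-connectivity (EC) and feature-invariant
   (FC) circular fingerprints, 1024 bits each; the 2048-bit EC‖FC vector
   doubles as the similarity representation.
3. **Splitting** — 80/20 stratified on pACTIVITY (random, Murcko-scaffold
   and max–min diversity splits available).
4. **Models** — gradient boosting (xgboost) and random forest (ranger)
   against a multi-linear baseline, tuned by Latin-hypercube seeding of a
   genetic algorithm minimizing 5-fold CV-RMSE, with stagnation and
   wall-clock early stopping.
5. **Validation** — external test-set metrics (Pearson R, R², RMSE) plus
   iterated 5-fold CV, 90/10 bootstrap and y-randomization; enrichment
   factor EF = (A_χ/M_χ)/(A/M) at 1/5/10% with top-2% active labelling and
   Mann–Whitney AUC.
6. **Profiling** — per-target predictions are flagged concern (C) / not
   concern (nC) at pACTIVITY ≥ 6.5 (~300 nM) and aggregated into seven
   liability-group scores *Ls*ᵢ = Cᵢ/(Cᵢ+nCᵢ) (cardiovascular, CNS,
   gastrointestinal, endocrine, pulmonary, renal, immune) via a packaged
   target–liability mapping; prediction reliability is the fraction of
   models whose applicability domain (max training-set Tanimoto > 0.7) is
   fulfilled.

A seeded **synthetic-data generator** (fragment-grammar SMILES assembly,
tunable structure–activity signal, artifact injection) makes the whole
pipeline testable with no external data, and a **chemical-space module**
provides Murcko scaffolds, all-carbon basic frameworks, scaffold-grouped
PCA maps and pairwise dataset comparison matrices (Kolmogorov–Smirnov on
activity distributions, mean inter-set Tanimoto).

## Worked example

```r
library(liabprof)

# a 3-target synthetic panel of 120 compounds with raw-data artifacts
pan <- generate_panel(n = 120, targets = c("KCNH2", "DRD2", "HTR2A"),
                      noise_sd = 0.3, seed = 42)

cfg <- default_config()           # 80/20 stratified, 5-fold CV, Tc 0.7 ...
cfg$validation$iterations <- 5
res <- run_pipeline(pan$raw, cfg, out_dir = "artifacts")
print(res)
#> Pipeline result: 3 target(s)
#>   KCNH2: n=120 champion=RF external R=0.374
#>   HTR2A: n=120 champion=RF external R=0.670
#>   DRD2: n=120 champion=RF external R=0.576

# profile a query compound against the champion registry
prof <- profile_compounds("CC(=O)Nc1ccc(O)cc1", res$registry)
profile_summary(prof)
#>               smiles    CV CNS GI ED PU RE IM AD error
#> 1 CC(=O)Nc1ccc(O)cc1 0.667 0.5 NA  0 NA NA NA  0  <NA>
```

The per-group columns are the liability scores *Ls*ᵢ ∈ [0, 1]: with this
three-target registry the probe is flagged concern on two of the three
cardiovascular-mapped targets (CV = 2/3) and one of the two CNS-mapped
ones; `NA` marks groups none of whose member targets is modelled by the
registry. `AD = 0` says the query fulfils no model's applicability domain
(its maximum Tanimoto similarity to every training set is below 0.7), so
all of these predictions are extrapolations — exactly the warning the AD
score exists to give for a probe that is far smaller than the synthetic
training compounds. At n = 120 per target the external correlations are
modest and random forest happens to win every champion slot; at the
package's 500-compound study scale gradient boosting typically leads.

Lower-level entry points: `curate_dataset()`, `build_feature_matrix()`,
`split_dataset()`, `tune()`/`fit_model()`, `validation_report()`,
`enrichment_factor()`, `liability_scores()`, `scaffold_table()`,
`dataset_distance_matrices()`. A thin CLI with the same stages lives at
`inst/cli/liabprof`.

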