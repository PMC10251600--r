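---
title: "Desk-scale QSAR liability profiling with liabprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale QSAR liability profiling with liabprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Small-molecule drug candidates routinely bind half a dozen or more proteins
beyond their intended target, and those off-target interactions — on hERG,
muscarinic receptors, COX enzymes, monoamine transporters and the like — are
a leading cause of clinical failure and market withdrawal. liabprof
implements a first-tier, ligand-based screening workflow for this problem:
per-target QSAR regressors predict the activity (pACTIVITY, the negative
decadic logarithm of the molar IC50/EC50/Ki/Kd) of a query compound on a
panel of safety-pharmacology targets, predictions are thresholded into
*concern* / *not-concern* flags, and the flags are aggregated into seven
mechanistic liability scores (cardiovascular, central nervous system,
gastrointestinal, endocrine disruption, pulmonary, renal, immune) via a
packaged target–liability mapping.

The per-group score is simply the concern fraction,

$$Ls_i = \frac{C_i}{C_i + nC_i},$$

ranging from 0 (no member target flagged) to 1 (all flagged). A target that
is relevant to several liability groups contributes to each of them. The
packaged mapping follows the published reference lists verbatim; we note
that the source table labels the cardiovascular group with 25 members while
enumerating 24, and that the union of all printed lists is 41 unique
symbols rather than the stated 46-target panel. We package the printed
lists and document the discrepancy rather than inventing entries.

## Pipeline stages and their assumptions

**Curation.** Raw records are filtered sequentially: only human
measurements (species label "homo sapiens" or "human", case-insensitive),
only IC50/EC50/Ki/Kd activity types, censored values (`>`/`<`) excluded.
Functional and binding readouts are pooled by default — the usual
first-tier compromise that maximizes training-set size — and a
configuration switch restricts to binding-only or functional-only when a
cleaner endpoint is wanted. Structures are standardized by keeping the
largest organic fragment (heavy-atom count, ties broken by lexicographic
canonical SMILES), rewriting nitro/N-oxide/azide groups in their
charge-separated form, neutralizing isolated charges, and canonicalizing
with OpenBabel. No 3D geometry is ever generated; every descriptor used
downstream is conformer-independent. De-duplication is keyed on exact
standardized-SMILES match and takes the per-compound **median** pACTIVITY,
which makes the result invariant to record order. Where a compound carries
measurements of several activity types the median pools across types; a
per-type median before pooling would be a defensible alternative, but
pooling matches the first-tier philosophy and is what the configuration
default does.

**Featurization.** Each compound is encoded by 2059 features: 11
physicochemical descriptors plus two circular fingerprints of radius 6
folded to 1024 bits each. The descriptor set — molecular weight, calculated
logP, topological polar surface area, H-bond donors and acceptors,
rotatable bonds, aromatic and aliphatic ring counts, annotated stereocentre
count, fraction of sp3 carbons, heavy atoms — was chosen to cover the
properties that matter for chemical-space interpretation (they are the ones
usually plotted when such panels are described). The extended-connectivity
(EC) fingerprint hashes atomic invariants (element, degree, H count,
charge, aromaticity, ring membership); the feature-invariant (FC) variant
hashes pharmacophoric atom roles (donor, acceptor, basic, acidic, halogen,
aromatic). Radius 6 is the circular-environment *radius*, not diameter.
The 2048-bit EC‖FC concatenation is the similarity vector used for the
applicability domain. Because no installed R package provides radius-6
circular fingerprints (or any feature-invariant variant), the hashing is
implemented in the package on the parsed molecular graph; it is
deterministic and folded by modulo, like any fixed-length hashed
fingerprint. Tree ensembles are scale-invariant, so descriptors are not
scaled before model fitting; autoscaling is applied only where the analysis
requires it (PCA, scaffold tables).

**Splitting.** The default is an 80/20 stratified split on pACTIVITY with
equal-width 1.0-log-unit bins (bins with fewer than two members are merged
into their nearest neighbour). Equal-width was chosen over equal-frequency
because the stratification variable has natural, assay-driven modes at 5
and 6 log units; both the bin width and the strategy are configurable.
Alternatives: plain random, Murcko-scaffold-disjoint (whole scaffold groups
assigned to one side; the 80/20 ratio is then only approximate, which is
inherent to scaffold splits), and diversity (max–min Tanimoto picking, test
set picked first so it is the diverse one).

**Models and tuning.** Gradient boosting (xgboost, histogram tree method)
and random forest (ranger) are the candidate models, with multi-linear
regression as the baseline. At 2059 features the linear design is always
singular, so the baseline silently degrades to a closed-form ridge
(penalty 0.01·n on centred features) and flags itself as
ridge-stabilized. Hyperparameters are tuned by a Latin-hypercube design
that seeds a small genetic algorithm (tournament size 3, uniform crossover
0.8, per-gene mutation 0.1, elitism 1), with 5-fold CV-RMSE on the training
partition as the objective, fixed folds across candidates for
comparability, and early stopping on five stagnant generations or a
wall-clock budget. The histogram bin count maps to xgboost's `max_bin`;
L1/L2 map to `alpha`/`lambda`. The desk-scale budget default is 5 minutes
per target; a long-run preset (100 minutes, the published protocol value)
is available via `default_config("full")`. When the budget expires
mid-evaluation the CV score of the completed folds is used, so the
procedure degrades gracefully instead of overrunning.

**Validation.** External validation uses the held-out test partition, which
never participates in tuning or training (overlap is a hard error).
Internal validation iterates 5-fold cross-validation, 90/10 bootstrap and
y-randomization; the desk default is 20 iterations with a 100-iteration
preset. y-randomization metrics are computed under cross-validation — a
scrambled response scored on training fits would report inflated, not
near-zero, performance, and near-zero is what the protocol is meant to
demonstrate. Compounds are put in a canonical order (response value, then
feature sum) before fold assignment, so reports are invariant to input row
order under a fixed seed. The champion per target is the ensemble with the
highest external Pearson R, ties to gradient boosting. R is preferred over
RMSE for champion selection because assay-threshold modes in the response
make RMSE the less robust summary.

**Screening power.** Actives are the top 2% of compounds by observed
pACTIVITY (deterministic tie-break: descending activity, then compound
identifier), the selection is the top χ ∈ {1%, 5%, 10%} of the prediction
ranking with ceiling rounding (so the 1% selection is never empty), and
EF = (A_χ/M_χ)/(A/M). The ranking AUC is the Mann–Whitney statistic with
midrank tie correction.

**Applicability domain.** For each model the maximum Tanimoto coefficient
between the query's 2048 similarity bits and the model's stored training
fingerprints; the AD is fulfilled when Tc exceeds 0.7 strictly, and the
overall AD score is the fulfilled fraction across the registry.

**Concern threshold.** The fixed cutoff is 6.5 log units (10^-6.5 M ≈
316 nM, conventionally rounded to 300 nM), applied inclusively: a
prediction exactly at 6.5 is a concern — the conservative choice for a
safety screen. A two-sigma variable cutoff (train mean + 2 SD) is available
per target, and liability scores accept optional per-target weights
(uniform by default) for users who want, say, hERG to dominate the
cardiovascular score.

## The synthetic-data generator

Real training corpora for this kind of platform come from proprietary and
public SAR databases and cannot ship with a package. The generator instead
emulates the *statistical shape* of such data so that every stage is
testable offline:

- **Structures** are assembled from a packaged fragment grammar (18 ring
  cores, 14 linkers, 23 substituents), standardized and de-duplicated;
  500 compounds span 50+ Murcko scaffolds.
- **Activities** follow pACTIVITY ~ mean 6.6, SD 0.6, matching the
  summary statistics reported for curated liability panels. The
  structure–activity function is linear in autoscaled descriptors plus a
  weighted sum over 64 seeded fingerprint bits drawn from
  informative-prevalence substructures (present in 5–95% of the library).
  Weights are heavy-tailed — a dozen dominant "pharmacophore" effects over
  a minor background — and a handful of pairwise bit interactions emulate
  activity cliffs. This is deliberate: a signal spread uniformly over 64
  rare bits is statistically unlearnable at n = 500 regardless of model,
  and real SAR series are dominated by a few key substructures. Gaussian
  noise of SD `noise_sd` (default 0.3 log units, the order of inter-assay
  variability) is added; the clean signal is scaled to
  sqrt(sd_target² − noise_sd²) so the realized sample SD lands on target.
- **Artifacts** are additive: censored and non-human records are extra
  corrupted copies, duplicates are extra jittered copies, salts are
  carbon-free counter-ions appended in place. Curation therefore
  provably round-trips to the clean compound set, with medians checkable
  against the generator's bookkeeping.

What passing tests on this generator do **not** show: performance on real
heterogeneous assay data (inter-laboratory shifts, activity cliffs sharper
than pairwise bit interactions, series bias), behaviour at corpus scale
(10³–10⁴ compounds per target), or the generalization claims one would make
from a prospective screen. They do show that the machinery — curation
algebra, encoding, resampling protocols, tuning, scoring — is correct and
that the models recover a known signal of realistic shape and noise.

## Problem sizes and numerical choices

Test and acceptance runs use 500 compounds per target (the lower end of
real panel sizes), 3-target panels, 20 validation iterations, and tuning
budgets of 1.5–5 minutes per algorithm; these are the package's desk-scale
defaults, with the published full-scale values exposed as presets. The
low-noise parameter-recovery run uses noise_sd 0.2 (within the "≤ 0.3"
regime that defines a learnable signal at this n). Degenerate inputs are
handled explicitly: zero-variance vectors make Pearson R undefined (NaN
with a flag, never a silent 0); an all-zero fingerprint pair has Tanimoto 1
by convention; frameworks that cannot re-aromatize after carbon abstraction
fall back to a single-bond skeleton with a warning; acyclic molecules have
no scaffold and are tabulated separately. The correlation filter drops the
*later* column of each offending pair in fixed column order, which makes it
deterministic and idempotent. Enrichment at a test-set size below 1/active
fraction is skipped rather than fabricated from a single "active".

## Known limitations

- OpenBabel's canonical SMILES, ring perception and logP/TPSA
  implementations differ numerically from other toolkits; fingerprints are
  package-specific hashes. Models and similarities are therefore internally
  consistent but not bit-compatible with fingerprints computed elsewhere.
- Stereocentre counting uses annotated stereocentres only; unannotated
  (potential) stereocentres are not perceived.
- The scaffold split makes no attempt to balance activity distributions
  across partitions, and the diversity split is greedy max–min, not an
  optimal design.
- The genetic algorithm is a small, honest implementation of the published
  tuning idea, not a general-purpose optimizer; with desk budgets it
  explores tens of configurations, not thousands.
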