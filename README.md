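# hybridsurv

Predicting migratory survival of hybrid-zone songbirds from genetic,
morphological, and behavioural traits.

## The problem

In a migratory divide, two songbird lineages with different inherited
migration programs meet and hybridize. Whether hybrids pay a survival cost
on migration — and which traits carry that cost — is a central question
for speciation research, but survival in the wild is hard to measure and
trait effects are correlated, nonlinear, and interactive.

`hybridsurv` implements a complete analysis pipeline for this question,
built around automated radio-telemetry (Motus-style) detection data from
fall-tagged juveniles:

1. **Survival labeling.** Detections over a 300-day window are binned into
   30 ten-day capture occasions. A Cormack–Jolly–Seber model — a two-state
   (alive/dead) hidden Markov model with per-interval apparent survival
   φ\_t and per-occasion detection probability p\_t — is fitted by maximum
   likelihood, and each bird's posterior probability of being alive on the
   final occasion is binarized at 0.5 into survived / not survived.
2. **Feature preparation.** A 14-feature panel (morphology, body condition
   = weight/tarsus in g/mm, fall orientation and timing derived from the
   detection stream, release metadata, genome-wide ancestry q and
   heterozygosity H, sex): Pearson pruning of pairs with |r| ≥ 0.7,
   a 25% missingness filter with a whitelist for the two behavioural
   features, standardization, and KNN imputation (k = 5, nan-Euclidean
   distance), then a stratified 80/20 split.
3. **Imbalance-aware classification.** SMOTE oversampling of the minority
   (survivor) class, a balanced random forest (majority class
   down-sampled in each bootstrap), randomized hyperparameter search with
   5-fold stratified CV on macro-F1, and a classification threshold tuned
   over 100 even steps on [0.40, 0.70].
4. **Interpretation.** Gini (mean-decrease-in-impurity) importance against
   the 1/k null line; a joint-permutation screen over all 91 feature pairs
   retaining pairs whose permutation drops macro-F1 by ≥ 0.1; exact
   path-dependent tree SHAP values (compiled, additivity to the model
   output at machine precision); and a bootstrap Spearman correlation
   network over the trait panel.

Because the field data are not redistributable, the package ships a
synthetic cohort generator (`simulate_cohort()`) that reproduces the
statistical structure the analysis assumes — hybrid-class genetics obeying
the triangle constraint H ≤ 2·min(q, 1−q), a correlated morphology block,
ancestry-linked von Mises fall orientation, ~69/31 class imbalance, 28%
behavioural missingness, and a planted nonlinear survival model — so every
stage is testable end to end with known ground truth.

## Worked example

The `analysis/` directory holds the numbered drivers of the full analysis;
run them in order from the repository root:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_label_survival.R
...
Rscript analysis/07_trait_network.R
```

Outputs land in `results/run/`. A run at the default seed prints, among
other things:

```
cohort: 600 birds; 189 planted survivors ( 31.5 % )
agreement with planted survival: 98.2 %
pruned (|r| >= 0.7): p7, p8, p9, weight
optimal threshold: 0.567
confusion (tn fp fn tp): 74 10 25 11
accuracy: 71 %
non-survivors: precision 0.75 recall 0.88 F1 0.81
survivors:     precision 0.52 recall 0.31 F1 0.39
features above the 1/k null line (0.071):
     condition   fall_bearing         tarsus heterozygosity     wing_chord
         0.176          0.099          0.094          0.083          0.081
91 feature pairs screened; 4 with an F1 drop >= 0.1
SHAP base value: 0.513 | additivity max error: 3.66e-15
```

Read: the CJS labeler recovers 98% of the planted outcomes; the pruner
removes exactly the redundant feather block (P7–P9 track wing chord) and
raw weight (absorbed into condition); the classifier predicts
non-survival much better than survival, as expected under class imbalance
with a noisy positive class; and the interpretation stages surface the
planted condition, orientation, and heterozygosity effects. Equivalent
single-call orchestration is available as `run_pipeline(run_config(...))`.

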