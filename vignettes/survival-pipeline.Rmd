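---
title: "Predicting migratory survival in a songbird hybrid zone: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting migratory survival in a songbird hybrid zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridsurv)
```

This vignette is the package's own account of the science it implements:
the models at each stage, the parameters that matter, the places where the
design was genuinely open and what we chose, and what the synthetic-data
tests do and do not demonstrate about real field data.

## 1. Survival labeling from telemetry

Automated radio telemetry yields, for each tagged bird, a stream of
station detections. We use detection in spring as a proxy for having
survived migration, but rather than thresholding raw detections we run the
stream through a capture–recapture model so that the full history informs
the call.

**Occasion binning.** Detections over a 300-day study window are binned
into 30 ten-day capture occasions; repeat detections within a bin collapse
to a single 1, so a stopover near a dense station cluster does not inflate
the history. Bins are half-open, `[10k, 10(k+1))` — the edge convention is
ours, as any is defensible. A detection after day 300 proves survival and
is folded onto the final occasion. The release itself is occasion 0 and is
always 1.

**The CJS hidden Markov model.** Conditional on release, the bird's latent
state evolves as a two-state Markov chain: alive at occasion t+1 with
probability φ\_t given alive at t; dead is absorbing and silent. Detection
given alive at occasion t+1 has probability p\_t. `cjs_likelihood()`
computes the standard CJS likelihood as a scaled forward pass, and the
suite verifies it against exhaustive enumeration of all alive/dead paths
to 1e-10 in log space.

**Fitting and identifiability.** Both φ and p vary with time.
`fit_cjs()` maximizes the summed log-likelihood by L-BFGS-B from a flat
0.5 start, with parameters boxed to [1e-6, 1−1e-6] to keep the likelihood
finite. Fitting all 58 time-varying parameters *per bird* to one binary
vector is unidentifiable — the optimizer simply runs to the boundary,
which is why per-bird fits produce the characteristic ~0/~1 survival
products. We keep that mode (`mode = "per_bird"`) for fidelity, but the
default is a cohort fit: one shared parameter set across birds, with each
bird labeled by its posterior probability of being alive at the final
occasion (the normalized forward variable at T). Two further choices:

* In the last interval only the product φ·p is identified (a standard CJS
  ridge). Cohort mode therefore ties the terminal φ and p to their
  penultimate values (`tie_terminal = TRUE`). Without the tie, a survivor
  missed only on the final occasion gets a posterior near 0.5 determined
  by where the optimizer happens to land on the ridge.
* Binarization is at 0.5. The labeling is insensitive to this: fitted
  cohorts produce probabilities that are near-binary (the demo run leaves
  fewer than 7% of birds between 0.001 and 0.999, and none at all between
  0.4 and 0.6).

## 2. The feature panel

Fourteen predictors: seven structural measures (distal wing length, P10,
body condition = weight/tarsus in g/mm, tarsus, Kipp's distance, tail,
wing chord), two detection-derived behaviours (fall timing: day of year
first detected within 30 km of the release site during a fall window,
default days 213–304; fall orientation: initial great-circle bearing to
the first station detected within 300 km, compass degrees), release day
and year, genome-wide ancestry q (0 = coastal, 1 = inland) and
heterozygosity H, and sex (0/1). Two conventions worth stating:

* The tagging event itself (timestamp 0) is not counted as a detection
  when deriving fall timing — otherwise timing would always equal release
  day. Release-site detections at positive timestamps do count (the
  tagging station re-hearing the bird), but carry no bearing (undefined
  at zero distance).
* Bearings and days of year enter the matrix as plain scalars. A sin/cos
  circular encoding would be defensible, but the linear treatment matches
  the analysis this package reproduces; distances use the haversine
  formula on a 6371-km sphere.

**Pruning and filtering.** Pairs with |Pearson r| ≥ 0.7 lose one member,
scanned in descending |r|; which member survives is governed by an
explicit priority list (default: wing chord over the inner primaries,
condition over raw weight), because the redundancy rule alone does not
determine the choice. Features over 25% missing are dropped (strictly
greater), except the two behavioural features, which are whitelisted at
their ~28% missingness for their ecological importance.

**Standardize, impute, split.** All features are standardized to mean 0,
sd 1 (parameters stored for reuse on held-out rows), then missing cells
are imputed by the unweighted mean of the k = 5 nearest rows under the
nan-Euclidean distance `sqrt(k_total/k_obs * sum of squared co-observed
differences)`; the suite checks this cell-for-cell against a brute-force
all-pairs implementation. Imputed sex is snapped to the nearest class
value. The default pipeline order is standardize → impute → split
(`mode = "pooled"`): imputation sees all rows, so a little
information crosses the split. Since fitting everything on training rows
only is equally defensible, a `mode = "strict"` variant fits
standardization and imputation on the training rows and applies them to
the test rows (each imputed against the training pool alone). The split
itself is stratified: per-class random partition at 20%, preserving the
survivor fraction to within one bird.

## 3. Class imbalance and the classifier

About 31% of birds survive. Two imbalance devices are applied in
sequence, deliberately mirroring the workflow this package reproduces:
SMOTE brings the survivor class up to parity by interpolating uniformly
along segments between minority rows and their k = 5 nearest minority
neighbours, and the forest then draws class-balanced bootstraps. On
SMOTE-balanced input the balanced bootstrap degenerates to an ordinary
bootstrap — the redundancy is intentional, not an oversight.

The classifier is a balanced random forest (ensemble of classification
trees; predicted probability = fraction of tree votes), backed by the
`randomForest` package. The search domains are: trees {100, 200, 300},
depth {10, 20, unbounded}, features per split {sqrt, log2, all}, minimum
split size {2, 5, 10}, minimum leaf size {1, 2, 4}. Depth and the split
minimum are enforced through the backend's controls (`maxnodes` = 2^depth;
`nodesize` = max(min leaf, ⌊min split / 2⌋)) — with ~500 training rows a
depth-10 cap is already non-binding, so these two knobs are nearly inert
here, as they are in any implementation at this sample size.
`tune_hyperparameters()` draws 50 candidates uniformly (the count is our
choice; it is not dictated by the method) and scores each by 5-fold
stratified CV macro-F1 with SMOTE applied inside each training fold only,
so no synthetic sample ever derives from a validation row — the SMOTE
output carries parent provenance precisely so the suite can assert this.

**Threshold.** The final decision threshold is the smallest of 100 evenly
spaced values on [0.40, 0.70] maximizing macro-F1 on the test set
(prediction rule: survived iff probability ≥ τ, inclusive). Tuning on the
test set is the literal protocol being reproduced; for methodological
hygiene the sweep is a pure function (`threshold_sweep()`) that can be
pointed at a validation set instead. Whether the headline metrics should
be read at τ* or at 0.5 is ambiguous in the source protocol; we report at
τ*.

## 4. Interpretation

**Gini importance** is the forest's total impurity decrease per feature,
normalized to sum to 1, read against the equal-contribution null 1/k
(= 1/14 ≈ 0.07 for the full panel).

**Pairwise interaction screen.** For each of the 91 unordered feature
pairs, both columns are permuted across the test rows and the drop in
macro-F1 (at the tuned threshold) from the unpermuted baseline is
recorded; pairs with a drop ≥ 0.1 are retained. We permute the two
columns with *independent* permutations: the stated aim of the procedure
is to destroy the pair's joint structure while preserving marginals, and
a single shared permutation of both columns would preserve exactly the
within-pair dependence the screen is supposed to break (the shared
variant is available behind `shared_permutation = TRUE`). Two caveats the
user should know:

* A single permutation (`n_repeats = 1`, the literal protocol) is a noisy
  estimate on a 120-row test set; `n_repeats = 30` is recommended, and
  the analysis drivers use 10.
* The drop conflates main effects with interactions: permuting pair
  (a, b) also destroys a's and b's individual contributions. A *pure*
  interaction with no main effects is therefore not separable from pairs
  that share one member with it — permuting either member alone already
  removes all signal. The screen's power test accordingly plants an
  interaction whose members also carry main effects, the regime in which
  the interacting pair strictly dominates and the regime the screened
  field data plausibly occupy.

**SHAP.** Per-bird, per-feature contributions are exact path-dependent
tree SHAP values, computed in compiled code over the extracted trees with
node covers counted from the training matrix (so cover(parent) =
cover(children) and the efficiency identity holds exactly: base value +
row sum = predicted probability, verified to < 1e-6 — in practice ~1e-15).
The suite also checks the kernel against brute-force Shapley subset
enumeration on small forests. Dependence tables (feature value vs SHAP
value) are emitted for plotting.

**Trait network.** Spearman rank correlations between all panel pairs on
pre-imputation, pairwise-complete values (a post-imputation variant is a
one-argument change), with significance from a bootstrap: resample rows
with replacement, recompute ρ, and flag the pair when the 95% percentile
interval excludes 0. The source protocol says "significantly correlated"
without naming a rule; the percentile-CI criterion is our choice, and no
multiple-testing correction is applied across the 91 pairs (the measured
per-pair false-flag rate is ≈4.7% at α = 0.05). Default replicates are
10,000 in the drivers; 100,000 is a config change.

## 5. The synthetic cohort generator

The generator exists so that every stage above can be tested against
known ground truth. It emulates:

* **Hybrid-class genetics** over 1495 ancestry-informative loci idealized
  as fixed differences: parentals homozygous, F1 fully heterozygous, F2
  drawing locus-wise from (¼, ½, ¼), backcrosses from (½, ½). This makes
  the triangle constraint H ≤ 2·min(q, 1−q) hold exactly by construction.
  The class mix (15/15/10/20/20/20% across coastal, inland, F1, F2, and
  the two backcrosses) is our choice of a plausible hybrid-zone sample.
  Ancestry polarity is 1 = inland; because the source material is
  internally inconsistent about which end of the axis is "inland" in its
  dependence plots, the generator exposes `polarity_inland_one` to flip
  the reported axis without touching the underlying truth.
* **Morphology** from a multivariate normal with a tight (r = 0.85) block
  over wing chord and P7–P9 and a tarsus–weight link, plus a small
  ancestry shift in wing shape; condition = weight/tarsus follows. The
  means and spreads are field-realistic for a ~30 g thrush.
* **Behaviour.** Fall bearing is von Mises (κ = 4) with mean rotating
  from 30° west of due south (coastal) to 30° east (inland); release day
  uniform on days 213–273; first near-release detection lags release by
  an exponential-tailed delay (mean ≈ 30 days, truncated at day 304). The
  swing, concentration and delay were set so that ancestry–bearing and
  timing–release-day correlations stay clearly below the 0.7 pruning
  threshold, as in the study panel, while remaining individually strong.
* **Planted survival**: Bernoulli on a logistic scale with a quadratic
  ancestry term, positive condition, heterozygosity, eastness and year
  effects, and condition×year, ancestry×year, eastness×tarsus products;
  the intercept is calibrated by root-finding so the marginal survival
  rate hits the configured 30.9% regardless of effect sizes.
* **Detections**: a release-day detection always; birds with observed
  timing/bearing get the corresponding near-release and within-300-km
  stations (placed along the bird's true bearing); each further ten-day
  occasion while alive yields a detection with probability 0.8 at a
  station along the trajectory, all beyond the 300-km orientation radius
  so they cannot contaminate the bearing derivation. Non-survivors draw a
  death occasion in fall (occasions 3–9) and fall silent; survivors keep
  emitting through the spring window, defined as day > 240 (~8 months
  after tagging; the source protocol never names a cutoff).
* **Missingness**: fall bearing and timing are independently masked for
  28% of birds, and the detection generator withholds the corresponding
  stations so detection-derived features agree with the masked traits.

What it deliberately does **not** emulate: real station geography and
coverage gaps, tag failure and detection-probability heterogeneity among
individuals, weather- or habitat-driven survival variation, permanent
emigration (confounded with death in apparent survival), and any
sequencing error in ancestry calls. Passing tests therefore demonstrate
that the pipeline's machinery is correct and recovers planted structure
under its own assumptions — not that the biological conclusions of any
particular field dataset are right.

## 6. Numerical conventions and problem sizes

Optimizer: L-BFGS-B, start 0.5, box [1e-6, 1−1e-6], max 500 iterations.
Ties in the threshold sweep and the greedy pruner break toward the
smaller threshold / the priority list then column order. Metrics with
zero denominators report 0 with an `undefined` flag and count as 0 in
macro averages. Display rounding is half-up, two decimals (percentages to
integers). All stage seeds derive from one global seed by stage-name
hashing, so stages rerun in isolation reproduce exactly; two runs of the
same config are identical.

The shipped tests and drivers run at desk scale, chosen to exercise every
code path with comfortable statistical margins: cohorts of 400–600 birds
(one 2000-bird and one 10,000-bird check where a rate needs tight
Monte-Carlo bounds), forests of 20–300 trees, 10 replicates for the
screen-power and planted-effect-recovery properties, and 10,000 bootstrap
replicates for the network (300 replicates when estimating its
false-flag rate).

## 7. Known limitations

* Apparent survival confounds mortality with permanent emigration; the
  labels inherit this.
* The cohort CJS assumes exchangeable birds; trait-dependent detection
  probability would bias labels for trait classes that are harder to
  detect, and is not modelled.
* Threshold tuning on the test set makes the headline metrics mildly
  optimistic; use a validation split for unbiased reporting.
* The interaction screen measures predictive reliance on a pair, not
  statistical interaction in the causal sense, and inherits permutation
  noise at small test sizes.
* SMOTE before a balanced bootstrap is redundant; it is retained for
  protocol fidelity.
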