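---
title: "Ensemble swarm-intelligence feature selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble swarm-intelligence feature selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zooselect)
```

## The problem

Transcriptome and methylome classification problems live in the "large p
small n" regime: tens of thousands of features measured on a few dozen
samples. A feature-selection wrapper searches for a small subset of features
whose induced classifier predicts the phenotype well, but the subset space is
exponentially large and a single stochastic search heuristic tends to land in
its own idiosyncratic local optimum. `zooselect` addresses this by running
*nine* different binary swarm-intelligence (SI) optimizers over the same
prefiltered feature space, combining their proposals by majority vote, and
then pruning the voted subset with a linear-SVM-driven dynamic recursive
feature elimination (dRFE). The intuition is that the engines' search biases
are complementary: features recommended by a majority of them are more likely
to carry real signal than features recommended by any single engine.

## Pipeline

Given a samples-by-features matrix with a binary phenotype, `run_zoo()`
executes:

1. **Stratified 1:1:1 split** into training, validation and test sets.
   Within each class, samples are shuffled with the seeded generator and
   dealt round-robin into the three parts, which forces per-class sizes to
   agree within one sample. The split is drawn once per (dataset, seed).
2. **t-test prefilter.** Every feature is scored by a pooled-variance
   two-sample t-test on the training set and the 1000 smallest p-values are
   kept (`prefilter_k`). This bounds the dimension the SI engines face.
   Ties break by larger |t|, then original index, so the ranking is a
   deterministic function of the data.
3. **Nine SI engines, ten runs each.** Each engine performs
   `runs_per_engine` independent seeded runs on the training set; each run's
   best mask is scored by training the fitness classifier on the training
   set and measuring accuracy on the validation set, and the best-validated
   mask represents the engine. Ties prefer fewer features, then the earlier
   run.
4. **Majority vote.** A feature enters the consensus subset when at least 5
   of the 9 engines ("more than four") selected it. If no feature reaches
   the threshold it is decremented until the subset is non-empty — failing
   outright would make small datasets unusable, and the decrement preserves
   the "most-agreed-upon features first" semantics.
5. **dRFE refinement** of the consensus subset on the training set (below).
6. **Final model.** A k-nearest-neighbour classifier (the default
   `final_classifier`) is trained on the training set restricted to the
   final subset and reports Sn/Sp/Acc on the validation and the test set.

The master seed derives every stage seed by fixed offsets (split = seed,
engine *e* run *r* = seed + 1000·e + r − 1, dRFE folds = seed + 777), so the
whole pipeline is reproducible and any stage can be re-run in isolation.

## The wrapper fitness

Every engine minimizes the same objective for a candidate mask:

fitness = ω·E + (1 − ω)·Selected/Dimension,  ω = 0.9,

where `E` is the classification error of the fitness classifier (Gaussian
naive Bayes by default) trained on two thirds and evaluated on one third of
the training set — a stratified 2:1 split drawn *once per run* and reused for
every evaluation in that run. Re-drawing the split per evaluation would make
the objective a random variable and fitness values incomparable across agents
and iterations; fixing it per run keeps the search landscape static while the
ten runs still see ten different splits. `E` is the error on the held-out
third only. With ω = 0.9 a one-percentage-point error reduction is worth
about a 10-percentage-point increase in subset density, so error dominates
but full-density solutions are never optimal.

The naive Bayes fitness classifier is implemented in the package. Because NB
log-likelihoods are additive over features, the per-feature log-density
margins of the held-out samples can be precomputed once per run, reducing
each mask evaluation to a single matrix product. A small absolute variance
floor (1e-9) guards constant features. The implementation is cross-checked
against `e1071::naiveBayes` in the test suite.

## The nine engines

All engines share one representation: an agent is a point that binarizes to
a 0/1 feature mask, all-zero masks are repaired by setting one uniformly
chosen bit, and a central tracker records the best mask ever evaluated (so
the best-so-far history is non-increasing by construction — elitism). The
position-based engines (GWO, WOA, MFO, CS, FA, MRFO) move in `[0,1]^d`,
clipped after every update, with bit = 1 iff position > 0.5. The
velocity/step-based engines (PSO, BA, DF) act on binary masks directly and
binarize their velocity through the S-shaped transfer `P(bit = 1) =
logistic(v)`, with velocities clamped to ±6 (outside that range the sigmoid
is saturated anyway).

Population sizes and the four tuned parameters are the package defaults:
GWO/WOA/MRFO N = 10, FA/BA/DF N = 30, MFO N = 90, PSO/CS N = 80; BA loudness
= pulse rate = 0.2 (held constant, no geometric decay); PSO inertia decays
0.9 → 0.1; CS abandonment probability 0.3; DF inertia decays 0.9 → 0.5;
T = 150 iterations. Constants the search metaphors need but that are not
tuned anywhere (BA frequency range [0, 2] and local-walk flip rate 0.1, CS
Lévy exponent 1.5 with Mantegna sampling and step scale 0.01, FA β₀ = 1,
γ = 1, α₀ = 0.5 with decay 0.97, WOA/MFO spiral constant b = 1, PSO
c₁ = c₂ = 2, MRFO somersault factor 2, DF behaviour weights on the canonical
decaying schedule my_c = 0.1 → 0 over T/2) follow the original algorithm
publications.

Two engine-level choices were genuinely open and are package decisions: WOA
draws its branch coefficients A and C per agent rather than per dimension,
and MRFO evaluates fitness once per iteration after the composite
foraging-plus-somersault move rather than twice, which keeps every engine
within the N·(T+1) evaluation budget (CS evaluates up to 2N per iteration by
design — its two phases are separate proposals).

## dRFE

Classical RFE removes a fixed number of features per iteration; *dynamic*
RFE re-ranks the surviving subset by the absolute weights of a freshly
fitted linear SVM, then evaluates removal of the k = 1..7 least-important
features and greedily moves to the best-scoring candidate (ties prefer the
larger removal). Every visited subset is scored by stratified three-fold
cross-validated SVM accuracy on folds fixed once per refinement, so
candidate comparisons are paired. The recorded subset with the highest
accuracy is returned — since the starting subset is itself recorded, the
refinement can never lose accuracy under its own evaluator, and with
`max_step = 1` the procedure provably reduces to classical RFE (a regression
test asserts this against an independent implementation).

## Evaluation utilities

`metrics()` computes Sn = TP/(TP+FN), Sp = TN/(TN+FP) and
Acc = (TP+TN)/total. `s3fcv_accuracy()` implements stratified three-fold
cross-validation with seed 0 by default; accuracy is pooled over folds
(every sample predicted exactly once), which coincides with the mean of fold
accuracies when folds are equal. `max_accuracy()` reports the best pooled
accuracy over a five-classifier panel (LR, KNN, NBayes, DT, SVM) — useful
when the final classifier choice should not be baked into a comparison.
`ifs_curve()` traces accuracy against the number of top-ranked features, the
standard incremental-feature-selection diagnostic for filter rankings.
Classifier hyperparameters are library defaults throughout (KNN k = 5
capped at the training size, RBF SVM with default cost, unregularized
logistic regression with aliased coefficients zeroed, fully grown decision
tree), since the method does not prescribe any tuning.

## Synthetic data

`generate_synth()` emulates the regime the pipeline targets: standard-normal
noise with a planted set of informative features whose class means sit at
±effect/2 (so the between-class difference equals the effect size in
noise-SD units and the pooled mean stays at zero, avoiding scale
interactions with classifier defaults). Planted features can share a latent
factor in blocks of pairwise correlation ρ, giving the redundancy-removal
stage something real to remove. The generator's defaults are the package's
reference study conditions: 45+45 samples, 2000 features, 10 informative at
effect 2.0.

What the generator does *not* emulate: real microarray/methylation marginal
distributions (probe-intensity skew, beta-value boundedness), batch
structure, or correlated noise among uninformative features. Tests passing
on this generator demonstrate that the machinery finds planted Gaussian
mean-shift signal; they do not certify performance on any particular GEO
dataset.

## Problem sizes used in the checks

The package's own validation runs at desk scale, chosen so the full suite
completes comfortably on one CPU: elitism is asserted over full-length
T = 150 runs of all nine engines on a 60 × 100 dataset; single-feature
recovery over 100 seeded reduced-budget runs (N = 10, T = 30) per engine on
a 60 × 50 dataset; and the end-to-end pipeline over 100 seeds at the
reference conditions with a reduced budget (T = 20, 3 runs per engine).
`scripts/acceptance.R` re-runs the end-to-end configuration on 10 replicate
datasets and reports the measured accuracies and recovery rates.

## Known limitations

- Binary phenotypes only; no multi-class extension.
- The engines' transfer functions and untuned constants are canonical
  choices, not fitted to data; other binarizations (V-shaped transfers,
  time-varying thresholds) are not implemented.
- dRFE's variable-step rule (evaluate all k = 1..7, move greedily) is the
  natural reading of "dynamic" elimination with a step cap; other schedules
  (halving, adaptive) are out of scope.
- Wall-clock cost is dominated by fitness evaluations; at the full budget
  (T = 150, 10 runs, 9 engines) expect minutes-to-hours per dataset
  depending on the fitness classifier.
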