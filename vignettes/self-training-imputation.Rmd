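---
title: "Self-training imputation for pose-level binding affinity regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-training imputation for pose-level binding affinity regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affimpute)
```

## The problem

Structure-based affinity models are trained on docked poses: each
pocket–ligand complex contributes many candidate placements, most of
them wrong (high RMSD to the crystal pose), and the experimental binding
affinity — when one exists at all — is a single pK value shared by every
pose of the complex. In large cross-docking corpora well over half of
the complexes have no affinity label, while every pose still carries a
good/bad classification label (RMSD below or above 2 Å).

`affimpute` implements a self-training remedy: train dual-head models
(pose score + affinity) on the labeled part, use them to *impute* the
missing affinity labels, retrain on the augmented label set, and
iterate. The package provides the data model, a synthetic corpus
generator, the training objective and a reference learner, eight
imputation schemes, the iterative loop, and the evaluation and
significance machinery — all reproducible from explicit seeds.

## The objective

Two losses are combined per minibatch. Pose classification uses the
logistic loss on the predicted probability that a pose is good, with
probabilities clipped to `[1e-6, 1 - 1e-6]` so degenerate predictions
stay finite. Affinity regression uses a pseudo-Huber loss
$\delta^2(\sqrt{1 + (d/\delta)^2} - 1)$ on the residual $d$, which is
quadratic for small errors and linear for large ones, *hinged* on bad
poses: a high-RMSD pose should not score a high affinity, so the loss is
exactly zero whenever the model under-predicts on a bad pose and only
over-prediction is penalised. Good poses are penalised symmetrically.
The rule applies identically to experimental and imputed labels. Poses
without a label are masked out of the affinity mean entirely (not
averaged in as zeros); a batch with no labeled pose has a zero affinity
term.

The transition scale defaults to $\delta = 4$ pK, which keeps the loss
effectively quadratic over realistic pK errors (0–3); both the scale and
the two term weights (1, 1 by default) are explicit knobs, since
published work on this loss family rarely prints them.

Minibatches (50 poses) are exactly class-balanced — 25 good, 25 bad —
and pocket-stratified: each slot draws a pocket uniformly at random
among pockets containing the required class, then a pose of that class
within the pocket uniformly with replacement. The minority class
(usually good poses, a few percent of the corpus) is thereby upsampled,
and pockets with thousands of poses do not drown out small ones. We read
"stratified with respect to the receptor" at the pocket level: pockets
are the unit that groups interchangeable receptor structures, so
per-receptor stratification within a pocket would re-weight essentially
identical binding sites.

## The reference learner

The learner contract is deliberately small: anything that maps a pose
table plus a feature matrix to a pose score in [0, 1] and an affinity in
pK can drive the imputation machinery. The built-in reference learner is
a feed-forward network on precomputed per-pose features — two shared
hidden layers of 64 rectified units feeding a logistic pose head and a
linear affinity head, so the two tasks are coupled through shared
weights exactly as in voxel-grid CNN scoring models, where that coupling
is what makes affinity supervision spill over into pose scoring.
Training is plain SGD: learning rate 0.01, momentum 0.9, weight decay
0.001 on weights (not biases), fresh He initialisation per seed.

Early stopping monitors a fixed "reduced set" — 13.2% of the training
complexes drawn once at start — every `eval_interval` iterations. The
monitored quantity is the combined loss: it is the only quantity defined
in every label regime, including fully unlabeled batches. After
`patience_evals` evaluations without improvement the learning rate drops
by 10×; at the third drop training ends. The production-scale schedule
(evaluate every 1000 iterations, patience 200) is the constructor
default; `desk_train_config()` (evaluate every 100, patience 10, cap
20,000 iterations) runs a full 5-seed experiment in about a minute per
round on one CPU and is used throughout the package's tests and
examples.

## The synthetic corpus

`generate_corpus()` emulates the statistical structure the framework
assumes, not molecular physics. Defaults: 40 pockets × 5 ligands × 20
poses; the first pose of each complex plays the cognate pose (good with
probability 0.8), other poses are good with probability 0.05, matching
corpora where high-RMSD poses are ~95% of the data; good rmsd ~
U(0.2, 1.8) Å and bad ~ U(2.5, 10) Å, since only the 2 Å dichotomy
matters downstream; per-complex true pK ~ Normal(6, 1.5) truncated to
[2, 12], a plausible assay range (the affinity distribution of real
corpora's labeled subsets is not well characterised, so this is a
stand-in, not a calibrated fit). pK values are recorded at the file
dialect's three-decimal precision so written corpora round-trip exactly.

The feature vector of a pose with quality $q = e^{-\mathrm{rmsd}/2}$ is

$$x = w_s \, (pK \cdot q)\, u + w_q\, q \, v + \varepsilon,$$

with $u, v$ fixed unit directions per corpus and i.i.d. Gaussian noise.
The affinity signal is deliberately *attenuated by pose quality*:
high-RMSD poses carry almost no affinity information, which is the
property that makes good-only aggregation meaningfully different from
all-pose aggregation. The default noise (sd 0.1) is chosen so that
ordinary least squares on good-pose features recovers the true pK with
Pearson R ≈ 0.83 — comfortably above the 0.8 floor the learner tests
assume, leaving headroom between the linear oracle and the sanity floor
(R > 0.5) demanded of the reference learner.

Label hiding is a separate, seeded step. The default mechanism is
missing-at-random at the complex level (59% of complexes), mirroring
label coverage that depends on whether a ligand appears in an affinity
database, which is a property of the complex, not the pocket. A
`by_pocket` mechanism that masks whole pockets is available to probe
bias; under it the missingness is *not* ignorable.

What the generator does not emulate: 3D coordinates, docking physics,
chemical series structure, inter-pocket ligand promiscuity, or heavy-
tailed pose-count imbalance. Passing tests on this corpus demonstrate
that the machinery is correct and that the self-training loop behaves
sanely when its assumptions hold; they are not evidence about any
particular real corpus.

## Imputation schemes

Eight schemes cover the cross of {per-pose, per-complex} × {median, max,
min} × {all poses, good poses only}:

* `individual` — each seed model's raw per-pose predictions become that
  seed's own labels, so per-seed training sets differ;
* `individual_ensemble` — one shared per-pose label, the mean over
  seeds;
* `{median,max,min}[_good_only]_ensemble` — per seed, the statistic over
  the complex's (selected) poses; the per-seed values are then averaged
  into a single label used for every pose of the complex, matching how
  experimental labels behave.

Imputed labels are clamped to [2, 12] pK so that model extrapolations
cannot inject physically impossible labels. The median of an even count
is the midpoint of the central pair.

**Zero-good-pose complexes.** A good-only scheme confronts complexes
with no pose under 2 Å. Hinge-trained models systematically
under-predict high-RMSD poses — that bias is the documented motivation
for good-only aggregation in the first place — so aggregating all poses
there produces labels several pK too low. On the default corpus such
fallback labels carry a bias near −4 pK, and including them made one
round of imputation *worsen* held-out RMSE in every replicate we ran,
while leaving those complexes unimputed made the same round mildly
beneficial. The package therefore defaults to leaving them unimputed
(`fallback = "skip"`, recorded in the provenance table); the all-pose
fallback remains available as `fallback = "all_pose"` for sensitivity
analyses. This is the one place where we depart from treating every
unlabeled complex as imputable: an unimputed complex simply remains in
the baseline condition, which is strictly safer than anchoring training
to a label known to be biased.

**The loop.** `run_rounds()` trains the seed ensemble on the original
labels (round 0), then per round: predict every pose of every unlabeled
training complex with the previous round's models, impute, optionally
keep a nested random fraction of the imputed labels (the 20/40/60/80%
design — subsets are nested under a fixed seed, so each increment adds
to the previous one), rebuild the training table from the pristine one,
and retrain all seeds from fresh initialisation. Each round re-imputes
*all* missing labels with the newest models rather than accumulating
older labels, and experimental labels are never overwritten (attempting
to is an error, and a test asserts it every round). The loop stops when
mean test RMSE fails to improve — RMSE is the headline affinity metric,
and a single scalar makes the stopping rule unambiguous — keeping the
worsened round in the history for inspection.

## Evaluation and significance

Per complex, the candidate pose is the one with the highest predicted
pose score (ties broken by lexicographically smallest pose id, for
determinism). Affinity metrics — RMSE, Pearson R, and the coefficient of
determination — are computed over labeled test complexes only. Because
"coefficient of determination" is genuinely ambiguous in this
literature, both readings are reported: $1 - SS_{res}/SS_{tot}$ as
`r_squared` and the squared Pearson correlation as `pearson_r2`. AUC is
computed rank-based over *all* test poses (ties count one half), not
per-complex-averaged, matching the global pose-classification framing of
prior cross-docking evaluations; Top1 is the fraction of complexes whose
candidate is below 2 Å, with all complexes in the denominator (the
alternative — only complexes possessing at least one good pose — is not
what a prospective user experiences, since they cannot know which
complexes those are).

Three significance tools mirror standard practice in this literature: a
percentile
bootstrap CI of the mean; an unpaired pooled-variance two-sample t-test
between per-model metric populations (the compared populations — five
seeds, retrained from scratch per round — are not naturally paired; with
zero pooled variance and equal means the p-value is 1 by convention);
and a 10,000-replicate bootstrap of the RMSE of two per-complex residual
vectors, flagging significance by non-overlapping 95% intervals and
reporting a one-tailed bootstrap p for the directional comparison.

## Numerical choices and degenerate inputs

* Missing affinity is `NA` in memory and the sentinel `0.000` only in
  the file dialect; pK 0 is outside the meaningful range, and an
  explicit marker prevents a real zero from masquerading as missing.
* The rmsd column is authoritative for the good/bad flag (strict
  `rmsd < 2`); a conflicting pose label is a logged warning, not an
  error. A pose at exactly 2.0 Å is bad ("less than 2 Å" read
  strictly).
* Negative affinities are rejected: some public dialects encode the
  pose-quality hinge in the label's sign, but this dialect carries pose
  quality in the rmsd column, and one source of truth beats two.
* Probability clipping at 1e-6 bounds the logistic loss, simplifying
  both optimisation and testing.
* Single-class tables, empty cluster maps, unlabeled-only metric
  requests, coverage gaps between predictions and tables, and train/test
  pocket leakage are all hard errors, not silent degradations.

## Worked example

A complete desk-scale experiment (sizes chosen so this runs in about a
minute on one CPU):

```{r example, eval = FALSE}
co <- generate_corpus(synthetic_config(), seed = 101)
hid <- hide_labels(co$table, 0.59, "by_complex", seed = 102)
pockets <- unique(co$table$pocket_id)
fa <- assign_clustered_folds(as.list(setNames(pockets, pockets)),
                             n_folds = 3, seed = 103)
test_p <- names(fa$folds)[fa$folds == 1]
history <- run_rounds(
  hid[!(hid$pocket_id %in% test_p), ],
  co$table[co$table$pocket_id %in% test_p, ],
  co$features,
  imputation_plan("median_good_only_ensemble", n_seeds = 5, max_rounds = 1),
  desk_train_config(), seeds = 1:5
)
history
```

## Known limitations

* The reference learner sees precomputed features, not structures; no
  rotational/translational augmentation analog exists in feature space
  and none is applied.
* The synthetic corpus is missing-at-random by construction; real label
  coverage correlates with target popularity, which the `by_pocket`
  mechanism only crudely probes.
* Effect sizes measured on the synthetic corpus do not transfer to real
  corpora; only the directional behaviour of the machinery is being
  exercised at desk scale. With clean, low-dimensional features the
  baseline learner already sits near the information ceiling, so the
  measurable benefit of imputation here is small by design.
* The iterative loop's stopping rule consults the test fold, as in the
  protocol it reproduces; for unbiased final reporting a third,
  untouched fold would be required.
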