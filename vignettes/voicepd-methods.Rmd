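---
title: "Methods: discriminant reduction, architecture search and subject-aware validation in voicePD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminant reduction, architecture search and subject-aware validation in voicePD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voicePD)
```

## The problem

Most people with Parkinson's disease (PD) develop dysphonia — impaired
voice production — early, often before the impairment is audible to a
listener. Acoustic analysis of sustained phonations (a prolonged "a",
"o" or "u") quantifies it through jitter (cycle-to-cycle period
perturbation), shimmer (amplitude perturbation), harmonicity
(HNR/NHR), pitch statistics, pulse/period counts and voicing measures.
voicePD implements a complete screening pipeline over such features:

1. **Fisher linear discriminant analysis (LDA)** reduces the 26
   standard dysphonic measures to at most $C-1$ discriminant
   coordinates ($C$ = number of classes; one coordinate for
   patient-vs-healthy).
2. A small **feed-forward neural network** classifies the reduced
   representation, trained by cross-entropy minimisation.
3. A **genetic algorithm (GA)** searches the network's architecture
   (number of hidden layers $L$, neurons per layer $H_\ell$), with the
   leave-one-subject-out (LOSO) accuracy of the whole stack as its
   fitness.
4. A **cross-dataset selection rule** picks, among the architectures
   the repeated searches return, the one whose *worst* accuracy across
   the per-vowel datasets and an independent testing cohort is
   largest.

Because several recordings per person exist, any row-wise split leaks
subject identity between training and test partitions ("subject
overlap") and inflates accuracy. Every validation in this package is
therefore subject-aware: LOSO holds out *all* recordings of one
subject per fold, and multi-recording subjects are scored by majority
vote over their rows.

## The discriminant reducer

For classes $c$ with means $\mu_c$ and counts $n_c$, the within- and
between-class scatter matrices are

$$
S_W = \sum_c \sum_{i \in c} (x_i - \mu_c)(x_i - \mu_c)^T,
\qquad
S_B = \sum_c n_c (\mu_c - \mu)(\mu_c - \mu)^T,
$$

and the discriminant directions are the leading eigenvectors of
$S_W^{-1} S_B$, maximising the projected ratio
$w^T S_B w / w^T S_W w$ — the multivariate form of the Fisher ratio
$(\mu_1-\mu_2)^2/(\sigma_1^2+\sigma_2^2)$. $S_B$ has rank at most
$C-1$, so a binary problem yields one coordinate and a four-class
differential-diagnosis problem three.

Numerical choices:

* **Standardisation.** Features are z-scored with *training* means and
  sds before the scatter computation; the parameters are stored inside
  the projection so held-out data is transformed with training
  statistics only. The raw features span several orders of magnitude
  (jitter in percent, pitch in Hz, periods in seconds), so unscaled
  scatter would be dominated by the large-unit features.
* **Stability.** The eigenproblem is solved in the symmetric form
  $S_W^{-1/2} S_B S_W^{-1/2}$; $S_W$ receives the shrinkage
  $S_W + \varepsilon\,\mathrm{tr}(S_W)/p\, I$ with
  $\varepsilon = 10^{-6}$ by default, enough to keep a singular
  within-scatter (possible when a fold has fewer rows than features)
  well-posed without materially moving well-conditioned solutions.
  Eigenvalues below $10^{-10}$ of the largest are treated as zero and
  never retained.
* **Reproducibility.** Eigenvectors are sign-ambiguous; each direction
  is unit-norm with its first nonzero component positive.

### Why the classifier pipeline uses Ledoit–Wolf shrinkage

The per-vowel experiments fit the reducer on 39 training subjects and
26 features — a regime where the sample within-class covariance is a
noisy estimate and the exact Fisher solve overfits it: on synthetic
data whose Bayes accuracy is essentially 1, the exact solve's LOSO
accuracy plateaus around 0.87–0.93. This is the textbook
$n \approx p$ failure of plug-in LDA, and the field-standard remedy is
regularised discriminant analysis. The classifier stack
(`nn_lda_factory()`) therefore shrinks the within-class covariance
toward a scaled identity with the closed-form Ledoit–Wolf intensity —
an analytic, parameter-free estimate, not a tuned constant. The
`fit_projection()` primitive keeps the near-zero default so that it
remains the exact Fisher discriminant (and provably maximises the raw
projected scatter ratio); the pipeline opts into the estimator suited
to its sample sizes. Users can override either choice through the
`shrinkage` argument.

## The neural classifier

The network has rectified-linear hidden layers (sizes given by the
architecture genome), a single logistic output unit, and minimises the
mean cross-entropy

$$
C(\beta) = \frac{1}{n} \sum_{j=1}^{n}
  \mathrm{cost}\!\left(h_\beta(x^{(j)}),\, y^{(j)}\right)
$$

plus an L2 weight penalty of $10^{-4}$, which stabilises training on
the tiny per-fold datasets (39 rows in one dimension after reduction).
The loss names the objective; the activation is this package's choice
and is configurable in the source. Two optimisers are provided, both
full-batch with analytic backpropagated gradients:

* **Quasi-Newton** (default): limited-memory BFGS with inverse-Hessian
  updates via `stats::optim(method = "L-BFGS-B")`.
* **Adaptive-moment**: a hand-written full-batch Adam loop
  (step size 0.05, standard moment decays).

Stopping is at 500 iterations or a loss change below $10^{-6}$,
whichever comes first. Both optimisers track the best-seen iterate, so
the reported loss never exceeds the initial loss and never worsens
with a larger budget. Weight initialisation is fan-scaled uniform from
the supplied seed; training is bit-deterministic given (seed, genome,
optimiser, data). The decision threshold is fixed at 0.5 with exact
ties classified PD — in a screening context the sensitivity-favouring
convention is the defensible one.

## The genetic architecture search

The chromosome codes the hyperparameters directly: the integer string
$(L, H_1, \dots, H_{L_{\max}})$, padded to the maximum layer count so
one-point crossover is always well defined (inactive neuron genes
carry values but are ignored at decode time). Defaults follow the
experimental protocol the package implements — population 15, 10
generations, per-gene mutation probability 0.10, tournament selection
of size 3 — with this package's documented completions where the
protocol is silent: crossover probability 0.9 per selected pair,
elitism of 1 (which makes best-so-far monotonicity a testable
contract), search space $L \in \{1,2\}$, $H_\ell \in 1..64$, and
$K = 5$ independent repetitions.

Fitness is the LOSO accuracy of the full reduction-plus-network stack,
with the reduction refitted *inside every fold*. The evaluation seed
is frozen into the fitness closure, making fitness a pure function of
the genome; evaluations are cached by gene string, so the number of
model fits is at most population × generations and strictly fewer
when genomes recur. Each of the $K$ repetitions runs from a seed
derived deterministically from the master seed; the per-run best
architectures become the candidate set for cross-dataset selection.

**Selection rule.** Candidates are scored on each vowel dataset (LOSO)
and on the testing cohort (train on the full training database, score
per subject); the winner maximises the *minimum* accuracy, with ties
broken toward fewer total neurons, then fewer layers. Max–min is this
package's explicit formalisation of "performs well everywhere", and it
deliberately counteracts the winner's-curse inflation that selecting
on a single dataset's best LOSO accuracy would produce.

## Evaluation metrics

From subject-level confusion counts (PD positive):

$$
\mathrm{Acc} = \frac{TP+TN}{TP+TN+FP+FN},\quad
\mathrm{Sen} = \frac{TP}{TP+FN},\quad
\mathrm{Spec} = \frac{TN}{TN+FP},
$$

$$
\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.
$$

MCC is reported because it stays informative under class imbalance;
it is flagged *undefined* (never fabricated) when any marginal of its
denominator is zero — which necessarily happens on an all-patient
testing cohort, where only accuracy and sensitivity are meaningful.

## The synthetic cohort generator

The generator emulates the two-part design of multi-phonation clinical
voice studies: a **training database** of 20 PD + 20 healthy subjects
with 26 recordings each (the three sustained vowels plus
word/sentence/number items; $40 \times 26 = 1040$ rows) and a
**testing database** of 28 PD-only subjects with three phonations each
of vowels "a" and "o" ($28 \times 6 = 168$ rows).

Features are class-conditional Gaussians with per-feature means and
sds from `synthetic_class_stats()`. The original clinical tabulation
is not redistributable, so those defaults are *synthetic
representative values* chosen once from the typical ranges of Praat
sustained-phonation measures in dysphonia studies (elevated
jitter/shimmer/NHR, reduced HNR/autocorrelation/voiced fraction in
PD); at the default separation they put the multivariate class
separation near $\delta \approx 3$, i.e. a Bayes accuracy in the
mid-90s — the regime such studies report. Structure the generator adds
on top of the marginals:

* **Independent features** (diagonal covariance) by default, because
  only marginal moments are specified; a correlation-matrix hook
  exists for users who want dependence.
* **Subject random effects**: each subject receives a mean offset with
  sd $0.25$ feature-sds, making rows of one subject correlated — this
  is what makes LOSO genuinely harder than row-wise validation, and
  what the no-leakage tests exercise.
* **Gender offsets**: female subjects get $+0.5$ feature-sds on the 11
  gender-dependent features (jitter local, shimmer local, the four
  pulse/period and five pitch measures), so the gender-confounding
  experiment is reproducible in simulation. Per-gender counts are not
  published for the source cohorts; the default gender ratio of 0.5 is
  an arbitrary documented choice.
* **A separation knob**: `separation_scale` multiplies the PD−healthy
  mean gap about its midpoint. So that a scale of 0 produces *identical*
  class distributions (a true null), the per-class sds interpolate
  geometrically toward the pooled sd on $[0, 1]$; beyond 1 only the
  mean gap keeps growing. Scale 1 reproduces the stated per-class
  moments exactly.

What the generator does **not** emulate: realistic feature
correlations, non-Gaussian tails and floor effects (Gaussian draws can
produce negative values for positive-valued measures), disease-duration
gradients, and recording-session effects. Tests passing on synthetic
data therefore demonstrate the *pipeline's* correctness — no leakage,
correct dimensionality, recovery of known separations — not clinical
performance on real voices.

## Problem sizes and determinism

The package's experiments run at two documented scales:

* **Protocol defaults** (population 15, 10 generations, $K=5$,
  $H \le 64$): the published-protocol settings, suitable for a real
  analysis run.
* **Desk scale** (population 8, 4 generations, $K=2$,
  $L \in \{1,2\}$, $H \in 1..8$, network budget 150 iterations): the
  configuration used by the package's own end-to-end recovery tests
  and examples, chosen so a full three-vowel protocol completes in
  about a minute on one core while still exercising every stage —
  search, caching, selection, cross-database validation.

Every stochastic component — generation, weight initialisation, GA
operators, fold seeds — flows from explicit integer seeds;
repetitions derive their seeds deterministically, and fold seeds
derive from the held-out subject's identity so results are invariant
to row order. Reports and serialized artifacts embed the seed and a
configuration fingerprint.

## Degenerate inputs and edge policies

* Zero total variance in the one-dimensional Fisher ratio: 0 when the
  means coincide, `Inf` otherwise (perfect separation).
* A class with fewer than two rows aborts the scatter computation with
  the class named.
* Single-class training folds abort LOSO by default (they cannot occur
  in the balanced design); a permissive mode scores such folds as
  misclassified.
* Even-split majority votes classify PD (consistent with the 0.5
  threshold tie rule).
* Crossover/mutation children are clamped into the search-space
  bounds, so every evaluated genome is admissible.

## Known limitations

* The default class statistics are representative, not estimated from
  any clinical cohort; absolute accuracies on synthetic data say
  nothing about accuracy on real recordings.
* Feature extraction from audio is out of scope; the package consumes
  feature tables.
* The GA optimises only the architecture (as the protocol prescribes),
  not learning-rate/regularisation/activation choices.
* Row-wise k-fold splitting is included *only* as a labelled
  subject-overlap baseline (`rowwise_kfold_folds()`); it should never
  be used for reporting.
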