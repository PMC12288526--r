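---
title: "Models and methods: trial-history coding in a freely moving decision task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: trial-history coding in a freely moving decision task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialhist)
```

## The scientific problem

In a self-initiated perceptual decision task, a mouse pokes a center port,
watches a 1-s train of visual flashes, and reports whether the flash rate was
above or below 12 events/s by poking a right or left port. The trial sequence
is random and the rule never changes, so the only information worth using is
the current stimulus. Nevertheless, animals' choices are biased by the
previous trial's choice and outcome ("trial history"), and neurons in the
anterior cingulate cortex carry strong, temporally extended signals for these
history contexts -- signals that must be disentangled from the posture and
movement correlates that pervade cortical activity in freely moving animals.

`trialhist` implements that full analysis chain on synthetic sessions with
known ground truth: a behavioral trial-history GLM and psychometric fits,
population decoding of the four history contexts with cross-temporal
generalization, a kernel-based linear encoding model with maximal/unique
explained-variance partitioning against movement regressors, and
PCA/Procrustes comparison of encoding-weight geometry across sessions and
subjects. The numbered drivers under `analysis/` run these stages in order;
every computation lives in the package and is exercised by the test suite.

## Why synthetic sessions

No public recordings accompany the study design this package targets, so the
pipeline ships with a generator (`simulate_behavior()`,
`simulate_tracking()`, `simulate_neural()`) whose output has exactly the
structure the analyses consume, with every generative parameter known. This
is a feature, not a stopgap: with ground truth in hand, each stage can be
held to a falsifiable standard (weight recovery, exact dimensionality,
chance-level controls) rather than to qualitative resemblance.

What the generator emulates:

* the task's trial structure -- stimulus rates drawn uniformly from
  {4, 6, 8, 10, 14, 16, 18, 20} Hz (the 12 Hz boundary is never shown),
  15-ms stimulus events at least 25 ms apart within a 1-s train (sampled
  uniformly over the feasible configurations via order statistics), early
  withdrawals, and event timestamps for initiation, stimulus onset, go cue,
  center-port exit, choice report and outcome end;
* a logistic choice policy `P(right) = sigmoid(b0 + b_stim * x + b_hist[c])`
  with scaled stimulus `x = (rate - 12)/8` and a weight per history context
  `c` -- the same model family the behavioral GLM fits, used generatively;
* neurons as linear functions of the encoding model's own design matrix
  (task kernels, occupancy bins, analog movement components) plus Gaussian
  noise and an optional exponential calcium kernel;
* chest trajectories in the 20 x 20 cm arena as smoothed random walks with
  port-directed excursions (reflected at the walls), bounded head-orientation
  processes, and latent movement factors mixed into 200 + 200 surrogate
  video / motion-energy components with configurable task coupling.

What it does not emulate: nonlinearities of calcium indicators and spike
inference, non-Gaussian noise, slow drift and representational instability,
photobleaching, neuron dropout, or genuinely high-dimensional video
statistics. Passing tests therefore certify the *estimators* -- not that
real recordings would meet any particular effect size.

Where the task literature gives a distribution family without parameters, we
chose once and kept: the center-fixation wait is 1 s plus an exponential
delay with mean 0.2 s; inter-trial intervals are uniform on 2-4 s; the
reward-port exit (which ends correct outcomes) occurs 2.0-2.6 s after the
choice report, while errors end after a fixed 2-s timeout. The generator
emits an explicit center-port-exit and outcome-end time per trial because
the alignment windows are anchored on them.

## Trial phases and alignment

Four windows tile a trial (half-open `[pre, post)`, snapped to the 30-Hz
frame grid by nearest-frame rounding of the anchor time): early ITI (0 to
+1 s around the previous trial's choice report), late ITI (-1 to +0.3 s
around the previous outcome's end), stimulus (-0.5 to +1 s around stimulus
onset) and action (-0.2 to +0.3 s around the center-port exit) -- 30, 39, 45
and 15 timepoints, 129 in total. Only completed trials directly preceded by
a completed trial carry a defined history context and enter the aligned
tensors; trials whose windows run past the recording are dropped with a
warning. How anchor times falling between frames should be assigned is
genuinely open; nearest-frame rounding is our choice and is applied
uniformly.

The generator's timing constraints guarantee the four windows never overlap
on the frame grid, so each design-matrix row owns its frame -- which is what
makes the noiseless-refit oracle (`R^2 = 1`) exact.

## Behavioral models

**Psychometric function.** `P(right | x) = gamma + (1 - gamma - lambda) *
Phi(beta * (x - alpha))`, with bias `alpha` (Hz), sensitivity `beta` (1/Hz)
and lower/upper lapse rates; the Gaussian integral is evaluated in closed
form as the standard normal CDF. Fitting is Bernoulli maximum likelihood
under box constraints (L-BFGS-B) from a small multistart grid; fits with a
lapse pinned at its bound are flagged as degenerate rather than hidden.

**Trial-history GLM.** Log odds of a rightward choice =
`b0 + b1 * x + b2 . h`, where `h` one-hot encodes the four contexts in the
fixed order (previous correct left, incorrect left, incorrect right,
correct right). Left/right trials are balanced by subsampling the majority
class (20 rounds, without replacement within a round); each round gets
10-fold cross-validated fits at a fixed L2 penalty of 1 -- fixed, not
optimized, so weights stay comparable across sessions. Reported weights are
unweighted means over all rounds x folds; *history strength* is the
Euclidean norm of the four mean history weights. The penalized logistic
solver is glmnet (ridge path; our penalty `c` corresponds to
`lambda = c/n`), with the intercept unpenalized -- standard practice where
the procedure's description is silent. A two-back variant swaps the context
dummies for choice, outcome and their interaction at trials t-1 and t-2
(right = 1, correct = 1); the t-1 terms linearly span the context dummies,
which the tests exploit as a reparameterization oracle.

## Population decoding

One-vs-all linear logistic decoders are trained at every timepoint on
Gaussian-smoothed (1-frame SD kernel, truncated at 4 SD and renormalized)
activity. The procedure mirrors the behavioral machinery: balanced
subsampling (20 rounds), 8 stratified 80/20 train/test splits per round,
per-neuron standardization with training-set statistics only, and an L2
penalty chosen from powers of 10 between 1e-10 and 1e12 by test-split
accuracy. Three conventions we fixed where the procedure is underdetermined:
the 8 splits are independent stratified draws (80/20 cannot form 8 disjoint
folds); penalty ties break toward the stronger penalty; one-vs-all argmax
ties break by fixed class order. Zero-variance neurons in a training fold
keep scale 1 instead of dividing by zero. Because the penalty is selected on
the same held-out split that is scored, very small test sets inflate the
shuffled control slightly above 1/k -- visible in the demo driver, and the
reason the chance-level check uses a binomial confidence band rather than a
point value.

Reported quantities: overall accuracy (unweighted mean over timepoints),
per-context accuracy over time, row-normalized confusion matrices, marginal
binary accuracies (collapsing predictions onto previous choice or outcome),
and the cross-temporal generalization matrix -- every timepoint's models
applied to every other timepoint of the same held-out trials, averaging
*prediction accuracies*, never coefficients. Binary previous-choice /
previous-outcome decoders balance the full 2 x 2 choice-by-outcome table so
the nuisance variable stays balanced within each class.

## Encoding model and variance partitioning

The design matrix concatenates the four phase windows per trial. Groups:
a trial-time indicator per timepoint (the time-varying intercept);
full-trial-span kernels gated by choice, outcome, and each history context;
stimulus-event kernels shifted 0 to 0.5 s; port-poke kernels from -0.5 to
+1 s for each of the three ports; one-hot occupancy over 60 six-degree bins
per head angle (yaw, pitch, roll) and over a 1.28-cm square grid anchored at
the arena origin (row-major, half-open bins; 16 x 16 over 20 x 20 cm);
and the analog video / motion-energy components, orthogonalized against the
stimulus columns by QR so they cannot smuggle in stimulus-locked signal.

Each neuron is fitted by ridge regression, solved in closed form through an
eigendecomposition of the smaller Gram matrix (primal or dual), with 10
folds that sample every trial timepoint equally and a per-neuron,
per-fold penalty search over 1e-3..1e5 (ties toward the stronger penalty).
Analog regressors and activity are standardized with training-fold
statistics. Held-out `R^2` is never clamped: the variance partition needs
signed values.

Maximal EV of a variable = `R^2` of the model with all *other* variables
shuffled, minus the trial-time-only `R^2` (temporal structure shared across
trials is not credited to the variable). Unique EV = full-model `R^2` minus
the `R^2` with *only* that variable shuffled. "Shuffled" means whole-trial
blocks of the variable's rows are permuted across trials, preserving the
within-trial kernel structure and its temporal autocorrelation; a plain
row-wise shuffle would destroy both and overstate unique variance. The
shuffle unit is configurable, and each shuffled model re-runs the penalty
search rather than inheriting the full model's penalty. Trial history is
treated as one variable spanning its four kernel groups; the three port-poke
groups and three head-angle groups are likewise pooled for reporting.
Time-resolved `R^2` re-orders the held-out predictions onto the trial-time
grid and scores each timepoint across trials, masking timepoints with fewer
than 3 trials or zero variance; these values are bounded above by the
globally regularized fit and are read as profiles, not absolute levels.

## Weight geometry

For a given variable, PCA across neurons of the weight matrix yields
explained-variance ratios; dimensionality `d90` is the smallest number of
components reaching 90% cumulative variance (a `1e-12` slack absorbs
floating-point round-off so that exactly-rank-k data give `d90 = k`).
Before comparing sessions, every session's shape is expressed in the
maximal `d90` across sessions for that variable. Shapes are matrices of
timepoint (or spatial-bin) coordinates in the matched principal dimensions;
we orient them points x dimensions so the Procrustes rotation acts on the
dimension axes and absorbs axis-order and sign indeterminacies of PCA --
principal axes are matched by index first, and the rotation cleans up the
rest. Both shapes are standardized (column-centered, unit Frobenius norm)
before matching, so the residual disparity after optimal translation,
orthogonal rotation (reflections allowed by default, excludable by flag)
and scaling lies in [0, 1]: 0 for identical shapes, 1 for maximal
dissimilarity. The implementation is checked in the tests against vegan's
symmetric Procrustes as an independent reference.

## Numerical choices and degenerate inputs

* Ridge solutions use the exact closed form; the solver is validated against
  the normal equations to 1e-8 and against OLS in the small-penalty limit.
* glmnet's ridge-logistic path occasionally stops early at the
  near-unpenalized tail of the decoding grid on separable data; the last
  converged solution stands in for the remaining grid points, which is the
  correct limit there.
* Balanced subsampling, splits, shuffles and fold assignments all derive
  their seeds from one master seed (`derive_seed()` hashes stage names into
  31-bit seeds), so every pipeline run is bit-reproducible.
* Degenerate inputs fail loudly and specifically: empty trial tables,
  missing CSV columns, infeasible stimulus trains, classes smaller than 8
  after balancing (with per-class counts), zero-variance weight matrices,
  zero-norm Procrustes shapes, constant correlation inputs. Constant
  regressors in the two-back model are dropped with a warning.

## Problem sizes

The shipped study uses sizes chosen to exercise every code path while
remaining comfortable on a laptop: 3 subjects x 3 sessions, 250 trials and
30 neurons per session, 30 surrogate video components, and a compact
two-phase trial grid for the demo encoding fits (the canonical four-window,
129-timepoint grid and 200-component design remain the defaults of
`design_config()` and are used in the alignment, refit and decoding tests).
The statistical checks use the sizes their questions demand: 20,000 trials
for GLM weight recovery, 5,000 for psychometric recovery (20 seeds), and a
520-trial session for the chance-level decoding control.

## Known limitations

* Timepoint-stratified CV folds mix timepoints of the same trial across
  folds, so temporally autocorrelated noise can leak across the split; this
  mirrors the fitting convention of the encoding-model literature the
  pipeline follows, and the generator's noise is white, but real-data
  `R^2` values read optimistic under slow noise.
* Per-split penalty selection on the scored split biases small-sample
  accuracies upward (see above); with the study's session sizes the bias is
  well inside the chance confidence band.
* The linear encoding model cannot represent the nonlinear mixed selectivity
  the generator can produce only additively; interactions beyond the four
  context kernels are out of scope.
* Procrustes comparison assumes matched neurons ordering is irrelevant
  (it compares dynamics, not neuron identities), and generalized (k > 2
  shapes) alignment is not implemented.
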