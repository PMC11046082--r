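---
title: "Methods: simulating and analyzing conflict-modulated response stopping"
author: "conflictstop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing conflict-modulated response stopping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, defaults, and numerical choices
behind the package's simulation-and-analysis chain for a combined Simon
and Stop-Signal experiment. The chain runs: behavioral race-model
simulation → behavioral summaries, SSRT and exclusions → group ICA per
condition → cross-condition component matching → per-pair decoding →
cluster-permutation inference → leave-one-out brain–behavior regression.

## The behavioral model

A session is a race between a *go* process (triggered by the letter
stimulus) and, on Stop trials, a *stop* process (triggered by the stop
signal after the stop-signal delay, SSD). The two finishing times are
independent — the context-independence assumption under which the mean
method of SSRT estimation is valid — and each is ex-Gaussian
(Gaussian plus exponential, the standard positively skewed RT family),
with separate parameters per congruency condition. A response is
emitted on a Stop trial iff the go process finishes inside the response
window and before `SSD + stop finishing time`.

Defaults (`race_params()`), in ms:

| quantity | congruent | incongruent | rationale |
|---|---|---|---|
| go mean (`mu + tau`) | 493.7 | 521.6 | matches the ~28 ms Simon cost on go RT |
| go `sigma` / `tau` | 45 / 100 | 45 / 110 | moderate skew typical of RT fits |
| stop mean (true SSRT) | 269.9 | 279.0 | ~9 ms congruency cost on stopping |
| stop `sigma` / `tau` | 25 / 30 | 25 / 30 | narrower than the go process |
| miss rate | 0.005 | — | omissions are rare |
| choice error rate | 0.045 | — | go accuracy ≈ 95% |

The `sigma`/`tau` split is not identified by condition means alone; a
moderate `tau` was chosen because the mean method is known to
overestimate SSRT when the go distribution is strongly right-skewed
(the staircase converges on the *median* of `go − stop`, while the
estimator subtracts the mean SSD from the *mean* go RT). With these
defaults the estimator's bias is about +11 to +13 ms at session scale,
inside the ±20 ms recovery band the tests enforce. Scale parameters may
be zero, which makes a finishing time deterministic; this supports
degenerate race constructions in tests (e.g. a stop process that always
wins).

The staircase (`next_ssd()`) moves the SSD per condition by ±50 ms in
[50, 1000] ms from a 250 ms start, up after a correct rejection and
down after a failed stop, tracking a stopping probability of 0.5.
Tracking is kept separately for congruent and incongruent Stop trials.
The speed warning (mean RT of the previous 50 responded trials above
450 ms) is logged as an event but does not feed back into simulated
RTs, since no behavioral model of the warning is available.

SSRT is estimated by the mean method: mean correct-go RT minus mean SSD
(`estimate_ssrt()`); only correct go RTs enter the go mean.

Exclusion rules (`apply_exclusions()`): stopping probability outside
[0.25, 0.75] in either condition; SSRT difference (incongruent minus
congruent — the sign convention used throughout, including the
brain–behavior target) above +50 ms; and Tukey-fence outliers
(1.5 × IQR, type-6 quantiles, the SPSS convention) in more than one of
the eight measurements {go RT, go accuracy, SSRT, p(respond|stop)} ×
condition. The Tukey rule is cohort-relative, so it is exempt from the
idempotence property the other two rules satisfy, and is skipped with a
warning below four subjects. Paired congruency contrasts use the
Wilcoxon signed-rank test, exact for n ≤ 25 without ties, otherwise the
continuity-corrected normal approximation; an all-zero difference
vector is degenerate and returns p = 1 with a warning rather than an
error, so that pipeline summaries of idealized data do not abort.

## The synthetic EEG generator

Only Stop trials are epoched. The time axis is fixed: 307 samples at
256 Hz on the half-open grid `t_i = -200 + i * 1000/256` ms (last
sample ≈ +995 ms); 1200 ms at 256 Hz is non-integral, so a convention
had to be fixed and this one is used everywhere. Epoch zero defaults to
letter onset (the generator accepts `epoch_event = "stop_signal"` as a
labeling alternative), because the SSD varies across trials and the
condition-effect windows are defined relative to stimulus onset.

Each of the (default four) ground-truth sources is a unit-norm spatial
topography over 60 channels, a baseline ERP waveform, and a condition
effect confined to a window. A trial's source activation is

```
activation(t) = gain_trial * baseline(t) + 1[t in window] * amp_trial
```

with `gain_trial ~ 1 + N(0, trial_gain_sd)` and `amp_trial ~
N(±effect_size/2, 1)`; the epoch is the sum of topography ⊗ activation
over sources plus i.i.d. Gaussian sensor noise. Three deliberate
choices:

* **Empirical centering.** Both `gain` and `amp` draws are centered
  (and `amp` scaled) exactly within subject × condition. Under a null
  effect the condition means are then *exactly* equal, which gives the
  tests a sharp null construction; the cost — a factor `sqrt(1 - 1/n)`
  on the realized SD — is negligible at the trial counts used.
* **Orthogonalized baselines.** The default baseline waveforms are
  Gram–Schmidt-orthogonalized over the epoch (preserving each
  waveform's RMS). Overlapping deterministic waveforms make the latent
  activations mutually correlated, which violates the independence
  premise of ICA; without this the decomposition cannot attribute the
  shared time-locked structure to the correct topographies no matter
  how little noise there is.
* **Trial-level variability dominates.** `trial_gain_sd = 1` by
  default: single-trial amplitude variability of the same order as the
  mean ERP, consistent with the fact that ERPs emerge from averaging.
  This matters for identifiability: the deterministic time-locked part
  of the activation carries no information about the correct rotation
  of the source subspace, so the independent trial-level part must be a
  substantial variance share.

Subject topographies are seeded jitters of the group topography
(`subject_jitter = 0.01`, re-normalized). The jitter is kept small
because subject-specific topography deviations are *condition-stable*
structure: with larger jitter the group decomposition splits sources
into subject-flavored components that replicate across conditions and
inflate the number of matched pairs.

Default effect size is 0.5 (peak ideal AUC ≈ 0.64, in the range of
realistic single-trial EEG decoding); default window placements emulate
early-attentional (85–245 ms), sustained (300–700 ms) and mid-latency
(100–450, 250–400 ms) effects. The signal-to-noise ratio is defined
component-wise — SD of a source's activation over trials × samples,
divided by the sensor noise SD — and is about 3–4 at the defaults.

What the generator does **not** emulate: volume conduction through a
head model, ocular/muscle artifacts, autocorrelated or spatially
colored sensor noise, go-trial EEG, and latency jitter of the ERP
components. Passing tests therefore demonstrate that the analysis chain
recovers what it is designed to recover under a clean, well-posed
generative model — not that it would survive the artifact structure of
raw recordings, which the emulated study removed with a dedicated
preprocessing pipeline before any of the analyses modeled here.

## Group ICA

The aggregate matrix concatenates all subjects' Stop-trial epochs per
condition, columns ordered (subject, trial, sample), channel means
removed. PCA retains the smallest dimension whose cumulative eigenvalue
fraction reaches 98%, capped at 20; with near-isotropic sensor noise
the cap binds, matching the emulated study's realized dimension of 20.
Fixed-point ICA on the whitened scores uses the tanh contrast with
symmetric decorrelation, seeded initialization, tolerance `1e-4` on the
maximal one-step rotation of any component, and a 200-iteration cap.
The cap is deliberate: retained dimensions spanned by near-Gaussian
noise have no stable fixed point, so the rotation inside the noise
subspace can wander indefinitely while the signal components lock
within a few dozen iterations. Like the reference fixed-point
implementations the fit returns the final iterate with a warning naming
the seed when the tolerance is not met (`on_nonconvergence = "error"`
restores a hard failure).

The channel-space demixing matrix composes the ICA rotation with the
whitening, so component activations are `C = W X` on raw (centered)
channel data, and the topography matrix `A` is the pseudo-inverse of
`W` (`W A = I` on the retained subspace). Sign and scale indeterminacy
are fixed by unit-norm topographies with a positive maximum-magnitude
entry; activations absorb scale, and the back-projection `A C` is
invariant. Back-reconstruction of per-subject activations is the direct
projection `C_s = W X_s`, which is exact under the shared-demixing
model (the partitioned alternative used by some group-ICA toolboxes
reduces to it when a single group demixing matrix is estimated).

## Component matching

Matching operates on topographies (the "inverse weights") with Pearson
correlation across the 60 channels, using absolute values because ICA
sign is arbitrary. Clusters grow greedily from template components
(membership at |r| ≥ 0.85, at most 3 members per condition, consumed
components unavailable to later clusters); each cluster emits the best
cross-condition pair. Because the outcome can depend on the template
order, the pass is repeated for 40 seeded orderings and the most
recurrent pairing is retained, with ties broken by total |r| and then
lower component indices. An empty result is a warning, not an error: no
matching components is a legitimate outcome on null data.

## Decoding

Per subject and matched pair, the two condition tensors are the
back-projected component data (rank-1 across channels at every sample
by construction). One linear maximum-margin classifier (hinge loss,
cost 1, no hyperparameter search) is trained per time sample on the 60
channel amplitudes; the majority class is under-sampled to the minority
count (seeded) and folds are stratified 5-fold. Features are
standardized with training-fold statistics computed per (channel, time)
— test statistics never leak — and the same per-time standardization is
used when a classifier trained at `t_train` is evaluated at `t_test` in
the temporal-generalization matrix, whose diagonal therefore equals the
time-resolved analysis under the same seed. Performance is the
decision-value AUC with the incongruent class positive, computed within
each test fold and averaged.

The inner solver is dual coordinate descent for the L1-loss linear SVM
(the LIBLINEAR algorithm) with the bias as an augmented constant
feature, epoch-wise shuffled coordinate order driven by a fixed
internal generator (so results depend only on the data), termination
when the projected-gradient range falls below 0.1, and a 500-epoch cap.
Shuffling matters: cyclic order converges poorly on strongly correlated
features, and rank-1 channel data are the extreme case. The test suite
cross-checks decision values against an independent SVM implementation.

Two structural notes. First, on rank-1 data the 60-channel classifier
is informationally equivalent to a 1-D classifier on the activation;
the 60-feature formulation is kept as specified and the equivalence is
exercised as a property (channel-profile norms equal |activation|).
Second, because the congruent and incongruent tensors pass through
*different* condition-specific decompositions, any systematic
difference between the two estimated projections — including noise in
the unmixing estimates applied to the large deterministic ERP — is
visible to the classifier. Decoding on matched pairs can therefore sit
above chance across the whole epoch even when the injected window
effect is small. This is a property of the analysis design being
modeled, not of the implementation; the calibration checks that must be
leak-free (chance level under a null effect, the closed-form AUC under
a d = 1 effect) are run on raw epochs and on single-decomposition
rank-1 constructions respectively.

## Inference

Group-level testing against chance uses the Wilcoxon signed-rank
statistic of (AUC − 0.5) per sample across subjects, standardized as
`z = S / sqrt(Var S)` with `Var S = Σ r_i²` (tie-robust), and two-sided
p values — exact via the signed-rank distribution when the sample has
no zeros or tied magnitudes and n ≤ 50, otherwise the
continuity-corrected normal approximation. Clusters form where the
sample-level p falls below 0.05 (two-sided; positive and negative
excursions separately), with adjacency connectivity in 1-D and
4-connectivity on the generalization matrix; cluster mass is the sum of
z inside the cluster, matching a "sum of Wilcoxon values" statistic.
The null distribution is the maximal absolute cluster mass under random
per-subject sign flips of (AUC − 0.5) — the exact exchangeable scheme
for a one-sample test against chance, chosen over trial-label
permutation (which would re-run the entire decoding inside every
permutation) for tractability; this is the one place where the modeled
study's under-specified "permutation process" had to be resolved, and
subject-level sign flipping is the standard resolution for one-sample
decoding inference. Cluster p values carry the `(1 + count)/(1 +
n_perm)` correction, so the attainable floor is `1/(n_perm + 1)`.
Permutations reuse the per-sample signed ranks (flipping a subject's
sign flips its rank's sign), which reduces each permutation to one
matrix product plus connected-component labeling.

## Brain–behavior regression

The literal reading of the modeled analysis is implemented: one scalar
per subject — the mean diagonal AUC over the pair's significant cluster
extent — predicts the per-subject SSRT congruency effect (incongruent
minus congruent, ms) through a feed-forward network with one hidden
layer of 5 units, linear output and mild weight decay (0.01 on
standardized data), trained full-batch with 5 seeded restarts per fit
(best penalized training loss kept), inputs and targets standardized by
training-set statistics. The decay is what keeps a scalar-input network
at the mean-predictor level when its input carries no information,
instead of contorting between training points. The implementation uses
`nnet`, whose logistic hidden units span the same function class as
tanh units up to an affine reparameterization; a scalar-input problem
needs no more capacity, and restarts tame the non-convexity. Held-out
predictions are de-standardized; accuracy is the RMSE over the LOO
predictions with a subject-level bootstrap 95% interval (1000
resamples). Pairs are compared by paired two-sided t-tests on the
per-subject squared errors; identical error vectors are reported as
degenerate with p = 1.

LOO integrity is enforced structurally (restart seeds depend only on
the master seed and the fold index, never on data) and verified by a
poisoning test: perturbing a held-out subject's target must not change
that subject's prediction.

## Pipeline and problem sizes

`run_pipeline()` executes the seven stages with stage seeds derived
from one master seed by a fixed affine counter scheme, caches each
stage under the run directory, and records a manifest (config
fingerprint, seeds, per-stage checksums). Re-running a downstream stage
verifies upstream checksums and refuses tampered caches. The numbered
drivers under `analysis/` present the chain as a narrative: the
committed configuration uses 16 subjects and 3 blocks (36 Stop trials
per condition) with 500 permutations — small enough to run in minutes,
large enough that every stage behaves qualitatively as at study scale.
The test suite makes analogous choices: 200 sessions for staircase
calibration, 100 for SSRT recovery, 20 subjects for decomposition
recovery, 20 null decoding runs, 200 replicates at 500 permutations for
family-wise error, and 100 replicates for the exchangeable-pair
comparison — sizes at which the Monte-Carlo error of each check is
comfortably below the tolerance it asserts.

## Known limitations

* The full repeated-measures ANOVA machinery (position factor,
  interactions, sphericity corrections) is intentionally out of scope;
  contrasts are paired tests only.
* The generator's clean-data premise means preprocessing robustness is
  untested by design.
* The mean method inherits its skew bias (documented above); no
  integration-method or Bayesian SSRT estimator is provided.
* Cross-decomposition leakage (see *Decoding*) means end-to-end AUC
  levels on matched pairs should not be read as pure window-effect
  sizes.
* With small cohorts the sign-flip cluster null is coarse (the p floor
  for an all-positive pattern is `2/2^n` per permutation draw), so
  end-to-end significance needs roughly 10+ subjects.
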