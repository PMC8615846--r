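---
title: "Modeling avoidance PIT behavior and effective connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling avoidance PIT behavior and effective connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitconnect)
```

## The problem this package addresses

Pavlovian-to-instrumental transfer (PIT) describes how a classically
conditioned cue changes instrumental responding: a *specific* transfer
effect biases the response that shares the cue's outcome, a *general*
effect elevates all responding. In an avoidance variant, participants
first learn two button presses that prevent two aversive outcomes
(instrumental phase), then learn five cue-outcome pairings (Pavlovian
phase), and finally respond freely while the cues are presented under
extinction (transfer phase). Alongside the behavioral question sits a
network question: how do the corticostriatal regions engaged by the task
— bilateral putamen, bilateral insula, right cingulate — influence one
another, and does the task input drive or modulate those influences?

`pitconnect` implements the full analysis chain as testable code: a
simulator for the three-phase task and its BOLD consequences, the
behavioral statistics, sphere-mask ROI extraction, person-specific HRF
estimation, and a group-then-individual effective-connectivity search.
Because every stage can be driven by simulated data with known ground
truth, each claim the pipeline makes is checkable against that truth.

## The generative and analysis model

Both the simulator and the estimator use an extended unified structural
equation model (euSEM) over $p = 5$ ROI series $y_t$ and $q = 2$
convolved task inputs $u_t$ (specific = CS1 and CS2 onsets, general = CS3
onsets):

$$ y_t = A\,y_t + \Phi\,y_{t-1} + \Gamma\,u_t + (\mathrm{T}\,u_t)\,y_t + \zeta_t,
\qquad \zeta_t \sim N(0, \mathrm{diag}(\sigma^2)) $$

* $A$ — contemporaneous (same-TR) directed influences, zero diagonal;
* $\Phi$ — lag-1 influences; its diagonal is the autoregressive (AR)
  baseline present in every model;
* $\Gamma$ — direct effects of the HRF-convolved inputs on ROI activity;
* $\mathrm{T}$ — bilinear terms: input-dependent modulation of ROI-to-ROI
  influences;
* $\zeta_t$ — white dynamic noise, independent across ROIs.

Estimation treats lagged series and convolved inputs as exogenous
regressors. When the contemporaneous dependency graph is acyclic the
maximum-likelihood fit is the equation-wise least-squares solution (the
Jacobian of the simultaneous system is 1 and the noise is diagonal); a
user-specified cyclic structure is fit by full-information ML with the
log-Jacobian term, after an order-condition identification check.
Bilinear regressors are built as the product of the convolved input with
the mean-centered source series; centering reduces their collinearity
with the direct effect.

### Fit indices

RMSEA, SRMR, CFI and NNFI are computed from the joint covariance of the
ROI block and its exogenous predictors, with the exogenous covariances
saturated; the baseline for the incremental indices is the independence
model with free variances — deliberately *not* the AR-only null model
that seeds the search, which is a different object. The "excellent fit"
verdict follows the two-of-four rule (CFI > 0.95, NNFI > 0.95,
RMSEA < 0.05, SRMR < 0.05). Columns with zero variance (an input with no
onsets) are dropped from the moment structure.

## Person-specific HRFs

The hemodynamic response is estimated per subject and per input by
smoothed finite impulse response (sFIR): a 16-TR (32 s) impulse response
minimizing $\|y - Xh\|^2 + \lambda\|Dh\|^2$ with $D$ the second-difference
operator, an unpenalized intercept, and $\lambda$ chosen by generalized
cross-validation over a log-spaced grid (a fixed $\lambda$ can be
supplied). At $\lambda = 0$ this is ordinary FIR least squares; as
$\lambda \to \infty$ the estimate flattens toward a line. The default
mode estimates one HRF per input per *target* ROI, so each candidate
direct effect uses the HRF of the region it points at; a `"mean"` mode
(average ROI signal) is available. HRFs are estimated once per subject,
before any model search, and held fixed. Peak times are read off with a
sub-TR quadratic interpolation around the maximum coefficient, which
removes the half-TR discretization bias of a raw argmax.

## The model search

The search mirrors the group iterative multiple model estimation (GIMME)
logic:

1. **Null model.** Five AR paths, nothing else. It must converge for
   every subject.
2. **Group forward selection.** For each absent candidate path, a
   one-degree-of-freedom score test (modification index) is computed per
   subject. The candidate significant for the most subjects is added as a
   group path, provided that count reaches $\lceil 0.75\,n \rceil$; ties
   break by summed MI, then lexicographic edge id, making the search
   fully deterministic.
3. **Group pruning.** Group paths whose estimate is significant for fewer
   than $\lceil 0.75\,n \rceil$ subjects are removed, iterating
   prune-and-refit to a fixed point (bounded at 50 iterations).
4. **Individual search.** Each subject starts from the group model and
   adds the largest significant MI candidate; individual (never group)
   paths that lose significance are pruned, with an oscillation guard.

Two design choices deserve emphasis:

* **Recursive candidate universe.** Candidate contemporaneous and
  bilinear paths that would create a cycle — including the reverse of a
  path already in the model — are excluded
  (`candidate_edges(acyclic_only = TRUE)`). The equation-wise score test
  is only calibrated when the candidate's source does not itself depend
  on the target; for cycle-creating candidates the source series contains
  the target equation's own shock, and the test would flag the reverse of
  every true path. Restricting the universe keeps the score tests exact,
  resolves path direction by MI magnitude, and matches how these searches
  behave in practice. Cyclic structures can still be *estimated* when
  specified explicitly.
* **Individual-level stopping rule.** By default no individual path is
  added once the subject's model already meets the two-of-four
  excellent-fit rule (`stop_individual = "excellent_fit"`). Forward
  selection on raw per-candidate significance alone would add roughly
  $\alpha \times$ (number of candidates) spurious paths per subject and
  ruin precision; stopping at excellent fit is what lets a subject whose
  data follow the group model exactly end up with zero private paths. The
  literal alternative (`"mi_only"`) is available.

$\alpha = 0.05$ throughout, with an optional Bonferroni division of
$\alpha$ by the candidate count for the MI tests (off by default; it is
the configuration used in the null-calibration check, where the group
search must add no spurious path in the vast majority of pure-noise
cohorts). The 75% cutoff is kept rather than the 51% relaxation sometimes
advocated for task effects.

## Behavioral statistics

* **Instrumental learning**: attacks are counted in six 30-s bins per
  180-s session; learning is a paired t test of first-bin vs last-bin
  counts. Zero-variance differences are surfaced as an explicit
  degenerate condition rather than an infinite statistic.
* **Exclusion rule**: per outcome, the incorrect-response shield rating is
  subtracted from the correct-response rating; any score at or below zero
  excludes the subject.
* **Transfer rates**: presses are assigned to the pre-stimulus fixation
  window or the 4-s CS window (recharge presses are ignored) and divided
  by the 12 presentations per CS. The pre-stimulus window defaults to 4 s
  — equal to the CS window — so pre/stim rates are compared over equal
  exposure.
* **Three-way RM-ANOVA** (interval x stimulus x response): sums of squares
  are computed from the balanced cell means with each effect tested
  against its effect-by-subject interaction. Degrees of freedom carry a
  Greenhouse-Geisser correction — the correction consistent with the
  fractional dfs this design produces — and effect sizes are generalized
  eta squared, $SS_e / (SS_e + SS_{subj} + \sum SS_{err})$.
* **Pairwise probes**: per CS, four paired contrasts (R1 pre/stim, R2
  pre/stim, R1/R2 within pre, R1/R2 within stim), Bonferroni-corrected as
  one 20-comparison family. The family is configurable.

## What the simulator emulates, and what it does not

The task generator reproduces the paradigm's stated timing: 180-s
instrumental sessions with a 1-s attack clock and a 3-s deferral per
correct press; 45 Pavlovian trials (9 per pairing, 4-s CS, 1-s outcome,
7/9/11-s jittered ITI); 60 transfer trials (12 per CS, 4-s CS, 2-12-s
recharge). Agents are deliberately simple: a linearly interpolated
correct-press probability for instrumental learning (defaults 0.55 to
0.80, which places expected first/last-bin attack counts in the range
this task produces), and an inhomogeneous Poisson press stream with
multiplicative gains for transfer (defaults: 0.1 presses/s baseline,
specific gain 5, general gain 1 — a cohort showing specific but not
general transfer). BOLD series come from the euSEM above with
subject-specific two-gamma HRFs (peak delays spread over 4.5-7.5 s),
events convolved on a 16x-upsampled microtime grid before decimation to
TR = 2 s, and a discarded burn-in so series start near stationarity.

Not emulated: scanner physics, motion, physiological noise and their
preprocessing; reinforcement-learning dynamics inside the agent;
non-Gaussian or temporally correlated dynamic noise; HRF shapes outside
the two-gamma family. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated generative assumptions, not
robustness to everything real fMRI data can do. Real inputs are expected
to arrive as residualized ROI series; the extraction stage accepts any
externally produced series.

## Numerical choices and degenerate inputs

* One random substream per subject per stage, derived from the master
  seed (`derive_seed`), so adding subjects or stages never perturbs
  earlier draws; every pipeline run is reproducible bit-for-bit.
* Onsets bin to `floor(onset / TR)`; sphere masks include
  boundary-distance ties; "10 mm diameter" is read as a 5-mm radius with
  a flag for the diameter-as-radius dialect.
* Problem sizes in the test-suite simulations (10 subjects x 200 TRs for
  recovery, 540 TRs for single-subject estimates, 20-100 replicates per
  property) were chosen as the smallest sizes at which the studied
  effects are clearly resolved.
* Degenerate cases fail loudly: empty sphere masks, onsets past the run
  end, incomplete ANOVA cells, zero-onset HRF estimation, singular
  simultaneous systems (named time point), non-identified cyclic
  structures (named cycle), and non-converged fits all raise errors;
  fit indices refuse non-converged fits.

## Known limitations

* The search explores recursive contemporaneous structures; a true
  reciprocal (cyclic) pair will be recovered as the dominant direction
  only.
* Lag-1 only; no higher-order lags, latent variables, or non-diagonal
  noise covariance.
* Score tests treat HRF-convolved inputs as fixed regressors; uncertainty
  in the HRF estimate is not propagated. At weak direct effects the
  estimated HRF peak is noisy (the search is robust to this because the
  HRF enters only as a regressor shape, but peak summaries should be read
  with care).
* No subgrouping of participants, and no confirmatory multi-group SEM.
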