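---
title: "Modelling social gaze with Bayesian hidden Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling social gaze with Bayesian hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

gazehmm treats a viewer's scanpath on a social scene as the output of a
hidden Markov process. The hidden states are regions of interest (ROIs) —
not hand-drawn boxes but learned 3-D Gaussians over fixation position
*and* log fixation duration, so a "region" carries a temporal signature as
well as a spatial footprint. The observable sequence is the fixation
triple $(x_t, y_t, d_t)$; the hidden chain is governed by an initial
probability vector $\pi$ and a transition matrix $A$, with a Gaussian
emission $\mathcal N(\mu_k, \Sigma_k)$ per state.

Inference is variational Bayesian EM over the conjugate posterior:
Dirichlet distributions on $\pi$ and each row of $A$, Normal–Wishart on
each $(\mu_k, \Lambda_k)$. The E-step runs the forward–backward recursion
under the expected log-parameters (implemented in C++ with per-step
scaling, so zero-likelihood observations never produce NaN); the M-step is
the closed-form conjugate update. The evidence lower bound (ELBO) — the
variational log normaliser minus the KL divergence of the posterior from
the prior — is non-decreasing over iterations and automatically penalizes
complexity, which is what lets the number of ROIs be chosen by fitting
each candidate $K$ and keeping the best ELBO (ties resolve to fewer
states).

Two-step group structure: Step 1 pools all participants' scanpaths of one
stimulus and fits a single representative model (mode `"pooled"`, the
default). Step 2 refits each participant at the representative $K$,
initialised from the representative parameters, so state $k$ means the
same region for every participant; a correspondence table flags any state
whose mean drifts far from its representative counterpart
(`drift_flag_px`, default 150 px). An alternative Step-1 mode reduces
per-participant models with variational hierarchical EM (`vhem_reduce()`):
input states act as sources of virtual samples (100 per state — the
classical algorithm's free parameter), all expectations taken in closed
form, and reduced states are responsibility-weighted moment matches of
input states.

Each fixation is assigned to the state with the highest smoothed marginal
probability (per-fixation argmax of the forward–backward responsibilities,
not the Viterbi path, matching the per-fixation "highest posterior"
reading); ties resolve to the lowest state index.

## Gaze variables

States are categorized as face, body or non-social; a visit is a maximal
run of consecutive same-state fixations; a transition is a change between
two *distinct* non-excluded states (self-transitions are not transitions,
but a change between two different face states does count as
face-to-face). Transitions touching an excluded state are dropped from
every tally; social-to-nonsocial changes are tallied as "mixed" only to
make the conservation identity ($\sum$ category counts + mixed = total)
checkable — they are not analyzed.

The category transition probability renormalizes each state's row over the
other non-excluded states and aggregates rows by expected state occupancy.
Occupancy is taken from the decoded responsibilities by default
(`"stationary"` and `"uniform"` are config options), and each state's
weight is additionally multiplied by its probability of leaving the state.
The departure factor makes the aggregate equal the long-run conditional
frequency of category transitions — simulated sequences converge to
exactly these values — where raw occupancy weighting would drift whenever
self-transition mass differs across states. For each source category the
probabilities over the three destination categories sum to one; an empty
source category yields a missing value, never a silent zero.

Fitted models usually devote one state to sparse, long-duration fixations
with no regional pattern. `flag_sparse_state()` flags a state only when it
tops *both* rankings — mean duration and spatial covariance determinant —
and the flagged state is labelled `excluded` pending confirmation. When
labels are derived from generator templates, a state whose fitted spatial
footprint exceeds eight times its matched template ROI's area is likewise
excluded as a regionless catch-all: pooled Gaussian tails form a diffuse
background haze that a forced-$K$ fit will happily spend a state on, and
that state is a construct to drop, not a semantic region. (The factor 8
keeps states that merely merged two neighbouring ROIs, whose area ratio
stays around 3–4, while catch-alls sit an order of magnitude higher.)

## Statistics

Each gaze variable and category is analyzed with

```
value ~ 1 + group + actors + group:actors + covariate + (1 | participant)
```

fitted by REML, with total transitions (transition counts) or total
fixation duration (fixation and visit counts) as the grand-mean-centered
covariate and none for probabilities. The group effect is a Type-III F
test with Satterthwaite degrees of freedom (the df method is a
configurable choice; at the planted effect sizes the conclusion is
insensitive to it). Estimated marginal means are evaluated at covariate
zero and balanced actor conditions; contrasts compare each clinical group
against TD, unadjusted at $\alpha = 0.05$ across the 16 models
(Benjamini–Hochberg is available behind `p_adjust = "BH"` but off by
default, matching the unadjusted reporting convention). Group effects on
the covariates themselves are pre-tested before use.

## The synthetic cohort

No recordings are deposited, so validation runs on a generator that
emulates the study conditions: three groups of 25/15/12 participants, two
four-actor and two one-actor stimuli, 120-s recordings of roughly 300
fixations. Four-actor templates carry 12 ROIs (5 faces, 3 bodies, 4
non-social), one-actor templates 9 (1 face, 1 body, 7 non-social); one
non-social ROI per template is the sparse catch-all (3x median duration,
4x spatial SD). Durations are lognormal with median ~300 ms (sdlog 0.4),
truncated below at 100 ms so generated fixations stay clear of the 60-ms
detector minimum; fixations are separated by 30-ms saccade gaps.

Group differences are planted *only* in transition structure. Category
transition rows derive from the reported group-level pattern (face row:
0.30 face / 0.11 body / 0.59 non-social; body row: 0.09 / 0.38 / 0.53;
non-social row renormalized with 0.24 to non-social), read as
per-source-category distributions; the clinical effect scales the
face-to-face mass (ASD 26/30, ASD+ADHD 22/30) and redistributes the rest
proportionally. Rows are expanded to states with 5% self-transition mass
and 8% routed to the catch-all state, constructed so the *measured*
category probabilities (which drop self-transitions and excluded states)
reproduce the planted values exactly. Participants jitter the category
rows with Dirichlet concentration 20, giving a between-participant SD of
about 0.10 on the face-to-face probability — consistent with a reported
standard error near 2% at $n = 25$ — and ROI means jitter by 10 px.

What the generator does not emulate: saccade trajectories between
fixations, calibration drift, heavy-tailed or participant-specific
duration distributions, emission differences between groups, and any
dependence of gaze on image content. Passing tests therefore demonstrate
that the pipeline recovers transition-level group structure planted under
its own modelling assumptions — not that those assumptions hold for any
particular eye tracker or population.

## Fixation detection and quality control

Raw 120 Hz streams are classified by dispersion thresholding (I-DT):
maximal windows of valid samples spanning at least 60 ms whose dispersion
stays within the pixel equivalent of 2 degrees (88.4 px at 70 cm on a
24-inch, 1920x1080 screen; physical size 53.1 x 29.9 cm derived from the
16:9 diagonal unless overridden). Dispersion is measured as
$\max(\text{range}_x, \text{range}_y)$: with the common sum-of-ranges
variant, ordinary 300–800-ms fixations already exceed the 2-degree budget
from ~15 px of sample noise alone (the expected per-axis sample range of
50–100 samples at $\sigma = 15$ px is ~60 px), splitting intact fixations;
the per-axis maximum keeps the nominal 2-degree meaning on each axis and
round-trips rendered streams at realistic noise. Invalid samples (blinks,
off-screen) break candidate windows; fixation position is the window
centroid.

Recording gates are strict inequalities: tracking ratio (valid /
expected samples) must exceed 0.75 and total fixation time must exceed
0.50 of the stimulus duration; boundary values fail. Fixation-only
exports without a tracking-ratio column skip the ratio test with a logged
message. Off-screen fixations are those whose centroid leaves
$[0, \text{resolution})$ on either axis (half-open, so the last
addressable pixel is on-screen).

## Numerical choices and defaults

* Priors: symmetric Dirichlet(1) on $\pi$ and each row of $A$;
  Normal–Wishart with mean at the grand mean, $\beta_0 = 1$,
  $\nu_0 = D + 2$, prior expected covariance diag(feature variances)$/4$
  (prior state SD half the data SD per axis). The scale is deliberately
  independent of $K$: tying the prior footprint to $K$ (e.g. shrinking it
  as $K^{-2/3}$) rewards larger models through the Wishart evidence terms
  and makes the ELBO increase monotonically in $K$, defeating state-count
  selection. All are explicit stand-ins for an unstated "default"; an
  informative per-state prior centred on the representative states backs
  the `individual_emission = "anchored"` option (default is free
  re-estimation).
* Features: $(x, y, \log d)$ standardized per stimulus; means/SDs stored
  for exact back-transformation. Log-standardization keeps the duration
  axis from dominating or vanishing against the pixel axes.
* Initialisation: first restart from model-based Gaussian-mixture
  clustering of the spatial axes (the duration axis is iid within a state
  and only blurs distance-based partitions — raw k-means on all three
  axes systematically splits the broad catch-all cloud and merges
  neighbouring faces); further restarts use seeded k-means on the full
  feature space. Five restarts by default.
* Convergence: relative ELBO change below 1e-6, at most 300 iterations.
  Covariance collapse is prevented by the Wishart prior floor.
* Point estimates: posterior means (Dirichlet means for $\pi$ and $A$;
  $\mathbb E[\Sigma_k]$ for covariances), so reported transition
  probabilities carry Dirichlet shrinkage toward uniform — group
  *differences* are preserved (the shrinkage is essentially a common
  linear contraction at equal sequence lengths), but absolute recovered
  probabilities sit below the planted values at ~300 fixations per
  recording.
* Ties: smaller $K$ on equal ELBO; lowest state index on equal posterior.

## Problem sizes in the validation suite

The test suite exercises the full pipeline at sizes a single CPU handles
comfortably while keeping the study's statistical conditions (group sizes
25/15, planted 0.30 vs 0.22 effect, 120-s recordings): 20 end-to-end
replicates for planted-effect recovery with the state count fixed at the
generator's ROI count and one restart; 100 null replicates for type-I
calibration computed from ground-truth state sequences (the LMM stage is
what calibration tests; refitting HMMs per replicate adds runtime, not
information); 20 replicates each for two-state parameter recovery
(40 x ~200 fixations) and ELBO state-count selection. The open
state-count search (`k_range = 1:15`, 5 restarts) is the package default
for real analyses.

## Known limitations

* Pooled Step-1 fitting is the default; true VHEM clustering of
  individual models is provided and cross-checked but not the default
  path, and the two can disagree when individual fits are poor.
* Transition probabilities from ~300-fixation recordings are
  substantially shrunk by the prior; comparisons across studies should
  use counts or longer recordings.
* Mixed social/non-social transitions are tallied but never analyzed.
* The LMM assumes Gaussian residuals for count responses; at ~300
  transitions per recording this is harmless, but very short recordings
  would call for a count model instead.
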