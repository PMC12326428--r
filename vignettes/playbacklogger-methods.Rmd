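---
title: "Methods: simulating and analysing autonomous playback bio-loggers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing autonomous playback bio-loggers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(playbacklogger)
```

## The system being modelled

`playbacklogger` is a desk-scale model of an animal-borne audio-playback
system for free-ranging seabirds. The device estimates the bird's
behavioural state (flying / non-flying) every second from a low-power
25 Hz tri-axial accelerometer. When flying is detected for five consecutive
seconds, the GPS switches to a 1 Hz high-rate mode and holds it for at
least three minutes. When the ten most recent GPS fixes are all 3D and all
more than 1 km from the colony centre, the device enters playback standby.
Five more consecutive flying seconds start video recording; after about
60 s of pre-playback footage, if the bird is still flying, one of two audio
stimuli (a predator call or white noise, drawn uniformly) is played and
recording continues for another ~60 s. If the bird stops flying during
pre-record, the session is cancelled. A 10-minute refractory lockout
separates sessions.

The package contains (i) a seeded multimodal stream generator with
ground-truth labels, (ii) a compact CART behaviour classifier, (iii) the
tick-synchronous playback controller, (iv) the three behavioural response
indicators (S-VeDBA, AD-Speed, AD-MPR), (v) a Bayesian hierarchical
random-intercept model of post-minus-pre responses with a self-contained
MCMC sampler, and (vi) a covariate-free local-level structural time-series
counterfactual with 97% credible intervals.

## Synthetic streams: what they emulate, and what they do not

Bout durations are exponential — the simplest memoryless model of
alternating behaviour states. Defaults are a 300 s mean flying bout and a
120 s mean non-flying bout, a plausible scale for gull foraging-flight legs
and colony rests; since published bout statistics for the study system are
not available, these are generator conditions, not field calibrations.
Flight carries a flapping sinusoid (default 4 Hz, amplitude 0.5 g) on the
heave axis on top of 1 g gravity, with 0.05 g Gaussian sensor noise on all
axes. Body-frame rotation during flight is deliberately not modelled:
gravity stays on the heave axis in both states, so classifier features must
not rely on absolute orientation beyond that convention.

GPS is generated at 1 Hz. Each flying bout is an *outbound excursion*: the
position integrates from the colony along one uniformly drawn bearing at a
fixed ground speed (default 10 m/s); during non-flying bouts the position
is pinned at the colony. Two consequences matter for interpreting tests.
First, the reported speed matches positional displacement (within 5%)
*within* a bout, but positions jump back to the colony at bout boundaries —
the return leg is not modelled. Second, any check of "was the bird really
outside the geofence at playback" is only physically meaningful for
sessions whose pre-record and playback fall inside one flight bout; the
suite restricts its raw-track recheck accordingly, while the
controller-level safety property (below) is asserted for every playback.
Each fix independently fails to be 3D with probability 0.05.

The 30 FPS mask-pixel-ratio stream (the fraction of video-frame pixels
covered by a segmented head/neck mask, the proxy for vigilance) is a
baseline (0.2) plus frame jitter (SD 0.02), clipped to [0, 1]. A
`response_injection()` adds zero-mean variability that decays exponentially
after onset, on any of the three indicator channels; it exists so that
parameter-recovery tests can place a known response into the streams.

Passing tests on these streams show that the pipeline recovers what the
generator put in; they do not show field validity. Real acceleration has
orientation drift, gust and glide structure; real GPS has correlated
dropouts; real mask ratios have segmentation failures. None of those is
emulated.

## Behaviour recognition

Features per 1-s window (25 samples, non-overlapping, matching the
device's per-second cadence): per-axis mean, SD, min, max, and the mean
absolute dynamic acceleration (mean over axes and samples of
|sample − axis window mean|) — 13 light-weight statistics a
microcontroller can afford. The on-board feature set of the real firmware
is not public; this set is an emulation and is configurable.

The classifier is a flat-array CART trained with Gini impurity and an
exhaustive feature × midpoint-threshold search. Determinism is part of the
contract: ties break toward the lowest feature index and then the lowest
threshold; samples with feature value equal to the threshold go left; leaf
majorities break toward the lexicographically smallest class; splits are
accepted even at zero impurity decrease whenever a node is impure and a
valid split exists (without this, parity problems such as XOR would never
be split at all under a strict-gain rule). The default depth cap of 3 is a
plausibility constraint for a 64 MHz / 256 KB-RAM target, not a claim
about the real firmware. Training bundles use 60 s mean bouts so that 200
labelled seconds contain both classes.

Classifier quality is reported as a 2×2 confusion matrix with per-class
and macro precision/recall/F1; a zero denominator yields 0 with an
explicit flag. On the generator's study conditions (0.5 g flap amplitude,
0.05 g noise) a depth-3 tree trained on 200 s reaches macro F1 ≥ 0.95 on
1000 held-out seconds — a qualitative mirror of the field-reported
accuracy, not a replication of it (the field training data are not
deposited).

## Controller semantics

The controller is tick-synchronous at 1 s, the granularity at which the
system's logic is specified. Open points were resolved as follows.

* **Eligibility ring.** The ring of "10 recent GPS points" collects only
  fixes consumed at the high rate (HIGH_GPS and STANDBY modes) and is
  cleared when the high-rate mode is entered. In other modes GPS is
  consumed at the low cadence (default one fix per 60 s) for logging but
  does not feed the ring. Hence the ring backing every `PLAYBACK_START` is
  exactly the ten 3D, outside-geofence fixes that justified standby — the
  safety property is structural rather than probabilistic, which is what
  makes it hold under any fix-dropout rate.
* **Standby re-check.** Eligibility is re-evaluated every tick in standby;
  on failure the controller falls back to HIGH_GPS with a restarted hold
  timer. The 3-min hold is treated as a lower bound, and the hold timer
  restarts whenever the 5-s flying trigger re-fires.
* **"If the target behaviour persists."** Playback fires at the first tick
  at or after the 60 s pre-record mark at which the bird is estimated
  flying, provided no non-flying run of `cancel_nonfly_s` (default 5 s,
  mirroring the detection constant) has occurred — such a run cancels the
  session at any time during pre-record. A sub-5-s landing that straddles
  the decision tick can defer playback by a few seconds; under the
  generator's bout statistics this is vanishingly rare, and the pre-roll
  stays within 60 ± 1 s across the randomized suite.
* **Audio.** Playback duration is symbolic (`PLAYBACK_START`/`PLAYBACK_END`
  one tick apart); the stimulus is a label drawn uniformly from
  {predator, noise}. The post-record clock starts at `PLAYBACK_START`.
* After a completed or cancelled session the controller is refractory for
  600 s; video starts are therefore always ≥ 600 s apart.

## Response indicators

VeDBA is computed per 25 Hz sample: the static component of each axis is a
centred running mean (default 2 s — the static-estimation window is a
package default, exposed as a parameter, since the source analyses defer
to the VeDBA literature); the dynamic residual's Euclidean norm is VeDBA,
and S-VeDBA smooths it with a centred 2-s moving average. Windows truncate
at the series edges. AD-Speed and AD-MPR are absolute successive
differences of 1 Hz ground speed and 30 FPS mask ratios, timestamped at
the *later* sample so that post-onset windows begin exactly at the
playback onset. All three channels are non-negative by construction.
Onset alignment is a pure time shift with pre < 0 ≤ post.

## Pre/post hierarchical model

Per session and channel, the response is the difference of means over the
5-s windows adjacent to the onset: pre over (−5, 0], post over (0, 5]
(an offset parameter can shift both windows; adjacency is the most
conservative default reading). Covariates follow the analysis convention:
audio type (0 noise, 1 predator), location (0 non-offshore, 1 offshore —
supplied as a flag, with a distance-from-colony proxy available since no
coastline model is in scope), standardised body mass, and the standardised
within-bird playback count, counted per audio type. Standardisation uses
the analysis-set mean and sample (n−1) SD — stated for bit-reproducibility;
zero-variance covariates are dropped with a warning.

The model is `y ~ Normal(alpha + a_bird + X beta, sigma)` with
`a_b ~ Normal(0, sigma_b)`. "Weakly informative" priors are made concrete
as Normal(0, 10²) on intercept and slopes and half-Normal(0, 5·SD(y)) on
both SDs; all are overridable. The sampler is self-contained: all location
parameters (fixed effects *and* random intercepts) are drawn in one joint
conjugate Gaussian update — drawing them in separate blocks would leave the
intercept and the random-intercept mean random-walking against each other —
and the two log-SDs are updated by univariate slice sampling, which has no
step size to tune (the configured 0.99 target acceptance is carried as
metadata for the configuration surface; it has no effect on a slice
kernel). The default run is 4 chains × 8000 iterations with 6000 warm-up
and thinning 1, pooling 8000 draws. Summaries are posterior medians with
equal-tailed 89% and 97% credible intervals using midpoint-interpolation
(type-5) quantiles, split-chain R-hat and an autocorrelation-based
effective sample size; R-hat ≥ 1.05 flags the fit loudly.

Calibration, checked by simulation: with a true coefficient of 1.0 and
σ = 0.1 over 200 sessions from 8 birds, the posterior median lands within
0.1 of truth; with all true coefficients 0, the 97% interval excludes 0 in
well under 10% of replicates. The large-replicate calibration runs use a
reduced 2-chain × 1500-iteration sampler (the chains mix essentially
immediately thanks to the joint location update); the single
recovery/R-hat fit uses the full published configuration.

## Local-level counterfactual

To analyse a single session as a time series, the onset-aligned indicator
is mean-aggregated to 1 Hz (S-VeDBA and AD-MPR arrive at 25 and 30
samples/s) and a local-level model
`y_t = mu_t + eps_t`, `mu_{t+1} = mu_t + eta_t`
is fitted to the default 60 s pre-period by Gibbs sampling: a
forward-filter backward-sampler draws the level path, and the two
variances get conjugate inverse-gamma updates under IG(0.01, 0.01·s²_y)
priors scaled to the pre-period variance (a constant pre-period pushes the
estimates to the prior floor and is flagged). No trend, seasonal or
covariate components are included — this is the simple covariate-free form
of the structural time-series counterfactual. Forecasts propagate each
retained draw's final level with fresh innovations plus observation noise;
pointwise and cumulative observed-minus-predicted differences are formed
per draw and summarised by medians with 97% equal-tailed intervals
(97%, not the conventional 95%, to match the reported analysis).

Numerical choices: the filter is initialised diffusely at `m0 = y[1]`,
`C0 = 10·var(y)`; backward-sampling variances are floored at 0 against
rounding; the default 2000 retained draws after 500 warm-up iterations are
ample for a 13-parameter-free scalar state model. Simulation checks: on
white noise the observation-SD posterior concentrates near truth with the
level-innovation SD near 0; on a pure random walk the level-innovation SD
stays away from 0; under the null the 97% cumulative interval covers 0 in
≥ 93% of replicates, and a sustained 5σ step is detected in ≥ 90%.

## Field-summary module

The packaged `deployments_table1.csv` carries the published ten-deployment
summary verbatim. Aggregation reproduces the printed totals (66 videos,
46 playbacks, 18 predator, 28 noise, 20 cancelled) exactly, the
8-deployment success count under the "at least 2 playbacks" rule, and the
medians/ranges of videos 7 (3–15) and playbacks 5 (2–12) — these are the
only printed numbers the package can reproduce exactly, and only the
successful-deployment reading of the medians reproduces them. Logging-time
aggregates are computed but not asserted against the printed hour totals:
sums and medians of per-row *rounded* values are rounding-ambiguous (the
eight successful rounded rows sum to 128.2 h and give a median of
16.75 h), and silently "fixing" that would misstate the arithmetic.

## Problem sizes and reproducibility

Every stochastic stage takes an explicit seed; one master seed spawns
decoupled per-stage seeds (`spawn_seeds()`), and the full
simulate → train → control → indicators pipeline is bit-reproducible under
a fixed master seed. The shipped test-and-verification sizes — 500
randomized 900-s bundles for the controller suite, 1000 held-out seconds
for the classifier, 100 hierarchical-model calibration replicates, 200
counterfactual replicates of 60 + 60 s — were chosen as the smallest sizes
at which the binomial/Monte-Carlo error of each checked rate is well below
its acceptance margin.

## Known limitations

* Generator realism is deliberately minimal (see above); nothing here
  validates the field pipeline against real sensor data.
* The excursion GPS model teleports positions at bout boundaries, so
  cross-bout position checks are not physically meaningful.
* The classifier is a functional emulation of an undocumented on-board
  model; its field F1 is not reproducible from published material.
* The hierarchical model's "offshore" covariate is an input flag; the
  published offshore definition is not available.
* The counterfactual model is local-level only; series with genuine trend
  or periodicity (e.g., flap harmonics surviving aggregation) would need
  richer state components that are out of scope here.
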