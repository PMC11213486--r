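---
title: "Modeling switching between hunting and escaping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling switching between hunting and escaping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`huntswitch` implements, end to end, the behavioral-computational analysis of
a pursuit-evasion switching task: a player in a 2D circular arena alternates,
on a cued 50/50 schedule, between hunting a fleeing prey and escaping a
pursuing predator. The package provides the task simulator, three generative
models of the player's movement, windowed maximum-likelihood fitting with
Bayesian model selection, decoder-based quantification of the
condition-specific movement-generation state ($C_p$), trajectory metrics, and
the statistics of what happens to that state after a task switch. Because no
human data ship with the package, a synthetic-cohort generator reproduces the
statistical structure the analysis assumes, so every stage is exercisable and
testable offline.

## The task and its simulator

Positions live in screen-height units; the arena is a disc (radius 0.5 by
default), frames advance every 16 ms, and the player moves at 0.006
units/frame. The scripted agent is a one-step greedy cost minimizer: each
frame it evaluates 30 candidate positions equally spaced on a circle of
radius equal to its current speed and moves to the cheapest. The predator's
cost increases with distance to the player and the prey's decreases with it;
both pay a center penalty $w\,d_c^2/R$ (a quadratic ramp that equals $w d_c$
at the wall) that keeps them off the boundary. The default is the
behaviorally consistent flee/chase sign convention; the opposite convention
(prey cost increasing with distance from the player, which makes the "prey"
approach) remains available via `cost_sign_literal = TRUE` for comparison.

Trials last 2–10 s (uniform) or end early when the player–agent distance
drops below the capture radius (0.02). A successful hunt is a capture; a
successful escape is the absence of one. Positions persist across trial
boundaries except after captures, which trigger respawns: the agent from an
isotropic Gaussian at the center (SD = radius/4, rejected to the disc), the
player with uniform radius and angle. Because the agent tends to reappear
near the center, the optimal preparation during the occasional pre-encounter
stage (probability 0.4 after a capture, 0–10 s) is to wait near the boundary
before escaping and near the center before hunting. The predator also
"boosts" at random (by default: 0.5/s hazard, ×1.8 for 12 frames), which
penalizes straight-line fleeing.

A staircase calibrates difficulty: every 4 completed trials of a condition
the agent speed moves by 0.0005 units/frame toward the speed that holds the
player's success rate at 50%, clipped to [0.0005, 0.015]. Sessions begin with
60 unrecorded warm-up trials so that recorded trials reflect the staircase
equilibrium rather than the cold start — without the warm-up the early
predator is far too fast, most escape trials end in early captures, and the
trial-count balance the decoding analyses assume is destroyed. Arena radius,
capture radius, center weight, boost parameters, staircase step and speed
range are package choices (the task description does not pin them down); all
are `arena_config()` fields.

## Generative models of player movement

Movement is discretized into 128 directions plus a null action with a
joystick (129 actions) or 8 plus null with a keyboard (9 actions); observed
displacements below a quarter step length count as null. All three models
score an action $a$ by the squared Euclidean distance between its landing
point and a predicted agent position $y_{pred}$, with value
$Q(a) = -d^2$ when hunting and $+d^2$ when escaping, passed through a
softmax $p(a) = \exp(\tau Q(a)) / \sum_{a'} \exp(\tau Q(a'))$, so $\tau$
acts as a precision: large positive values make the task-appropriate
movement near-deterministic, values near zero make movement random, and
negative values favor task-inappropriate movement.

* **M1 (reactive)**: $y_{pred} = y(t)$; decisions every frame; free
  parameter $\tau$.
* **M2 (one-step predictive)**: $y_{pred} = y + y'\theta + y''\theta^2/2$
  with per-frame differences $y' = y(t)-y(t-1)$,
  $y'' = y'(t)-y'(t-1)$; during fitting $\theta$ is fixed at 1 frame, so
  the free parameter is again $\tau$.
* **M3 (variable timescale with momentum)**: the same prediction equation,
  but velocity and acceleration are lagged differences at lag
  $\mathrm{round}(\theta)$ and decisions are only taken every
  $\mathrm{round}(\theta)$ frames; between decisions the planned action is
  repeated with probability $\mu$ and otherwise an action is drawn
  uniformly. Free parameters $\theta \in (0, 30]$ frames,
  $\tau \in [-1000, 1000]$, $\mu \in [0, 1]$.

$\theta$ is continuous during optimization; it is rounded (minimum 1)
wherever it indexes frames, while the prediction horizon uses the continuous
value. At trial start, lags that reach before the first frame degrade
gracefully (zero acceleration with one lag available, zero velocity with
none). M1 and M2 decide every frame, leaving no intermediate frames, so they
are implemented without the momentum parameter; that also fixes the
free-parameter counts entering BIC at 1, 1 and 3.

## Window fitting

Each trial is segmented from its first movement frame into 30-frame (500 ms)
windows stepping by 15 frames — 250 ms is 15.625 frames, truncated to keep
integer alignment, a documented divergence of ≤ 10 ms per step. The window
negative log-likelihood sums $-\log p$ over frames: decision frames use the
softmax; M3's intermediate frames use
$p = \mu\,[a = a_{planned}] + (1-\mu)/|A|$. Two pragmatic identifications
make this tractable without marginalizing a latent plan: the planned action
at a decision frame is identified with the action
observed there, and the phase of the decision grid relative to the window
start — unknowable, since windows are laid out by the analyst, not the
player — is profiled out as a discrete nuisance (the likelihood is maximized
over offsets $0..\mathrm{round}(\theta)-1$). Omitting the offset profile
biases $\theta$ and $\mu$ downward noticeably in recovery experiments
(ground-truth correlation for $\theta$ rises from ~0.7 to ~0.95 with it).

Per window, fitting proceeds from a deterministic multi-start: for each
$\theta$ on the grid {1, 2, 3, 5, 8, 12, 18, 25, 30} and each offset, the
optimal $\mu$ is closed-form in the intermediate match counts and the
likelihood is concave in $\tau$ given the grid (so Brent's method suffices);
the two best starts are then polished jointly over $(\theta, \tau, \mu)$
with bounded L-BFGS-B (nll tolerance ~1e-6). Profiled starts dominate the
random draws a generic multi-start would use and make every fit exactly
reproducible. Probabilities are floored at 1e-12 before logs; windows where
the floor engages are the pathological-$\tau$ corners of the search, not the
optima. BIC is $2\,\mathrm{nll} + k\ln n$ with $n$ the scored frames (30)
and $k$ = 1, 1, 3 for M1, M2, M3.

## Model selection

Per-subject log evidence is $-\mathrm{BIC}/2$ summed over the subject's
windows. Random-effects selection treats each subject's model identity as a
draw from population frequencies with a Dirichlet prior (all ones): a
variational loop alternates subject-wise posterior model assignments with
Dirichlet updates; exceedance probabilities come from 10^5 Monte-Carlo draws
of the posterior Dirichlet; the Bayes omnibus risk (BOR) compares the free
energy of that model against the null of equal frequencies, and
$\mathrm{PXP} = \mathrm{EP}\,(1-\mathrm{BOR}) + \mathrm{BOR}/M$. No
installed package provides this statistic, so it is implemented here and
tested at its fixed points (symmetric evidence gives PXP = 1/M; unanimous
strong evidence gives PXP ≈ 1) and by generator-recovery (cohorts generated
under each model are attributed to it).

## Decoding and the condition-specific state

Fitted M3 parameters are averaged within trial, giving one
$(\theta, \tau, \mu)$ feature triple per trial. Per subject, a linear-kernel
SVM (cost 1) with features z-scored on the training fold decodes hunt vs
escape under leave-one-trial-out cross-validation; posteriors come from
Platt's sigmoid fit on the training fold only. The classifier carries
inverse-frequency class weights: leave-one-trial-out always removes one
trial of the left-out class, and the resulting majority bias otherwise pulls
the label-permutation null about two points below 50% at 60 trials per
subject. With the weights the null sits at chance, which is the property the
permutation control exists to certify. Accuracy is computed within subject
and averaged; whether the reference analysis pooled subjects is not stated,
and within-subject matches the cross-validation unit.

$C_p$, the condition-specific state of a window or trial, is the
task-appropriate posterior: $P(\mathrm{hunt})$ on hunt trials and
$1 - P(\mathrm{hunt})$ on escape trials, so 0.5 is an undifferentiated state
and 1 a fully condition-specific one. Window-level $C_p$ respects the
leave-one-trial-out discipline (each window is scored by the decoder trained
without its own trial). A trial's series is summarized by its first window
(initial $C_p$; using the first few windows instead is a possible variant,
the single first window is the implemented convention), last window, and
mean.

## Switching statistics

For a switch trial, the transition magnitude is
$C_p^{init} - (1 - C_p^{prev,final})$: how far the state moved toward the
new task relative to where it stood just before the cue (the worked example:
a hunt trial ending at 76% hunt followed by an escape trial starting at 60%
escape gives 0.36). Time-to-criterion is the window start time at the first
$C_p \ge 0.6$, censored if never reached; censored trials are excluded from
the linear model. The
suppression-load regression predicts the post-switch initial $C_p$ (or the
time to criterion) from the previous trial's final $C_p$ with random
intercepts for subject and, when present, run — random intercepts only,
since only grouping variables are named — falling back, flagged, to
fixed-effects fits when the grouping is singular. Trial success is related
to trial-mean $C_p$ by a mixed logistic regression with the same structure.

## The synthetic cohort

Subjects' condition-specific M3 parameters are truncated-normal draws around
the reported group means — joystick: $\theta$ 15.5 (hunt) / 11.4 (escape),
$\tau$ 322.0 / 49.6, $\mu$ 0.68 / 0.74; keyboard: 15.6 / 10.9, 383.8 / 29.3,
0.95 / 0.95 — with between-subject SD equal to 15% of each mean (the true
dispersion is not reported; this is a documented stand-in) and within-trial
jitter of 5%. Each subject plays full sessions against the scripted agent
with calibration on, so success-rate analyses are meaningful. Synthetic
trials default to 2–4 s (2 s fixed in the acceptance cohort) to keep fitting
desk-scale; the full 2–10 s protocol is a config change. Problem sizes used
by the tests and the acceptance script: 5 subjects × 60 trials (decoding,
~1500 windows), 20 subjects × ~110 keyboard windows (model selection), 100
label permutations (null).

What the generator does and does not emulate — and hence what passing tests
show: it reproduces the action-selection process, the condition-specific
parameter structure, the arena protocol and the calibrated difficulty; it
holds each trial's parameters fixed (plus i.i.d. jitter), so there is no
within-trial ramp of $C_p$ of the kind human players show as they settle
into a trial's task, no learning across trials, no reaction-time or
biomechanical constraints, and no reward/shock sensitivity. Consequently the
transition and suppression analyses are validated here for correctness of
the estimators (planted-effect recovery), not for reproducing human effect
sizes. One qualitative contrast the generator fails to reproduce: human
escape movement has larger frame-to-frame heading change than hunt, but in
the generator that metric is dominated by the $(1-\mu)$ uniform-action
noise, and the reported group means put $\mu$(hunt) at or below
$\mu$(escape) in both modalities, so simulated hunting comes out at least
as variable as escaping (a further contribution is high-$\tau$ dithering
between adjacent discrete directions while tracking the prey). The
corresponding directional check is kept in the suite as specified and is
expected to fail; the linearity contrast (hunting more linear) and the
thigmotaxis contrasts are reproduced robustly.

## Numerical choices and degenerate inputs

Softmax uses max-subtraction; likelihood logs are floored at 1e-12; ties in
the agent's candidate argmin resolve to the lowest index within a 1e-12 cost
tolerance (candidate 0 points along +x); action discretization ties go to
the lower index; policy steps longer than the player speed are renormalized
with a warning; trials with no movement or fewer than 30 post-movement
frames contribute no windows and are excluded listwise downstream;
single-condition subjects are an error for the decoder; probabilities
outside [0, 1] are an error for $C_p$. The movement-variability metric is
reported both as mean absolute heading change per frame (the primary
definition) and as direction changes per second capped at 59 (the two
definitions are not equivalent and both are provided, the per-frame one as
primary). Heading is defined
only on moving frames and pauses break the chain.

## Known limitations

Simulated agent kinematics are deterministic given the RNG, but libsvm's
Platt calibration shuffles internally in C and cannot be seeded from R in
the installed e1071 version: class decisions and accuracies are exactly
reproducible, posteriors (and hence $C_p$ values) only to about 1e-2. The
$\tau$ estimate for weakly directed behavior (escape-like, $\tau \approx
50$) is heavy-tailed at the window level and meaningful mainly after
trial- or subject-level averaging. The staircase cannot bring hunt success
all the way to 50% in 2-s trials (a softmax player with the reported hunt
$\tau$ rarely closes a capture within 125 frames even against a slow prey),
so the synthetic success asymmetry between conditions is larger than the
human one; direction-level properties are unaffected.
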