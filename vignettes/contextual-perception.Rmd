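---
title: "Contextual perception as precision control: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual perception as precision control: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(contextmdp)
```

## The task

An agent explores a 3×3 scene of discrete fixation locations to decide
whether a target face is happy or sad. Location 1 is the initial central
fixation; locations 2 and 3 show the eyes and mouth of the target face
(top-left quadrant); locations 4/5 and 6/7 show the eyes and mouths of two
further faces that define the *social context*; fixating location 8 or 9
reports "happy" or "sad" and ends the trial with corrective feedback.

Faces are coded by two features. A happy face shows narrow eyelids and
exposed teeth; a sad face shows pulled-together eyebrows and covered teeth;
an *ambiguous* face shows pulled-together eyebrows with exposed teeth —
one feature borrowed from each emotion, so its features alone cannot decide
the emotion. The context faces are never ambiguous, so a single feature of
a context face identifies its emotion. Crossing context (happy, sad, or one
of two incoherent happy+sad arrangements) with target emotion and
target ambiguity yields 16 trial cells in four classes
(`enumerate_conditions()`): *green* (unambiguous target, affectively
congruent coherent context), *red* (unambiguous, incongruent), *blue*
(ambiguous target, coherent context — where context should shape
perception) and *grey* (incoherent context).

## Generative model

The agent holds a discrete-state model of the trial with three hidden-state
factors — context (4 levels), target face (4 levels: happy/sad ×
unambiguous/ambiguous) and fixated location (9) — giving
4 × 4 × 9 = 144 state combinations, and three outcome modalities: facial
expression (5 levels, including *null* for featureless locations), fixated
location (9) and feedback (null / correct / incorrect). The likelihood
arrays $A^m$ give $P(o^m \mid s)$ for every state combination; transitions
$B^f$ are identity for context and target face (the scene does not change
within a trial) and fully action-controlled for location (a saccade moves
fixation anywhere); $D^f$ are the initial priors (uniform over context and
target face — the two incoherent arrangements jointly carry probability
0.5 — and a delta on the centre); and the log-preference vector $C$ is
zero everywhere except feedback: 0 for null, $+0.5$ for correct, $-10$ for
incorrect. The strongly negative incorrect preference makes the agent
report only once it has accumulated evidence.

We deliberately model target emotion and ambiguity as **one joined factor**
rather than two. A single target feature (say, pulled-together eyebrows)
carries *joint* evidence about emotion and ambiguity — it excludes only the
combination "happy and unambiguous" — and a likelihood of that shape cannot
be represented as independent messages to two separate mean-field factors:
with split factors the fixed point provably misstates the marginals after
one feature has been seen. With the joined factor the within-face coupling
is exact, and the derived emotion and ambiguity marginals are sums over the
joined levels (reported in `records_to_df()` as `p_emotion_happy` and
`p_type_ambiguous`).

## Precision as attention and contextualisation

Every likelihood column can be exponent-weighted
(`apply_precision()`): column $\bar A_{\cdot s} \propto
\exp\{\zeta_s \ln A_{\cdot s}\}$. $\zeta = 1$ leaves the mapping unchanged,
$\zeta = 0$ renders the channel uninformative (uniform), and large $\zeta$
sharpens it. Because the base task likelihoods are already one-hot,
$\zeta = 1$ is the natural encoding of "arbitrarily high precision"; any
numeric value can be supplied instead. The agent variants
(`make_agent_variant()`) differ only in the facial-expression precisions;
the location and feedback channels always keep $\zeta = 1$:

* **contextualising** — the mapping from an *ambiguously sad* face to
  expressions gets $\zeta = z$ (default 0) under the happy context, and the
  ambiguously happy face gets $z$ under the sad context. With $z = 0$ an
  ambiguous face can only be attributed the context-consistent emotion.
  We apply this at all six face locations (2–7), not only at the target:
  context-face columns for the discounted state combinations then carry a
  mild likelihood penalty, so the emotion belief already shifts toward the
  context while the context faces are being sampled, which matches the
  single-trial narratives this package reproduces. We do not apply it at
  the featureless locations 1/8/9: uniform-ising a null column would move
  beliefs at the blank initial fixation, which should be uninformative.
* **non_contextualising** — all $\zeta = 1$; identical to the base model.
* **local_viewer** — context-face locations 4–7 get $\zeta = z_{sc}$
  (default 0) for every state combination, target locations 2–3 get
  $z_{tf}$ (default 1). When both a contextualisation scheme and a location
  scheme are supplied, the exponents multiply entry-wise (both act as
  exponents, and they never target the same entries by default).
* **global_viewer** — $z_{sc} = z_{tf} = 1$.

## Inference

Beliefs are categorical marginals per factor (mean field). At each time
step the marginals solve the fixed point
$s^{*}_f = \sigma(\ln(\text{prior}_f) + \text{message}_f)$, where the prior
is $D$ at the first step and $B\,s_{t-1}$ afterwards, and the message to
factor $f$ is the summed log precision-weighted likelihood of the step's
observations contracted against the other factors' current marginals. The
fixed point is found by damped gradient steps on the state prediction error
$\varepsilon = \ln s^{*} - \ln s$, i.e.
$s \leftarrow \sigma(\ln s + \lambda\,\varepsilon)$, sweeping factors in
ascending order.

**Messages are passed forward in time only.** With identity transitions, a
backward message $\ln(B\,s_{t+1})$ from a predicted (unobserved) future
step equals $\ln s_t$ at any putative fixed point, so including it
double-counts evidence and the update has no interior fixed point — beliefs
would drift to certainty regardless of the data. Forward-only filtering has
the correct fixed point: for a single factor observed once it is exactly
the Bayes posterior $\sigma(\ln D + \zeta \ln A \cdot o)$, and across a
task trial the filtered marginals match posteriors obtained by exhaustive
enumeration over the 16 context × target combinations (this is tested to
$10^{-6}$). The trade-off is that *past* beliefs are filtered rather than
smoothed — the recorded belief trajectory is what the agent believed at
each step, which is also what the single-trial figures of this literature
display. A known limit of the mean-field family remains: when a single
observation couples two factors while both are uncertain (the
contextualising agent's very first context-face sample couples context and
target face), the mean-field marginals deviate from the exact joint
marginals; once the context is resolved — one step later in every
simulation here — they agree again. The package's oracle-equivalence tests
therefore run the agent whose likelihoods factorise at every step, and a
property test documents the deviation and recovery for the contextualising
agent.

Numerical choices: probabilities are clamped by $\epsilon = 10^{-16}$
before logarithms (one-hot columns otherwise produce $-\infty$);
$\lambda = 0.25$; convergence is declared when
$\max|\varepsilon| < 10^{-4}$. The log-space error contracts by a factor
$(1-\lambda)$ per sweep, and collapsing a belief from uniform to the clamp
floor ($\ln 10^{-16} \approx -36.8$) therefore needs on the order of 45
sweeps, so the default iteration cap is 64; tests that compare against
enumerated posteriors tighten `tol` and `max_iters`. All four settings are
arguments of `build_generative_model()` and `generative_model()`.

## Policy evaluation and action

Policies are depth one — one saccade per policy, re-planned every step —
so each policy $\pi$ is scored by its free energy $F_\pi$ (zero at a
converged fixed point, and identical across policies because they share the
observed past) plus the expected free energy of its predicted next state:

$$G_\pi = \mathbf o_\pi \cdot (\ln \mathbf o_\pi - C) +
  \mathbf H \cdot \mathbf s_\pi,$$

with $\mathbf o_\pi$ the predicted outcome distribution and $\mathbf H$ the
per-state outcome entropy of the precision-weighted likelihood. Two exact
decompositions are exposed by `efe_decompose()`: epistemic + extrinsic
value ($G = -\text{MI}(s;o) - \mathbf o\cdot C$), and risk + ambiguity,
where risk is the KL divergence from $\mathbf o_\pi$ to the *normalised*
preference distribution $\sigma(C)$. Because $C$ enters $G$ as raw
utilities, the two decompositions differ by the constant
$\log\sum_o e^{C_o}$ per modality; the constant is shared by all policies
and cancels in the policy posterior $\sigma(-F-G)$, and `efe_decompose()`
reports it (`pref_lognorm`) so either identity can be verified exactly.
Actions are taken either from the MAP policy — with ties (common, since
several saccades often carry exactly the same information) broken uniformly
at random within $10^{-8}$ of the maximum — or sampled from the posterior
(`"stochastic"`), which avoids ceiling effects in condition comparisons.

## What the simulations emulate — and what they do not

The generative process *is* the study design: deterministic feature
emission, a static scene, exact feedback. Trials differ only through the
agent's stochastic saccade choices (and MAP tie-breaks), all driven by a
single per-trial seed, so every run is exactly reproducible. This emulates
the logic of context-congruence experiments, not their measurement noise:
there is no oculomotor noise, no fixation-duration model, no stimulus
variability, and "decision time" counts fixations, not milliseconds.
Passing behavioural-ordering tests therefore shows that the *mechanism*
(precision-weighted evidence accumulation plus expected-free-energy
saccade selection) produces the qualitative effects — congruent contexts
speed and improve report, coherent features speed it — not that the model
is calibrated to human latencies.

Two behavioural conventions matter when reading the summaries. Decision
time is the step index of the report fixation (central fixation = step 1).
Trials that never report within the horizon (default 8 steps; the
narratives here end by step 6) are *censored*: they are excluded from the
accuracy denominator and enter decision-time comparisons at the horizon.
Much of the congruence effect expresses itself through the probability of
deciding within the horizon, so comparisons on censored times are the
informative ones. Batch comparisons default to stochastic action selection;
single-trial narratives to MAP.

On the schizophrenia-motivated variants, the model makes a sharper — and
honestly reported — prediction than "the local viewer never looks at the
other faces". With $z_{sc} = 0$ a context-face saccade has zero epistemic
value, but it also costs nothing: its expected free energy is *identical*
to that of the blank locations, in both decompositions. The local viewer
therefore never *seeks* social cues (its first saccades go to the target
face, and its policy posterior never favours a context face over the blank
centre), but once the ambiguous target is resolved and no report is worth
risking, it wanders indifferently — and indifference plus random
tie-breaking occasionally lands on a context face. A strict zero-fixation
scan path would require an explicit repulsion (e.g. a fixation cost or a
negative preference) that nothing in this model supplies.

## Problem sizes

The test suite and the reproduction script use 20 seeded MAP trials per
single-trial claim, 200 stochastic trials per condition cell for the
behavioural orderings (400 green, 400 red, 800 blue, 800 grey-ambiguous),
100 random models for the decomposition identity, and bootstrap intervals
with 2000 resamples. At these sizes the whole suite runs in a few minutes
on one core; the congruence effect on decision time is a fraction of a
fixation on the censored scale, so it is the replicate counts above — not
smaller ones — that give the ordering checks their resolution.

## A worked example

```{r example}
agent <- make_agent_variant(build_generative_model(), "contextualising")
scene <- build_generative_process(context = "happy", emotion = "happy",
                                  type = "ambiguous")
trial <- run_trial(scene, agent, mode = "map", seed = 11)
trial
round(trial$posterior[[1L]], 3)   # context beliefs per step
```

The agent fixates the two context faces (steps 2–3), infers the happy
context, samples the target's eyes and mouth (steps 4–5), attributes the
context-consistent emotion to the ambiguous face, and reports *happy* at
step 6, receiving correct feedback.
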