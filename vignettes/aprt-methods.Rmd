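---
title: "Simulating and analyzing a tri-outcome physical risk-taking task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing a tri-outcome physical risk-taking task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aprt)
```

## The task

The Assessment of Physical Risk Taking (APRT) is a computerized sequential
gamble. On each of 64 trials a participant sees a physically risky scenario
(one of four picture categories: animal, cliff, disaster, hero) and decides,
press by press, whether to proceed ("go press") or to quit and bank the
trial's points. Each press resolves into exactly one of three outcomes:

* **reward** — gain points;
* **neutral** — gain nothing, lose nothing;
* **injury** — lose the drawn magnitude from *both* health and points.

Each trial starts at 100 health and 0 points. If health reaches zero or
below, the trial ends in "death" and all of its points are forfeited;
quitting banks the current points into the grand total. Five factors are
crossed to make every trial unique: picture category (4 levels) and four
binary low/high factors — injury probability (1/15 vs 1/5 per press),
reward probability (2/3 vs 9/10), injury magnitude (uniform on 5–35 vs
60–90 points of health), and reward magnitude (uniform on 5–25 vs 50–250
points). The two probability factors are cued by the picture border (solid
= high reward probability, striped = low; yellow = high injury risk, blue
= low); the magnitude factors are only experienced through outcomes.

The full crossing 4 × 2⁴ gives the 64 unique trials; `generate_design()`
produces exactly one replicate of that crossing in a seed-determined random
presentation order. "Counterbalanced" is interpreted as this full factorial
(it is the only design with 64 unique trials covering all five factors);
no ordering constraints are imposed because none are documented. Four
flagged practice trials (one per category, binary levels drawn from the
seed) precede the scored trials.

### Outcome composition

The marginal injury and reward probabilities would exceed 1 if the three
outcomes were drawn from one categorical distribution at the high/high
levels (1/5 + 9/10 > 1). The engine therefore samples **sequentially**:
injury with probability $p_I$; otherwise reward with probability $p_R$;
otherwise neutral. This is the only simple scheme that keeps the three
outcomes exclusive while honoring both printed probabilities; it implies,
for example, a neutral rate of $(1-p_I)(1-p_R)$, which the tests verify by
enumeration and Monte Carlo.

### Bookkeeping decisions

* **Points clamp.** An injury larger than the current point balance leaves
  the trial at 0 points (the worked trial in the source material shows a
  64-point injury against 63 held points followed by play continuing, not a
  negative balance). The clamp is configurable
  (`engine_config(points_floor_at_zero = FALSE)`).
* **Death threshold.** Health ≤ 0 terminates the trial; the prose uses both
  "drops to zero" and "drop below 0", and ≤ 0 covers both readings.
* **Timestamps** are simulated, not wall-clock: press $k$ of a trial occurs
  at $k \cdot 1500$ ms in the delayed ("cool") mode and at
  $k \cdot$ `response_latency_ms` (default 600) in the immediate ("hot")
  mode. The 1500 ms delay applies between consecutive presses within a
  trial; whether the original program also delayed the quit key is
  undocumented, so quitting is not delayed.
* A configurable press cap (default 10⁴) guards against non-terminating
  policies.

## Simulated agents

No response model is published for this task; the decision policy here is
the package's own construction, chosen for monotonicity and closed-form
checkability. An agent presses with probability

$$\pi = \mathrm{clip}\!\left(\theta_{\mathrm{eff}}
  \, e^{-s\,I(\mathrm{trial})} \, (h_{\mathrm{cur}}/100)^{h},\; 0, 1\right),$$

and quits deterministically once trial points reach the satisficing target
$T$. Here $I \in \{0,1,2\}$ counts the trial's high injury cues
(probability and magnitude), $\theta$ is the baseline press drive, $s \ge 0$
the injury-cue sensitivity ($s=0$ is the task's operationalization of
maximal risk taking: behavior insensitive to injury-condition changes), $h$
a health-caution exponent, and in cool mode
$\theta_{\mathrm{eff}} = (1-a)\theta + a\,\theta_{\mathrm{cool}}$ shrinks
the drive toward a cautious baseline — a descriptive stand-in for the
hypothesized effect of the enforced delay, not a cognitive process model.

### Cohort defaults and their calibration

A synthetic cohort draws, per participant, $\theta \sim \mathrm{Beta}(4,
1.5)$, $s \sim \Gamma(0.6, \mathrm{rate}=4)$, $T \sim
\mathrm{Lognormal}(\log 45, 0.2)$; health caution, delay attenuation
($a = 0.6$), and the cool baseline ($\theta_{\mathrm{cool}} = 0.3$) are
fixed cohort-wide. These parameters (the distribution families are part of
the design; their parameters are free) were calibrated **once** against the
design's own identifiability gates: with 200 hot-mode agents, the rank
correlation between $\theta$ and total go presses should reach 0.8, and
between $s$ and the injury-probability go-press difference score 0.6.

Two lessons from that calibration are worth recording. First, leaving the
health-caution exponent heterogeneous confounds the cue-sensitivity
difference score (injuries deplete health most in exactly the high-injury
conditions), so it is fixed. Second, because the policy is multiplicative
and the expected press count $\pi/(1-\pi)$ is convex, any low-minus-high
difference score scales with $\theta$ as well as with $s$; together with
the binomial noise of 32-trial condition means this caps the achievable
$s$-recovery near $\rho \approx 0.55$ on the frontier where
$\theta$-recovery stays above 0.8. The 0.6 gate for $s$ is therefore
asserted but known to sit at, not under, the attainable frontier — the
acceptance test reports it honestly rather than loosening it. A direct
consequence of the calibrated satisficing target (median 45 points) is
that simulated press counts and points run lower than the human means
reported for the task; identifiability was given priority over matching
that scale, since no gate constrains it.

Each participant also receives synthetic self-report scale scores:
convergent scales are $\lambda z(\theta) + \sqrt{1-\lambda^2}\,
\varepsilon$ (standardized; default loading $\lambda = 0.35$, the size of
the convergent correlations reported for the task) and divergent scales are
independent noise. Even-numbered participants are assigned to the delayed
arm and odd-numbered to the immediate arm, matching the task's assignment
rule.

### What the generator does *not* emulate

Agents have no learning, memory errors, fatigue, or sequential dependence:
presses are conditionally independent given the trait profile, and trait
distributions are unimodal and independent. A green simulation test
therefore establishes that the *pipeline* behaves as specified on a world
with known ground truth — not that the policy family describes human
players (a third of the human sample pressed nothing on most trials, a
behavior the default cohort does not reproduce).

## Scoring

Four outcome scores are computed per trial: banked points (0 on death), go
presses, injuries, and remaining health (floored at 0). Per participant
the package emits per-trial-mean totals (plus the grand point sum), each
factor-level condition mean, and six low-minus-high difference scores: the
four binary factors plus the picture contrasts Animal−Cliff and
Disaster−Hero (animal and disaster play the "low" role; published tables
label the latter contrast "Hero-Disaster" but footnote hero as "High", so
all contrasts are standardized here as low − high). Small difference
scores index insensitivity to the manipulation, i.e. higher risk taking.

Internal consistency uses Cronbach's α with a condition's trials as items
(whether the original analysis treated trials or trial pairs as items is
undocumented; trials-as-items is implemented), and difference-score
reliability uses the classical formula from component reliabilities, SDs
and their correlation.

## Statistical pipeline

Each outcome is aggregated per participant × design cell (one trial per
cell at the default design), Winsorized one-sidedly at mean + 3 SD
(computed across all rows of that variable, single pass), and — for the
skewed press and injury counts — log-transformed as $\log(x+1)$ (the +1
shift accommodates zeros; the original transform is stated without a
shift). The transform order (Winsorize, then log) and the aggregation
level are the package's documented choices where the source is silent.

The factorial model contains 21 terms: 6 main effects (five within-subject
factors and the between-subject delay), the 10 two-way interactions among
the within factors, and the 5 within × delay interactions. Inference uses
a Gaussian marginal model with participants as clusters, solved by
iterated generalized least squares under a working correlation, with
robust (sandwich) covariance and per-term Wald χ² tests; sum-to-zero
contrasts make those Wald blocks Type-III-like. The published analysis
assumes an unstructured working correlation over the repeated cells; that
matrix is only estimable with more participants than cells (64), so
smaller panels fall back to an exchangeable structure with a warning.
Because inference is sandwich-based, misspecifying the working correlation
costs efficiency, not validity — which the null-calibration tests verify.
The solver was cross-checked against an independent estimating-equation
implementation to 10 decimals and is also validated in-tree against an
OLS-plus-sandwich oracle.

Multiplicity uses the Holm–Šidák step-down procedure: order the $m$
p-values, adjust $p_{(i)} \mapsto 1-(1-p_{(i)})^{m-i+1}$ (computed via
`expm1`/`log1p` so that tiny p-values do not underflow), enforce
monotonicity by a running maximum, and reject while the adjusted value
stays at or below α = .05. Interaction decompositions test df-1 simple
effects (for the picture factor, the two contrasts) with estimated
marginal means and robust SEs, adjusted within the decomposition family.
Correlation screens compute Pearson correlations per delay arm and adjust
within each (score, family, arm) family, the convergent/divergent validity
layout of the published tables.

## Degenerate inputs and numerical conventions

Probabilities of exactly 0 or 1 are accepted so tests can force outcome
branches; zero-variance vectors pass through Winsorizing unchanged and are
flagged (not dropped) in correlation screens; Cronbach's α refuses
zero-variance totals; difference-score reliability refuses a non-positive
denominator. All randomness flows from explicit integer seeds; derived
sub-stream seeds stay below 2³¹.

## Out of scope

Human data and all human-derived cell values; the questionnaires' item
content (only scale-level synthetic scores are generated); the χ²(42)
equality-of-correlation-pattern test between arms (its construction is not
documented); the a-priori power computation; stimulus rendering and GUI
interaction.
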