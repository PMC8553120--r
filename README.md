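# aprt

Simulation, scoring and factorial analysis of a tri-outcome behavioral
risk-taking task.

## The problem

Behavioral risk-taking tasks (balloon-inflation tasks, card tasks) usually
confound the probabilities of gain and loss: one is the complement of the
other, and loss magnitude barely varies. The Assessment of Physical Risk
Taking (APRT) separates them. On each of 64 trials a player repeatedly
chooses to *proceed* with a depicted physically risky activity or to *quit*
and bank the trial's points. Every press resolves into exactly one of three
outcomes — gain points, gain nothing, or lose both points and health — and
five factors are fully crossed across trials: picture category (animal,
cliff, disaster, hero) and low/high levels of injury probability (1/15 vs
1/5), reward probability (2/3 vs 9/10), injury magnitude (5–35 vs 60–90)
and reward magnitude (5–25 vs 50–250). Trials start at 100 health, 0
points; health ≤ 0 is "death" and forfeits the trial's points.

This package is for task developers and methodologists who want to exercise
the task's mechanics, psychometrics and statistical pipeline without human
participants. It provides:

* **task_design** — the counterbalanced factorial trial set, practice
  trials, and border-cue encoding (`generate_design()`, `cue_encoding()`,
  `design_balance_report()`);
* **task_engine** — per-press outcome sampling (injury first with
  probability `p_I`, else reward with probability `p_R`, else neutral),
  health/points bookkeeping, death/quit semantics, the 1500 ms "cool"-mode
  inter-press delay, and auditable CSV event logs (`run_session()`,
  `write_session()`);
* **agents** — trait-parameterized press/quit policies
  (`pi = clip(theta_eff * exp(-s * I) * (health/100)^h, 0, 1)` with a
  satisficing quit at target `T`) and a synthetic cohort generator with
  trait-correlated self-report scale scores (`generate_cohort()`,
  `simulate_cohort()`);
* **scoring** — the four outcome scores (Points, Go Presses, Injuries,
  Remaining Health) as totals, condition means and six low−high difference
  scores, plus Cronbach's α and difference-score reliability
  (`score_table()`, `cronbach_alpha()`);
* **analysis** — Winsorizing at +3 SD, `log(x+1)` transforms, a 21-term
  within-subject factorial marginal model with cluster-robust Wald χ²
  tests, Holm–Šidák step-down correction, post hoc interaction
  decomposition, and family-wise correlation screens
  (`fit_factorial_effects()`, `holm_sidak_adjust()`,
  `correlation_families()`);
* **cli_io** — JSON/YAML configs, an end-to-end pipeline with a JSON run
  manifest (`run_pipeline()`), and an `aprt` command-line wrapper
  (`inst/exec/aprt`).

See `vignettes/aprt-methods.Rmd` for the model, its assumptions, and every
place a design decision had to fill a gap in the documented task.

## Worked example

```r
library(aprt)

design <- generate_design(aprt_config(), seed = 1)
table(design$picture_category, design$injury_prob_level)
#>            high low
#>   animal      8   8
#>   cliff       8   8
#>   disaster    8   8
#>   hero        8   8

profile <- trait_profile(theta = 0.85, cue_sensitivity = 0.4,
                         satisficing_target = 60)
session <- run_session(with_practice(design),
                       make_policy("cue_sensitive", profile = profile),
                       engine_config("hot", seed = 2))
session
#> <aprt_session> participant p0, hot mode (64 trials, 4 practice)
#>   grand total points: 3088 | presses: 74 | deaths: 0

ts <- score_session(session, design)
round(condition_means(ts, "injury_prob", "go_presses"), 2)
#> high  low
#> 0.94 1.28
round(difference_scores(ts, "go_presses"), 2)
#>    injury_mag   injury_prob    reward_mag   reward_prob  animal_cliff
#>          0.97          0.34          0.72          0.16          0.38
#> disaster_hero
#>         -1.19
```

The session banked 3088 points over 64 scored trials. The positive
`injury_prob` difference score (0.34 presses) says this agent pressed less
often when the yellow high-injury-risk border was shown — the task's
signature of a risk-averse player; an agent with `cue_sensitivity = 0`
would show ≈ 0 on both injury difference scores (that insensitivity is the
task's operational definition of high risk taking).

A cohort-level analysis (20 agents, even ids delayed):

```r
cohort   <- generate_cohort(cohort_spec(n = 20, seed = 3))
sessions <- simulate_cohort(cohort, design)
panel    <- build_panel(sessions, design, "go_presses", log_transform = TRUE)
fit      <- fit_factorial_effects(panel)   # falls back to exchangeable (n < 64 cells)
head(fit$effects[order(-fit$effects$wald),
                 c("term", "df", "wald", "p", "p_adj")], 5)
#>              term df wald        p    p_adj
#>        reward_mag  1 44.8 2.19e-11 4.59e-10
#>             delay  1 29.1 6.93e-08 1.39e-06
#>  reward_mag:delay  1 20.9 4.93e-06 9.37e-05
#>       injury_prob  1 14.2 1.60e-04 2.88e-03
#>        injury_mag  1 13.3 2.61e-04 4.43e-03
```

Wald χ² values are cluster-robust; `p_adj` is Holm–Šidák across the 21
model terms. (The strong reward-magnitude effect in this small synthetic
cohort reflects the agents' satisficing: big rewards hit the quit target
sooner.)

The same flow from the shell:

```sh
Rscript inst/exec/aprt run --seed 7 --n 20 --out runs/demo
```

writes `design.csv`, `participants.csv`, `events.csv`, `trials.csv`,
`scores.csv`, `effects.csv`, `correlations.csv` and `manifest.json`.

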