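---
title: "Methods: restriction coaching, simulation, and trial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restriction coaching, simulation, and trial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepcoach)
```

This vignette documents the algorithms, the statistical model, the
simulator calibration, and the deliberate design decisions behind
`sleepcoach`.

## Diary identities

Nightly metrics follow the consensus sleep-diary definitions. With bed
time $b$ and arising time $a$ in minutes-of-day,

$$\mathrm{TIB} = a - b \;(+\,1440 \text{ if } a \le b), \qquad
\mathrm{TST} = \mathrm{TIB} - \mathrm{SOL} - \mathrm{WASO} - \mathrm{TWAK},
\qquad \mathrm{SE} = 100\,\mathrm{TST}/\mathrm{TIB},$$

with SE reported to one decimal. Terminal wakefulness (TWAK) is derived
from the final-wake and arising clock times when not supplied explicitly.

## Restriction coach

Eligibility after the baseline week requires at least 6 diaries and mean
SE strictly below 85%. The proposal is

- ideal TIB = mean TST, rounded half-up, floored at 300 minutes (5 hours);
- maximum TIB = mean TIB − 60 minutes, clamped up to the ideal when the
  window collapses.

The source material states both "between average TST and average TIB" and
"at least 1 hour less than average TIB"; these conflict when TST is within
an hour of TIB. We resolve in favor of the 1-hour rule for the maximum and
the TST anchor (with the 5-hour floor) for the ideal, which keeps
$300 \le \text{ideal} \le \text{max} \le \overline{\mathrm{TIB}}$ on every
input.

Negotiation is upward-only: a request between ideal and max is accepted;
anything outside is answered with a capped counter-offer; the participant
may opt out. Weekly titration moves the agreed TIB by +15 minutes when
weekly SE > 85, −15 when SE < 85 *and* the week was adherent (mean
absolute deviation < 60 minutes), and holds otherwise — SE exactly 85
holds, and the 300-minute floor is never crossed. The safety monitor
watches the trailing five *reported* nights: mean TST strictly below 300
minutes raises a warning; a second strike on five fresh nights after the
first warning refers to the GP and stops the exercise.

## Program engine

The engine is a pure fold over a dated input stream: each day takes the
state, that morning's diary entry, and user actions, and returns a new
state plus events. Day 1 queues a welcome conversation and introduces the
relaxation exercise; four days later a one-shot adherence check fires if
fewer than 3 relaxations were done. Day 7 introduces restriction if 6
diaries are present, otherwise postpones until the 6th diary arrives
(eligibility is then evaluated over the most recent up-to-7 reported
nights). Weekly evaluations run every 7th day and apply titration.
Reminders fire from noon, once per day per unfinished conversation, and
only one conversation can be open at a time. The program runs 42 days plus
any postponement, capped at 49. State serializes to JSON and round-trips
exactly, so a serialize–resume cycle reproduces an uninterrupted run byte
for byte.

## Adequate dose

The strict adherence flags are: diaries > 35, relaxations > 35,
conversation completion > 90%, and mean absolute deviation from the agreed
schedule < 60 minutes (undefined when no schedule was ever agreed).

## Simulator

`sleeper_profile()` parameterizes a sleeper by habitual TIB
(506 ± 44 min), baseline SE (77.6 ± 7.3%), and the SOL/WASO/TWAK means
(33/45/35). A night is generated by drawing TIB and SE, then splitting
total wakefulness $\mathrm{TIB}(1-\mathrm{SE}/100)$ proportionally to the
three wakefulness means. Parameterizing by SE (rather than drawing the
components independently) makes the configured mean SE exactly recoverable
— a ratio of independent draws would bias $E[\mathrm{TST}/\mathrm{TIB}]$.
Under a prescription, sleepers overstay (probability 0.55, +67 ± 45 min)
or understay (0.25, −42 ± 29 min); the deviation draws are untruncated so
the configured means recover exactly in Monte-Carlo checks. Restriction
response is modeled as weekly exponential approach toward a target SE.

`simulate_trial()` generates a two-arm pre/post(/follow-up) dataset. Each
participant gets an independent RNG substream (`sub_seed`), so outputs are
bit-identical under a fixed seed and a participant's data do not change
when the cohort grows. Outcomes follow a random-intercept model with ICC
0.5; the arm effect is injected on the post score as
$\delta = d\sqrt{2}\,\sigma_e$, which makes the change-score Cohen *d*
equal the configured *d* by construction. Missingness is MAR: logistic in
standardized dropout covariates with intercepts matching observed
completion rates.

## Mixed model

`fit_random_intercept()` implements a two-level random-intercept model by
maximum likelihood (not REML, so likelihood-ratio χ² across fixed-effect
specifications is valid). Writing $\lambda = \sigma_u^2/\sigma_e^2$, the
compound-symmetry structure gives closed forms per group,

$$X'V^{-1}X = X'X - \textstyle\sum_g c_g (X_g'\mathbf 1)(\mathbf 1'X_g),
\quad c_g = \frac{\lambda}{1 + n_g\lambda}, \quad
\log|V_g| = \log(1 + n_g\lambda),$$

and the profile likelihood is optimized over $\log\lambda$, with the
$\lambda = 0$ boundary checked explicitly. A fit takes milliseconds and
matches `lme4::lmer(REML = FALSE)` to ~1e-8 in the test suite.
`compare_models()` reports $\chi^2 = 2\Delta\ell$, df = parameter
difference, and level-1 R² as the proportional reduction in residual
variance.

Effect sizes use the change-score convention: between-group
$d = (\overline{\Delta}_{wl} - \overline{\Delta}_{app})/SD_{pooled}$ with
$\Delta = \text{pre} - \text{post}$; within-group pools the pre and post
SDs. Responder classification uses ISI drop ≥ 8 (meaningful) and post ≤ 7
(remitted). Pearson χ² is uncorrected — the dialect fixed by reproducing
the published 15.19 and 12.20 exactly. Imputation is hand-rolled
predictive mean matching (no `mice` dependency): chained linear models,
5 donors on predicted means, 5 sweeps, independent sub-seeded completions,
pooled by Rubin's rules.

## Verification and problem sizes

- Every formula has a brute-force oracle test; χ² golden values reproduce
  published tables to 2 decimals.
- Type-I error of the interaction LR test is calibrated over 2000 null
  replicates (runs in ~15 s).
- Effect-size recovery uses 200 replicates at 500/arm (~30 s after the
  flat-accumulator rewrite of the trial generator). Recovery is checked on
  *complete* data: with MAR missingness the complete-case change-score *d*
  is not expected to equal the generating *d*, so missingness is switched
  off for that check and exercised separately.
- Replay equivalence is checked on 100 seeded runs interrupted at random
  days.

## Limitations and open questions

- Conversation content is reduced to typed stubs; dialogue text is out of
  scope.
- The published imputed-sample between-group effect sizes and completion
  percentages are not reproducible without the raw data; they are covered
  by simulation-recovery checks instead.
- Some published within-group *d* values do not reproduce from the printed
  rounded means/SDs (the per-imputation pooling used is unstated); only
  the reproducible instance is used as a golden value.
- The sleep-quality scale direction in the source tables is ambiguous; the
  simulator treats higher as better and the analysis code is agnostic.
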