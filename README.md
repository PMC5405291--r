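# sleepcoach

An R toolkit for app-based cognitive behavioral therapy for insomnia (CBT-I)
built around a modified sleep-restriction exercise. It provides:

- **Diary core** — consensus sleep-diary metrics (time in bed, total sleep
  time, sleep efficiency), validation, weekly summaries, and CSV/JSON I/O.
- **Restriction coach** — eligibility screening, the ideal/maximum
  time-in-bed proposal, a bounded negotiation step, ±15-minute weekly
  titration with a 5-hour floor, and a two-stage short-sleep safety monitor
  with GP-referral stop.
- **Program engine** — a deterministic day-by-day protocol state machine
  (baseline week, postponement, weekly evaluations, relaxation adherence
  trigger, noon reminders, conversation gating) with exact JSON state
  serialization and replay.
- **Adherence metrics** — diary counts, relaxation counts, conversation
  completion, and mean absolute deviation from the agreed schedule, with
  strict adequate-dose flags.
- **Sleeper simulator** — synthetic nightly diaries from configurable
  sleeper profiles, a coupled engine+sleeper program simulation, and a
  two-arm randomized-trial generator with seeded substreams and MAR
  missingness.
- **Trial statistics** — an own maximum-likelihood random-intercept
  mixed-model fitter, likelihood-ratio model comparison with level-1 R²,
  change-score effect sizes, predictive-mean-matching imputation with
  Rubin pooling, responder classification, and Pearson χ² tests.

## Quick start

```r
library(sleepcoach)

# simulate a coached participant end to end
p <- sleeper_profile()
run <- simulate_program(p, seed = 42)
adherence_from_state(run$state)

# a two-arm trial and its analysis
trial <- simulate_trial(74, 77, seed = 1)
report <- run_analysis(trial, outcomes = c("isi", "se"))
report$outcomes$isi$comparisons
```

Diary workflow:

```r
d <- diary_entry(date = as.Date("2024-03-01"), bed_time = "23:30",
                 try_sleep_time = "23:45", sol = 30, n_awakenings = 2L,
                 waso = 40, final_wake_time = "06:50",
                 arising_time = "07:10", quality = 3L,
                 used_medication = FALSE)
summarize_window(d)
```

## Command line

A single CLI wrapper covers simulation, coaching, reporting, and analysis:

```sh
Rscript inst/cli/sleepcoach.R simulate --weeks 6 --seed 7 --out diary.csv
Rscript inst/cli/sleepcoach.R coach --init --out state.json
Rscript inst/cli/sleepcoach.R coach --state state.json --date 2024-01-01 \
    --diary diary.csv
Rscript inst/cli/sleepcoach.R analyze --trial trial.csv --out report.json
```

## Testing

```r
testthat::test_dir("tests/testthat", package = "sleepcoach",
                   load_package = "installed")
```

The suite includes golden-value checks against published summary
statistics, brute-force oracles for every formula, Monte-Carlo calibration
of the mixed-model test, and byte-exact engine replay checks.
`scripts/acceptance.R --seed 1 --out results/acceptance.json` writes the
headline acceptance target.

See the methods vignette (`vignettes/coaching-methods.Rmd`) for the
algorithmic details, simulator calibration, and design decisions.
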