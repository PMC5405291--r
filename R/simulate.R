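# Synthetic participant generator. Produces (a) nightly diary streams with
# the statistical structure the coaching engine assumes — habitual sleep
# around a baseline sleep-efficiency level, behavioral deviation from a
# prescribed time in bed, gradual sleep consolidation under restriction —
# and (b) long-format two-arm trial datasets with a participant-level random
# intercept, configured standardized effects, and missing-at-random dropout.
# Purely statistical: no circadian physiology is modeled.

#' Synthetic sleeper profile
#'
#' Defaults describe a chronic-insomnia sleeper anchored to typical baseline
#' diary values from app-delivered CBT-I trials: mean time in bed around 506
#' minutes (SD 44), wakefulness split SOL/WASO/TWAK around 33/45/35 minutes,
#' hence a baseline sleep efficiency near 77.6% with a nightly SD of 7.3
#' percentage points. Behavioral deviation from a prescribed time in bed is
#' calibrated to a mostly-overstay pattern with overstays of about 67 minutes
#' (SD 45) and understays of about 42 minutes (SD 29), giving a mean absolute
#' deviation near one hour.
#'
#' @param habitual_bed_time Habitual bed time, minutes-of-day.
#' @param bed_time_sd Nightly Gaussian jitter of bed time, minutes.
#' @param habitual_tib_mean,habitual_tib_sd Habitual nightly time in bed,
#'   minutes (arising time is derived).
#' @param baseline_se Baseline mean nightly sleep efficiency, percent.
#' @param se_sd Nightly SD of sleep efficiency, percentage points.
#' @param baseline_sol,baseline_waso,baseline_twak Mean minutes of the three
#'   wakefulness components; each night's total wakefulness is split in these
#'   proportions with multiplicative jitter.
#' @param diary_compliance Probability a night's diary is filled out.
#' @param relaxation_rate Expected relaxation exercises per week.
#' @param overstay_prob,understay_prob Nightly probabilities of staying in
#'   bed longer / shorter than prescribed (the remainder matches exactly).
#' @param overstay_mean,overstay_sd,understay_mean,understay_sd Deviation
#'   draws, minutes (normal, so configured means are recovered exactly).
#' @param responsiveness Fraction of the gap to the target sleep efficiency
#'   closed per week under restriction (0 = non-responder).
#' @param se_target Sleep-efficiency asymptote under restriction, percent.
#' @param dropout_hazard Per-week probability of abandoning the program.
#' @return A `sleeper_profile` list.
#' @export
sleeper_profile <- function(habitual_bed_time = parse_clock("23:15"),
                            bed_time_sd = 30,
                            habitual_tib_mean = 506, habitual_tib_sd = 44,
                            baseline_se = 77.6, se_sd = 7.3,
                            baseline_sol = 33, baseline_waso = 45,
                            baseline_twak = 35,
                            diary_compliance = 0.9, relaxation_rate = 3,
                            overstay_prob = 0.55, understay_prob = 0.25,
                            overstay_mean = 67, overstay_sd = 45,
                            understay_mean = 42, understay_sd = 29,
                            responsiveness = 0.35, se_target = 90,
                            dropout_hazard = 0.03) {
  p <- as.list(environment())
  stopifnot(p$diary_compliance >= 0, p$diary_compliance <= 1,
            p$overstay_prob >= 0, p$understay_prob >= 0,
            p$overstay_prob + p$understay_prob <= 1,
            p$responsiveness >= 0, p$responsiveness <= 1,
            p$dropout_hazard >= 0, p$dropout_hazard <= 1)
  structure(p, class = "sleeper_profile")
}

# internal: truncated-at-zero normal via rejection (for duration noise)
rtnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Simulate one diary night
#'
#' Without a prescription the night is drawn from the habitual parameters:
#' time in bed around the habitual mean, nightly sleep efficiency around
#' `current_se` (defaults to the profile baseline), and the night's
#' wakefulness split into SOL/WASO/TWAK in the profile's proportions with
#' jitter. With a prescription, the intended time in bed is the agreed
#' value distorted by an overstay or understay draw; the caller passes the
#' consolidated `current_se` so efficiency drifts upward across restriction
#' weeks.
#'
#' @param profile A `sleeper_profile`.
#' @param date Diary date (the morning of report).
#' @param prescription Agreed time in bed in minutes, or `NULL`.
#' @param current_se Tonight's expected sleep efficiency, percent.
#' @return A one-row validated `sleep_diary` tibble.
#' @export
simulate_night <- function(profile, date, prescription = NULL,
                           current_se = NULL) {
  p <- profile
  current_se <- current_se %||% p$baseline_se
  if (is.null(prescription)) {
    tib <- rtnorm_pos(1, p$habitual_tib_mean, p$habitual_tib_sd)
  } else {
    u <- runif(1)
    dev <- if (u < p$overstay_prob) {
      rnorm(1, p$overstay_mean, p$overstay_sd)
    } else if (u < p$overstay_prob + p$understay_prob) {
      -rnorm(1, p$understay_mean, p$understay_sd)
    } else 0
    tib <- prescription + dev
  }
  tib <- round_half_up(min(max(tib, 180), 1080))
  se <- min(max(rnorm(1, current_se, p$se_sd), 1), 100)
  wake <- tib * (1 - se / 100)
  # split wakefulness into SOL/WASO/TWAK around the configured proportions
  w <- rtnorm_pos(3, c(p$baseline_sol, p$baseline_waso, p$baseline_twak),
                  0.3 * c(p$baseline_sol, p$baseline_waso, p$baseline_twak))
  split <- w / sum(w)
  sol <- round_half_up(wake * split[1])
  twak <- round_half_up(wake * split[3])
  waso <- max(round_half_up(wake) - sol - twak, 0)
  bed <- (round_half_up(rnorm(1, p$habitual_bed_time, p$bed_time_sd)) +
            1440L) %% 1440L
  arise <- (bed + tib) %% 1440L
  if (arise == bed) arise <- (arise + 1L) %% 1440L
  final_wake <- (arise - twak + 1440L) %% 1440L
  quality <- min(max(round_half_up(rnorm(1, 4 + 3 * (se - 60) / 40, 1.2)), 1),
                 10)
  diary_entry(
    date = date,
    bed_time = as.integer(bed),
    try_sleep_time = as.integer((bed + 15L) %% 1440L),
    sol = sol,
    n_awakenings = rpois(1, 2),
    waso = waso,
    final_wake_time = as.integer(final_wake),
    arising_time = as.integer(arise),
    quality = quality,
    used_medication = runif(1) < 0.05,
    twak = twak)
}

#' Simulate a diary stream
#'
#' Generates `weeks` weeks of nightly diaries from one profile. Nights are
#' skipped independently with probability `1 - diary_compliance`. When a
#' prescription schedule is supplied (tibble `date`, `agreed_tib`), those
#' nights follow the prescription and sleep efficiency consolidates weekly:
#' each restriction week closes `responsiveness` of the remaining gap to
#' `se_target`. A fixed seed reproduces the stream bit for bit.
#'
#' @param profile A `sleeper_profile`.
#' @param weeks Number of weeks to simulate.
#' @param start_date First diary date.
#' @param prescriptions Optional tibble (`date`, `agreed_tib`).
#' @param seed Integer seed.
#' @return A validated `sleep_diary` tibble.
#' @export
simulate_diary <- function(profile, weeks = 7, start_date = "2024-01-02",
                           prescriptions = NULL, seed = 1) {
  start_date <- as.Date(start_date)
  if (!is.null(prescriptions)) {
    prescriptions$date <- as.Date(prescriptions$date)
  }
  withr::with_seed(seed, {
    rows <- list()
    current_se <- profile$baseline_se
    restriction_weeks <- 0L
    for (day in seq_len(weeks * 7L)) {
      date <- start_date + day - 1L
      rx <- if (!is.null(prescriptions)) {
        i <- match(date, prescriptions$date)
        if (is.na(i)) NULL else prescriptions$agreed_tib[i]
      }
      if (!is.null(rx) && (day - 1L) %% 7L == 0L) {
        restriction_weeks <- restriction_weeks + 1L
        if (restriction_weeks > 1L) {
          current_se <- current_se +
            profile$responsiveness * (profile$se_target - current_se)
        }
      }
      filled <- runif(1) < profile$diary_compliance
      night <- simulate_night(profile, date, prescription = rx,
                              current_se = if (is.null(rx))
                                profile$baseline_se else current_se)
      if (filled) rows[[length(rows) + 1L]] <- night
    }
    if (!length(rows)) empty_diary() else
      validate_diary(dplyr::bind_rows(rows))
  })
}

#' Default trial outcome configuration
#'
#' One row per outcome with its baseline mean and SD (anchored to typical
#' baseline values for a mild-insomnia sample), the direction of benefit,
#' the within-group time effect in raw units, and the targeted between-group
#' change-score effect size `d` (waitlist change minus app change over the
#' pooled change-score SD, with change = pre - post, so lower-is-better
#' scales get negative `d`).
#'
#' @param icc Intraclass correlation: share of baseline variance from the
#'   participant-level random intercept.
#' @return A tibble with columns `outcome`, `baseline_mean`, `baseline_sd`,
#'   `time_effect`, `d_between`, `icc`, `lo`, `hi` (admissible score range).
#' @export
trial_outcomes <- function(icc = 0.5) {
  tibble::tibble(
    outcome = c("isi", "psqi", "dbas", "cesd", "hads", "se"),
    baseline_mean = c(16.4, 10.8, 5.25, 15.75, 5.85, 77.3),
    baseline_sd = c(3.2, 2.8, 1.3, 5.9, 3.05, 7.75),
    time_effect = c(-3.0, -0.9, -0.35, 0.5, 0.4, 1.3),
    d_between = c(-0.66, -0.77, -0.15, -0.94, -0.75, 0.71),
    icc = icc,
    lo = c(0, 0, 0, 0, 0, 0),
    hi = c(28, 21, 10, 60, 21, 100))
}

#' Default missingness configuration
#'
#' Completion rates and MAR structure for the simulated trial: posttest
#' completion near 61% in the app arm and 81% in the waitlist arm, follow-up
#' completion near 39% (app only). Nonresponse depends on age, baseline sleep
#' quality, terminal wakefulness and number of awakenings, the covariates the
#' dropout analysis path adjusts for.
#'
#' @param post_rate_app,post_rate_wl,followup_rate_app Target completion
#'   probabilities.
#' @param mar_strength Log-odds slope per SD of each covariate.
#' @return A list of missingness parameters.
#' @export
trial_missingness <- function(post_rate_app = 45 / 74,
                              post_rate_wl = 62 / 77,
                              followup_rate_app = 29 / 74,
                              mar_strength = 0.3) {
  list(post_rate_app = post_rate_app, post_rate_wl = post_rate_wl,
       followup_rate_app = followup_rate_app, mar_strength = mar_strength)
}

#' Simulate a two-arm trial dataset
#'
#' Generates a long-format pre/post(/follow-up) dataset for an app vs
#' waitlist trial. Each participant has a random intercept (inducing the
#' pre-post correlation), pre scores drawn around the configured baseline
#' means, a common time effect, and an app-arm shift calibrated so the
#' between-group change-score Cohen d equals the configured `d_between`
#' exactly in expectation. Follow-up rows exist only for the app arm (the
#' waitlist received the intervention after the posttest). Missingness is
#' missing-at-random in the covariates via a logistic model.
#'
#' @param n_app,n_wl Participants per arm.
#' @param outcomes Outcome configuration tibble, see [trial_outcomes()].
#' @param missingness Missingness configuration, see [trial_missingness()];
#'   `NULL` disables missingness entirely.
#' @param followup Simulate follow-up rows for the app arm?
#' @param seed Integer seed; participants use independent substreams, so
#'   adding a participant does not perturb the others.
#' @return A `trial_dataset` list with `data` (tibble `participant`,
#'   `condition`, `time`, `outcome`, `value`) and `covariates` (tibble
#'   `participant`, `condition`, `age`, `sex`, `sleep_quality`, `twak`,
#'   `n_awakenings`).
#' @export
simulate_trial <- function(n_app = 74, n_wl = 77,
                           outcomes = trial_outcomes(),
                           missingness = trial_missingness(),
                           followup = TRUE, seed = 1) {
  n <- n_app + n_wl
  condition <- rep(c("app", "waitlist"), c(n_app, n_wl))
  ids <- sprintf("p%04d", seq_len(n))

  # flat accumulators; tibbles are assembled once at the end for speed
  age_v <- numeric(n); sex_v <- character(n); sq_v <- numeric(n)
  twak_v <- numeric(n); awak_v <- integer(n)
  time_l <- vector("list", n); out_l <- vector("list", n)
  val_l <- vector("list", n)
  oc <- as.list(outcomes)
  n_oc <- nrow(outcomes)
  for (i in seq_len(n)) {
    withr::with_seed(sub_seed(seed, i), {
      age_v[i] <- round_half_up(min(max(rnorm(1, 39.66, 13.44), 18), 80))
      sex_v[i] <- if (runif(1) < 0.623) "female" else "male"
      sq_v[i] <- min(max(rnorm(1, 2.95, 0.47), 1), 5)
      twak_v[i] <- rtnorm_pos(1, 36, 21)
      awak_v[i] <- rpois(1, 2.1)

      times <- character(0); outs <- character(0); vals_all <- numeric(0)
      for (j in seq_len(n_oc)) {
        sd_b <- oc$baseline_sd[j] * sqrt(oc$icc[j])
        sd_e <- oc$baseline_sd[j] * sqrt(1 - oc$icc[j])
        b <- rnorm(1, 0, sd_b)
        pre <- oc$baseline_mean[j] + b + rnorm(1, 0, sd_e)
        # interaction shift calibrated so the change-score d equals d_between
        delta_int <- oc$d_between[j] * sqrt(2) * sd_e
        shift <- oc$time_effect[j] +
          if (condition[i] == "app") delta_int else 0
        post <- oc$baseline_mean[j] + b + shift + rnorm(1, 0, sd_e)
        vals <- c(pre = pre, post = post)
        if (followup && condition[i] == "app") {
          vals <- c(vals, followup = oc$baseline_mean[j] + b + shift +
                      rnorm(1, 0, sd_e * 1.2))
        }
        vals <- pmin(pmax(vals, oc$lo[j]), oc$hi[j])
        times <- c(times, names(vals))
        outs <- c(outs, rep(oc$outcome[j], length(vals)))
        vals_all <- c(vals_all, unname(vals))
      }
      time_l[[i]] <- times; out_l[[i]] <- outs; val_l[[i]] <- vals_all
    })
  }
  covariates <- tibble::tibble(
    participant = ids, condition = condition, age = age_v, sex = sex_v,
    sleep_quality = sq_v, twak = twak_v, n_awakenings = awak_v)
  counts <- lengths(val_l)
  data <- tibble::tibble(
    participant = rep(ids, counts), condition = rep(condition, counts),
    time = unlist(time_l), outcome = unlist(out_l),
    value = unlist(val_l))

  if (!is.null(missingness)) {
    withr::with_seed(sub_seed(seed, n + 1L), {
      z <- scale(cbind(covariates$age, covariates$sleep_quality,
                       covariates$twak, covariates$n_awakenings))
      lin <- missingness$mar_strength * rowSums(z) / 2
      base_rate <- ifelse(covariates$condition == "app",
                          missingness$post_rate_app, missingness$post_rate_wl)
      p_post <- stats::plogis(stats::qlogis(base_rate) + lin)
      miss_post <- runif(n) > p_post
      p_fu <- stats::plogis(stats::qlogis(missingness$followup_rate_app) + lin)
      miss_fu <- runif(n) > p_fu
      drop_post <- covariates$participant[miss_post]
      drop_fu <- covariates$participant[miss_fu]
      keep <- !(data$time == "post" & data$participant %in% drop_post) &
        !(data$time == "followup" & data$participant %in% drop_fu)
      data <- data[keep, , drop = FALSE]
    })
  }
  structure(list(data = data, covariates = covariates,
                 outcomes = outcomes, seed = seed),
            class = "trial_dataset")
}
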