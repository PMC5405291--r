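# Treatment-adherence components: diaries filled, relaxation exercises,
# conversation completion, and deviation from the agreed time in bed, with
# the per-component adequate-dose flags.

#' Mean deviation from the agreed time in bed
#'
#' Averages, over the nights with an active restriction agreement, the
#' absolute difference between the actual and the agreed time in bed.
#' Overstay (longer in bed than agreed) and understay means are reported
#' separately as well. Nights without an agreement are excluded; with no
#' restriction nights at all the deviation is absent (`NA`), not zero.
#'
#' @param entries A validated `sleep_diary` tibble.
#' @param agreed_tib_by_date Tibble with columns `date` and `agreed_tib`
#'   giving the prescription active on each night.
#' @return A one-row tibble: `n_nights`, `mean_deviation`, `mean_overstay`,
#'   `mean_understay` (minutes; `NA` where undefined).
#' @export
restriction_deviation <- function(entries, agreed_tib_by_date) {
  agreed_tib_by_date$date <- as.Date(agreed_tib_by_date$date)
  if (!"tib" %in% names(entries) && nrow(entries) > 0) {
    entries <- add_night_metrics(entries)
  }
  m <- dplyr::inner_join(
    entries[, c("date", "tib"), drop = FALSE], agreed_tib_by_date,
    by = "date")
  m <- m[is.finite(m$agreed_tib), , drop = FALSE]
  if (nrow(m) == 0) {
    return(tibble::tibble(n_nights = 0L, mean_deviation = NA_real_,
                          mean_overstay = NA_real_,
                          mean_understay = NA_real_))
  }
  dev <- m$tib - m$agreed_tib
  tibble::tibble(
    n_nights = nrow(m),
    mean_deviation = mean(abs(dev)),
    mean_overstay = if (any(dev > 0)) mean(dev[dev > 0]) else NA_real_,
    mean_understay = if (any(dev < 0)) mean(-dev[dev < 0]) else NA_real_)
}

#' Adherence report with adequate-dose flags
#'
#' Builds the four-component adherence report. A component counts as an
#' adequate dose under strict thresholds: more than 35 diaries, more than 35
#' relaxation exercises, more than 90% of conversations completed, and a mean
#' deviation from the agreed time in bed of strictly less than 60 minutes.
#' Exactly 35 diaries, exactly 90.0% completion, or a deviation of exactly
#' 60.0 minutes are all inadequate.
#'
#' @param n_diaries Number of sleep diaries filled out.
#' @param n_relaxations Number of relaxation exercises performed.
#' @param conversation_completion Percent of scheduled conversations
#'   finished, in [0, 100].
#' @param restriction_deviation Mean absolute deviation from the agreed time
#'   in bed in minutes, or `NA` when restriction was never agreed.
#' @return An `adherence_report` list with the component values and an
#'   `adequate` named logical vector (`NA` for an absent deviation).
#' @export
adherence_report <- function(n_diaries, n_relaxations,
                             conversation_completion,
                             restriction_deviation = NA_real_) {
  stopifnot(conversation_completion >= 0, conversation_completion <= 100,
            is.na(restriction_deviation) || restriction_deviation >= 0)
  structure(list(
    n_diaries = n_diaries,
    n_relaxations = n_relaxations,
    conversation_completion = conversation_completion,
    restriction_deviation = restriction_deviation,
    adequate = c(diaries = n_diaries > 35,
                 relaxations = n_relaxations > 35,
                 conversations = conversation_completion > 90,
                 restriction = if (is.na(restriction_deviation)) NA else
                   restriction_deviation < 60)
  ), class = "adherence_report")
}

#' Adherence report from engine state
#'
#' Derives the four components from a `program_state`: diary and relaxation
#' counts from their logs, conversation completion as finished over
#' scheduled-to-date, and the restriction deviation over nights with an
#' active agreement reconstructed from the titration history.
#'
#' @param state A `program_state`.
#' @return An `adherence_report`.
#' @export
adherence_from_state <- function(state) {
  cv <- state$conversations
  completion <- if (nrow(cv)) 100 * mean(cv$finished) else 100
  dev <- restriction_deviation(state$diary, agreed_schedule(state))
  adherence_report(
    n_diaries = nrow(state$diary),
    n_relaxations = nrow(state$relaxation_log),
    conversation_completion = completion,
    restriction_deviation = dev$mean_deviation)
}

# internal: the engine logs the prescription active for each night (keyed by
# the diary report date, i.e. the morning after) as it advances
agreed_schedule <- function(state) {
  state$prescription_log %||%
    tibble::tibble(date = as.Date(character()), agreed_tib = numeric())
}

#' @export
print.adherence_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else format(round(v, 1))
  flag <- function(a) if (is.na(a)) "n/a" else if (a) "adequate" else
    "inadequate"
  cat("Treatment adherence\n")
  cat(sprintf("  %-34s %8s  %s\n", "Component", "Value", "Adequate dose"))
  cat(sprintf("  %-34s %8s  %s\n", "Diaries filled out (>35)",
              fmt(x$n_diaries), flag(x$adequate["diaries"])))
  cat(sprintf("  %-34s %8s  %s\n", "Relaxation exercises (>35)",
              fmt(x$n_relaxations), flag(x$adequate["relaxations"])))
  cat(sprintf("  %-34s %8s  %s\n", "Conversations completed, % (>90)",
              fmt(x$conversation_completion), flag(x$adequate["conversations"])))
  cat(sprintf("  %-34s %8s  %s\n", "Restriction deviation, min (<60)",
              fmt(x$restriction_deviation), flag(x$adequate["restriction"])))
  invisible(x)
}
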