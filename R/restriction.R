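# Modified sleep-restriction coach: eligibility, ideal/maximum time-in-bed
# proposal, upward-only negotiation, 15-minute weekly titration, and the
# short-sleep safety monitor.

TIB_FLOOR <- 300    # advised time in bed is never below 5 hours
SE_THRESHOLD <- 85  # titration / eligibility sleep-efficiency cutoff, percent
SAFETY_TST <- 300   # mean TST below 5 h over 5 nights triggers a warning

#' Create a fresh restriction state
#'
#' @return A `restriction_state` list: `status` (one of `not_started`,
#'   `proposed`, `agreed`, `declined`, `stopped_safety`), `agreed_tib`
#'   (minutes, `NA` unless agreed), `week_index`, `titration_history`
#'   (tibble of week/SE/decision/new TIB), `warning_level` (0, 1, 2),
#'   `proposal`, and the date of the last safety warning.
#' @export
restriction_state <- function() {
  structure(list(
    status = "not_started",
    agreed_tib = NA_real_,
    week_index = 0L,
    titration_history = tibble::tibble(week = integer(), se = numeric(),
                                       decision = character(),
                                       new_tib = numeric()),
    warning_level = 0L,
    proposal = NULL,
    last_warning_date = NA_character_
  ), class = "restriction_state")
}

#' Check eligibility for sleep restriction
#'
#' After the baseline diary week, restriction is introduced only for
#' participants who filled at least 6 diaries and whose average sleep
#' efficiency is strictly below 85%.
#'
#' @param summary A one-row window summary from [summarize_window()].
#' @return A list with `eligible` (logical) and `reason` (`"ok"`,
#'   `"too_few_diaries"`, or `"se_not_below_85"`).
#' @export
check_eligibility <- function(summary) {
  if (summary$n_entries < 6) {
    list(eligible = FALSE, reason = "too_few_diaries")
  } else if (!(summary$mean_se < SE_THRESHOLD)) {
    list(eligible = FALSE, reason = "se_not_below_85")
  } else {
    list(eligible = TRUE, reason = "ok")
  }
}

#' Compute the ideal and maximum time-in-bed proposal
#'
#' The ideal time in bed equals the past week's average total sleep time
#' (the classical sleep-restriction prescription), floored at 5 hours; the
#' maximum negotiable time in bed is the average time in bed minus one hour,
#' clamped up to the ideal so the negotiation window never inverts. Both are
#' whole minutes (half-up rounding).
#'
#' @param summary A one-row window summary from [summarize_window()].
#' @return A `restriction_proposal` list: `ideal_tib`, `max_tib`, `basis`.
#' @examples
#' wk <- tibble::tibble(n_entries = 7L, mean_tib = 506, mean_tst = 393,
#'                      mean_sol = 33, mean_waso = 45, mean_twak = 35,
#'                      mean_se = 77.7, mean_quality = 4, mean_awakenings = 2)
#' compute_proposal(wk)
#' @export
compute_proposal <- function(summary) {
  if (!is.finite(summary$mean_tib) || summary$mean_tib <= 0) {
    abort("cannot propose restriction: non-positive mean time in bed")
  }
  ideal <- max(round_half_up(summary$mean_tst), TIB_FLOOR)
  maxt <- max(round_half_up(summary$mean_tib) - 60, ideal)
  structure(list(ideal_tib = as.numeric(ideal), max_tib = as.numeric(maxt),
                 basis = summary),
            class = "restriction_proposal")
}

#' Negotiate a restriction proposal
#'
#' The coach first suggests the ideal time in bed. The participant may accept
#' it, negotiate a longer time in bed up to the calculated maximum, or opt out
#' of sleep restriction entirely. Negotiation is upward only: requests below
#' the ideal are refused, and requests above the maximum receive a
#' counter-offer at the maximum rather than an error.
#'
#' @param proposal A `restriction_proposal` from [compute_proposal()].
#' @param request `"accept"`, `"opt_out"`, or a number of minutes.
#' @param state Optional existing `restriction_state` to update.
#' @return An updated `restriction_state`; when a request is refused the
#'   status stays `"proposed"` and `counter_offer` holds the restated bound.
#' @export
negotiate <- function(proposal, request, state = restriction_state()) {
  stopifnot(inherits(proposal, "restriction_proposal"))
  state$proposal <- proposal
  state$counter_offer <- NULL
  if (identical(request, "accept")) {
    state$status <- "agreed"
    state$agreed_tib <- proposal$ideal_tib
  } else if (identical(request, "opt_out")) {
    state$status <- "declined"
    state$agreed_tib <- NA_real_
  } else if (is.numeric(request) && length(request) == 1) {
    if (request > proposal$max_tib) {
      state$status <- "proposed"
      state$counter_offer <- proposal$max_tib
      state$agreed_tib <- NA_real_
    } else if (request < proposal$ideal_tib) {
      state$status <- "proposed"
      state$counter_offer <- proposal$ideal_tib
      state$agreed_tib <- NA_real_
    } else {
      state$status <- "agreed"
      state$agreed_tib <- as.numeric(round_half_up(request))
    }
  } else {
    abort("request must be \"accept\", \"opt_out\", or minutes")
  }
  if (state$status == "agreed") state$week_index <- max(state$week_index, 1L)
  state
}

#' Weekly titration of the agreed time in bed
#'
#' At each weekly evaluation: sleep efficiency above 85% earns 15 minutes
#' extra in bed; below 85% the prescription is tightened by 15 minutes when
#' the participant adhered to the current window (mean nightly deviation under
#' an hour), and left unchanged otherwise; exactly 85% leaves it unchanged
#' (both conditions are strict). The agreed time never drops below
#' the 5-hour floor. The decision is appended to the titration history.
#'
#' @param state A `restriction_state` with status `"agreed"`.
#' @param weekly_se Average sleep efficiency over the past week, percent.
#' @param adherent Logical: did the participant follow the prescription?
#' @return The updated `restriction_state`.
#' @export
weekly_titration <- function(state, weekly_se, adherent) {
  if (!identical(state$status, "agreed")) {
    abort("titration requires an agreed restriction")
  }
  old <- state$agreed_tib
  if (weekly_se > SE_THRESHOLD) {
    new <- old + 15
    decision <- "extend"
  } else if (weekly_se < SE_THRESHOLD && isTRUE(adherent)) {
    new <- max(old - 15, TIB_FLOOR)
    decision <- "restrict"
  } else {
    new <- old
    decision <- "hold"
  }
  state$week_index <- state$week_index + 1L
  state$agreed_tib <- new
  state$titration_history <- dplyr::bind_rows(
    state$titration_history,
    tibble::tibble(week = state$week_index, se = as.numeric(weekly_se),
                   decision = decision, new_tib = new))
  state
}

#' Short-sleep safety monitor
#'
#' Watches the trailing five reported nights (missing diaries do not count).
#' When their mean total sleep time falls strictly below 5 hours, a first
#' warning against sleepiness-sensitive activities (e.g. driving) is issued;
#' if a fresh five-night window after that warning is still below 5 hours the
#' monitor escalates to a general-practitioner referral and stops the sleep
#' restriction exercise. Recovery above the threshold resets the window but
#' never lowers the warning level.
#'
#' @param entries A validated `sleep_diary` tibble, ordered by date.
#' @param state A `restriction_state`.
#' @return A list with the updated `state` and `warnings`, a tibble of
#'   structured warning records (`level`, `code`, `text`).
#' @export
safety_monitor <- function(entries, state) {
  warnings <- tibble::tibble(level = integer(), code = character(),
                             text = character())
  if (nrow(entries) >= 5) {
    entries <- entries[order(entries$date), , drop = FALSE]
    last5 <- tail(entries, 5)
    if (mean(last5$tst) < SAFETY_TST) {
      if (state$warning_level == 0L) {
        state$warning_level <- 1L
        state$last_warning_date <- format(max(last5$date))
        warnings <- dplyr::bind_rows(warnings, tibble::tibble(
          level = 1L, code = "short_sleep_warning",
          text = "Average sleep below 5 hours: beware of sleepiness during activities such as driving."))
      } else if (state$warning_level == 1L &&
                 all(last5$date > as.Date(state$last_warning_date))) {
        state$warning_level <- 2L
        state$last_warning_date <- format(max(last5$date))
        state$status <- "stopped_safety"
        state$agreed_tib <- NA_real_
        warnings <- dplyr::bind_rows(warnings, tibble::tibble(
          level = 2L, code = "gp_referral_stop",
          text = "Average sleep still below 5 hours: please consult your general practitioner. Sleep restriction has been stopped."))
      }
    }
  }
  list(state = state, warnings = warnings)
}
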