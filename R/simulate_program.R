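#' Simulate a full coached program for one synthetic participant
#'
#' Couples the synthetic sleeper to the protocol engine: each day the
#' previous night is generated from the profile — following the engine's
#' currently agreed time in bed when restriction is active, with the
#' profile's overstay/understay behavior — the diary is filled with the
#' profile's compliance probability, relaxation exercises occur at the
#' profile's weekly rate, and queued conversations are finished the day they
#' appear (restriction introductions are answered with `negotiation`).
#' Sleep efficiency consolidates weekly under restriction: each week under
#' an agreement closes `responsiveness` of the remaining gap to the
#' profile's target. Fully deterministic given the seed.
#'
#' @param profile A `sleeper_profile`.
#' @param start_date Program start date.
#' @param negotiation Reply to the restriction introduction (`"accept"`,
#'   minutes, or `"opt_out"`).
#' @param seed Integer seed.
#' @return A list: final `state`, `events`, and the `diary` actually
#'   generated (including unreported nights).
#' @export
simulate_program <- function(profile, start_date = "2024-01-01",
                             negotiation = "accept", seed = 1) {
  withr::with_seed(seed, {
    state <- program_new(start_date)
    date <- as.Date(start_date)
    events <- NULL
    all_nights <- list()
    current_se <- profile$baseline_se
    nights_under_rx <- 0L
    while (identical(state$status, "active")) {
      # last night's prescription, as logged by the engine
      sched <- agreed_schedule(state)
      i <- match(date, sched$date)
      rx <- if (is.na(i)) NULL else sched$agreed_tib[i]
      if (!is.null(rx)) {
        nights_under_rx <- nights_under_rx + 1L
        if (nights_under_rx %% 7L == 0L) {
          current_se <- current_se +
            profile$responsiveness * (profile$se_target - current_se)
        }
      }
      night <- if (date > as.Date(start_date)) {
        simulate_night(profile, date, prescription = rx,
                       current_se = if (is.null(rx)) profile$baseline_se
                       else current_se)
      }
      if (!is.null(night)) all_nights[[length(all_nights) + 1L]] <- night
      filled <- !is.null(night) && runif(1) < profile$diary_compliance
      acts <- list()
      if (runif(1) < profile$relaxation_rate / 7) {
        acts$relaxation <- sample(1:16, 1)
      }
      pend <- state$conversations[!state$conversations$finished, ,
                                  drop = FALSE]
      if (nrow(pend)) {
        acts$finish <- list(
          id = pend$id[1],
          outcome = if (pend$type[1] == "restriction_introduction")
            list(negotiation = negotiation))
      }
      step <- advance_day(state, date,
                          entries = if (filled) night,
                          actions = acts)
      state <- step$state
      events <- dplyr::bind_rows(events, step$events)
      date <- date + 1L
    }
    diary <- if (length(all_nights)) {
      validate_diary(dplyr::bind_rows(all_nights))
    } else empty_diary()
    list(state = state, events = events, diary = diary)
  })
}
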