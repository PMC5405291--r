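# Protocol state machine for the 6-7 week coaching program: schedules the
# baseline diary week, introduces (or postpones) sleep restriction, runs
# weekly evaluations with titration, fires the relaxation-adherence
# conversation, gates conversations to one open at a time, and issues noon
# reminders. The engine is a deterministic pure fold over a dated event
# stream: the clock is injected, nothing reads wall time.

BASE_PROGRAM_DAYS <- 42L  # 6 weeks; postponement may extend up to 49

#' Create a fresh program state
#'
#' @param start_date Program start date (`Date` or ISO string). Day 1 of the
#'   protocol falls on this date.
#' @return A `program_state` list holding the diary log, relaxation log,
#'   conversation queue, restriction state, and scheduling bookkeeping.
#' @export
program_new <- function(start_date) {
  structure(list(
    start_date = as.Date(start_date),
    day_index = 0L,
    status = "active",
    diary = empty_diary(),
    relaxation_log = tibble::tibble(date = as.Date(character()),
                                    duration = numeric()),
    relaxation_intro_date = NA_character_,
    relaxation_trigger_checked = FALSE,
    conversations = tibble::tibble(id = character(), type = character(),
                                   scheduled_date = character(),
                                   opened = logical(), finished = logical(),
                                   outcome = character()),
    restriction = restriction_state(),
    prescription_log = tibble::tibble(date = as.Date(character()),
                                      agreed_tib = numeric()),
    introduction_pending = FALSE,
    restriction_intro_day = NA_integer_,
    postponement_days = 0L,
    last_reminder_date = NA_character_,
    last_eligibility = NA_character_,
    conv_counter = 0L
  ), class = "program_state")
}

# internal: queue a conversation of a given type on a given date
queue_conversation <- function(state, type, date) {
  state$conv_counter <- state$conv_counter + 1L
  state$conversations <- dplyr::bind_rows(
    state$conversations,
    tibble::tibble(id = sprintf("c%03d_%s", state$conv_counter, type),
                   type = type, scheduled_date = format(as.Date(date)),
                   opened = FALSE, finished = FALSE, outcome = NA_character_))
  state
}

# internal: event record constructor
event <- function(date, code, payload = NULL) {
  tibble::tibble(date = format(as.Date(date)), code = code,
                 payload = if (is.null(payload)) NA_character_ else
                   as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                                 digits = NA)))
}

no_events <- function() {
  tibble::tibble(date = character(), code = character(), payload = character())
}

#' Advance the program by one day
#'
#' Processes one protocol day: logs the morning's diary entry and any
#' relaxation exercises or conversation actions, then applies the scheduled
#' protocol logic — restriction introduction after the baseline week (or its
#' postponement until 6 diaries exist), weekly evaluations with titration,
#' the relaxation-adherence trigger, the short-sleep safety monitor, and
#' program completion. Deterministic given its inputs.
#'
#' @param state A `program_state`.
#' @param date The calendar date being processed; must be exactly one day
#'   after the last processed date (monotone clock).
#' @param entries Optional `sleep_diary` rows reported this morning (the
#'   previous night); must not be future-dated.
#' @param actions Optional named list: `relaxation` (numeric vector of
#'   exercise durations in minutes, 1--16), `open` (conversation id),
#'   `finish` (list with `id` and optional `outcome`, e.g.
#'   `list(negotiation = "accept")`).
#' @return A list with the updated `state` and `events`, a tibble of
#'   structured records (`date`, `code`, JSON `payload`).
#' @export
advance_day <- function(state, date, entries = NULL, actions = list()) {
  stopifnot(inherits(state, "program_state"))
  date <- as.Date(date)
  expected <- state$start_date + state$day_index
  if (date != expected) {
    abort(paste0("out-of-order date: expected ", format(expected),
                 ", got ", format(date)))
  }
  if (!identical(state$status, "active")) {
    abort("program is not active")
  }
  d <- state$day_index + 1L
  events <- no_events()

  # --- intake: diary, relaxation, conversation actions -----------------
  if (!is.null(entries) && nrow(entries) > 0) {
    entries <- validate_diary(entries, today = date)
    state$diary <- validate_diary(dplyr::bind_rows(state$diary, entries))
    events <- dplyr::bind_rows(events,
      event(date, "diary_logged", list(n = nrow(entries))))
  }
  for (dur in actions$relaxation %||% numeric()) {
    if (dur < 1 || dur > 16) abort("relaxation duration must be 1-16 minutes")
    state$relaxation_log <- dplyr::bind_rows(
      state$relaxation_log, tibble::tibble(date = date, duration = dur))
    events <- dplyr::bind_rows(events,
      event(date, "relaxation_done", list(duration = dur)))
  }
  if (!is.null(actions$open)) {
    state <- open_conversation(state, actions$open)
    events <- dplyr::bind_rows(events,
      event(date, "conversation_opened", list(id = actions$open)))
  }
  if (!is.null(actions$finish)) {
    res <- finish_conversation(state, actions$finish$id,
                               actions$finish$outcome)
    state <- res$state
    events <- dplyr::bind_rows(events, res$events,
      event(date, "conversation_finished", list(id = actions$finish$id)))
  }

  # --- day-1 setup: diary + relaxation introduced ----------------------
  if (d == 1L) {
    state$relaxation_intro_date <- format(date)
    state <- queue_conversation(state, "welcome", date)
    events <- dplyr::bind_rows(events, event(date, "program_started"))
  }

  # --- relaxation adherence trigger, once, 4 days after introduction ---
  if (!state$relaxation_trigger_checked &&
      !is.na(state$relaxation_intro_date) &&
      date == as.Date(state$relaxation_intro_date) + 4L) {
    state$relaxation_trigger_checked <- TRUE
    if (relaxation_adherence_check(state$relaxation_log,
                                   as.Date(state$relaxation_intro_date),
                                   date)) {
      state <- queue_conversation(state, "relaxation_adherence", date)
      events <- dplyr::bind_rows(events,
        event(date, "relaxation_adherence_conversation"))
    }
  }

  # --- restriction introduction after the baseline week ----------------
  n_diaries <- nrow(state$diary)
  if (d == 7L && state$restriction$status == "not_started") {
    if (n_diaries >= 6) {
      state <- maybe_introduce_restriction(state, date)
      events <- dplyr::bind_rows(events,
        restriction_intro_events(state, date))
    } else {
      state$introduction_pending <- TRUE
      events <- dplyr::bind_rows(events,
        event(date, "restriction_postponed", list(n_diaries = n_diaries)))
    }
  }
  if (state$introduction_pending && d > 7L && n_diaries >= 6) {
    state$introduction_pending <- FALSE
    state$postponement_days <- min(d - 7L, 7L)
    state <- maybe_introduce_restriction(state, date)
    events <- dplyr::bind_rows(events, restriction_intro_events(state, date))
  }

  # --- weekly evaluation + titration -----------------------------------
  if (d %% 7L == 0L) {
    wk <- summarize_window(state$diary, window_days = 7, end_date = date)
    events <- dplyr::bind_rows(events,
      event(date, "weekly_evaluation",
            list(n_entries = wk$n_entries, mean_se = wk$mean_se)))
    if (state$restriction$status == "agreed" && d > 7L && wk$n_entries > 0) {
      week_entries <- state$diary[state$diary$date > date - 7L &
                                    state$diary$date <= date, , drop = FALSE]
      dev <- restriction_deviation(week_entries, agreed_schedule(state))
      adherent <- is.finite(dev$mean_deviation) && dev$mean_deviation < 60
      state$restriction <- weekly_titration(state$restriction, wk$mean_se,
                                            adherent)
      last <- tail(state$restriction$titration_history, 1)
      events <- dplyr::bind_rows(events,
        event(date, "titration", list(decision = last$decision,
                                      agreed_tib = last$new_tib,
                                      weekly_se = wk$mean_se,
                                      adherent = adherent)))
    }
  }

  # --- daily safety monitor --------------------------------------------
  if (nrow(state$diary) >= 5) {
    sm <- safety_monitor(state$diary, state$restriction)
    state$restriction <- sm$state
    if (nrow(sm$warnings)) {
      for (i in seq_len(nrow(sm$warnings))) {
        events <- dplyr::bind_rows(events,
          event(date, "safety_warning",
                list(level = sm$warnings$level[i],
                     code = sm$warnings$code[i],
                     text = sm$warnings$text[i])))
      }
    }
  }

  # --- log tonight's prescription (reported in tomorrow's diary) --------
  if (state$restriction$status == "agreed") {
    state$prescription_log <- dplyr::bind_rows(
      state$prescription_log,
      tibble::tibble(date = date + 1L,
                     agreed_tib = state$restriction$agreed_tib))
  }

  # --- completion -------------------------------------------------------
  total_days <- min(BASE_PROGRAM_DAYS + state$postponement_days +
                      (if (state$introduction_pending) 7L else 0L), 49L)
  state$day_index <- d
  if (d >= total_days) {
    state$status <- "finished"
    events <- dplyr::bind_rows(events, event(date, "program_finished"))
  }
  list(state = state, events = events)
}

# internal: compute eligibility + proposal and queue the introduction
maybe_introduce_restriction <- function(state, date) {
  # baseline summary over the most recent (up to) 7 reported nights, so a
  # postponed introduction fires the day the 6th diary arrives even when the
  # reports straddle more than 7 calendar days
  base <- state$diary[order(state$diary$date), , drop = FALSE]
  base <- utils::tail(base, 7L)
  span <- if (nrow(base)) as.integer(date - min(base$date)) + 1L else 7L
  wk <- summarize_window(base, window_days = max(span, 7L), end_date = date)
  elig <- check_eligibility(wk)
  if (elig$eligible) {
    state$restriction$status <- "proposed"
    state$restriction$proposal <- compute_proposal(wk)
    state <- queue_conversation(state, "restriction_introduction", date)
  } else {
    state$restriction$status <- "declined"
  }
  state$last_eligibility <- elig$reason
  state
}

restriction_intro_events <- function(state, date) {
  if (identical(state$last_eligibility, "ok")) {
    p <- state$restriction$proposal
    event(date, "restriction_introduced",
          list(ideal_tib = p$ideal_tib, max_tib = p$max_tib))
  } else {
    event(date, "restriction_not_indicated",
          list(reason = state$last_eligibility))
  }
}

#' Relaxation adherence trigger
#'
#' An adherence conversation starts when the relaxation exercise was done
#' fewer than 3 times within 4 days of its introduction. The trigger is
#' evaluated exactly once, on the fourth day after the introduction; before
#' that the window has not elapsed.
#'
#' @param relaxation_log Tibble with a `date` column of performed exercises.
#' @param introduction_date Date the exercise was introduced.
#' @param today Current engine date.
#' @return `TRUE` if the adherence conversation should start today.
#' @export
relaxation_adherence_check <- function(relaxation_log, introduction_date,
                                       today) {
  introduction_date <- as.Date(introduction_date)
  today <- as.Date(today)
  stopifnot(introduction_date <= today)
  if (today != introduction_date + 4L) return(FALSE)
  n <- sum(relaxation_log$date > introduction_date &
             relaxation_log$date <= introduction_date + 4L)
  n < 3
}

#' Noon reminders for unfinished conversations
#'
#' One reminder per unfinished conversation when the injected clock crosses
#' 12:00 local time; idempotent within a day (a second query the same day
#' emits nothing). Scheduled conversations that are already finished are
#' silent.
#'
#' @param state A `program_state`.
#' @param now Current date-time (`POSIXct` or `"YYYY-MM-DD HH:MM"` string).
#' @return A list with the updated `state` (reminder bookkeeping) and
#'   `notifications`, a tibble (`conversation_id`, `type`, `text`).
#' @export
reminders <- function(state, now) {
  if (is.character(now)) now <- as.POSIXct(now, tz = "UTC")
  today <- format(as.Date(now))
  hour <- as.integer(format(now, "%H"))
  notifications <- tibble::tibble(conversation_id = character(),
                                  type = character(), text = character())
  if (hour >= 12 &&
      (is.na(state$last_reminder_date) || state$last_reminder_date < today)) {
    open <- state$conversations[!state$conversations$finished, , drop = FALSE]
    if (nrow(open)) {
      notifications <- tibble::tibble(
        conversation_id = open$id, type = "conversation_reminder",
        text = paste0("You have an unfinished conversation: ", open$type))
      state$last_reminder_date <- today
    }
  }
  list(state = state, notifications = notifications)
}

#' Open and finish conversations
#'
#' Conversations are gated: a new one can be opened only after the previous
#' conversation is finished. Finishing a restriction-introduction
#' conversation applies its negotiation outcome (`"accept"`, minutes, or
#' `"opt_out"`) to the restriction state.
#'
#' @param state A `program_state`.
#' @param conversation_id Id of a queued conversation.
#' @param outcome Optional structured outcome; for a restriction
#'   introduction, a list with element `negotiation`.
#' @return `open_conversation()` returns the updated state (or aborts when
#'   another conversation is open); `finish_conversation()` returns a list
#'   with `state` and `events`.
#' @export
open_conversation <- function(state, conversation_id) {
  cv <- state$conversations
  if (any(cv$opened & !cv$finished)) {
    abort(paste0("cannot open \"", conversation_id, "\": conversation \"",
                 cv$id[cv$opened & !cv$finished][1], "\" is still open"))
  }
  i <- match(conversation_id, cv$id)
  if (is.na(i)) abort(paste0("unknown conversation: ", conversation_id))
  if (cv$finished[i]) abort("conversation already finished")
  state$conversations$opened[i] <- TRUE
  state
}

#' @rdname open_conversation
#' @export
finish_conversation <- function(state, conversation_id, outcome = NULL) {
  cv <- state$conversations
  i <- match(conversation_id, cv$id)
  if (is.na(i)) abort(paste0("unknown conversation: ", conversation_id))
  state$conversations$finished[i] <- TRUE
  state$conversations$opened[i] <- TRUE
  events <- no_events()
  if (!is.null(outcome)) {
    state$conversations$outcome[i] <-
      as.character(jsonlite::toJSON(outcome, auto_unbox = TRUE, digits = NA))
    if (cv$type[i] == "restriction_introduction" &&
        !is.null(outcome$negotiation)) {
      state$restriction <- negotiate(state$restriction$proposal,
                                     outcome$negotiation, state$restriction)
      events <- event(cv$scheduled_date[i], "negotiation_result",
                      list(status = state$restriction$status,
                           agreed_tib = state$restriction$agreed_tib,
                           counter_offer = state$restriction$counter_offer))
    }
  }
  list(state = state, events = events)
}

#' Run the engine over a dated event stream
#'
#' Folds [advance_day()] over consecutive days. The stream is a list of
#' per-day inputs (`date`, optional `entries`, optional `actions`); days
#' absent from the stream are processed with empty inputs. Same stream, same
#' final state and event log.
#'
#' @param state A `program_state`.
#' @param stream List of per-day input lists, each with a `date` element.
#' @param until Last date to process; defaults to the last stream date.
#' @return A list with the final `state` and the concatenated `events`.
#' @export
run_program <- function(state, stream = list(), until = NULL) {
  by_date <- list()
  for (s in stream) by_date[[format(as.Date(s$date))]] <- s
  last <- as.Date(until %||% (if (length(stream))
    max(vapply(stream, function(s) format(as.Date(s$date)), character(1)))
    else state$start_date + BASE_PROGRAM_DAYS - 1L))
  events <- no_events()
  date <- state$start_date + state$day_index
  while (date <= last && identical(state$status, "active")) {
    s <- by_date[[format(date)]] %||% list()
    step <- advance_day(state, date, entries = s$entries,
                        actions = s$actions %||% list())
    state <- step$state
    events <- dplyr::bind_rows(events, step$events)
    date <- date + 1L
  }
  list(state = state, events = events)
}
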