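# JSON (de)serialization of engine state. Round-tripping mid-run and
# resuming must reproduce an uninterrupted run exactly, so every field is
# written with full precision and rebuilt with its original type.

#' Serialize and restore program state
#'
#' `program_state_to_json()` writes a `program_state` as a JSON string;
#' `program_state_from_json()` rebuilds it. Serializing mid-stream and
#' resuming yields the same final state as an uninterrupted run.
#'
#' @param state A `program_state`.
#' @param txt JSON text produced by `program_state_to_json()`.
#' @param path Optional file path to write to / read from.
#' @return A JSON string (invisibly, when `path` is given) or a
#'   `program_state`.
#' @export
program_state_to_json <- function(state, path = NULL) {
  rs <- state$restriction
  obj <- list(
    start_date = format(state$start_date),
    day_index = state$day_index,
    status = state$status,
    diary = jsonlite::fromJSON(diary_to_json(state$diary),
                               simplifyVector = FALSE),
    relaxation_log = list(date = format(state$relaxation_log$date),
                          duration = state$relaxation_log$duration),
    relaxation_intro_date = state$relaxation_intro_date,
    relaxation_trigger_checked = state$relaxation_trigger_checked,
    conversations = as.list(state$conversations),
    restriction = list(
      status = rs$status,
      agreed_tib = rs$agreed_tib,
      week_index = rs$week_index,
      titration_history = as.list(rs$titration_history),
      warning_level = rs$warning_level,
      last_warning_date = rs$last_warning_date,
      counter_offer = rs$counter_offer,
      proposal = if (is.null(rs$proposal)) NULL else list(
        ideal_tib = rs$proposal$ideal_tib,
        max_tib = rs$proposal$max_tib,
        basis = as.list(rs$proposal$basis))
    ),
    prescription_log = list(date = format(state$prescription_log$date),
                            agreed_tib = state$prescription_log$agreed_tib),
    introduction_pending = state$introduction_pending,
    restriction_intro_day = state$restriction_intro_day,
    postponement_days = state$postponement_days,
    last_reminder_date = state$last_reminder_date,
    last_eligibility = state$last_eligibility,
    conv_counter = state$conv_counter
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                          na = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname program_state_to_json
#' @export
program_state_from_json <- function(txt = NULL, path = NULL) {
  if (is.null(txt)) txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  o <- jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  num1 <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  state <- program_new(o$start_date)
  state$day_index <- as.integer(o$day_index)
  state$status <- o$status
  state$diary <- if (length(o$diary)) {
    diary_from_json(jsonlite::toJSON(o$diary, auto_unbox = TRUE, digits = NA))
  } else empty_diary()
  state$relaxation_log <- tibble::tibble(
    date = as.Date(unlist(o$relaxation_log$date) %||% character()),
    duration = as.numeric(unlist(o$relaxation_log$duration) %||% numeric()))
  state$relaxation_intro_date <- chr1(o$relaxation_intro_date)
  state$relaxation_trigger_checked <- isTRUE(o$relaxation_trigger_checked)
  conv_id <- as.character(unlist(o$conversations$id) %||% character())
  # an all-NA outcome column serializes as null (and a single NA unboxes to
  # null), so rebuild it to the row count implied by id
  conv_outcome <- if (is.null(o$conversations$outcome)) {
    rep(NA_character_, length(conv_id))
  } else {
    vapply(as.list(o$conversations$outcome), chr1, character(1))
  }
  state$conversations <- tibble::tibble(
    id = conv_id,
    type = as.character(unlist(o$conversations$type) %||% character()),
    scheduled_date = as.character(unlist(o$conversations$scheduled_date) %||%
                                    character()),
    opened = as.logical(unlist(o$conversations$opened) %||% logical()),
    finished = as.logical(unlist(o$conversations$finished) %||% logical()),
    outcome = conv_outcome)
  rs <- restriction_state()
  rs$status <- o$restriction$status
  rs$agreed_tib <- num1(o$restriction$agreed_tib)
  rs$week_index <- as.integer(o$restriction$week_index)
  rs$titration_history <- tibble::tibble(
    week = as.integer(unlist(o$restriction$titration_history$week) %||%
                        integer()),
    se = as.numeric(unlist(o$restriction$titration_history$se) %||% numeric()),
    decision = as.character(unlist(o$restriction$titration_history$decision)
                            %||% character()),
    new_tib = as.numeric(unlist(o$restriction$titration_history$new_tib) %||%
                           numeric()))
  rs$warning_level <- as.integer(o$restriction$warning_level)
  rs$last_warning_date <- chr1(o$restriction$last_warning_date)
  rs$counter_offer <- o$restriction$counter_offer
  if (!is.null(o$restriction$proposal)) {
    basis <- tibble::as_tibble(lapply(o$restriction$proposal$basis,
                                      function(x) x %||% NA_real_))
    basis$n_entries <- as.integer(basis$n_entries)
    rs$proposal <- structure(
      list(ideal_tib = num1(o$restriction$proposal$ideal_tib),
           max_tib = num1(o$restriction$proposal$max_tib),
           basis = basis),
      class = "restriction_proposal")
  }
  state$restriction <- rs
  state$prescription_log <- tibble::tibble(
    date = as.Date(unlist(o$prescription_log$date) %||% character()),
    agreed_tib = as.numeric(unlist(o$prescription_log$agreed_tib) %||%
                              numeric()))
  state$introduction_pending <- isTRUE(o$introduction_pending)
  state$restriction_intro_day <-
    if (is.null(o$restriction_intro_day)) NA_integer_ else
      as.integer(o$restriction_intro_day)
  state$postponement_days <- as.integer(o$postponement_days)
  state$last_reminder_date <- chr1(o$last_reminder_date)
  state$last_eligibility <- chr1(o$last_eligibility)
  state$conv_counter <- as.integer(o$conv_counter)
  state
}
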