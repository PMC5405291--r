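#' Parse and format clock times
#'
#' Diary clock times are stored as minutes-of-day (0--1439). `parse_clock()`
#' converts `"HH:MM"` strings; `format_clock()` is its inverse.
#'
#' @param x Character vector of `"HH:MM"` times (`parse_clock`) or integer
#'   minutes-of-day (`format_clock`).
#' @return Integer minutes-of-day, or a `"HH:MM"` character vector.
#' @examples
#' parse_clock("23:30")
#' format_clock(1410L)
#' @export
parse_clock <- function(x) {
  out <- rep(NA_integer_, length(x))
  ok <- grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x)
  hh <- as.integer(sub(":.*", "", x[ok]))
  mm <- as.integer(sub(".*:", "", x[ok]))
  out[ok] <- hh * 60L + mm
  if (any(!ok & !is.na(x))) {
    abort(paste0("unparseable clock time(s): ",
                 paste(unique(x[!ok & !is.na(x)]), collapse = ", ")))
  }
  out
}

#' @rdname parse_clock
#' @export
format_clock <- function(x) {
  sprintf("%02d:%02d", x %/% 60L, x %% 60L)
}

#' Time in bed for one night
#'
#' Time in bed is the span from going to bed to finally arising. Nights that
#' cross midnight are resolved by adding 24 h whenever the arising time does
#' not exceed the bed time, so a 23:30 bed time with a 07:00 arising time
#' yields 450 minutes while a 06:00 bed time with a 22:00 arising time is
#' taken as a same-day (daytime-sleeper) interval of 960 minutes.
#'
#' @param bed_time,arising_time Clock times in minutes-of-day (0--1439).
#' @return Time in bed in minutes, in (0, 1440].
#' @examples
#' time_in_bed(parse_clock("23:30"), parse_clock("07:00"))
#' @export
time_in_bed <- function(bed_time, arising_time) {
  stopifnot(all(bed_time >= 0 & bed_time <= 1439, na.rm = TRUE),
            all(arising_time >= 0 & arising_time <= 1439, na.rm = TRUE))
  if (any(bed_time == arising_time, na.rm = TRUE)) {
    abort("bed time equals arising time: zero-length night is unresolvable")
  }
  ifelse(arising_time < bed_time, arising_time + 1440L, arising_time) - bed_time
}

#' Total sleep time from its diary components
#'
#' Total sleep time is time in bed minus sleep-onset latency, wake after
#' sleep onset, and terminal wakefulness.
#'
#' @param tib Time in bed (minutes).
#' @param sol Sleep-onset latency (minutes).
#' @param waso Wake after sleep onset (minutes).
#' @param twak Terminal wakefulness (minutes).
#' @return Total sleep time in minutes (non-negative).
#' @examples
#' total_sleep_time(506, 33, 45, 35)
#' @export
total_sleep_time <- function(tib, sol, waso, twak) {
  stopifnot(all(tib >= 0, na.rm = TRUE), all(sol >= 0, na.rm = TRUE),
            all(waso >= 0, na.rm = TRUE), all(twak >= 0, na.rm = TRUE))
  tst <- tib - sol - waso - twak
  bad <- which(tst < 0)
  if (length(bad)) {
    abort(paste0("wakefulness exceeds time in bed for entry/entries: ",
                 paste(bad, collapse = ", ")))
  }
  tst
}

#' Sleep efficiency
#'
#' Sleep efficiency is total sleep time as a percentage of time in bed,
#' reported to one decimal place.
#'
#' @param tst Total sleep time (minutes).
#' @param tib Time in bed (minutes), strictly positive.
#' @return Percent in [0, 100], rounded to one decimal.
#' @examples
#' sleep_efficiency(393, 506)
#' @export
sleep_efficiency <- function(tst, tib) {
  if (any(tib <= 0, na.rm = TRUE)) abort("time in bed must be positive")
  stopifnot(all(tst >= 0 & tst <= tib, na.rm = TRUE))
  round(100 * tst / tib, 1)
}

#' Construct sleep diary entries
#'
#' Builds a validated tibble of consensus-sleep-diary nights. Each row is one
#' morning report: raw clock times plus latencies, a 1--10 quality rating, and
#' a medication flag. Terminal wakefulness (`twak`) is derived as
#' `arising_time - final_wake_time` (cross-midnight rule as in
#' [time_in_bed()]); when a `twak` column is also supplied it is checked for
#' consistency with the derivable value.
#'
#' @param date Calendar date of the morning of report (`Date` or ISO string).
#' @param bed_time,try_sleep_time,final_wake_time,arising_time Clock times as
#'   minutes-of-day integers or `"HH:MM"` strings.
#' @param sol,waso Latencies in minutes (non-negative).
#' @param n_awakenings Number of awakenings (non-negative integer).
#' @param quality Sleep quality, integer 1 ("very bad") to 10 ("very good").
#' @param used_medication Logical (or 0/1) sleep-medication flag.
#' @param twak Optional explicit terminal wakefulness; checked against the
#'   derived value when both are available.
#' @return A `sleep_diary` tibble, one row per night, with derived columns
#'   `twak`, `tib`, `tst`, `se`.
#' @examples
#' diary_entry(date = "2024-03-02", bed_time = "23:00", try_sleep_time = "23:15",
#'             sol = 30, n_awakenings = 2, waso = 40, final_wake_time = "06:30",
#'             arising_time = "07:00", quality = 5, used_medication = FALSE)
#' @export
diary_entry <- function(date, bed_time, try_sleep_time, sol, n_awakenings,
                        waso, final_wake_time, arising_time, quality,
                        used_medication, twak = NULL) {
  to_min <- function(x) if (is.character(x)) parse_clock(x) else as.integer(x)
  df <- tibble::tibble(
    date = as.Date(date),
    bed_time = to_min(bed_time),
    try_sleep_time = to_min(try_sleep_time),
    sol = as.numeric(sol),
    n_awakenings = as.integer(n_awakenings),
    waso = as.numeric(waso),
    final_wake_time = to_min(final_wake_time),
    arising_time = to_min(arising_time),
    quality = as.integer(quality),
    used_medication = as.logical(used_medication)
  )
  # equal final-wake/arising means the participant got up immediately (twak 0);
  # otherwise the same cross-midnight rule as time_in_bed applies
  derived_twak <- as.numeric(
    ifelse(df$arising_time < df$final_wake_time,
           df$arising_time + 1440L, df$arising_time) - df$final_wake_time)
  if (!is.null(twak)) {
    twak <- as.numeric(twak)
    off <- which(abs(twak - derived_twak) > 0.5)
    if (length(off)) {
      warn(paste0("explicit twak disagrees with arising - final wake for ",
                  "entry/entries: ", paste(off, collapse = ", "),
                  "; keeping the explicit value"))
    }
    df$twak <- twak
  } else {
    df$twak <- derived_twak
  }
  validate_diary(df)
}

# internal: recompute the derived night metrics columns
add_night_metrics <- function(df) {
  df$tib <- as.numeric(time_in_bed(df$bed_time, df$arising_time))
  df$tst <- total_sleep_time(df$tib, df$sol, df$waso, df$twak)
  df$se <- sleep_efficiency(df$tst, df$tib)
  df
}

#' Validate a sleep diary
#'
#' Checks every row of a diary tibble against the diary invariants: clock
#' fields in range, durations non-negative, wakefulness not exceeding time in
#' bed (so total sleep time is non-negative), quality in 1--10, and — when a
#' reference clock is supplied — no future-dated entries (a diary can only be
#' filled out for the previous night). Returns the diary with derived
#' `tib`/`tst`/`se` columns refreshed.
#'
#' @param df A diary tibble with the raw columns of [diary_entry()].
#' @param today Optional `Date`: entries after this date are rejected.
#' @return The validated `sleep_diary` tibble.
#' @export
validate_diary <- function(df, today = NULL) {
  req <- c("date", "bed_time", "try_sleep_time", "sol", "n_awakenings",
           "waso", "final_wake_time", "arising_time", "quality",
           "used_medication", "twak")
  miss <- setdiff(req, names(df))
  if (length(miss)) abort(paste0("missing diary column(s): ",
                                 paste(miss, collapse = ", ")))
  fail <- function(rows, why) {
    if (length(rows)) abort(paste0("invalid diary row(s) ",
                                   paste(rows, collapse = ", "), ": ", why))
  }
  fail(which(!is.finite(df$sol) | df$sol < 0), "negative or non-finite sol")
  fail(which(!is.finite(df$waso) | df$waso < 0), "negative or non-finite waso")
  fail(which(!is.finite(df$twak) | df$twak < 0), "negative or non-finite twak")
  fail(which(df$n_awakenings < 0), "negative awakening count")
  fail(which(df$quality < 1 | df$quality > 10), "quality outside 1-10")
  tib <- as.numeric(time_in_bed(df$bed_time, df$arising_time))
  fail(which(df$sol + df$waso + df$twak > tib),
       "sol + waso + twak exceeds time in bed (negative total sleep time)")
  if (!is.null(today)) {
    fail(which(df$date > as.Date(today)), "future-dated entry")
  }
  df <- add_night_metrics(df)
  class(df) <- c("sleep_diary", class(tibble::as_tibble(df)))
  df
}

#' Summarize a trailing diary window
#'
#' Unweighted arithmetic means of the nightly metrics over the entries that
#' fall inside a trailing window. Mean sleep efficiency is the mean of the
#' nightly efficiencies (not pooled TST over pooled TIB); set
#' `pooled_se = TRUE` for the pooled-ratio alternative. Missing nights are
#' skipped, never imputed; `n_entries` carries the count so eligibility rules
#' can count diaries.
#'
#' @param entries A validated `sleep_diary` tibble.
#' @param window_days Length of the trailing window in days (>= 1).
#' @param end_date Last date of the window; defaults to the latest entry.
#' @param pooled_se If `TRUE`, weekly SE is `100 * sum(tst) / sum(tib)`.
#' @return A one-row tibble: `n_entries`, `mean_tib`, `mean_tst`, `mean_sol`,
#'   `mean_waso`, `mean_twak`, `mean_se`, `mean_quality`, `mean_awakenings`.
#'   Means are `NA` when the window holds no entries.
#' @export
summarize_window <- function(entries, window_days = 7, end_date = NULL,
                             pooled_se = FALSE) {
  stopifnot(window_days >= 1)
  if (nrow(entries) == 0) {
    return(tibble::tibble(n_entries = 0L, mean_tib = NA_real_,
                          mean_tst = NA_real_, mean_sol = NA_real_,
                          mean_waso = NA_real_, mean_twak = NA_real_,
                          mean_se = NA_real_, mean_quality = NA_real_,
                          mean_awakenings = NA_real_))
  }
  if (!all(c("tib", "tst", "se") %in% names(entries))) {
    entries <- add_night_metrics(entries)
  }
  end_date <- as.Date(end_date %||% max(entries$date))
  inside <- entries$date > end_date - window_days & entries$date <= end_date
  w <- entries[inside, , drop = FALSE]
  if (nrow(w) == 0) return(summarize_window(w[0, ], window_days))
  mean_se <- if (pooled_se) 100 * sum(w$tst) / sum(w$tib) else mean(w$se)
  tibble::tibble(
    n_entries = nrow(w),
    mean_tib = mean(w$tib), mean_tst = mean(w$tst), mean_sol = mean(w$sol),
    mean_waso = mean(w$waso), mean_twak = mean(w$twak), mean_se = mean_se,
    mean_quality = mean(w$quality), mean_awakenings = mean(w$n_awakenings)
  )
}

#' Read and write diary CSV files
#'
#' The on-disk schema has header
#' `date,bed_time,try_sleep_time,sol,n_awakenings,waso,final_wake_time,arising_time,quality,used_medication`
#' with `HH:MM` clock times, ISO-8601 dates and 0/1 booleans. A `twak` column
#' is accepted and written when present. Writing then reading a valid diary
#' is lossless. Malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @param entries A validated `sleep_diary` tibble.
#' @return `read_diary_csv()` returns a validated `sleep_diary` tibble;
#'   `write_diary_csv()` returns `path` invisibly.
#' @export
read_diary_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req <- c("date", "bed_time", "try_sleep_time", "sol", "n_awakenings",
           "waso", "final_wake_time", "arising_time", "quality",
           "used_medication")
  miss <- setdiff(req, names(raw))
  if (length(miss)) abort(paste0("diary CSV missing column(s): ",
                                 paste(miss, collapse = ", ")))
  parse_row <- function(i) {
    r <- raw[i, ]
    diary_entry(date = r$date, bed_time = r$bed_time,
                try_sleep_time = r$try_sleep_time, sol = as.numeric(r$sol),
                n_awakenings = as.integer(r$n_awakenings),
                waso = as.numeric(r$waso), final_wake_time = r$final_wake_time,
                arising_time = r$arising_time, quality = as.integer(r$quality),
                used_medication = r$used_medication %in% c("1", "TRUE", "true"),
                twak = if ("twak" %in% names(raw)) as.numeric(r$twak))
  }
  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    rows[[i]] <- tryCatch(parse_row(i), error = function(e) {
      abort(paste0("diary CSV line ", i + 1L, ": ", conditionMessage(e)))
    })
  }
  validate_diary(dplyr::bind_rows(rows))
}

#' @rdname read_diary_csv
#' @export
write_diary_csv <- function(entries, path) {
  out <- tibble::tibble(
    date = format(entries$date),
    bed_time = format_clock(entries$bed_time),
    try_sleep_time = format_clock(entries$try_sleep_time),
    sol = entries$sol,
    n_awakenings = entries$n_awakenings,
    waso = entries$waso,
    final_wake_time = format_clock(entries$final_wake_time),
    arising_time = format_clock(entries$arising_time),
    quality = entries$quality,
    used_medication = as.integer(entries$used_medication),
    twak = entries$twak
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Diary JSON mirror
#'
#' Serializes a diary to the same schema as the CSV interface, as a JSON
#' array of night objects, for embedding in engine state.
#'
#' @param entries A validated `sleep_diary` tibble.
#' @param txt JSON text produced by `diary_to_json()`.
#' @return A JSON string / a validated `sleep_diary` tibble.
#' @export
diary_to_json <- function(entries) {
  out <- tibble::tibble(
    date = format(entries$date),
    bed_time = format_clock(entries$bed_time),
    try_sleep_time = format_clock(entries$try_sleep_time),
    sol = entries$sol, n_awakenings = entries$n_awakenings,
    waso = entries$waso,
    final_wake_time = format_clock(entries$final_wake_time),
    arising_time = format_clock(entries$arising_time),
    quality = entries$quality,
    used_medication = as.integer(entries$used_medication),
    twak = entries$twak
  )
  jsonlite::toJSON(out, dataframe = "rows", auto_unbox = TRUE, digits = NA)
}

#' @rdname diary_to_json
#' @export
diary_from_json <- function(txt) {
  raw <- jsonlite::fromJSON(txt)
  if (length(raw) == 0 || nrow(raw) == 0) return(empty_diary())
  diary_entry(date = raw$date, bed_time = raw$bed_time,
              try_sleep_time = raw$try_sleep_time, sol = raw$sol,
              n_awakenings = raw$n_awakenings, waso = raw$waso,
              final_wake_time = raw$final_wake_time,
              arising_time = raw$arising_time, quality = raw$quality,
              used_medication = as.logical(raw$used_medication),
              twak = raw$twak)
}

# internal: a zero-row diary with the full column set
empty_diary <- function() {
  df <- tibble::tibble(
    date = as.Date(character()), bed_time = integer(),
    try_sleep_time = integer(), sol = numeric(), n_awakenings = integer(),
    waso = numeric(), final_wake_time = integer(), arising_time = integer(),
    quality = integer(), used_medication = logical(), twak = numeric(),
    tib = numeric(), tst = numeric(), se = numeric()
  )
  class(df) <- c("sleep_diary", class(tibble::as_tibble(df)))
  df
}
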