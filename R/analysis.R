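# Trial analysis pipeline: the model-0..5 random-intercept sequence with
# likelihood-ratio comparisons and level-1 R-squared, change-score effect
# sizes, and responder classification with contingency-table tests.

#' Read and write long-format trial CSVs
#'
#' Schema: `participant,condition,time,outcome,value` with `condition` in
#' `{app, waitlist}` and `time` in `{pre, post, followup}`. An optional
#' companion covariates CSV (`participant,condition,age,sex,sleep_quality,
#' twak,n_awakenings`) travels with the dataset.
#'
#' @param path Trial CSV path.
#' @param covariates_path Optional covariates CSV path.
#' @param trial A `trial_dataset`.
#' @return `read_trial_csv()` returns a `trial_dataset`;
#'   `write_trial_csv()` returns `path` invisibly.
#' @export
read_trial_csv <- function(path, covariates_path = NULL) {
  d <- readr::read_csv(path, col_types = readr::cols(
    participant = "c", condition = "c", time = "c", outcome = "c",
    value = "d"), progress = FALSE)
  bad <- setdiff(unique(d$condition), c("app", "waitlist"))
  if (length(bad)) abort(paste0("unknown condition(s): ",
                                paste(bad, collapse = ", ")))
  bad <- setdiff(unique(d$time), c("pre", "post", "followup"))
  if (length(bad)) abort(paste0("unknown time point(s): ",
                                paste(bad, collapse = ", ")))
  cov <- if (!is.null(covariates_path)) {
    readr::read_csv(covariates_path, col_types = readr::cols(
      participant = "c", condition = "c", sex = "c", .default = "d"),
      progress = FALSE)
  }
  structure(list(data = d, covariates = cov), class = "trial_dataset")
}

#' @rdname read_trial_csv
#' @export
write_trial_csv <- function(trial, path, covariates_path = NULL) {
  readr::write_csv(trial$data, path, progress = FALSE)
  if (!is.null(covariates_path) && !is.null(trial$covariates)) {
    readr::write_csv(trial$covariates, covariates_path, progress = FALSE)
  }
  invisible(path)
}

#' Run the full trial analysis
#'
#' For each outcome, fits the model sequence on the pre/post rows — model 0:
#' random intercept only; model 1: + time; model 2: + condition; model 3:
#' + time x condition — and, on the app arm's pre/follow-up rows, model 4
#' (random intercept) vs model 5 (+ time). Dropout covariates are added to
#' every model when available. Reports model-3 coefficients with standard
#' errors and p values, the 0v1 / 1v2 / 2v3 / 0v3 / 4v5 likelihood-ratio
#' comparisons with level-1 R-squared, between- and within-group change-score
#' effect sizes, and — for the ISI — meaningful-change and remission counts
#' with their chi-square tests.
#'
#' @param trial A `trial_dataset`. Follow-up rows in the waitlist arm are a
#'   design violation and raise an error.
#' @param outcomes Outcome ids to analyze; defaults to all present.
#' @param covariates Covariate columns to adjust for; defaults to the
#'   dropout-associated set present in the data.
#' @return An `analysis_report` list: per-outcome `coefficients`,
#'   `comparisons`, `effect_sizes`, plus `classification` (ISI responder
#'   table and tests).
#' @export
run_analysis <- function(trial, outcomes = NULL,
                         covariates = c("age", "sleep_quality", "twak",
                                        "n_awakenings")) {
  if (any(trial$data$condition == "waitlist" &
            trial$data$time == "followup")) {
    abort("design violation: waitlist rows at follow-up")
  }
  outcomes <- outcomes %||% unique(trial$data$outcome)
  covariates <- intersect(covariates,
                          names(trial$covariates %||% data.frame()))
  cov_terms <- if (length(covariates))
    paste("+", paste(covariates, collapse = " + ")) else ""
  f <- function(rhs) as.formula(paste("value ~", rhs, cov_terms))

  per_outcome <- lapply(outcomes, function(oc) {
    d <- prepost_frame(trial, oc)
    m0 <- fit_random_intercept(d, f("1"))
    m1 <- fit_random_intercept(d, f("time"))
    m2 <- fit_random_intercept(d, f("time + condition"))
    m3 <- fit_random_intercept(d, f("time * condition"))
    comps <- dplyr::bind_rows(
      dplyr::mutate(compare_models(m0, m1), comparison = "0v1"),
      dplyr::mutate(compare_models(m1, m2), comparison = "1v2"),
      dplyr::mutate(compare_models(m2, m3), comparison = "2v3"),
      dplyr::mutate(compare_models(m0, m3), comparison = "0v3"))
    dfu <- prepost_frame(trial, oc, times = c("pre", "followup"))
    dfu <- dfu[dfu$condition == 1, , drop = FALSE]
    if (nrow(dfu) > 0 && any(dfu$time == 1)) {
      m4 <- fit_random_intercept(dfu, f("1"))
      m5 <- fit_random_intercept(dfu, f("time"))
      comps <- dplyr::bind_rows(
        comps, dplyr::mutate(compare_models(m4, m5), comparison = "4v5"))
    }
    wide <- tidyr_pivot(d)
    es_between <- tryCatch(
      cohen_d_between(wide$change[wide$condition == 0],
                      wide$change[wide$condition == 1]),
      error = function(e) NULL)
    list(outcome = oc, coefficients = m3$coefficients,
         comparisons = comps[, c("comparison", "chi_square", "df",
                                 "p_value", "r2_level1")],
         effect_between = es_between, fit3 = m3)
  })
  names(per_outcome) <- outcomes

  classification <- NULL
  if ("isi" %in% outcomes) {
    wide <- tidyr_pivot(prepost_frame(trial, "isi"))
    wide <- wide[is.finite(wide$change), , drop = FALSE]
    cls <- classify_change(wide$pre, wide$post)
    tab_mc <- table(factor(wide$condition, levels = c(1, 0),
                           labels = c("app", "waitlist")),
                    factor(cls$meaningful_change, levels = c(TRUE, FALSE)))
    tab_rem <- table(factor(wide$condition, levels = c(1, 0),
                            labels = c("app", "waitlist")),
                     factor(cls$remitted, levels = c(TRUE, FALSE)))
    # degenerate tables (a zero margin, e.g. in tiny cohorts) leave the test
    # undefined rather than aborting the whole report
    safe_chi2 <- function(tab) {
      tryCatch(pearson_chi2(unclass(tab)), error = function(e)
        list(chi_square = NA_real_, df = NA_integer_, p_value = NA_real_))
    }
    classification <- list(
      meaningful_change = list(table = tab_mc, test = safe_chi2(tab_mc)),
      remission = list(table = tab_rem, test = safe_chi2(tab_rem)))
  }
  structure(list(outcomes = per_outcome, classification = classification),
            class = "analysis_report")
}

# internal: one row per participant with pre, post, change = pre - post
tidyr_pivot <- function(d) {
  pre <- d[d$time == 0, c("participant", "condition", "value")]
  post <- d[d$time == 1, c("participant", "value")]
  names(pre)[3] <- "pre"
  names(post)[2] <- "post"
  wide <- dplyr::left_join(pre, post, by = "participant")
  wide$change <- wide$pre - wide$post
  wide
}

#' @export
print.analysis_report <- function(x, ...) {
  for (oc in names(x$outcomes)) {
    r <- x$outcomes[[oc]]
    cat("==", toupper(oc), "==\n")
    print(as.data.frame(r$coefficients), digits = 3, row.names = FALSE)
    print(as.data.frame(r$comparisons), digits = 3, row.names = FALSE)
    if (!is.null(r$effect_between)) print(r$effect_between)
    cat("\n")
  }
  if (!is.null(x$classification)) {
    mc <- x$classification$meaningful_change
    rem <- x$classification$remission
    cat(sprintf("Meaningful change: chi2(%d) = %.2f, p = %.3g\n",
                mc$test$df, mc$test$chi_square, mc$test$p_value))
    cat(sprintf("Remission: chi2(%d) = %.2f, p = %.3g\n",
                rem$test$df, rem$test$chi_square, rem$test$p_value))
  }
  invisible(x)
}
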