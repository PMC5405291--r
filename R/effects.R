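# Change-score effect sizes, clinically-meaningful-change classification,
# and the contingency-table test used for the randomization check and the
# responder comparisons.

#' Between-group Cohen d on change scores
#'
#' `d = (mean change waitlist - mean change app) / SD_pooled`, where each
#' change score is pre minus post and the pooled SD is the usual
#' n-weighted pooled standard deviation of the two change-score samples. On
#' a lower-is-better scale, an app arm improving more than the waitlist gives
#' a negative d. The 95% CI uses the large-sample standard error of a
#' standardized mean difference.
#'
#' @param change_wl,change_app Numeric change scores (pre - post) per arm.
#' @return An `effect_size` list: `d`, `ci95` (length-2), `mean_change_wl`,
#'   `mean_change_app`, `sd_pooled`, `n`.
#' @export
cohen_d_between <- function(change_wl, change_app) {
  change_wl <- change_wl[is.finite(change_wl)]
  change_app <- change_app[is.finite(change_app)]
  n1 <- length(change_wl); n2 <- length(change_app)
  stopifnot(n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * var(change_wl) + (n2 - 1) * var(change_app)) /
               (n1 + n2 - 2))
  if (sp == 0) abort("zero pooled SD: effect size undefined")
  d <- (mean(change_wl) - mean(change_app)) / sp
  se_d <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  structure(list(d = d, ci95 = d + c(-1, 1) * qnorm(0.975) * se_d,
                 mean_change_wl = mean(change_wl),
                 mean_change_app = mean(change_app),
                 sd_pooled = sp, n = c(wl = n1, app = n2)),
            class = "effect_size")
}

#' Within-group Cohen d
#'
#' `d = (mean pre - mean post) / SD_pooled`, pooling the pre and post
#' standard deviations. `cohen_d_within()` works on raw paired vectors (its
#' CI comes from the change-score SD); `cohen_d_within_means()` applies the
#' same formula to reported summary means/SDs (no CI, since the pre-post
#' correlation is unknown).
#'
#' @param pre,post Numeric vectors of paired scores.
#' @param mean_pre,sd_pre,mean_post,sd_post Summary statistics.
#' @return An `effect_size` list (`cohen_d_within_means()` returns the bare
#'   d as a number inside the same structure, with `ci95 = NULL`).
#' @examples
#' cohen_d_within_means(77.0, 8.2, 78.3, 7.6)$d
#' @export
cohen_d_within <- function(pre, post) {
  ok <- is.finite(pre) & is.finite(post)
  pre <- pre[ok]; post <- post[ok]
  n <- length(pre)
  stopifnot(n >= 2)
  sp <- sqrt((var(pre) + var(post)) / 2)
  if (sp == 0) abort("zero pooled SD: effect size undefined")
  d <- (mean(pre) - mean(post)) / sp
  change <- pre - post
  se_mean <- sd(change) / sqrt(n)
  ci <- (mean(change) + c(-1, 1) * qnorm(0.975) * se_mean) / sp
  structure(list(d = d, ci95 = ci, sd_pooled = sp, n = n),
            class = "effect_size")
}

#' @rdname cohen_d_within
#' @export
cohen_d_within_means <- function(mean_pre, sd_pre, mean_post, sd_post) {
  sp <- sqrt((sd_pre^2 + sd_post^2) / 2)
  if (sp == 0) abort("zero pooled SD: effect size undefined")
  structure(list(d = (mean_pre - mean_post) / sp, ci95 = NULL,
                 sd_pooled = sp, n = NA_integer_),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen d = %.2f", x$d))
  if (!is.null(x$ci95)) cat(sprintf(" (95%% CI %.2f to %.2f)",
                                    x$ci95[1], x$ci95[2]))
  cat("\n")
  invisible(x)
}

#' Classify clinically meaningful change and remission on the ISI
#'
#' A pre-to-post drop of at least 8 points on the Insomnia Severity Index is
#' a clinically meaningful change; a posttest score of at most 7 counts as
#' remission (below the insomnia threshold). Both boundaries are inclusive
#' (drop >= 8, post <= 7).
#'
#' @param pre_isi,post_isi ISI scores in 0--28 (vectorized).
#' @return A tibble with logical columns `meaningful_change`, `remitted`.
#' @export
classify_change <- function(pre_isi, post_isi) {
  if (any(pre_isi < 0 | pre_isi > 28 | post_isi < 0 | post_isi > 28,
          na.rm = TRUE)) {
    abort("ISI scores must lie in [0, 28]")
  }
  tibble::tibble(meaningful_change = (pre_isi - post_isi) >= 8,
                 remitted = post_isi <= 7)
}

#' Pearson chi-square test for a contingency table
#'
#' Uncorrected Pearson statistic (no Yates continuity correction) with
#' `df = (r - 1)(c - 1)`.
#'
#' @param table An r x c matrix of non-negative integer counts with no zero
#'   marginal totals.
#' @return A list: `chi_square`, `df`, `p_value`.
#' @examples
#' pearson_chi2(matrix(c(20, 7, 25, 55), 2))
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero marginal total: test undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi_square = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}
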