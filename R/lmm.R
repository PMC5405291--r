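# Two-level random-intercept linear model, fitted by maximum likelihood.
#
# For participant i with n_i observations, y_i = X_i beta + b_i + e_i with
# b_i ~ N(0, sigma_u^2) and e_i ~ N(0, sigma_e^2 I). Writing lambda =
# sigma_u^2 / sigma_e^2, the marginal covariance is sigma_e^2 (I + lambda J),
# whose inverse and determinant are closed-form:
#   (I + lambda J)^{-1} = I - lambda/(1 + n_i lambda) J,
#   |I + lambda J| = 1 + n_i lambda.
# beta and sigma_e^2 profile out analytically, leaving a 1-D likelihood in
# lambda that is optimized on a log grid. ML (not REML) is used throughout so
# likelihood-ratio chi-squares between nested fixed-effect specifications
# are valid.

# internal: per-group sufficient statistics for the profiled likelihood
lmm_suffstats <- function(X, y, group) {
  group <- as.factor(group)
  XtX_g <- list(); Xs_g <- list(); ys_g <- numeric(); yy_g <- numeric()
  Xty <- crossprod(X, y)
  XtX <- crossprod(X)
  yy <- sum(y^2)
  Xsum <- rowsum(X, group)          # groups x p
  ysum <- rowsum(y, group)[, 1]
  n_g <- as.integer(table(group))
  list(XtX = XtX, Xty = Xty, yy = yy, Xsum = Xsum, ysum = ysum,
       n_g = n_g, N = length(y), p = ncol(X))
}

# internal: profiled negative log-likelihood pieces at a given lambda
lmm_profile <- function(ss, lambda) {
  c_g <- lambda / (1 + ss$n_g * lambda)
  XtVX <- ss$XtX - crossprod(ss$Xsum * sqrt(c_g))
  XtVy <- ss$Xty - crossprod(ss$Xsum, c_g * ss$ysum)
  yVy <- ss$yy - sum(c_g * ss$ysum^2)
  beta <- tryCatch(solve(XtVX, XtVy), error = function(e)
    abort("singular fixed-effect design"))
  rss <- as.numeric(yVy - 2 * crossprod(beta, XtVy) +
                      crossprod(beta, XtVX %*% beta))
  rss <- max(rss, 1e-12)
  sigma2 <- rss / ss$N
  ll <- -0.5 * (ss$N * (log(2 * pi) + log(sigma2) + 1) +
                  sum(log1p(ss$n_g * lambda)))
  list(beta = beta, sigma2 = sigma2, loglik = ll, XtVX = XtVX)
}

#' Fit a random-intercept multilevel model by maximum likelihood
#'
#' Fits a two-level linear model with a participant-specific random intercept
#' and arbitrary fixed effects, by profiling the likelihood down to the
#' variance ratio and optimizing it numerically to high precision. Handles
#' participants with a single observation (intention-to-treat inclusion) and
#' the boundary case of zero intercept variance, where the fit reduces to
#' ordinary least squares.
#'
#' @param data Data frame with the response, fixed-effect terms, and the
#'   grouping column.
#' @param formula Fixed-effects formula, e.g. `value ~ time * condition`.
#' @param group Name of the grouping (participant) column.
#' @param lambda Optional fixed variance ratio `sigma_u^2 / sigma_e^2`; when
#'   supplied the ratio is not estimated (0 forces the OLS limit).
#' @return An `lmm_fit` list: `coefficients` tibble (`term`, `estimate`,
#'   `se`, `z`, `p`), `sigma2_residual`, `sigma2_intercept`, `loglik`,
#'   `n_obs`, `n_groups`, `df_model` (fixed parameters + 2 variances),
#'   `formula`.
#' @examples
#' tr <- simulate_trial(n_app = 30, n_wl = 30, missingness = NULL, seed = 1)
#' d <- prepost_frame(tr, "isi")
#' fit_random_intercept(d, value ~ time * condition)
#' @export
fit_random_intercept <- function(data, formula, group = "participant",
                                 lambda = NULL) {
  data <- as.data.frame(data)
  rownames(data) <- NULL
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  kept <- as.integer(rownames(mf))
  y <- stats::model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  g <- data[[group]][kept]
  if (length(unique(g)) < 2) abort("need at least 2 participants")
  if (length(y) == 0) abort("zero observations")
  ss <- lmm_suffstats(X, y, g)
  if (ss$N <= ss$p) abort("more parameters than observations")

  if (is.null(lambda)) {
    obj <- function(loglam) -lmm_profile(ss, exp(loglam))$loglik
    opt <- optimize(obj, interval = c(log(1e-8), log(1e4)), tol = 1e-10)
    lambda_hat <- exp(opt$minimum)
    # compare against the boundary lambda = 0 (no intercept variance)
    at0 <- lmm_profile(ss, 0)
    athat <- lmm_profile(ss, lambda_hat)
    if (at0$loglik >= athat$loglik) {
      lambda_hat <- 0
      athat <- at0
    }
  } else {
    lambda_hat <- lambda
    athat <- lmm_profile(ss, lambda_hat)
  }
  beta <- drop(athat$beta)
  vcov_beta <- athat$sigma2 * solve(athat$XtVX)
  se <- sqrt(diag(vcov_beta))
  z <- beta / se
  structure(list(
    coefficients = tibble::tibble(term = colnames(X), estimate = beta,
                                  se = se, z = z,
                                  p = 2 * pnorm(-abs(z))),
    sigma2_residual = athat$sigma2,
    sigma2_intercept = lambda_hat * athat$sigma2,
    lambda = lambda_hat,
    loglik = athat$loglik,
    n_obs = ss$N,
    n_groups = length(unique(g)),
    df_model = ss$p + 2L,
    formula = formula,
    vcov = vcov_beta
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept model (ML):",
      deparse(x$formula), "\n")
  cat(sprintf("  %d obs, %d participants; logLik %.2f\n",
              x$n_obs, x$n_groups, x$loglik))
  cat(sprintf("  residual var %.3f, intercept var %.3f\n",
              x$sigma2_residual, x$sigma2_intercept))
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio comparison of nested random-intercept models
#'
#' Compares two model fits on the same data by the likelihood-ratio
#' chi-square (twice the log-likelihood difference, degrees of freedom equal
#' to the difference in fixed parameters) and reports the level-1 variance
#' explained: the proportional reduction in residual variance of the fuller
#' model relative to the null.
#'
#' @param null,full `lmm_fit` objects; `full` must nest `null` (same data,
#'   superset of fixed-effect terms).
#' @return A tibble: `chi_square`, `df`, `p_value`, `r2_level1`.
#' @export
compare_models <- function(null, full) {
  if (null$n_obs != full$n_obs) {
    abort("models were fitted to different data")
  }
  t_null <- attr(terms(null$formula), "term.labels")
  t_full <- attr(terms(full$formula), "term.labels")
  if (!all(t_null %in% t_full)) abort("models are not nested")
  df <- full$df_model - null$df_model
  if (df < 0) abort("null model has more parameters than the full model")
  chi2 <- 2 * (full$loglik - null$loglik)
  tibble::tibble(
    chi_square = chi2,
    df = df,
    p_value = if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_,
    r2_level1 = 1 - full$sigma2_residual / null$sigma2_residual)
}

#' Reshape a trial dataset for the pre/post models
#'
#' Extracts one outcome's pre/post rows into a modeling frame with numeric
#' `time` (0 = pre, 1 = post), `condition` (0 = waitlist, 1 = app), and the
#' participant covariates joined in.
#'
#' @param trial A `trial_dataset` from [simulate_trial()] or
#'   [read_trial_csv()].
#' @param outcome Outcome id, e.g. `"isi"`.
#' @param times Time points to keep (default pre and post).
#' @return A tibble ready for [fit_random_intercept()].
#' @export
prepost_frame <- function(trial, outcome, times = c("pre", "post")) {
  d <- trial$data[trial$data$outcome == outcome &
                    trial$data$time %in% times, , drop = FALSE]
  d$time <- as.numeric(d$time == times[2])
  d$condition <- as.numeric(d$condition == "app")
  if (!is.null(trial$covariates)) {
    d <- dplyr::left_join(d, trial$covariates[, setdiff(
      names(trial$covariates), "condition"), drop = FALSE],
      by = "participant")
  }
  d
}
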