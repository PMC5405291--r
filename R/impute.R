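# Multiple imputation by chained predictive mean matching (PMM), and Rubin
# pooling. Each missing cell is filled with an observed donor value whose
# linear-model predicted mean is among the k closest to the missing cell's
# prediction, so imputed values are always real observed values.

#' Predictive mean matching multiple imputation
#'
#' Chained-equations PMM over the numeric columns of a wide data frame. For
#' each target variable with missing values, a linear model on the other
#' variables (current completions) predicts all cells; each missing cell is
#' filled by sampling one of the `k_donors` observed values with the closest
#' predicted means. After a fixed number of sweeps the completion is
#' recorded; `m` completions are generated from independent sub-seeds.
#' Observed cells are never altered.
#'
#' @param data A data frame; only numeric columns are imputed, other columns
#'   may serve as predictors if numeric-codable (factors/characters are
#'   excluded from the predictor matrix).
#' @param m Number of completed datasets.
#' @param k_donors Donor-pool size for matching.
#' @param sweeps Chained-equation sweeps per completion.
#' @param seed Integer seed.
#' @param vars Columns to impute/use as predictors; defaults to all numeric
#'   columns.
#' @return A list of `m` completed data frames.
#' @export
pmm_impute <- function(data, m = 10, k_donors = 5, sweeps = 5, seed = 1,
                       vars = NULL) {
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  vars <- vars %||% num_cols
  vars <- intersect(vars, num_cols)
  for (v in vars) {
    if (all(is.na(data[[v]]))) {
      abort(paste0("variable with no observed values: ", v))
    }
  }
  miss_vars <- vars[vapply(vars, function(v) anyNA(data[[v]]), logical(1))]
  if (!length(miss_vars)) {
    return(replicate(m, data, simplify = FALSE))
  }
  lapply(seq_len(m), function(rep) {
    withr::with_seed(sub_seed(seed, rep), {
      imp <- data
      # initial fill: random draws from each variable's observed values
      for (v in miss_vars) {
        na_i <- which(is.na(imp[[v]]))
        obs <- data[[v]][!is.na(data[[v]])]
        imp[[v]][na_i] <- sample(obs, length(na_i), replace = TRUE)
      }
      for (s in seq_len(sweeps)) {
        for (v in miss_vars) {
          na_i <- which(is.na(data[[v]]))
          obs_i <- which(!is.na(data[[v]]))
          preds <- setdiff(vars, v)
          Xfull <- as.matrix(imp[preds])
          keep <- apply(Xfull, 2, function(col) var(col) > 0)
          Xfull <- cbind(1, Xfull[, keep, drop = FALSE])
          yobs <- data[[v]][obs_i]
          fit <- stats::lm.fit(Xfull[obs_i, , drop = FALSE], yobs)
          beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
          yhat <- drop(Xfull %*% beta)
          for (i in na_i) {
            dist <- abs(yhat[obs_i] - yhat[i])
            donors <- obs_i[order(dist)][seq_len(min(k_donors,
                                                     length(obs_i)))]
            imp[[v]][i] <- data[[v]][sample(rep(donors, 2), 1)]
          }
        }
      }
      imp
    })
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines per-imputation point estimates and their variances: the pooled
#' estimate is the mean, and the total variance is the within-imputation
#' variance plus `(1 + 1/m)` times the between-imputation variance.
#'
#' @param estimates Numeric vector of per-imputation estimates.
#' @param variances Numeric vector of per-imputation squared standard errors.
#' @return A list: `estimate`, `se`, `var_within`, `var_between`, `m`.
#' @export
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  stopifnot(m >= 2, length(variances) == m)
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- var(estimates)
  tot <- w + (1 + 1 / m) * b
  list(estimate = qbar, se = sqrt(tot), var_within = w, var_between = b,
       m = m)
}
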