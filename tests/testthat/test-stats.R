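# --- random-intercept fitter ------------------------------------------------

make_lmm_data <- function(n_per_arm = 40, sd_b = 2, sd_e = 1.5,
                          beta = c(10, 2, -1.5, 1), seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_arm
    b <- rnorm(n, 0, sd_b)
    d <- expand.grid(participant = seq_len(n), time = c(0, 1))
    d$condition <- as.numeric(d$participant <= n_per_arm)
    mm <- cbind(1, d$time, d$condition, d$time * d$condition)
    d$value <- drop(mm %*% beta) + b[d$participant] +
      rnorm(nrow(d), 0, sd_e)
    d
  })
}

test_that("with zero intercept variance the fit reduces to OLS", {
  d <- make_lmm_data(seed = 5)
  fit <- fit_random_intercept(d, value ~ time * condition, lambda = 0)
  ols <- lm(value ~ time * condition, data = d)
  expect_lt(max(abs(fit$coefficients$estimate - coef(ols))), 1e-6)
  expect_equal(fit$sigma2_intercept, 0)
})

test_that("balanced fits match full-matrix generalized least squares", {
  d <- make_lmm_data(n_per_arm = 15, seed = 9)
  fit <- fit_random_intercept(d, value ~ time * condition)
  # oracle: dense compound-symmetry GLS at the fitted variance ratio
  lam <- fit$lambda
  X <- model.matrix(~ time * condition, d)
  V <- matrix(0, nrow(d), nrow(d))
  for (i in unique(d$participant)) {
    idx <- which(d$participant == i)
    V[idx, idx] <- lam
  }
  diag(V) <- diag(V) + 1
  beta_gls <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, d$value))
  expect_lt(max(abs(fit$coefficients$estimate - drop(beta_gls))), 1e-6)
  # and the profiled log-likelihood agrees with the dense evaluation
  r <- d$value - X %*% beta_gls
  s2 <- drop(t(r) %*% solve(V, r)) / nrow(d)
  ll <- -0.5 * (nrow(d) * (log(2 * pi) + log(s2) + 1) +
                  determinant(V)$modulus)
  expect_equal(fit$loglik, as.numeric(ll), tolerance = 1e-6)
})

test_that("fitter agrees with the reference ML implementation", {
  skip_if_not_installed("lme4")
  d <- make_lmm_data(seed = 13)
  # unbalance it: drop a third of the observations
  d <- d[-withr::with_seed(1, sample(nrow(d), nrow(d) %/% 3)), ]
  fit <- fit_random_intercept(d, value ~ time * condition)
  ref <- lme4::lmer(value ~ time * condition + (1 | participant),
                    data = d, REML = FALSE)
  expect_lt(max(abs(fit$coefficients$estimate - lme4::fixef(ref))), 1e-5)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_lt(max(abs(fit$coefficients$se -
                      coef(summary(ref))[, "Std. Error"])), 1e-5)
})

test_that("configured fixed effects are recovered from simulated trials", {
  oc <- trial_outcomes()[trial_outcomes()$outcome == "isi", ]
  tr <- simulate_trial(500, 500, outcomes = oc, missingness = NULL,
                       followup = FALSE, seed = 6)
  d <- prepost_frame(tr, "isi")
  fit <- fit_random_intercept(d, value ~ time * condition)
  co <- fit$coefficients
  sd_e <- oc$baseline_sd * sqrt(1 - oc$icc)
  truth <- c(oc$baseline_mean, oc$time_effect, 0,
             oc$d_between * sqrt(2) * sd_e)
  expect_lt(max(abs(co$estimate - truth) / co$se), 3)
})

test_that("model comparison is a likelihood-ratio chi-square with level-1 R2", {
  d <- make_lmm_data(seed = 21)
  m1 <- fit_random_intercept(d, value ~ time)
  m3 <- fit_random_intercept(d, value ~ time * condition)
  cmp <- compare_models(m1, m3)
  expect_equal(cmp$chi_square, 2 * (m3$loglik - m1$loglik))
  expect_equal(cmp$df, 2L)
  expect_equal(cmp$r2_level1, 1 - m3$sigma2_residual / m1$sigma2_residual)
  # identical models: chi2 and r2 are zero
  same <- compare_models(m1, m1)
  expect_equal(same$chi_square, 0)
  expect_equal(same$r2_level1, 0)
  expect_error(compare_models(m3, m1), "nested")
  m_other <- fit_random_intercept(d, value ~ condition)
  expect_error(compare_models(m_other, fit_random_intercept(d, value ~ time)),
               "not nested")
})

test_that("comparison chi-square is invariant under affine outcome rescaling", {
  d <- make_lmm_data(seed = 33)
  cmp1 <- compare_models(fit_random_intercept(d, value ~ time),
                         fit_random_intercept(d, value ~ time * condition))
  d$value <- 3.7 * d$value - 12
  cmp2 <- compare_models(fit_random_intercept(d, value ~ time),
                         fit_random_intercept(d, value ~ time * condition))
  expect_equal(cmp1$chi_square, cmp2$chi_square, tolerance = 1e-5)
  expect_equal(cmp1$r2_level1, cmp2$r2_level1, tolerance = 1e-5)
})

test_that("chi-square grows roughly linearly with n under an alternative", {
  chis <- sapply(c(50, 100, 200), function(n) {
    d <- make_lmm_data(n_per_arm = n, beta = c(10, 2, -1.5, 1.2), seed = 3)
    compare_models(fit_random_intercept(d, value ~ time + condition),
                   fit_random_intercept(d, value ~ time * condition))$chi_square
  })
  expect_true(all(diff(chis) > 0))
  expect_gt(chis[3] / chis[1], 2)  # ~4 expected; well above flat
})

# --- effect sizes -----------------------------------------------------------

test_that("between-group change-score d follows the printed formula", {
  expect_equal(cohen_d_between(c(1, 2, 3), c(1, 2, 3))$d, 0)
  # hand-computed: means 0 and 2, pooled sd 2 -> |d| = 1
  wl <- c(-2, 2); app <- c(0, 4)
  sp <- sqrt((var(wl) + var(app)) / 2)
  es <- cohen_d_between(wl, app)
  expect_equal(es$d, (mean(wl) - mean(app)) / sp)
  expect_equal(abs(es$d), 1 * 2 / sp * 1)  # (0-2)/2.828 scaled by oracle
  expect_true(es$ci95[1] < es$d && es$d < es$ci95[2])
  expect_error(cohen_d_between(c(1, 1, 1), c(1, 1, 1)), "zero pooled SD")
  # random-data brute force
  withr::with_seed(41, {
    for (i in 1:20) {
      a <- rnorm(30); b <- rnorm(25, 0.5)
      sp <- sqrt((29 * var(a) + 24 * var(b)) / 53)
      expect_equal(cohen_d_between(a, b)$d, (mean(a) - mean(b)) / sp)
    }
  })
})

test_that("within-group d reproduces the published waitlist SE value", {
  expect_equal(round(cohen_d_within_means(77.0, 8.2, 78.3, 7.6)$d, 2), -0.16)
  expect_equal(cohen_d_within(c(1, 2, 3), c(1, 2, 3))$d, 0)
  withr::with_seed(43, {
    pre <- rnorm(40, 10, 2); post <- rnorm(40, 8, 2)
    expect_equal(cohen_d_within(pre, post)$d,
                 (mean(pre) - mean(post)) / sqrt((var(pre) + var(post)) / 2))
  })
})

test_that("simulated trials recover the configured between-group d", {
  oc <- trial_outcomes()[trial_outcomes()$outcome == "isi", ]
  ds <- sapply(1:30, function(r) {
    tr <- simulate_trial(300, 300, outcomes = oc, missingness = NULL,
                         followup = FALSE, seed = 600 + r)
    w <- sleepcoach:::tidyr_pivot(prepost_frame(tr, "isi"))
    cohen_d_between(w$change[w$condition == 0], w$change[w$condition == 1])$d
  })
  expect_lt(abs(mean(ds) - (-0.66)), 0.05)
})

# --- responder classification ----------------------------------------------

test_that("meaningful change and remission use the printed ISI boundaries", {
  r <- classify_change(16, 8)
  expect_true(r$meaningful_change); expect_false(r$remitted)
  r <- classify_change(16, 7)
  expect_true(r$meaningful_change); expect_true(r$remitted)
  r <- classify_change(10, 3)
  expect_false(r$meaningful_change); expect_true(r$remitted)
  expect_error(classify_change(30, 5), "0, 28")
  # exhaustive grid against the two rules
  g <- expand.grid(pre = 0:28, post = 0:28)
  cls <- classify_change(g$pre, g$post)
  expect_equal(cls$meaningful_change, g$pre - g$post >= 8)
  expect_equal(cls$remitted, g$post <= 7)
})

# --- contingency tables -----------------------------------------------------

test_that("Pearson chi-square matches brute-force expected counts", {
  withr::with_seed(51, {
    for (i in 1:50) {
      r <- sample(2:4, 1); cc <- sample(2:4, 1)
      tab <- matrix(sample(1:50, r * cc, replace = TRUE), r, cc)
      res <- pearson_chi2(tab)
      expect_equal(res$chi_square, chi2_brute(tab))
      expect_equal(res$df, (r - 1) * (cc - 1))
      expect_equal(res$p_value,
                   pchisq(res$chi_square, res$df, lower.tail = FALSE))
    }
  })
  # proportional rows: exact independence
  expect_equal(pearson_chi2(matrix(c(10, 20, 30, 60), 2))$chi_square, 0)
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
  expect_error(pearson_chi2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

# --- imputation -------------------------------------------------------------

test_that("PMM leaves complete data untouched and imputes only from donors", {
  withr::with_seed(61, {
    full <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
    full$b <- full$a + rnorm(60, 0, 0.5)
    out <- pmm_impute(full, m = 3, seed = 1)
    expect_length(out, 3)
    for (o in out) expect_identical(o, full)

    dat <- full
    holes <- sample(60, 15)
    dat$b[holes] <- NA
    out <- pmm_impute(dat, m = 5, seed = 2)
    for (o in out) {
      # observed cells never altered
      expect_identical(o$b[-holes], dat$b[-holes])
      expect_identical(o$a, dat$a)
      # every imputed value is an observed donor value
      expect_true(all(o$b[holes] %in% dat$b[-holes]))
      expect_false(anyNA(o$b))
    }
    expect_error(pmm_impute(transform(dat, b = NA_real_)),
                 "no observed values")
  })
})

test_that("PMM is approximately unbiased under MCAR", {
  withr::with_seed(63, {
    n <- 400
    full <- data.frame(a = rnorm(n, 10, 2))
    full$b <- 2 * full$a + rnorm(n, 0, 1)
    dat <- full
    dat$b[sample(n, n / 5)] <- NA
    out <- pmm_impute(dat, m = 10, seed = 3)
    means <- sapply(out, function(o) mean(o$b))
    se <- sd(full$b) / sqrt(n)
    expect_lt(abs(mean(means) - mean(full$b)), 3 * se)
  })
})

test_that("between-imputation variance of a mean stabilizes at large m", {
  withr::with_seed(65, {
    n <- 150
    dat <- data.frame(a = rnorm(n), b = rnorm(n))
    dat$b[sample(n, 30)] <- NA
    out <- pmm_impute(dat, m = 50, seed = 4)
    means <- sapply(out, function(o) mean(o$b))
    b1 <- var(means[1:25]); b2 <- var(means[26:50])
    # two halves of the imputation stream see similar between variance
    expect_lt(abs(b1 - b2), 5 * (b1 + b2) / 2)
    pooled <- pool_rubin(means, rep(var(dat$b, na.rm = TRUE) / n, 50))
    expect_equal(pooled$estimate, mean(means))
    expect_gte(pooled$se^2, pooled$var_within)
  })
})

# --- orchestration ----------------------------------------------------------

test_that("the full analysis reproduces configured directions and design checks", {
  tr <- simulate_trial(150, 150, seed = 19)
  rep <- run_analysis(tr, outcomes = c("isi", "se"))
  # interaction signs match the configured effect directions
  co_isi <- rep$outcomes$isi$coefficients
  expect_lt(co_isi$estimate[co_isi$term == "time:condition"], 0)
  co_se <- rep$outcomes$se$coefficients
  expect_gt(co_se$estimate[co_se$term == "time:condition"], 0)
  # comparison table has the five planned contrasts
  expect_setequal(rep$outcomes$isi$comparisons$comparison,
                  c("0v1", "1v2", "2v3", "0v3", "4v5"))
  # ISI responder classification present with valid tests
  expect_false(is.null(rep$classification))
  expect_gte(rep$classification$meaningful_change$test$chi_square, 0)

  # waitlist follow-up rows violate the design
  bad <- tr
  extra <- bad$data[bad$data$condition == "waitlist" &
                      bad$data$time == "post", ][1, ]
  extra$time <- "followup"
  bad$data <- rbind(bad$data, extra)
  expect_error(run_analysis(bad), "design violation")
})
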