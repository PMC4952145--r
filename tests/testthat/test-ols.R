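test_that("fit_ols reproduces hand-solvable cases", {
  # perfect fit
  f <- fit_ols(c(1, 2, 3), cbind(1, c(1, 2, 3)))
  expect_equal(unname(f$coefficients), c(0, 1), tolerance = 1e-12)
  expect_equal(f$residuals, rep(0, 3), tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  # intercept-only mean model
  f <- fit_ols(c(2, 4, 6), cbind(`(Intercept)` = rep(1, 3)))
  expect_equal(unname(f$coefficients), 4)
  expect_equal(f$residuals, c(-2, 0, 2))
  expect_equal(f$r_squared, 0)

  # normal equations by hand: Sxy = 10, Sxx = 10 -> slope 1, intercept 0.4
  f <- fit_ols(c(1, 1, 2, 3, 5), cbind(1, 0:4))
  expect_equal(unname(f$coefficients), c(0.4, 1.0), tolerance = 1e-12)
})

test_that("fit invariants hold on random problems: residual sum, hat bounds, hat trace", {
  for (seed in 1:20) {
    pr <- rand_problem(seed, n = 40, p = 5)
    f <- fit_ols(pr$y, pr$X)
    expect_lt(abs(sum(f$residuals)), 1e-8 * f$n * sd(pr$y))
    expect_true(all(f$hat_diag >= 1 / f$n - 1e-10 & f$hat_diag <= 1 + 1e-10))
    expect_equal(sum(f$hat_diag), f$p, tolerance = 1e-8)
    expect_true(f$r_squared >= 0 && f$r_squared <= 1)
    expect_equal(f$log_likelihood,
                 -(f$n / 2) * (log(2 * pi) + log(f$sigma2_mle) + 1))
  }
})

test_that("underdetermined and degenerate inputs are rejected or downgraded", {
  expect_error(fit_ols(1:3, cbind(1, diag(3))), "underdetermined")
  expect_warning(f <- fit_ols(rep(2, 10), cbind(1, rnorm(10))),
                 "zero-variance")
  expect_equal(f$r_squared, 0)
})

test_that("rank-deficient designs get the minimum-norm solution with effective rank as p", {
  set.seed(42)
  X <- cbind(1, matrix(rnorm(60), 30))
  X <- cbind(X, X[, 2] + X[, 3])  # exact collinearity
  colnames(X) <- c("(Intercept)", "a", "b", "ab")
  y <- rnorm(30)
  f <- fit_ols(y, X)
  expect_equal(f$p, 3L)
  orc <- ginv_fit_oracle(y, X)
  expect_lt(max(abs(unname(f$coefficients) - orc$beta)), 1e-8)
  expect_lt(max(abs(f$hat_diag - orc$h)), 1e-8)
})

test_that("externally studentized residuals equal the physical leave-one-out oracle", {
  pr <- rand_problem(314, n = 50, p = 6)
  f <- fit_ols(pr$y, pr$X)
  t_pkg <- studentized_residuals(f)
  t_loo <- loo_studentized_oracle(pr$y, pr$X)
  expect_lt(max(abs(unname(t_pkg) - t_loo)), 1e-8)
  # independent cross-check against stats::rstudent
  lm_fit <- lm(pr$y ~ pr$X - 1)
  expect_lt(max(abs(unname(t_pkg) - unname(rstudent(lm_fit)))), 1e-8)
})

test_that("the largest outlier carries the largest |t| and signs follow residuals", {
  x <- 1:5
  y <- c(2, 1, 4, 3, 10)
  f <- fit_ols(y, cbind(1, x))
  t_i <- studentized_residuals(f)
  expect_equal(unname(which.max(abs(t_i))), 5L)
  nz <- abs(f$residuals) > 1e-12
  expect_equal(sign(t_i[nz]), sign(f$residuals[nz]), ignore_attr = TRUE)
})

test_that("perfect fits give zero studentized residuals; tiny samples error", {
  f <- fit_ols(c(1, 2, 3, 4), cbind(1, 1:4))
  expect_equal(unname(studentized_residuals(f)), rep(0, 4))
  f2 <- fit_ols(c(1, 2, 3.1), cbind(1, 1:3))
  expect_error(studentized_residuals(f2), "insufficient degrees of freedom")
})

test_that("the Gaussian log-likelihood matches its closed form, scale law, and stats::logLik", {
  # n = 2, residuals (1, -1): RSS = 2 -> ll = -(ln 2pi + 1)
  f <- fit_ols(c(1, -1), matrix(1, 2, 1, dimnames = list(NULL, "(Intercept)")))
  expect_equal(f$log_likelihood, -(log(2 * pi) + 1), tolerance = 1e-12)

  pr <- rand_problem(7, n = 30, p = 4)
  f1 <- fit_ols(pr$y, pr$X)
  c_scale <- 3.7
  f2 <- fit_ols(c_scale * pr$y, pr$X)
  expect_equal(f2$log_likelihood, f1$log_likelihood - f1$n * log(c_scale),
               tolerance = 1e-8)
  lm_fit <- lm(pr$y ~ pr$X - 1)
  expect_equal(f1$log_likelihood, as.numeric(logLik(lm_fit)),
               tolerance = 1e-8)
})

test_that("LRT: df-0 and equal-RSS cases give statistic 0, p 1; statistic identity holds", {
  pr <- rand_problem(11, n = 40, p = 4)
  f_red <- fit_ols(pr$y, pr$X)
  f_same <- fit_ols(pr$y, pr$X)
  lrt0 <- likelihood_ratio_test(f_red, f_same)
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p_value, 1)

  # adding a duplicated column: no extra rank, no better fit
  Xdup <- cbind(pr$X, dup = pr$X[, 2])
  lrt_dup <- likelihood_ratio_test(f_red, fit_ols(pr$y, Xdup))
  expect_equal(lrt_dup$df, 0L)
  expect_equal(lrt_dup$p_value, 1)

  set.seed(12)
  Xfull <- cbind(pr$X, matrix(rnorm(40 * 3), 40,
                              dimnames = list(NULL, paste0("w", 1:3))))
  f_full <- fit_ols(pr$y, Xfull)
  lrt <- likelihood_ratio_test(f_red, f_full)
  expect_equal(lrt$df, 3L)
  expect_equal(lrt$statistic, f_full$n * log(f_red$rss / f_full$rss),
               tolerance = 1e-10)
  expect_equal(lrt$statistic, 2 * (f_full$log_likelihood - f_red$log_likelihood),
               tolerance = 1e-8)
  # p-value against a quadrature oracle of the chi-square density
  quad <- integrate(function(u) dchisq(u, df = 3), lower = lrt$statistic,
                    upper = Inf, rel.tol = 1e-12)$value
  expect_lt(abs(lrt$p_value - quad), 1e-8)
})

test_that("LRT rejects mismatched units and non-nested models", {
  pr <- rand_problem(13, n = 30, p = 3)
  f1 <- fit_ols(pr$y, pr$X, unit_ids = paste0("u", 1:30))
  f2 <- fit_ols(pr$y[-1], pr$X[-1, ], unit_ids = paste0("u", 2:30))
  expect_error(likelihood_ratio_test(f1, f2), "same unit set")
  X_other <- pr$X; colnames(X_other) <- c("(Intercept)", "q1", "q2")
  f3 <- fit_ols(pr$y, X_other, unit_ids = paste0("u", 1:30))
  expect_error(likelihood_ratio_test(f1, f3), "not a subset")
})

test_that("Cook's distance matches both the refit oracle and stats::cooks.distance", {
  pr <- rand_problem(21, n = 35, p = 5)
  f <- fit_ols(pr$y, pr$X)
  inf <- influence_diagnostics(f)
  D_oracle <- cooks_oracle(pr$y, pr$X)
  expect_lt(max(abs(inf$table$cooks_d - D_oracle)), 1e-8)
  lm_fit <- lm(pr$y ~ pr$X - 1)
  expect_lt(max(abs(inf$table$cooks_d - unname(cooks.distance(lm_fit)))), 1e-8)
})

test_that("influence flags require both high leverage and high Cook's distance", {
  # balanced design: every h_ii = p/n exactly, so nothing can be flagged
  X <- cbind(1, rep(c(-1, 1), each = 10))
  y <- rnorm(20)
  f <- fit_ols(y, X)
  expect_equal(f$hat_diag, rep(2 / 20, 20), tolerance = 1e-10)
  expect_length(influence_diagnostics(f)$flagged, 0L)

  # one covariate value 10 sample-sd out: that unit dominates leverage
  set.seed(31)
  x <- rnorm(19)
  x <- c(x, mean(x) + 10 * sd(x))
  y <- 0.5 * x + rnorm(20)
  f <- fit_ols(y, cbind(1, x))
  expect_equal(which.max(f$hat_diag), 20L)
  expect_gt(f$hat_diag[20], 2 * f$p / f$n)
})

test_that("coefficient intervals have the textbook form", {
  pr <- rand_problem(17, n = 45, p = 4)
  f <- fit_ols(pr$y, pr$X)
  ci <- confint(f)
  lm_fit <- lm(pr$y ~ pr$X - 1)
  ci_lm <- confint(lm_fit)
  expect_equal(unname(ci[, "lower"]), unname(ci_lm[, 1]), tolerance = 1e-8)
  expect_equal(unname(ci[, "upper"]), unname(ci_lm[, 2]), tolerance = 1e-8)
})

test_that("pooled studentized residuals under a correct model follow Student-t", {
  # 250 simulated fits (n = 40, p = 5) pooled: KS against t(34) must not
  # reject at the 1% level
  set.seed(5150)
  pool <- unlist(lapply(1:250, function(i) {
    X <- cbind(1, matrix(rnorm(40 * 4), 40))
    y <- drop(X %*% c(1, 0.5, -0.5, 0.3, 0)) + rnorm(40)
    unname(studentized_residuals(fit_ols(y, X)))
  }))
  ks <- suppressWarnings(ks.test(pool, function(q) pt(q, df = 34)))
  expect_gt(ks$p.value, 0.01)
})
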