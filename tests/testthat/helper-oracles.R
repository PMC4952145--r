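# Independent oracles and in-code fixtures shared across the test files.
# The oracles deliberately use a different computational route than the
# package (normal equations / pseudo-inverse / physical refitting) so that
# agreement is informative.

# Random well-conditioned regression problem with an intercept column.
rand_problem <- function(seed, n = 50, p = 6, sd_noise = 1) {
  set.seed(seed)
  X <- cbind(`(Intercept)` = 1,
             matrix(rnorm(n * (p - 1)), n,
                    dimnames = list(NULL, paste0("x", seq_len(p - 1)))))
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, sd = sd_noise)
  list(y = y, X = X, beta = beta)
}

# Externally studentized residuals by physically deleting each unit,
# refitting on the remaining n-1 rows, and predicting the held-out point.
loo_studentized_oracle <- function(y, X) {
  n <- length(y); p <- ncol(X)
  t_i <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    XtX <- crossprod(Xi)
    b <- solve(XtX, crossprod(Xi, yi))
    res <- yi - drop(Xi %*% b)
    s2 <- sum(res^2) / (length(yi) - p)
    xi <- X[i, ]
    pred_var <- s2 * (1 + drop(t(xi) %*% solve(XtX, xi)))
    t_i[i] <- (y[i] - drop(xi %*% b)) / sqrt(pred_var)
  }
  t_i
}

# Cook's distance by physical refitting: D_i = (b - b_(i))' X'X (b - b_(i)) / (p s^2).
cooks_oracle <- function(y, X) {
  n <- length(y); p <- ncol(X)
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - drop(X %*% b)
  s2 <- sum(res^2) / (n - p)
  D <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    bi <- solve(crossprod(Xi), crossprod(Xi, yi))
    d <- b - bi
    D[i] <- drop(t(d) %*% XtX %*% d) / (p * s2)
  }
  D
}

# Pseudo-inverse fit oracle (minimum-norm coefficients, hat diagonal,
# R-squared, Gaussian ML log-likelihood) via MASS::ginv.
ginv_fit_oracle <- function(y, X) {
  Xp <- MASS::ginv(X)
  beta <- drop(Xp %*% y)
  H <- X %*% Xp
  fitted <- drop(H %*% y)
  e <- y - fitted
  n <- length(y)
  rss <- sum(e^2)
  list(beta = beta, h = diag(H), fitted = fitted,
       r2 = 1 - rss / sum((y - mean(y))^2),
       ll = -(n / 2) * (log(2 * pi) + log(rss / n) + 1))
}

# Tiny two-context-variable role map and config for generator edge cases.
tiny_role_map <- function() {
  role_map(outcome_vars = c("rate_a", "rate_b"),
           context_vars = c("z1", "z2", "ctype"),
           mechanism_vars = "x1",
           reporting_vars = "pc_e",
           categorical_levels = list(ctype = c("metropolitan", "rural")))
}

tiny_config <- function(seed = 1L, n = 30L, sigma = 1, planted = NULL,
                        years = c(2009L, 2010L)) {
  rm <- tiny_role_map()
  beta <- c(z1 = 0.8, z2 = -0.5, ctyperural = 1.0, x1 = -0.7)
  simulation_config(
    states = c(AA = n), years = years,
    context_spec = list(z1 = list(dist = "normal", mean = 0, sd = 1),
                        z2 = list(dist = "normal", mean = 5, sd = 2),
                        ctype = list(levels = c("metropolitan", "rural"),
                                     probs = c(0.6, 0.4))),
    correlation = diag(2),
    mechanism_spec = list(x1 = list(dist = "normal", mean = 0, sd = 1)),
    coefficients = list(
      rate_a = list(alpha = 10, beta = beta, sigma = sigma),
      rate_b = list(alpha = 5, beta = beta / 2, sigma = sigma)),
    planted = planted,
    reporting_spec = list(pc_e = list(meanlog = 1, sdlog = 0.5)),
    rm = rm, seed = seed)
}

# Hand-built deterministic panel data frame for IO tests (one state, two
# years, small numbers, one incomplete row).
small_panel_df <- function(n = 10L) {
  set.seed(99)
  ids <- sprintf("AA-%03d", seq_len(n))
  rows <- list()
  for (yr in c(2009L, 2010L)) {
    rows[[as.character(yr)]] <- data.frame(
      jurisdiction = ids, state = "AA", year = yr,
      rate_a = round(runif(n, 5, 15), 3), rate_b = round(runif(n, 1, 9), 3),
      z1 = round(rnorm(n), 3), z2 = round(rnorm(n, 5, 2), 3),
      ctype = sample(c("metropolitan", "rural"), n, replace = TRUE),
      x1 = round(rnorm(n), 3), pc_e = round(rlnorm(n, 1, 0.5), 3),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# Build a flag matrix directly (for consolidation contract tests).
manual_pd_matrix <- function(flag_list, cols) {
  jurs <- sort(names(flag_list))
  m <- matrix(FALSE, length(jurs), length(cols),
              dimnames = list(jurs, cols))
  for (j in jurs) m[j, flag_list[[j]]] <- TRUE
  rb <- m; rb[] <- TRUE
  structure(m, class = c("pd_matrix", "matrix"), robust = rb)
}
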