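#' Ordinary least squares fit with diagnostics
#'
#' Fits `y = X b + e` by minimum-norm least squares via the singular value
#' decomposition and returns, alongside the coefficients, everything the
#' positive-deviance workflow needs downstream: residuals, hat-matrix
#' diagonal (leverage), maximum-likelihood and unbiased error variances,
#' the maximized Gaussian log-likelihood, and R-squared.
#'
#' Rank-deficient designs (which arise deliberately in the
#' correlated-covariate sensitivity analysis) are handled by the
#' minimum-norm solution; the effective rank is reported as `p` and used as
#' the degrees-of-freedom count everywhere, so nested-model likelihood-ratio
#' tests remain well defined under collinearity.
#'
#' @param y numeric outcome vector, no missing values.
#' @param design numeric matrix including an explicit intercept column;
#'   `nrow(design) == length(y)` and `length(y) > ncol(design)`.
#' @param unit_ids optional identifiers aligned to the rows of `design`.
#' @param outcome_name,stratum,step optional labels carried through to
#'   reports.
#' @param tol relative singular-value cutoff for the effective rank.
#'
#' @return an object of class `pd_fit` with fields `coefficients`,
#'   `residuals`, `fitted_values`, `hat_diag`, `sigma2_mle`,
#'   `sigma2_unbiased`, `log_likelihood`, `r_squared`, `n`, `p` (effective
#'   rank), `rss`, `column_names`, `unit_ids`, plus the design and outcome
#'   (kept for influence refits).
#' @export
fit_ols <- function(y, design, unit_ids = NULL, outcome_name = NULL,
                    stratum = NULL, step = NULL, tol = 1e-10) {
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(design) != n)
    stop("design and outcome lengths differ", call. = FALSE)
  if (anyNA(y) || anyNA(design))
    stop("missing values in outcome or design", call. = FALSE)
  if (n <= ncol(design))
    stop(sprintf("underdetermined fit: n = %d rows for %d design columns",
                 n, ncol(design)), call. = FALSE)
  if (is.null(unit_ids)) unit_ids <- as.character(seq_len(n))

  sv <- svd(design)
  r <- sum(sv$d > tol * max(sv$d[1L], 1))
  U <- sv$u[, seq_len(r), drop = FALSE]
  V <- sv$v[, seq_len(r), drop = FALSE]
  d <- sv$d[seq_len(r)]

  uty <- drop(crossprod(U, y))
  beta <- drop(V %*% (uty / d))
  names(beta) <- colnames(design)
  fitted <- drop(U %*% uty)
  e <- y - fitted
  h <- pmin(pmax(rowSums(U^2), 0), 1)
  rss <- sum(e^2)

  tss <- sum((y - mean(y))^2)
  if (tss <= 0) {
    warning("zero-variance outcome: degenerate fit, R-squared set to 0",
            call. = FALSE)
    r2 <- 0
  } else {
    r2 <- min(1, max(0, 1 - rss / tss))
  }

  sigma2_mle <- rss / n
  sigma2_unbiased <- rss / (n - r)
  ll <- if (sigma2_mle <= 0) Inf else
    -(n / 2) * (log(2 * pi) + log(sigma2_mle) + 1)

  structure(list(coefficients = beta, residuals = e, fitted_values = fitted,
                 hat_diag = h, sigma2_mle = sigma2_mle,
                 sigma2_unbiased = sigma2_unbiased, log_likelihood = ll,
                 r_squared = r2, n = n, p = r, rss = rss,
                 column_names = colnames(design), unit_ids = unit_ids,
                 outcome_name = outcome_name, stratum = stratum, step = step,
                 design = design, y = y,
                 svd = list(V = V, d = d)),
            class = "pd_fit")
}

#' @export
print.pd_fit <- function(x, ...) {
  cat(sprintf("OLS fit%s: n = %d, p = %d (effective rank), R^2 = %.3f, logLik = %.2f\n",
              if (!is.null(x$step)) paste0(" [", x$step, "]") else "",
              x$n, x$p, x$r_squared, x$log_likelihood))
  invisible(x)
}

#' Externally studentized residuals
#'
#' Returns `t_i = e_i / (s_(i) * sqrt(1 - h_ii))` where `s_(i)^2` is the
#' unbiased error variance of the fit that excludes unit `i`, obtained by
#' the closed-form leave-one-out downdate
#' `s_(i)^2 = ((n - p) s^2 - e_i^2 / (1 - h_ii)) / (n - p - 1)`
#' without refitting. Under a correct Gaussian model each `t_i` follows a
#' Student-t distribution with `n - p - 1` degrees of freedom, which is what
#' makes a fixed threshold such as -1 interpretable across cells of
#' different sizes.
#'
#' Units with `h_ii = 1` (self-determined fitted values) get `NA`; they are
#' surfaced through [influence_diagnostics()] instead. Exact zero residuals
#' give `t_i = 0`.
#'
#' @param fit a `pd_fit` with `n > p + 1`.
#' @return numeric vector named by `unit_ids`.
#' @export
studentized_residuals <- function(fit) {
  stopifnot(inherits(fit, "pd_fit"))
  n <- fit$n; p <- fit$p
  if (n <= p + 1L)
    stop(sprintf("insufficient degrees of freedom: n = %d, p = %d", n, p),
         call. = FALSE)
  e <- fit$residuals
  h <- fit$hat_diag
  s2 <- fit$sigma2_unbiased

  scale <- max(abs(fit$y), 1)
  t_i <- numeric(n)
  for (i in seq_len(n)) {
    if (h[i] >= 1 - 1e-10) { t_i[i] <- NA_real_; next }
    if (abs(e[i]) <= 1e-13 * scale) { t_i[i] <- 0; next }
    s2_loo <- ((n - p) * s2 - e[i]^2 / (1 - h[i])) / (n - p - 1)
    if (s2_loo <= 0) {
      t_i[i] <- sign(e[i]) * Inf
    } else {
      t_i[i] <- e[i] / sqrt(s2_loo * (1 - h[i]))
    }
  }
  names(t_i) <- fit$unit_ids
  t_i
}

#' Likelihood-ratio test for nested least-squares fits
#'
#' Compares two Gaussian maximum-likelihood fits of the same outcome on the
#' same units, the reduced model's columns a subset of the full model's.
#' The statistic is `2 (ll_full - ll_reduced)` (equivalently
#' `n log(RSS_reduced / RSS_full)`), referred to a chi-square distribution
#' with degrees of freedom equal to the difference in effective rank.
#'
#' The chi-square reference is asymptotic; at small `n` it rejects somewhat
#' more than the nominal level (see the methods vignette). An optional
#' Bartlett-style correction `n -> n - p_full - (q + 1)/2 ...` is available
#' via `correction = "bartlett"`, which replaces the multiplier `n` in the
#' statistic by `n - p_full + q/2 - 1` (Box's scaling for the Gaussian
#' linear model); the default applies no correction.
#'
#' @param reduced,full `pd_fit` objects, reduced nested in full.
#' @param correction `"none"` (default) or `"bartlett"`.
#' @return an object of class `pd_lrt`: `statistic`, `df`, `p_value`,
#'   `degenerate` (TRUE when the full model interpolates, RSS = 0).
#' @export
likelihood_ratio_test <- function(reduced, full,
                                  correction = c("none", "bartlett")) {
  stopifnot(inherits(reduced, "pd_fit"), inherits(full, "pd_fit"))
  correction <- match.arg(correction)
  if (reduced$n != full$n ||
      !identical(sort(reduced$unit_ids), sort(full$unit_ids)))
    stop("models were not fitted on the same unit set", call. = FALSE)
  if (max(abs(sort(reduced$y) - sort(full$y))) > 1e-12 * max(1, max(abs(full$y))))
    stop("models were not fitted on the same outcome vector", call. = FALSE)
  if (!all(reduced$column_names %in% full$column_names))
    stop("reduced model columns are not a subset of the full model's",
         call. = FALSE)

  df <- full$p - reduced$p
  degenerate <- is.infinite(full$log_likelihood)
  if (df == 0L) {
    stat <- 0; p <- 1
  } else if (degenerate) {
    stat <- Inf; p <- 0
  } else {
    mult <- switch(correction,
                   none = full$n,
                   bartlett = full$n - full$p + df / 2 - 1)
    stat <- mult * log(reduced$rss / full$rss)
    stat <- max(stat, 0)
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  structure(list(statistic = stat, df = df, p_value = p,
                 degenerate = degenerate, correction = correction),
            class = "pd_lrt")
}

#' @export
print.pd_lrt <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: statistic = %.4f, df = %d, p = %s%s\n",
              x$statistic, x$df, format_pvalue(x$p_value),
              if (x$degenerate) " (degenerate: full model interpolates)" else ""))
  invisible(x)
}

#' Leverage and influence diagnostics
#'
#' Computes, per unit, the leverage `h_ii`, the externally studentized
#' residual, and Cook's distance
#' `D_i = e_i^2 / (p s^2) * h_ii / (1 - h_ii)^2` (with `s^2` the unbiased
#' error variance). A unit is flagged as an influential leverage point when
#' both conditions hold: `h_ii > hat_multiplier * p / n` and
#' `D_i > cooks_threshold`. The joint rule reflects that an influential
#' leverage point must both sit far out in covariate space and actually move
#' the fit; both cutoffs are the field-standard defaults and are exposed as
#' arguments.
#'
#' @param fit a `pd_fit` with `n > p + 1`.
#' @param hat_multiplier leverage cutoff multiplier (default 2, i.e.
#'   `h_ii > 2 p / n`).
#' @param cooks_threshold Cook's distance cutoff (default `4 / n`).
#' @return an object of class `pd_influence`: data frame `table`
#'   (unit, h, t, cooks_d, flagged) and `flagged` (unit ids).
#' @export
influence_diagnostics <- function(fit, hat_multiplier = 2,
                                  cooks_threshold = NULL) {
  stopifnot(inherits(fit, "pd_fit"))
  n <- fit$n; p <- fit$p
  if (is.null(cooks_threshold)) cooks_threshold <- 4 / n
  h <- fit$hat_diag
  e <- fit$residuals
  s2 <- fit$sigma2_unbiased

  D <- ifelse(h >= 1 - 1e-10, Inf,
              (e^2 / (p * s2)) * h / (1 - h)^2)
  t_i <- studentized_residuals(fit)
  flagged <- (h > hat_multiplier * p / n) & (D > cooks_threshold)
  flagged[is.na(flagged)] <- TRUE  # h_ii = 1 units are influential by fiat

  tab <- data.frame(unit = fit$unit_ids, h = h, t = t_i, cooks_d = D,
                    flagged = flagged, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(list(table = tab, flagged = fit$unit_ids[flagged],
                 hat_multiplier = hat_multiplier,
                 cooks_threshold = cooks_threshold),
            class = "pd_influence")
}

#' @export
print.pd_influence <- function(x, ...) {
  cat(sprintf("Influence diagnostics: %d of %d unit(s) flagged (h > %g p/n and D > %g)\n",
              length(x$flagged), nrow(x$table), x$hat_multiplier,
              x$cooks_threshold))
  if (length(x$flagged))
    print.data.frame(x$table[x$table$flagged, , drop = FALSE],
                     row.names = FALSE)
  invisible(x)
}

#' Coefficient confidence intervals for a `pd_fit`
#'
#' Classical t-intervals from the unbiased error variance and the
#' (pseudo-inverse) coefficient covariance `s^2 V D^-2 V'`.
#'
#' @param object a `pd_fit`.
#' @param parm ignored (all coefficients are returned).
#' @param level confidence level.
#' @param ... unused.
#' @return matrix with columns `estimate`, `lower`, `upper`, `se`.
#' @export
confint.pd_fit <- function(object, parm = NULL, level = 0.95, ...) {
  V <- object$svd$V; d <- object$svd$d
  se <- sqrt(object$sigma2_unbiased * rowSums((V %*% diag(1 / d, length(d)))^2))
  q <- stats::qt(1 - (1 - level) / 2, df = object$n - object$p)
  est <- object$coefficients
  cbind(estimate = est, lower = est - q * se, upper = est + q * se, se = se)
}
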