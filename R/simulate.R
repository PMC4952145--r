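#' Simulation configuration for synthetic jurisdiction-year panels
#'
#' Describes a panel generator whose statistical structure matches what the
#' positive-deviance analysis assumes: context variables drawn once per
#' jurisdiction (slowly varying county attributes, held fixed across years),
#' mechanism variables drawn once per jurisdiction, and outcomes generated
#' from the linear model `Y = alpha + beta1 Z + beta2 X + sigma e` with
#' independent standard-normal noise per (jurisdiction, outcome, year) cell,
#' plus optional planted positive deviants: additive `shift * sigma` mean
#' shifts (`shift <= 0` for lower-is-better outcomes) in chosen cells.
#'
#' @param states named integer vector: jurisdictions per state.
#' @param years integer vector of calendar years.
#' @param context_spec named list over continuous context variables; each
#'   element `list(dist = "normal"|"lognormal", ...params, clamp = c(lo, hi))`.
#'   Categorical context variables instead give `list(levels =, probs =)`.
#' @param correlation correlation matrix over the continuous context
#'   variables (Gaussian copula); must be symmetric, unit-diagonal, PSD.
#' @param mechanism_spec named list over mechanism variables:
#'   `list(dist = "bernoulli", prob =)` or `list(dist = "normal", mean =, sd =)`.
#' @param coefficients named list over outcomes:
#'   `list(alpha =, beta = <named vector over design columns>, sigma =)`.
#' @param planted data frame with columns `jurisdiction`, `outcome`, `year`,
#'   `shift` (in units of that outcome's sigma, non-positive).
#' @param reporting_spec named list over reporting variables (per-capita
#'   expenditures), each `list(meanlog =, sdlog =)`, drawn independently per
#'   jurisdiction-year.
#' @param rm role map tying variable names to roles.
#' @param seed master integer seed; per-state substreams are derived from it
#'   deterministically so adding a state does not perturb the others.
#' @return an object of class `pd_sim_config`.
#' @export
simulation_config <- function(states, years, context_spec, correlation,
                              mechanism_spec, coefficients, planted = NULL,
                              reporting_spec = list(), rm = default_role_map(),
                              seed = 1L) {
  states <- as.integer(states) |> stats::setNames(names(states))
  if (is.null(names(states)) || any(!nzchar(names(states))))
    stop("states must be a named vector", call. = FALSE)
  if (any(states < 2L)) stop("each state needs at least 2 jurisdictions",
                             call. = FALSE)

  cont <- names(context_spec)[vapply(context_spec,
                                     function(s) is.null(s$levels), TRUE)]
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      any(abs(diag(correlation) - 1) > 1e-12))
    stop("correlation matrix must be symmetric with unit diagonal",
         call. = FALSE)
  if (min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8)
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  if (!identical(dim(correlation), c(length(cont), length(cont))))
    stop("correlation matrix dimension does not match the continuous ",
         "context variables", call. = FALSE)
  dimnames(correlation) <- list(cont, cont)

  for (oc in names(coefficients)) {
    if (!is.numeric(coefficients[[oc]]$sigma) || coefficients[[oc]]$sigma < 0)
      stop("sigma must be >= 0 for outcome ", oc, call. = FALSE)
  }
  if (is.null(planted))
    planted <- data.frame(jurisdiction = character(), outcome = character(),
                          year = integer(), shift = numeric())
  if (nrow(planted) && any(planted$shift > 0))
    stop("planted shifts must be <= 0 (lower-is-better outcomes)",
         call. = FALSE)

  structure(list(states = states, years = sort(as.integer(years)),
                 context_spec = context_spec, correlation = correlation,
                 mechanism_spec = mechanism_spec, coefficients = coefficients,
                 planted = planted, reporting_spec = reporting_spec,
                 role_map = rm, seed = as.integer(seed)),
            class = "pd_sim_config")
}

# Deterministic substream seed (kept below 2^31).
derive_seed <- function(master, k) {
  as.integer((as.double(master) * 7919 + as.double(k) * 104729) %% 2147483629)
}

draw_marginal <- function(z, spec) {
  x <- switch(spec$dist,
              normal = spec$mean + spec$sd * z,
              lognormal = exp(spec$meanlog + spec$sdlog * z),
              stop("unknown marginal distribution: ", spec$dist,
                   call. = FALSE))
  if (!is.null(spec$clamp)) x <- pmin(pmax(x, spec$clamp[1L]), spec$clamp[2L])
  x
}

marginal_sd <- function(spec) {
  switch(spec$dist,
         normal = spec$sd,
         lognormal = sqrt(exp(spec$sdlog^2) - 1) *
           exp(spec$meanlog + spec$sdlog^2 / 2),
         bernoulli = sqrt(spec$prob * (1 - spec$prob)),
         stop("unknown marginal distribution: ", spec$dist, call. = FALSE))
}

marginal_mean <- function(spec) {
  switch(spec$dist,
         normal = spec$mean,
         lognormal = exp(spec$meanlog + spec$sdlog^2 / 2),
         bernoulli = spec$prob,
         stop("unknown marginal distribution: ", spec$dist, call. = FALSE))
}

#' Generate a synthetic panel with known ground truth
#'
#' Deterministic given the config's seed: the same config always produces a
#' bit-identical panel. Context and mechanism variables are drawn once per
#' jurisdiction and repeated across years; outcome noise is independent
#' across all (jurisdiction, outcome, year) cells.
#'
#' @param config a `pd_sim_config`.
#' @return list with elements `panel` (a `pd_panel`) and `truth` (class
#'   `pd_ground_truth`: the planted-deviant table and the true
#'   coefficients).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "pd_sim_config"))
  rm <- config$role_map
  cont <- rownames(config$correlation)
  cat_vars <- setdiff(names(config$context_spec), cont)
  years <- config$years
  chol_R <- chol(config$correlation)

  state_frames <- vector("list", length(config$states))
  for (si in seq_along(config$states)) {
    st <- names(config$states)[si]
    n <- config$states[[si]]
    ids <- sprintf("%s-%03d", st, seq_len(n))
    set.seed(derive_seed(config$seed, si))

    Zc <- matrix(stats::rnorm(n * length(cont)), n) %*% chol_R
    jur <- data.frame(row.names = seq_len(n))
    for (j in seq_along(cont))
      jur[[cont[j]]] <- draw_marginal(Zc[, j], config$context_spec[[cont[j]]])
    for (v in cat_vars) {
      sp <- config$context_spec[[v]]
      jur[[v]] <- sample(sp$levels, n, replace = TRUE, prob = sp$probs)
    }
    for (v in names(config$mechanism_spec)) {
      sp <- config$mechanism_spec[[v]]
      jur[[v]] <- switch(sp$dist,
                         bernoulli = stats::rbinom(n, 1L, sp$prob),
                         normal = stats::rnorm(n, sp$mean, sp$sd),
                         stop("unknown mechanism distribution: ", sp$dist,
                              call. = FALSE))
    }

    noise <- list()
    for (yr in years) for (oc in rm$outcome_vars)
      noise[[paste(yr, oc)]] <- stats::rnorm(n)
    reporting <- list()
    for (yr in years) for (v in names(config$reporting_spec)) {
      sp <- config$reporting_spec[[v]]
      reporting[[paste(yr, v)]] <- stats::rlnorm(n, sp$meanlog, sp$sdlog)
    }

    rows <- list()
    for (yr in years) {
      d <- jur
      d[[rm$id_var]] <- ids
      d[[rm$state_var]] <- st
      d[[rm$year_var]] <- yr
      X <- build_design(d, rm, include_mechanism = TRUE)
      for (oc in rm$outcome_vars) {
        cf <- config$coefficients[[oc]]
        beta <- cf$beta[colnames(X)[-1L]]
        if (anyNA(beta))
          stop("coefficient spec for outcome '", oc,
               "' does not cover all design columns", call. = FALSE)
        d[[oc]] <- cf$alpha + drop(X[, -1L, drop = FALSE] %*% beta) +
          cf$sigma * noise[[paste(yr, oc)]]
      }
      for (v in names(config$reporting_spec))
        d[[v]] <- reporting[[paste(yr, v)]]
      rows[[as.character(yr)]] <- d
    }
    state_frames[[si]] <- do.call(rbind, rows)
  }

  data <- do.call(rbind, state_frames)
  rownames(data) <- NULL

  pl <- config$planted
  if (nrow(pl)) {
    bad <- setdiff(pl$jurisdiction, data[[rm$id_var]])
    if (length(bad))
      stop("planted deviant references nonexistent jurisdiction(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (!all(pl$outcome %in% rm$outcome_vars) || !all(pl$year %in% years))
      stop("planted deviant references unknown outcome or year",
           call. = FALSE)
    for (k in seq_len(nrow(pl))) {
      i <- which(data[[rm$id_var]] == pl$jurisdiction[k] &
                   data[[rm$year_var]] == pl$year[k])
      oc <- pl$outcome[k]
      data[i, oc] <- data[i, oc] +
        pl$shift[k] * config$coefficients[[oc]]$sigma
    }
  }

  ord <- order(data[[rm$state_var]], data[[rm$id_var]], data[[rm$year_var]])
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  front <- c(rm$id_var, rm$state_var, rm$year_var)
  data <- data[, c(front, setdiff(names(data), front)), drop = FALSE]

  truth <- structure(list(planted = pl, coefficients = config$coefficients),
                     class = "pd_ground_truth")
  list(panel = as_panel(data, rm), truth = truth)
}

#' Default study configuration
#'
#' Emulates the shape of the three-state study panel: states sized 35, 67
#' and 48 jurisdictions, two years, ten context variables (one 3-level
#' community-type category; heavy-tailed log-normal spending, population and
#' Medicaid-birth counts; index and percentage variables), moderate pairwise
#' copula correlation 0.3 among the continuous context variables with one
#' deliberately collinear pair at 0.85 (social disadvantage vs child
#' poverty, exercising the correlated-covariate sensitivity analysis), three
#' mechanism variables (two Bernoulli service-arrangement indicators and a
#' standard-normal latent service-delivery score), and four lower-is-better
#' outcomes.
#'
#' About 10% of jurisdictions per state are planted as true positive
#' deviants with `-2.5 sigma` shifts in two (outcome, year) cells, and about
#' 5% in exactly one cell; the latter group exercises the consolidation
#' rule's intended filtering of one-off flags.
#'
#' @param seed master integer seed.
#' @return a `pd_sim_config`.
#' @export
default_study_config <- function(seed = 1L) {
  rm <- default_role_map()
  states <- c(WA = 35L, FL = 67L, NY = 48L)
  years <- c(2009L, 2010L)

  context_spec <- list(
    total_expenditure = list(dist = "lognormal", meanlog = 13.5, sdlog = 0.9),
    population = list(dist = "lognormal", meanlog = 11.3, sdlog = 1.0),
    medicaid_births = list(dist = "lognormal", meanlog = 6.2, sdlog = 0.8),
    social_disadvantage = list(dist = "normal", mean = 0, sd = 1),
    pct_child_poverty = list(dist = "normal", mean = 20, sd = 6,
                             clamp = c(0, 100)),
    pct_hs_plus = list(dist = "normal", mean = 85, sd = 6, clamp = c(0, 100)),
    pct_african_american = list(dist = "normal", mean = 12, sd = 9,
                                clamp = c(0, 100)),
    pct_hispanic = list(dist = "normal", mean = 10, sd = 7,
                        clamp = c(0, 100)),
    providers_per_capita = list(dist = "lognormal", meanlog = -5.9,
                                sdlog = 0.5),
    community_type = list(levels = c("metropolitan", "micropolitan", "rural"),
                          probs = c(0.52, 0.23, 0.25))
  )
  cont <- setdiff(names(context_spec), "community_type")
  R <- matrix(0.3, length(cont), length(cont),
              dimnames = list(cont, cont))
  diag(R) <- 1
  R["social_disadvantage", "pct_child_poverty"] <- 0.85
  R["pct_child_poverty", "social_disadvantage"] <- 0.85

  mechanism_spec <- list(
    alt_provider = list(dist = "bernoulli", prob = 0.4),
    clinician_exec = list(dist = "bernoulli", prob = 0.35),
    service_delivery_score = list(dist = "normal", mean = 0, sd = 1)
  )

  # Context effects expressed per marginal SD, then rescaled to the observed
  # scale; outcome-specific gains spread step-1 R^2 over roughly 0.15-0.7.
  per_sd <- c(total_expenditure = -0.10, population = -0.10,
              medicaid_births = 0.15, social_disadvantage = 0.45,
              pct_child_poverty = 0.45, pct_hs_plus = -0.35,
              pct_african_american = 0.15, pct_hispanic = 0.10,
              providers_per_capita = -0.10)
  gains <- c(teen_birth_rate = 1.6, late_prenatal_care_rate = 1.0,
             infant_mortality_rate = 0.55, low_birth_weight_pct = 0.9)
  alphas <- c(teen_birth_rate = 30, late_prenatal_care_rate = 18,
              infant_mortality_rate = 7, low_birth_weight_pct = 8)
  sigmas <- c(teen_birth_rate = 6, late_prenatal_care_rate = 4,
              infant_mortality_rate = 1.8, low_birth_weight_pct = 1.2)

  coefficients <- list()
  for (oc in rm$outcome_vars) {
    g <- gains[[oc]]; s <- sigmas[[oc]]
    beta <- numeric(0)
    for (v in cont)
      beta[v] <- g * per_sd[[v]] * s / marginal_sd(context_spec[[v]])
    beta["community_typemicropolitan"] <- g * 0.15 * s
    beta["community_typerural"] <- g * 0.25 * s
    beta["alt_provider"] <- -0.45 * s
    beta["clinician_exec"] <- -0.40 * s
    beta["service_delivery_score"] <- -0.35 * s
    # the intercept absorbs the expected covariate contribution so outcome
    # levels sit at realistic positive rates
    exp_contrib <-
      sum(vapply(cont, function(v)
        beta[[v]] * marginal_mean(context_spec[[v]]), 0)) +
      beta[["community_typemicropolitan"]] * context_spec$community_type$probs[2L] +
      beta[["community_typerural"]] * context_spec$community_type$probs[3L] +
      beta[["alt_provider"]] * mechanism_spec$alt_provider$prob +
      beta[["clinician_exec"]] * mechanism_spec$clinician_exec$prob +
      beta[["service_delivery_score"]] * mechanism_spec$service_delivery_score$mean
    coefficients[[oc]] <- list(alpha = alphas[[oc]] - exp_contrib,
                               beta = beta, sigma = s)
  }

  reporting_spec <- list(
    pc_total_mch_exp = list(meanlog = log(12), sdlog = 0.6),
    pc_wic_exp = list(meanlog = log(3), sdlog = 0.8),
    pc_family_planning_exp = list(meanlog = log(2.5), sdlog = 0.9),
    pc_mica_exp = list(meanlog = log(4), sdlog = 0.8)
  )

  # Planted deviants: deterministic draw from a dedicated substream.
  set.seed(derive_seed(seed, 997L))
  cells <- expand.grid(outcome = rm$outcome_vars, year = years,
                       stringsAsFactors = FALSE)
  pl <- list()
  for (si in seq_along(states)) {
    st <- names(states)[si]; n <- states[[si]]
    ids <- sprintf("%s-%03d", st, seq_len(n))
    n_multi <- round(0.10 * n)
    n_single <- round(0.05 * n)
    chosen <- sample(ids, n_multi + n_single)
    multi <- chosen[seq_len(n_multi)]
    single <- chosen[n_multi + seq_len(n_single)]
    for (j in multi) {
      ci <- sample(nrow(cells), 2L)
      pl[[length(pl) + 1L]] <- data.frame(
        jurisdiction = j, outcome = cells$outcome[ci], year = cells$year[ci],
        shift = -2.5, n_cells = 2L, stringsAsFactors = FALSE)
    }
    for (j in single) {
      ci <- sample(nrow(cells), 1L)
      pl[[length(pl) + 1L]] <- data.frame(
        jurisdiction = j, outcome = cells$outcome[ci], year = cells$year[ci],
        shift = -2.5, n_cells = 1L, stringsAsFactors = FALSE)
    }
  }
  planted <- do.call(rbind, pl)

  simulation_config(states = states, years = years,
                    context_spec = context_spec, correlation = R,
                    mechanism_spec = mechanism_spec,
                    coefficients = coefficients, planted = planted,
                    reporting_spec = reporting_spec, rm = rm, seed = seed)
}

#' @export
print.pd_sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %s; years {%s}; %d planted deviant cell(s); seed %d\n",
              paste(sprintf("%s=%d", names(x$states), x$states),
                    collapse = ", "),
              paste(x$years, collapse = ", "), nrow(x$planted), x$seed))
  invisible(x)
}
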