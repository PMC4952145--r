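#' Identify candidate positive deviants in one analysis cell
#'
#' One cell is a (state, outcome, year) stratum. The three-step procedure:
#' fit the context-only model `Y = alpha + beta1 Z + e` (step 1), the full
#' model `Y = alpha + beta1 Z + beta2 X + e` (step 2) on the identical unit
#' set, and compare them with a likelihood-ratio test (step 3). Externally
#' studentized residuals are taken from the residual-source model (step 2 by
#' default, regardless of the LRT outcome, so that every cell is scored on
#' the same model form; the LRT is reported, not gating) and a jurisdiction
#' is flagged when its residual is strictly below the threshold (default
#' -1), i.e. its outcome is substantially better than predicted.
#'
#' Influential leverage points (joint leverage and Cook's-distance rule, see
#' [influence_diagnostics()]) are identified on the residual-source fit; the
#' cell is then refitted without them and a jurisdiction is recorded as
#' *robust* when its flag agrees between the two fits (units that were
#' themselves removed get `NA`).
#'
#' @param panel a `pd_panel`.
#' @param state,outcome,year the cell; `year = NULL` pools all years.
#' @param threshold studentized-residual cutoff, default -1 (strict `<`).
#' @param residual_source `"step2"` (default) or `"step1"`.
#' @param drop_vars model columns to omit (used by the covariate
#'   sensitivity analysis).
#' @param hat_multiplier,cooks_threshold influence-rule cutoffs, passed to
#'   [influence_diagnostics()].
#' @return an object of class `pd_cell_result`.
#' @export
identify_cell <- function(panel, state, outcome, year = NULL,
                          threshold = -1, residual_source = c("step2", "step1"),
                          drop_vars = character(), hat_multiplier = 2,
                          cooks_threshold = NULL) {
  stopifnot(inherits(panel, "pd_panel"))
  residual_source <- match.arg(residual_source)
  rm <- panel$role_map

  d <- cell_rows(panel, state, outcome, year, drop_vars)
  if (nrow(d) == 0L)
    stop(sprintf("cell (%s, %s, %s) has no complete rows", state, outcome,
                 if (is.null(year)) "pooled" else year), call. = FALSE)
  y <- d[[outcome]]
  if (nrow(d) > 1L && stats::var(y) == 0)
    stop(sprintf("degenerate cell (%s, %s, %s): outcome is constant", state,
                 outcome, if (is.null(year)) "pooled" else year),
         call. = FALSE)
  uid <- if (is.null(year))
    paste0(d[[rm$id_var]], "@", d[[rm$year_var]]) else d[[rm$id_var]]

  fit_pair <- function(dd, ids) {
    yy <- dd[[outcome]]
    X1 <- build_design(dd, rm, include_mechanism = FALSE,
                       drop_vars = drop_vars)
    X2 <- build_design(dd, rm, include_mechanism = TRUE,
                       drop_vars = drop_vars)
    stratum <- list(state = state, year = year %||% "pooled")
    list(step1 = fit_ols(yy, X1, ids, outcome, stratum, "context_only"),
         step2 = fit_ols(yy, X2, ids, outcome, stratum, "full"))
  }

  fits <- fit_pair(d, uid)
  if (fits$step2$n <= fits$step2$p + 1L)
    stop(sprintf("cell (%s, %s, %s) is not fittable: n = %d, p = %d", state,
                 outcome, if (is.null(year)) "pooled" else year,
                 fits$step2$n, fits$step2$p), call. = FALSE)
  lrt <- likelihood_ratio_test(fits$step1, fits$step2)
  src_fit <- if (residual_source == "step2") fits$step2 else fits$step1
  scores <- studentized_residuals(src_fit)
  flags <- !is.na(scores) & scores < threshold

  influence <- influence_diagnostics(src_fit, hat_multiplier, cooks_threshold)

  if (length(influence$flagged) &&
      (nrow(d) - length(influence$flagged)) >
      n_design_cols(rm, setdiff(model_vars(rm), drop_vars)) + 1L) {
    keep <- !(uid %in% influence$flagged)
    fits2 <- fit_pair(d[keep, , drop = FALSE], uid[keep])
    src2 <- if (residual_source == "step2") fits2$step2 else fits2$step1
    scores2 <- studentized_residuals(src2)
    flags2 <- !is.na(scores2) & scores2 < threshold
    robust <- rep(NA, length(uid))
    names(robust) <- uid
    robust[names(flags2)] <- flags[names(flags2)] == flags2
  } else {
    scores2 <- scores
    flags2 <- flags
    robust <- stats::setNames(rep(TRUE, length(uid)), uid)
  }

  structure(list(state = state, outcome = outcome,
                 year = year %||% "pooled", threshold = threshold,
                 residual_source = residual_source, drop_vars = drop_vars,
                 step1_fit = fits$step1, step2_fit = fits$step2, lrt = lrt,
                 scores = scores, flags = flags, influence = influence,
                 leverage_sensitivity = list(scores = scores2,
                                             flags = flags2,
                                             robust = robust)),
            class = "pd_cell_result")
}

#' @export
print.pd_cell_result <- function(x, ...) {
  cat(sprintf("Cell (%s, %s, %s): n = %d, R^2 %.2f -> %.2f, LRT p = %s, %d flagged (t < %g)\n",
              x$state, x$outcome, x$year, x$step2_fit$n,
              x$step1_fit$r_squared, x$step2_fit$r_squared,
              format_pvalue(x$lrt$p_value), sum(x$flags), x$threshold))
  if (any(x$flags))
    cat("  flagged:", paste(names(x$flags)[x$flags], collapse = ", "), "\n")
  invisible(x)
}

#' Run the identification over every analysis cell
#'
#' Iterates (state, outcome, year) cells in lexicographic order, skipping
#' and recording non-fittable or degenerate cells rather than failing the
#' whole run.
#'
#' @inheritParams identify_cell
#' @param pooled_years fit one pooled cell per (state, outcome) instead of
#'   one per year.
#' @return list of `pd_cell_result` (class `pd_cell_results`) with a
#'   `skips` attribute: data frame of skipped cells and reasons.
#' @export
run_all_cells <- function(panel, threshold = -1,
                          residual_source = c("step2", "step1"),
                          drop_vars = character(), pooled_years = FALSE,
                          hat_multiplier = 2, cooks_threshold = NULL) {
  stopifnot(inherits(panel, "pd_panel"))
  residual_source <- match.arg(residual_source)
  rm <- panel$role_map
  states <- sort(unique(panel$data[[rm$state_var]]))
  outcomes <- sort(rm$outcome_vars)

  results <- list()
  skips <- list()
  for (st in states) {
    years <- if (pooled_years) list(NULL) else
      as.list(sort(unique(
        panel$data[[rm$year_var]][panel$data[[rm$state_var]] == st])))
    for (oc in outcomes) for (yr in years) {
      res <- tryCatch(
        identify_cell(panel, st, oc, yr, threshold, residual_source,
                      drop_vars, hat_multiplier, cooks_threshold),
        error = function(e) e)
      if (inherits(res, "error")) {
        skips[[length(skips) + 1L]] <- data.frame(
          state = st, outcome = oc, year = as.character(yr %||% "pooled"),
          reason = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        results[[length(results) + 1L]] <- res
      }
    }
  }
  skips <- if (length(skips)) do.call(rbind, skips) else
    data.frame(state = character(), outcome = character(),
               year = character(), reason = character())
  structure(results, class = "pd_cell_results", skips = skips)
}

#' @export
print.pd_cell_results <- function(x, ...) {
  cat(sprintf("Positive-deviance cell results: %d cell(s), %d skipped, %d flag(s) total\n",
              length(x), nrow(attr(x, "skips")),
              sum(vapply(x, function(r) sum(r$flags), 0L))))
  invisible(x)
}

# Flagged (jurisdiction, outcome, year) triples of one result, resolving
# pooled unit ids "jur@year" back to (jurisdiction, year).
flag_triples <- function(res, which_flags = res$flags) {
  ids <- names(which_flags)[which_flags]
  if (!length(ids)) return(character())
  if (identical(res$year, "pooled")) {
    parts <- strsplit(ids, "@", fixed = TRUE)
    vapply(parts, function(p) paste(p[1L], res$outcome, p[2L], sep = "|"), "")
  } else {
    paste(ids, res$outcome, res$year, sep = "|")
  }
}

#' Build the jurisdiction-by-(outcome, year) flag matrix
#'
#' Rows are all jurisdictions that entered any cell; columns are
#' `(outcome, year)` pairs. Entries are `TRUE`/`FALSE` flags, and `NA` where
#' the jurisdiction was not scored in that cell (different state roster with
#' a missing cell, or excluded as incomplete) -- absence is distinct from a
#' negative result.
#'
#' @param results a `pd_cell_results` (or list of `pd_cell_result`).
#' @return a logical matrix of class `pd_matrix` with a parallel `robust`
#'   attribute holding the leverage-sensitivity agreement per entry.
#' @export
build_pd_matrix <- function(results) {
  keys <- vapply(results, function(r) paste(r$state, r$outcome, r$year), "")
  if (anyDuplicated(keys))
    stop("duplicate (state, outcome, year) results: ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "),
         call. = FALSE)

  entries <- list()
  for (res in results) {
    pooled <- identical(res$year, "pooled")
    ids <- names(res$flags)
    jur <- if (pooled) sub("@.*$", "", ids) else ids
    yrs <- if (pooled) sub("^.*@", "", ids) else rep(as.character(res$year),
                                                     length(ids))
    entries[[length(entries) + 1L]] <- data.frame(
      jurisdiction = jur, col = paste(res$outcome, yrs, sep = "|"),
      flag = unname(res$flags),
      robust = unname(res$leverage_sensitivity$robust[ids]),
      stringsAsFactors = FALSE)
  }
  e <- do.call(rbind, entries)
  jurs <- sort(unique(e$jurisdiction))
  cols <- sort(unique(e$col))
  m <- matrix(NA, length(jurs), length(cols), dimnames = list(jurs, cols))
  rb <- m
  m[cbind(match(e$jurisdiction, jurs), match(e$col, cols))] <- e$flag
  rb[cbind(match(e$jurisdiction, jurs), match(e$col, cols))] <- e$robust
  structure(m, class = c("pd_matrix", "matrix"), robust = rb)
}

#' Consolidate the flag matrix into the final positive-deviant set
#'
#' A jurisdiction is a consolidated positive deviant when it is flagged in
#' at least `min_cells` (outcome, year) cells, counting over all cells: two
#' outcomes in one year qualify, as does the same outcome in two years.
#'
#' @param pd_matrix a `pd_matrix`.
#' @param min_cells minimum flagged cells for membership (default 2).
#' @return an object of class `pd_set`: `members` (jurisdiction ids),
#'   `cells` (named list of flagged cell labels per member), `robust_frac`
#'   (per member, share of its flagged cells whose flag was robust to
#'   influential-point removal), `n_flagged_any` (jurisdictions with >= 1
#'   flag).
#' @export
consolidate <- function(pd_matrix, min_cells = 2L) {
  stopifnot(inherits(pd_matrix, "pd_matrix"))
  if (min_cells < 1L) stop("min_cells must be >= 1", call. = FALSE)
  counts <- rowSums(pd_matrix == TRUE, na.rm = TRUE)
  members <- sort(names(counts)[counts >= min_cells])
  rb <- attr(pd_matrix, "robust")
  cells <- lapply(members, function(j)
    colnames(pd_matrix)[which(pd_matrix[j, ] == TRUE)])
  names(cells) <- members
  robust_frac <- vapply(members, function(j) {
    idx <- which(pd_matrix[j, ] == TRUE)
    mean(rb[j, idx], na.rm = TRUE)
  }, 0)
  structure(list(members = members, cells = cells,
                 robust_frac = robust_frac, min_cells = as.integer(min_cells),
                 n_flagged_any = sum(counts >= 1L),
                 n_jurisdictions = nrow(pd_matrix)),
            class = "pd_set")
}

#' @export
print.pd_set <- function(x, ...) {
  cat(sprintf("Consolidated positive-deviant set: %d member(s) of %d jurisdictions (>= %d flagged cells); %d with >= 1 flag\n",
              length(x$members), x$n_jurisdictions, x$min_cells,
              x$n_flagged_any))
  if (length(x$members)) {
    for (j in x$members)
      cat(sprintf("  %s: %s\n", j, paste(x$cells[[j]], collapse = ", ")))
  }
  invisible(x)
}

#' Covariate and parsimony sensitivity analysis
#'
#' Checks that the flagged set is stable under (a) dropping one member of
#' each highly correlated continuous covariate pair and (b) scoring on the
#' parsimonious context-only model instead of the full model. For each
#' correlated pair the dropped member is the one with the larger mean
#' absolute correlation to all other continuous covariates (ties broken
#' alphabetically, dropping the alphabetically first name). Stability is
#' summarised as the Jaccard similarity between each variant's flagged
#' (jurisdiction, outcome, year) set and the primary run's.
#'
#' @param panel a `pd_panel`.
#' @param correlation_cutoff absolute within-state correlation above which a
#'   covariate pair is considered highly correlated (default 0.8).
#' @param threshold residual threshold passed through to the runs.
#' @param primary optionally, a precomputed primary `pd_cell_results`.
#' @return an object of class `pd_sensitivity`: data frame `variants`
#'   (variant label, dropped variable, Jaccard, flag counts) plus the
#'   variant results.
#' @export
covariate_sensitivity <- function(panel, correlation_cutoff = 0.8,
                                  threshold = -1, primary = NULL) {
  stopifnot(inherits(panel, "pd_panel"))
  rm <- panel$role_map
  if (is.null(primary)) primary <- run_all_cells(panel, threshold)
  primary_set <- unique(unlist(lapply(primary, flag_triples)))

  cont <- setdiff(model_vars(rm), names(rm$categorical_levels))
  is_binary <- vapply(cont, function(v) {
    x <- panel$data[[v]]
    all(stats::na.omit(x) %in% c(0, 1))
  }, TRUE)
  cont <- cont[!is_binary]

  pairs <- list()
  cors <- list()
  for (st in unique(panel$data[[rm$state_var]])) {
    d <- panel$data[panel$data[[rm$state_var]] == st, cont, drop = FALSE]
    C <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
    cors[[st]] <- C
    hi <- which(abs(C) > correlation_cutoff & upper.tri(C), arr.ind = TRUE)
    if (nrow(hi))
      for (k in seq_len(nrow(hi)))
        pairs[[length(pairs) + 1L]] <- sort(c(rownames(C)[hi[k, 1L]],
                                              colnames(C)[hi[k, 2L]]))
  }
  pairs <- unique(pairs)

  jaccard <- function(a, b) {
    if (!length(a) && !length(b)) return(1)
    length(intersect(a, b)) / length(union(a, b))
  }

  variants <- list()
  rows <- list()
  for (pr in pairs) {
    # mean |cor| to all others, averaged over states
    mean_abs <- vapply(pr, function(v) {
      mean(vapply(cors, function(C) mean(abs(C[v, setdiff(cont, v)]),
                                         na.rm = TRUE), 0))
    }, 0)
    drop_v <- if (abs(diff(mean_abs)) < 1e-12) sort(pr)[1L] else
      pr[which.max(mean_abs)]
    res <- run_all_cells(panel, threshold, drop_vars = drop_v)
    fs <- unique(unlist(lapply(res, flag_triples)))
    lbl <- paste0("drop_", drop_v)
    variants[[lbl]] <- res
    rows[[length(rows) + 1L]] <- data.frame(
      variant = lbl, pair = paste(pr, collapse = " ~ "), dropped = drop_v,
      jaccard = jaccard(primary_set, fs), n_flags = length(fs),
      stringsAsFactors = FALSE)
  }

  res_p <- run_all_cells(panel, threshold, residual_source = "step1")
  fs_p <- unique(unlist(lapply(res_p, flag_triples)))
  variants[["parsimonious"]] <- res_p
  rows[[length(rows) + 1L]] <- data.frame(
    variant = "parsimonious", pair = NA_character_, dropped = NA_character_,
    jaccard = jaccard(primary_set, fs_p), n_flags = length(fs_p),
    stringsAsFactors = FALSE)

  structure(list(table = do.call(rbind, rows),
                 primary_flags = primary_set, variants = variants,
                 correlation_cutoff = correlation_cutoff),
            class = "pd_sensitivity")
}

#' @export
print.pd_sensitivity <- function(x, ...) {
  cat(sprintf("Covariate/parsimony sensitivity (|r| > %g): %d variant(s), primary has %d flags\n",
              x$correlation_cutoff, nrow(x$table), length(x$primary_flags)))
  print.data.frame(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
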