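#' Format a p-value for display
#'
#' Values below 0.001 render as `"< 0.001"`; otherwise three decimals.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p)))
}

#' Model summary table (R-squared by step and LRT p-value)
#'
#' One row per fitted cell: step-1 (context-only) and step-2 (full)
#' R-squared and the likelihood-ratio p-value for adding the mechanism
#' variables, with a display column using the `"< 0.001"` convention.
#'
#' @param results a `pd_cell_results`.
#' @return data frame of class `pd_model_summary`.
#' @export
model_summary_table <- function(results) {
  rows <- lapply(results, function(r) data.frame(
    state = r$state, outcome = r$outcome, year = as.character(r$year),
    n = r$step2_fit$n, r2_step1 = r$step1_fit$r_squared,
    r2_step2 = r$step2_fit$r_squared, lrt_df = r$lrt$df,
    lrt_p = r$lrt$p_value, lrt_p_display = format_pvalue(r$lrt$p_value),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$state, out$outcome, out$year), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pd_model_summary", "data.frame")
  out
}

#' Expenditure comparison between positive deviants and their peers
#'
#' For each state, community type, and group (PD / non-PD), and for each
#' per-capita expenditure variable: the group size, its share of the
#' group's state total, and the min--max (mean) summary. A jurisdiction's
#' expenditure values are averaged over years first, so multi-year panels
#' do not double-count jurisdictions. A `Combined` block pools all states.
#' `pd_mean_lower` marks, on both rows of a (stratum, variable) pair,
#' whether the PD group's mean is below the non-PD group's -- the pattern
#' highlighted in the study tables.
#'
#' @param panel a `pd_panel` whose role map declares a community-type
#'   categorical context variable.
#' @param pd_set a `pd_set` from [consolidate()].
#' @param expenditure_vars columns to summarise; defaults to the role map's
#'   reporting variables.
#' @param community_var name of the community-type column.
#' @return data frame of class `pd_expenditure_comparison`: one row per
#'   (state, community_type, group, variable).
#' @export
expenditure_comparison <- function(panel, pd_set, expenditure_vars = NULL,
                                   community_var = "community_type") {
  stopifnot(inherits(panel, "pd_panel"), inherits(pd_set, "pd_set"))
  rm <- panel$role_map
  if (is.null(expenditure_vars)) expenditure_vars <- rm$reporting_vars
  if (!all(expenditure_vars %in% c(rm$reporting_vars, model_vars(rm))))
    stop("expenditure_vars must be declared panel columns", call. = FALSE)
  d <- panel$data
  if (anyNA(d[[community_var]]))
    stop("every jurisdiction needs a community-type value", call. = FALSE)

  # jurisdiction-level frame: community type, state, year-averaged spending
  agg <- stats::aggregate(d[, expenditure_vars, drop = FALSE],
                          by = list(jurisdiction = d[[rm$id_var]]),
                          FUN = mean, na.rm = TRUE)
  first <- !duplicated(d[[rm$id_var]])
  meta <- data.frame(jurisdiction = d[[rm$id_var]][first],
                     state = d[[rm$state_var]][first],
                     community = d[[community_var]][first],
                     stringsAsFactors = FALSE)
  jd <- merge(meta, agg, by = "jurisdiction")
  jd$group <- ifelse(jd$jurisdiction %in% pd_set$members, "PD", "non-PD")

  ct_levels <- rm$categorical_levels[[community_var]] %||%
    sort(unique(jd$community))

  summarise_block <- function(block, state_label) {
    rows <- list()
    for (grp in c("non-PD", "PD")) {
      g_total <- sum(block$group == grp)
      for (ct in ct_levels) {
        cell <- block[block$group == grp & block$community == ct, ,
                      drop = FALSE]
        n <- nrow(cell)
        for (v in expenditure_vars) {
          vals <- cell[[v]]
          rows[[length(rows) + 1L]] <- data.frame(
            state = state_label, community_type = ct, group = grp, n = n,
            pct_of_group = if (g_total > 0) 100 * n / g_total else NA_real_,
            variable = v,
            min = if (n) min(vals) else NA_real_,
            max = if (n) max(vals) else NA_real_,
            mean = if (n) mean(vals) else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  }

  blocks <- lapply(sort(unique(jd$state)),
                   function(st) summarise_block(jd[jd$state == st, ], st))
  blocks[[length(blocks) + 1L]] <- summarise_block(jd, "Combined")
  out <- do.call(rbind, blocks)

  out$pd_mean_lower <- NA
  key <- paste(out$state, out$community_type, out$variable)
  for (k in unique(key)) {
    i <- which(key == k)
    pd_mean <- out$mean[i][out$group[i] == "PD"]
    np_mean <- out$mean[i][out$group[i] == "non-PD"]
    if (length(pd_mean) == 1L && length(np_mean) == 1L &&
        !is.na(pd_mean) && !is.na(np_mean))
      out$pd_mean_lower[i] <- pd_mean < np_mean
  }
  rownames(out) <- NULL
  class(out) <- c("pd_expenditure_comparison", "data.frame")
  out
}

#' @export
print.pd_expenditure_comparison <- function(x, digits = 2, ...) {
  cat("Expenditure comparison (PD vs non-PD; * = PD mean lower)\n")
  disp <- data.frame(
    state = x$state, community = x$community_type, group = x$group,
    n = sprintf("%d (%s%%)", x$n,
                ifelse(is.na(x$pct_of_group), "-",
                       sprintf("%.0f", x$pct_of_group))),
    variable = x$variable,
    `min-max (mean)` = ifelse(
      x$n == 0, "-",
      sprintf("%.2f-%.2f (%.2f)%s", x$min, x$max, x$mean,
              ifelse(!is.na(x$pd_mean_lower) & x$pd_mean_lower, " *", ""))),
    check.names = FALSE, stringsAsFactors = FALSE)
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}
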