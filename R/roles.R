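#' Declare variable roles for a jurisdiction-year panel
#'
#' A role map records which panel columns play which part in the
#' positive-deviance analysis: outcomes (Y), context variables (Z, factors a
#' jurisdiction cannot readily change), mechanism variables (X, factors under
#' some jurisdiction control), identifier columns, and reporting-only columns
#' (per-capita expenditures summarised in the final tables but never entered
#' into any model).
#'
#' @param outcome_vars character vector of outcome column names (Y).
#' @param context_vars character vector of context column names (Z).
#' @param mechanism_vars character vector of mechanism column names (X).
#' @param id_var name of the jurisdiction identifier column.
#' @param state_var name of the state column.
#' @param year_var name of the calendar-year column.
#' @param reporting_vars character vector of reporting-only columns
#'   (per-capita expenditure variables); may be empty.
#' @param categorical_levels named list; each element gives the allowed
#'   category labels of one categorical context/mechanism column. The first
#'   label is the reference level used when the column is encoded as
#'   indicator columns.
#' @param lower_is_better named logical over `outcome_vars`; `TRUE` means a
#'   smaller value of the outcome is the good direction (the default for
#'   rate-type outcomes such as infant mortality).
#'
#' @return an object of class `pd_role_map`.
#' @seealso [default_role_map()] for the roles used by the bundled
#'   synthetic study panel.
#' @export
role_map <- function(outcome_vars, context_vars, mechanism_vars = character(),
                     id_var = "jurisdiction", state_var = "state",
                     year_var = "year", reporting_vars = character(),
                     categorical_levels = list(),
                     lower_is_better = NULL) {
  stopifnot(is.character(outcome_vars), is.character(context_vars),
            is.character(mechanism_vars), is.character(reporting_vars))
  if (length(outcome_vars) < 1L)
    stop("at least one outcome variable must be declared", call. = FALSE)
  if (length(context_vars) < 1L)
    stop("at least one context variable must be declared", call. = FALSE)

  groups <- list(outcome = outcome_vars, context = context_vars,
                 mechanism = mechanism_vars, reporting = reporting_vars,
                 id = c(id_var, state_var, year_var))
  all_cols <- unlist(groups, use.names = FALSE)
  dup <- unique(all_cols[duplicated(all_cols)])
  if (length(dup))
    stop("column(s) declared in more than one role: ",
         paste(dup, collapse = ", "), call. = FALSE)

  bad_cat <- setdiff(names(categorical_levels),
                     c(context_vars, mechanism_vars))
  if (length(bad_cat))
    stop("categorical declaration for column(s) not in context or mechanism ",
         "variables: ", paste(bad_cat, collapse = ", "), call. = FALSE)

  if (is.null(lower_is_better)) {
    lower_is_better <- rep(TRUE, length(outcome_vars))
    names(lower_is_better) <- outcome_vars
  }
  if (!all(outcome_vars %in% names(lower_is_better)))
    stop("lower_is_better must name every outcome variable", call. = FALSE)

  structure(list(outcome_vars = outcome_vars, context_vars = context_vars,
                 mechanism_vars = mechanism_vars, id_var = id_var,
                 state_var = state_var, year_var = year_var,
                 reporting_vars = reporting_vars,
                 categorical_levels = categorical_levels,
                 lower_is_better = lower_is_better[outcome_vars]),
            class = "pd_role_map")
}

#' Default role map for the synthetic study panel
#'
#' Mirrors the variable set of the maternal-and-child-health application:
#' ten context variables (spending, population, Medicaid-funded births,
#' community type, social-disadvantage index, child poverty, education,
#' race/ethnicity composition, provider supply), three mechanism variables
#' (two service-arrangement indicators and a latent service-delivery score),
#' four lower-is-better outcomes, and four per-capita expenditure reporting
#' columns.
#'
#' @return a `pd_role_map`.
#' @export
default_role_map <- function() {
  role_map(
    outcome_vars = c("teen_birth_rate", "late_prenatal_care_rate",
                     "infant_mortality_rate", "low_birth_weight_pct"),
    context_vars = c("total_expenditure", "population", "medicaid_births",
                     "community_type", "social_disadvantage",
                     "pct_child_poverty", "pct_hs_plus",
                     "pct_african_american", "pct_hispanic",
                     "providers_per_capita"),
    mechanism_vars = c("alt_provider", "clinician_exec",
                       "service_delivery_score"),
    id_var = "jurisdiction", state_var = "state", year_var = "year",
    reporting_vars = c("pc_total_mch_exp", "pc_wic_exp",
                       "pc_family_planning_exp", "pc_mica_exp"),
    categorical_levels = list(
      community_type = c("metropolitan", "micropolitan", "rural"))
  )
}

#' @export
print.pd_role_map <- function(x, ...) {
  cat("Variable role map\n")
  cat("  id:        ", x$id_var, " / ", x$state_var, " / ", x$year_var, "\n",
      sep = "")
  cat("  outcomes:  ", paste(x$outcome_vars, collapse = ", "), "\n", sep = "")
  cat("  context:   ", paste(x$context_vars, collapse = ", "), "\n", sep = "")
  cat("  mechanism: ", paste(x$mechanism_vars, collapse = ", "), "\n", sep = "")
  if (length(x$reporting_vars))
    cat("  reporting: ", paste(x$reporting_vars, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

# All model columns (context + mechanism), in declaration order.
model_vars <- function(rm) c(rm$context_vars, rm$mechanism_vars)

# Number of design columns (intercept + continuous + indicator encodings)
# for the given variable subset.
n_design_cols <- function(rm, vars) {
  k <- 1L  # intercept
  for (v in vars) {
    lev <- rm$categorical_levels[[v]]
    k <- k + if (is.null(lev)) 1L else length(lev) - 1L
  }
  k
}

# Load a role map from a YAML or JSON file.
read_role_map <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  lib <- spec$lower_is_better
  if (!is.null(lib)) lib <- unlist(lib)
  role_map(outcome_vars = unlist(spec$outcome_vars),
           context_vars = unlist(spec$context_vars),
           mechanism_vars = unlist(spec$mechanism_vars %||% character()),
           id_var = spec$id_var %||% "jurisdiction",
           state_var = spec$state_var %||% "state",
           year_var = spec$year_var %||% "year",
           reporting_vars = unlist(spec$reporting_vars %||% character()),
           categorical_levels = lapply(spec$categorical_levels %||% list(),
                                       unlist),
           lower_is_better = lib)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
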