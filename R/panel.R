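#' Construct a panel from a data frame
#'
#' A panel couples one jurisdiction-year table with a [role_map()] declaring
#' how its columns are used. Construction validates the schema: all declared
#' columns present, `(jurisdiction, year)` unique, categorical cells drawn
#' from their declared label sets, and numeric model columns numeric.
#' Rows with missing values are retained; completeness is assessed per
#' analysis cell by [validate_panel()] and model fitting excludes incomplete
#' rows cell-locally (a row incomplete only for one outcome's columns still
#' participates in the other outcomes' models).
#'
#' @param data data frame with one row per (jurisdiction, year).
#' @param rm a `pd_role_map`.
#' @return an object of class `pd_panel` with elements `data` and `role_map`.
#' @export
as_panel <- function(data, rm) {
  stopifnot(is.data.frame(data), inherits(rm, "pd_role_map"))
  data <- as.data.frame(data, stringsAsFactors = FALSE)

  declared <- c(rm$id_var, rm$state_var, rm$year_var, rm$outcome_vars,
                rm$context_vars, rm$mechanism_vars, rm$reporting_vars)
  missing_cols <- setdiff(declared, names(data))
  if (length(missing_cols))
    stop("panel is missing declared column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  key <- paste(data[[rm$id_var]], data[[rm$year_var]], sep = "\r")
  if (anyDuplicated(key)) {
    d <- data[duplicated(key), c(rm$id_var, rm$year_var)]
    stop("duplicate (jurisdiction, year) row(s): ",
         paste(unique(paste0(d[[1L]], "/", d[[2L]])), collapse = ", "),
         call. = FALSE)
  }

  for (v in names(rm$categorical_levels)) {
    lev <- rm$categorical_levels[[v]]
    vals <- data[[v]]
    bad <- which(!is.na(vals) & !(vals %in% lev))
    if (length(bad))
      stop(sprintf("column '%s', row %d: value '%s' not among declared categories {%s}",
                   v, bad[1L], vals[bad[1L]], paste(lev, collapse = ", ")),
           call. = FALSE)
  }

  numeric_model <- setdiff(c(rm$outcome_vars, rm$context_vars,
                             rm$mechanism_vars, rm$reporting_vars),
                           names(rm$categorical_levels))
  for (v in numeric_model) {
    if (!is.numeric(data[[v]])) {
      raw <- data[[v]]
      conv <- suppressWarnings(as.numeric(ifelse(raw == "", NA, raw)))
      bad <- which(!is.na(raw) & raw != "" & is.na(conv))
      if (length(bad))
        stop(sprintf("column '%s', row %d: cannot parse '%s' as a number",
                     v, bad[1L], raw[bad[1L]]), call. = FALSE)
      data[[v]] <- conv
    }
  }
  data[[rm$year_var]] <- as.integer(data[[rm$year_var]])
  data[[rm$id_var]] <- as.character(data[[rm$id_var]])
  data[[rm$state_var]] <- as.character(data[[rm$state_var]])

  structure(list(data = data, role_map = rm), class = "pd_panel")
}

#' Read a panel from a delimited text file
#'
#' Expects a comma-separated UTF-8 file with a header row, `.` decimal
#' marks, and missing values written as empty cells or `NA`.
#'
#' @param path path to the panel CSV.
#' @param rm a `pd_role_map`, or the path of a YAML/JSON role-map file.
#' @return a `pd_panel`.
#' @export
load_panel <- function(path, rm) {
  if (is.character(rm)) rm <- read_role_map(rm)
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("", "NA"), fileEncoding = "UTF-8")
  as_panel(data, rm)
}

#' Write a panel to a delimited text file
#'
#' Numeric cells are serialized with 17 significant digits so that
#' `load_panel(write_panel(p))` round-trips every double bit-exactly.
#'
#' @param panel a `pd_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "pd_panel"))
  out <- panel$data
  for (v in names(out)) {
    if (is.double(out[[v]])) {
      s <- sprintf("%.17g", out[[v]])
      s[is.na(out[[v]])] <- NA
      out[[v]] <- s
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.pd_panel <- function(x, ...) {
  d <- x$data; rm <- x$role_map
  cat(sprintf("Jurisdiction-year panel: %d rows, %d jurisdictions, %d state(s), years {%s}\n",
              nrow(d), length(unique(d[[rm$id_var]])),
              length(unique(d[[rm$state_var]])),
              paste(sort(unique(d[[rm$year_var]])), collapse = ", ")))
  invisible(x)
}

# Rows of `panel$data` belonging to one analysis cell, complete for the
# given outcome's model columns, sorted by jurisdiction id (canonical order
# so results do not depend on input row order). `year = NULL` pools years.
cell_rows <- function(panel, state, outcome, year = NULL,
                      drop_vars = character()) {
  rm <- panel$role_map
  d <- panel$data
  sel <- d[[rm$state_var]] == state
  if (!is.null(year)) sel <- sel & d[[rm$year_var]] == year
  d <- d[sel, , drop = FALSE]
  needed <- c(outcome, setdiff(model_vars(rm), drop_vars))
  complete <- stats::complete.cases(d[, needed, drop = FALSE])
  d <- d[complete, , drop = FALSE]
  d[order(d[[rm$id_var]], d[[rm$year_var]]), , drop = FALSE]
}

#' Per-cell completeness and fittability report
#'
#' For every (state, outcome, year) analysis cell, counts the rows complete
#' in that cell's model columns (listwise within the cell), the rows
#' excluded as incomplete, and whether the cell is fittable
#' (`n_complete > design columns + 1`). Report-only: no errors are raised.
#' Negative values in outcome columns are listed as notes, since rate-type
#' outcomes are expected to be non-negative in real data.
#'
#' @param panel a `pd_panel`.
#' @return an object of class `pd_validation`: a data frame of cells plus a
#'   `notes` attribute.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "pd_panel"))
  rm <- panel$role_map
  d <- panel$data
  states <- sort(unique(d[[rm$state_var]]))
  years <- sort(unique(d[[rm$year_var]]))
  p_full <- n_design_cols(rm, model_vars(rm))

  rows <- list()
  for (st in states) for (oc in rm$outcome_vars) for (yr in years) {
    in_cell <- d[[rm$state_var]] == st & d[[rm$year_var]] == yr
    n_cell <- sum(in_cell)
    needed <- c(oc, model_vars(rm))
    n_complete <- sum(stats::complete.cases(
      d[in_cell, needed, drop = FALSE]))
    rows[[length(rows) + 1L]] <- data.frame(
      state = st, outcome = oc, year = yr, n = n_cell,
      n_complete = n_complete, n_incomplete = n_cell - n_complete,
      p = p_full, fittable = n_complete > p_full + 1L,
      stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, rows)

  notes <- character()
  for (oc in rm$outcome_vars) {
    neg <- sum(d[[oc]] < 0, na.rm = TRUE)
    if (neg > 0)
      notes <- c(notes, sprintf("outcome '%s' has %d negative value(s)",
                                oc, neg))
  }
  yr_by_state <- tapply(d[[rm$year_var]], d[[rm$state_var]],
                        function(y) paste(sort(unique(y)), collapse = ","))
  if (length(unique(yr_by_state)) > 1L)
    notes <- c(notes, "states do not share an identical year set")

  structure(rep, class = c("pd_validation", "data.frame"), notes = notes)
}

#' @export
print.pd_validation <- function(x, ...) {
  cat("Panel validation report\n")
  print.data.frame(x, row.names = FALSE)
  notes <- attr(x, "notes")
  if (length(notes)) cat("Notes:\n", paste(" -", notes, collapse = "\n"), "\n")
  invisible(x)
}

# Design matrix (with explicit intercept) for the given rows and variable
# subset; categorical columns are indicator-encoded against their first
# declared level.
build_design <- function(df, rm, include_mechanism = TRUE,
                         drop_vars = character()) {
  vars <- rm$context_vars
  if (include_mechanism) vars <- c(vars, rm$mechanism_vars)
  vars <- setdiff(vars, drop_vars)

  n <- nrow(df)
  cols <- list(`(Intercept)` = rep(1, n))
  for (v in vars) {
    lev <- rm$categorical_levels[[v]]
    if (is.null(lev)) {
      cols[[v]] <- as.numeric(df[[v]])
    } else {
      for (l in lev[-1L]) cols[[paste0(v, l)]] <- as.numeric(df[[v]] == l)
    }
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(cols)
  mat
}
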