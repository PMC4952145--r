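test_that("the flag rule is strictly 'less than': a score exactly at the threshold is not flagged", {
  sim <- generate_panel(default_study_config(4L))
  res <- identify_cell(sim$panel, "FL", "low_birth_weight_pct", 2009L)
  expect_identical(unname(res$flags),
                   unname(!is.na(res$scores) & res$scores < -1))
  # rerun with the threshold placed exactly on an achieved negative score
  k <- which.min(res$scores)
  t0 <- res$scores[[k]]
  res2 <- identify_cell(sim$panel, "FL", "low_birth_weight_pct", 2009L,
                        threshold = t0)
  expect_false(res2$flags[[k]])
  expect_equal(res2$scores[[k]], t0)
})

test_that("tightening the threshold from -1 to -2 never enlarges the flag set", {
  sim <- generate_panel(default_study_config(9L))
  r1 <- run_all_cells(sim$panel, threshold = -1)
  r2 <- run_all_cells(sim$panel, threshold = -2)
  f1 <- unlist(lapply(r1, posdev:::flag_triples))
  f2 <- unlist(lapply(r2, posdev:::flag_triples))
  expect_true(all(f2 %in% f1))
  expect_lt(length(f2), length(f1))
})

test_that("step-2 residuals are the default scoring source and both steps share the unit set", {
  sim <- generate_panel(default_study_config(4L))
  res <- identify_cell(sim$panel, "NY", "teen_birth_rate", 2010L)
  expect_identical(res$residual_source, "step2")
  expect_identical(res$step1_fit$unit_ids, res$step2_fit$unit_ids)
  expect_gte(res$step2_fit$r_squared, res$step1_fit$r_squared)
  t_manual <- studentized_residuals(res$step2_fit)
  expect_equal(res$scores, t_manual)
})

test_that("run_all_cells covers 3 states x 4 outcomes x 2 years and skips missing cells", {
  sim <- generate_panel(default_study_config(12L))
  res <- run_all_cells(sim$panel)
  expect_length(res, 24L)
  expect_equal(nrow(attr(res, "skips")), 0L)

  # removing one state-year leaves 20 results and 4 skip records
  d <- sim$panel$data
  d$teen_birth_rate[d$state == "WA" & d$year == 2010L] <- NA
  d$late_prenatal_care_rate[d$state == "WA" & d$year == 2010L] <- NA
  d$infant_mortality_rate[d$state == "WA" & d$year == 2010L] <- NA
  d$low_birth_weight_pct[d$state == "WA" & d$year == 2010L] <- NA
  res2 <- run_all_cells(as_panel(d, sim$panel$role_map))
  expect_length(res2, 20L)
  expect_equal(nrow(attr(res2, "skips")), 4L)
  expect_true(all(attr(res2, "skips")$state == "WA"))
})

test_that("results are invariant to input row order", {
  sim <- generate_panel(default_study_config(3L))
  res_a <- run_all_cells(sim$panel)
  set.seed(1)
  shuffled <- sim$panel$data[sample(nrow(sim$panel$data)), ]
  res_b <- run_all_cells(as_panel(shuffled, sim$panel$role_map))
  fa <- lapply(res_a, function(r) r$flags)
  fb <- lapply(res_b, function(r) r$flags)
  expect_identical(fa, fb)
})

test_that("the PD matrix is faithful bookkeeping of cell flags", {
  sim <- generate_panel(default_study_config(6L))
  res <- run_all_cells(sim$panel)
  m <- build_pd_matrix(res)
  expect_equal(ncol(m), 8L)  # 4 outcomes x 2 years
  expect_equal(nrow(m), 150L)
  for (r in res[1:4]) {
    col <- paste(r$outcome, r$year, sep = "|")
    expect_identical(unname(m[names(r$flags), col]), unname(r$flags))
  }
  total_flags <- sum(vapply(res, function(r) sum(r$flags), 0L))
  expect_equal(sum(m == TRUE, na.rm = TRUE), total_flags)
  expect_error(build_pd_matrix(c(res, res[1])), "duplicate")
})

test_that("consolidation implements the multiple-cells membership rule", {
  cols <- c("low_birth_weight_pct|2009", "low_birth_weight_pct|2010",
            "teen_birth_rate|2009", "teen_birth_rate|2010")
  m <- manual_pd_matrix(list(
    # flagged LBW 2009 + LBW and teen 2010 -> in
    A = c("low_birth_weight_pct|2009", "low_birth_weight_pct|2010",
          "teen_birth_rate|2010"),
    B = "low_birth_weight_pct|2009",              # one cell only -> out
    C = c("low_birth_weight_pct|2009", "teen_birth_rate|2009"),  # same year -> in
    D = character()), cols)
  s <- consolidate(m, min_cells = 2L)
  expect_setequal(s$members, c("A", "C"))
  expect_setequal(s$cells$A, c("low_birth_weight_pct|2009",
                               "low_birth_weight_pct|2010",
                               "teen_birth_rate|2010"))
  expect_equal(s$n_flagged_any, 3L)
  expect_error(consolidate(m, min_cells = 0L), "min_cells")
  empty <- manual_pd_matrix(list(A = character(), B = character()), cols)
  expect_length(consolidate(empty)$members, 0L)
})

test_that("members always sit inside the >=1-flag set and min_cells = 1 recovers it", {
  sim <- generate_panel(default_study_config(8L))
  m <- build_pd_matrix(run_all_cells(sim$panel))
  s2 <- consolidate(m, 2L)
  s1 <- consolidate(m, 1L)
  any_flag <- rownames(m)[rowSums(m == TRUE, na.rm = TRUE) >= 1L]
  expect_true(all(s2$members %in% any_flag))
  expect_setequal(s1$members, any_flag)
})

test_that("dropping an exactly duplicated covariate leaves the flags unchanged (Jaccard 1)", {
  rm <- role_map(outcome_vars = "y", context_vars = c("z1", "z2", "z1_copy"),
                 mechanism_vars = "x1")
  set.seed(77)
  n <- 40L
  df <- data.frame(jurisdiction = sprintf("AA-%03d", 1:n), state = "AA",
                   year = 2009L, z1 = rnorm(n), z2 = rnorm(n), x1 = rnorm(n),
                   stringsAsFactors = FALSE)
  df$z1_copy <- df$z1
  df$y <- 2 + df$z1 - df$z2 + 0.5 * df$x1 + rnorm(n)
  panel <- as_panel(df, rm)
  sens <- covariate_sensitivity(panel, correlation_cutoff = 0.8)
  drop_row <- sens$table[grepl("^drop_", sens$table$variant), ]
  expect_equal(nrow(drop_row), 1L)
  expect_true(drop_row$dropped %in% c("z1", "z1_copy"))
  expect_equal(drop_row$jaccard, 1.0)
})

test_that("the default panel's collinear pair triggers a drop variant; a clean panel only the parsimonious one", {
  sim <- generate_panel(default_study_config(2L))
  res <- run_all_cells(sim$panel)
  sens <- covariate_sensitivity(sim$panel, primary = res)
  expect_true(any(grepl("^drop_", sens$table$variant)))
  expect_true("parsimonious" %in% sens$table$variant)
  expect_true(all(sens$table$jaccard >= 0 & sens$table$jaccard <= 1))

  clean <- generate_panel(tiny_config(seed = 5L, n = 40L))
  sens2 <- covariate_sensitivity(clean$panel)
  expect_identical(sens2$table$variant, "parsimonious")
})

test_that("leverage sensitivity re-runs without influential units and annotates agreement", {
  sim <- generate_panel(default_study_config(10L))
  res <- run_all_cells(sim$panel)
  had_influential <- vapply(res, function(r) length(r$influence$flagged) > 0, TRUE)
  expect_true(any(had_influential))  # heavy-tailed context makes these likely
  for (r in res) {
    rb <- r$leverage_sensitivity$robust
    expect_true(all(is.na(rb) | rb %in% c(TRUE, FALSE)))
    if (length(r$influence$flagged) == 0L) {
      expect_true(all(rb))
      expect_identical(r$leverage_sensitivity$flags, r$flags)
    } else {
      removed <- intersect(names(rb), r$influence$flagged)
      expect_true(all(is.na(rb[removed])))
      kept <- setdiff(names(rb), r$influence$flagged)
      agree <- r$flags[kept] == r$leverage_sensitivity$flags[kept]
      expect_identical(unname(rb[kept]), unname(agree))
    }
  }
})

test_that("pooled-years fitting produces one cell per state-outcome with per-year scores", {
  sim <- generate_panel(default_study_config(7L))
  res <- run_all_cells(sim$panel, pooled_years = TRUE)
  expect_length(res, 12L)
  expect_true(all(vapply(res, function(r) identical(r$year, "pooled"), TRUE)))
  expect_equal(res[[1]]$step2_fit$n, 134L)  # FL: 67 x 2 years
  m <- build_pd_matrix(res)
  expect_equal(ncol(m), 8L)  # flags still resolve to (outcome, year)
})
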