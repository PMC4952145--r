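test_that("model summary rows keep the nested-model R-squared ordering and display rule", {
  sim <- generate_panel(default_study_config(14L))
  res <- run_all_cells(sim$panel)
  ms <- model_summary_table(res)
  expect_equal(nrow(ms), 24L)
  expect_true(all(ms$r2_step2 >= ms$r2_step1))
  expect_true(all(ms$lrt_p >= 0 & ms$lrt_p <= 1))
  small <- ms$lrt_p < 0.001
  expect_identical(ms$lrt_p_display[small],
                   rep("< 0.001", sum(small)))
})

test_that("p-value display follows the under-0.001 convention", {
  expect_identical(format_pvalue(c(0.0004, 0.001, 0.03, 0.17)),
                   c("< 0.001", "0.001", "0.030", "0.170"))
})

test_that("LRT p-values are approximately uniform when the mechanism truly adds nothing", {
  # tiny config with mechanism coefficient forced to zero
  cfg <- tiny_config(seed = 55L, n = 60L, years = 2009L)
  for (oc in names(cfg$coefficients)) cfg$coefficients[[oc]]$beta["x1"] <- 0
  ps <- vapply(1:300, function(i) {
    cfg$seed <- 1000L + i
    sim <- generate_panel(cfg)
    identify_cell(sim$panel, "AA", "rate_a", 2009L)$lrt$p_value
  }, 0)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("expenditure comparison averages within jurisdiction before grouping", {
  rm <- tiny_role_map()
  df <- small_panel_df(4L)
  # jurisdiction means (2,4)->3 and (6,6)->6; group mean 4.5
  df$pc_e[df$jurisdiction == "AA-001"] <- c(2, 4)
  df$pc_e[df$jurisdiction == "AA-002"] <- c(6, 6)
  df$ctype <- "rural"
  panel <- as_panel(df, rm)
  pd_set <- consolidate(manual_pd_matrix(
    list(`AA-003` = c("a|2009", "a|2010"), `AA-004` = character()),
    c("a|2009", "a|2010")), 2L)
  cmp <- expenditure_comparison(panel, pd_set, expenditure_vars = "pc_e",
                                community_var = "ctype")
  row <- cmp[cmp$state == "AA" & cmp$group == "non-PD" &
               cmp$community_type == "rural", ]
  # non-PD group holds AA-001, AA-002, AA-004
  expect_equal(row$n, 3L)
  jm <- c(3, 6, mean(df$pc_e[df$jurisdiction == "AA-004"]))
  expect_equal(row$mean, mean(jm))
  expect_equal(row$min, min(jm))
})

test_that("singleton groups collapse to min = max = mean and empty groups are marked absent", {
  rm <- tiny_role_map()
  df <- small_panel_df(3L)
  df$ctype <- c("metropolitan", "rural", "rural")[match(df$jurisdiction,
                                                        unique(df$jurisdiction))]
  df$pc_e[df$jurisdiction == "AA-001"] <- 5.0
  panel <- as_panel(df, rm)
  pd_set <- consolidate(manual_pd_matrix(
    list(`AA-002` = c("a|2009", "a|2010")), c("a|2009", "a|2010")), 2L)
  cmp <- expenditure_comparison(panel, pd_set, expenditure_vars = "pc_e",
                                community_var = "ctype")
  single <- cmp[cmp$group == "non-PD" & cmp$community_type == "metropolitan" &
                  cmp$state == "AA", ]
  expect_equal(single$n, 1L)
  expect_equal(single$min, 5.0)
  expect_equal(single$max, 5.0)
  expect_equal(single$mean, 5.0)
  empty <- cmp[cmp$group == "PD" & cmp$community_type == "metropolitan" &
                 cmp$state == "AA", ]
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean))
})

test_that("pd_mean_lower marks exactly the strata where PDs spent less, and percents sum to 100", {
  sim <- generate_panel(default_study_config(4L))
  res <- run_all_cells(sim$panel)
  pd_set <- consolidate(build_pd_matrix(res))
  cmp <- expenditure_comparison(sim$panel, pd_set)
  key <- paste(cmp$state, cmp$community_type, cmp$variable)
  for (k in unique(key)) {
    pair <- cmp[key == k, ]
    pd <- pair[pair$group == "PD", ]; np <- pair[pair$group == "non-PD", ]
    if (!is.na(pd$mean) && !is.na(np$mean))
      expect_identical(unique(pair$pd_mean_lower), pd$mean < np$mean)
  }
  sums <- tapply(cmp$pct_of_group[cmp$variable == cmp$variable[1]],
                 paste(cmp$state, cmp$group)[cmp$variable == cmp$variable[1]],
                 sum, na.rm = TRUE)
  expect_true(all(abs(sums - 100) < 1e-8))
})
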