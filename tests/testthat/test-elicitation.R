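# Expert-panel aggregation: consensus medians, dissent records, coverage.

test_that("unanimous panels reproduce their sheet with no dissent", {
  sh <- uniform_sheet(prio_model, 2)
  panel <- panel_from_sheets(list(sh, sh, sh))
  out <- aggregate_panel(panel, prio_model)
  expect_equal(out$consensus$scores, sh$scores)
  expect_identical(nrow(out$dissent), 0L)
})

test_that("consensus is the median with halves rounded away from zero", {
  base <- uniform_sheet(prio_model, 2)
  s1 <- with_score(base, "Disease knowledge", "Speed of spread", 1)
  s2 <- with_score(base, "Disease knowledge", "Speed of spread", 2)
  s3 <- with_score(base, "Disease knowledge", "Speed of spread", 4)
  out <- aggregate_panel(panel_from_sheets(list(s1, s2, s3)), prio_model,
                         dissent_threshold = 1)
  expect_identical(out$consensus$scores[["Disease knowledge"]][["Speed of spread"]], 2L)
  expect_identical(nrow(out$dissent), 1L)
  expect_identical(out$dissent$range, 3L)
  expect_identical(out$dissent$sub_criterion, "Speed of spread")
  expect_identical(out$dissent$expert_scores, "1,2,4")

  # even panel {2, 3}: median 2.5 rounds away from zero to 3
  s2b <- with_score(base, "Disease knowledge", "Speed of spread", 3)
  even <- aggregate_panel(panel_from_sheets(list(s2, s2b)), prio_model)
  expect_identical(even$consensus$scores[["Disease knowledge"]][["Speed of spread"]], 3L)
  # and toward-zero rounding is available as the documented alternative
  even2 <- aggregate_panel(panel_from_sheets(list(s2, s2b)), prio_model,
                           half = "toward_zero")
  expect_identical(even2$consensus$scores[["Disease knowledge"]][["Speed of spread"]], 2L)
})

test_that("negative-scale halves also round away from zero", {
  base <- uniform_sheet(gap_model, 0)
  a <- with_score(base, "Diagnostic tools", "Speed", -1)
  b <- with_score(base, "Diagnostic tools", "Speed", -2)
  out <- aggregate_panel(panel_from_sheets(list(a, b)), gap_model)
  expect_identical(out$consensus$scores[["Diagnostic tools"]][["Speed"]], -2L)
})

test_that("aggregation is invariant to expert order and stays in range", {
  set.seed(21)
  sheets <- lapply(1:5, function(i) random_sheet(prio_model))
  out1 <- aggregate_panel(panel_from_sheets(sheets), prio_model)
  out2 <- aggregate_panel(panel_from_sheets(rev(sheets)), prio_model)
  expect_equal(out1$consensus$scores, out2$consensus$scores)
  ord <- do.call(order, out1$dissent[c("criterion", "sub_criterion")])
  ord2 <- do.call(order, out2$dissent[c("criterion", "sub_criterion")])
  expect_equal(out1$dissent[ord, ], out2$dissent[ord2, ], ignore_attr = TRUE)

  for (cr in prio_model$criteria) {
    for (sub in cr$sub_criteria) {
      v <- vapply(sheets, function(s) s$scores[[cr$name]][[sub]], integer(1))
      cons <- out1$consensus$scores[[cr$name]][[sub]]
      expect_gte(cons, min(v))
      expect_lte(cons, max(v))
      expect_true(cons %in% cr$scale$values)
    }
  }
})

test_that("threshold zero records every sub-criterion with any disagreement", {
  set.seed(33)
  sheets <- lapply(1:4, function(i) random_sheet(prio_model))
  out <- aggregate_panel(panel_from_sheets(sheets), prio_model,
                         dissent_threshold = 0)
  expected <- 0L
  for (cr in prio_model$criteria) {
    for (sub in cr$sub_criteria) {
      v <- vapply(sheets, function(s) s$scores[[cr$name]][[sub]], integer(1))
      if (max(v) > min(v)) expected <- expected + 1L
    }
  }
  expect_identical(nrow(out$dissent), expected)
})

test_that("degenerate panels are rejected", {
  expect_error(panel_scores("dz", list()), class = "priogap_invalid_argument")
  sh <- uniform_sheet(prio_model, 1)
  other <- uniform_sheet(prio_model, 1, id = "other")
  expect_error(panel_from_sheets(list(sh, other), id = "dz"),
               class = "priogap_validation_error")
  dup <- list(list(expert_id = "e1", role = "other", sheet = sh),
              list(expert_id = "e1", role = "other", sheet = sh))
  expect_error(panel_scores("dz", dup), class = "priogap_invalid_argument")
})

test_that("coverage summary reproduces counts, percent and mean size", {
  sh <- uniform_sheet(prio_model, 1)
  full <- panel_from_sheets(rep(list(sh), 7))   # 7 experts, four roles covered
  small <- panel_from_sheets(rep(list(sh), 3))  # too few experts
  expect_true(full$minimum_coverage_met)
  expect_false(small$minimum_coverage_met)

  one <- panel_coverage_summary(list(full))
  expect_equal(one, list(n_panels = 1L, n_meeting_minimum = 1L,
                         percent_meeting_minimum = 100L, mean_panel_size = 7))

  panels <- c(rep(list(full), 43), rep(list(small), 9))
  s <- panel_coverage_summary(panels)
  expect_identical(s$n_panels, 52L)
  expect_identical(s$n_meeting_minimum, 43L)
  expect_identical(s$percent_meeting_minimum, 83L)

  expect_equal(panel_coverage_summary(rep(list(full), 3))$mean_panel_size, 7)

  # four experts spanning only three roles do not meet the minimum
  uncovered <- panel_scores("dz", lapply(1:4, function(i) {
    list(expert_id = sprintf("e%d", i),
         role = c("diagnostic", "epidemiology", "industry", "other")[i],
         sheet = sh)
  }))
  expect_false(uncovered$minimum_coverage_met)
})
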