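# The scoring engine: criterion totals, overall totals, gap totals with the
# availability override, and their structural properties.

test_that("criterion totals hit the normalised extremes", {
  zero <- uniform_sheet(prio_model, 0)
  expect_equal(criterion_total(zero, prio_model$criteria[["Disease knowledge"]]), 0)

  mx <- max_sheet(prio_model)
  for (cr in prio_model$criteria) {
    expect_equal(criterion_total(mx, cr), 100, tolerance = 1e-9)
  }
  for (cr in gap_model$criteria) {
    expect_equal(criterion_total(max_sheet(gap_model), cr), 100, tolerance = 1e-9)
    expect_equal(criterion_total(min_sheet(gap_model), cr), -100, tolerance = 1e-9)
  }
  # control tools all -2
  mn <- uniform_sheet(prio_model, 9)
  mn$scores[["Control tools"]][] <- -2L
  expect_equal(criterion_total(mn, prio_model$criteria[["Control tools"]]), -100)
})

test_that("criterion_total names the offending sub-criterion", {
  s <- uniform_sheet(prio_model, 1)
  s$scores[["Impact on trade"]] <- s$scores[["Impact on trade"]][-2]
  err <- expect_error(criterion_total(s, prio_model$criteria[["Impact on trade"]]),
                      class = "priogap_validation_error")
  expect_match(conditionMessage(err), "Impact on EC trade")

  s2 <- with_score(uniform_sheet(prio_model, 1), "Disease knowledge",
                   "Speed of spread", 7)
  expect_error(criterion_total(s2, prio_model$criteria[["Disease knowledge"]]),
               class = "priogap_validation_error")
})

test_that("overall totals match the extremes and the naive summation oracle", {
  expect_equal(disease_total(uniform_sheet(prio_model, 0), prio_model)$overall, 0)

  # first five criteria at max, control tools all -2: 5 * 100 - 100
  s <- max_sheet(prio_model)
  s$scores[["Control tools"]][] <- -2L
  expect_equal(disease_total(s, prio_model)$overall, 400, tolerance = 1e-9)

  set.seed(42)
  for (rep in 1:100) {
    sh <- random_sheet(prio_model)
    dt <- disease_total(sh, prio_model)
    expect_equal(dt$overall, naive_overall(sh, prio_model), tolerance = 1e-9)
    expect_equal(dt$overall, sum(dt$per_criterion), tolerance = 1e-9)
  }
})

test_that("totals are monotone in every raw score and bounded", {
  set.seed(7)
  for (rep in 1:10) {
    sh <- random_sheet(prio_model)
    dt <- disease_total(sh, prio_model)
    expect_gte(dt$overall, -100 - 1e-9)
    expect_lte(dt$overall, 600 + 1e-9)
    cr <- prio_model$criteria[[sample(6, 1)]]
    sub <- sample(cr$sub_criteria, 1)
    cur <- sh$scores[[cr$name]][[sub]]
    if (cur < cr$scale$max) {
      up <- with_score(sh, cr$name, sub, cur + 1L)
      expect_gte(criterion_total(up, cr), criterion_total(sh, cr))
      expect_gte(disease_total(up, prio_model)$overall, dt$overall)
    }
  }
})

test_that("permuting scores within a criterion leaves its total unchanged", {
  set.seed(11)
  for (m in list(prio_model, gap_model)) {
    sh <- random_sheet(m)
    for (cr in m$criteria) {
      perm <- sh
      v <- perm$scores[[cr$name]]
      perm$scores[[cr$name]] <- stats::setNames(sample(unname(v)), names(v))
      expect_equal(criterion_total(perm, cr), criterion_total(sh, cr),
                   tolerance = 1e-12)
    }
  }
})

test_that("gap totals round half away from zero to integers", {
  z <- uniform_sheet(gap_model, 0)
  one <- with_score(z, "Vaccination tools", "Strategic reserve", 1)
  g <- gap_totals(one, gap_model)
  expect_identical(g$vaccines, 5L) # 100/22 = 4.5454... -> 5
  expect_identical(g$diagnostics, 0L)
  expect_identical(unname(g$is_gap), c(FALSE, TRUE, FALSE))

  g2 <- gap_totals(min_sheet(gap_model), gap_model)
  expect_identical(g2$diagnostics, -100L)
})

test_that("availability override caps areas with no product at all", {
  flags <- c("Vaccination tools" = "none")
  sh <- uniform_sheet(gap_model, 0, flags = flags)
  # raw_cap: raw sum forced to 20, then weighted: 20 * 100/22 = 90.9 -> 91
  expect_identical(gap_totals(sh, gap_model, "raw_cap")$vaccines, 91L)
  expect_identical(gap_totals(sh, gap_model, "display_cap")$vaccines, 40L)
  # diagnostics area: 20 * 100/24 = 83.3 -> 83
  shd <- uniform_sheet(gap_model, 0, flags = c("Diagnostic tools" = "none"))
  expect_identical(gap_totals(shd, gap_model, "raw_cap")$diagnostics, 83L)

  sh$availability_flags[["Vaccination tools"]] <- "in_development"
  expect_identical(gap_totals(sh, gap_model)$vaccines, 0L)

  bad <- sh
  bad$availability_flags[["Vaccination tools"]] <- "sold_out"
  expect_error(gap_totals(bad, gap_model), class = "priogap_validation_error")
})

test_that("gap totals stay within [-100, 100] in both override modes", {
  set.seed(3)
  for (rep in 1:20) {
    flags <- stats::setNames(sample(c("available", "in_development", "none"), 3,
                                    replace = TRUE),
                             names(gap_model$criteria))
    sh <- random_sheet(gap_model, flags = flags)
    for (mode in c("raw_cap", "display_cap")) {
      g <- gap_totals(sh, gap_model, mode)
      vals <- c(g$diagnostics, g$vaccines, g$pharmaceuticals)
      expect_true(all(vals >= -100L & vals <= 100L))
      expect_identical(unname(g$is_gap), vals > 0L)
    }
  }
})

test_that("incomplete sheets fail validation rather than being imputed", {
  s <- uniform_sheet(prio_model, 1)
  s$scores[["Impact on trade"]] <- NULL
  expect_gt(length(validate_sheet(s, prio_model)), 0)
  expect_error(disease_total(s, prio_model), class = "priogap_validation_error")
})
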