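# Rankings, tie semantics, re-weighting and rank concordance.

totals_df <- function(names, scores, categories = "epizootic") {
  data.frame(disease_id = slugify(names), disease_name = names,
             category = rep(categories, length.out = length(names)),
             score = scores, stringsAsFactors = FALSE)
}

test_that("competition ranking shares ranks on ties and orders them alphabetically", {
  df <- totals_df(c("Delta", "Alpha", "Charlie", "Bravo"), c(10, 20, 20, 5))
  r <- rank_diseases(df)
  expect_identical(r$rank, c(1L, 1L, 3L, 4L))
  expect_identical(r$disease_name, c("Alpha", "Charlie", "Delta", "Bravo"))

  # 1,2,2,4 pattern
  r2 <- rank_diseases(totals_df(c("A", "B", "C", "D"), c(9, 7, 7, 1)))
  expect_identical(r2$rank, c(1L, 2L, 2L, 4L))
})

test_that("ranking validates its inputs", {
  expect_error(rank_diseases(totals_df(character(0), numeric(0))),
               class = "priogap_invalid_argument")
  df <- totals_df(c("A", "A"), c(1, 2))
  expect_error(rank_diseases(df), class = "priogap_invalid_argument")
  expect_error(rank_diseases(totals_df("A", 1), "category:unheard_of"),
               class = "priogap_invalid_argument")
  expect_error(rank_diseases(totals_df("A", 1), "sideways"),
               class = "priogap_invalid_argument")
})

test_that("category and criterion scopes restrict and re-score correctly", {
  set.seed(5)
  sheets <- lapply(1:6, function(i) {
    random_sheet(prio_model, id = sprintf("d%d", i),
                 category = disease_categories()[1 + i %% 3])
  })
  totals <- lapply(sheets, disease_total, model = prio_model)
  zoo <- rank_diseases(totals, "category:zoonotic")
  expect_identical(nrow(zoo), 2L)
  expect_true(all(zoo$disease_id %in% c("d2", "d5")))

  byct <- rank_diseases(totals, "criterion:Control tools")
  expected <- vapply(totals, function(t) t$per_criterion[["Control tools"]], numeric(1))
  expect_setequal(byct$score, expected)
  expect_true(all(diff(byct$score) <= 0))
})

test_that("removing a non-top disease preserves the relative order of the rest", {
  set.seed(9)
  df <- totals_df(sprintf("Disease %02d", 1:12), sample(50:400, 12))
  full <- rank_diseases(df)
  drop_id <- full$disease_id[5]
  reduced <- rank_diseases(df[df$disease_id != drop_id, ])
  expect_identical(reduced$disease_id,
                   setdiff(full$disease_id, drop_id))
})

test_that("gap rankings match an independent sort oracle", {
  set.seed(13)
  gaps <- lapply(1:15, function(i) {
    flags <- stats::setNames(sample(c("available", "none"), 3, TRUE,
                                    prob = c(0.9, 0.1)),
                             names(gap_model$criteria))
    gap_totals(random_sheet(gap_model, id = sprintf("d%02d", i), flags = flags),
               gap_model)
  })
  for (area in c("diagnostics", "vaccines", "pharmaceuticals")) {
    r <- rank_gaps(gaps, area)
    scores <- vapply(gaps, `[[`, integer(1), area)
    names(scores) <- vapply(gaps, `[[`, character(1), "disease_id")
    oracle <- names(sort(scores, decreasing = TRUE))
    # oracle sorted by score only: compare the score sequences
    expect_identical(r$score, unname(sort(scores, decreasing = TRUE)) * 1)
    expect_setequal(r$disease_id, names(scores))
  }

  same <- lapply(gaps, function(g) { g$diagnostics <- 7L; g })
  expect_true(all(rank_gaps(same, "diagnostics")$rank == 1L))
  expect_identical(rank_gaps(gaps[1], "vaccines")$rank, 1L)
})

test_that("reweighting with the model's own coefficients is the identity", {
  set.seed(17)
  sheets <- lapply(1:8, function(i) random_sheet(prio_model, id = sprintf("d%d", i)))
  base <- lapply(sheets, disease_total, model = prio_model)
  rew <- reweight(sheets, prio_model, default_weight_scheme(prio_model))
  expect_equal(vapply(rew, `[[`, numeric(1), "overall"),
               vapply(base, `[[`, numeric(1), "overall"), tolerance = 1e-12)

  # common positive scaling leaves the ranking unchanged (tau-b == 1)
  sc <- default_weight_scheme(prio_model)
  sc$weights <- sc$weights * 3.7
  tau <- rank_concordance(rank_diseases(base),
                          rank_diseases(reweight(sheets, prio_model, sc)))
  expect_equal(tau, 1)

  # zeroing one criterion removes its contribution
  zero <- default_weight_scheme(prio_model)
  zero$weights[["Impact on trade"]] <- 0
  rz <- reweight(sheets, prio_model, zero)
  expect_true(all(vapply(rz, function(t) t$per_criterion[["Impact on trade"]],
                         numeric(1)) == 0))

  incomplete <- weight_scheme("partial", c("Disease knowledge" = 1))
  expect_error(reweight(sheets, prio_model, incomplete),
               class = "priogap_invalid_argument")
})

test_that("rank concordance is Kendall tau-b and matches pair enumeration", {
  a <- rank_diseases(totals_df(c("A", "B", "C", "D"), c(4, 3, 2, 1)))
  expect_equal(rank_concordance(a, a), 1)
  b <- rank_diseases(totals_df(c("A", "B", "C", "D"), c(1, 2, 3, 4)))
  expect_equal(rank_concordance(a, b), -1)

  set.seed(29)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    nms <- LETTERS[1:n]
    s1 <- sample(1:4, n, replace = TRUE) # ties likely
    s2 <- sample(1:4, n, replace = TRUE)
    if (max(s1) == min(s1) || max(s2) == min(s2)) next # tau-b undefined
    r1 <- rank_diseases(totals_df(nms, s1))
    r2 <- rank_diseases(totals_df(nms, s2))
    x <- r1$rank
    y <- r2$rank[match(r1$disease_id, r2$disease_id)]
    expect_equal(rank_concordance(r1, r2), brute_tau_b(x, y), tolerance = 1e-12)
  }

  c_tab <- rank_diseases(totals_df(c("A", "B", "E"), c(3, 2, 1)))
  expect_error(rank_concordance(a, c_tab), class = "priogap_invalid_argument")
})

test_that("weight schemes require a positive weight and serialise to JSON", {
  expect_error(weight_scheme("w", c(a = 0, b = 0)),
               class = "priogap_invalid_argument")
  expect_error(weight_scheme("w", c(a = -1, b = 2)),
               class = "priogap_invalid_argument")
  path <- withr::local_tempfile(fileext = ".json")
  sc <- weight_scheme("trade-heavy", c("Impact on trade" = 5, "Disease knowledge" = 1))
  write_weight_scheme(sc, path)
  back <- read_weight_scheme(path)
  expect_identical(back$name, sc$name)
  expect_equal(back$weights[names(sc$weights)], sc$weights)
})
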