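# Shared fixtures-in-code for the test suite.

prio_model <- default_prioritisation_model()
gap_model <- default_gap_model()

# A sheet with the same value everywhere (clamped to each criterion's scale).
uniform_sheet <- function(model, value, id = "dz", category = "epizootic",
                          flags = NULL) {
  scores <- lapply(model$criteria, function(cr) {
    v <- max(min(cr$scale$values), min(cr$scale$max, value))
    stats::setNames(rep.int(v, cr$n_levels), cr$sub_criteria)
  })
  names(scores) <- names(model$criteria)
  score_sheet(id, paste("Disease", id), category, scores,
              availability_flags = flags)
}

max_sheet <- function(model, ...) uniform_sheet(model, Inf, ...)
min_sheet <- function(model, ...) uniform_sheet(model, -Inf, ...)

# Random valid sheet; draws come from the caller's RNG state.
random_sheet <- function(model, id = "dz", category = "epizootic", flags = NULL) {
  scores <- lapply(model$criteria, function(cr) {
    stats::setNames(sample(cr$scale$values, cr$n_levels, replace = TRUE),
                    cr$sub_criteria)
  })
  names(scores) <- names(model$criteria)
  score_sheet(id, paste("Disease", id), category, scores,
              availability_flags = flags)
}

# Independent naive oracle: walk every sub-criterion, recompute the per-level
# weight from first principles and accumulate score-by-score.
naive_criterion_total <- function(sheet, model, criterion_name) {
  cr <- model$criteria[[criterion_name]]
  w <- 100 / (max(cr$scale$values) * length(cr$sub_criteria))
  tot <- 0
  for (sub in cr$sub_criteria) tot <- tot + w * sheet$scores[[criterion_name]][[sub]]
  tot
}

naive_overall <- function(sheet, model) {
  sum(vapply(names(model$criteria), function(nm) {
    naive_criterion_total(sheet, model, nm)
  }, numeric(1)))
}

# Brute-force Kendall tau-b by exhaustive pair enumeration.
brute_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(outer(x, x, "==")[upper.tri(diag(n))])
  ty <- sum(outer(y, y, "==")[upper.tri(diag(n))])
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Panel of identical-role-covered experts whose sheets are `sheets`.
panel_from_sheets <- function(sheets, id = sheets[[1]]$disease_id) {
  roles <- rep(c("diagnostic", "epidemiology", "industry", "economics", "other"),
               length.out = length(sheets))
  panel_scores(id, lapply(seq_along(sheets), function(i) {
    list(expert_id = sprintf("e%02d", i), role = roles[i], sheet = sheets[[i]])
  }))
}

# Modify one sub-criterion score of a sheet, returning a new sheet.
with_score <- function(sheet, criterion, sub, value) {
  sheet$scores[[criterion]][[sub]] <- as.integer(value)
  sheet
}
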