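# Expert-panel aggregation: consensus score sheets and dissent records.

#' Expert panel for one disease
#'
#' A set of per-expert score sheets for a single disease. The minimum
#' coverage requirement reflects the elicitation design: at least four
#' experts jointly spanning the four named areas of expertise (diagnostic,
#' epidemiology, industry, economics); additional experts take the role
#' `other`.
#'
#' @param disease_id The disease all sheets must belong to.
#' @param experts List of entries `list(expert_id =, role =, sheet =)` where
#'   `role` is one of diagnostic, epidemiology, industry, economics, other,
#'   and `sheet` is a [score_sheet()] for `disease_id`.
#' @return A `panel_scores` object with a computed `minimum_coverage_met`
#'   flag.
#' @export
panel_scores <- function(disease_id, experts) {
  if (length(experts) < 1L) abort_invalid("a panel needs at least one expert")
  ids <- vapply(experts, `[[`, character(1), "expert_id")
  if (anyDuplicated(ids)) abort_invalid("expert_ids must be unique within a panel")
  roles <- vapply(experts, `[[`, character(1), "role")
  bad <- setdiff(unique(roles), expert_roles())
  if (length(bad)) {
    abort_validation(sprintf("unknown expert role(s): %s", paste(bad, collapse = ", ")))
  }
  sheet_ids <- vapply(experts, function(e) e$sheet$disease_id, character(1))
  if (any(sheet_ids != disease_id)) {
    abort_validation(sprintf(
      "panel '%s' contains sheets for other diseases: %s",
      disease_id, paste(unique(sheet_ids[sheet_ids != disease_id]), collapse = ", ")))
  }
  covered <- length(experts) >= 4L &&
    all(c("diagnostic", "epidemiology", "industry", "economics") %in% roles)
  structure(list(disease_id = disease_id, experts = experts,
                 minimum_coverage_met = covered),
            class = "panel_scores")
}

#' @export
print.panel_scores <- function(x, ...) {
  cat(sprintf("<panel_scores: %s, %d expert(s), coverage %s>\n",
              x$disease_id, length(x$experts),
              if (x$minimum_coverage_met) "met" else "not met"))
  invisible(x)
}

# Snap a (possibly fractional) consensus value onto the scale: round halves
# per `half`, then clamp to the scale range. Scales are contiguous integer
# ranges, so clamping lands on an allowed value.
consensus_value <- function(med, scale, half) {
  v <- switch(half,
              away_from_zero = round_half_away(med),
              toward_zero = trunc(med))
  as.integer(clamp(v, min(scale$values), scale$max))
}

#' Aggregate an expert panel into a consensus score sheet
#'
#' The consensus score of each sub-criterion is the median of the expert
#' scores; with an even panel the half-valued median is rounded away from
#' zero by default (toward the more extreme value — higher priority, or
#' deeper gap) and the result is clamped to the criterion's scale. Whenever
#' the spread of expert scores on a sub-criterion exceeds
#' `dissent_threshold`, a dissent record is emitted: failure to converge is
#' itself a knowledge gap worth reporting, so a consensus value and a dissent
#' record are both produced rather than suppressing either.
#'
#' Availability flags on gap sheets are aggregated by majority, ties resolved
#' toward the more severe level (`none` > `in_development` > `available`).
#'
#' @param panel A [panel_scores()] object.
#' @param model The governing [model_spec()].
#' @param dissent_threshold Maximum expert score range treated as agreement
#'   (default 1: adjacent scores do not count as dissent).
#' @param half Rounding rule for even-panel medians: `"away_from_zero"`
#'   (default) or `"toward_zero"`.
#' @return A list with `consensus` (a [score_sheet()]) and `dissent` (a
#'   data.frame with columns `disease_id`, `criterion`, `sub_criterion`,
#'   `expert_scores`, `range`, `consensus_value`).
#' @export
aggregate_panel <- function(panel, model, dissent_threshold = 1L,
                            half = c("away_from_zero", "toward_zero")) {
  half <- match.arg(half)
  if (!inherits(panel, "panel_scores")) abort_invalid("panel must be a panel_scores object")
  if (length(panel$experts) < 1L) abort_invalid("empty panel")
  if (!is.numeric(dissent_threshold) || dissent_threshold < 0) {
    abort_invalid("dissent_threshold must be a non-negative integer")
  }
  sheets <- lapply(panel$experts, `[[`, "sheet")
  for (s in sheets) assert_sheet(s, model)
  if (any(vapply(sheets, `[[`, character(1), "disease_id") != panel$disease_id)) {
    abort_validation("panel contains mixed disease_ids")
  }

  ref <- sheets[[1]]
  scores <- list()
  dis <- list()
  for (cr in model$criteria) {
    mat <- vapply(sheets, function(s) s$scores[[cr$name]][cr$sub_criteria],
                  numeric(cr$n_levels))
    mat <- matrix(mat, nrow = cr$n_levels)
    cons <- integer(cr$n_levels)
    for (i in seq_len(cr$n_levels)) {
      v <- mat[i, ]
      cons[i] <- consensus_value(stats::median(v), cr$scale, half)
      rng <- max(v) - min(v)
      if (rng > dissent_threshold) {
        dis[[length(dis) + 1L]] <- data.frame(
          disease_id = panel$disease_id,
          criterion = cr$name,
          sub_criterion = cr$sub_criteria[i],
          expert_scores = paste(sort(v), collapse = ","),
          range = as.integer(rng),
          consensus_value = cons[i],
          stringsAsFactors = FALSE)
      }
    }
    names(cons) <- cr$sub_criteria
    scores[[cr$name]] <- cons
  }

  flags <- NULL
  if (model$model_kind == "gap") {
    all_flags <- lapply(sheets, function(s) s$availability_flags)
    if (any(!vapply(all_flags, is.null, logical(1)))) {
      flags <- vapply(criterion_names(model), function(nm) {
        fv <- vapply(all_flags, function(f) {
          x <- (f %||% character(0))[nm]
          if (is.na(x)) "available" else unname(x)
        }, character(1))
        tab <- table(factor(fv, levels = availability_levels()))
        top <- names(tab)[tab == max(tab)]
        # severity order: none > in_development > available
        rev(availability_levels())[rev(availability_levels()) %in% top][1]
      }, character(1))
    }
  }

  dissent <- if (length(dis)) do.call(rbind, dis) else data.frame(
    disease_id = character(0), criterion = character(0),
    sub_criterion = character(0), expert_scores = character(0),
    range = integer(0), consensus_value = integer(0),
    stringsAsFactors = FALSE)

  list(
    consensus = score_sheet(panel$disease_id, ref$disease_name, ref$category,
                            scores, availability_flags = flags),
    dissent = dissent
  )
}

#' Summarise expertise coverage across panels
#'
#' @param panels Non-empty list of [panel_scores()] objects.
#' @return A list: `n_panels`, `n_meeting_minimum`,
#'   `percent_meeting_minimum` (integer percent, halves away from zero) and
#'   `mean_panel_size`.
#' @examples
#' # 43 of 52 panels meeting the four-role minimum reports 83%
#' @export
panel_coverage_summary <- function(panels) {
  if (length(panels) < 1L) abort_invalid("panel_coverage_summary() needs at least one panel")
  if (!all(vapply(panels, inherits, logical(1), "panel_scores"))) {
    abort_invalid("panels must be panel_scores objects")
  }
  met <- vapply(panels, `[[`, logical(1), "minimum_coverage_met")
  sizes <- vapply(panels, function(p) length(p$experts), integer(1))
  list(
    n_panels = length(panels),
    n_meeting_minimum = sum(met),
    percent_meeting_minimum = as.integer(round_half_away(100 * mean(met))),
    mean_panel_size = mean(sizes)
  )
}
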