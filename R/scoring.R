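# The scoring engine: weighted criterion totals, overall prioritisation
# scores, and gap-area scores with the availability override.

#' Weighted total of one criterion
#'
#' `coefficient * sum(raw scores)`, unrounded. Because the coefficient is per
#' level (not per sub-criterion), permuting scores within a criterion leaves
#' the total unchanged, and a criterion with every level at the scale maximum
#' totals exactly 100.
#'
#' @param sheet A validated [score_sheet()].
#' @param criterion A [criterion_spec()] belonging to the sheet's model.
#' @return The weighted criterion total (numeric scalar).
#' @export
criterion_total <- function(sheet, criterion) {
  if (!inherits(criterion, "criterion_spec")) {
    abort_invalid("criterion must be a criterion_spec")
  }
  v <- sheet$scores[[criterion$name]]
  if (is.null(v)) {
    abort_validation(sprintf("sheet '%s' has no scores for criterion '%s'",
                             sheet$disease_id, criterion$name))
  }
  missing <- setdiff(criterion$sub_criteria, names(v))
  if (length(missing)) {
    abort_validation(sprintf("sheet '%s', criterion '%s': missing score for '%s'",
                             sheet$disease_id, criterion$name, missing[1]))
  }
  v <- v[criterion$sub_criteria]
  off <- criterion$sub_criteria[!(v %in% criterion$scale$values)]
  if (length(off)) {
    abort_validation(sprintf("sheet '%s', criterion '%s': score for '%s' outside the scale",
                             sheet$disease_id, criterion$name, off[1]))
  }
  criterion$coefficient * sum(v)
}

#' Overall prioritisation total for one disease
#'
#' Sums the weighted totals of all criteria of a prioritisation model. With
#' the default model the first five criterion totals lie in `[0, 100]`, control
#' tools in `[-100, 100]`, and the overall score in `[-100, 600]`. No rounding is
#' applied at any stage.
#'
#' @param sheet A validated [score_sheet()].
#' @param model A [model_spec()] of kind `"prioritisation"`.
#' @return A `disease_total` object: `disease_id`, `disease_name`, `category`,
#'   `per_criterion` (named numeric) and `overall`.
#' @export
disease_total <- function(sheet, model) {
  if (!inherits(model, "model_spec") || model$model_kind != "prioritisation") {
    abort_invalid("disease_total() requires a prioritisation model")
  }
  assert_sheet(sheet, model)
  per <- vapply(model$criteria, function(cr) criterion_total(sheet, cr), numeric(1))
  structure(list(disease_id = sheet$disease_id,
                 disease_name = sheet$disease_name,
                 category = sheet$category,
                 per_criterion = per,
                 overall = sum(per)),
            class = "disease_total")
}

#' @export
print.disease_total <- function(x, ...) {
  cat(sprintf("<disease_total: %s, overall %.2f>\n", x$disease_name, x$overall))
  invisible(x)
}

#' Gap-area scores for one disease
#'
#' Computes the weighted total of each control-tool area of a gap model and
#' rounds it half away from zero to an integer; a positive score indicates a
#' research gap, a negative one adequate existing tools.
#'
#' When an area's availability flag is `"none"` (no product exists, not even
#' in development) the area is overridden before rounding:
#' \describe{
#'   \item{`raw_cap`}{the raw score sum is set to 20 and then weighted — the
#'     literal reading of the availability rule (e.g. a vaccines area with 11
#'     levels becomes `20 * 100/22 = 90.9 -> 91`);}
#'   \item{`display_cap`}{the final value is set to `display_cap` (default
#'     40), the ceiling observed in the published score table.}
#' }
#'
#' @param sheet A validated gap [score_sheet()].
#' @param model A [model_spec()] of kind `"gap"` with the three areas in the
#'   order diagnostics, vaccines, pharmaceuticals.
#' @param availability_mode `"raw_cap"` (default) or `"display_cap"`.
#' @param display_cap Cap used by `display_cap` mode.
#' @return A `gap_totals` object with integer fields `diagnostics`,
#'   `vaccines`, `pharmaceuticals` and a logical `is_gap` per area
#'   (`TRUE` iff the rounded score is positive).
#' @export
gap_totals <- function(sheet, model,
                       availability_mode = c("raw_cap", "display_cap"),
                       display_cap = 40) {
  availability_mode <- match.arg(availability_mode)
  if (!inherits(model, "model_spec") || model$model_kind != "gap") {
    abort_invalid("gap_totals() requires a gap model")
  }
  if (length(model$criteria) != 3L) {
    abort_invalid("gap_totals() expects the three-area gap model")
  }
  assert_sheet(sheet, model)
  areas <- c("diagnostics", "vaccines", "pharmaceuticals")
  vals <- integer(3)
  for (i in seq_len(3)) {
    cr <- model$criteria[[i]]
    flag <- (sheet$availability_flags %||% character(0))[cr$name]
    flag <- if (is.na(flag)) "available" else unname(flag)
    if (!flag %in% availability_levels()) {
      abort_validation(sprintf("unknown availability flag '%s' for '%s'", flag, cr$name))
    }
    raw <- sum(sheet$scores[[cr$name]][cr$sub_criteria])
    weighted <- if (flag == "none") {
      switch(availability_mode,
             raw_cap = cr$coefficient * 20,
             display_cap = display_cap)
    } else {
      cr$coefficient * raw
    }
    vals[i] <- as.integer(round_half_away(weighted))
  }
  names(vals) <- areas
  structure(list(disease_id = sheet$disease_id,
                 disease_name = sheet$disease_name,
                 category = sheet$category,
                 diagnostics = vals[["diagnostics"]],
                 vaccines = vals[["vaccines"]],
                 pharmaceuticals = vals[["pharmaceuticals"]],
                 is_gap = vals > 0L),
            class = "gap_totals")
}

#' @export
print.gap_totals <- function(x, ...) {
  cat(sprintf("<gap_totals: %s: diagnostics %d, vaccines %d, pharmaceuticals %d>\n",
              x$disease_name, x$diagnostics, x$vaccines, x$pharmaceuticals))
  invisible(x)
}
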