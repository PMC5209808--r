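# Score sheets: one disease's integer scores for every level of a model.

#' Closed set of disease categories
#'
#' The three-way taxonomy used throughout: `epizootic` (introduction/spread
#' risks), `food_producing_complex` (major enzootic livestock diseases) and
#' `zoonotic` (animal infections important for human health). Unknown labels
#' are rejected wherever a category is parsed.
#'
#' @return Character vector of the three category labels.
#' @export
disease_categories <- function() c("epizootic", "food_producing_complex", "zoonotic")

expert_roles <- function() c("diagnostic", "epidemiology", "industry", "economics", "other")

availability_levels <- function() c("available", "in_development", "none")

#' Score sheet for one disease
#'
#' Holds one integer score per sub-criterion of a governing [model_spec()],
#' as a named list of named integer vectors (one vector per criterion, names
#' matching the model's sub-criteria). Gap sheets may additionally carry one
#' product-availability flag per area (`available`, `in_development`, `none`).
#'
#' @param disease_id Stable identifier (see [slugify()]).
#' @param disease_name Display name.
#' @param category One of [disease_categories()].
#' @param scores Named list: criterion name -> named integer vector of
#'   sub-criterion scores.
#' @param availability_flags Optional named character vector: gap-area
#'   criterion name -> availability level. `NULL` for prioritisation sheets.
#' @param notes Optional free-text remarks.
#' @return A `score_sheet` object.
#' @seealso [validate_sheet()], [disease_total()], [gap_totals()]
#' @export
score_sheet <- function(disease_id, disease_name, category, scores,
                        availability_flags = NULL, notes = NULL) {
  if (!is.character(disease_id) || length(disease_id) != 1L || !nzchar(disease_id)) {
    abort_invalid("disease_id must be a non-empty string")
  }
  if (!category %in% disease_categories()) {
    abort_validation(sprintf("unknown disease category '%s' (expected one of: %s)",
                             category, paste(disease_categories(), collapse = ", ")))
  }
  if (!is.list(scores) || is.null(names(scores))) {
    abort_invalid("scores must be a named list of named integer vectors")
  }
  scores <- lapply(scores, function(v) {
    out <- as.integer(v)
    names(out) <- names(v)
    out
  })
  if (!is.null(availability_flags)) {
    bad <- setdiff(unique(availability_flags), availability_levels())
    if (length(bad)) {
      abort_validation(sprintf("unknown availability flag(s): %s",
                               paste(bad, collapse = ", ")))
    }
  }
  structure(list(disease_id = disease_id,
                 disease_name = as.character(disease_name),
                 category = category,
                 scores = scores,
                 availability_flags = availability_flags,
                 notes = notes),
            class = "score_sheet")
}

#' @export
print.score_sheet <- function(x, ...) {
  cat(sprintf("<score_sheet: %s (%s), %s; %d criteria>\n",
              x$disease_name, x$disease_id, x$category, length(x$scores)))
  invisible(x)
}

#' Validate a score sheet against a model
#'
#' Returns a character vector of violations (empty when valid): every
#' sub-criterion of every model criterion must carry exactly one score, every
#' score must belong to its criterion's scale, and availability flags (if
#' present) must name model criteria and use known levels. Incomplete sheets
#' are violations — no imputation is performed.
#'
#' @param sheet A [score_sheet()].
#' @param model The governing [model_spec()].
#' @return Character vector of violation descriptions.
#' @export
validate_sheet <- function(sheet, model) {
  if (!inherits(sheet, "score_sheet")) return("not a score_sheet object")
  if (!inherits(model, "model_spec")) return("not a model_spec object")
  out <- character(0)
  for (cr in model$criteria) {
    v <- sheet$scores[[cr$name]]
    if (is.null(v)) {
      out <- c(out, sprintf("criterion '%s': no scores present", cr$name))
      next
    }
    missing <- setdiff(cr$sub_criteria, names(v))
    extra <- setdiff(names(v), cr$sub_criteria)
    if (length(missing)) {
      out <- c(out, sprintf("criterion '%s': missing score for sub-criterion '%s'",
                            cr$name, missing))
    }
    if (length(extra)) {
      out <- c(out, sprintf("criterion '%s': unknown sub-criterion '%s'",
                            cr$name, extra))
    }
    present <- intersect(cr$sub_criteria, names(v))
    off <- present[!(v[present] %in% cr$scale$values) | is.na(v[present])]
    if (length(off)) {
      out <- c(out, sprintf("criterion '%s': score for '%s' outside scale %s..%s",
                            cr$name, off, min(cr$scale$values), cr$scale$max))
    }
  }
  extra_crit <- setdiff(names(sheet$scores), criterion_names(model))
  if (length(extra_crit)) {
    out <- c(out, sprintf("unknown criterion '%s' on sheet", extra_crit))
  }
  if (!is.null(sheet$availability_flags)) {
    badc <- setdiff(names(sheet$availability_flags), criterion_names(model))
    if (length(badc)) {
      out <- c(out, sprintf("availability flag for unknown criterion '%s'", badc))
    }
    badv <- setdiff(unique(sheet$availability_flags), availability_levels())
    if (length(badv)) {
      out <- c(out, sprintf("unknown availability flag '%s'", badv))
    }
  }
  out
}

assert_sheet <- function(sheet, model) {
  v <- validate_sheet(sheet, model)
  if (length(v)) {
    abort_validation(sprintf("invalid score sheet '%s': %s",
                             if (inherits(sheet, "score_sheet")) sheet$disease_id else "?",
                             paste(v, collapse = "; ")))
  }
  invisible(sheet)
}
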