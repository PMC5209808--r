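# Scoring-model definitions: score scales, criteria, model specs, the
# weighting-coefficient formula, and the two reference models.

#' Weighting coefficient for the levels of a criterion
#'
#' In a closed weighted scoring system each criterion is normalised so that
#' its maximum weighted total is 100: every level (sub-criterion) of a
#' criterion receives the coefficient
#' \deqn{W = \frac{100}{X \cdot I}}{W = 100 / (X * I)}
#' where `X` is the maximum score of the criterion's scale and `I` the number
#' of levels. Coefficients are returned at full precision; use
#' [display_weight()] for the two-decimal presentation form.
#'
#' @param max_score Maximum score of a level (`X`), a positive integer.
#' @param n_levels Number of levels within the criterion (`I`), a positive
#'   integer.
#' @return The coefficient `100 / (max_score * n_levels)`, unrounded.
#' @examples
#' compute_weight(4, 10) # 2.5
#' compute_weight(4, 4)  # 6.25
#' display_weight(compute_weight(2, 11)) # 4.55
#' @export
compute_weight <- function(max_score, n_levels) {
  for (v in list(max_score = max_score, n_levels = n_levels)) {
    if (length(v) != 1L || !is.numeric(v) || is.na(v) || v < 1 || v != floor(v)) {
      abort_invalid("compute_weight() requires positive integer max_score and n_levels")
    }
  }
  100 / (max_score * n_levels)
}

#' Score scale of a criterion
#'
#' An ordered set of allowed integer scores, e.g. `0:4` for impact criteria or
#' `-2:2` for control-tool criteria (negative = adequate tools exist, positive
#' = tools are missing and priority rises).
#'
#' @param values Strictly increasing integer vector of allowed scores.
#' @return A `score_scale` object with elements `values` and `max`.
#' @export
score_scale <- function(values) {
  if (length(values) == 0L || anyNA(values) || !is.numeric(values) ||
      any(values != floor(values))) {
    abort_invalid("score_scale values must be non-missing integers")
  }
  if (any(diff(values) <= 0)) abort_invalid("score_scale values must be strictly increasing")
  structure(list(values = as.integer(values), max = as.integer(max(values))),
            class = "score_scale")
}

#' Criterion of a scoring model
#'
#' Bundles a named criterion with its ordered sub-criteria (levels), a score
#' scale and the normalising weighting coefficient, which is always computed
#' with [compute_weight()] and never supplied by the caller.
#'
#' @param name Criterion name, stored exactly as presented in the reference
#'   tables.
#' @param sub_criteria Character vector of level names, unique within the
#'   criterion.
#' @param scale A [score_scale()].
#' @param availability_marker Optional 1-based index of the sub-criterion that
#'   carries the product-availability rule of the gap model (`NA` when none).
#' @return A `criterion_spec` object with fields `name`, `sub_criteria`,
#'   `scale`, `coefficient`, `n_levels` and `availability_marker`.
#' @export
criterion_spec <- function(name, sub_criteria, scale, availability_marker = NA_integer_) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_invalid("criterion name must be a non-empty string")
  }
  if (!inherits(scale, "score_scale")) abort_invalid("scale must be a score_scale")
  if (length(sub_criteria) < 1L || !is.character(sub_criteria)) {
    abort_invalid("sub_criteria must be a non-empty character vector")
  }
  if (anyDuplicated(sub_criteria)) {
    abort_invalid(sprintf("duplicate sub-criterion names in '%s'", name))
  }
  if (!is.na(availability_marker) &&
      !(availability_marker %in% seq_along(sub_criteria))) {
    abort_invalid("availability_marker must index a sub-criterion")
  }
  structure(list(
    name = name,
    sub_criteria = sub_criteria,
    scale = scale,
    n_levels = length(sub_criteria),
    coefficient = compute_weight(scale$max, length(sub_criteria)),
    availability_marker = as.integer(availability_marker)
  ), class = "criterion_spec")
}

#' Scoring-model specification
#'
#' An ordered, immutable collection of criteria of one model kind:
#' `"prioritisation"` (six impact/knowledge criteria summed to one overall
#' score) or `"gap"` (three control-tool areas scored independently, a
#' positive weighted score indicating a research gap).
#'
#' @param model_kind `"prioritisation"` or `"gap"`.
#' @param criteria List of [criterion_spec()] objects with unique names.
#' @param version Free-text model version label.
#' @return A `model_spec` object.
#' @seealso [default_prioritisation_model()], [default_gap_model()],
#'   [validate_model()]
#' @export
model_spec <- function(model_kind = c("prioritisation", "gap"), criteria, version = "1.0") {
  model_kind <- match.arg(model_kind)
  if (!is.list(criteria) || length(criteria) == 0L ||
      !all(vapply(criteria, inherits, logical(1), "criterion_spec"))) {
    abort_invalid("criteria must be a non-empty list of criterion_spec objects")
  }
  nms <- vapply(criteria, `[[`, character(1), "name")
  if (anyDuplicated(nms)) abort_invalid("criterion names must be unique")
  names(criteria) <- nms
  structure(list(model_kind = model_kind, criteria = criteria,
                 version = as.character(version)),
            class = "model_spec")
}

criterion_names <- function(model) names(model$criteria)

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec: %s, version %s>\n", x$model_kind, x$version))
  for (cr in x$criteria) {
    marker <- if (!is.na(cr$availability_marker)) {
      sprintf(" [availability rule on level %d]", cr$availability_marker)
    } else ""
    cat(sprintf("  %-45s %2d levels, scale %d..%d, coef %.2f%s\n",
                cr$name, cr$n_levels, min(cr$scale$values), cr$scale$max,
                display_weight(cr$coefficient), marker))
  }
  invisible(x)
}

#' Default six-criterion prioritisation model
#'
#' The reference prioritisation model: six equally weighted criteria (disease
#' knowledge; impact on animal health and welfare; impact on public health;
#' impact on wider society; impact on trade; control tools) with 10, 3, 6, 3,
#' 4 and 3 levels respectively. The first five use the 0..4 scale; control
#' tools use -2..+2 so that effective existing tools reduce a disease's
#' priority and missing tools raise it. Every coefficient comes from
#' [compute_weight()], so each criterion's maximum weighted total is 100 and
#' the overall score lies in `[-100, 600]`.
#'
#' @return A `model_spec` of kind `"prioritisation"`.
#' @export
default_prioritisation_model <- function() {
  s04 <- score_scale(0:4)
  s22 <- score_scale(-2:2)
  model_spec("prioritisation", list(
    criterion_spec("Disease knowledge", c(
      "Speed of spread",
      "Number of species involved",
      "Persistence of infectious agent in the environment",
      "Risk of spread to susceptible populations",
      "Potential for silent spread",
      "Wildlife reservoir and potential spread",
      "Vector reservoir and potential spread",
      "Variability of the agent",
      "Understanding of fundamental immunology",
      "Host pathogen interaction"
    ), s04),
    criterion_spec("Impact on animal health and welfare", c(
      "Disease impact on production",
      "Duration of animal welfare impact",
      "Proportion of animals affected and suffering pain/injury/distress as a result of the disease"
    ), s04),
    criterion_spec("Impact on public health \u2013 human health", c(
      "Impact of occurrence on human health",
      "Likelihood of occurrence",
      "Impact of occurrence on food safety",
      "Transmissibility (spread from animals to humans)",
      "Spread in humans",
      "Bioterrorism potential"
    ), s04),
    criterion_spec("Impact on wider society", c(
      "Economic direct impact (including cumulative cost, e.g. enzootic vs. epizootic)",
      "Economic indirect impact (social, market)",
      "Agriterrorism potential"
    ), s04),
    criterion_spec("Impact on trade", c(
      "Impact on international trade due to existing regulations",
      "Impact on EC trade due to existing regulations",
      "Potential for regionalisation",
      "Impact on security of food supply"
    ), s04),
    criterion_spec("Control tools", c(
      "Appropriate diagnostics",
      "Appropriate vaccines",
      "Appropriate pharmaceuticals"
    ), s22)
  ), version = "reference-1.0")
}

#' Default three-area control-tool gap model
#'
#' The reference gap-analysis model: diagnostics (12 levels), vaccines (11)
#' and pharmaceuticals (11), each on the -2..+2 scale where +2 marks an
#' important gap and -2 adequate current tools. The first level of each area
#' is the product-availability item; when no product exists at all (not even
#' in development) the whole area is overridden, see [gap_totals()].
#'
#' @return A `model_spec` of kind `"gap"`.
#' @export
default_gap_model <- function() {
  s22 <- score_scale(-2:2)
  model_spec("gap", list(
    criterion_spec("Diagnostic tools", c(
      "Availability",
      "Prevention and control - Differentiation of infected from vaccinated (DIVA)",
      "Strategic reserve",
      "Capacity of production",
      "Market potential",
      "Affordable",
      "Quality/stability durability",
      "Sensitivity",
      "Specificity",
      "Reproducibility",
      "Simplicity/ease of use",
      "Speed"
    ), s22, availability_marker = 1L),
    criterion_spec("Vaccination tools", c(
      "Commercial availability",
      "Monitoring for infection in a vaccinated population",
      "Strategic reserve",
      "Capacity of production",
      "Market potential",
      "Affordable",
      "Quality/stability",
      "Safety of vaccines",
      "Efficacy",
      "Immunity",
      "Convenience of use"
    ), s22, availability_marker = 1L),
    criterion_spec("Pharmaceutical tools", c(
      "Availability",
      "Prevention and control",
      "Strategic reserve",
      "Capacity of production",
      "Market potential",
      "Cost",
      "Quality",
      "Safety animal",
      "Safety consumer/user concerns",
      "Safety environment",
      "Resistance"
    ), s22, availability_marker = 1L)
  ), version = "reference-1.0")
}

#' Check a model specification against its invariants
#'
#' Side-effect-free validation: returns a character vector of human-readable
#' violations (empty when the model is sound) instead of raising. Checked per
#' criterion: non-empty strictly increasing integer scale, unique level names,
#' at least one level, and the normalisation guarantee
#' `coefficient * X * I == 100` (within 1e-9); model-wide: unique criterion
#' names and a known model kind.
#'
#' @param spec A `model_spec`.
#' @return Character vector of violation descriptions; `character(0)` if none.
#' @export
validate_model <- function(spec) {
  out <- character(0)
  if (!inherits(spec, "model_spec")) {
    return("not a model_spec object")
  }
  if (!spec$model_kind %in% c("prioritisation", "gap")) {
    out <- c(out, sprintf("unknown model_kind '%s'", spec$model_kind))
  }
  nms <- vapply(spec$criteria, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    out <- c(out, sprintf("duplicate criterion names: %s",
                          paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  for (cr in spec$criteria) {
    sc <- cr$scale$values
    if (length(sc) == 0L || any(diff(sc) <= 0)) {
      out <- c(out, sprintf("criterion '%s': scale is not strictly increasing", cr$name))
    }
    if (cr$scale$max != max(sc)) {
      out <- c(out, sprintf("criterion '%s': scale max does not match values", cr$name))
    }
    if (cr$n_levels < 1L || cr$n_levels != length(cr$sub_criteria)) {
      out <- c(out, sprintf("criterion '%s': n_levels inconsistent with sub-criteria", cr$name))
    }
    if (anyDuplicated(cr$sub_criteria)) {
      out <- c(out, sprintf("criterion '%s': duplicate sub-criterion names", cr$name))
    }
    if (cr$coefficient < 0) {
      out <- c(out, sprintf("criterion '%s': negative coefficient", cr$name))
    }
    if (abs(cr$coefficient * cr$scale$max * cr$n_levels - 100) > 1e-9) {
      out <- c(out, sprintf(
        "criterion '%s': coefficient %.6f breaks the normalisation coefficient * %d * %d == 100",
        cr$name, cr$coefficient, cr$scale$max, cr$n_levels))
    }
  }
  out
}

#' Write / read a model specification as JSON
#'
#' The on-disk document stores `model_kind`, `version` and, per criterion, the
#' name, scale values, sub-criterion names and optional availability marker.
#' Coefficients are deliberately not stored: they are recomputed from the
#' formula on load so a file can never smuggle in a de-normalised weight.
#'
#' @param model A `model_spec`.
#' @param path File path.
#' @return `read_model_json()` returns a `model_spec`; `write_model_json()`
#'   returns `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  v <- validate_model(model)
  if (length(v)) abort_validation(paste(v, collapse = "; "))
  doc <- list(
    model_kind = model$model_kind,
    version = model$version,
    criteria = lapply(unname(model$criteria), function(cr) {
      out <- list(name = cr$name,
                  scale = list(values = cr$scale$values),
                  sub_criteria = cr$sub_criteria)
      if (!is.na(cr$availability_marker)) out$availability_marker <- cr$availability_marker
      out
    })
  )
  write_atomic(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA), path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("model file not found: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = TRUE)
  criteria <- lapply(doc$criteria, function(cr) {
    criterion_spec(cr$name, as.character(cr$sub_criteria),
                   score_scale(cr$scale$values),
                   availability_marker = cr$availability_marker %||% NA_integer_)
  })
  model <- model_spec(doc$model_kind, criteria, version = doc$version %||% "1.0")
  v <- validate_model(model)
  if (length(v)) abort_validation(paste(v, collapse = "; "))
  model
}
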