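# Rankings (overall, per category, per criterion), re-weighting sensitivity
# analysis and Kendall tau-b rank concordance.

new_ranking_table <- function(df, scope) {
  rownames(df) <- NULL
  structure(df, scope = scope, class = c("ranking_table", "data.frame"))
}

#' @export
print.ranking_table <- function(x, n = 10, ...) {
  cat(sprintf("<ranking_table: scope %s, %d entries>\n", attr(x, "scope"), nrow(x)))
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("  ... %d more\n", nrow(x) - n))
  invisible(x)
}

#' Scope of a ranking table
#' @param table A `ranking_table`.
#' @return The scope string (`"overall"`, `"category:<label>"`,
#'   `"criterion:<name>"` or `"gap:<area>"`).
#' @export
ranking_scope <- function(table) attr(table, "scope")

# Competition ranking ("1,2,2,4"): sort by score descending, ties ordered
# alphabetically by display name (byte order, deterministic across locales);
# tied scores share the smallest rank of their group.
rank_table_impl <- function(ids, names, scores, scope) {
  if (length(ids) == 0L) abort_invalid("cannot rank an empty disease set")
  if (anyDuplicated(ids)) abort_invalid("disease_ids must be unique")
  ord <- order(-scores, names, method = "radix")
  s <- scores[ord]
  rnk <- vapply(s, function(x) 1L + sum(s > x), integer(1))
  new_ranking_table(data.frame(
    rank = rnk,
    disease_id = ids[ord],
    disease_name = names[ord],
    score = s,
    stringsAsFactors = FALSE
  ), scope)
}

totals_to_df <- function(totals) {
  if (is.data.frame(totals)) {
    df <- totals
    if (!"score" %in% names(df) && "overall" %in% names(df)) df$score <- df$overall
    need <- c("disease_id", "disease_name", "category", "score")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      abort_invalid(sprintf("totals data.frame lacks column(s): %s",
                            paste(miss, collapse = ", ")))
    }
    df[need]
  } else {
    if (!all(vapply(totals, inherits, logical(1), "disease_total"))) {
      abort_invalid("totals must be disease_total objects or a data.frame")
    }
    data.frame(
      disease_id = vapply(totals, `[[`, character(1), "disease_id"),
      disease_name = vapply(totals, `[[`, character(1), "disease_name"),
      category = vapply(totals, `[[`, character(1), "category"),
      score = vapply(totals, `[[`, numeric(1), "overall"),
      stringsAsFactors = FALSE)
  }
}

#' Rank diseases by prioritisation score
#'
#' Produces a ranking table in one of three scopes: `"overall"` (rank by
#' overall score), `"category:<label>"` (restrict to one disease category) or
#' `"criterion:<name>"` (rank by a single criterion's weighted total, which
#' requires `disease_total` inputs). Ties share a competition rank and are
#' listed alphabetically.
#'
#' @param totals List of [disease_total()] objects, or a data.frame with
#'   columns `disease_id`, `disease_name`, `category` and `score` (or
#'   `overall`).
#' @param scope Scope string, default `"overall"`.
#' @return A `ranking_table` (data.frame with columns `rank`, `disease_id`,
#'   `disease_name`, `score`).
#' @export
rank_diseases <- function(totals, scope = "overall") {
  if (identical(scope, "overall")) {
    df <- totals_to_df(totals)
    return(rank_table_impl(df$disease_id, df$disease_name, df$score, "overall"))
  }
  if (startsWith(scope, "category:")) {
    label <- sub("^category:", "", scope)
    if (!label %in% disease_categories()) {
      abort_invalid(sprintf("unknown category '%s'", label))
    }
    df <- totals_to_df(totals)
    df <- df[df$category == label, , drop = FALSE]
    if (nrow(df) == 0L) abort_invalid(sprintf("no diseases in category '%s'", label))
    return(rank_table_impl(df$disease_id, df$disease_name, df$score, scope))
  }
  if (startsWith(scope, "criterion:")) {
    nm <- sub("^criterion:", "", scope)
    if (is.data.frame(totals) ||
        !all(vapply(totals, inherits, logical(1), "disease_total"))) {
      abort_invalid("criterion scope requires disease_total inputs")
    }
    if (!all(vapply(totals, function(t) nm %in% names(t$per_criterion), logical(1)))) {
      abort_invalid(sprintf("unknown criterion '%s'", nm))
    }
    return(rank_table_impl(
      vapply(totals, `[[`, character(1), "disease_id"),
      vapply(totals, `[[`, character(1), "disease_name"),
      vapply(totals, function(t) t$per_criterion[[nm]], numeric(1)),
      scope))
  }
  abort_invalid(sprintf("unknown ranking scope '%s'", scope))
}

#' Rank diseases by a gap-analysis area
#'
#' @param gaps List of [gap_totals()] objects.
#' @param area `"diagnostics"`, `"vaccines"` or `"pharmaceuticals"`.
#' @return A `ranking_table` ordered by the area's integer gap score
#'   descending (largest gap first), with the same tie semantics as
#'   [rank_diseases()].
#' @export
rank_gaps <- function(gaps, area = c("diagnostics", "vaccines", "pharmaceuticals")) {
  area <- match.arg(area)
  if (length(gaps) == 0L) abort_invalid("cannot rank an empty disease set")
  if (!all(vapply(gaps, inherits, logical(1), "gap_totals"))) {
    abort_invalid("gaps must be gap_totals objects")
  }
  rank_table_impl(
    vapply(gaps, `[[`, character(1), "disease_id"),
    vapply(gaps, `[[`, character(1), "disease_name"),
    vapply(gaps, function(g) as.numeric(g[[area]]), numeric(1)),
    paste0("gap:", area))
}

#' Alternative weight scheme
#'
#' A named criterion-to-weight assignment for sensitivity analysis. Weights
#' replace the model's per-level coefficients wholesale (they multiply each
#' criterion's raw score sum), so the default scheme is the model's own
#' coefficients.
#'
#' @param name Scheme label.
#' @param weights Named non-negative numeric vector, criterion name ->
#'   weight; at least one weight must be strictly positive.
#' @return A `weight_scheme` object.
#' @export
weight_scheme <- function(name, weights) {
  if (!is.numeric(weights) || is.null(names(weights)) || anyNA(weights)) {
    abort_invalid("weights must be a named numeric vector")
  }
  if (any(weights < 0) || !any(weights > 0)) {
    abort_invalid("weights must be non-negative with at least one positive entry")
  }
  structure(list(name = as.character(name), weights = weights),
            class = "weight_scheme")
}

#' Default weight scheme of a model
#'
#' @param model A [model_spec()].
#' @return A [weight_scheme()] holding each criterion's own coefficient.
#' @export
default_weight_scheme <- function(model) {
  w <- vapply(model$criteria, `[[`, numeric(1), "coefficient")
  weight_scheme("baseline", w)
}

#' Read / write a weight scheme as JSON (`{name, weights}`)
#' @param scheme A [weight_scheme()].
#' @param path File path.
#' @export
write_weight_scheme <- function(scheme, path) {
  write_atomic(jsonlite::toJSON(list(name = scheme$name, weights = as.list(scheme$weights)),
                                auto_unbox = TRUE, pretty = TRUE, digits = NA), path)
}

#' @rdname write_weight_scheme
#' @export
read_weight_scheme <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("weight scheme not found: %s", path))
  doc <- jsonlite::fromJSON(path)
  weight_scheme(doc$name %||% "unnamed", unlist(doc$weights))
}

#' Recompute disease totals under an alternative weight scheme
#'
#' Each criterion's total becomes `raw score sum * scheme weight`; the
#' overall score is their sum. With the scheme equal to the model's own
#' coefficients this reproduces [disease_total()] exactly, and scaling all
#' weights by a common positive constant leaves the ranking unchanged.
#'
#' @param sheets List of validated [score_sheet()]s.
#' @param model The governing prioritisation [model_spec()].
#' @param scheme A [weight_scheme()] covering every model criterion.
#' @return List of `disease_total` objects.
#' @export
reweight <- function(sheets, model, scheme) {
  if (!inherits(scheme, "weight_scheme")) abort_invalid("scheme must be a weight_scheme")
  missing <- setdiff(criterion_names(model), names(scheme$weights))
  if (length(missing)) {
    abort_invalid(sprintf("weight scheme '%s' lacks weight(s) for: %s",
                          scheme$name, paste(missing, collapse = ", ")))
  }
  lapply(sheets, function(sheet) {
    assert_sheet(sheet, model)
    per <- vapply(model$criteria, function(cr) {
      scheme$weights[[cr$name]] * sum(sheet$scores[[cr$name]][cr$sub_criteria])
    }, numeric(1))
    structure(list(disease_id = sheet$disease_id,
                   disease_name = sheet$disease_name,
                   category = sheet$category,
                   per_criterion = per,
                   overall = sum(per)),
              class = "disease_total")
  })
}

#' Kendall tau-b concordance between two rankings
#'
#' Compares two ranking tables over the same disease set by the tau-b rank
#' correlation (concordant minus discordant pairs, with the tie correction in
#' the denominator): 1 for identical orderings, -1 for exact reversals.
#' Chosen over Spearman because weight-sensitivity questions are about
#' pairwise order reversals.
#'
#' @param a,b `ranking_table`s containing the same `disease_id` set.
#' @return Tau-b in `[-1, 1]` (`NaN` when either ranking is entirely tied).
#' @export
rank_concordance <- function(a, b) {
  for (t in list(a, b)) {
    if (!inherits(t, "ranking_table")) abort_invalid("inputs must be ranking_tables")
  }
  if (!setequal(a$disease_id, b$disease_id) || nrow(a) != nrow(b)) {
    abort_invalid("rankings cover different disease sets")
  }
  rb <- b$rank[match(a$disease_id, b$disease_id)]
  suppressWarnings(stats::cor(a$rank, rb, method = "kendall"))
}
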