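# Packaged reference fixtures: the two model structures, the published
# 52-disease overall and per-category score tables, and the 30-disease
# gap-score table, transcribed once and guarded by checksums.

fixture_files <- c(
  table2_model = "model_prioritisation.json",
  table3_model = "model_gap.json",
  table4_overall = "overall_scores.csv",
  table5_by_category = "category_scores.csv",
  table6_gaps = "gap_scores.csv"
)

#' Identifiers of the packaged reference tables
#' @return Character vector of fixture ids accepted by [load_fixture()].
#' @export
fixture_ids <- function() names(fixture_files)

fixture_dir <- function() system.file("extdata", package = "priogap")

verify_checksum <- function(file, dir) {
  sums <- jsonlite::fromJSON(file.path(dir, "checksums.json"))
  expected <- sums[[file]]
  if (is.null(expected)) abort_io(sprintf("no recorded checksum for %s", file))
  actual <- unname(tools::md5sum(file.path(dir, file)))
  if (!identical(as.character(actual), expected)) {
    abort_io(sprintf("fixture %s is corrupted (checksum mismatch)", file))
  }
  invisible(TRUE)
}

read_fixture_csv <- function(file, dir, int_cols) {
  df <- utils::read.csv(file.path(dir, file), colClasses = "character",
                        check.names = FALSE, encoding = "UTF-8")
  for (cc in int_cols) df[[cc]] <- as.integer(ascii_minus(df[[cc]]))
  df
}

#' Load a packaged reference table
#'
#' Fixtures are shipped data, transcribed once from the published tables of
#' the reference 52-disease prioritisation exercise, never regenerated at run
#' time; each load verifies an MD5 checksum and the table's structural
#' invariants (52 diseases overall; the category table partitions the same
#' 52 with identical scores; the gap table holds 30 diseases, 10 per
#' category).
#'
#' @param table_id One of [fixture_ids()]: `table2_model` / `table3_model`
#'   (the prioritisation and gap model structures), `table4_overall` (overall
#'   scores in published rank order), `table5_by_category` (the same scores
#'   ranked within category) or `table6_gaps` (integer gap scores for the top
#'   10 diseases of each category).
#' @param dir Fixture directory; defaults to the installed package data.
#' @return A `fixture` object with elements `table_id` and `payload` (a
#'   `model_spec` for the model fixtures, a data.frame otherwise).
#' @export
load_fixture <- function(table_id, dir = fixture_dir()) {
  if (length(table_id) != 1L || !table_id %in% names(fixture_files)) {
    abort_invalid(sprintf("unknown fixture id '%s' (known: %s)",
                          paste(table_id, collapse = ","),
                          paste(names(fixture_files), collapse = ", ")))
  }
  file <- fixture_files[[table_id]]
  if (!file.exists(file.path(dir, file))) {
    abort_io(sprintf("fixture file missing: %s", file.path(dir, file)))
  }
  verify_checksum(file, dir)

  payload <- switch(table_id,
    table2_model = ,
    table3_model = {
      m <- read_model_json(file.path(dir, file))
      v <- validate_model(m)
      if (length(v)) abort_validation(paste(v, collapse = "; "))
      m
    },
    table4_overall = {
      df <- read_fixture_csv(file, dir, "score")
      if (nrow(df) != 52L || anyDuplicated(df$disease_id)) {
        abort_validation("overall score fixture must hold 52 unique diseases")
      }
      if (any(diff(df$score) > 0)) {
        abort_validation("overall score fixture is not in descending score order")
      }
      df
    },
    table5_by_category = {
      df <- read_fixture_csv(file, dir, c("position", "score"))
      t4 <- load_fixture("table4_overall", dir)$payload
      if (!setequal(df$disease_id, t4$disease_id) || nrow(df) != 52L) {
        abort_validation("category fixture does not partition the 52 diseases")
      }
      sc <- t4$score[match(df$disease_id, t4$disease_id)]
      if (!identical(sc, df$score)) {
        abort_validation("category fixture scores disagree with the overall table")
      }
      df
    },
    table6_gaps = {
      df <- read_fixture_csv(file, dir, c("diagnostics", "vaccines", "pharmaceuticals"))
      if (nrow(df) != 30L || !all(table(df$category) == 10L)) {
        abort_validation("gap score fixture must hold 10 diseases per category")
      }
      rng <- range(df[c("diagnostics", "vaccines", "pharmaceuticals")])
      if (rng[1] < -100 || rng[2] > 100) {
        abort_validation("gap scores out of the [-100, 100] bound")
      }
      df
    })
  structure(list(table_id = table_id, payload = payload), class = "fixture")
}

#' @export
print.fixture <- function(x, ...) {
  n <- if (is.data.frame(x$payload)) sprintf("%d rows", nrow(x$payload)) else "model_spec"
  cat(sprintf("<fixture %s: %s>\n", x$table_id, n))
  invisible(x)
}

#' Ranking-ready view of a score fixture
#'
#' Converts the `table4_overall` or `table5_by_category` fixture payload into
#' the data.frame accepted by [rank_diseases()].
#'
#' @param fixture A `fixture` holding a score table.
#' @return data.frame with columns `disease_id`, `disease_name`, `category`,
#'   `score`.
#' @export
fixture_totals <- function(fixture) {
  if (!inherits(fixture, "fixture") ||
      !fixture$table_id %in% c("table4_overall", "table5_by_category")) {
    abort_invalid("fixture_totals() needs an overall or category score fixture")
  }
  df <- fixture$payload
  df[c("disease_id", "disease_name", "category", "score")]
}
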