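# CSV / JSON readers and writers for score sheets, panels and rankings.
# Writers are hand-assembled line-by-line so identical inputs always produce
# byte-identical files, and all writes go through an atomic temp-file rename.

sheet_header <- "disease_id,disease_name,category,criterion,sub_criterion,score,availability_flag"
panel_header <- "disease_id,disease_name,category,expert_id,role,criterion,sub_criterion,score,availability_flag"

sheet_rows <- function(sheet, prefix) {
  rows <- character(0)
  for (crn in names(sheet$scores)) {
    v <- sheet$scores[[crn]]
    flag <- (sheet$availability_flags %||% character(0))[crn]
    flag <- if (is.na(flag)) "" else unname(flag)
    for (sub in names(v)) {
      rows <- c(rows, csv_line(prefix, crn, sub, v[[sub]], flag))
    }
  }
  rows
}

#' Write / read score sheets as CSV
#'
#' One row per (disease, criterion, sub-criterion) with columns
#' `disease_id, disease_name, category, criterion, sub_criterion, score,
#' availability_flag` (UTF-8, comma-separated, header row). On input the
#' Unicode minus sign is accepted in scores; output is plain ASCII. Reading
#' with a model validates every sheet and reports offending line numbers.
#'
#' @param sheets List of [score_sheet()]s.
#' @param path CSV file path.
#' @param model Optional [model_spec()]; when given, every parsed sheet must
#'   validate against it.
#' @return `read_sheets()` returns a list of `score_sheet`s in file order;
#'   `write_sheets()` returns `path` invisibly.
#' @export
write_sheets <- function(sheets, path) {
  if (inherits(sheets, "score_sheet")) sheets <- list(sheets)
  lines <- sheet_header
  for (sheet in sheets) {
    lines <- c(lines, sheet_rows(sheet, c(sheet$disease_id, sheet$disease_name,
                                          sheet$category)))
  }
  write_atomic(lines, path)
}

parse_score_rows <- function(df, path) {
  df$score_chr <- trimws(ascii_minus(df$score))
  num <- suppressWarnings(as.numeric(df$score_chr))
  bad <- which(is.na(num) | num != floor(num))
  if (length(bad)) {
    abort_validation(sprintf("%s: malformed integer score on line(s) %s",
                             path, paste(bad + 1L, collapse = ", ")))
  }
  df$score <- as.integer(num)
  df
}

read_sheet_like <- function(path, required) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        encoding = "UTF-8")
  miss <- setdiff(required, names(df))
  # availability_flag may be absent in hand-written prioritisation files
  miss <- setdiff(miss, "availability_flag")
  if (length(miss)) {
    abort_validation(sprintf("%s: missing column(s): %s", path,
                             paste(miss, collapse = ", ")))
  }
  if (!"availability_flag" %in% names(df)) df$availability_flag <- ""
  if (nrow(df) == 0L) abort_validation(sprintf("%s: no data rows", path))
  parse_score_rows(df, path)
}

build_sheet <- function(rows, model, path) {
  scores <- split(rows, rows$criterion)
  scores <- lapply(scores, function(g) stats::setNames(g$score, g$sub_criterion))
  # preserve model (or file) criterion order
  ord <- unique(rows$criterion)
  scores <- scores[ord]
  flags_rows <- rows[nzchar(rows$availability_flag), , drop = FALSE]
  flags <- NULL
  if (nrow(flags_rows)) {
    flags <- vapply(split(flags_rows, flags_rows$criterion),
                    function(g) g$availability_flag[1], character(1))
  }
  sheet <- score_sheet(rows$disease_id[1], rows$disease_name[1], rows$category[1],
                       scores, availability_flags = flags)
  if (!is.null(model)) {
    v <- validate_sheet(sheet, model)
    if (length(v)) {
      lines <- paste(rows$line, collapse = ", ")
      abort_validation(sprintf("%s: invalid sheet '%s' (lines %s): %s",
                               path, sheet$disease_id, lines,
                               paste(v, collapse = "; ")))
    }
  }
  sheet
}

#' @rdname write_sheets
#' @export
read_sheets <- function(path, model = NULL) {
  df <- read_sheet_like(path, strsplit(sheet_header, ",")[[1]])
  df$line <- seq_len(nrow(df)) + 1L
  if (!is.null(model)) {
    # name the offending row when a score is outside its criterion's scale
    for (cr in model$criteria) {
      sel <- df$criterion == cr$name
      off <- sel & !(df$score %in% cr$scale$values)
      if (any(off)) {
        abort_validation(sprintf(
          "%s: line %d: score %d outside scale %d..%d for '%s'",
          path, df$line[off][1], df$score[off][1],
          min(cr$scale$values), cr$scale$max, cr$name))
      }
    }
  }
  unname(lapply(split(df, factor(df$disease_id, levels = unique(df$disease_id))),
                build_sheet, model = model, path = path))
}

#' Write / read expert panels as CSV
#'
#' Long format with columns `disease_id, disease_name, category, expert_id,
#' role, criterion, sub_criterion, score, availability_flag`; one
#' [panel_scores()] per disease on read, experts in file order.
#'
#' @param panels List of [panel_scores()].
#' @param path CSV file path.
#' @param model Optional [model_spec()] used to validate every expert sheet.
#' @return `read_panels()` returns a list of `panel_scores`;
#'   `write_panels()` returns `path` invisibly.
#' @export
write_panels <- function(panels, path) {
  if (inherits(panels, "panel_scores")) panels <- list(panels)
  lines <- panel_header
  for (p in panels) {
    for (e in p$experts) {
      lines <- c(lines, sheet_rows(e$sheet, c(p$disease_id, e$sheet$disease_name,
                                              e$sheet$category, e$expert_id, e$role)))
    }
  }
  write_atomic(lines, path)
}

#' @rdname write_panels
#' @export
read_panels <- function(path, model = NULL) {
  df <- read_sheet_like(path, strsplit(panel_header, ",")[[1]])
  df$line <- seq_len(nrow(df)) + 1L
  panels <- lapply(split(df, factor(df$disease_id, levels = unique(df$disease_id))),
                   function(pd) {
    experts <- lapply(split(pd, factor(pd$expert_id, levels = unique(pd$expert_id))),
                      function(ed) {
      list(expert_id = ed$expert_id[1], role = ed$role[1],
           sheet = build_sheet(ed, model, path))
    })
    panel_scores(pd$disease_id[1], unname(experts))
  })
  unname(panels)
}

#' Export a ranking table
#'
#' `csv` and `json` are lossless machine formats (see [read_ranking()]);
#' `txt` is a fixed-width presentation mirroring the reference tables. Output
#' is deterministic: identical tables produce byte-identical files.
#'
#' @param table A `ranking_table`.
#' @param path Output file path.
#' @param format `"csv"`, `"txt"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(table, path, format = c("csv", "txt", "json")) {
  format <- match.arg(format)
  if (!inherits(table, "ranking_table")) abort_invalid("table must be a ranking_table")
  scope <- ranking_scope(table)
  score_chr <- vapply(table$score, function(s) {
    if (s == round(s)) sprintf("%d", as.integer(s)) else format(s, digits = 15)
  }, character(1))
  lines <- switch(format,
    csv = c(sprintf("# scope: %s", scope),
            "rank,disease_id,disease_name,score",
            vapply(seq_len(nrow(table)), function(i) {
              csv_line(table$rank[i], table$disease_id[i],
                       table$disease_name[i], score_chr[i])
            }, character(1))),
    txt = c(sprintf("Ranking (%s)", scope),
            sprintf("%4s  %-52s %10s", "Rank", "Disease", "Score"),
            sprintf("%4d  %-52s %10s", table$rank, table$disease_name, score_chr)),
    json = jsonlite::toJSON(list(scope = scope,
                                 entries = as.data.frame(table)),
                            dataframe = "rows", auto_unbox = TRUE,
                            pretty = TRUE, digits = NA)
  )
  write_atomic(lines, path)
}

#' Re-load an exported ranking
#'
#' @param path File written by [write_ranking()] in `csv` or `json` format.
#' @param format Format; inferred from the file extension when `NULL`.
#' @return A `ranking_table`.
#' @export
read_ranking <- function(path, format = NULL) {
  if (!file.exists(path)) abort_io(sprintf("ranking file not found: %s", path))
  format <- format %||% tolower(tools::file_ext(path))
  if (format == "csv") {
    first <- readLines(path, n = 1L, encoding = "UTF-8")
    scope <- sub("^# scope: ", "", first)
    df <- utils::read.csv(path, skip = 1L, colClasses = c("integer", "character",
                                                          "character", "numeric"),
                          check.names = FALSE, encoding = "UTF-8")
    return(new_ranking_table(df, scope))
  }
  if (format == "json") {
    doc <- jsonlite::fromJSON(path)
    df <- doc$entries
    df$rank <- as.integer(df$rank)
    return(new_ranking_table(df[c("rank", "disease_id", "disease_name", "score")],
                             doc$scope))
  }
  abort_invalid(sprintf("cannot re-load format '%s'", format))
}

#' Export dissent records as CSV
#'
#' Writes the dissent data.frame of [aggregate_panel()] in the layout used
#' for "gaps identified" reporting.
#'
#' @param dissent data.frame of dissent records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dissent <- function(dissent, path) {
  cols <- c("disease_id", "criterion", "sub_criterion", "expert_scores",
            "range", "consensus_value")
  lines <- c(paste(cols, collapse = ","),
             vapply(seq_len(nrow(dissent)), function(i) {
               do.call(csv_line, as.list(unlist(dissent[i, cols], use.names = FALSE)))
             }, character(1)))
  write_atomic(lines, path)
}

#' Read a generator configuration from YAML or JSON
#'
#' Accepts the fields of [generator_config()]; `category_effects` is a list
#' of `{category, criterion, shift}` mappings.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path) else jsonlite::fromJSON(path)
  args <- doc
  if (!is.null(doc$category_proportions)) {
    args$category_proportions <- unlist(doc$category_proportions)
  }
  if (!is.null(doc$category_effects)) {
    ce <- doc$category_effects
    if (!is.data.frame(ce)) ce <- do.call(rbind, lapply(ce, as.data.frame))
    args$category_effects <- ce
  }
  do.call(generator_config, args)
}
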