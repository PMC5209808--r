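# Shared internal helpers: conditions, rounding, slugs, atomic writes.

pg_stop <- function(message, class, call = NULL) {
  stop(structure(
    class = c(class, "priogap_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_invalid    <- function(msg) pg_stop(msg, "priogap_invalid_argument")
abort_validation <- function(msg) pg_stop(msg, "priogap_validation_error")
abort_io         <- function(msg) pg_stop(msg, "priogap_io_error")

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves carried away from zero
#' (2.5 -> 3, -2.5 -> -3), the display and consensus convention used
#' throughout the package; contrast with [base::round()], which rounds halves
#' to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_away(c(2.5, -2.5, 100 / 24), c(0, 0, 2))
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  # small guard so rationals stored a hair under .5 (e.g. 100/22 scaled) round as intended
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Display form of a weighting coefficient
#'
#' Coefficients are stored at full precision; tables display them at two
#' decimal places, halves away from zero (100/24 -> 4.17, 100/6 -> 16.67).
#'
#' @param w Numeric vector of coefficients.
#' @return Numeric vector rounded to 2 decimal places.
#' @export
display_weight <- function(w) round_half_away(w, 2)

#' Normalised slug for a name
#'
#' Lower-cases, strips accents/dashes and collapses non-alphanumeric runs to
#' single underscores; used for disease and criterion identifiers in files and
#' on the command line.
#'
#' @param x Character vector of names.
#' @return Character vector of slugs.
#' @export
slugify <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write UTF-8 lines to `path` via a temp file + rename so a failed write never
# leaves a partial file behind.
write_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) abort_io(sprintf("directory does not exist: %s", dir))
  tmp <- tempfile(pattern = ".priogap", tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, open = "wb")
  ok <- FALSE
  tryCatch(
    {
      writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
      ok <- TRUE
    },
    finally = close(con)
  )
  if (!ok || !file.rename(tmp, path)) abort_io(sprintf("failed to write %s", path))
  invisible(path)
}

# Minimal CSV field escaping (RFC 4180): quote when the field contains a
# delimiter, quote or newline.
csv_escape <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

csv_line <- function(...) paste(csv_escape(c(...)), collapse = ",")

# Accept the Unicode minus sign on numeric input.
ascii_minus <- function(x) gsub("\u2212", "-", x)
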