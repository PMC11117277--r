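#' Serialize and parse day-offset event strings
#'
#' Drug and procedure administrations are stored in the raw-record table as a
#' single character column of semicolon-delimited `code:day` pairs (for
#' example `"ABPC_SBT:0;CTRX:1"`), which keeps the raw cohort a flat CSV.
#' `parse_events()` expands one admission's string into a tibble of events;
#' `serialize_events()` is its inverse.
#'
#' @param x A single event string (possibly `NA` or `""` for no events).
#' @return `parse_events()`: a tibble with columns `code` (character) and
#'   `day` (integer). `serialize_events()`: a character scalar.
#' @export
#' @examples
#' parse_events("PIPC_TAZ:0;VCM:1")
parse_events <- function(x) {
  stopifnot(length(x) == 1L)
  if (is.na(x) || !nzchar(x)) {
    return(tibble::tibble(code = character(), day = integer()))
  }
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  pieces <- strsplit(parts, ":", fixed = TRUE)
  ok <- vapply(pieces, length, integer(1)) == 2L
  if (!all(ok)) {
    stop_empyemapba(
      paste0("Malformed event token(s): ",
             paste(parts[!ok], collapse = ", ")),
      "empyemapba_parse_error"
    )
  }
  code <- vapply(pieces, `[[`, character(1), 1L)
  day_chr <- vapply(pieces, `[[`, character(1), 2L)
  day <- suppressWarnings(as.numeric(day_chr))
  if (anyNA(day) || any(day != floor(day)) || any(day < 0)) {
    stop_empyemapba(
      paste0("Event day offsets must be non-negative integers, got: ",
             paste(day_chr[is.na(day) | day != floor(day) | day < 0],
                   collapse = ", ")),
      "empyemapba_parse_error"
    )
  }
  tibble::tibble(code = code, day = as.integer(day))
}

#' @param events A data frame with columns `code` and `day`.
#' @rdname parse_events
#' @export
serialize_events <- function(events) {
  if (nrow(events) == 0) return("")
  paste(paste0(events$code, ":", events$day), collapse = ";")
}

# Vectorized: for each event string, does any event with code class in
# `classes` (per dict) fall on a day in `days`? Assumes well-formed strings
# (read_raw_csv validates on ingest).
has_event_in_window <- function(event_strings, dict, classes, days = c(0L, 1L)) {
  es <- ifelse(is.na(event_strings), "", event_strings)
  toks <- strsplit(es, ";", fixed = TRUE)
  idx <- rep.int(seq_along(es), lengths(toks))
  flat <- unlist(toks, use.names = FALSE)
  out <- rep(FALSE, length(es))
  keep <- nzchar(flat)
  if (!any(keep)) return(out)
  flat <- flat[keep]
  idx <- idx[keep]
  colon <- regexpr(":", flat, fixed = TRUE)
  code <- substr(flat, 1L, colon - 1L)
  day <- suppressWarnings(as.integer(substring(flat, colon + 1L)))
  hit <- classify_drug_codes(code, dict) %in% classes & day %in% days
  out[unique(idx[hit])] <- TRUE
  out
}
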