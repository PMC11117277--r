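raw_record_columns <- c(
  "patient_id", "age", "sex", "admission_day", "drug_events",
  "procedure_events", "bun", "albumin", "barthel", "hugh_jones", "jcs",
  "dialysis", "immunodeficiency", "prior_antibiotics_90d",
  "residence_healthcare_facility", "source_of_infection",
  "oxygen_on_admission", "death_day", "surgery_day", "lost_to_followup_day",
  "transfer_day", "hidden_confounder"
)

#' Read and write raw admission records as CSV
#'
#' One row per admission, missing values encoded as empty fields, drug and
#' procedure events serialized as semicolon-delimited `code:day` pairs. The
#' round trip is lossless.
#'
#' @param records A raw-record tibble as produced by [generate_cohort()].
#' @param path File path.
#' @return `read_raw_csv()` returns a raw-record tibble; `write_raw_csv()`
#'   returns `path` invisibly.
#' @export
write_raw_csv <- function(records, path) {
  missing_cols <- setdiff(raw_record_columns, names(records))
  if (length(missing_cols) > 0) {
    stop_empyemapba(
      paste0("records are missing columns: ",
             paste(missing_cols, collapse = ", ")),
      "empyemapba_schema_error"
    )
  }
  readr::write_csv(records[raw_record_columns], path, na = "")
  invisible(path)
}

#' @rdname write_raw_csv
#' @export
read_raw_csv <- function(path) {
  if (!file.exists(path)) {
    stop_empyemapba(paste0("No such file: ", path), "empyemapba_io_error")
  }
  spec <- readr::cols(
    patient_id = "c", age = "d", sex = "c", admission_day = "c",
    drug_events = "c", procedure_events = "c", bun = "d", albumin = "d",
    barthel = "c", hugh_jones = "c", jcs = "c",
    dialysis = "l", immunodeficiency = "l", prior_antibiotics_90d = "l",
    residence_healthcare_facility = "l", source_of_infection = "c",
    oxygen_on_admission = "l",
    death_day = "c", surgery_day = "c", lost_to_followup_day = "c",
    transfer_day = "c", hidden_confounder = "c"
  )
  raw <- readr::read_csv(path, col_types = spec, na = "")
  missing_cols <- setdiff(raw_record_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop_empyemapba(
      paste0("raw CSV is missing columns: ",
             paste(missing_cols, collapse = ", ")),
      "empyemapba_parse_error"
    )
  }
  int_cols <- c("admission_day", "barthel", "hugh_jones", "jcs", "death_day",
                "surgery_day", "lost_to_followup_day", "transfer_day",
                "hidden_confounder")
  for (col in int_cols) {
    vals <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & (is.na(parsed) | parsed != floor(parsed)))
    if (length(bad) > 0) {
      stop_empyemapba(
        paste0("Non-integer value in column '", col, "' at data row ",
               bad[1], ": '", vals[bad[1]], "'"),
        "empyemapba_parse_error"
      )
    }
    raw[[col]] <- as.integer(parsed)
  }
  day_cols <- c("death_day", "surgery_day", "lost_to_followup_day",
                "transfer_day")
  for (col in day_cols) {
    bad <- which(!is.na(raw[[col]]) & raw[[col]] < 0)
    if (length(bad) > 0) {
      stop_empyemapba(
        paste0("Negative day offset in column '", col, "' at data row ",
               bad[1]),
        "empyemapba_parse_error"
      )
    }
  }
  # validate event strings eagerly so malformed rows fail with a row number
  for (col in c("drug_events", "procedure_events")) {
    for (i in seq_len(nrow(raw))) {
      val <- raw[[col]][i]
      tryCatch(parse_events(if (is.na(val)) "" else val), error = function(e) {
        stop_empyemapba(
          paste0("Malformed '", col, "' at data row ", i, ": ",
                 conditionMessage(e)),
          "empyemapba_parse_error"
        )
      })
    }
  }
  raw$drug_events[is.na(raw$drug_events)] <- ""
  raw$procedure_events[is.na(raw$procedure_events)] <- ""
  raw[raw_record_columns]
}
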