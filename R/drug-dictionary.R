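#' Drug dictionary for exposure classification
#'
#' The analysis classifies day-0/1 intravenous drugs into anti-pseudomonal
#' antibiotics, non-anti-pseudomonal antibiotics, vasopressors, and other
#' agents. The dictionary shipped with the package covers the agents most
#' frequently used for empyema in Japanese hospitals (piperacillin/tazobactam,
#' anti-pseudomonal carbapenems and quinolones, cefepime, ceftazidime,
#' aztreonam on the anti-pseudomonal side; ampicillin/sulbactam, ceftriaxone,
#' clindamycin, vancomycin, metronidazole on the comparator side). It is a
#' plain CSV so users can substitute their own formulary.
#'
#' @param path Path to a dictionary CSV with columns `code`, `name`, `class`.
#'   Defaults to the dictionary bundled with the package.
#' @return A tibble with columns `code`, `name`, and `class` where `class` is
#'   one of `"anti_pseudomonal"`, `"non_anti_pseudomonal"`, `"vasopressor"`,
#'   `"other"`.
#' @export
#' @examples
#' head(drug_dictionary())
drug_dictionary <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "drug_dictionary.csv", package = "empyemapba")
  dict <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  required <- c("code", "name", "class")
  if (!all(required %in% names(dict))) {
    stop_empyemapba(
      paste0("Drug dictionary must have columns: ",
             paste(required, collapse = ", ")),
      "empyemapba_dictionary_error"
    )
  }
  allowed <- c("anti_pseudomonal", "non_anti_pseudomonal", "vasopressor",
               "other")
  bad <- setdiff(unique(dict$class), allowed)
  if (length(bad) > 0) {
    stop_empyemapba(
      paste0("Unknown drug classes in dictionary: ",
             paste(bad, collapse = ", ")),
      "empyemapba_dictionary_error"
    )
  }
  tibble::as_tibble(dict)
}

# Map a vector of drug codes to classes; unknown codes become "other".
classify_drug_codes <- function(codes, dict) {
  cls <- dict$class[match(codes, dict$code)]
  cls[is.na(cls)] <- "other"
  cls
}
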