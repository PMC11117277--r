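#' Apply eligibility and exclusion rules to raw admission records
#'
#' The analysis population is adults aged 40 or older who underwent
#' thoracostomy and received an intravenous antibiotic upon admission or the
#' following day (day offset 0 or 1). Admissions receiving an intravenous
#' vasopressor on day 0/1 are excluded (they plausibly need broad-spectrum
#' cover regardless), as are admissions that ended in death or transfer to
#' another hospital within 24 hours.
#'
#' A record failing several rules is counted once, under the first failing
#' rule in the order: age, antibiotic timing, vasopressor, early death or
#' transfer. The first two rules determine whether a record is "identified"
#' (meets the inclusion criteria); the last two are exclusions among
#' identified records, so
#' `n_analyzed = n_identified - n_excluded_vasopressor -
#' n_excluded_early_death_or_transfer`.
#'
#' @param records Raw-record tibble ([generate_cohort()] / [read_raw_csv()]).
#' @param dict Drug dictionary tibble; see [drug_dictionary()].
#' @param require_early_thoracostomy If `TRUE`, additionally require a
#'   thoracostomy procedure event on day 0/1. Default `FALSE`: only the
#'   antibiotic is time-constrained, thoracostomy is assumed from cohort
#'   identification.
#' @return An object of class `eligibility_result`: a list with `records`
#'   (the input plus an `eligibility` reason column) and `counts` (a one-row
#'   tibble `n_identified`, `n_excluded_vasopressor`,
#'   `n_excluded_early_death_or_transfer`, `n_analyzed`).
#' @export
apply_eligibility <- function(records, dict = drug_dictionary(),
                              require_early_thoracostomy = FALSE) {
  n <- nrow(records)
  if (n == 0) {
    reason <- character()
  } else {
    has_abx <- has_event_in_window(
      records$drug_events, dict,
      classes = c("anti_pseudomonal", "non_anti_pseudomonal"))
    has_vaso <- has_event_in_window(records$drug_events, dict,
                                    classes = "vasopressor")
    early_end <- (!is.na(records$death_day) & records$death_day == 0) |
      (!is.na(records$transfer_day) & records$transfer_day == 0)
    ok_thoraco <- if (require_early_thoracostomy) {
      vapply(records$procedure_events, function(s) {
        ev <- parse_events(if (is.na(s)) "" else s)
        any(ev$code == "THORACOSTOMY" & ev$day %in% c(0L, 1L))
      }, logical(1), USE.NAMES = FALSE)
    } else {
      rep(TRUE, n)
    }
    reason <- rep("eligible", n)
    reason[early_end] <- "excluded_early_death_or_transfer"
    reason[has_vaso] <- "excluded_vasopressor"
    reason[!has_abx | !ok_thoraco] <- "not_identified_no_early_antibiotic"
    reason[is.na(records$age) | records$age < 40] <- "not_identified_age"
  }
  records$eligibility <- reason
  identified <- !reason %in% c("not_identified_age",
                               "not_identified_no_early_antibiotic")
  counts <- tibble::tibble(
    n_raw = n,
    n_identified = sum(identified),
    n_excluded_vasopressor = sum(reason == "excluded_vasopressor"),
    n_excluded_early_death_or_transfer =
      sum(reason == "excluded_early_death_or_transfer"),
    n_analyzed = sum(reason == "eligible")
  )
  structure(list(records = records, counts = counts),
            class = "eligibility_result")
}

#' @export
print.eligibility_result <- function(x, ...) {
  cat("Eligibility flow\n")
  print(x$counts)
  invisible(x)
}

#' @export
glance.eligibility_result <- function(x, ...) x$counts

#' @export
tidy.eligibility_result <- function(x, ...) {
  dplyr::count(x$records, .data$eligibility, name = "n")
}

#' Classify exposure from day-0/1 intravenous antibiotics
#'
#' An admission is labelled `anti_pseudomonal` if *any* intravenous
#' antibiotic administered on day 0 or 1 is anti-pseudomonal (regardless of
#' dose or co-administered agents), and `non_anti_pseudomonal` otherwise.
#' Eligible records are guaranteed by [apply_eligibility()] to have at least
#' one day-0/1 antibiotic; records without one raise an error.
#'
#' @param records Raw-record tibble (eligible rows).
#' @param dict Drug dictionary tibble.
#' @return Factor vector with levels `non_anti_pseudomonal`,
#'   `anti_pseudomonal` (reference level first).
#' @export
classify_exposure <- function(records, dict = drug_dictionary()) {
  has_ap <- has_event_in_window(records$drug_events, dict,
                                classes = "anti_pseudomonal")
  has_abx <- has_event_in_window(
    records$drug_events, dict,
    classes = c("anti_pseudomonal", "non_anti_pseudomonal"))
  if (any(!has_abx)) {
    stop_empyemapba(
      paste0(sum(!has_abx), " record(s) have no day-0/1 intravenous ",
             "antibiotic; run apply_eligibility() first"),
      "empyemapba_contract_error"
    )
  }
  factor(ifelse(has_ap, "anti_pseudomonal", "non_anti_pseudomonal"),
         levels = c("non_anti_pseudomonal", "anti_pseudomonal"))
}

#' Derive analysis covariates from raw fields
#'
#' Categorisations: ADL dependence is Barthel index < 50; low exercise
#' tolerance is Hugh-Jones class > 3; abnormal mental status is Japan Coma
#' Scale > 0; blood urea nitrogen is binned into `<14`, `14-<22.4` and
#' `>=22.4` mg/dL (half-open bins, the boundary value 22.4 falls in the high
#' bin); low albumin is <= 2.7 g/dL; infection source is dichotomised as
#' community versus hospital/nursing-care acquired. A row with any missing
#' source field among the model covariates has `complete_case = FALSE`.
#'
#' @param records Raw-record tibble (eligible rows).
#' @return Tibble of derived covariates, one row per input record.
#' @export
derive_covariates <- function(records) {
  bad_barthel <- which(!is.na(records$barthel) &
                         (records$barthel < 0 | records$barthel > 100))
  if (length(bad_barthel) > 0) {
    stop_empyemapba(
      paste0("Barthel index out of [0, 100] for patient ",
             records$patient_id[bad_barthel[1]]),
      "empyemapba_validation_error"
    )
  }
  bad_lab <- which((!is.na(records$bun) & records$bun < 0) |
                     (!is.na(records$albumin) & records$albumin < 0))
  if (length(bad_lab) > 0) {
    stop_empyemapba(
      paste0("Negative laboratory value for patient ",
             records$patient_id[bad_lab[1]]),
      "empyemapba_validation_error"
    )
  }
  cov <- tibble::tibble(
    patient_id = records$patient_id,
    age = records$age,
    sex = factor(records$sex, levels = c("female", "male")),
    adl_dependent = records$barthel < 50,
    low_exercise_tolerance = records$hugh_jones > 3,
    abnormal_mental_status = records$jcs > 0,
    immunodeficiency = records$immunodeficiency,
    prior_antibiotics_90d = records$prior_antibiotics_90d,
    source_hospital_nursing = records$source_of_infection != "community",
    bun_category = cut(records$bun, breaks = c(-Inf, 14, 22.4, Inf),
                       labels = c("<14", "14-<22.4", ">=22.4"),
                       right = FALSE),
    low_albumin = records$albumin <= 2.7,
    oxygen_use = records$oxygen_on_admission,
    dialysis = records$dialysis,
    residence_healthcare_facility = records$residence_healthcare_facility
  )
  model_cols <- c("age", "sex", "adl_dependent", "low_exercise_tolerance",
                  "immunodeficiency", "prior_antibiotics_90d",
                  "source_hospital_nursing", "abnormal_mental_status",
                  "bun_category", "low_albumin", "oxygen_use")
  cov$complete_case <- stats::complete.cases(cov[model_cols])
  cov
}

#' Derive competing-risk follow-up times and event indicators
#'
#' For thoracic surgery, follow-up runs to the earliest of surgery, death,
#' loss to follow-up, transfer, or the 90-day horizon; surgery is an event
#' only if it comes first (death is a competing event that ends surgery
#' follow-up). For death, follow-up runs to the earliest of death, loss to
#' follow-up, transfer, or day 90: surgery does not preclude death, so death
#' follow-up continues past a surgery. If surgery and death fall on the same
#' day the surgery is counted as occurring first, and the death still counts
#' as an event at that time in the death model.
#'
#' @param records Raw-record tibble (eligible rows).
#' @param horizon Follow-up horizon in days (default 90).
#' @return Tibble with `time_surgery`, `event_surgery`, `time_death`,
#'   `event_death` (events coded 1/0).
#' @export
derive_outcomes <- function(records, horizon = 90) {
  inf_if_na <- function(x) ifelse(is.na(x), Inf, x)
  d_death <- inf_if_na(records$death_day)
  d_surg <- inf_if_na(records$surgery_day)
  d_lost <- pmin(inf_if_na(records$lost_to_followup_day),
                 inf_if_na(records$transfer_day))

  time_death <- pmin(d_death, d_lost, horizon)
  event_death <- as.integer(d_death <= d_lost & d_death <= horizon)

  time_surgery <- pmin(d_surg, d_death, d_lost, horizon)
  event_surgery <- as.integer(d_surg <= pmin(d_death, d_lost) &
                                d_surg <= horizon)

  tibble::tibble(
    time_surgery = as.numeric(time_surgery),
    event_surgery = event_surgery,
    time_death = as.numeric(time_death),
    event_death = event_death
  )
}

#' Flag the multidrug-resistant-organism risk subgroup
#'
#' A patient is at risk for multidrug-resistant organisms if at least one of
#' the following holds: residence in a healthcare facility, dialysis,
#' antibiotic use within the 90 days before admission, or immunodeficiency.
#'
#' @param rows Tibble with logical columns `residence_healthcare_facility`,
#'   `dialysis`, `prior_antibiotics_90d`, `immunodeficiency`.
#' @return Logical vector.
#' @export
flag_mdr_risk <- function(rows) {
  rows$residence_healthcare_facility | rows$dialysis |
    rows$prior_antibiotics_90d | rows$immunodeficiency
}

#' Build the analysis cohort from raw records
#'
#' Runs the full cohort-construction stage: eligibility filtering, exposure
#' classification, covariate derivation, competing-risk outcome derivation,
#' and MDR-risk subgroup flagging. The returned table has one row per
#' eligible patient and is the input to the propensity and survival stages.
#'
#' @inheritParams apply_eligibility
#' @param horizon Follow-up horizon in days.
#' @return A tibble of analysis rows; the eligibility counts are attached as
#'   attribute `"eligibility_counts"`.
#' @export
#' @examples
#' raw <- generate_cohort(cohort_config(n_total = 120, seed = 3))
#' cohort <- build_analysis_cohort(raw)
#' dplyr::count(cohort, exposure)
build_analysis_cohort <- function(records, dict = drug_dictionary(),
                                  horizon = 90,
                                  require_early_thoracostomy = FALSE) {
  elig <- apply_eligibility(records, dict,
                            require_early_thoracostomy =
                              require_early_thoracostomy)
  keep <- elig$records$eligibility == "eligible"
  eligible <- records[keep, , drop = FALSE]
  cov <- derive_covariates(eligible)
  out <- derive_outcomes(eligible, horizon = horizon)
  rows <- dplyr::bind_cols(
    cov[, "patient_id", drop = FALSE],
    tibble::tibble(exposure = classify_exposure(eligible, dict)),
    cov[, setdiff(names(cov), "patient_id")],
    out
  )
  rows$mdr_risk <- flag_mdr_risk(rows)
  rows$hidden_confounder <- eligible$hidden_confounder
  attr(rows, "eligibility_counts") <- elig$counts
  rows
}
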