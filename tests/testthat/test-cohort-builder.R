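raw_row <- function(age = 70, drug = "ABPC_SBT:0", death = NA_integer_,
                    surgery = NA_integer_, lost = NA_integer_,
                    transfer = NA_integer_, bun = 15, albumin = 3.5,
                    barthel = 80L, hugh_jones = 2L, jcs = 0L,
                    source = "community") {
  tibble::tibble(
    patient_id = "X", age = age, sex = "male", admission_day = 0L,
    drug_events = drug, procedure_events = "THORACOSTOMY:0",
    bun = bun, albumin = albumin, barthel = barthel,
    hugh_jones = hugh_jones, jcs = jcs,
    dialysis = FALSE, immunodeficiency = FALSE,
    prior_antibiotics_90d = FALSE, residence_healthcare_facility = FALSE,
    source_of_infection = source, oxygen_on_admission = FALSE,
    death_day = death, surgery_day = surgery, lost_to_followup_day = lost,
    transfer_day = transfer, hidden_confounder = NA_integer_
  )
}

test_that("eligibility reasons and counts follow the rule precedence", {
  recs <- dplyr::bind_rows(
    raw_row(),                                   # eligible
    raw_row(age = 39),                           # too young
    raw_row(drug = "ABPC_SBT:2"),                # antibiotics too late
    raw_row(drug = "ABPC_SBT:0;NAD:1"),          # vasopressor day 0/1
    raw_row(death = 0L),                         # died within 24 h
    raw_row(transfer = 0L),                      # transferred within 24 h
    raw_row(age = 39, drug = "ABPC_SBT:0;NAD:0") # fails age AND vasopressor
  )
  res <- apply_eligibility(recs)
  expect_equal(res$records$eligibility,
               c("eligible", "not_identified_age",
                 "not_identified_no_early_antibiotic",
                 "excluded_vasopressor",
                 "excluded_early_death_or_transfer",
                 "excluded_early_death_or_transfer",
                 "not_identified_age"))
  cnt <- res$counts
  expect_equal(cnt$n_identified, 4)
  expect_equal(cnt$n_analyzed,
               cnt$n_identified - cnt$n_excluded_vasopressor -
                 cnt$n_excluded_early_death_or_transfer)
  expect_equal(glance(res), cnt)
})

test_that("empty input yields zero counts", {
  res <- apply_eligibility(raw_row()[0, ])
  expect_equal(res$counts$n_analyzed, 0)
  expect_equal(res$counts$n_identified, 0)
})

test_that("exposure is anti-pseudomonal if any day-0/1 antibiotic is", {
  recs <- dplyr::bind_rows(
    raw_row(drug = "PIPC_TAZ:0;VCM:0"),   # AP + MRSA cover -> AP
    raw_row(drug = "ABPC_SBT:0"),         # comparator
    raw_row(drug = "ABPC_SBT:0;MEPM:1"),  # day-1 AP after day-0 non-AP
    raw_row(drug = "CTRX:1")
  )
  expect_equal(as.character(classify_exposure(recs)),
               c("anti_pseudomonal", "non_anti_pseudomonal",
                 "anti_pseudomonal", "non_anti_pseudomonal"))
  expect_error(classify_exposure(raw_row(drug = "NAD:0")),
               class = "empyemapba_contract_error")
})

test_that("covariate categorisation honours the documented boundaries", {
  recs <- dplyr::bind_rows(
    raw_row(bun = 22.4, albumin = 2.7, barthel = 50L),   # all boundaries
    raw_row(bun = 13.9, albumin = 2.8, barthel = 45L),
    raw_row(bun = 14.0, albumin = NA, barthel = 80L, source = "nursing")
  )
  cov <- derive_covariates(recs)
  expect_equal(as.character(cov$bun_category), c(">=22.4", "<14", "14-<22.4"))
  expect_equal(cov$low_albumin, c(TRUE, FALSE, NA))
  expect_equal(cov$adl_dependent, c(FALSE, TRUE, FALSE))
  expect_equal(cov$source_hospital_nursing, c(FALSE, FALSE, TRUE))
  expect_equal(cov$complete_case, c(TRUE, TRUE, FALSE))

  expect_error(derive_covariates(raw_row(barthel = 120L)),
               class = "empyemapba_validation_error")
  expect_error(derive_covariates(raw_row(bun = -1)),
               class = "empyemapba_validation_error")
})

test_that("competing-risk outcome derivation follows the cause-specific convention", {
  recs <- dplyr::bind_rows(
    raw_row(death = 30L),                       # death censors surgery
    raw_row(lost = 45L),                        # loss censors both
    raw_row(surgery = 10L, death = 40L),        # death follow-up continues
    raw_row(surgery = 5L, death = 5L),          # same-day tie: surgery first
    raw_row(death = 100L)                       # beyond horizon
  )
  out <- derive_outcomes(recs)
  expect_equal(out$time_death, c(30, 45, 40, 5, 90))
  expect_equal(out$event_death, c(1L, 0L, 1L, 1L, 0L))
  expect_equal(out$time_surgery, c(30, 45, 10, 5, 90))
  expect_equal(out$event_surgery, c(0L, 0L, 1L, 1L, 0L))
  expect_true(all(out$time_surgery <= 90 & out$time_death <= 90))
})

test_that("hand-enumerated risk sets match the derived outcome data", {
  # 5-record fixture: surgery day 10 + death day 40 contributes a surgery
  # event at 10 AND a death event at 40; death day 30 censors surgery at 30.
  recs <- dplyr::bind_rows(
    raw_row(surgery = 10L, death = 40L),
    raw_row(death = 30L),
    raw_row(lost = 20L),
    raw_row(surgery = 50L),
    raw_row()
  )
  out <- derive_outcomes(recs)
  # death risk set at day 40: records 1, 4, 5 (2 died/censored earlier)
  expect_equal(sum(out$time_death >= 40), 3)
  # surgery risk set at day 50: records 4 and 5 only
  expect_equal(sum(out$time_surgery >= 50), 2)
  expect_equal(out$event_surgery, c(1L, 0L, 0L, 1L, 0L))
  expect_equal(out$event_death, c(1L, 1L, 0L, 0L, 0L))
})

test_that("MDR-risk flag is any of the four risk factors", {
  rows <- tibble::tibble(
    residence_healthcare_facility = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    dialysis = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    prior_antibiotics_90d = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    immunodeficiency = c(FALSE, FALSE, TRUE, FALSE, TRUE)
  )
  expect_equal(flag_mdr_risk(rows), c(TRUE, TRUE, TRUE, FALSE, TRUE))
})

test_that("cohort build is internally consistent on generated data", {
  raw <- generate_cohort(cohort_config(n_total = 600, seed = 21))
  cohort <- build_analysis_cohort(raw)
  cnt <- attr(cohort, "eligibility_counts")
  expect_equal(nrow(cohort), cnt$n_analyzed)
  expect_equal(cnt$n_identified,
               cnt$n_analyzed + cnt$n_excluded_vasopressor +
                 cnt$n_excluded_early_death_or_transfer)
  expect_true(all(cohort$time_surgery <= 90 & cohort$time_death <= 90))
  # event implies the time equals that cause's event day
  raw_el <- raw[apply_eligibility(raw)$records$eligibility == "eligible", ]
  died <- cohort$event_death == 1
  expect_equal(cohort$time_death[died], as.numeric(raw_el$death_day[died]))
})

test_that("no missingness means every row is a complete case", {
  cohort <- build_analysis_cohort(generate_cohort(cohort_config(
    n_total = 300, seed = 9,
    missing_rate = c(albumin = 0, bun = 0, jcs = 0, hugh_jones = 0,
                     barthel = 0))))
  expect_true(all(cohort$complete_case))
})
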