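#' Generate a synthetic raw admission cohort
#'
#' Simulates patient-level admission records with the statistical structure
#' the downstream analysis assumes: confounded exposure assignment through a
#' logistic model on the analysis covariates, competing event processes for
#' thoracic surgery and death generated from independent latent exponential
#' times whose cause-specific hazards are multiplied by `exp(log-HR x
#' covariates)`, per-day loss to follow-up, completely-at-random covariate
#' missingness, and (optionally) a hidden binary confounder that multiplies
#' the death hazard. A configurable share of records is made deliberately
#' ineligible (age below 40, antibiotics starting on day 2 or later, a
#' vasopressor on day 0/1, death or transfer within 24 hours) so every
#' eligibility filter is exercised.
#'
#' The output is a flat tibble, one row per admission, with drug and
#' procedure administrations serialized as `code:day` event strings (see
#' [parse_events()]). The column `hidden_confounder` is simulation truth for
#' validating the bias-analysis module; no analysis stage reads it.
#'
#' @param config A [cohort_config()] object.
#' @return A tibble of raw admission records.
#' @export
#' @examples
#' raw <- generate_cohort(cohort_config(n_total = 50, seed = 7))
#' nrow(raw)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_empyemapba("`config` must be built by cohort_config()",
                    "empyemapba_config_error")
  }
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_total
  cs <- config$covariate_spec
  hz <- config$hazard_spec

  # --- covariates ---------------------------------------------------------
  age <- pmin(pmax(rnorm(n, cs$age_mean, cs$age_sd), cs$age_min), cs$age_max)
  sex <- ifelse(runif(n) < cs$male, "male", "female")
  adl_dep <- runif(n) < cs$adl_dependent
  low_ext <- runif(n) < cs$low_exercise_tolerance
  ams <- runif(n) < cs$abnormal_mental_status
  immunodef <- runif(n) < cs$immunodeficiency
  prior_abx <- runif(n) < cs$prior_antibiotics
  source <- sample(names(cs$source_probs), n, replace = TRUE,
                   prob = cs$source_probs)
  oxygen <- runif(n) < cs$oxygen
  dialysis <- runif(n) < cs$dialysis
  residence <- runif(n) < cs$residence_facility
  bun <- round(exp(rnorm(n, cs$bun_meanlog, cs$bun_sdlog)), 1)
  albumin <- round(pmax(rnorm(n, cs$albumin_mean, cs$albumin_sd), 1.0), 1)

  # raw functional scores consistent with the derived binary covariates
  barthel <- ifelse(adl_dep, sample(seq(0, 45, by = 5), n, replace = TRUE),
                    sample(seq(50, 100, by = 5), n, replace = TRUE))
  hugh_jones <- ifelse(low_ext, sample(4:5, n, replace = TRUE),
                       sample(1:3, n, replace = TRUE))
  jcs <- ifelse(ams, sample(c(1L, 2L, 3L, 10L, 20L), n, replace = TRUE), 0L)

  # --- covariate terms shared by the exposure and hazard models ----------
  terms <- cbind(
    age10 = (age - 75) / 10,
    male = as.numeric(sex == "male"),
    adl_dependent = as.numeric(adl_dep),
    low_exercise_tolerance = as.numeric(low_ext),
    immunodeficiency = as.numeric(immunodef),
    prior_antibiotics_90d = as.numeric(prior_abx),
    source_hospital_nursing = as.numeric(source != "community"),
    abnormal_mental_status = as.numeric(ams),
    bun_mid = as.numeric(bun >= 14 & bun < 22.4),
    bun_high = as.numeric(bun >= 22.4),
    low_albumin = as.numeric(albumin <= 2.7),
    oxygen_use = as.numeric(oxygen)
  )

  beta <- config$ps_coefficients
  lp <- beta[["intercept"]] +
    drop(terms[, names(beta)[-1], drop = FALSE] %*% beta[-1])
  exposed <- runif(n) < plogis(lp)

  # --- hidden confounder (simulation truth only) --------------------------
  if (!is.null(config$confounder_spec)) {
    p_c <- ifelse(exposed, config$confounder_spec$p1, config$confounder_spec$p0)
    hidden <- as.integer(runif(n) < p_c)
    rr_death <- config$confounder_spec$rr_death
  } else {
    hidden <- rep(NA_integer_, n)
    rr_death <- 1
  }

  # --- latent event times -------------------------------------------------
  lhr_s <- hz$loghr_covariates$surgery
  lhr_d <- hz$loghr_covariates$death
  rate_s <- hz$base_surgery *
    exp(drop(terms[, names(lhr_s), drop = FALSE] %*% lhr_s) +
          hz$loghr_exposure[["surgery"]] * exposed)
  rate_d <- hz$base_death *
    exp(drop(terms[, names(lhr_d), drop = FALSE] %*% lhr_d) +
          hz$loghr_exposure[["death"]] * exposed +
          log(rr_death) * ifelse(is.na(hidden), 0, hidden))
  t_surg <- rexp(n, pmax(rate_s, 1e-12))
  t_death <- rexp(n, pmax(rate_d, 1e-12))
  t_lost <- if (config$censor_rate > 0) rexp(n, config$censor_rate) else
    rep(Inf, n)

  # events are only in the record if they happened while still followed;
  # surgery additionally requires the patient to be alive
  max_record <- 365
  death_day <- ifelse(t_death <= t_lost & t_death <= max_record,
                      ceiling(t_death), NA_real_)
  surgery_day <- ifelse(t_surg <= pmin(t_death, t_lost) &
                          t_surg <= max_record,
                        ceiling(t_surg), NA_real_)
  lost_day <- ifelse(is.finite(t_lost) & t_lost < pmin(t_death, max_record),
                     ceiling(t_lost), NA_real_)
  transfer_day <- rep(NA_real_, n)

  # --- drug events: day-0/1 intravenous antibiotics -----------------------
  abx_day <- rbinom(n, 1L, 0.2)
  ap_primary <- sample(
    c("PIPC_TAZ", "MEPM", "IPM_CS", "DRPM", "CFPM", "CAZ", "LVFX"),
    n, replace = TRUE,
    prob = c(0.66, 0.20, 0.05, 0.02, 0.03, 0.02, 0.02))
  nap_primary <- sample(
    c("ABPC_SBT", "CTRX", "CLDM", "CEZ"),
    n, replace = TRUE, prob = c(0.90, 0.06, 0.02, 0.02))
  extra_vcm <- runif(n) < 0.03
  extra_ctrx <- runif(n) < 0.05
  primary <- ifelse(exposed, ap_primary, nap_primary)
  drug_events <- paste0(
    primary, ":", abx_day,
    ifelse(!exposed & extra_ctrx & nap_primary != "CTRX", ";CTRX:1", ""),
    ifelse(extra_vcm, ";VCM:0", "")
  )
  procedure_events <- rep("THORACOSTOMY:0", n)

  # --- deliberately ineligible records ------------------------------------
  counts <- round(config$ineligible_fracs * n)
  pool <- sample.int(n)
  take <- function(k) {
    idx <- utils::head(pool, k)
    pool <<- utils::tail(pool, length(pool) - k)
    idx
  }
  idx_age <- take(counts[["age_under_40"]])
  idx_late <- take(counts[["late_antibiotics"]])
  idx_vaso <- take(counts[["vasopressor"]])
  idx_early <- take(counts[["early_death_or_transfer"]])

  if (length(idx_age) > 0) {
    age[idx_age] <- runif(length(idx_age), 18, 39.5)
  }
  if (length(idx_late) > 0) {
    # antibiotics start on day 2-3: outside the empirical-treatment window
    drug_events[idx_late] <- vapply(drug_events[idx_late], function(s) {
      ev <- parse_events(s)
      ev$day <- ev$day + 2L
      serialize_events(ev)
    }, character(1), USE.NAMES = FALSE)
  }
  if (length(idx_vaso) > 0) {
    drug_events[idx_vaso] <- paste0(drug_events[idx_vaso], ";NAD:0")
  }
  if (length(idx_early) > 0) {
    is_death <- seq_along(idx_early) %% 2L == 1L
    death_day[idx_early[is_death]] <- 0
    surgery_day[idx_early[is_death]] <- NA_real_
    transfer_day[idx_early[!is_death]] <- 0
  }

  # --- covariate missingness (MCAR) ---------------------------------------
  mr <- config$missing_rate
  if (mr[["albumin"]] > 0) albumin[runif(n) < mr[["albumin"]]] <- NA_real_
  if (mr[["bun"]] > 0) bun[runif(n) < mr[["bun"]]] <- NA_real_
  if (mr[["jcs"]] > 0) jcs[runif(n) < mr[["jcs"]]] <- NA_integer_
  if (mr[["hugh_jones"]] > 0) {
    hugh_jones[runif(n) < mr[["hugh_jones"]]] <- NA_integer_
  }
  if (mr[["barthel"]] > 0) barthel[runif(n) < mr[["barthel"]]] <- NA_integer_

  tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = round(age, 1),
    sex = sex,
    admission_day = 0L,
    drug_events = drug_events,
    procedure_events = procedure_events,
    bun = bun,
    albumin = albumin,
    barthel = as.integer(barthel),
    hugh_jones = as.integer(hugh_jones),
    jcs = as.integer(jcs),
    dialysis = dialysis,
    immunodeficiency = immunodef,
    prior_antibiotics_90d = prior_abx,
    residence_healthcare_facility = residence,
    source_of_infection = source,
    oxygen_on_admission = oxygen,
    death_day = as.integer(death_day),
    surgery_day = as.integer(surgery_day),
    lost_to_followup_day = as.integer(lost_day),
    transfer_day = as.integer(transfer_day),
    hidden_confounder = hidden
  )
}
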