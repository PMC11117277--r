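test_that("exchangeable arms give a null log hazard ratio", {
  rows <- tibble::tibble(
    exposure = as_exposure(rep(c("anti_pseudomonal",
                                 "non_anti_pseudomonal"), each = 4)),
    time_death = rep(c(2, 5, 7, 9), 2),
    event_death = rep(c(1L, 1L, 0L, 1L), 2),
    time_surgery = rep(c(2, 5, 7, 9), 2),
    event_surgery = rep(c(1L, 1L, 0L, 1L), 2)
  )
  fit <- fit_cause_specific_cox(rows, "death")
  expect_lt(abs(fit$log_hr), 1e-10)
  expect_lt(abs(fit$hr - 1), 1e-10)
})

test_that("the fitted log-HR matches a brute-force partial-likelihood grid search", {
  fix <- six_record_fixture()
  fit <- suppressWarnings(fit_cause_specific_cox(fix, "death"))
  oracle <- cox_grid_oracle(fix$time_death, fix$event_death,
                            as.integer(fix$exposure == "anti_pseudomonal"))
  expect_lt(abs(fit$log_hr - oracle), 1e-4)
  expect_equal(fit$ci95, exp(fit$log_hr + c(-1, 1) * 1.96 * fit$robust_se))
})

test_that("doubling all weights changes neither the estimate nor the sandwich SE", {
  fix <- six_record_fixture()
  f1 <- suppressWarnings(fit_cause_specific_cox(fix, "death",
                                                weights = rep(1, 6)))
  f2 <- suppressWarnings(fit_cause_specific_cox(fix, "death",
                                                weights = rep(2, 6)))
  expect_lt(abs(f2$log_hr - f1$log_hr), 1e-10)
  expect_lt(abs(robust_sandwich_se(f2) - robust_sandwich_se(f1)), 1e-10)
})

test_that("robust and model-based SEs agree under correct specification", {
  # unweighted exponential two-sample data, large n
  set.seed(99)
  n <- 4000
  z <- rep(c(0, 1), each = n / 2)
  t_ev <- rexp(n, 0.01 * exp(0.4 * z))
  rows <- tibble::tibble(
    exposure = as_exposure(ifelse(z == 1, "anti_pseudomonal",
                                  "non_anti_pseudomonal")),
    time_death = pmin(t_ev, 90), event_death = as.integer(t_ev <= 90),
    time_surgery = pmin(t_ev, 90), event_surgery = as.integer(t_ev <= 90)
  )
  fit <- fit_cause_specific_cox(rows, "death")
  expect_lt(abs(fit$robust_se / fit$model_se - 1), 0.10)
})

test_that("boundary fits stay finite and flag low information", {
  rows <- tibble::tibble(
    exposure = as_exposure(c("anti_pseudomonal", "non_anti_pseudomonal",
                             "non_anti_pseudomonal")),
    time_death = c(5, 8, 9), event_death = c(1L, 0L, 0L),
    time_surgery = c(5, 8, 9), event_surgery = c(0L, 0L, 0L)
  )
  fit <- suppressWarnings(fit_cause_specific_cox(rows, "death"))
  expect_true(is.finite(fit$robust_se))
  expect_true(fit$low_information)
  expect_error(fit_cause_specific_cox(rows, "surgery"),
               class = "empyemapba_no_event_error")
})

test_that("Aalen-Johansen estimates match hand-computed risk sets", {
  rows <- tibble::tibble(
    patient_id = as.character(1:4),
    exposure = as_exposure(rep("anti_pseudomonal", 4)),
    time_surgery = c(2, 3, 4, 90), event_surgery = c(1L, 0L, 0L, 0L),
    time_death = c(2, 3, 4, 90), event_death = c(0L, 0L, 1L, 0L)
  )
  cif <- cumulative_incidence(rows, by_group = FALSE)
  # hand enumeration: surgery at t=2 (4 at risk) -> 1/4; censor at 3;
  # death at t=4 (2 at risk) -> 0.75 * 1/2 = 0.375
  surg <- dplyr::filter(cif, state == "surgery", time == 2)$estimate
  dth <- dplyr::filter(cif, state == "death", time == 4)$estimate
  expect_equal(surg, 0.25, tolerance = 1e-12)
  expect_equal(dth, 0.375, tolerance = 1e-12)
})

test_that("the CIFs and event-free probability always sum to one", {
  cohort <- small_cohort(n = 600, seed = 19)
  cif <- cumulative_incidence(cohort)
  sums <- cif |>
    dplyr::group_by(.data$group, .data$time) |>
    dplyr::summarise(total = sum(.data$estimate), .groups = "drop")
  expect_lt(max(abs(sums$total - 1)), 1e-10)
  # CIFs are nondecreasing step functions
  mono <- cif |>
    dplyr::filter(.data$state != "event_free") |>
    dplyr::group_by(.data$group, .data$state) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::summarise(ok = all(diff(.data$estimate) >= -1e-12),
                     .groups = "drop")
  expect_true(all(mono$ok))
})

test_that("with a single cause the CIF equals one minus Kaplan-Meier", {
  set.seed(4)
  n <- 150
  t_ev <- ceiling(rexp(n, 0.02))
  t_c <- ceiling(rexp(n, 0.01))
  rows <- tibble::tibble(
    exposure = as_exposure(rep("anti_pseudomonal", n)),
    time_death = pmin(t_ev, t_c, 90),
    event_death = as.integer(t_ev <= pmin(t_c, 90)),
    time_surgery = pmin(t_ev, t_c, 90),
    event_surgery = 0L
  )
  cif <- cumulative_incidence(rows, by_group = FALSE)
  km <- survival::survfit(survival::Surv(time_death, event_death) ~ 1,
                          data = rows)
  got <- dplyr::filter(cif, state == "death")
  expect_equal(got$estimate, 1 - km$surv[match(got$time, km$time)],
               tolerance = 1e-12)
})

test_that("fully censored data yield zero incidence and empty input an empty grid", {
  rows <- tibble::tibble(
    exposure = as_exposure(rep("anti_pseudomonal", 5)),
    time_death = rep(90, 5), event_death = 0L,
    time_surgery = rep(90, 5), event_surgery = 0L
  )
  cif <- cumulative_incidence(rows, by_group = FALSE)
  expect_true(all(dplyr::filter(cif, state != "event_free")$estimate == 0))
  expect_equal(nrow(cumulative_incidence(rows[0, ])), 0)
})

test_that("model-implied survival curves follow the exponentiated Breslow baseline", {
  fix <- six_record_fixture()
  fit <- suppressWarnings(fit_cause_specific_cox(fix, "death"))
  sc <- weighted_survival_curves(fit)
  b <- fit$log_hr
  z <- as.integer(fix$exposure == "anti_pseudomonal")
  dL0 <- vapply(1:6, function(i) 1 / sum(exp(b * z[fix$time_death >= i])),
                numeric(1))
  L0 <- cumsum(dL0)
  s0 <- dplyr::filter(sc, group == "non_anti_pseudomonal")$estimate
  s1 <- dplyr::filter(sc, group == "anti_pseudomonal")$estimate
  expect_equal(s0, exp(-L0), tolerance = 1e-6)
  expect_equal(s1, exp(-L0 * exp(b)), tolerance = 1e-6)
})

test_that("a null effect gives identical curves in both arms", {
  rows <- tibble::tibble(
    exposure = as_exposure(rep(c("anti_pseudomonal",
                                 "non_anti_pseudomonal"), each = 4)),
    time_death = rep(c(2, 5, 7, 9), 2),
    event_death = rep(c(1L, 1L, 0L, 1L), 2),
    time_surgery = rep(c(2, 5, 7, 9), 2),
    event_surgery = rep(c(1L, 1L, 0L, 1L), 2)
  )
  sc <- weighted_survival_curves(fit_cause_specific_cox(rows, "death"))
  wide <- tidyr::pivot_wider(sc[c("group", "time", "estimate")],
                             names_from = "group",
                             values_from = "estimate")
  expect_lt(max(abs(wide$anti_pseudomonal - wide$non_anti_pseudomonal)),
            1e-10)
})
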