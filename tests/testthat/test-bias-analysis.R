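test_that("beta solver reproduces the mean exactly and the interval at mean 0.5", {
  ab <- beta_from_mean_interval(0.5, 0.1)
  expect_equal(unname(ab["alpha"]), unname(ab["beta"]))  # symmetry
  expect_equal(unname(ab["alpha"] / sum(ab)), 0.5, tolerance = 1e-12)
  expect_lt(abs(qbeta(0.025, ab["alpha"], ab["beta"]) - 0.4), 1e-4)
  expect_lt(abs(qbeta(0.975, ab["alpha"], ab["beta"]) - 0.6), 1e-4)

  for (m in c(0.2, 0.3, 0.6)) {
    ab <- beta_from_mean_interval(m, 0.1)
    expect_equal(unname(ab["alpha"] / sum(ab)), m, tolerance = 1e-10)
    width <- qbeta(0.975, ab["alpha"], ab["beta"]) -
      qbeta(0.025, ab["alpha"], ab["beta"])
    expect_lt(abs(width - 0.2), 1e-6)
  }
  expect_error(beta_from_mean_interval(0.05, 0.1),
               class = "empyemapba_solver_error")
})

test_that("trapezoid draws follow the closed-form distribution", {
  corners <- c(2.8, 2.9, 3.1, 3.2)
  draws <- withr::with_seed(1, rtrapezoid(1e5, corners))
  expect_true(all(draws >= 2.8 & draws <= 3.2))
  expect_lt(abs(mean(draws) - 3.0), 0.005)  # symmetric density
  # Kolmogorov distance against the piecewise-quadratic CDF
  xs <- sort(draws)
  ks <- max(abs(seq_along(xs) / length(xs) - ptrapezoid(xs, corners)))
  expect_lt(ks, 0.01)
  # CDF consistent with numerically integrated density
  for (q in c(2.85, 2.95, 3.05, 3.15)) {
    num <- integrate(dtrapezoid, 2.8, q, corners = corners,
                     rel.tol = 1e-10)$value
    expect_equal(ptrapezoid(q, corners), num, tolerance = 1e-8)
  }
  expect_error(rtrapezoid(1, c(3, 2, 4, 5)),
               class = "empyemapba_config_error")
})

test_that("imputation probabilities follow Bayes' rule and total probability", {
  probs <- imputation_probs(c(unexposed = 0.4, exposed = 0.4), 3,
                            c(unexposed = 0.1, exposed = 0.1))
  pr <- setNames(probs$pr_c, paste(probs$exposed, probs$death))
  expect_equal(unname(pr[["1 1"]]), 2 / 3, tolerance = 1e-10)
  expect_equal(unname(pr[["1 0"]]), 0.4 * (1 - 3 * 0.1 / 1.8) / 0.9,
               tolerance = 1e-10)
  # self-check: 2/3 * 0.1 + 0.37037 * 0.9 = 0.4
  expect_equal(unname(pr[["1 1"]] * 0.1 + pr[["1 0"]] * 0.9), 0.4,
               tolerance = 1e-10)

  # null risk ratio: confounder independent of outcome
  p_null <- imputation_probs(c(unexposed = 0.3, exposed = 0.5), 1,
                             c(unexposed = 0.2, exposed = 0.1))
  expect_equal(p_null$pr_c, c(0.3, 0.3, 0.5, 0.5), tolerance = 1e-12)

  # zero prevalence propagates
  p_zero <- imputation_probs(c(unexposed = 0, exposed = 0), 3,
                             c(unexposed = 0.1, exposed = 0.1))
  expect_equal(p_zero$pr_c, rep(0, 4))

  expect_error(
    imputation_probs(c(unexposed = 0.1, exposed = 0.1), 4,
                     c(unexposed = 0.5, exposed = 0.5)),
    class = "empyemapba_incompatible_parameters_error")
})

test_that("prevalence reconstruction holds across random parameter draws", {
  withr::with_seed(7, {
    for (i in 1:200) {
      p <- runif(2, 0.05, 0.7)
      rr <- runif(1, 1, 5)
      pd <- runif(2, 0.02, 0.25)
      probs <- tryCatch(
        imputation_probs(setNames(p, c("unexposed", "exposed")), rr,
                         setNames(pd, c("unexposed", "exposed"))),
        empyemapba_incompatible_parameters_error = function(e) NULL)
      if (is.null(probs)) next
      recon <- c(
        probs$pr_c[2] * pd[1] + probs$pr_c[1] * (1 - pd[1]),
        probs$pr_c[4] * pd[2] + probs$pr_c[3] * (1 - pd[2])
      )
      expect_lt(max(abs(recon - p)), 1e-10)
    }
  })
})

test_that("record-level imputation hits the cell probabilities", {
  rows <- tibble::tibble(
    exposure = as_exposure(rep(c("anti_pseudomonal",
                                 "non_anti_pseudomonal"), each = 10000)),
    event_death = rep(c(1L, 0L), 10000)
  )
  zero <- imputation_probs(c(unexposed = 0, exposed = 0), 2,
                           c(unexposed = 0.5, exposed = 0.5))
  expect_true(all(withr::with_seed(1, impute_confounder(rows, zero)) == 0))

  one <- zero; one$pr_c <- rep(1, 4)
  expect_true(all(withr::with_seed(1, impute_confounder(rows, one)) == 1))

  probs <- imputation_probs(c(unexposed = 0.2, exposed = 0.5), 3,
                            c(unexposed = 0.3, exposed = 0.3))
  cimp <- withr::with_seed(5, impute_confounder(rows, probs))
  emp <- tapply(cimp, list(rows$exposure, rows$event_death), mean)
  for (e in exposure_levels) {
    for (d in c("0", "1")) {
      target <- probs$pr_c[probs$exposed ==
                             as.integer(e == "anti_pseudomonal") &
                             probs$death == as.integer(d == "1")]
      expect_lt(abs(emp[e, d] - target),
                3 * sqrt(target * (1 - target) / 5000))
    }
  }
})

test_that("the PBA is reproducible and handles incompatible cells", {
  cohort <- small_cohort(n = 1200, seed = 61)
  sub <- dplyr::filter(cohort, mdr_risk)
  grid <- tibble::tibble(p1 = 0.5, p0 = 0.2, rr_cd = 3)
  p1 <- suppressWarnings(run_pba(sub, grid, iterations = 30, seed = 17))
  p2 <- suppressWarnings(run_pba(sub, grid, iterations = 30, seed = 17))
  expect_identical(p1$draws$log_hr, p2$draws$log_hr)
  expect_equal(nrow(p1$cells), 1)
  expect_true(p1$cells$hr_low <= p1$cells$median_hr &
                p1$cells$median_hr <= p1$cells$hr_high)

  # a cell whose risk ratio is impossible given a 50% observed death risk
  half_dead <- dplyr::mutate(sub, event_death = rep_len(c(1L, 0L),
                                                        dplyr::n()))
  bad_grid <- tibble::tibble(p1 = 0.1, p0 = 0.1, rr_cd = 4)
  res <- suppressWarnings(run_pba(half_dead, bad_grid, iterations = 20,
                                  seed = 2))
  expect_gt(res$cells$n_skipped, 4)
  expect_true(res$cells$unreliable)
})

test_that("tidy, glance and the forest plot expose the PBA result", {
  cohort <- small_cohort(n = 1200, seed = 62)
  sub <- dplyr::filter(cohort, mdr_risk)
  pba <- suppressWarnings(run_pba(sub, tibble::tibble(p1 = 0.4, p0 = 0.1,
                                                      rr_cd = 3),
                                  iterations = 15, seed = 3))
  expect_equal(nrow(tidy(pba)), 1)
  expect_equal(glance(pba)$n_cells, 1)
  expect_s3_class(autoplot(pba), "ggplot")
})
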