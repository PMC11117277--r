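#' Solve Beta parameters from a mean and central-interval half width
#'
#' Finds `(alpha, beta)` such that the Beta mean equals `mean` exactly and
#' the central 95% interval is as close as possible to
#' `mean +/- half_width`. With the mean fixed there is one free parameter
#' (the concentration `kappa = alpha + beta`), so the solver matches the
#' central-interval *width* `q(0.975) - q(0.025) = 2 * half_width` by a
#' monotone root find; for a symmetric mean of 0.5 this reproduces both
#' percentiles exactly.
#'
#' @param mean Desired Beta mean in (0, 1).
#' @param half_width Half width of the central interval (default 0.1).
#' @param level Central interval probability (default 0.95).
#' @return Named vector `c(alpha =, beta =)`.
#' @export
#' @examples
#' beta_from_mean_interval(0.5, 0.1)
beta_from_mean_interval <- function(mean, half_width = 0.1, level = 0.95) {
  if (!is_scalar_prob(mean) || mean <= 0 || mean >= 1) {
    stop_empyemapba("`mean` must lie strictly in (0, 1)",
                    "empyemapba_solver_error")
  }
  if (mean - half_width < 0 || mean + half_width > 1) {
    stop_empyemapba(
      paste0("infeasible constraints: interval ", mean, " +/- ", half_width,
             " leaves (0, 1)"),
      "empyemapba_solver_error"
    )
  }
  a_tail <- (1 - level) / 2
  width <- function(kappa) {
    qbeta(1 - a_tail, mean * kappa, (1 - mean) * kappa) -
      qbeta(a_tail, mean * kappa, (1 - mean) * kappa)
  }
  target <- 2 * half_width
  f <- function(kappa) width(kappa) - target
  lo <- 1e-3; hi <- 1e6
  if (f(lo) < 0 || f(hi) > 0) {
    stop_empyemapba("could not bracket the concentration solving the width",
                    "empyemapba_solver_error")
  }
  kappa <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  c(alpha = mean * kappa, beta = (1 - mean) * kappa)
}

#' Trapezoidal distribution
#'
#' Density rising linearly on `[a, b]`, flat on `[b, c]`, falling linearly
#' on `[c, d]`. Used as the uncertainty distribution of the
#' confounder-death risk ratio, with corners
#' `(rr - 0.2, rr - 0.1, rr + 0.1, rr + 0.2)` around each grid value.
#'
#' @param x,q Quantiles.
#' @param n Number of draws.
#' @param corners Numeric length-4 vector `(a, b, c, d)`, strictly
#'   increasing.
#' @return `dtrapezoid()`/`ptrapezoid()` return numeric vectors;
#'   `rtrapezoid()` returns `n` draws via inverse-CDF sampling.
#' @export
#' @examples
#' mean(rtrapezoid(1e4, c(2.8, 2.9, 3.1, 3.2)))
dtrapezoid <- function(x, corners) {
  check_corners(corners)
  a <- corners[1]; b <- corners[2]; cc <- corners[3]; d <- corners[4]
  h <- 2 / ((d + cc) - (a + b))
  out <- numeric(length(x))
  ris <- x >= a & x < b
  out[ris] <- h * (x[ris] - a) / (b - a)
  mid <- x >= b & x <= cc
  out[mid] <- h
  fal <- x > cc & x <= d
  out[fal] <- h * (d - x[fal]) / (d - cc)
  out
}

#' @rdname dtrapezoid
#' @export
ptrapezoid <- function(q, corners) {
  check_corners(corners)
  a <- corners[1]; b <- corners[2]; cc <- corners[3]; d <- corners[4]
  h <- 2 / ((d + cc) - (a + b))
  out <- numeric(length(q))
  out[q >= d] <- 1
  ris <- q >= a & q < b
  out[ris] <- h * (q[ris] - a)^2 / (2 * (b - a))
  mid <- q >= b & q <= cc
  out[mid] <- h * (b - a) / 2 + h * (q[mid] - b)
  fal <- q > cc & q < d
  out[fal] <- 1 - h * (d - q[fal])^2 / (2 * (d - cc))
  out
}

#' @rdname dtrapezoid
#' @export
rtrapezoid <- function(n, corners) {
  check_corners(corners)
  u <- runif(n)
  a <- corners[1]; b <- corners[2]; cc <- corners[3]; d <- corners[4]
  h <- 2 / ((d + cc) - (a + b))
  p_rise <- h * (b - a) / 2
  p_flat <- h * (cc - b)
  out <- numeric(n)
  i1 <- u < p_rise
  out[i1] <- a + sqrt(2 * u[i1] * (b - a) / h)
  i2 <- !i1 & u < p_rise + p_flat
  out[i2] <- b + (u[i2] - p_rise) / h
  i3 <- !i1 & !i2
  out[i3] <- d - sqrt(2 * (1 - u[i3]) * (d - cc) / h)
  out
}

check_corners <- function(corners) {
  if (length(corners) != 4 || any(diff(corners) <= 0)) {
    stop_empyemapba("trapezoid corners must be 4 strictly increasing values",
                    "empyemapba_config_error")
  }
  invisible(corners)
}

#' Confounder imputation probabilities within treatment-outcome strata
#'
#' Given the sampled confounder prevalence in an arm (`p_e`), the
#' confounder-death risk ratio (`rr_cd`), and the observed death risk in
#' that arm (`pr_d_given_e`), Bayes' rule yields the probability of carrying
#' the confounder within each treatment-by-outcome cell. Writing `q_e` for
#' the implied death risk among the confounder-free,
#' `q_e = Pr(D|E=e) / (1 - p_e + rr_cd * p_e)`:
#'
#' * `Pr(C | E=e, D=1) = p_e * rr_cd / (1 - p_e + rr_cd * p_e)`
#' * `Pr(C | E=e, D=0) = p_e * (1 - rr_cd * q_e) / (1 - Pr(D|E=e))`
#'
#' Each call verifies the law of total probability — the two cell
#' probabilities recombine with the death risk to return `p_e` to 1e-10 —
#' and rejects parameter draws implying `Pr(D | C=1, E=e) > 1`.
#'
#' @param p_e Named or length-2 vector of confounder prevalences
#'   `c(unexposed =, exposed =)` (or scalars via `p1`, `p0` upstream).
#' @param rr_cd Risk ratio of the confounder on death.
#' @param pr_d_given_e Observed death risks `c(unexposed =, exposed =)`.
#' @return Tibble with columns `exposed`, `death`, `pr_c` (four rows).
#' @export
#' @examples
#' imputation_probs(c(unexposed = 0.2, exposed = 0.4), 3,
#'                  c(unexposed = 0.08, exposed = 0.1))
imputation_probs <- function(p_e, rr_cd, pr_d_given_e) {
  stopifnot(length(p_e) == 2, length(pr_d_given_e) == 2)
  if (any(p_e < 0 | p_e > 1) || any(pr_d_given_e < 0 | pr_d_given_e > 1) ||
      rr_cd <= 0) {
    stop_empyemapba("invalid probability or risk-ratio input",
                    "empyemapba_contract_error")
  }
  denom <- 1 - p_e + rr_cd * p_e
  q_e <- pr_d_given_e / denom           # death risk when C absent
  if (any(rr_cd * q_e > 1)) {
    stop_empyemapba(
      "implied Pr(D | C=1, E) exceeds 1: incompatible bias parameters",
      "empyemapba_incompatible_parameters_error"
    )
  }
  pr_c_d1 <- p_e * rr_cd / denom
  pr_c_d0 <- ifelse(pr_d_given_e < 1,
                    p_e * (1 - rr_cd * q_e) / (1 - pr_d_given_e),
                    0)
  # law of total probability self-check
  recon <- pr_c_d1 * pr_d_given_e + pr_c_d0 * (1 - pr_d_given_e)
  if (any(abs(recon - p_e) > 1e-10)) {
    stop_empyemapba("internal inconsistency reconstructing the prevalence",
                    "empyemapba_internal_error")
  }
  tibble::tibble(
    exposed = c(0L, 0L, 1L, 1L),
    death = c(0L, 1L, 0L, 1L),
    pr_c = unname(c(pr_c_d0[1], pr_c_d1[1], pr_c_d0[2], pr_c_d1[2]))
  )
}

#' Impute the unmeasured confounder record by record
#'
#' Draws an independent Bernoulli confounder indicator for each row with
#' the probability matched to the row's treatment-by-outcome cell. The
#' outcome status is the binary 90-day death indicator; a record censored
#' before day 90 contributes its last observed status (alive as last seen).
#'
#' @param rows Analysis-row tibble with `exposure` and `event_death`.
#' @param probs Output of [imputation_probs()].
#' @return Integer vector of 0/1 confounder indicators.
#' @export
impute_confounder <- function(rows, probs) {
  exposed <- as.integer(rows$exposure == "anti_pseudomonal")
  death <- as.integer(rows$event_death == 1)
  key <- paste(exposed, death)
  pr <- setNames(probs$pr_c, paste(probs$exposed, probs$death))
  p <- unname(pr[key])
  as.integer(runif(nrow(rows)) < p)
}

#' Bias-parameter grid
#'
#' The default grid pairs the confounder prevalences
#' `(p1, p0) in {(0.4, 0.1), (0.5, 0.2), (0.6, 0.3)}` (prevalence among
#' exposed always 0.3 higher than among unexposed) and crosses them with
#' confounder-death risk ratios `rr_cd in {3, 4, 5}`, giving nine cells.
#' Set `pair_prevalences = FALSE` for the full 27-cell crossing.
#'
#' @param p1,p0,rr_cd Grid values.
#' @param pair_prevalences Pair `p1` and `p0` by position instead of
#'   crossing them.
#' @return Tibble with columns `p1`, `p0`, `rr_cd`.
#' @export
pba_grid <- function(p1 = c(0.4, 0.5, 0.6), p0 = c(0.1, 0.2, 0.3),
                     rr_cd = c(3, 4, 5), pair_prevalences = TRUE) {
  if (pair_prevalences) {
    stopifnot(length(p1) == length(p0))
    prev <- tibble::tibble(p1 = p1, p0 = p0)
    grid <- tidyr::crossing(prev, rr_cd = rr_cd)
  } else {
    grid <- tidyr::crossing(p1 = p1, p0 = p0, rr_cd = rr_cd)
  }
  dplyr::arrange(grid, .data$p1, .data$p0, .data$rr_cd)
}

#' Probabilistic bias analysis for an unmeasured binary confounder
#'
#' Monte-Carlo quantification of how a binary unmeasured confounder `C`
#' could shift the weighted cause-specific hazard ratio of exposure on
#' 90-day death. For each grid cell and iteration:
#'
#' 1. sample the prevalences `p1 ~ Beta`, `p0 ~ Beta` (parameters solved so
#'    the mean is the grid value and the central 95% interval spans the grid
#'    value +/- 0.1) and the risk ratio
#'    `rr_cd ~ Trapezoidal(rr - 0.2, rr - 0.1, rr + 0.1, rr + 0.2)`;
#' 2. convert the draw into treatment-by-outcome imputation probabilities
#'    via [imputation_probs()], using the observed arm-specific death risks;
#' 3. impute `C` record by record;
#' 4. refit the propensity model with `C` added as a covariate, recompute
#'    ATE weights, and refit the weighted cause-specific Cox model for
#'    death (i.e. repeat the conventional analysis with `C` measured);
#' 5. record the bias-adjusted log hazard ratio.
#'
#' Draws incompatible with the observed death risks (implied
#' `Pr(D|C=1) > 1`) are skipped and counted; a cell with more than 20%
#' skips is flagged unreliable. Per cell, the iteration distribution is
#' summarised by its median and 2.5th/97.5th percentiles. Optionally a
#' normal draw scaled by the robust standard error can be added to each
#' iteration (`include_sampling_error = TRUE`) to propagate random error;
#' the default summarises systematic error only.
#'
#' @param rows Analysis-row (sub)cohort, complete cases.
#' @param grid Tibble of bias-parameter cells; see [pba_grid()].
#' @param iterations Monte-Carlo iterations per cell.
#' @param seed Integer seed; results are fully reproducible.
#' @param covariates Propensity covariates for the conventional model;
#'   defaults to [subgroup_covariates()].
#' @param adjust_method `"weight"` (default: `C` enters the propensity
#'   model) or `"covariate"` (`C` enters the Cox model directly).
#' @param include_sampling_error Add a random-error draw per iteration.
#' @param prior_half_width Half width of the prevalence priors.
#' @return Object of class `pba_result`: list with `cells` (per-cell
#'   summary tibble), `draws` (long tibble of per-iteration adjusted log
#'   hazard ratios), `conventional` (the unadjusted [fit_cause_specific_cox()]
#'   summary on the same rows), and `seed`.
#' @export
run_pba <- function(rows, grid = pba_grid(), iterations = 2000,
                    seed = 1L, covariates = subgroup_covariates(),
                    adjust_method = c("weight", "covariate"),
                    include_sampling_error = FALSE,
                    prior_half_width = 0.1) {
  adjust_method <- match.arg(adjust_method)
  if (iterations < 1) {
    stop_empyemapba("iterations must be >= 1", "empyemapba_config_error")
  }
  if (anyNA(rows[covariates])) {
    stop_empyemapba("rows must be complete cases on the model covariates",
                    "empyemapba_contract_error")
  }
  exposed <- rows$exposure == "anti_pseudomonal"
  pr_d <- c(unexposed = mean(rows$event_death[!exposed]),
            exposed = mean(rows$event_death[exposed]))

  conv_fit <- fit_propensity(rows, covariates)
  conv_cox <- fit_cause_specific_cox(rows, "death",
                                     weights = ate_weights(conv_fit))

  withr::with_seed(seed, {
    all_cells <- vector("list", nrow(grid))
    all_draws <- vector("list", nrow(grid))
    for (g in seq_len(nrow(grid))) {
      cell <- grid[g, ]
      ab1 <- beta_from_mean_interval(cell$p1, prior_half_width)
      ab0 <- beta_from_mean_interval(cell$p0, prior_half_width)
      corners <- cell$rr_cd + c(-0.2, -0.1, 0.1, 0.2)
      lhr <- rep(NA_real_, iterations)
      n_skipped <- 0L
      for (it in seq_len(iterations)) {
        p1_draw <- rbeta(1, ab1["alpha"], ab1["beta"])
        p0_draw <- rbeta(1, ab0["alpha"], ab0["beta"])
        rr_draw <- rtrapezoid(1, corners)
        probs <- tryCatch(
          imputation_probs(c(unexposed = p0_draw, exposed = p1_draw),
                           rr_draw, pr_d),
          empyemapba_incompatible_parameters_error = function(e) NULL
        )
        if (is.null(probs)) {
          n_skipped <- n_skipped + 1L
          next
        }
        c_imp <- impute_confounder(rows, probs)
        est <- tryCatch(
          pba_adjusted_loghr(rows, c_imp, covariates, adjust_method),
          error = function(e) NULL
        )
        if (is.null(est)) {
          n_skipped <- n_skipped + 1L
          next
        }
        if (include_sampling_error) {
          est[1] <- est[1] + rnorm(1, 0, est[2])
        }
        lhr[it] <- est[1]
      }
      lhr <- lhr[!is.na(lhr)]
      qs <- if (length(lhr) > 0) {
        stats::quantile(lhr, c(0.025, 0.5, 0.975), names = FALSE)
      } else {
        rep(NA_real_, 3)
      }
      all_cells[[g]] <- tibble::tibble(
        p1 = cell$p1, p0 = cell$p0, rr_cd = cell$rr_cd,
        iterations = iterations, n_used = length(lhr),
        n_skipped = n_skipped,
        unreliable = n_skipped > 0.2 * iterations,
        median_hr = exp(qs[2]), hr_low = exp(qs[1]), hr_high = exp(qs[3]),
        median_log_hr = qs[2]
      )
      all_draws[[g]] <- tibble::tibble(
        p1 = cell$p1, p0 = cell$p0, rr_cd = cell$rr_cd,
        log_hr = lhr
      )
    }
    structure(
      list(
        cells = dplyr::bind_rows(all_cells),
        draws = dplyr::bind_rows(all_draws),
        conventional = tidy(conv_cox),
        adjust_method = adjust_method,
        include_sampling_error = include_sampling_error,
        seed = seed
      ),
      class = "pba_result"
    )
  })
}

# One bias-adjusted estimate: the conventional weighted analysis with the
# imputed confounder treated as measured.
pba_adjusted_loghr <- function(rows, c_imp, covariates, adjust_method) {
  if (adjust_method == "weight") {
    if (length(unique(c_imp)) < 2) {
      # a constant imputed confounder cannot enter the model; it also
      # cannot confound, so fall back to the conventional fit
      fit <- fit_propensity(rows, covariates)
    } else {
      fit <- fit_propensity(rows, covariates,
                            extra_terms = cbind(confounder = c_imp))
    }
    cox <- fit_cause_specific_cox(rows, "death", weights = ate_weights(fit))
    c(cox$log_hr, cox$robust_se)
  } else {
    fit <- fit_propensity(rows, covariates)
    w <- ate_weights(fit)
    df <- tibble::tibble(time = rows$time_death, event = rows$event_death,
                         exposure = rows$exposure, confounder = c_imp,
                         .w = w)
    cox <- survival::coxph(
      survival::Surv(time, event) ~ exposure + confounder, data = df,
      weights = .w, ties = "efron", robust = TRUE,
      control = survival::coxph.control(eps = 1e-9, iter.max = 100))
    c(unname(coef(cox)[1]), sqrt(cox$var[1, 1]))
  }
}

#' @export
print.pba_result <- function(x, ...) {
  cat("Probabilistic bias analysis:", nrow(x$cells), "grid cells,",
      x$cells$iterations[1], "iterations each\n")
  print(x$cells)
  invisible(x)
}

#' @export
tidy.pba_result <- function(x, ...) x$cells

#' @export
glance.pba_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells),
    iterations = x$cells$iterations[1],
    n_unreliable = sum(x$cells$unreliable),
    conventional_hr = x$conventional$hr,
    adjust_method = x$adjust_method,
    seed = x$seed
  )
}

#' Forest plot of bias-analysis results
#'
#' Median bias-adjusted hazard ratio with 2.5th-97.5th percentile interval
#' per bias-parameter cell, with the conventional estimate as a reference
#' line.
#'
#' @param object A [run_pba()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pba_result <- function(object, ...) {
  df <- object$cells
  df$label <- sprintf("p1=%.1f p0=%.1f RR=%.0f", df$p1, df$p0, df$rr_cd)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median_hr, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$hr_low, xmax = .data$hr_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$conventional$hr,
                        linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "bias-adjusted hazard ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
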