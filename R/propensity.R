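#' Covariate sets for the propensity model
#'
#' `main_covariates()` is the full confounder list for the primary analysis:
#' age (continuous), sex, ADL dependence, low exercise tolerance,
#' immunodeficiency, prior antibiotic use within 90 days, infection source
#' (community vs hospital/nursing), abnormal mental status, blood urea
#' nitrogen category, low albumin, and oxygen use. `subgroup_covariates()`
#' drops the covariates that define the multidrug-resistance risk subgroup
#' (immunodeficiency, prior antibiotics, infection source) because the
#' subgroup propensity model incorporates all confounders *other than* the
#' MDR risk factors.
#'
#' @return Character vector of covariate column names.
#' @export
main_covariates <- function() {
  c("age", "sex", "adl_dependent", "low_exercise_tolerance",
    "immunodeficiency", "prior_antibiotics_90d", "source_hospital_nursing",
    "abnormal_mental_status", "bun_category", "low_albumin", "oxygen_use")
}

#' @rdname main_covariates
#' @export
subgroup_covariates <- function() {
  setdiff(main_covariates(),
          c("immunodeficiency", "prior_antibiotics_90d",
            "source_hospital_nursing"))
}

#' Fit the exposure propensity model
#'
#' Maximum-likelihood logistic regression of treatment on the chosen
#' covariates, with explicit checks for rank deficiency (naming the
#' offending column) and perfect separation. Convergence is declared when
#' the maximum absolute score (gradient of the binomial log-likelihood) is
#' below `tol`.
#'
#' @param rows Analysis-row tibble with an `exposure` factor; must be
#'   complete cases on `covariates` (filter on `complete_case` first).
#' @param covariates Character vector of covariate columns; defaults to
#'   [main_covariates()].
#' @param extra_terms Optional numeric matrix/data frame of additional
#'   design columns (used by the bias analysis to add the simulated
#'   confounder).
#' @param tol Score-norm convergence tolerance.
#' @param max_iter Maximum number of iterations.
#' @return An object of class `propensity_fit` with elements `model` (the
#'   underlying `glm`), `coefficients`, `scores` (fitted probabilities),
#'   `converged`, `n_iterations`, plus the data used.
#' @export
#' @examples
#' raw <- generate_cohort(cohort_config(n_total = 400, seed = 11))
#' cohort <- dplyr::filter(build_analysis_cohort(raw), complete_case)
#' fit <- fit_propensity(cohort)
#' glance(fit)
fit_propensity <- function(rows, covariates = main_covariates(),
                           extra_terms = NULL, tol = 1e-8, max_iter = 100) {
  if (anyNA(rows[covariates])) {
    stop_empyemapba(
      "rows contain missing covariates; restrict to complete cases first",
      "empyemapba_contract_error"
    )
  }
  y <- as.integer(rows$exposure == "anti_pseudomonal")
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop_empyemapba("need at least one exposed and one unexposed row",
                    "empyemapba_contract_error")
  }
  fml <- if (length(covariates) == 0) "~ 1" else
    paste("~", paste(covariates, collapse = " + "))
  x <- stats::model.matrix(as.formula(fml), data = rows)
  if (!is.null(extra_terms)) {
    extra_terms <- as.matrix(extra_terms)
    x <- cbind(x, extra_terms)
  }
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    stop_empyemapba(
      paste0("design matrix is rank deficient; collinear column(s): ",
             paste(dropped, collapse = ", ")),
      "empyemapba_collinearity_error"
    )
  }
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = binomial(),
                   control = list(epsilon = 1e-12, maxit = max_iter))
  )
  # Newton polish: glm.fit stops on a deviance criterion; drive the score
  # (log-likelihood gradient) itself below `tol`, which is scale-aware for
  # covariates like age measured in years.
  b <- fit$coefficients
  n_iter <- fit$iter
  for (k in seq_len(25)) {
    e <- drop(plogis(x %*% b))
    score <- drop(crossprod(x, y - e))
    if (max(abs(score)) < tol) break
    h <- crossprod(x, x * (e * (1 - e)))
    step <- tryCatch(solve(h, score), error = function(err) NULL)
    if (is.null(step)) break
    b <- b + step
    n_iter <- n_iter + 1L
  }
  e <- drop(plogis(x %*% b))
  fit$coefficients <- b
  eps <- 1e-10
  if (any(e < eps) || any(e > 1 - eps) || any(abs(b) > 30)) {
    stop_empyemapba(
      "fitted propensity scores numerically 0 or 1: perfect separation",
      "empyemapba_separation_error"
    )
  }
  score <- drop(crossprod(x, y - e))
  converged <- max(abs(score)) < tol
  if (!converged) {
    stop_empyemapba(
      paste0("propensity model did not reach score tolerance ",
             format(tol), " in ", max_iter, " iterations"),
      "empyemapba_convergence_error"
    )
  }
  structure(
    list(
      model = fit,
      coefficients = stats::setNames(fit$coefficients, colnames(x)),
      scores = e,
      exposed = y == 1L,
      covariates = covariates,
      design = x,
      rows = rows,
      converged = converged,
      n_iterations = n_iter,
      max_abs_score = max(abs(score)),
      log_lik = sum(y * log(e) + (1 - y) * log(1 - e))
    ),
    class = "propensity_fit"
  )
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("Propensity model (logistic):", length(x$coefficients),
      "coefficients,", sum(x$exposed), "exposed /", length(x$scores),
      "rows\n")
  invisible(x)
}

#' @export
tidy.propensity_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.propensity_fit <- function(x, ...) {
  tibble::tibble(
    n = length(x$scores), n_exposed = sum(x$exposed),
    converged = x$converged, n_iterations = x$n_iterations,
    max_abs_score = x$max_abs_score, log_lik = x$log_lik
  )
}

#' Average-treatment-effect inverse-probability weights
#'
#' `w = 1 / e` for exposed and `w = 1 / (1 - e)` for unexposed rows, where
#' `e` is the fitted propensity score. This targets the average treatment
#' effect: each arm is reweighted to resemble the full cohort. No truncation
#' is applied by default.
#'
#' @param fit A [fit_propensity()] object.
#' @param truncate_quantiles Optional length-2 vector of lower/upper score
#'   quantiles at which to truncate scores before weighting (sensitivity
#'   use only).
#' @return Numeric weight vector aligned with the rows used in the fit.
#' @export
ate_weights <- function(fit, truncate_quantiles = NULL) {
  e <- fit$scores
  if (!is.null(truncate_quantiles)) {
    qs <- stats::quantile(e, truncate_quantiles)
    e <- pmin(pmax(e, qs[1]), qs[2])
  }
  eps <- 1e-10
  if (any(e < eps) || any(e > 1 - eps)) {
    stop_empyemapba("degenerate propensity score (0 or 1); cannot weight",
                    "empyemapba_degenerate_score_error")
  }
  ifelse(fit$exposed, 1 / e, 1 / (1 - e))
}

#' Standardized mean differences before and after weighting
#'
#' For each covariate (factors expanded to indicator columns), computes the
#' standardized mean difference between the exposed and unexposed arms,
#' unweighted and weighted. Binary covariates use the proportion-based
#' pooled standard deviation `sqrt((p1(1-p1) + p0(1-p0)) / 2)`; continuous
#' covariates use the *unweighted* pooled standard deviation in both
#' columns so the two SMDs are on the same scale. A covariate with zero
#' pooled standard deviation is reported as SMD 0 with a warning.
#'
#' @param rows Analysis-row tibble.
#' @param weights Positive weight vector (e.g. [ate_weights()]).
#' @param covariates Covariate columns to balance-check.
#' @return Tibble with columns `term`, `smd_unweighted`, `smd_weighted`.
#' @export
balance_smd <- function(rows, weights, covariates = main_covariates()) {
  if (any(weights <= 0)) {
    stop_empyemapba("weights must be positive", "empyemapba_contract_error")
  }
  x <- stats::model.matrix(
    as.formula(paste("~", paste(covariates, collapse = " + "))),
    data = rows
  )[, -1, drop = FALSE]
  exposed <- rows$exposure == "anti_pseudomonal"
  binary <- apply(x, 2, function(col) all(col %in% c(0, 1)))

  wmean <- function(col, w, grp) sum(col[grp] * w[grp]) / sum(w[grp])
  one_term <- function(j) {
    col <- x[, j]
    m1 <- mean(col[exposed]); m0 <- mean(col[!exposed])
    if (binary[j]) {
      pooled <- sqrt((m1 * (1 - m1) + m0 * (1 - m0)) / 2)
    } else {
      pooled <- sqrt((var(col[exposed]) + var(col[!exposed])) / 2)
    }
    wm1 <- wmean(col, weights, exposed)
    wm0 <- wmean(col, weights, !exposed)
    if (binary[j]) {
      pooled_w <- sqrt((wm1 * (1 - wm1) + wm0 * (1 - wm0)) / 2)
    } else {
      pooled_w <- pooled
    }
    if (pooled == 0 || pooled_w == 0) {
      rlang::warn(paste0("zero pooled SD for '", colnames(x)[j],
                         "'; SMD reported as 0"))
      return(c(0, 0))
    }
    c((m1 - m0) / pooled, (wm1 - wm0) / pooled_w)
  }
  res <- t(vapply(seq_len(ncol(x)), one_term, numeric(2)))
  tibble::tibble(term = colnames(x),
                 smd_unweighted = res[, 1],
                 smd_weighted = res[, 2])
}

#' Love plot of covariate balance
#'
#' @param object A [fit_propensity()] object.
#' @param weights Weights to use; defaults to [ate_weights()] of the fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.propensity_fit <- function(object, weights = NULL, ...) {
  weights <- weights %||% ate_weights(object)
  smd <- balance_smd(object$rows, weights, object$covariates)
  long <- tidyr::pivot_longer(smd, cols = dplyr::starts_with("smd_"),
                              names_to = "stage", values_to = "smd")
  long$stage <- ifelse(long$stage == "smd_weighted", "weighted",
                       "unweighted")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = abs(.data$smd), y = .data$term,
                               colour = .data$stage)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0.1, linetype = "dashed") +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
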