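#' Weighted cause-specific Cox model with robust standard errors
#'
#' Fits the Cox proportional-hazards model for one cause (thoracic surgery
#' or death) with exposure as the sole model covariate; confounding is
#' handled by the inverse-probability weights. The partial likelihood is
#' case-weighted with Efron handling of tied event days, and the variance is
#' the subject-level sandwich estimator (inverse information x empirical
#' variation of the weighted score residuals x inverse information), which
#' treats the weights as fixed known quantities. 95% confidence intervals
#' use the normal approximation on the log hazard-ratio scale and the
#' p-value is a two-sided robust Wald test.
#'
#' @param rows Analysis-row tibble with `time_surgery`/`event_surgery` and
#'   `time_death`/`event_death` columns and an `exposure` factor.
#' @param cause `"surgery"` or `"death"`.
#' @param weights Positive case weights; default all 1 (unweighted).
#' @return An object of class `cs_cox_fit`.
#' @export
#' @examples
#' raw <- generate_cohort(cohort_config(n_total = 500, seed = 5))
#' cohort <- dplyr::filter(build_analysis_cohort(raw), complete_case)
#' w <- ate_weights(fit_propensity(cohort))
#' tidy(fit_cause_specific_cox(cohort, "death", weights = w))
fit_cause_specific_cox <- function(rows, cause = c("surgery", "death"),
                                   weights = NULL) {
  cause <- match.arg(cause)
  weights <- weights %||% rep(1, nrow(rows))
  if (length(weights) != nrow(rows) || any(weights <= 0)) {
    stop_empyemapba("weights must be positive and match rows",
                    "empyemapba_contract_error")
  }
  time <- rows[[paste0("time_", cause)]]
  event <- rows[[paste0("event_", cause)]]
  n_events <- sum(event)
  if (n_events == 0) {
    stop_empyemapba(paste0("no ", cause, " events: cannot fit a ",
                           "cause-specific hazard model"),
                    "empyemapba_no_event_error")
  }
  df <- tibble::tibble(time = time, event = event,
                       exposure = rows$exposure, .w = weights)
  fit <- survival::coxph(
    survival::Surv(time, event) ~ exposure, data = df, weights = .w,
    ties = "efron", robust = TRUE,
    control = survival::coxph.control(eps = 1e-9, iter.max = 100)
  )
  log_hr <- unname(coef(fit)[1])
  # with >1 event a huge coefficient signals a monotone partial likelihood;
  # a single-event fit is always boundary-ish and is returned flagged instead
  if (!is.finite(log_hr) || (abs(log_hr) > 15 && n_events > 1)) {
    stop_empyemapba(
      paste0("cause-specific Cox fit diverged (monotone likelihood); ",
             "consider a Firth-type penalized fit"),
      "empyemapba_divergence_error"
    )
  }
  robust_se <- sqrt(fit$var[1, 1])
  model_se <- sqrt(fit$naive.var[1, 1])
  low_information <- n_events < 5
  if (low_information) {
    rlang::warn(paste0("only ", n_events, " ", cause,
                       " event(s): low-information fit"))
  }
  structure(
    list(
      cause = cause,
      model = fit,
      log_hr = log_hr,
      hr = exp(log_hr),
      robust_se = robust_se,
      model_se = model_se,
      ci95 = exp(log_hr + c(-1, 1) * 1.96 * robust_se),
      p_value = 2 * pnorm(-abs(log_hr / robust_se)),
      n_used = nrow(rows),
      n_events = n_events,
      low_information = low_information
    ),
    class = "cs_cox_fit"
  )
}

#' @export
print.cs_cox_fit <- function(x, ...) {
  cat(sprintf(
    "Cause-specific Cox (%s): HR %.2f (95%% CI %.2f-%.2f), p = %.3f [%d events / %d rows]\n",
    x$cause, x$hr, x$ci95[1], x$ci95[2], x$p_value, x$n_events, x$n_used))
  invisible(x)
}

#' @export
tidy.cs_cox_fit <- function(x, ...) {
  tibble::tibble(
    cause = x$cause, term = "exposure",
    estimate = x$log_hr, hr = x$hr, robust_se = x$robust_se,
    conf_low = x$ci95[1], conf_high = x$ci95[2], p_value = x$p_value
  )
}

#' @export
glance.cs_cox_fit <- function(x, ...) {
  tibble::tibble(cause = x$cause, n = x$n_used, n_events = x$n_events,
                 low_information = x$low_information)
}

#' Robust sandwich standard error of a cause-specific Cox fit
#'
#' Exposes the subject-level sandwich standard error of the exposure log
#' hazard ratio: `invI %*% sum_i (w_i U_i)(w_i U_i)' %*% invI` with `U_i`
#' the per-subject score residual and weights treated as fixed. Because
#' there is one record per subject, subject and record aggregation
#' coincide. The model-based (inverse-information) standard error is
#' available for comparison as `model_se` on the fit.
#'
#' @param fit A [fit_cause_specific_cox()] object.
#' @return The robust standard error (positive scalar).
#' @export
robust_sandwich_se <- function(fit) {
  stopifnot(inherits(fit, "cs_cox_fit"))
  v <- fit$model$var[1, 1]
  if (!is.finite(v) || v <= 0) {
    stop_empyemapba("singular information: degenerate fit",
                    "empyemapba_degenerate_fit_error")
  }
  sqrt(v)
}

#' Aalen-Johansen cumulative incidence of surgery and death
#'
#' Nonparametric cumulative incidence functions for the two competing
#' events, unadjusted (this mirrors the descriptive, pre-weighting display:
#' actual probabilities a patient has for each event). At each event time
#' the cause-specific increment multiplies the overall event-free survival
#' just before that time. Pointwise 95% bands use the log(-log)
#' transformation.
#'
#' For the competing-risk decomposition the first transition out of the
#' event-free state is used: a death after surgery does not re-enter here
#' (it belongs to the cause-specific death model, not the CIF display).
#'
#' @param rows Analysis-row tibble.
#' @param by_group Split by exposure arm? Default `TRUE`.
#' @return A tibble of class `cif_estimate` with columns `group`, `time`,
#'   `state` (`"surgery"`/`"death"`/`"event_free"`), `estimate`,
#'   `conf_low`, `conf_high`.
#' @export
cumulative_incidence <- function(rows, by_group = TRUE) {
  if (nrow(rows) == 0) {
    return(structure(
      tibble::tibble(group = character(), time = numeric(),
                     state = character(), estimate = numeric(),
                     conf_low = numeric(), conf_high = numeric()),
      class = c("cif_estimate", "tbl_df", "tbl", "data.frame")
    ))
  }
  # time to first transition and its cause
  first_time <- rows$time_surgery
  cause <- dplyr::case_when(
    rows$event_surgery == 1 ~ "surgery",
    rows$event_death == 1 & rows$time_death <= first_time ~ "death",
    .default = "censor"
  )
  df <- tibble::tibble(
    time = first_time,
    status = factor(cause, levels = c("censor", "surgery", "death")),
    group = if (by_group) as.character(rows$exposure) else "all"
  )
  out <- lapply(split(df, df$group), function(d) {
    if (all(d$status == "censor")) {
      # no transitions at all: both incidences identically zero
      tm <- sort(unique(d$time))
      return(tibble::tibble(
        group = d$group[1],
        time = rep(tm, times = 3),
        state = rep(c("event_free", "surgery", "death"), each = length(tm)),
        estimate = rep(c(1, 0, 0), each = length(tm)),
        conf_low = rep(c(1, 0, 0), each = length(tm)),
        conf_high = rep(c(1, 0, 0), each = length(tm))
      ))
    }
    sf <- survival::survfit(survival::Surv(time, status) ~ 1, data = d)
    states <- sf$states
    states[states == "(s0)"] <- "event_free"
    est <- sf$pstate
    se <- sf$std.err
    # log(-log) pointwise bands on the incidence scale
    lo <- hi <- matrix(NA_real_, nrow(est), ncol(est))
    pos <- est > 0 & est < 1
    z <- 1.96
    theta <- suppressWarnings(z * se[pos] / (est[pos] * log(est[pos])))
    lo[pos] <- est[pos]^exp(theta)
    hi[pos] <- est[pos]^exp(-theta)
    lo[!pos] <- est[!pos]
    hi[!pos] <- est[!pos]
    tibble::tibble(
      group = d$group[1],
      time = rep(sf$time, times = ncol(est)),
      state = rep(states, each = length(sf$time)),
      estimate = as.vector(est),
      conf_low = as.vector(pmin(lo, hi)),
      conf_high = as.vector(pmax(lo, hi))
    )
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("cif_estimate", class(res))
  res
}

#' @export
autoplot.cif_estimate <- function(object, ...) {
  df <- dplyr::filter(object, .data$state != "event_free")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_low), linetype = "dotted") +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_high),
                       linetype = "dotted") +
    ggplot2::facet_wrap(~state) +
    ggplot2::labs(x = "days since admission", y = "cumulative incidence",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Weighted survival curves from a cause-specific Cox fit
#'
#' Per-arm survival functions implied by the weighted Cox model: the
#' baseline cumulative hazard uses the weighted Breslow increments and the
#' arm curve is `exp(-Lambda0(t))` raised to `exp(log HR x arm)`. With
#' log HR = 0 both arms coincide with the exponentiated Nelson-Aalen
#' estimate of the pooled weighted sample.
#'
#' @param fit A [fit_cause_specific_cox()] object.
#' @return Tibble with columns `group`, `time`, `estimate`, `conf_low`,
#'   `conf_high`.
#' @export
weighted_survival_curves <- function(fit) {
  stopifnot(inherits(fit, "cs_cox_fit"))
  nd <- data.frame(exposure = factor(
    c("non_anti_pseudomonal", "anti_pseudomonal"),
    levels = c("non_anti_pseudomonal", "anti_pseudomonal")))
  sf <- survival::survfit(fit$model, newdata = nd, stype = 2, ctype = 1,
                          conf.type = "log-log")
  tibble::tibble(
    group = rep(as.character(nd$exposure), each = length(sf$time)),
    time = rep(sf$time, times = 2),
    estimate = as.vector(sf$surv),
    conf_low = as.vector(sf$lower),
    conf_high = as.vector(sf$upper)
  )
}
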