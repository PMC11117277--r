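# Shared fixtures and independent oracles, all built in code.

exposure_levels <- c("non_anti_pseudomonal", "anti_pseudomonal")

as_exposure <- function(x) factor(x, levels = exposure_levels)

# Six records, times 1..6, alternating arms, all events for both causes.
six_record_fixture <- function() {
  tibble::tibble(
    patient_id = as.character(1:6),
    exposure = as_exposure(rep(c("anti_pseudomonal",
                                 "non_anti_pseudomonal"), 3)),
    time_surgery = as.numeric(1:6), event_surgery = 1L,
    time_death = as.numeric(1:6), event_death = 1L
  )
}

# Independent Newton maximizer of the binomial log-likelihood (the oracle
# for the propensity fit; no IRLS shortcut shared with the implementation).
newton_logistic_oracle <- function(x, y, tol = 1e-12, max_iter = 200) {
  b <- rep(0, ncol(x))
  for (i in seq_len(max_iter)) {
    p <- 1 / (1 + exp(-drop(x %*% b)))
    g <- drop(crossprod(x, y - p))
    if (max(abs(g)) < tol) break
    h <- crossprod(x, x * (p * (1 - p)))
    b <- b + solve(h, g)
  }
  b
}

# Brute-force grid maximizer of the (unweighted, untied) Cox partial
# log-likelihood with exposure as sole covariate.
cox_grid_oracle <- function(time, event, z, grid = seq(-5, 5, by = 1e-4)) {
  pl <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      s <- s + b * z[i] - log(sum(exp(b * z[time >= time[i]])))
    }
    s
  }
  grid[which.max(vapply(grid, pl, numeric(1)))]
}

# Minimal propensity_fit stand-in for weight arithmetic tests.
fake_ps_fit <- function(scores, exposed) {
  structure(list(scores = scores, exposed = exposed),
            class = "propensity_fit")
}

# A small analysis cohort from the generator, complete cases only.
small_cohort <- function(n = 500, seed = 11, ...) {
  raw <- generate_cohort(cohort_config(n_total = n, seed = seed, ...))
  dplyr::filter(build_analysis_cohort(raw), complete_case)
}
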