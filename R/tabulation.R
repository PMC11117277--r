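#' Chi-squared test on a 2x2 contingency table
#'
#' Pearson chi-squared on one degree of freedom with Yates continuity
#' correction (on by default; the correction term is clamped so the
#' statistic is never negative). Counts are ordered
#' (exposed-event, exposed-no-event, unexposed-event, unexposed-no-event).
#'
#' @param a,b,c,d Cell counts, or pass a 2x2 matrix as `a`.
#' @param correct Apply the Yates continuity correction (default `TRUE`).
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_squared_test(97, 174, 164, 420)
chi_squared_test <- function(a, b = NULL, c = NULL, d = NULL,
                             correct = TRUE) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    m <- a
  } else {
    m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  }
  if (any(m < 0) || sum(m) == 0) {
    stop_empyemapba("counts must be non-negative with a positive total",
                    "empyemapba_contract_error")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_empyemapba(
      "a table margin is zero: the chi-squared test is undefined; consider an exact test",
      "empyemapba_undefined_test_error"
    )
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value))
}

#' Descriptive characteristics table by exposure arm
#'
#' Frequencies with percentages for categorical variables (missing values
#' reported as their own category) and mean (SD) for age, split by exposure
#' arm with an overall column — the layout of a standard baseline
#' characteristics table. The SD of a single observation is reported blank.
#'
#' @param rows Analysis-row tibble.
#' @return Tibble with columns `variable`, `level`,
#'   `non_anti_pseudomonal`, `anti_pseudomonal`, `overall` (formatted
#'   strings) plus numeric helper columns `n_*`.
#' @export
describe_cohort <- function(rows) {
  arms <- list(
    non_anti_pseudomonal = rows[rows$exposure == "non_anti_pseudomonal", ],
    anti_pseudomonal = rows[rows$exposure == "anti_pseudomonal", ],
    overall = rows
  )
  fmt_mean_sd <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return("")
    if (length(x) == 1) return(sprintf("%.1f ()", mean(x)))
    sprintf("%.1f (%.1f)", mean(x), sd(x))
  }
  cat_row <- function(var, level_fun, label) {
    vals <- lapply(arms, function(d) {
      v <- level_fun(d)
      n <- sum(v, na.rm = TRUE)
      pct <- if (nrow(d) > 0) 100 * n / nrow(d) else 0
      list(n = n, txt = sprintf("%d (%.1f)", n, pct))
    })
    tibble::tibble(
      variable = var, level = label,
      non_anti_pseudomonal = vals$non_anti_pseudomonal$txt,
      anti_pseudomonal = vals$anti_pseudomonal$txt,
      overall = vals$overall$txt,
      n_non_anti_pseudomonal = vals$non_anti_pseudomonal$n,
      n_anti_pseudomonal = vals$anti_pseudomonal$n,
      n_overall = vals$overall$n
    )
  }
  cat_block <- function(var, column) {
    lv <- levels(factor(rows[[column]]))
    out <- lapply(lv, function(l) {
      cat_row(var, function(d) !is.na(d[[column]]) & d[[column]] == l, l)
    })
    miss <- if (anyNA(rows[[column]])) {
      list(cat_row(var, function(d) is.na(d[[column]]), "Missing"))
    } else NULL
    dplyr::bind_rows(c(out, miss))
  }
  logical_row <- function(var, column) {
    out <- cat_row(var, function(d) !is.na(d[[column]]) & d[[column]], "Yes")
    miss <- if (anyNA(rows[[column]])) {
      cat_row(var, function(d) is.na(d[[column]]), "Missing")
    } else NULL
    dplyr::bind_rows(out, miss)
  }
  age_row <- tibble::tibble(
    variable = "Age, mean (SD)", level = "",
    non_anti_pseudomonal = fmt_mean_sd(arms$non_anti_pseudomonal$age),
    anti_pseudomonal = fmt_mean_sd(arms$anti_pseudomonal$age),
    overall = fmt_mean_sd(arms$overall$age),
    n_non_anti_pseudomonal = nrow(arms$non_anti_pseudomonal),
    n_anti_pseudomonal = nrow(arms$anti_pseudomonal),
    n_overall = nrow(arms$overall)
  )
  dplyr::bind_rows(
    age_row,
    cat_row("Male", function(d) !is.na(d$sex) & d$sex == "male", "Yes"),
    cat_block("Source of infection",
              "source_hospital_nursing") |>
      dplyr::mutate(level = dplyr::recode(.data$level,
                                          "FALSE" = "Community-acquired",
                                          "TRUE" = "Hospital/nursing-acquired")),
    logical_row("ADL dependent (Barthel < 50)", "adl_dependent"),
    logical_row("Low exercise tolerance", "low_exercise_tolerance"),
    logical_row("Abnormal mental status", "abnormal_mental_status"),
    logical_row("Immunodeficiency", "immunodeficiency"),
    logical_row("Prior antibiotics (90 d)", "prior_antibiotics_90d"),
    logical_row("Dialysis", "dialysis"),
    cat_block("Blood urea nitrogen (mg/dL)", "bun_category"),
    logical_row("Low albumin (<= 2.7 g/dL)", "low_albumin"),
    logical_row("Oxygen use on admission", "oxygen_use")
  )
}

#' Per-agent frequency of day-0/1 empirical antibiotics
#'
#' Counts each antibiotic agent administered intravenously on day 0 or 1,
#' split into anti-pseudomonal and non-anti-pseudomonal sections. A patient
#' contributes once to every distinct agent received, so percentages within
#' a section (denominated by the classified arm size) can exceed 100% in
#' total. Drug codes missing from the dictionary are logged and bucketed
#' under "Other antibiotics".
#'
#' @param records Raw-record tibble restricted to eligible rows.
#' @param dict Drug dictionary.
#' @return Tibble with columns `class`, `name`, `n`, `pct`.
#' @export
antibiotic_frequency_table <- function(records, dict = drug_dictionary()) {
  exposure <- classify_exposure(records, dict)
  arm_n <- table(exposure)
  events <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    ev <- parse_events(records$drug_events[i])
    ev <- ev[ev$day %in% c(0L, 1L), , drop = FALSE]
    if (nrow(ev) == 0) return(NULL)
    ev$class <- classify_drug_codes(ev$code, dict)
    ev <- ev[ev$class %in% c("anti_pseudomonal", "non_anti_pseudomonal"), ]
    if (nrow(ev) == 0) return(NULL)
    unknown <- !ev$code %in% dict$code
    name <- dict$name[match(ev$code, dict$code)]
    name[unknown] <- "Other antibiotics"
    dplyr::distinct(tibble::tibble(class = ev$class, name = name))
  })
  counts <- dplyr::count(events, .data$class, .data$name, name = "n")
  counts$pct <- 100 * counts$n / ifelse(
    counts$class == "anti_pseudomonal",
    arm_n[["anti_pseudomonal"]], arm_n[["non_anti_pseudomonal"]])
  dplyr::arrange(counts, .data$class, dplyr::desc(.data$n))
}
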