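#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join if_else n across count rename pull
#' @importFrom stats plogis qlogis rbinom rexp rnorm runif qbeta rbeta glm
#'   binomial coef vcov pchisq pnorm qnorm quantile median sd var as.formula
#'   model.matrix complete.cases setNames integrate
NULL

# Internal: stop with a classed condition so callers can test error contracts.
stop_empyemapba <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "empyemapba_error"), ...)
}

is_scalar_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

is_scalar_pos <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0
}

`%||%` <- rlang::`%||%`
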