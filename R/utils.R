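#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows bind_cols left_join n across all_of desc row_number
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats plogis qlogis rnorm rbinom rexp uniroot fisher.test
#'   t.test chisq.test aov lm glm binomial coef vcov predict anova pchisq
#'   complete.cases quantile sd median qnorm setNames na.omit model.matrix
#'   fitted
#' @importFrom utils head modifyList
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

ENDPOINTS <- c("continuous", "binary", "survival")

check_endpoint <- function(endpoint) {
  endpoint <- match.arg(endpoint, ENDPOINTS)
  endpoint
}

#' Numerically stable log(1 + exp(v))
#' @noRd
log1pexp <- function(v) {
  out <- numeric(length(v))
  big <- v > 0
  out[big] <- v[big] + log1p(exp(-v[big]))
  out[!big] <- log1p(exp(v[!big]))
  out
}

sigmoid <- function(v) plogis(v)

#' Dense rank by descending value
#' @noRd
dense_rank_desc <- function(x) match(x, sort(unique(x), decreasing = TRUE))

stop_not_trial <- function(x, arg = "data") {
  if (!inherits(x, "trial_data")) {
    abort(sprintf("`%s` must be a <trial_data> object; see `trial_data()`.", arg))
  }
  invisible(x)
}
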