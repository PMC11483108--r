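#' ROC curve of a biomarker against a binary outcome
#'
#' Sweeps every distinct biomarker value as a threshold and returns the
#' (FPR, TPR) step curve from (0, 0) to (1, 1) with the trapezoidal AUC.
#' `direction = "greater"` treats larger biomarker values as more
#' outcome-positive; `"auto"` picks the orientation whose AUC is at least
#' 0.5. Tied biomarker values are collapsed into a single diagonal segment,
#' which makes the trapezoidal AUC equal to the Mann-Whitney U statistic
#' with ties counted 1/2.
#'
#' @param data A data frame or `trial_data` object.
#' @param biomarker Numeric biomarker column.
#' @param outcome Binary outcome column in {0, 1}.
#' @param direction `"auto"`, `"greater"`, or `"less"`.
#' @return A `roc_result` object: `points` (tibble with `threshold`, `fpr`,
#'   `tpr`), `auc`, `direction`, `n_pos`, `n_neg`, `n_dropped`.
#' @export
roc_curve <- function(data, biomarker, outcome = "y",
                      direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  if (inherits(data, "trial_data")) {
    td <- data; data <- td$data
    if (missing(outcome) && !is.null(td$outcome)) outcome <- td$outcome
  }
  data <- as_tibble(data)
  keep <- complete.cases(data[, c(biomarker, outcome), drop = FALSE])
  x <- data[[biomarker]][keep]
  y <- data[[outcome]][keep]
  if (!all(y %in% c(0, 1))) abort("`outcome` must be coded 0/1.")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) abort("Both outcome classes must be present.")

  build <- function(score) {
    ord <- order(score, decreasing = TRUE)
    s <- score[ord]; yy <- y[ord]
    grp_end <- !duplicated(s, fromLast = TRUE) # collapse tied scores
    tp <- cumsum(yy == 1)[grp_end]
    fp <- cumsum(yy == 0)[grp_end]
    points <- tibble(threshold = s[grp_end],
                     fpr = fp / n_neg, tpr = tp / n_pos)
    points <- bind_rows(tibble(threshold = Inf, fpr = 0, tpr = 0), points)
    auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
    list(points = points, auc = auc)
  }
  res_g <- build(x)
  if (direction == "auto") {
    direction <- if (res_g$auc >= 0.5) "greater" else "less"
  }
  res <- if (direction == "greater") res_g else build(-x)
  if (identical(direction, "less")) res$points$threshold <- -res$points$threshold
  structure(list(points = res$points, auc = res$auc, direction = direction,
                 n_pos = n_pos, n_neg = n_neg, n_dropped = sum(!keep)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (direction '%s'; %d positive, %d negative)\n",
              x$auc, x$direction, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$points

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, direction = x$direction, n_pos = x$n_pos,
         n_neg = x$n_neg)
}

#' Empirical CDF of a biomarker, optionally by group
#'
#' Right-continuous empirical distribution function per group, plus — for
#' any queried cutoffs — the fraction of patients at or below and strictly
#' above each cutoff (the two fractions sum to one exactly).
#'
#' @inheritParams roc_curve
#' @param by Optional grouping column; empty groups are dropped with a
#'   notice.
#' @param cutoffs Optional numeric cutoffs to query.
#' @return An `ecdf_result`: `points` tibble (`group`, `value`, `ecdf`) and,
#'   when `cutoffs` is given, a `cutoff_fractions` tibble.
#' @export
ecdf_curve <- function(data, biomarker, by = NULL, cutoffs = NULL) {
  if (inherits(data, "trial_data")) data <- data$data
  data <- as_tibble(data)
  x_all <- data[[biomarker]]
  g_all <- if (is.null(by)) rep("all", nrow(data)) else as.character(data[[by]])
  keep <- !is.na(x_all) & !is.na(g_all)
  x_all <- x_all[keep]; g_all <- g_all[keep]
  if (!length(x_all)) abort("No finite biomarker values.")

  pieces <- lapply(split(x_all, g_all), function(x) {
    xs <- sort(unique(x))
    tibble(value = xs, ecdf = stats::ecdf(x)(xs))
  })
  points <- bind_rows(pieces, .id = "group")
  fractions <- NULL
  if (!is.null(cutoffs)) {
    fractions <- bind_rows(lapply(split(x_all, g_all), function(x) {
      bind_rows(lapply(cutoffs, function(cut) {
        tibble(cutoff = cut, frac_at_or_below = mean(x <= cut),
               frac_above = mean(x > cut))
      }))
    }), .id = "group")
  }
  structure(list(points = points, cutoff_fractions = fractions,
                 biomarker = biomarker, n = length(x_all)),
            class = "ecdf_result")
}

#' @export
tidy.ecdf_result <- function(x, ...) x$points

#' @export
print.ecdf_result <- function(x, ...) {
  cat(sprintf("<ecdf_result> '%s', %d values, %d group(s)\n", x$biomarker,
              x$n, length(unique(x$points$group))))
  if (!is.null(x$cutoff_fractions)) print(x$cutoff_fractions)
  invisible(x)
}

# Fit a penalized cubic-regression-spline smooth of a working response on a
# biomarker; returns the mgcv fit and the effective k used.
fit_spline <- function(x, resp, k, family = stats::gaussian()) {
  n_distinct <- length(unique(x))
  if (k > n_distinct) {
    warn(sprintf("Basis dimension k = %d exceeds the %d distinct biomarker values; reduced.",
                 k, n_distinct))
    k <- max(3, n_distinct - 1)
  }
  df <- data.frame(.x = x, .resp = resp)
  fit <- mgcv::gam(.resp ~ s(.x, k = k, bs = "cr"), data = df, family = family,
                   method = "GCV.Cp")
  list(fit = fit, k = k)
}

# Endpoint-specific working response + family on the link scale; survival
# uses martingale residuals from a null Cox model (the standard
# functional-form diagnostic).
smooth_response <- function(d, endpoint, outcome, time, event) {
  if (endpoint == "continuous") {
    list(resp = d[[outcome]], family = stats::gaussian(), scale = "identity")
  } else if (endpoint == "binary") {
    list(resp = d[[outcome]], family = binomial(), scale = "logit")
  } else {
    null_fit <- survival::coxph(survival::Surv(d[[time]], d[[event]]) ~ 1)
    list(resp = stats::residuals(null_fit, type = "martingale"),
         family = stats::gaussian(), scale = "martingale")
  }
}

#' Smoothed biomarker-outcome curve
#'
#' Penalized cubic-regression-spline smooth of the outcome on a biomarker on
#' the endpoint's natural link scale (identity / logit / martingale
#' residuals of a null Cox model for survival), with a pointwise 95% band,
#' evaluated on a regular grid over the biomarker range.
#'
#' @inheritParams roc_curve
#' @param endpoint Endpoint kind.
#' @param time,event Survival columns.
#' @param k Spline basis dimension (reduced with a warning when the distinct
#'   value support is smaller).
#' @param grid_n Number of grid points.
#' @param trim_outliers If `TRUE`, the grid spans the 1st-99th percentile of
#'   the biomarker instead of the full range.
#' @return A `smooth_contrast` object: `grid` tibble (`x`, `fit`, `lower`,
#'   `upper`), `k`, `scale`, and the observed (`x`, `resp`) points.
#' @export
smooth_outcome_curve <- function(data, biomarker, endpoint = "continuous",
                                 outcome = "y", time = NULL, event = NULL,
                                 k = 10, grid_n = 100, trim_outliers = FALSE) {
  endpoint <- check_endpoint(endpoint)
  if (inherits(data, "trial_data")) {
    td <- data; data <- td$data
    if (missing(outcome) && !is.null(td$outcome)) outcome <- td$outcome
    if (is.null(time)) time <- td$time
    if (is.null(event)) event <- td$event
  }
  data <- as_tibble(data)
  ycols <- if (endpoint == "survival") c(time, event) else outcome
  keep <- complete.cases(data[, c(biomarker, ycols), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  x <- d[[biomarker]]
  sr <- smooth_response(d, endpoint, outcome, time, event)
  fk <- fit_spline(x, sr$resp, k, sr$family)
  grid_x <- grid_over(x, grid_n, trim_outliers)
  pr <- predict(fk$fit, newdata = data.frame(.x = grid_x), type = "link",
                se.fit = TRUE)
  grid <- tibble(x = grid_x, fit = as.numeric(pr$fit),
                 lower = as.numeric(pr$fit - qnorm(0.975) * pr$se.fit),
                 upper = as.numeric(pr$fit + qnorm(0.975) * pr$se.fit))
  structure(list(grid = grid, k = fk$k, scale = sr$scale,
                 points = tibble(x = x, resp = sr$resp),
                 biomarker = biomarker, kind = "outcome"),
            class = "smooth_contrast")
}

grid_over <- function(x, grid_n, trim_outliers) {
  rng <- if (trim_outliers) quantile(x, c(0.01, 0.99), names = FALSE) else
    range(x)
  seq(rng[1], rng[2], length.out = grid_n)
}

#' Smoothed treatment-contrast curve over a biomarker
#'
#' Fits the outcome smooth of [smooth_outcome_curve()] separately within
#' each arm and returns the treatment-minus-control difference on the link
#' scale, with a pointwise 95% band combining both arms' standard errors. A
#' flat contrast at zero indicates the biomarker is not predictive. Optional
#' covariates enter each arm's model as additive linear terms.
#'
#' @inheritParams smooth_outcome_curve
#' @param trt Treatment column coded `+1` / `-1` (`trial_data` inputs use
#'   `.trt`).
#' @param adjust_covariates Optional additive linear adjusters.
#' @return A `smooth_contrast` object whose `grid` has the contrast `fit`
#'   with `lower`/`upper`, plus per-arm curves `fit_treatment`,
#'   `fit_control`.
#' @export
smooth_treatment_contrast <- function(data, biomarker, trt = ".trt",
                                      endpoint = "continuous", outcome = "y",
                                      time = NULL, event = NULL, k = 5,
                                      grid_n = 100, trim_outliers = FALSE,
                                      adjust_covariates = NULL) {
  endpoint <- check_endpoint(endpoint)
  if (inherits(data, "trial_data")) {
    td <- data; data <- td$data
    if (missing(outcome) && !is.null(td$outcome)) outcome <- td$outcome
    if (is.null(time)) time <- td$time
    if (is.null(event)) event <- td$event
    trt <- ".trt"
  }
  data <- as_tibble(data)
  if (!all(data[[trt]] %in% c(-1, 1))) abort("`trt` must be coded +1 / -1.")
  ycols <- if (endpoint == "survival") c(time, event) else outcome
  keep <- complete.cases(data[, c(biomarker, trt, ycols, adjust_covariates),
                              drop = FALSE])
  d <- data[keep, , drop = FALSE]
  if (length(unique(d[[trt]])) < 2) abort("Both arms must be present.")
  grid_x <- grid_over(d[[biomarker]], grid_n, trim_outliers)

  arm_fit <- function(di) {
    sr <- smooth_response(di, endpoint, outcome, time, event)
    x <- di[[biomarker]]
    n_distinct <- length(unique(x))
    kk <- k
    if (kk > n_distinct) {
      warn(sprintf("k = %d exceeds %d distinct values in an arm; reduced.",
                   kk, n_distinct))
      kk <- max(3, n_distinct - 1)
    }
    df <- data.frame(.x = x, .resp = sr$resp)
    rhs <- c(sprintf("s(.x, k = %d, bs = 'cr')", kk), adjust_covariates)
    if (!is.null(adjust_covariates)) {
      df <- cbind(df, di[, adjust_covariates, drop = FALSE])
    }
    fit <- mgcv::gam(stats::as.formula(paste(".resp ~", paste(rhs, collapse = " + "))),
                     data = df, family = sr$family, method = "GCV.Cp")
    nd <- data.frame(.x = grid_x)
    if (!is.null(adjust_covariates)) {
      for (v in adjust_covariates) nd[[v]] <- mean(di[[v]])
    }
    pr <- predict(fit, newdata = nd, type = "link", se.fit = TRUE)
    list(fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
         scale = sr$scale, k = kk)
  }
  ft <- arm_fit(d[d[[trt]] == 1, , drop = FALSE])
  fc <- arm_fit(d[d[[trt]] == -1, , drop = FALSE])
  se <- sqrt(ft$se^2 + fc$se^2)
  contrast <- ft$fit - fc$fit
  grid <- tibble(x = grid_x, fit = contrast,
                 lower = contrast - qnorm(0.975) * se,
                 upper = contrast + qnorm(0.975) * se,
                 fit_treatment = ft$fit, fit_control = fc$fit)
  structure(list(grid = grid, k = min(ft$k, fc$k), scale = ft$scale,
                 biomarker = biomarker, kind = "treatment_contrast"),
            class = "smooth_contrast")
}

#' @export
print.smooth_contrast <- function(x, ...) {
  cat(sprintf("<smooth_contrast> %s curve for '%s' on the %s scale (k = %d, %d grid points)\n",
              x$kind, x$biomarker, x$scale, x$k, nrow(x$grid)))
  invisible(x)
}

#' @export
tidy.smooth_contrast <- function(x, ...) x$grid
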