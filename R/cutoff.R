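#' Evaluate candidate biomarker cutoffs
#'
#' Dichotomizes a numeric biomarker at each candidate cutoff
#' ("biomarker-positive" strictly meets the direction: `x > c` for
#' `"greater"`, `x < c` for `"less"`; values equal to the cutoff are
#' negative under `"greater"`) and computes classification/association
#' metrics against the outcome. The selected cutoff maximizes the Youden
#' index or kappa, or minimizes the association p-value, per `method`; ties
#' are broken toward the cutoff with the larger biomarker-positive group.
#'
#' Methods by endpoint: `"fisher"`, `"youden"`, `"kappa"` for binary
#' outcomes; `"two_sample"` (Welch t-test) for continuous; `"logrank"` for
#' survival. Rows with a missing biomarker or outcome value are dropped and
#' counted. No multiplicity adjustment is applied across candidates; the
#' number of candidates is reported.
#'
#' @param data A data frame or [trial_data()] object.
#' @param biomarker Numeric biomarker column name.
#' @param cutoffs Numeric vector of candidate cutoffs.
#' @param direction `"greater"` or `"less"`: the biomarker-positive side.
#' @param method Selection metric (see above).
#' @param outcome Outcome column (binary/continuous methods).
#' @param time,event Survival columns (`method = "logrank"`).
#' @return A `cutoff_result` object: `metrics` (one tibble row per
#'   candidate), `selected`, `method`, `direction`, `n_used`, `n_dropped`,
#'   `n_candidates`.
#' @export
evaluate_cutoffs <- function(data, biomarker, cutoffs,
                             direction = c("greater", "less"),
                             method = c("fisher", "youden", "kappa",
                                        "two_sample", "logrank"),
                             outcome = "y", time = NULL, event = NULL) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  if (inherits(data, "trial_data")) {
    td <- data
    data <- td$data
    if (missing(outcome) && !is.null(td$outcome)) outcome <- td$outcome
    if (is.null(time)) time <- td$time
    if (is.null(event)) event <- td$event
  }
  data <- as_tibble(data)
  if (!length(cutoffs) || any(!is.finite(cutoffs))) {
    abort("Supply at least one finite cutoff.")
  }
  if (!is.numeric(data[[biomarker]])) abort("`biomarker` must be numeric.")

  ycols <- if (method == "logrank") c(time, event) else outcome
  keep <- complete.cases(data[, c(biomarker, ycols), drop = FALSE])
  n_dropped <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  x <- d[[biomarker]]
  if (any(cutoffs >= max(x) | cutoffs <= min(x)) &&
      !all(cutoffs < max(x) & cutoffs > min(x))) {
    warn("Some cutoffs fall at or outside the observed biomarker range; their metrics may be degenerate.")
  }

  rows <- lapply(cutoffs, function(cut) {
    pos <- if (direction == "greater") x > cut else x < cut
    res <- tibble(cutoff = cut, n_positive = sum(pos), n_negative = sum(!pos))
    if (method %in% c("fisher", "youden", "kappa")) {
      yv <- d[[outcome]]
      if (!all(yv %in% c(0, 1))) abort("Binary methods need an outcome in {0, 1}.")
      cbind(res, binary_cut_metrics(pos, yv))
    } else if (method == "two_sample") {
      yv <- d[[outcome]]
      cbind(res, continuous_cut_metrics(pos, yv))
    } else {
      cbind(res, survival_cut_metrics(pos, d[[time]], d[[event]]))
    }
  })
  metrics <- as_tibble(bind_rows(rows))
  selected <- select_cutoff(metrics, method)
  structure(list(metrics = metrics, selected = selected, method = method,
                 direction = direction, biomarker = biomarker,
                 n_used = nrow(d), n_dropped = n_dropped,
                 n_candidates = length(cutoffs)),
            class = "cutoff_result")
}

binary_cut_metrics <- function(pos, y) {
  tp <- sum(pos & y == 1); fn <- sum(!pos & y == 1)
  fp <- sum(pos & y == 0); tn <- sum(!pos & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  n <- tp + fn + fp + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (abs(1 - pe) < 1e-15) NA_real_ else (po - pe) / (1 - pe)
  degenerate <- (tp + fp == 0) || (tn + fn == 0)
  p <- fisher.test(matrix(c(tp, fp, fn, tn), 2))$p.value
  or <- if (fn * fp > 0) (tp * tn) / (fn * fp) else NA_real_
  tibble(tp = tp, fn = fn, fp = fp, tn = tn,
         sensitivity = if (degenerate) NA_real_ else sens,
         specificity = if (degenerate) NA_real_ else spec,
         youden = if (degenerate) NA_real_ else sens + spec - 1,
         kappa = if (degenerate) NA_real_ else kappa,
         ppv = ppv, npv = npv, odds_ratio = or, p_value = p,
         note = if (degenerate) "all patients on one side of the cutoff" else NA_character_)
}

continuous_cut_metrics <- function(pos, y) {
  if (sum(pos) < 2 || sum(!pos) < 2) {
    return(tibble(mean_positive = mean(y[pos]), mean_negative = mean(y[!pos]),
                  mean_difference = NA_real_, p_value = NA_real_,
                  note = "a group has fewer than 2 patients"))
  }
  tt <- t.test(y[pos], y[!pos])
  tibble(mean_positive = mean(y[pos]), mean_negative = mean(y[!pos]),
         mean_difference = mean(y[pos]) - mean(y[!pos]),
         p_value = tt$p.value, note = NA_character_)
}

survival_cut_metrics <- function(pos, time, event) {
  if (sum(pos) == 0 || sum(!pos) == 0 || sum(event) == 0) {
    return(tibble(events_positive = sum(event[pos]),
                  events_negative = sum(event[!pos]),
                  hazard_ratio = NA_real_, p_value = NA_real_,
                  note = "degenerate grouping or no events"))
  }
  grp <- factor(ifelse(pos, "positive", "negative"),
                levels = c("negative", "positive"))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  p <- pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(survival::Surv(time, event) ~ grp)
  tibble(events_positive = sum(event[pos]), events_negative = sum(event[!pos]),
         hazard_ratio = unname(exp(coef(cx)[1])), p_value = p,
         note = NA_character_)
}

select_cutoff <- function(metrics, method) {
  key <- switch(method, youden = "youden", kappa = "kappa", "p_value")
  val <- metrics[[key]]
  if (all(is.na(val))) return(NA_real_)
  score <- if (key == "p_value") -val else val
  best <- which(!is.na(score) & score == max(score, na.rm = TRUE))
  if (length(best) > 1) {
    # ties broken toward the larger biomarker-positive group (enrichment)
    best <- best[which.max(metrics$n_positive[best])]
  }
  metrics$cutoff[best[1]]
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff_result> biomarker '%s', %d candidate(s), method '%s' (%s)\n",
              x$biomarker, x$n_candidates, x$method, x$direction))
  cat(sprintf("  selected cutoff: %s; %d rows used, %d dropped (missing values)\n",
              format(x$selected), x$n_used, x$n_dropped))
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.cutoff_result <- function(x, ...) x$metrics

#' Performance at a fixed biomarker cutoff
#'
#' Summarizes the endpoint by biomarker-positive / biomarker-negative group
#' at one cutoff and tests the between-group difference: Welch t-test (or a
#' covariate-adjusted linear model) for continuous outcomes; Fisher exact
#' test plus the response-rate difference for binary; log-rank test,
#' Kaplan-Meier medians with 95% CI, and a Cox hazard ratio for survival.
#'
#' @inheritParams evaluate_cutoffs
#' @param cutoff A single finite cutoff.
#' @param endpoint Endpoint kind.
#' @param adjust_covariates Optional covariate columns for regression
#'   adjustment of the continuous comparison.
#' @return A `cutoff_performance` object: `groups` (per-group summary
#'   tibble), `test` (one-row tibble), plus bookkeeping fields.
#' @export
cutoff_performance <- function(data, biomarker, cutoff,
                               direction = c("greater", "less"),
                               endpoint = "continuous", outcome = "y",
                               time = NULL, event = NULL,
                               adjust_covariates = NULL) {
  direction <- match.arg(direction)
  endpoint <- check_endpoint(endpoint)
  if (inherits(data, "trial_data")) {
    td <- data; data <- td$data
    if (missing(outcome) && !is.null(td$outcome)) outcome <- td$outcome
    if (is.null(time)) time <- td$time
    if (is.null(event)) event <- td$event
  }
  data <- as_tibble(data)
  if (length(cutoff) != 1 || !is.finite(cutoff)) abort("`cutoff` must be a single finite number.")
  ycols <- if (endpoint == "survival") c(time, event) else outcome
  keep <- complete.cases(data[, c(biomarker, ycols, adjust_covariates), drop = FALSE])
  n_dropped <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  x <- d[[biomarker]]
  pos <- if (direction == "greater") x > cutoff else x < cutoff
  d$.group <- factor(ifelse(pos, "biomarker_positive", "biomarker_negative"),
                     levels = c("biomarker_negative", "biomarker_positive"))

  groups <- endpoint_group_summary(d, ".group", endpoint, outcome, time, event)
  if (any(groups$n == 0)) {
    test <- tibble(test = NA_character_, statistic = NA_real_,
                   p_value = NA_real_, note = "empty group: no comparison")
  } else {
    test <- two_group_test(d, ".group", endpoint, outcome, time, event,
                           adjust_covariates)
  }
  structure(list(groups = groups, test = test, cutoff = cutoff,
                 direction = direction, biomarker = biomarker,
                 endpoint = endpoint, n_used = nrow(d), n_dropped = n_dropped),
            class = "cutoff_performance")
}

# Per-group endpoint summaries shared with subgroup_performance.
endpoint_group_summary <- function(d, group_col, endpoint, outcome, time, event) {
  gcol <- d[[group_col]]
  lv <- if (is.factor(gcol)) levels(gcol) else levels(factor(gcol))
  rows <- lapply(lv, function(g) {
    di <- d[d[[group_col]] == g, , drop = FALSE]
    base <- tibble(group = g, n = nrow(di))
    if (nrow(di) == 0) return(base)
    if (endpoint == "continuous") {
      y <- di[[outcome]]
      bind_cols(base, tibble(mean = mean(y), sd = sd(y), median = median(y)))
    } else if (endpoint == "binary") {
      y <- di[[outcome]]
      bind_cols(base, tibble(responders = sum(y == 1), rate = mean(y == 1)))
    } else {
      km <- survival::survfit(survival::Surv(di[[time]], di[[event]]) ~ 1,
                              conf.type = "log-log")
      q <- stats::quantile(km, probs = 0.5)
      med <- unname(q$quantile)
      bind_cols(base, tibble(events = sum(di[[event]]),
                             km_median = med,
                             km_median_lower = unname(q$lower),
                             km_median_upper = unname(q$upper),
                             median_reached = !is.na(med)))
    }
  })
  bind_rows(rows)
}

two_group_test <- function(d, group_col, endpoint, outcome, time, event,
                           adjust_covariates = NULL) {
  g <- factor(d[[group_col]])
  if (endpoint == "continuous") {
    if (is.null(adjust_covariates)) {
      tt <- t.test(d[[outcome]] ~ g)
      tibble(test = "welch_t", statistic = unname(tt$statistic),
             estimate = -diff(tt$estimate), p_value = tt$p.value,
             note = NA_character_)
    } else {
      fml <- stats::reformulate(c(group_col, adjust_covariates), response = outcome)
      fit <- lm(fml, data = d)
      co <- summary(fit)$coefficients
      term <- grep(paste0("^", group_col), rownames(co), value = TRUE)[1]
      tibble(test = "adjusted_lm", statistic = co[term, "t value"],
             estimate = co[term, "Estimate"], p_value = co[term, "Pr(>|t|)"],
             note = NA_character_)
    }
  } else if (endpoint == "binary") {
    tab <- table(g, factor(d[[outcome]], levels = c(0, 1)))
    ft <- fisher.test(tab)
    rates <- tapply(d[[outcome]], g, mean)
    tibble(test = "fisher_exact", statistic = NA_real_,
           estimate = unname(rates[2] - rates[1]), p_value = ft$p.value,
           note = "estimate is the rate difference (level 2 - level 1)")
  } else {
    if (sum(d[[event]]) == 0) {
      return(tibble(test = "logrank", statistic = NA_real_,
                    estimate = NA_real_, p_value = NA_real_,
                    note = "all patients censored: no test"))
    }
    sd_ <- survival::survdiff(survival::Surv(d[[time]], d[[event]]) ~ g)
    cx <- survival::coxph(survival::Surv(d[[time]], d[[event]]) ~ g)
    tibble(test = "logrank", statistic = sd_$chisq,
           estimate = unname(exp(coef(cx)[1])),
           p_value = pchisq(sd_$chisq, df = length(sd_$n) - 1, lower.tail = FALSE),
           note = "estimate is the hazard ratio (level 2 vs level 1)")
  }
}

#' @export
print.cutoff_performance <- function(x, ...) {
  cat(sprintf("<cutoff_performance> '%s' %s %s, %s endpoint (%d used, %d dropped)\n",
              x$biomarker, if (x$direction == "greater") ">" else "<",
              format(x$cutoff), x$endpoint, x$n_used, x$n_dropped))
  print(x$groups)
  print(x$test)
  invisible(x)
}

#' @export
tidy.cutoff_performance <- function(x, ...) x$groups
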