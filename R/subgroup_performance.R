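#' Per-group endpoint summaries with a global across-group test
#'
#' Summarizes the endpoint within each level of a grouping variable and, for
#' two or more groups, tests across groups: one-way ANOVA (continuous),
#' chi-square — or Fisher exact when any expected cell count falls below 5 —
#' (binary), or the log-rank test (survival).
#'
#' @param data A data frame or [trial_data()] object.
#' @param group Grouping column name (labels per patient).
#' @param endpoint Endpoint kind.
#' @param outcome,time,event Outcome column names per endpoint.
#' @return A `subgroup_summary` object: `groups` tibble and a one-row `test`
#'   tibble (test `NA` with a notice when only one group is present).
#' @export
subgroup_summary <- function(data, group, endpoint = "continuous",
                             outcome = "y", time = NULL, event = NULL) {
  endpoint <- check_endpoint(endpoint)
  if (inherits(data, "trial_data")) {
    td <- data; data <- td$data
    if (missing(outcome) && !is.null(td$outcome)) outcome <- td$outcome
    if (is.null(time)) time <- td$time
    if (is.null(event)) event <- td$event
  }
  data <- as_tibble(data)
  ycols <- if (endpoint == "survival") c(time, event) else outcome
  keep <- complete.cases(data[, c(group, ycols), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  d[[group]] <- factor(d[[group]])
  groups <- endpoint_group_summary(d, group, endpoint, outcome, time, event)

  if (nlevels(d[[group]]) < 2) {
    inform("Only one group present: no across-group test performed.")
    test <- tibble(test = NA_character_, statistic = NA_real_,
                   p_value = NA_real_, note = "single group")
  } else {
    test <- across_group_test(d, group, endpoint, outcome, time, event)
  }
  structure(list(groups = groups, test = test, group = group,
                 endpoint = endpoint, n_used = nrow(d),
                 n_dropped = sum(!keep)),
            class = "subgroup_summary")
}

across_group_test <- function(d, group, endpoint, outcome, time, event) {
  g <- d[[group]]
  if (endpoint == "continuous") {
    fit <- aov(d[[outcome]] ~ g)
    sm <- summary(fit)[[1]]
    tibble(test = "anova_F", statistic = sm[["F value"]][1],
           p_value = sm[["Pr(>F)"]][1], note = NA_character_)
  } else if (endpoint == "binary") {
    tab <- table(g, factor(d[[outcome]], levels = c(0, 1)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- fisher.test(tab)
      tibble(test = "fisher_exact", statistic = NA_real_,
             p_value = ft$p.value, note = "expected count < 5")
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      tibble(test = "chi_square", statistic = unname(ct$statistic),
             p_value = ct$p.value, note = NA_character_)
    }
  } else {
    sd_ <- survival::survdiff(survival::Surv(d[[time]], d[[event]]) ~ g)
    tibble(test = "logrank", statistic = sd_$chisq,
           p_value = pchisq(sd_$chisq, df = length(sd_$n) - 1,
                            lower.tail = FALSE),
           note = NA_character_)
  }
}

#' @export
print.subgroup_summary <- function(x, ...) {
  cat(sprintf("<subgroup_summary> by '%s', %s endpoint (%d used, %d dropped)\n",
              x$group, x$endpoint, x$n_used, x$n_dropped))
  print(x$groups); print(x$test)
  invisible(x)
}

#' @export
tidy.subgroup_summary <- function(x, ...) x$groups

#' Arm-by-group performance table with treatment contrasts
#'
#' The predictive-biomarker layout: one cell per (biomarker group, treatment
#' arm) with endpoint summaries, a within-group treatment contrast (mean
#' difference from a linear model / odds ratio and rate difference from a
#' logistic model / hazard ratio from a Cox model, each with 95% CI and
#' p-value), and a treatment-by-group interaction test from a single model
#' containing group, arm, and their interaction (Wald test on the
#' interaction term; likelihood-ratio test when the grouping has more than
#' two levels).
#'
#' @inheritParams subgroup_summary
#' @param trt Treatment column coded `+1` / `-1` (a `trial_data` input uses
#'   its internal `.trt`).
#' @param adjust_covariates Optional covariates added linearly to the
#'   contrast and interaction models.
#' @param min_n Groups with fewer patients than this in either arm are
#'   summarized but excluded from model-based contrasts.
#' @return A `subgroup_perf_table` object: `cells`, `contrasts`,
#'   `interaction` tibbles.
#' @export
subgroup_treatment_summary <- function(data, group, trt = ".trt",
                                       endpoint = "continuous",
                                       outcome = "y", time = NULL,
                                       event = NULL, adjust_covariates = NULL,
                                       min_n = 2) {
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
  keep <- complete.cases(data[, c(group, trt, ycols, adjust_covariates),
                              drop = FALSE])
  d <- data[keep, , drop = FALSE]
  if (length(unique(d[[trt]])) < 2) abort("Both arms must be present.")
  d$.grp <- factor(d[[group]])
  d$.arm <- factor(ifelse(d[[trt]] == 1, "treatment", "control"),
                   levels = c("control", "treatment"))

  cells <- bind_rows(lapply(split(d, d$.grp), function(di) {
    s <- endpoint_group_summary(di, ".arm", endpoint, outcome, time, event)
    names(s)[names(s) == "group"] <- "arm"
    bind_cols(tibble(group = rep(as.character(di$.grp[1]), nrow(s))), s)
  }))

  contrasts <- bind_rows(lapply(levels(d$.grp), function(g) {
    di <- d[d$.grp == g, , drop = FALSE]
    arm_n <- table(factor(di$.arm, levels = c("control", "treatment")))
    if (any(arm_n < min_n)) {
      return(tibble(group = g, contrast = NA_character_, estimate = NA_real_,
                    conf_low = NA_real_, conf_high = NA_real_,
                    p_value = NA_real_,
                    note = sprintf("an arm has fewer than %d patients", min_n)))
    }
    within_group_contrast(di, endpoint, outcome, time, event, adjust_covariates) |>
      mutate(group = g, .before = 1)
  }))

  interaction <- interaction_test(d, endpoint, outcome, time, event,
                                  adjust_covariates)
  structure(list(cells = cells, contrasts = contrasts,
                 interaction = interaction, group = group,
                 endpoint = endpoint, n_used = nrow(d),
                 n_dropped = sum(!keep)),
            class = "subgroup_perf_table")
}

within_group_contrast <- function(di, endpoint, outcome, time, event,
                                  adjust_covariates) {
  adj <- adjust_covariates
  if (endpoint == "continuous") {
    fml <- stats::reformulate(c(".arm", adj), response = outcome)
    fit <- lm(fml, data = di)
    co <- summary(fit)$coefficients[".armtreatment", , drop = FALSE]
    ci <- co[1, "Estimate"] + c(-1, 1) * qnorm(0.975) * co[1, "Std. Error"]
    tibble(contrast = "mean_difference", estimate = co[1, "Estimate"],
           conf_low = ci[1], conf_high = ci[2],
           p_value = co[1, "Pr(>|t|)"], note = NA_character_)
  } else if (endpoint == "binary") {
    fml <- stats::reformulate(c(".arm", adj), response = outcome)
    fit <- suppressWarnings(glm(fml, data = di, family = binomial()))
    co <- summary(fit)$coefficients
    if (!".armtreatment" %in% rownames(co)) {
      return(tibble(contrast = "odds_ratio", estimate = NA_real_,
                    conf_low = NA_real_, conf_high = NA_real_,
                    p_value = NA_real_, note = "degenerate model"))
    }
    est <- co[".armtreatment", "Estimate"]
    se <- co[".armtreatment", "Std. Error"]
    rates <- tapply(di[[outcome]], di$.arm, mean)
    tibble(contrast = "odds_ratio", estimate = exp(est),
           conf_low = exp(est - qnorm(0.975) * se),
           conf_high = exp(est + qnorm(0.975) * se),
           p_value = co[".armtreatment", "Pr(>|z|)"],
           rate_difference = unname(rates["treatment"] - rates["control"]),
           note = NA_character_)
  } else {
    if (sum(di[[event]]) == 0) {
      return(tibble(contrast = "hazard_ratio", estimate = NA_real_,
                    conf_low = NA_real_, conf_high = NA_real_,
                    p_value = NA_real_, note = "no events in group"))
    }
    fml <- stats::reformulate(c(".arm", adj),
                              response = sprintf("survival::Surv(%s, %s)",
                                                 time, event))
    fit <- survival::coxph(fml, data = di)
    co <- summary(fit)$coefficients[".armtreatment", , drop = FALSE]
    est <- co[1, "coef"]; se <- co[1, "se(coef)"]
    tibble(contrast = "hazard_ratio", estimate = exp(est),
           conf_low = exp(est - qnorm(0.975) * se),
           conf_high = exp(est + qnorm(0.975) * se),
           p_value = co[1, "Pr(>|z|)"], note = NA_character_)
  }
}

interaction_test <- function(d, endpoint, outcome, time, event,
                             adjust_covariates) {
  cell_n <- table(d$.grp, d$.arm)
  if (any(cell_n == 0) || nlevels(d$.grp) < 2) {
    inform("Empty cell or single group: interaction test skipped.")
    return(tibble(test = NA_character_, statistic = NA_real_,
                  p_value = NA_real_, note = "empty cell or single group"))
  }
  adj <- adjust_covariates
  two_groups <- nlevels(d$.grp) == 2
  if (endpoint == "survival") {
    resp <- sprintf("survival::Surv(%s, %s)", time, event)
    full <- survival::coxph(stats::reformulate(c(".grp * .arm", adj),
                                               response = resp), data = d)
    if (two_groups) {
      co <- summary(full)$coefficients
      term <- grep(":", rownames(co), value = TRUE)[1]
      return(tibble(test = "wald_cox", statistic = co[term, "z"],
                    p_value = co[term, "Pr(>|z|)"], note = NA_character_))
    }
    red <- survival::coxph(stats::reformulate(c(".grp", ".arm", adj),
                                              response = resp), data = d)
    lrt <- 2 * (full$loglik[2] - red$loglik[2])
    df <- length(coef(full)) - length(coef(red))
    return(tibble(test = "lrt_cox", statistic = lrt,
                  p_value = pchisq(lrt, df, lower.tail = FALSE),
                  note = NA_character_))
  }
  fml <- stats::reformulate(c(".grp * .arm", adj), response = outcome)
  if (endpoint == "continuous") {
    fit <- lm(fml, data = d)
    co <- summary(fit)$coefficients
    if (two_groups) {
      term <- grep(":", rownames(co), value = TRUE)[1]
      return(tibble(test = "wald_lm", statistic = co[term, "t value"],
                    p_value = co[term, "Pr(>|t|)"], note = NA_character_))
    }
    red <- lm(stats::reformulate(c(".grp", ".arm", adj), response = outcome),
              data = d)
    an <- anova(red, fit)
    return(tibble(test = "F_lm", statistic = an$F[2],
                  p_value = an$`Pr(>F)`[2], note = NA_character_))
  }
  fit <- suppressWarnings(glm(fml, data = d, family = binomial()))
  co <- summary(fit)$coefficients
  if (two_groups) {
    term <- grep(":", rownames(co), value = TRUE)[1]
    return(tibble(test = "wald_glm", statistic = co[term, "z value"],
                  p_value = co[term, "Pr(>|z|)"], note = NA_character_))
  }
  red <- suppressWarnings(glm(stats::reformulate(c(".grp", ".arm", adj),
                                                 response = outcome),
                              data = d, family = binomial()))
  lrt <- red$deviance - fit$deviance
  df <- red$df.residual - fit$df.residual
  tibble(test = "lrt_glm", statistic = lrt,
         p_value = pchisq(lrt, df, lower.tail = FALSE), note = NA_character_)
}

#' @export
print.subgroup_perf_table <- function(x, ...) {
  cat(sprintf("<subgroup_perf_table> by '%s' x arm, %s endpoint (%d used, %d dropped)\n",
              x$group, x$endpoint, x$n_used, x$n_dropped))
  print(x$cells); print(x$contrasts); print(x$interaction)
  invisible(x)
}

#' @export
tidy.subgroup_perf_table <- function(x, ...) x$cells

#' @export
glance.subgroup_perf_table <- function(x, ...) {
  bind_cols(tibble(n = x$n_used, endpoint = x$endpoint), x$interaction)
}

#' Counts and percentages of a categorical variable
#'
#' Level counts and percentages, optionally cross-tabulated by a second
#' column with a chi-square test of independence (Fisher exact when any
#' expected cell count is below 5).
#'
#' @param data A data frame or `trial_data` object.
#' @param variable Categorical column to summarize.
#' @param by Optional grouping column for a cross-tabulation.
#' @return A tibble of counts and percentages; with `by`, the association
#'   test is attached as attribute `"test"` (also a tibble).
#' @export
categorical_summary <- function(data, variable, by = NULL) {
  if (inherits(data, "trial_data")) data <- data$data
  data <- as_tibble(data)
  x <- data[[variable]]
  keep <- !is.na(x) & (if (is.null(by)) TRUE else !is.na(data[[by]]))
  x <- x[keep]
  if (is.null(by)) {
    tab <- table(x)
    return(tibble(level = names(tab), n = as.integer(tab),
                  percent = 100 * as.integer(tab) / sum(tab)))
  }
  g <- data[[by]][keep]
  tab <- table(x, g)
  out <- as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))
  names(out) <- c("level", by, "n")
  out <- out |>
    group_by(.data[[by]]) |>
    mutate(percent = 100 * .data$n / sum(.data$n)) |>
    ungroup()
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  test <- if (any(expected < 5)) {
    ft <- fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 16)
    tibble(test = "fisher_exact", statistic = NA_real_, p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble(test = "chi_square", statistic = unname(ct$statistic),
           p_value = ct$p.value)
  }
  attr(out, "test") <- test
  out
}
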