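#' Effect functional forms for the trial simulator
#'
#' Serializable descriptions of the prognostic main effect h(X) and the
#' treatment contrast z(X). `linear_effect()` is
#' `intercept + sum(coef * X[, names(coef)])`; `threshold_effect()` is a step
#' in one biomarker: `below` when `x <= threshold`, `above` when
#' `x > threshold`.
#'
#' @param coef Named numeric vector of slopes (names are biomarker columns).
#' @param intercept Constant term.
#' @return An `effect_form` list.
#' @export
linear_effect <- function(coef = c(x1 = 1), intercept = 0) {
  structure(list(type = "linear", coef = coef, intercept = intercept),
            class = "effect_form")
}

#' @rdname linear_effect
#' @param var Biomarker column the step acts on.
#' @param threshold Step location.
#' @param below,above Values taken on either side (`x <= threshold` is
#'   "below").
#' @export
threshold_effect <- function(var = "x1", threshold = 0, below = -1, above = 1) {
  structure(list(type = "threshold", var = var, threshold = threshold,
                 below = below, above = above),
            class = "effect_form")
}

#' @rdname linear_effect
#' @param value Constant effect level.
#' @export
constant_effect <- function(value = 0) {
  structure(list(type = "constant", value = value), class = "effect_form")
}

eval_effect <- function(form, X) {
  switch(form$type,
    linear = {
      vars <- names(form$coef)
      miss <- setdiff(vars, colnames(X))
      if (length(miss)) abort(sprintf("Effect references unknown biomarker(s): %s",
                                      paste(miss, collapse = ", ")))
      form$intercept + as.numeric(as.matrix(X[, vars, drop = FALSE]) %*% form$coef)
    },
    threshold = ifelse(X[[form$var]] > form$threshold, form$above, form$below),
    constant = rep(form$value, nrow(X)),
    abort(sprintf("Unknown effect form '%s'.", form$type)))
}

#' Specify a synthetic two-arm trial
#'
#' The generative model is `E(Y | A, X) = h(X) + z(X) * A` on the endpoint's
#' natural scale: identity for continuous outcomes (Gaussian noise), logit
#' for binary outcomes, log-hazard for exponential survival times with
#' independent exponential censoring calibrated to a target censoring
#' fraction.
#'
#' @param n Number of patients.
#' @param p Number of biomarkers (`x1` ... `xp`, iid standard normal).
#' @param h,z [linear_effect()] / [threshold_effect()] / [constant_effect()]
#'   forms for the main effect and the treatment contrast.
#' @param endpoint Endpoint kind.
#' @param propensity P(A = +1), in (0, 1).
#' @param noise_sd Continuous endpoint: residual standard deviation.
#' @param baseline_hazard Survival: baseline event rate.
#' @param censoring_rate Survival: target fraction censored, in [0, 1).
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @param categorical Optional named list `list(colname = levels)` of extra
#'   categorical biomarkers sampled uniformly over their levels.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(n, p = 10, h = constant_effect(0),
                        z = linear_effect(c(x1 = 1)),
                        endpoint = "continuous", propensity = 0.5,
                        noise_sd = 1, baseline_hazard = 0.1,
                        censoring_rate = 0.3, seed = 1, categorical = NULL) {
  endpoint <- check_endpoint(endpoint)
  if (p < 1) abort("`p` must be >= 1.")
  if (propensity <= 0 || propensity >= 1) abort("`propensity` must be in (0, 1).")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    abort("`censoring_rate` must lie in [0, 1).")
  }
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  structure(list(n = as.integer(n), p = as.integer(p), h = h, z = z,
                 endpoint = endpoint, propensity = propensity,
                 noise_sd = noise_sd, baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate, seed = as.integer(seed),
                 categorical = categorical),
            class = "effect_spec")
}

#' Simulate a randomized two-arm trial with known effect heterogeneity
#'
#' Draws biomarkers, arms, and endpoint-appropriate outcomes from an
#' [effect_spec()]. The returned dataset carries the generative truth per
#' patient: `true_z` (the contrast on the model scale) and `true_subgroup`,
#' the benefit sign: `+1` iff `z > 0` for continuous/binary outcomes, `+1`
#' iff `z < 0` on the log-hazard scale (lower hazard = benefit);
#' `z = 0` maps to `-1`.
#'
#' @param spec An [effect_spec()].
#' @return A [trial_data()] object whose `data` also contains `true_z` and
#'   `true_subgroup`; the spec is attached as `$sim_spec`.
#' @export
simulate_trial <- function(spec) {
  if (!inherits(spec, "effect_spec")) abort("`spec` must be an <effect_spec>.")
  set.seed(spec$seed)
  n <- spec$n
  X <- as_tibble(matrix(rnorm(n * spec$p), nrow = n,
                        dimnames = list(NULL, paste0("x", seq_len(spec$p)))))
  for (nm in names(spec$categorical)) {
    X[[nm]] <- sample(spec$categorical[[nm]], n, replace = TRUE)
  }
  A <- ifelse(rbinom(n, 1, spec$propensity) == 1, 1L, -1L)
  hX <- eval_effect(spec$h, X)
  zX <- eval_effect(spec$z, X)
  lin <- hX + zX * A

  df <- X
  df$trt <- A
  if (spec$endpoint == "continuous") {
    df$y <- lin + rnorm(n, 0, spec$noise_sd)
    benefit <- zX > 0
  } else if (spec$endpoint == "binary") {
    df$y <- rbinom(n, 1, plogis(lin))
    benefit <- zX > 0
  } else {
    rate <- spec$baseline_hazard * exp(lin)
    event_time <- rexp(n, rate)
    if (spec$censoring_rate == 0) {
      df$y_time <- event_time
      df$y_event <- rep(1L, n)
    } else {
      theta <- solve_censoring_rate(rate, spec$censoring_rate)
      cens_time <- rexp(n, theta)
      df$y_time <- pmin(event_time, cens_time)
      df$y_event <- as.integer(event_time <= cens_time)
    }
    benefit <- zX < 0
  }
  df$true_z <- zX
  df$true_subgroup <- ifelse(benefit, 1L, -1L)

  td <- trial_data(df, biomarkers = c(paste0("x", seq_len(spec$p)),
                                      names(spec$categorical)),
                   trt = "trt", endpoint = spec$endpoint,
                   outcome = if (spec$endpoint != "survival") "y",
                   time = if (spec$endpoint == "survival") "y_time",
                   event = if (spec$endpoint == "survival") "y_event",
                   default_propensity = spec$propensity)
  td$sim_spec <- spec
  td
}

# Exponential censoring C ~ Exp(theta) independent of T_i ~ Exp(rate_i):
# P(censored_i) = theta / (theta + rate_i). Solve mean_i of that = target.
solve_censoring_rate <- function(rate, target) {
  f <- function(log_theta) mean(exp(log_theta) / (exp(log_theta) + rate)) - target
  sol <- tryCatch(uniroot(f, lower = log(min(rate)) - 20,
                          upper = log(max(rate)) + 20, tol = 1e-12),
                  error = function(e) NULL)
  if (is.null(sol)) {
    abort(sprintf("Cannot calibrate censoring rate %.3f for these hazards.", target))
  }
  exp(sol$root)
}

#' A deterministic 10-biomarker demonstration trial
#'
#' A fixed-seed synthetic randomized 1:1 trial of 600 patients with ten
#' standard-normal biomarkers `x1` ... `x10`. Biomarker `x1` is both
#' prognostic and predictive with an effective threshold at 0.5: patients
#' with `x1 > 0.5` respond more and benefit from treatment, on both the
#' binary response `y` and the survival pair `y_time` / `y_event` (treatment
#' lowers the hazard only above the threshold). All other biomarkers are
#' noise. The object is a binary-endpoint `trial_data`; the survival columns
#' ride along for survival-endpoint examples. This is a synthetic emulation
#' constructed for documentation and tests, not a published dataset.
#'
#' @return A `trial_data` object (binary endpoint) whose `data` has columns
#'   `x1..x10`, `trt`, `y`, `y_time`, `y_event`, `true_z`, `true_subgroup`.
#' @export
tutorial_fixture <- function() {
  set.seed(20240901)
  n <- 600
  p <- 10
  X <- as_tibble(matrix(rnorm(n * p), nrow = n,
                        dimnames = list(NULL, paste0("x", seq_len(p)))))
  A <- ifelse(rbinom(n, 1, 0.5) == 1, 1L, -1L)
  hX <- ifelse(X$x1 > 0.5, 0.4, -1.0)
  zX <- ifelse(X$x1 > 0.5, 1.2, -0.2)
  y <- rbinom(n, 1, plogis(hX + zX * A))

  # survival companion: benefit (lower hazard) above the same threshold
  zs <- -zX
  rate <- 0.1 * exp(0.5 * hX + zs * A)
  event_time <- rexp(n, rate)
  theta <- solve_censoring_rate(rate, 0.3)
  cens_time <- rexp(n, theta)

  df <- X
  df$trt <- A
  df$y <- y
  df$y_time <- pmin(event_time, cens_time)
  df$y_event <- as.integer(event_time <= cens_time)
  df$true_z <- zX
  df$true_subgroup <- ifelse(zX > 0, 1L, -1L)
  trial_data(df, biomarkers = paste0("x", seq_len(p)), trt = "trt",
             endpoint = "binary", outcome = "y", default_propensity = 0.5)
}
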