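#' Loss configuration for contrast estimation
#'
#' Pairs an endpoint with the modified-loss flavour used to estimate the
#' treatment-contrast score f(X): A-learning (treatment indicator centred at
#' the propensity) or weight-learning (inverse-propensity weighting).
#'
#' @param endpoint `"continuous"`, `"binary"`, or `"survival"`.
#' @param loss_type `"a_learning"` or `"weight_learning"`.
#' @param tau Survival horizon: events after `tau` do not contribute. Must
#'   not exceed the largest observed time. `NULL` (default) resolves to the
#'   largest observed event time.
#' @param inner_weights Survival + weight-learning only: if `TRUE`, the
#'   inverse-propensity weights also enter the risk-set mean; by default they
#'   multiply only the outer per-patient contribution.
#' @return A `loss_config` object.
#' @export
loss_config <- function(endpoint,
                        loss_type = c("a_learning", "weight_learning"),
                        tau = NULL, inner_weights = FALSE) {
  endpoint <- check_endpoint(endpoint)
  loss_type <- match.arg(loss_type)
  if (!is.null(tau)) {
    if (endpoint != "survival") abort("`tau` applies to survival endpoints only.")
    if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
      abort("`tau` must be a single positive number.")
    }
  }
  structure(list(endpoint = endpoint, loss_type = loss_type, tau = tau,
                 inner_weights = isTRUE(inner_weights)),
            class = "loss_config")
}

#' Per-patient A-learning multiplier and inverse-propensity weight
#'
#' Computes `c = (A + 1)/2 - pi`, the propensity-centred treatment indicator
#' that multiplies f(X) in the A-learning loss, and
#' `w = 1 / (A * pi + (1 - A)/2)`, the inverse-propensity weight of the
#' weight-learning loss (`1/pi` on the treated arm, `1/(1 - pi)` on control).
#'
#' @param trt Treatment arm per patient, in `{+1, -1}`.
#' @param propensity Propensity score per patient, in (0, 1).
#' @return A tibble with columns `c` and `w`.
#' @export
#' @examples
#' modified_signal(c(1, -1), c(0.5, 0.5)) # c = +-0.5, w = 2
modified_signal <- function(trt, propensity) {
  if (!all(trt %in% c(-1, 1))) abort("`trt` must be coded +1 / -1.")
  if (any(!is.finite(propensity) | propensity <= 0 | propensity >= 1)) {
    abort("`propensity` must lie strictly inside (0, 1).")
  }
  tibble(c = (trt + 1) / 2 - propensity,
         w = 1 / (trt * propensity + (1 - trt) / 2))
}

#' The per-patient loss kernel M(y, v)
#'
#' The kernel must be convex in `v` with a derivative at `v = 0` monotone in
#' `y`; those two conditions make sign(f) a Fisher-consistent estimate of the
#' benefit subgroup. Kernels by endpoint:
#' * continuous: `(v - y)^2`;
#' * binary: `log(1 + e^v) - y * v` (Bernoulli negative log-likelihood,
#'   logit link, numerically stabilized);
#' * survival: `-event * in_horizon * (v - risk_log_mean)`, the per-event
#'   partial-likelihood contribution, where `risk_log_mean` is the log of
#'   the empirical mean of `e^v` over the risk set at the patient's event
#'   time.
#'
#' @param endpoint Endpoint kind.
#' @param y Outcome value (continuous/binary). Ignored for survival, where
#'   `event` and `in_horizon` carry the information.
#' @param v Score at which the kernel is evaluated; must be finite.
#' @param risk_log_mean Survival only: precomputed log risk-set mean at the
#'   patient's event time.
#' @param event Survival only: event indicator (1 observed, 0 censored).
#' @param in_horizon Survival only: indicator that the observed time is at or
#'   before the horizon tau.
#' @return Numeric vector of kernel values.
#' @export
m_value <- function(endpoint, y, v, risk_log_mean = NULL, event = NULL,
                    in_horizon = TRUE) {
  endpoint <- check_endpoint(endpoint)
  if (any(!is.finite(v))) abort("`v` must be finite.")
  switch(endpoint,
    continuous = (v - y)^2,
    binary = log1pexp(v) - y * v,
    survival = {
      if (is.null(event) || is.null(risk_log_mean)) {
        abort("Survival kernel needs `event` and `risk_log_mean`.")
      }
      -event * as.numeric(in_horizon) * (v - risk_log_mean)
    })
}

# Assemble the per-patient pieces shared by composite_loss and loss_gradient.
# mult: dv/df (c for A-learning, A for weight-learning)
# wt:   outer weight (1 for A-learning, w for weight-learning)
loss_parts <- function(td, config) {
  stop_not_trial(td)
  if (!inherits(config, "loss_config")) abort("`config` must be a <loss_config>.")
  if (config$endpoint != td$endpoint) {
    abort(sprintf("Endpoint mismatch: config is '%s' but data is '%s'.",
                  config$endpoint, td$endpoint))
  }
  d <- td$data
  sig <- modified_signal(d$.trt, d$.pi)
  a_learn <- config$loss_type == "a_learning"
  parts <- list(
    n = nrow(d),
    mult = if (a_learn) sig$c else as.numeric(d$.trt),
    wt = if (a_learn) rep(1, nrow(d)) else sig$w,
    endpoint = td$endpoint)
  if (td$endpoint == "survival") {
    parts$time <- d[[td$time]]
    parts$event <- d[[td$event]]
    tau <- config$tau %||% suppressWarnings(max(parts$time[parts$event == 1]))
    if (!is.finite(tau)) abort("No observed events: survival loss undefined.")
    if (tau > max(parts$time)) abort("`tau` exceeds the largest observed time.")
    parts$tau <- tau
    parts$delta_tau <- as.numeric(parts$event == 1 & parts$time <= tau)
    if (sum(parts$delta_tau) == 0) {
      abort("No events at or before `tau`: survival loss is degenerate.")
    }
  } else {
    parts$y <- d[[td$outcome]]
  }
  parts
}

# Breslow risk-set statistics at each patient's observed time, O(N log N).
# Returns, per patient i:
#   lrm      log((1/N) * sum_j rw_j e^{v_j} I(time_j >= time_i))
#   cum1     sum over events k with time_k <= time_i of wt_k * dt_k / S_k
#   cum2     same with 1 / S_k^2
# where S_k is the (centred) risk-set sum at event time k and dt the horizon
# indicator. Ties share a denominator (Breslow).
risk_set_stats <- function(time, v, delta_tau, wt, riskwt) {
  n <- length(time)
  vmax <- max(v)
  ev <- riskwt * exp(v - vmax)
  ord <- order(time, decreasing = TRUE)
  # cumulative risk sums walking from the largest time down
  cs <- cumsum(ev[ord])
  # for tied times all members of the tie belong to the risk set
  t_sorted <- time[ord]
  first_of_tie <- !duplicated(t_sorted)
  # S at each sorted position = risk sum including the whole tie group
  tie_id <- cumsum(first_of_tie)
  S_tie <- tapply(cs, tie_id, max) # max of cumsum within tie = full tie sum
  S_sorted <- as.numeric(S_tie[tie_id])
  S <- numeric(n); S[ord] <- S_sorted

  lrm <- log(S) + vmax - log(n)

  # event-time cumulative terms: for each patient i, sum over events with
  # time_k <= time_i of wt_k * delta_tau_k / S_k (and /S_k^2)
  asc <- order(time)
  term1 <- (wt * delta_tau / S)[asc]
  term2 <- (wt * delta_tau / S^2)[asc]
  c1 <- cumsum(term1)
  c2 <- cumsum(term2)
  t_asc <- time[asc]
  grp_end <- !duplicated(t_asc, fromLast = TRUE)
  # take, within tied ascending times, the cumulative value at the end of the
  # tie group (all tied events have time_k <= time_i for every i in the tie)
  idx <- seq_len(n)
  end_pos <- rev(cummin(rev(ifelse(grp_end, idx, Inf))))
  cum1 <- numeric(n); cum1[asc] <- c1[end_pos]
  cum2 <- numeric(n); cum2[asc] <- c2[end_pos]
  list(lrm = lrm, cum1 = cum1, cum2 = cum2, ev_centred = exp(v - vmax), S = S)
}

#' Composite modified loss
#'
#' Evaluates the mean modified loss over patients at score vector `f`:
#' A-learning averages `M(y_i, c_i f_i)`; weight-learning averages
#' `w_i * M(y_i, A_i f_i)`. For survival endpoints the kernel is the negative
#' partial-likelihood contribution with Breslow tie handling, counting events
#' up to the horizon `tau` only.
#'
#' @param td A `trial_data` object.
#' @param f Numeric score per patient (length N).
#' @param config A [loss_config()].
#' @return A single numeric loss value.
#' @export
composite_loss <- function(td, f, config) {
  parts <- loss_parts(td, config)
  if (length(f) != parts$n) abort("`f` must have one score per patient.")
  if (any(!is.finite(f))) abort("`f` must be finite.")
  v <- parts$mult * f
  if (parts$endpoint == "survival") {
    riskwt <- if (config$inner_weights) parts$wt else rep(1, parts$n)
    rs <- risk_set_stats(parts$time, v, parts$delta_tau, parts$wt, riskwt)
    contrib <- -parts$delta_tau * (v - rs$lrm)
  } else {
    contrib <- m_value(parts$endpoint, parts$y, v)
  }
  mean(parts$wt * contrib)
}

#' Gradient and Hessian of the summed modified loss
#'
#' Exact first derivative `g` and a nonnegative diagonal second derivative
#' `h` of `N * composite_loss` with respect to `f`, in the form consumed by a
#' gradient-boosting custom objective. For survival endpoints the gradient is
#' the exact partial-likelihood derivative (risk-set cross terms included)
#' and `h` is the diagonal Breslow approximation
#' `mult^2 * sum_k wt_k p_k (1 - p_k)` over event times, with `p` the
#' risk-set softmax weight.
#'
#' @inheritParams composite_loss
#' @param hessian_floor Lower bound applied elementwise to `h` so boosting
#'   steps stay defined.
#' @return A tibble with columns `g` and `h`.
#' @export
loss_gradient <- function(td, f, config, hessian_floor = 1e-16) {
  parts <- loss_parts(td, config)
  if (length(f) != parts$n) abort("`f` must have one score per patient.")
  gh <- loss_gradient_parts(parts, f, config)
  gh$h <- pmax(gh$h, hessian_floor)
  as_tibble(gh)
}

# Core shared with the boosting objective: works from precomputed parts.
loss_gradient_parts <- function(parts, f, config) {
  v <- parts$mult * f
  if (parts$endpoint == "survival") {
    riskwt <- if (config$inner_weights) parts$wt else rep(1, parts$n)
    rs <- risk_set_stats(parts$time, v, parts$delta_tau, parts$wt, riskwt)
    e <- riskwt * rs$ev_centred
    # p_{ki} summed over events k with time_k <= time_i
    sum_p <- e * rs$cum1
    sum_p2 <- e^2 * rs$cum2
    g <- parts$mult * (-parts$wt * parts$delta_tau + sum_p)
    h <- parts$mult^2 * pmax(sum_p - sum_p2, 0)
  } else if (parts$endpoint == "binary") {
    s <- sigmoid(v)
    g <- parts$wt * parts$mult * (s - parts$y)
    h <- parts$wt * parts$mult^2 * s * (1 - s)
  } else {
    g <- parts$wt * parts$mult * 2 * (v - parts$y)
    h <- parts$wt * parts$mult^2 * 2
  }
  list(g = as.numeric(g), h = as.numeric(h))
}
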