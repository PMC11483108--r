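# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles (enumeration, double loops, pairwise
# statistics) and share no code with the implementation they check.

# Two-sided Fisher exact p by full enumeration over tables with the observed
# margins: sum the hypergeometric probabilities of all tables no more
# probable than the observed one (same convention as the exact test).
fisher_oracle <- function(tp, fp, fn, tn) {
  m1 <- tp + fn # outcome-positive margin
  m0 <- fp + tn
  k <- tp + fp  # biomarker-positive margin
  a_min <- max(0, k - m0)
  a_max <- min(k, m1)
  probs <- vapply(a_min:a_max, function(a) {
    stats::dhyper(a, m1, m0, k)
  }, numeric(1))
  p_obs <- stats::dhyper(tp, m1, m0, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Cohen's kappa from the 2x2 cell counts, via the agreement definition.
kappa_oracle <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  observed <- (tp + tn) / n
  expected <- ((tp + fp) / n) * ((tp + fn) / n) +
    ((fn + tn) / n) * ((fp + tn) / n)
  (observed - expected) / (1 - expected)
}

# AUC as the Mann-Whitney U statistic over all (positive, negative) pairs,
# ties counted one half.
auc_oracle <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Kaplan-Meier survival curve by the product-limit definition (loop over
# distinct event times). Median: first time S drops below 0.5; when S hits
# 0.5 exactly the median is the midpoint of that time and the next time the
# curve drops further (the standard convention).
km_median_oracle <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  s <- 1
  hit_half_at <- NA_real_
  for (t in unique(time)) {
    d <- sum(time == t & event == 1)
    n <- sum(time >= t)
    if (d > 0) s <- s * (1 - d / n)
    if (!is.na(hit_half_at) && s < 0.5) return((hit_half_at + t) / 2)
    if (s < 0.5) return(t)
    if (d > 0 && abs(s - 0.5) < 1e-12 && is.na(hit_half_at)) hit_half_at <- t
  }
  NA_real_ # curve never drops below 0.5
}

toy_2x2_data <- function(tp = 8, fn = 2, fp = 3, tn = 7, cutoff = 0) {
  # biomarker-positive = x > cutoff; outcome-1 rows: tp positive, fn negative
  tibble::tibble(
    x = c(rep(cutoff + 1, tp), rep(cutoff - 1, fn),
          rep(cutoff + 1, fp), rep(cutoff - 1, tn)),
    y = c(rep(1, tp + fn), rep(0, fp + tn)))
}

# Survival modified loss by naive double loops over patients and risk sets.
# mult/wt are the per-patient chain multiplier and outer weight.
naive_survival_loss <- function(time, event, f, mult, wt, tau) {
  n <- length(time)
  v <- mult * f
  total <- 0
  for (i in seq_len(n)) {
    if (event[i] == 1 && time[i] <= tau) {
      risk_mean <- mean(exp(v) * (time >= time[i]))
      total <- total + wt[i] * (-(v[i] - log(risk_mean)))
    }
  }
  total / n
}

# Central finite differences of composite_loss, elementwise.
fd_gradient <- function(td, f, config, eps = 1e-5) {
  vapply(seq_along(f), function(i) {
    fp <- f; fp[i] <- f[i] + eps
    fm <- f; fm[i] <- f[i] - eps
    (composite_loss(td, fp, config) - composite_loss(td, fm, config)) / (2 * eps)
  }, numeric(1))
}

# Small deterministic trial builders --------------------------------------

make_continuous_td <- function(n = 100, seed = 1, p = 3, z_coef = 1) {
  simulate_trial(effect_spec(n = n, p = p,
                             z = linear_effect(c(x1 = z_coef)),
                             h = linear_effect(c(x2 = 0.5)),
                             endpoint = "continuous", seed = seed))
}

make_binary_td <- function(n = 100, seed = 1, p = 3) {
  simulate_trial(effect_spec(n = n, p = p, z = linear_effect(c(x1 = 1)),
                             h = linear_effect(c(x2 = 0.3)),
                             endpoint = "binary", seed = seed))
}

make_survival_td <- function(n = 100, seed = 1, p = 3, censoring = 0.2) {
  simulate_trial(effect_spec(n = n, p = p, z = linear_effect(c(x1 = 0.8)),
                             h = linear_effect(c(x2 = 0.3)),
                             endpoint = "survival", censoring_rate = censoring,
                             seed = seed))
}

all_loss_configs <- function(tau = NULL) {
  list(
    cont_a = list(make = make_continuous_td, cfg = loss_config("continuous", "a_learning")),
    cont_w = list(make = make_continuous_td, cfg = loss_config("continuous", "weight_learning")),
    bin_a = list(make = make_binary_td, cfg = loss_config("binary", "a_learning")),
    bin_w = list(make = make_binary_td, cfg = loss_config("binary", "weight_learning")),
    sur_a = list(make = make_survival_td, cfg = loss_config("survival", "a_learning", tau = tau)),
    sur_w = list(make = make_survival_td, cfg = loss_config("survival", "weight_learning", tau = tau)))
}

quick_params <- function(seed = 1, n_rounds = 60, learning_rate = 0.1, ...) {
  boosting_params(learning_rate = learning_rate, n_rounds = n_rounds,
                  seed = seed, ...)
}
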