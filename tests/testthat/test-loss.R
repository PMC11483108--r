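test_that("m_value matches its closed forms", {
  expect_identical(m_value("continuous", y = 2, v = 2), 0)
  expect_identical(m_value("continuous", y = 0, v = 3), 9)
  expect_equal(m_value("binary", y = 0, v = 0), log(2))
  # logistic kernel at a few hand-computed points
  expect_equal(m_value("binary", y = 1, v = 2), log(1 + exp(2)) - 2)
  # survival integrand vanishes when the score equals the risk log-mean
  expect_identical(m_value("survival", y = 5, v = 1.3, risk_log_mean = 1.3,
                           event = 1), 0)
  # censored or out-of-horizon patients contribute nothing
  expect_identical(m_value("survival", y = 5, v = 2, risk_log_mean = 0,
                           event = 0), 0)
  expect_identical(m_value("survival", y = 5, v = 2, risk_log_mean = 0,
                           event = 1, in_horizon = 0), 0)
  expect_error(m_value("continuous", y = 1, v = Inf), "finite")
})

test_that("m_value is numerically stable at extreme logistic scores", {
  expect_equal(m_value("binary", y = 1, v = 800), 0)
  expect_equal(m_value("binary", y = 0, v = -800), 0)
  expect_equal(m_value("binary", y = 0, v = 800), 800)
})

test_that("modified_signal computes c and w from the printed formulas", {
  s <- modified_signal(c(1, -1, 1), c(0.5, 0.5, 0.25))
  expect_equal(s$c, c(0.5, -0.5, 0.75))
  expect_equal(s$w, c(2, 2, 4))
  # invariants: c in (-1, 1), w > 1
  set.seed(1)
  trt <- sample(c(-1, 1), 50, replace = TRUE)
  pp <- runif(50, 0.05, 0.95)
  s2 <- modified_signal(trt, pp)
  expect_true(all(s2$c > -1 & s2$c < 1))
  expect_true(all(s2$w > 1))
  expect_error(modified_signal(c(1, 0), c(0.5, 0.5)), "\\+1 / -1")
  expect_error(modified_signal(c(1, -1), c(0.5, 1)), "\\(0, 1\\)")
})

test_that("continuous A-learning loss at f = 0 is mean(y^2)", {
  td <- make_continuous_td(n = 50, seed = 2)
  cfg <- loss_config("continuous", "a_learning")
  expect_equal(composite_loss(td, rep(0, 50), cfg),
               mean(td$data$y^2))
})

test_that("weight-learning with pi = 0.5 is twice the unweighted mean kernel", {
  for (make in list(make_continuous_td, make_binary_td)) {
    td <- make(n = 60, seed = 3)
    f <- rnorm(60)
    cfg <- loss_config(td$endpoint, "weight_learning")
    lhs <- composite_loss(td, f, cfg)
    rhs <- 2 * mean(m_value(td$endpoint, td$data$y, td$data$.trt * f))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("survival loss matches a naive double-loop oracle", {
  td <- make_survival_td(n = 40, seed = 4)
  tm <- td$data$y_time; ev <- td$data$y_event
  tau <- max(tm[ev == 1])
  sig <- modified_signal(td$data$.trt, td$data$.pi)

  # null loss, A-learning
  cfg_a <- loss_config("survival", "a_learning")
  expect_equal(composite_loss(td, rep(0, 40), cfg_a),
               naive_survival_loss(tm, ev, rep(0, 40), sig$c, rep(1, 40), tau),
               tolerance = 1e-9)
  # random scores, both loss types
  set.seed(5)
  f <- rnorm(40)
  expect_equal(composite_loss(td, f, cfg_a),
               naive_survival_loss(tm, ev, f, sig$c, rep(1, 40), tau),
               tolerance = 1e-9)
  cfg_w <- loss_config("survival", "weight_learning")
  expect_equal(composite_loss(td, f, cfg_w),
               naive_survival_loss(tm, ev, f, td$data$.trt, sig$w, tau),
               tolerance = 1e-9)
})

test_that("survival loss handles tied event times by the Breslow convention", {
  df <- data.frame(x1 = rnorm(8), trt = rep(c(1, -1), 4),
                   tm = c(2, 2, 2, 5, 5, 7, 8, 9),
                   ev = c(1, 1, 0, 1, 1, 0, 1, 0))
  td <- trial_data(df, "x1", "trt", "survival", time = "tm", event = "ev")
  sig <- modified_signal(td$data$.trt, td$data$.pi)
  set.seed(6)
  f <- rnorm(8)
  cfg <- loss_config("survival", "a_learning")
  expect_equal(composite_loss(td, f, cfg),
               naive_survival_loss(df$tm, df$ev, f, sig$c, rep(1, 8),
                                   max(df$tm[df$ev == 1])),
               tolerance = 1e-12)
})

test_that("tau restricts the event horizon and must be attainable", {
  td <- make_survival_td(n = 40, seed = 7)
  tm <- td$data$y_time; ev <- td$data$y_event
  tau <- stats::median(tm)
  cfg <- loss_config("survival", "a_learning", tau = tau)
  sig <- modified_signal(td$data$.trt, td$data$.pi)
  f <- rnorm(40)
  expect_equal(composite_loss(td, f, cfg),
               naive_survival_loss(tm, ev, f, sig$c, rep(1, 40), tau),
               tolerance = 1e-9)
  expect_error(composite_loss(td, f, loss_config("survival", "a_learning",
                                                 tau = max(tm) * 2)),
               "exceeds")
  expect_error(
    composite_loss(td, f, loss_config("survival", "a_learning",
                                      tau = min(tm) / 2)),
    "degenerate")
})

test_that("analytic gradients match finite differences for all six losses", {
  for (nm in names(all_loss_configs())) {
    combo <- all_loss_configs()[[nm]]
    td <- combo$make(n = 30, seed = 11)
    n <- nrow(td$data)
    set.seed(12)
    for (rep in 1:3) {
      f <- rnorm(n)
      g <- loss_gradient(td, f, combo$cfg)$g / n
      fd <- fd_gradient(td, f, combo$cfg)
      expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-5,
                label = paste("gradient", nm, "rep", rep))
    }
  }
})

test_that("gradient at f = 0 has the closed continuous A-learning form", {
  td <- make_continuous_td(n = 40, seed = 13)
  cfg <- loss_config("continuous", "a_learning")
  sig <- modified_signal(td$data$.trt, td$data$.pi)
  gh <- loss_gradient(td, rep(0, 40), cfg)
  expect_equal(gh$g, -2 * sig$c * td$data$y)
  expect_equal(gh$h, 2 * sig$c^2)
})

test_that("binary gradient saturates for well-classified extreme scores", {
  td <- make_binary_td(n = 20, seed = 14)
  cfg <- loss_config("binary", "weight_learning")
  # v = A * f; force v very large where y = 1 so sigma(v) -> 1
  f <- ifelse(td$data$y == 1, td$data$.trt * 50, 0)
  gh <- loss_gradient(td, f, cfg)
  expect_true(all(abs(gh$g[td$data$y == 1]) < 1e-12))
  expect_true(all(gh$h >= 1e-16))
})

test_that("kernels are convex: nonnegative second differences in v", {
  set.seed(15)
  for (ep in c("continuous", "binary")) {
    for (rep in 1:20) {
      y <- if (ep == "binary") rbinom(1, 1, 0.5) else rnorm(1)
      v <- rnorm(1); h <- 0.05
      second_diff <- m_value(ep, y, v + h) - 2 * m_value(ep, y, v) +
        m_value(ep, y, v - h)
      expect_gte(second_diff, -1e-12)
    }
  }
  # survival kernel is linear in v (convex) for fixed risk term
  sd_sur <- m_value("survival", 1, 1.1, risk_log_mean = 0.2, event = 1) -
    2 * m_value("survival", 1, 1.0, risk_log_mean = 0.2, event = 1) +
    m_value("survival", 1, 0.9, risk_log_mean = 0.2, event = 1)
  expect_equal(sd_sur, 0)
})

test_that("the kernel derivative at v = 0 is monotone in y", {
  dv <- function(ep, y, h = 1e-6) {
    (m_value(ep, y, h) - m_value(ep, y, -h)) / (2 * h)
  }
  ys <- seq(-2, 2, by = 0.5)
  expect_true(all(diff(vapply(ys, function(y) dv("continuous", y),
                              numeric(1))) < 0)) # -2y decreasing in y
  expect_true(all(diff(vapply(c(0, 1), function(y) dv("binary", y),
                              numeric(1))) < 0)) # 1/2 - y
})

test_that("A-learning and weight-learning are algebraically linked at pi = 0.5", {
  # With pi = 0.5, c_i = A_i / 2, so the continuous A-learning loss at score
  # 2f equals half the weight-learning loss at f (all w_i = 2):
  # L_A(2f) uses v = A f; L_W(f) = 2 * mean M(y, A f).
  td <- make_continuous_td(n = 50, seed = 16)
  f <- rnorm(50)
  la <- composite_loss(td, 2 * f, loss_config("continuous", "a_learning"))
  lw <- composite_loss(td, f, loss_config("continuous", "weight_learning"))
  expect_equal(2 * la, lw, tolerance = 1e-12)
})

test_that("loss configuration is validated", {
  expect_error(loss_config("continuous", "a_learning", tau = 3), "survival")
  expect_error(loss_config("survival", "a_learning", tau = -1), "positive")
  td <- make_continuous_td(n = 10, seed = 1)
  expect_error(composite_loss(td, rep(0, 5),
                              loss_config("continuous", "a_learning")),
               "one score per patient")
  expect_error(composite_loss(td, rep(0, 10), loss_config("binary", "a_learning")),
               "mismatch")
})
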