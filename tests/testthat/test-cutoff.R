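test_that("2x2 classification metrics match their definitions", {
  d <- toy_2x2_data()
  res <- evaluate_cutoffs(d, "x", cutoffs = 0, method = "youden",
                          outcome = "y")
  m <- res$metrics
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.7)
  expect_equal(m$youden, 0.5)
  expect_equal(m$n_positive, 11L)
  expect_equal(m$n_negative, 9L)
  expect_equal(m$ppv, 8 / 11)
  expect_equal(m$npv, 7 / 9)
})

test_that("Fisher p and kappa match brute-force oracles on all small tables", {
  for (tp in 0:6) for (fp in 0:4) {
    fn <- 6 - tp
    tn <- 6 - fp
    if (tp + fp == 0 || fn + tn == 0) next
    d <- toy_2x2_data(tp, fn, fp, tn)
    m <- evaluate_cutoffs(d, "x", 0, method = "fisher", outcome = "y")$metrics
    expect_equal(m$p_value, fisher_oracle(tp, fp, fn, tn), tolerance = 1e-12,
                 label = sprintf("fisher p (%d,%d,%d,%d)", tp, fn, fp, tn))
    if (!is.na(m$kappa)) {
      expect_equal(m$kappa, kappa_oracle(tp, fp, fn, tn), tolerance = 1e-12,
                   label = sprintf("kappa (%d,%d,%d,%d)", tp, fn, fp, tn))
    }
  }
})

test_that("kappa is 1 under perfect agreement and near 0 under independence", {
  perfect <- toy_2x2_data(tp = 10, fn = 0, fp = 0, tn = 10)
  expect_equal(evaluate_cutoffs(perfect, "x", 0, method = "kappa",
                                outcome = "y")$metrics$kappa, 1)
  set.seed(40)
  indep <- tibble::tibble(x = rnorm(10000), y = rbinom(10000, 1, 0.4))
  k <- evaluate_cutoffs(indep, "x", 0, method = "kappa",
                        outcome = "y")$metrics$kappa
  expect_lt(abs(k), 0.1)
})

test_that("youden = sensitivity + specificity - 1 on every emitted row", {
  set.seed(41)
  d <- tibble::tibble(x = rnorm(300), y = rbinom(300, 1, plogis(rnorm(300) + 1 * (rnorm(300) > 0))))
  d$y <- rbinom(300, 1, plogis(d$x))
  res <- evaluate_cutoffs(d, "x", cutoffs = seq(-1.5, 1.5, by = 0.25),
                          method = "youden", outcome = "y")
  ok <- !is.na(res$metrics$youden)
  expect_equal(res$metrics$youden[ok],
               res$metrics$sensitivity[ok] + res$metrics$specificity[ok] - 1)
  # selected cutoff is the brute-force maximizer
  expect_equal(res$selected,
               res$metrics$cutoff[which.max(res$metrics$youden)])
})

test_that("flipping direction swaps the classification but not the Fisher p", {
  set.seed(42)
  d <- tibble::tibble(x = rnorm(120), y = rbinom(120, 1, plogis(2 * rnorm(120))))
  d$y <- rbinom(120, 1, plogis(1.5 * d$x))
  g <- evaluate_cutoffs(d, "x", 0.2, method = "fisher", outcome = "y")$metrics
  l <- evaluate_cutoffs(d, "x", 0.2, direction = "less", method = "fisher",
                        outcome = "y")$metrics
  expect_equal(g$p_value, l$p_value, tolerance = 1e-12)
  # under 'less' the positive side is the complement, minus ties at the cutoff
  expect_equal(g$tp + g$fn, l$tp + l$fn)
  expect_equal(g$sensitivity, 1 - l$sensitivity, tolerance = 1e-12)
})

test_that("values equal to the cutoff are negative under 'greater'", {
  d <- tibble::tibble(x = c(0.5, 0.5, 1, 0), y = c(1, 0, 1, 0))
  m <- evaluate_cutoffs(d, "x", 0.5, method = "youden", outcome = "y")$metrics
  expect_equal(m$n_positive, 1L)
  ml <- evaluate_cutoffs(d, "x", 0.5, direction = "less", method = "youden",
                         outcome = "y")$metrics
  expect_equal(ml$n_positive, 1L)
})

test_that("missing biomarker rows are dropped and counted", {
  d <- tibble::tibble(x = c(NA, NA, rnorm(20)), y = rbinom(22, 1, 0.5))
  d$y[3:12] <- 1; d$y[13:22] <- 0
  res <- evaluate_cutoffs(d, "x", 0, method = "fisher", outcome = "y")
  expect_identical(res$n_dropped, 2L)
  expect_identical(res$n_used, 20L)
  expect_identical(res$n_candidates, 1L)
})

test_that("degenerate cutoffs warn and yield NA metrics with explanation", {
  d <- toy_2x2_data()
  expect_warning(res <- evaluate_cutoffs(d, "x", 10, method = "youden",
                                         outcome = "y"),
                 "range")
  expect_true(is.na(res$metrics$youden))
  expect_match(res$metrics$note, "one side")
})

test_that("p-value ties select the cutoff with the larger positive group", {
  # symmetric data: cutoffs at -1 and 1 give mirrored tables, equal p
  d <- tibble::tibble(x = c(-2, -2, 0, 0, 2, 2), y = c(0, 0, 1, 0, 1, 1))
  res <- evaluate_cutoffs(d, "x", c(-1, 1), method = "fisher", outcome = "y")
  expect_equal(res$metrics$p_value[1], res$metrics$p_value[2], tolerance = 1e-12)
  expect_equal(res$selected, -1) # larger biomarker-positive group
})

test_that("continuous and survival cutoff methods run with sensible outputs", {
  set.seed(43)
  d <- tibble::tibble(x = rnorm(200))
  d$y <- ifelse(d$x > 0.5, 1, 0) + rnorm(200, 0, 0.5)
  res <- evaluate_cutoffs(d, "x", c(0.1, 0.3, 0.5), method = "two_sample",
                          outcome = "y")
  expect_equal(res$selected, 0.5)

  tds <- make_survival_td(n = 200, seed = 44)
  resx <- evaluate_cutoffs(tds$data, "x1", c(-0.5, 0, 0.5), method = "logrank",
                           time = "y_time", event = "y_event")
  expect_identical(nrow(resx$metrics), 3L)
  expect_true(all(resx$metrics$p_value > 0 & resx$metrics$p_value <= 1))
})

test_that("cutoff_performance recovers group means and flags degenerate cases", {
  set.seed(45)
  n <- 1000
  d <- tibble::tibble(x = c(rnorm(n / 2, 1), rnorm(n / 2, -1)))
  d$y <- ifelse(d$x > 0, rnorm(n, 1), rnorm(n, 0))
  cp <- cutoff_performance(d, "x", 0, endpoint = "continuous", outcome = "y")
  pos <- cp$groups[cp$groups$group == "biomarker_positive", ]
  neg <- cp$groups[cp$groups$group == "biomarker_negative", ]
  expect_lt(abs(pos$mean - 1), 0.15)
  expect_lt(abs(neg$mean - 0), 0.15)
  expect_lt(cp$test$p_value, 0.001)
  expect_identical(pos$n + neg$n, cp$n_used)

  # all-censored survival: medians undefined, no test
  ds <- tibble::tibble(x = rnorm(30), tm = rexp(30, 1), ev = rep(0L, 30))
  cps <- cutoff_performance(ds, "x", 0, endpoint = "survival",
                            time = "tm", event = "ev")
  expect_true(all(!cps$groups$median_reached))
  expect_true(is.na(cps$test$p_value))

  # empty group contract
  de <- tibble::tibble(x = rnorm(20) + 10, y = rnorm(20))
  cpe <- cutoff_performance(de, "x", 0, direction = "less",
                            endpoint = "continuous", outcome = "y")
  expect_true(is.na(cpe$test$p_value))
  expect_match(cpe$test$note, "empty")
})

test_that("identical distributions give well-behaved null p-values", {
  hits <- 0
  for (i in 1:200) {
    set.seed(1000 + i)
    d <- tibble::tibble(x = rnorm(60), y = rnorm(60))
    cp <- cutoff_performance(d, "x", 0, endpoint = "continuous", outcome = "y")
    if (cp$test$p_value > 0.01) hits <- hits + 1
  }
  expect_gte(hits, 190) # >= 95% of null replicates
})

test_that("covariate-adjusted continuous comparison uses the linear model", {
  set.seed(46)
  d <- tibble::tibble(x = rnorm(300), z = rnorm(300))
  d$y <- 0.8 * (d$x > 0) + 2 * d$z + rnorm(300)
  cp <- cutoff_performance(d, "x", 0, endpoint = "continuous", outcome = "y",
                           adjust_covariates = "z")
  expect_identical(cp$test$test, "adjusted_lm")
  expect_lt(abs(cp$test$estimate - 0.8), 0.3)
})
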