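test_that("tutorial defaults run end-to-end on a 10-biomarker binary trial", {
  td <- tutorial_fixture()
  m <- fit_subgroup_model(td, loss_config("binary", "a_learning"),
                          boosting_params())
  expect_s3_class(m, "subgroup_model")
  expect_identical(nrow(m$history), 300L)
  expect_true(all(is.finite(m$history$loss)))
  expect_identical(m$benefit_direction, "positive_score")
})

test_that("history has exactly one entry per round", {
  td <- make_continuous_td(n = 40, seed = 1)
  m <- fit_subgroup_model(td, loss_config("continuous", "a_learning"),
                          quick_params(n_rounds = 1))
  expect_identical(nrow(m$history), 1L)
})

test_that("training loss is non-increasing for all six endpoint/loss combos", {
  for (nm in names(all_loss_configs())) {
    combo <- all_loss_configs()[[nm]]
    td <- combo$make(n = 300, seed = 21)
    m <- fit_subgroup_model(td, combo$cfg, quick_params(n_rounds = 40))
    expect_true(all(diff(m$history$loss) <= 1e-9),
                label = paste("descent", nm))
  }
})

test_that("predictions reproduce the final training loss and are name-aligned", {
  td <- make_binary_td(n = 150, seed = 22)
  cfg <- loss_config("binary", "a_learning")
  m <- fit_subgroup_model(td, cfg, quick_params())
  s <- predict_score(m, td$data)
  expect_equal(composite_loss(td, s, cfg),
               m$history$loss[nrow(m$history)], tolerance = 1e-9)
  expect_equal(evaluate_loss(m, td), m$history$loss[nrow(m$history)],
               tolerance = 1e-9)

  shuffled <- td$data[, sample(ncol(td$data)), drop = FALSE]
  expect_identical(predict_score(m, shuffled), s)
  expect_error(predict_score(m, td$data[, -1]), "missing")
})

test_that("evaluate_loss is invariant to patient row order", {
  td <- make_continuous_td(n = 80, seed = 23)
  cfg <- loss_config("continuous", "weight_learning")
  m <- fit_subgroup_model(td, cfg, quick_params(n_rounds = 20))
  l1 <- evaluate_loss(m, td)
  perm <- sample(nrow(td$data))
  td2 <- td
  td2$data <- td$data[perm, , drop = FALSE]
  td2$patient_id <- td$patient_id[perm]
  expect_equal(evaluate_loss(m, td2), l1, tolerance = 1e-12)
})

test_that("a known threshold contrast separates predicted scores", {
  td <- simulate_trial(effect_spec(
    n = 800, p = 5, z = threshold_effect("x1", 0, below = -1, above = 1),
    endpoint = "continuous", seed = 24))
  m <- fit_subgroup_model(td, loss_config("continuous", "a_learning"),
                          quick_params())
  s <- predict_score(m, td$data)
  expect_gt(mean(s[td$data$x1 > 0]), mean(s[td$data$x1 <= 0]))
})

test_that("assign_subgroup thresholds at zero with ties to control", {
  td <- make_continuous_td(n = 60, seed = 25)
  m <- fit_subgroup_model(td, loss_config("continuous", "a_learning"),
                          quick_params(n_rounds = 20))
  s <- predict_score(m, td$data)
  rec <- assign_subgroup(m, td$data)
  expect_identical(rec, ifelse(s > 0, 1L, -1L))

  # survival defaults to benefit = negative score
  tds <- make_survival_td(n = 120, seed = 26)
  ms <- fit_subgroup_model(tds, loss_config("survival", "a_learning"),
                           quick_params(n_rounds = 20))
  ss <- predict_score(ms, tds$data)
  expect_identical(assign_subgroup(ms, tds$data), ifelse(ss < 0, 1L, -1L))

  # a degenerate all-zero ensemble recommends control everywhere
  m0 <- fit_subgroup_model(td, loss_config("continuous", "a_learning"),
                           boosting_params(learning_rate = 0.01, n_rounds = 1,
                                           reg_lambda = 1e12, seed = 1))
  expect_true(all(abs(predict_score(m0, td$data)) < 1e-6))
})

test_that("fitting is deterministic given seed, params and data", {
  td <- make_binary_td(n = 200, seed = 27)
  cfg <- loss_config("binary", "weight_learning")
  m1 <- fit_subgroup_model(td, cfg, quick_params(seed = 9))
  m2 <- fit_subgroup_model(td, cfg, quick_params(seed = 9))
  expect_identical(predict_score(m1, td$data), predict_score(m2, td$data))
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(biomarker_importance(m1), biomarker_importance(m2))
})

test_that("importance ranks a single informative biomarker first", {
  td <- simulate_trial(effect_spec(n = 600, p = 10,
                                   z = linear_effect(c(x1 = 1.5)),
                                   endpoint = "continuous", seed = 28))
  m <- fit_subgroup_model(td, loss_config("continuous", "a_learning"),
                          quick_params())
  imp <- biomarker_importance(m)
  expect_identical(imp$biomarker[1], "x1")
  expect_identical(imp$rank[1], 1L)
  expect_gt(imp$gain[1], 0.5)
  expect_equal(sum(imp$gain), 1, tolerance = 1e-12)
  expect_true(all(imp$gain >= 0))
  expect_true(all(diff(imp$rank) >= 0))
})

test_that("an ensemble with no splits raises an informative error", {
  td <- make_continuous_td(n = 40, seed = 29)
  m <- fit_subgroup_model(td, loss_config("continuous", "a_learning"),
                          boosting_params(learning_rate = 0.01, n_rounds = 1,
                                          reg_lambda = 1e12, seed = 1,
                                          gamma = 1e12))
  expect_error(biomarker_importance(m), "[Nn]o informative splits")
})

test_that("tidy/glance summarize a fitted model", {
  td <- make_continuous_td(n = 100, seed = 30)
  m <- fit_subgroup_model(td, loss_config("continuous", "a_learning"),
                          quick_params(n_rounds = 20))
  expect_identical(tidy(m), biomarker_importance(m))
  g <- glance(m)
  expect_identical(g$n, 100L)
  expect_identical(g$n_rounds, 20L)
  expect_equal(g$final_loss, m$history$loss[20])
})

test_that("models round-trip through save/load", {
  td <- make_binary_td(n = 120, seed = 31)
  cfg <- loss_config("binary", "a_learning")
  m <- fit_subgroup_model(td, cfg, quick_params(n_rounds = 25))
  path <- withr::local_tempfile(fileext = ".ubj")
  save_subgroup_model(m, path)
  m2 <- load_subgroup_model(path)
  expect_identical(predict_score(m2, td$data), predict_score(m, td$data))
  expect_identical(m2$benefit_direction, m$benefit_direction)
  expect_equal(m2$history$loss, m$history$loss)
  expect_equal(evaluate_loss(m2, td), evaluate_loss(m, td))
})

test_that("endpoint mismatches and bad params are rejected", {
  td <- make_continuous_td(n = 30, seed = 32)
  expect_error(fit_subgroup_model(td, loss_config("binary", "a_learning"),
                                  quick_params()),
               "mismatch")
  expect_error(boosting_params(n_rounds = 0), "n_rounds")
  expect_error(boosting_params(learning_rate = 1.5), "learning_rate")
})
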