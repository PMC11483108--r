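#' Boosting hyper-parameters
#'
#' Defaults are the tutorial configuration used throughout the package
#' examples: shallow stumps, small learning rate, L2 penalty 5, 300 rounds,
#' histogram tree method.
#'
#' @param learning_rate Shrinkage per round, in (0, 1].
#' @param max_depth Maximum tree depth.
#' @param reg_lambda L2 regularization on leaf weights.
#' @param n_rounds Number of boosting rounds (>= 1).
#' @param tree_method xgboost tree construction algorithm.
#' @param seed Integer seed for the boosting engine.
#' @param ... Extra parameters passed straight to the engine.
#' @return A `boosting_params` object.
#' @export
boosting_params <- function(learning_rate = 0.01, max_depth = 1,
                            reg_lambda = 5, n_rounds = 300,
                            tree_method = "hist", seed = 0, ...) {
  if (n_rounds < 1) abort("`n_rounds` must be >= 1.")
  if (learning_rate <= 0 || learning_rate > 1) {
    abort("`learning_rate` must lie in (0, 1].")
  }
  if (reg_lambda < 0) abort("`reg_lambda` must be nonnegative.")
  structure(list(learning_rate = learning_rate, max_depth = max_depth,
                 reg_lambda = reg_lambda, n_rounds = as.integer(n_rounds),
                 tree_method = tree_method, seed = as.integer(seed),
                 extra = list(...)),
            class = "boosting_params")
}

# One-hot expand categorical biomarkers; numeric pass through (NA allowed,
# the tree learner routes missing values along its default direction).
# `encoding` re-applies a stored training-time expansion to new data.
encode_biomarkers <- function(data, biomarkers, encoding = NULL) {
  data <- as_tibble(data)
  missing_cols <- setdiff(biomarkers, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Biomarker column(s) missing from data: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (is.null(encoding)) {
    encoding <- lapply(setNames(biomarkers, biomarkers), function(bm) {
      col <- data[[bm]]
      if (is.numeric(col)) list(type = "numeric") else
        list(type = "categorical", levels = sort(unique(as.character(col[!is.na(col)]))))
    })
  }
  cols <- lapply(biomarkers, function(bm) {
    enc <- encoding[[bm]]
    col <- data[[bm]]
    if (enc$type == "numeric") {
      if (!is.numeric(col)) abort(sprintf("Column '%s' must be numeric.", bm))
      m <- matrix(as.numeric(col), ncol = 1,
                  dimnames = list(NULL, bm))
    } else {
      lv <- enc$levels
      m <- sapply(lv, function(l) as.numeric(as.character(col) == l))
      m <- matrix(m, ncol = length(lv),
                  dimnames = list(NULL, paste0(bm, "=", lv)))
      m[is.na(col), ] <- NA_real_
    }
    m
  })
  list(X = do.call(cbind, cols), encoding = encoding)
}

# Map an expanded feature name back to its source biomarker.
feature_to_biomarker <- function(features, encoding) {
  out <- features
  for (bm in names(encoding)) {
    if (encoding[[bm]]$type == "categorical") {
      hit <- features %in% paste0(bm, "=", encoding[[bm]]$levels)
      out[hit] <- bm
    }
  }
  out
}

#' Fit a boosted treatment-contrast model
#'
#' Trains a gradient-boosted tree ensemble for the contrast score f(X) by
#' minimizing the configured modified loss: the analytic gradient/Hessian of
#' [composite_loss()] is supplied to xgboost as a custom objective, with the
#' initial margin fixed at 0. The per-round training loss is recorded.
#'
#' @param td A [trial_data()] object.
#' @param config A [loss_config()] whose endpoint matches the data.
#' @param params A [boosting_params()].
#' @param benefit_direction Which sign of f(X) means "treatment benefits the
#'   patient". Default `"auto"`: positive score for continuous and binary
#'   outcomes (higher outcome better), negative score for survival (f is on
#'   the log-hazard scale, lower hazard better). Override with
#'   `"positive_score"` / `"negative_score"`.
#' @return A `subgroup_model` object with elements `booster`, `config`,
#'   `params`, `feature_names`, `history` (tibble of per-round training
#'   loss), and `benefit_direction`.
#' @export
fit_subgroup_model <- function(td, config, params = boosting_params(),
                               benefit_direction = c("auto", "positive_score",
                                                     "negative_score")) {
  stop_not_trial(td)
  if (!inherits(params, "boosting_params")) {
    abort("`params` must be created with `boosting_params()`.")
  }
  benefit_direction <- match.arg(benefit_direction)
  if (benefit_direction == "auto") {
    benefit_direction <- if (td$endpoint == "survival") "negative_score" else
      "positive_score"
  }
  parts <- loss_parts(td, config) # also validates endpoint match
  enc <- encode_biomarkers(td$data, td$biomarkers)
  dtrain <- xgboost::xgb.DMatrix(enc$X, nthread = 1)

  objective <- function(preds, dtrain) {
    gh <- loss_gradient_parts(parts, preds, config)
    list(grad = gh$g, hess = pmax(gh$h, 1e-16))
  }
  history_env <- new.env()
  history_env$loss <- numeric(0)
  metric <- function(preds, dtrain) {
    val <- mean(parts$wt * contrib_at(parts, preds, config))
    history_env$loss <- c(history_env$loss, val)
    list(metric = "modified_loss", value = val)
  }
  xgb_params <- c(list(learning_rate = params$learning_rate,
                       max_depth = params$max_depth,
                       reg_lambda = params$reg_lambda,
                       tree_method = params$tree_method,
                       base_score = 0, seed = params$seed,
                       nthread = 1),
                  params$extra)
  booster <- xgboost::xgb.train(
    params = do.call(xgboost::xgb.params, xgb_params),
    data = dtrain, nrounds = params$n_rounds,
    objective = objective, custom_metric = metric,
    evals = list(train = dtrain), verbose = 0)

  history <- tibble(round = seq_along(history_env$loss),
                    loss = history_env$loss)
  structure(
    list(booster = booster, config = config, params = params,
         feature_names = td$biomarkers, encoding = enc$encoding,
         history = history, benefit_direction = benefit_direction,
         n = nrow(td$data)),
    class = "subgroup_model")
}

# Per-patient loss contribution at raw scores f (kernel value, pre outer wt).
contrib_at <- function(parts, f, config) {
  v <- parts$mult * f
  if (parts$endpoint == "survival") {
    riskwt <- if (config$inner_weights) parts$wt else rep(1, parts$n)
    rs <- risk_set_stats(parts$time, v, parts$delta_tau, parts$wt, riskwt)
    -parts$delta_tau * (v - rs$lrm)
  } else {
    m_value(parts$endpoint, parts$y, v)
  }
}

#' Predict contrast scores
#'
#' @param model A fitted [fit_subgroup_model()] object.
#' @param newdata A data frame containing the model's biomarker columns (any
#'   order; matched by name), or a `trial_data` object.
#' @return Numeric score per row.
#' @export
predict_score <- function(model, newdata) {
  if (!inherits(model, "subgroup_model")) abort("`model` must be a <subgroup_model>.")
  if (inherits(newdata, "trial_data")) newdata <- newdata$data
  enc <- encode_biomarkers(newdata, model$feature_names, model$encoding)
  as.numeric(predict(model$booster, xgboost::xgb.DMatrix(enc$X, nthread = 1)))
}

#' Assign the individualized treatment rule
#'
#' Recommends `+1` (treatment) when the predicted score lies strictly on the
#' benefit side of zero, `-1` otherwise. A score of exactly 0 — no evidence
#' of benefit — yields `-1`.
#'
#' @inheritParams predict_score
#' @return Integer vector of arm recommendations in `{+1, -1}`.
#' @export
assign_subgroup <- function(model, newdata) {
  s <- predict_score(model, newdata)
  benefit <- if (model$benefit_direction == "positive_score") s > 0 else s < 0
  ifelse(benefit, 1L, -1L)
}

#' Modified loss of a fitted model on a dataset
#'
#' Equals `composite_loss(td, predict_score(model, td), model$config)`.
#'
#' @inheritParams predict_score
#' @param td A `trial_data` object with the model's endpoint.
#' @return A single numeric loss value.
#' @export
evaluate_loss <- function(model, td) {
  stop_not_trial(td)
  composite_loss(td, predict_score(model, td$data), model$config)
}

#' Predictive-biomarker importance ranking
#'
#' Gain-based importance of each biomarker in the fitted ensemble, aggregated
#' over one-hot levels of categorical biomarkers and normalized to sum to 1;
#' split frequency is reported alongside. Rank is dense by descending gain.
#'
#' @param model A fitted `subgroup_model`.
#' @return A tibble with columns `biomarker`, `gain`, `frequency`, `rank`,
#'   sorted by descending gain.
#' @export
biomarker_importance <- function(model) {
  if (!inherits(model, "subgroup_model")) abort("`model` must be a <subgroup_model>.")
  imp <- tryCatch(xgboost::xgb.importance(model = model$booster),
                  error = function(e) NULL)
  if (is.null(imp) || nrow(imp) == 0) {
    abort("No informative splits in the ensemble; importance is undefined.")
  }
  tibble(biomarker = feature_to_biomarker(imp$Feature, model$encoding),
         gain = imp$Gain, frequency = imp$Frequency) |>
    group_by(.data$biomarker) |>
    summarise(gain = sum(.data$gain), frequency = sum(.data$frequency),
              .groups = "drop") |>
    mutate(gain = .data$gain / sum(.data$gain)) |>
    arrange(desc(.data$gain)) |>
    mutate(rank = dense_rank_desc(.data$gain))
}

#' @export
print.subgroup_model <- function(x, ...) {
  cat(sprintf("<subgroup_model> %s endpoint, %s loss, %d rounds\n",
              x$config$endpoint, x$config$loss_type, x$params$n_rounds))
  cat(sprintf("  trained on %d patients, %d biomarkers; final loss %.6g\n",
              x$n, length(x$feature_names),
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @rdname tidy.subgroup_model
#' @export
glance.subgroup_model <- function(x, ...) {
  tibble(n = x$n, n_biomarkers = length(x$feature_names),
         endpoint = x$config$endpoint, loss_type = x$config$loss_type,
         n_rounds = x$params$n_rounds,
         final_loss = x$history$loss[nrow(x$history)])
}

#' Tidy a fitted subgroup model
#'
#' `tidy()` returns the biomarker-importance table; `glance()` returns a
#' one-row model summary.
#'
#' @param x A `subgroup_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.subgroup_model <- function(x, ...) biomarker_importance(x)

#' Save / load a fitted subgroup model
#'
#' The ensemble is written with the boosting engine's native serializer plus
#' a JSON sidecar (`<path>.meta.json`) holding the loss configuration,
#' feature names and encoding, benefit direction, and training history.
#'
#' @param model A `subgroup_model`.
#' @param path Path for the model file.
#' @return `path` invisibly (`save_subgroup_model`); a `subgroup_model`
#'   (`load_subgroup_model`).
#' @export
save_subgroup_model <- function(model, path) {
  xgboost::xgb.save(model$booster, path)
  meta <- list(config = unclass(model$config), params = unclass(model$params),
               feature_names = model$feature_names, encoding = model$encoding,
               history = model$history, benefit_direction = model$benefit_direction,
               n = model$n)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_subgroup_model
#' @export
load_subgroup_model <- function(path) {
  booster <- xgboost::xgb.load(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  tau <- meta$config$tau
  if (length(tau) == 0) tau <- NULL
  cfg <- loss_config(meta$config$endpoint, meta$config$loss_type, tau = tau,
                     inner_weights = isTRUE(meta$config$inner_weights))
  params <- do.call(boosting_params,
                    meta$params[c("learning_rate", "max_depth", "reg_lambda",
                                  "n_rounds", "tree_method", "seed")])
  enc <- lapply(meta$encoding, function(e) {
    e$levels <- as.character(e$levels); e
  })
  structure(list(booster = booster, config = cfg, params = params,
                 feature_names = meta$feature_names, encoding = enc,
                 history = as_tibble(meta$history),
                 benefit_direction = meta$benefit_direction, n = meta$n),
            class = "subgroup_model")
}
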