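#' Run the end-to-end subgroup and biomarker analysis workflow
#'
#' Executes the full pipeline on one dataset: load/validate, fit the boosted
#' contrast model, write ITR subgroup assignments, evaluate the modified
#' loss, rank biomarker importance, evaluate candidate cutoffs on the
#' top-ranked (or configured) biomarker, summarize performance at the
#' selected cutoff, build the arm-by-biomarker-group table, and draw the
#' treatment-contrast and ROC diagnostics. Each step writes its table (CSV)
#' and plot (PNG) under `out_dir`; any failure aborts with the step named.
#' Re-running with an identical config and seed reproduces every numeric
#' output.
#'
#' @param config Path to a JSON/YAML configuration, or an equivalent list.
#'   Recognized fields: `data` (CSV path) or `tutorial = TRUE`; `roles`
#'   (list: `biomarkers`, `trt`, `outcome`, `time`, `event`, `propensity`,
#'   `trt_positive`, `default_propensity`); `endpoint`; `loss_type`;
#'   `params` (list for [boosting_params()]); `biomarker` (cutoff analysis
#'   target, default = top importance); `cutoffs`; `cutoff_direction`;
#'   `cutoff_method`; `k` (contrast-smooth basis dimension); `seed`.
#' @param out_dir Output directory (created if absent). Defaults to
#'   `config$out_dir` or a temporary directory.
#' @param seed Overrides `config$seed`.
#' @return A `run_manifest` object: tibble of steps with output paths and
#'   row counts, plus input checksum, seed, and package versions; also
#'   written to `manifest.json`.
#' @export
run_workflow <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) read_workflow_config(config) else config
  if (!is.list(cfg)) abort("`config` must be a path or a list.")
  out_dir <- out_dir %||% cfg$out_dir %||% tempfile("itrboost_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)

  # ---- pre-flight: load + schema checks before any compute ----
  checksum <- NA_character_
  if (isTRUE(cfg$tutorial)) {
    td <- tutorial_fixture()
  } else {
    if (is.null(cfg$data)) abort("Config must give `data` or `tutorial: true`.")
    roles <- cfg$roles %||% list()
    td <- do.call(load_trial, c(list(path = cfg$data,
                                     endpoint = cfg$endpoint), roles))
    checksum <- unname(tools::md5sum(cfg$data))
  }
  endpoint <- cfg$endpoint %||% td$endpoint
  lcfg <- loss_config(endpoint, cfg$loss_type %||% "a_learning",
                      tau = cfg$tau)
  bp <- do.call(boosting_params,
                modifyList(list(seed = seed), cfg$params %||% list()))

  steps <- list()
  t_all <- Sys.time()
  run_step <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      abort(sprintf("Workflow step '%s' failed: %s", name, conditionMessage(e)))
    })
    steps[[length(steps) + 1]] <<- tibble(
      step = name,
      output = paste(res$outputs %||% NA_character_, collapse = ";"),
      n = res$n %||% NA_integer_)
    res$value
  }
  save_plot <- function(p, path) {
    ok <- tryCatch({
      suppressMessages(ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 120))
      TRUE
    }, error = function(e) FALSE)
    if (ok) path else character(0)
  }
  out <- function(name) file.path(out_dir, name)
  set.seed(seed)

  run_step("validate", function() {
    issues <- validate_trial(td)
    if (nrow(issues)) abort("input data failed validation")
    list(value = NULL, n = nrow(td$data), outputs = character(0))
  })
  model <- run_step("fit", function() {
    m <- fit_subgroup_model(td, lcfg, bp)
    readr::write_csv(m$history, out("training_history.csv"), progress = FALSE)
    list(value = m, n = nrow(td$data), outputs = out("training_history.csv"))
  })
  run_step("subgroups", function() {
    res <- tibble(patient_id = td$patient_id,
                  score = predict_score(model, td$data),
                  recommended_arm = assign_subgroup(model, td$data))
    readr::write_csv(res, out("subgroups.csv"), progress = FALSE)
    list(value = res, n = nrow(res), outputs = out("subgroups.csv"))
  })
  run_step("loss", function() {
    val <- evaluate_loss(model, td)
    jsonlite::write_json(list(modified_loss = val, loss_type = lcfg$loss_type,
                              endpoint = endpoint),
                         out("loss.json"), auto_unbox = TRUE, digits = NA)
    list(value = val, n = nrow(td$data), outputs = out("loss.json"))
  })
  imp <- run_step("importance", function() {
    imp <- biomarker_importance(model)
    readr::write_csv(imp, out("importance.csv"), progress = FALSE)
    p <- save_plot(plot_importance(model), out("importance.png"))
    list(value = imp, n = nrow(imp), outputs = c(out("importance.csv"), p))
  })
  target_bm <- cfg$biomarker %||% imp$biomarker[1]
  cut_method <- cfg$cutoff_method %||%
    switch(endpoint, binary = "fisher", continuous = "two_sample", "logrank")
  cut_dir <- cfg$cutoff_direction %||% "greater"
  cuts <- run_step("fixcut", function() {
    cr <- evaluate_cutoffs(td, target_bm,
                           cutoffs = cfg$cutoffs %||% c(0.1, 0.3, 0.5),
                           direction = cut_dir, method = cut_method)
    readr::write_csv(cr$metrics, out("cutoff_metrics.csv"), progress = FALSE)
    p <- save_plot(autoplot(cr), out("cutoff_metrics.png"))
    list(value = cr, n = nrow(cr$metrics),
         outputs = c(out("cutoff_metrics.csv"), p))
  })
  run_step("cutperf", function() {
    cp <- cutoff_performance(td, target_bm, cutoff = cuts$selected,
                             direction = cut_dir, endpoint = endpoint)
    readr::write_csv(cp$groups, out("cutoff_performance.csv"), progress = FALSE)
    list(value = cp, n = cp$n_used, outputs = out("cutoff_performance.csv"))
  })
  run_step("perf", function() {
    d <- td$data
    x <- d[[target_bm]]
    pos <- if (cut_dir == "greater") x > cuts$selected else x < cuts$selected
    d$biogroup <- ifelse(pos, "biomarker_positive", "biomarker_negative")
    sp <- subgroup_treatment_summary(d, "biogroup", trt = ".trt",
                                     endpoint = endpoint, outcome = td$outcome,
                                     time = td$time, event = td$event)
    readr::write_csv(sp$cells, out("subgroup_cells.csv"), progress = FALSE)
    readr::write_csv(sp$contrasts, out("subgroup_contrasts.csv"), progress = FALSE)
    readr::write_csv(sp$interaction, out("subgroup_interaction.csv"),
                     progress = FALSE)
    list(value = sp, n = sp$n_used,
         outputs = out(c("subgroup_cells.csv", "subgroup_contrasts.csv",
                         "subgroup_interaction.csv")))
  })
  run_step("contrast", function() {
    sc <- smooth_treatment_contrast(td, target_bm, endpoint = endpoint,
                                    k = cfg$k %||% 5)
    readr::write_csv(sc$grid, out("contrast_curve.csv"), progress = FALSE)
    p <- save_plot(autoplot(sc), out("contrast_curve.png"))
    list(value = sc, n = nrow(sc$grid),
         outputs = c(out("contrast_curve.csv"), p))
  })
  if (!is.null(td$outcome) && all(td$data[[td$outcome]] %in% c(0, 1))) {
    run_step("roc", function() {
      rc <- roc_curve(td, target_bm, direction = "auto")
      readr::write_csv(rc$points, out("roc_points.csv"), progress = FALSE)
      p <- save_plot(autoplot(rc), out("roc_curve.png"))
      jsonlite::write_json(list(auc = rc$auc, direction = rc$direction),
                           out("roc.json"), auto_unbox = TRUE, digits = NA)
      list(value = rc, n = rc$n_pos + rc$n_neg,
           outputs = c(out("roc_points.csv"), out("roc.json"), p))
    })
  }

  manifest <- structure(
    list(steps = bind_rows(steps), out_dir = out_dir, seed = seed,
         input = cfg$data %||% "tutorial_fixture", input_md5 = checksum,
         selected_cutoff = cuts$selected, target_biomarker = target_bm,
         elapsed_s = as.numeric(difftime(Sys.time(), t_all, units = "secs")),
         versions = list(
           itrboost = as.character(utils::packageVersion("itrboost")),
           xgboost = as.character(utils::packageVersion("xgboost")),
           r = R.version.string)),
    class = "run_manifest")
  jsonlite::write_json(manifest[setdiff(names(manifest), "steps")] |>
                         c(list(steps = manifest$steps)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

read_workflow_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d steps in %.1fs, outputs under %s\n",
              nrow(x$steps), x$elapsed_s, x$out_dir))
  print(x$steps)
  invisible(x)
}
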