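#' Assemble a two-arm trial dataset
#'
#' Validates and packages a patient-level table for downstream modelling.
#' Treatment arms are recoded internally to `+1` (treatment) / `-1` (control);
#' a missing propensity column is filled with a constant (0.5 by default, the
#' 1:1 randomized-trial value).
#'
#' @param data A data frame with one row per patient.
#' @param biomarkers Character vector of biomarker column names (numeric or
#'   categorical; categorical columns are one-hot expanded at model-fitting
#'   time, original labels are kept for summaries).
#' @param trt Name of the treatment-arm column. Must have exactly two distinct
#'   non-missing values.
#' @param endpoint One of `"continuous"`, `"binary"`, `"survival"`.
#' @param outcome Outcome column (continuous or binary endpoints).
#' @param time,event Follow-up time and event-indicator columns (survival
#'   endpoint). `event = 1` is an observed event, `0` is censored.
#' @param propensity Optional propensity-score column, values in (0, 1).
#' @param default_propensity Constant propensity used when `propensity` is
#'   `NULL`.
#' @param trt_positive The treatment-column value mapped to `+1`. Defaults:
#'   `1` for `{1, -1}` or `{0, 1}` codings (the latter with a warning),
#'   otherwise required.
#' @param id Optional patient-identifier column; row numbers are used when
#'   absent.
#'
#' @return A `trial_data` object: a list with `data` (tibble carrying the
#'   original columns plus `.trt` in `{+1, -1}` and `.pi`), `biomarkers`,
#'   `endpoint`, outcome-role names, `arm_labels`, and `n_dropped` (rows
#'   removed for missing treatment/outcome).
#' @export
#' @examples
#' df <- data.frame(x1 = rnorm(6), arm = rep(c("T", "P"), 3), y = rnorm(6))
#' td <- trial_data(df, biomarkers = "x1", trt = "arm",
#'                  endpoint = "continuous", outcome = "y",
#'                  trt_positive = "T")
#' td$data$.trt
trial_data <- function(data, biomarkers, trt, endpoint,
                       outcome = NULL, time = NULL, event = NULL,
                       propensity = NULL, default_propensity = 0.5,
                       trt_positive = NULL, id = NULL) {
  endpoint <- check_endpoint(endpoint)
  data <- as_tibble(data)

  needed <- c(biomarkers, trt, outcome, time, event, propensity, id)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Column(s) not found in `data`: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(biomarkers)) abort("Biomarker names must be unique.")
  if (endpoint == "survival") {
    if (is.null(time) || is.null(event)) {
      abort("Survival endpoint requires both `time` and `event` columns.")
    }
  } else if (is.null(outcome)) {
    abort(sprintf("%s endpoint requires an `outcome` column.", endpoint))
  }

  outcome_cols <- if (endpoint == "survival") c(time, event) else outcome
  keep <- complete.cases(data[, c(trt, outcome_cols), drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warn(sprintf("Dropped %d row(s) with missing treatment or outcome.", n_dropped))
    data <- data[keep, , drop = FALSE]
  }
  if (nrow(data) < 1) abort("No complete rows remain.")

  arm <- recode_treatment(data[[trt]], trt_positive)
  data$.trt <- arm$trt

  if (is.null(propensity)) {
    if (!is.numeric(default_propensity) || length(default_propensity) != 1 ||
        default_propensity <= 0 || default_propensity >= 1) {
      abort("`default_propensity` must be a single value in (0, 1).")
    }
    data$.pi <- rep(default_propensity, nrow(data))
  } else {
    pi_vals <- data[[propensity]]
    if (any(!is.finite(pi_vals)) || any(pi_vals <= 0) || any(pi_vals >= 1)) {
      abort("Propensity scores must lie strictly inside (0, 1).")
    }
    data$.pi <- pi_vals
  }

  patient_id <- if (is.null(id)) as.character(seq_len(nrow(data))) else
    as.character(data[[id]])

  td <- structure(
    list(data = data, biomarkers = biomarkers, endpoint = endpoint,
         outcome = outcome, time = time, event = event,
         trt_col = trt, propensity_col = propensity,
         arm_labels = arm$labels, patient_id = patient_id,
         n_dropped = n_dropped),
    class = "trial_data")
  issues <- validate_trial(td)
  if (nrow(issues)) {
    abort(paste0("Invalid trial data:\n",
                 paste(utils::capture.output(print(as.data.frame(issues))),
                       collapse = "\n")))
  }
  td
}

# Map a 2-level treatment column onto {+1, -1}.
recode_treatment <- function(x, trt_positive = NULL) {
  vals <- sort(unique(x[!is.na(x)]))
  if (length(vals) != 2) {
    abort(sprintf("Treatment column must have exactly 2 distinct values, found %d.",
                  length(vals)))
  }
  if (is.null(trt_positive)) {
    if (is.numeric(x) && setequal(vals, c(-1, 1))) {
      trt_positive <- 1
    } else if (is.numeric(x) && setequal(vals, c(0, 1))) {
      trt_positive <- 1
      warn("Treatment coded {0, 1}: mapping 1 -> +1 and 0 -> -1.")
    } else {
      abort("Supply `trt_positive`: the treatment label to map to +1.")
    }
  }
  if (!trt_positive %in% vals) {
    abort(sprintf("`trt_positive` value '%s' not found among treatment labels.",
                  trt_positive))
  }
  pos <- vals[match(trt_positive, vals)]
  neg <- setdiff(vals, pos)
  list(trt = ifelse(x == pos, 1L, -1L),
       labels = c(positive = as.character(pos), negative = as.character(neg)))
}

#' Report violations of the trial-data invariants
#'
#' @param td A `trial_data` object.
#' @return A tibble with columns `row`, `column`, `message`; zero rows when
#'   the dataset is valid.
#' @export
validate_trial <- function(td) {
  stop_not_trial(td, "td")
  d <- td$data
  issues <- list()
  add <- function(rows, column, msg) {
    if (length(rows)) {
      issues[[length(issues) + 1]] <<- tibble(row = rows, column = column,
                                              message = msg)
    }
  }
  bad_trt <- which(!d$.trt %in% c(-1L, 1L))
  add(bad_trt, ".trt", "treatment arm must be +1 or -1")
  bad_pi <- which(!is.finite(d$.pi) | d$.pi <= 0 | d$.pi >= 1)
  add(bad_pi, ".pi", "propensity must lie in (0, 1)")

  if (td$endpoint == "binary") {
    y <- d[[td$outcome]]
    add(which(!y %in% c(0, 1)), td$outcome, "binary outcome must be 0 or 1")
  }
  if (td$endpoint == "survival") {
    tm <- d[[td$time]]
    ev <- d[[td$event]]
    add(which(!is.finite(tm) | tm <= 0), td$time, "survival time must be > 0")
    add(which(!ev %in% c(0, 1)), td$event, "event indicator must be 0 or 1")
  }
  if (td$endpoint == "continuous") {
    y <- d[[td$outcome]]
    add(which(!is.finite(y)), td$outcome, "continuous outcome must be finite")
  }
  if (length(issues)) bind_rows(issues) else
    tibble(row = integer(), column = character(), message = character())
}

#' Read a delimited trial table from disk
#'
#' Reads a CSV/TSV file (delimiter chosen by extension) and assembles a
#' [trial_data()] object. Column roles may be given as arguments or collected
#' in a JSON/YAML config file with fields `biomarkers`, `trt`, `endpoint`,
#' and optionally `outcome`, `time`, `event`, `propensity`,
#' `trt_positive`, `default_propensity`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param config Optional path to a JSON or YAML role-configuration file;
#'   explicit arguments override its entries.
#' @inheritParams trial_data
#' @param ... Passed on to [trial_data()].
#' @return A `trial_data` object.
#' @export
load_trial <- function(path, config = NULL, biomarkers = NULL, trt = NULL,
                       endpoint = NULL, ...) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  # base strtod parsing round-trips doubles written at 17 significant digits
  data <- as_tibble(utils::read.delim(path, sep = delim, header = TRUE,
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE))
  roles <- list()
  if (!is.null(config)) roles <- read_roles_config(config)
  args <- modifyList(roles, Filter(Negate(is.null),
                                   c(list(biomarkers = biomarkers, trt = trt,
                                          endpoint = endpoint), list(...))))
  do.call(trial_data, c(list(data = data), args))
}

read_roles_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- c("biomarkers", "trt", "endpoint", "outcome", "time", "event",
               "propensity", "default_propensity", "trt_positive", "id")
  cfg[intersect(names(cfg), allowed)]
}

#' Write a trial dataset to CSV
#'
#' Writes the canonical patient table (original columns plus `.trt` and
#' `.pi`) at full numeric precision, so that re-loading reproduces every
#' finite numeric value exactly.
#'
#' @param td A `trial_data` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(td, path) {
  stop_not_trial(td, "td")
  out <- td$data
  # 17 significant digits round-trips IEEE doubles bit-for-bit
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA_character_
      out[[col]] <- v
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Estimate propensity scores by logistic regression
#'
#' Fits arm ~ biomarkers by logistic regression and replaces `.pi` with the
#' fitted probabilities of assignment to the `+1` arm. Never done silently by
#' any other function: propensities are otherwise taken as supplied.
#'
#' @param td A `trial_data` object.
#' @return `td` with `.pi` replaced by fitted values.
#' @export
estimate_propensity <- function(td) {
  stop_not_trial(td, "td")
  d <- td$data
  X <- d[, td$biomarkers, drop = FALSE]
  fit <- glm((d$.trt + 1) / 2 ~ ., data = X, family = binomial())
  p <- fitted(fit)
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  td$data$.pi <- as.numeric(p)
  td
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("<trial_data> %d patients, %d biomarkers, %s endpoint\n",
              nrow(x$data), length(x$biomarkers), x$endpoint))
  cat(sprintf("  arms: +1 = '%s' (n = %d), -1 = '%s' (n = %d)\n",
              x$arm_labels[["positive"]], sum(x$data$.trt == 1),
              x$arm_labels[["negative"]], sum(x$data$.trt == -1)))
  invisible(x)
}
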