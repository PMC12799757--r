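#' Leave-one-subject-out folds
#'
#' One fold per subject: the fold's test set is that subject's samples and
#' its training set is everyone else's. Folds are returned in order of first
#' appearance of each subject and partition the dataset.
#'
#' @param dataset A `feature_dataset` with at least 2 subjects.
#' @return List of folds, each `list(subject, train, test)` with integer row
#'   indices.
#' @export
lopo_folds <- function(dataset) {
  stopifnot(inherits(dataset, "feature_dataset"))
  subjects <- unique(dataset$subject)
  if (length(subjects) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects", call. = FALSE)
  lapply(subjects, function(s) {
    test <- which(dataset$subject == s)
    list(subject = s, train = setdiff(seq_along(dataset$subject), test),
         test = test)
  })
}

#' Pooled RMSE of age predictions, in days
#'
#' \eqn{\sqrt{\mathrm{mean}((\hat y - y)^2)}} over all predictions pooled
#' across folds, with the hour-scale errors converted to days. This is the
#' expected age-estimation error for an unseen hematoma.
#'
#' @param predictions Data frame with numeric columns `true_hours` and
#'   `predicted_hours` (one row per held-out prediction).
#' @return RMSE in days.
#' @export
rmse_days <- function(predictions) {
  if (is.null(predictions) || nrow(predictions) == 0L)
    stop("no predictions to summarize", call. = FALSE)
  err <- (predictions$predicted_hours - predictions$true_hours) / 24
  sqrt(mean(err^2))
}

#' Age-window deviation summaries across subjects
#'
#' For each window — young (`true age <= threshold`), old (`> threshold`)
#' and the full observation period — computes each subject's mean absolute
#' deviation (MAD, days) over that subject's predictions whose *true* age
#' falls in the window, then reports the across-subject mean `M` and sample
#' standard deviation `SD` (n-1 denominator). Day-7 recordings fall in the
#' young window (boundary inclusive below). A window in which a subject has
#' no predictions simply omits that subject; a window empty for everyone is
#' reported as absent (`NULL`).
#'
#' @param predictions Data frame with columns `subject_id`, `true_hours`,
#'   `predicted_hours`.
#' @param threshold_hours Boundary between the young and old windows.
#' @return Named list (`young`, `old`, `full`); each element is `NULL` or a
#'   list with `M`, `SD` (`NA` for a single subject), `n_subjects`, and the
#'   named vector `per_subject` of MADs in days.
#' @export
window_stats <- function(predictions, threshold_hours = 168) {
  if (is.null(predictions) || nrow(predictions) == 0L)
    stop("no predictions to summarize", call. = FALSE)
  windows <- list(
    young = predictions$true_hours <= threshold_hours,
    old = predictions$true_hours > threshold_hours,
    full = rep(TRUE, nrow(predictions))
  )
  lapply(windows, function(in_w) {
    sub <- predictions[in_w, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    mad <- tapply(abs(sub$predicted_hours - sub$true_hours) / 24,
                  sub$subject_id, mean)
    mad <- mad[!is.na(mad)]
    list(M = mean(mad),
         SD = if (length(mad) > 1L) stats::sd(mad) else NA_real_,
         n_subjects = length(mad),
         per_subject = mad)
  })
}

#' Run one full leave-one-subject-out experiment
#'
#' The evaluation backbone: normalize the recordings with the requested
#' method, form LOPO folds, fit the requested architecture on each training
#' fold, predict the held-out subject, and assemble a cross-validation
#' report. A leakage guard asserts on every fold that the held-out subject
#' contributes no training rows. Fully reproducible from
#' `(recordings, method, architecture, config)`.
#'
#' For the `gender` architecture each training fold is additionally
#' restricted to the held-out subject's sex, and the reported RMSE pools
#' predictions across both sexes into one number.
#'
#' @param recordings List of [recording()]s (pre-injection baselines are
#'   dropped by [normalize()]).
#' @param method Normalization method, see [normalize()].
#' @param architecture `"plain"`, `"hierarchical"` or `"gender"`.
#' @param config A [cv_config()].
#' @param exclude_train Optional character vector of [recording_key()]s
#'   removed from *training* folds only; held-out predictions still cover
#'   every recording.
#' @return An object of class `"cv_report"`: `predictions` (data frame with
#'   `subject_id`, `sex`, `true_hours`, `predicted_hours`, `model_tag`),
#'   `rmse_days`, `per_subject_mad_days`, `window_stats`, `model_tag`,
#'   `method`, `architecture`, `config`.
#' @export
run_experiment <- function(recordings,
                           method = c("divide", "subtract", "raw"),
                           architecture = c("plain", "hierarchical", "gender"),
                           config = cv_config(), exclude_train = NULL) {
  method <- match.arg(method)
  architecture <- match.arg(architecture)
  dataset <- normalize(recordings, method)
  keys <- vapply(Filter(Negate(is_pre_injection), recordings),
                 recording_key, character(1))
  excl_idx <- integer(0)
  if (!is.null(exclude_train) && length(exclude_train) > 0L) {
    unknown <- setdiff(exclude_train, keys)
    if (length(unknown) > 0L)
      stop(sprintf("unknown recording key(s): %s",
                   paste(utils::head(unknown, 3), collapse = ", ")),
           call. = FALSE)
    excl_idx <- which(keys %in% exclude_train)
  }
  folds <- lopo_folds(dataset)
  tag <- sprintf("%s-%s", method, architecture)
  preds <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    train_idx <- setdiff(fold$train, excl_idx)
    if (architecture == "gender") {
      test_sex <- dataset$sex[fold$test[1]]
      train_idx <- train_idx[dataset$sex[train_idx] == test_sex]
    }
    # leakage guard: the held-out subject never contributes training rows
    if (fold$subject %in% dataset$subject[train_idx])
      stop(sprintf("leakage: subject %s appears in its own training fold",
                   fold$subject), call. = FALSE)
    train <- subset_dataset(dataset, train_idx)
    fold_seed <- derive_seed(config$seed, fi)
    pred <- tryCatch(
      fit_and_predict(train, dataset$X[fold$test, , drop = FALSE],
                      dataset$sex[fold$test], architecture, config, fold_seed),
      error = function(e)
        stop(sprintf("fold for subject %s: %s", fold$subject,
                     conditionMessage(e)), call. = FALSE))
    if (config$clip) pred <- pmin(pmax(pred, 0), config$clip_max_hours)
    preds[[fi]] <- data.frame(
      subject_id = dataset$subject[fold$test],
      sex = dataset$sex[fold$test],
      true_hours = dataset$y[fold$test],
      predicted_hours = pred,
      model_tag = tag,
      stringsAsFactors = FALSE
    )
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  ws <- window_stats(predictions, config$threshold_hours)
  structure(
    list(predictions = predictions,
         rmse_days = rmse_days(predictions),
         per_subject_mad_days = ws$full$per_subject,
         window_stats = ws,
         model_tag = tag, method = method, architecture = architecture,
         config = config),
    class = "cv_report"
  )
}

fit_and_predict <- function(train, test_X, test_sex, architecture, config,
                            seed) {
  common <- list(inner_folds = config$inner_folds, rule = config$rule,
                 n_lambda = config$n_lambda,
                 lambda_min_ratio = config$lambda_min_ratio, seed = seed)
  switch(architecture,
    plain = {
      fit <- do.call(fit_lasso, c(list(train), common))
      predict(fit, test_X)
    },
    hierarchical = {
      fit <- do.call(fit_hierarchical,
                     c(list(train), common,
                       list(threshold_hours = config$threshold_hours,
                            gate_variant = config$gate_variant)))
      predict(fit, test_X)
    },
    gender = {
      # training fold is already restricted to the held-out subject's sex
      fit <- do.call(fit_lasso, c(list(train), common))
      predict(fit, test_X)
    })
}

#' Re-run an experiment with flagged recordings excluded from training
#'
#' Mirrors a post-hoc robustness check: recordings with visibly deviating
#' lighting or geometry are removed from the training folds only, while
#' held-out predictions still cover every recording, and the experiment is
#' repeated.
#'
#' @inheritParams run_experiment
#' @param exclude Character vector of [recording_key()]s to drop from
#'   training folds; every key must exist.
#' @return A `"cv_report"`.
#' @export
exclusion_rerun <- function(recordings, exclude,
                            method = c("divide", "subtract", "raw"),
                            architecture = c("plain", "hierarchical", "gender"),
                            config = cv_config()) {
  stopifnot(length(exclude) > 0L)
  run_experiment(recordings, method, architecture, config,
                 exclude_train = exclude)
}

#' Cross-validation configuration
#'
#' @param inner_folds Subject-grouped inner CV folds for λ selection.
#' @param rule λ selection rule, `"min"` or `"1se"` (see [fit_lasso()]).
#' @param n_lambda,lambda_min_ratio λ grid size and lower end.
#' @param threshold_hours Day-7 gate / window boundary (168 h).
#' @param gate_variant Hierarchical gate type, see [fit_hierarchical()].
#' @param clip If `TRUE`, clamp predictions to `[0, clip_max_hours]`;
#'   off by default so error statistics describe the unconstrained model.
#' @param clip_max_hours Upper clip bound (504 h = 21 days).
#' @param seed Master seed for all fold assignments.
#' @return A list of class `"cv_config"`.
#' @export
cv_config <- function(inner_folds = 5L, rule = c("min", "1se"),
                      n_lambda = 100L, lambda_min_ratio = 1e-4,
                      threshold_hours = 168,
                      gate_variant = c("logistic", "regression"),
                      clip = FALSE, clip_max_hours = 504, seed = 1L) {
  structure(
    list(inner_folds = as.integer(inner_folds), rule = match.arg(rule),
         n_lambda = as.integer(n_lambda), lambda_min_ratio = lambda_min_ratio,
         threshold_hours = threshold_hours,
         gate_variant = match.arg(gate_variant),
         clip = isTRUE(clip), clip_max_hours = clip_max_hours,
         seed = as.integer(seed)),
    class = "cv_config"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("LOPO report [%s]: %d predictions, %d subjects\n",
              x$model_tag, nrow(x$predictions),
              length(unique(x$predictions$subject_id))))
  cat(sprintf("  pooled RMSE: %.3f days\n", x$rmse_days))
  for (w in c("young", "old", "full")) {
    s <- x$window_stats[[w]]
    if (!is.null(s))
      cat(sprintf("  %-5s window: M = %.2f, SD = %s d (%d subjects)\n", w,
                  s$M, ifelse(is.na(s$SD), "-", sprintf("%.2f", s$SD)),
                  s$n_subjects))
  }
  invisible(x)
}

#' Serialize a cross-validation report
#'
#' `write_report_json()` embeds the predictions, summary statistics and the
#' config echo; `write_predictions_csv()` writes the flat prediction table.
#'
#' @param report A `"cv_report"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  ws <- lapply(report$window_stats, function(s) {
    if (is.null(s)) return(NULL)
    list(M = s$M, SD = s$SD, n_subjects = s$n_subjects,
         per_subject = as.list(s$per_subject))
  })
  jsonlite::write_json(
    list(model_tag = report$model_tag, method = report$method,
         architecture = report$architecture,
         rmse_days = report$rmse_days, window_stats = ws,
         config = unclass(report$config),
         predictions = report$predictions),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_predictions_csv <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  df <- report$predictions
  df$true_hours <- format(df$true_hours, digits = 15)
  df$predicted_hours <- format(df$predicted_hours, digits = 15)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
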