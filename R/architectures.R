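#' Hierarchical (day-7 gated) age model
#'
#' Hematoma trajectories are biphasic, with intensity changes reversing
#' around day 7; a single linear readout must compromise across both phases.
#' The hierarchical architecture first decides whether a sample is younger
#' or older than `threshold_hours` (168 h = 7 days) and then routes it to a
#' phase-specific regressor:
#'
#' * `gate`: fit on all samples. By default an L1-penalized logistic
#'   classifier of old-vs-young; set `gate_variant = "regression"` for a
#'   Lasso regression whose prediction is thresholded at 168 h instead.
#'   The classifier default matters because ratio-normalized spectra of a
#'   fresh hematoma resemble those of a fully resolved one (both are close
#'   to unaffected skin): a squared-error gate maps that shared corner of
#'   feature space to a mid-range age and misroutes day-0 samples into the
#'   old branch, while the two-phase classifier separates them.
#' * `young`: Lasso fit on samples with `y <= 168`;
#' * `old`: Lasso fit on samples with `y >= 168`.
#'
#' Day-7 samples belong to both branch training sets (boundary inclusive on
#' both sides); a gate output of exactly 168 h routes to the `old` branch.
#'
#' @inheritParams fit_lasso
#' @param threshold_hours Gate threshold (default 168 h = 7 days).
#' @param gate_variant `"logistic"` (L1 logistic classifier, default) or
#'   `"regression"` (thresholded Lasso regression).
#' @param ... Passed to [fit_lasso()] for all three sub-fits.
#' @return An object of class `"hierarchical_fit"` with elements `gate`,
#'   `young`, `old`, `threshold_hours`, `gate_variant`.
#' @export
fit_hierarchical <- function(dataset, lambda_grid = NULL, inner_folds = 5L,
                             threshold_hours = 168,
                             gate_variant = c("logistic", "regression"),
                             seed = 1L, ...) {
  stopifnot(inherits(dataset, "feature_dataset"))
  gate_variant <- match.arg(gate_variant)
  young_idx <- which(dataset$y <= threshold_hours)
  old_idx <- which(dataset$y >= threshold_hours)
  for (nm in c("young", "old")) {
    idx <- if (nm == "young") young_idx else old_idx
    if (length(idx) == 0L)
      stop(sprintf("empty '%s' age stratum", nm), call. = FALSE)
    if (length(unique(dataset$subject[idx])) < 2L)
      stop(sprintf("age stratum '%s' has fewer than 2 subjects", nm),
           call. = FALSE)
  }
  dots <- list(...)
  gate <- if (gate_variant == "regression")
    fit_lasso(dataset, lambda_grid = lambda_grid, inner_folds = inner_folds,
              seed = derive_seed(seed, 1L), ...)
  else
    fit_l1_logistic_gate(dataset, threshold_hours, lambda_grid, inner_folds,
                         seed = derive_seed(seed, 1L),
                         n_lambda = dots$n_lambda %||% 100L,
                         lambda_min_ratio = dots$lambda_min_ratio %||% 1e-4)
  young <- fit_lasso(subset_dataset(dataset, young_idx),
                     lambda_grid = lambda_grid, inner_folds = inner_folds,
                     seed = derive_seed(seed, 2L), ...)
  old <- fit_lasso(subset_dataset(dataset, old_idx),
                   lambda_grid = lambda_grid, inner_folds = inner_folds,
                   seed = derive_seed(seed, 3L), ...)
  structure(
    list(gate = gate, young = young, old = old,
         threshold_hours = threshold_hours, gate_variant = gate_variant),
    class = "hierarchical_fit"
  )
}

# L1-penalized logistic classifier of old (y >= threshold) vs young, with
# the same subject-grouped inner CV as fit_lasso (held-out binomial
# deviance); returns an object whose predict() yields threshold +/- 1 so
# the common >= threshold routing rule applies.
fit_l1_logistic_gate <- function(dataset, threshold_hours, lambda_grid,
                                 inner_folds, seed, n_lambda = 100L,
                                 lambda_min_ratio = 1e-4, thresh = 1e-7) {
  z <- as.numeric(dataset$y >= threshold_hours)
  X <- dataset$X
  n <- nrow(X)
  center <- colMeans(X)
  scale_ <- sqrt(colMeans(sweep(X, 2, center)^2))
  ok_col <- scale_ > 0
  Xs <- sweep(sweep(X[, ok_col, drop = FALSE], 2, center[ok_col]), 2,
              scale_[ok_col], "/")
  lmax <- max(abs(crossprod(Xs, z - mean(z)))) / n
  grid_used <- if (is.null(lambda_grid))
    exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
  else sort(as.numeric(lambda_grid), decreasing = TRUE)
  foldid <- subject_folds(dataset$subject, inner_folds, seed)
  nf <- max(foldid)
  dev <- matrix(NA_real_, nf, length(grid_used))
  for (f in seq_len(nf)) {
    tr <- foldid != f
    if (length(unique(z[tr])) < 2L) next  # one-class fold carries no signal
    fitf <- glmnet::glmnet(X[tr, , drop = FALSE], z[tr], family = "binomial",
                           alpha = 1, lambda = grid_used, standardize = TRUE,
                           thresh = thresh, maxit = 10^6)
    p <- stats::predict(fitf, newx = X[!tr, , drop = FALSE],
                        type = "response")
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    dev[f, seq_len(ncol(p))] <-
      colMeans(-2 * (z[!tr] * log(p) + (1 - z[!tr]) * log(1 - p)))
  }
  cvm <- colMeans(dev, na.rm = TRUE)
  ok <- which(is.finite(cvm))
  if (length(ok) == 0L)
    stop("logistic gate: no inner fold contained both age classes",
         call. = FALSE)
  lambda <- grid_used[ok[which.min(cvm[ok])]]
  fit <- glmnet::glmnet(X, z, family = "binomial", alpha = 1,
                        lambda = grid_used, standardize = TRUE,
                        thresh = thresh, maxit = 10^6)
  k <- which.min(abs(fit$lambda - lambda))
  structure(
    list(intercept = as.numeric(fit$a0[k]),
         coefficients = stats::setNames(as.numeric(fit$beta[, k]),
                                        colnames(X)),
         lambda = lambda, selected_bands = which(fit$beta[, k] != 0),
         threshold_hours = threshold_hours),
    class = "logistic_gate"
  )
}

#' @export
predict.logistic_gate <- function(object, newx, ...) {
  if (is.null(dim(newx))) newx <- matrix(as.numeric(newx), nrow = 1L)
  eta <- drop(object$intercept + newx %*% object$coefficients)
  # map onto the common routing scale: >= threshold means old
  ifelse(eta >= 0, object$threshold_hours + 1, object$threshold_hours - 1)
}

#' @describeIn fit_hierarchical Predict: gate output below the threshold
#'   routes to the `young` branch, at or above it to the `old` branch.
#' @param object A `"hierarchical_fit"`.
#' @param newx Feature vector or matrix as in [predict.lasso_fit()].
#' @export
predict.hierarchical_fit <- function(object, newx, ...) {
  if (is.null(dim(newx))) newx <- matrix(as.numeric(newx), nrow = 1L)
  g <- predict(object$gate, newx)
  out <- numeric(nrow(newx))
  is_old <- g >= object$threshold_hours
  if (any(!is_old)) out[!is_old] <- predict(object$young, newx[!is_old, , drop = FALSE])
  if (any(is_old)) out[is_old] <- predict(object$old, newx[is_old, , drop = FALSE])
  out
}

#' @export
print.hierarchical_fit <- function(x, ...) {
  cat(sprintf("hierarchical age model: %s gate at %g h\n",
              x$gate_variant, x$threshold_hours))
  invisible(x)
}

#' Sex-stratified age model
#'
#' Two Lasso regressions, one fit on each sex's samples; prediction routes
#' by the sample's recorded sex.
#'
#' @inheritParams fit_lasso
#' @param ... Passed to [fit_lasso()] for both sub-fits.
#' @return An object of class `"gender_fit"` with `by_sex`, a list mapping
#'   `"M"`/`"F"` to a `"lasso_fit"`.
#' @export
fit_gender <- function(dataset, lambda_grid = NULL, inner_folds = 5L,
                       seed = 1L, ...) {
  stopifnot(inherits(dataset, "feature_dataset"))
  sexes <- sort(unique(dataset$sex))
  by_sex <- list()
  for (s in sexes) {
    idx <- which(dataset$sex == s)
    if (length(unique(dataset$subject[idx])) < 2L)
      stop(sprintf("sex stratum '%s' has fewer than 2 subjects", s),
           call. = FALSE)
    by_sex[[s]] <- fit_lasso(subset_dataset(dataset, idx),
                             lambda_grid = lambda_grid,
                             inner_folds = inner_folds,
                             seed = derive_seed(seed, match(s, sexes)), ...)
  }
  structure(list(by_sex = by_sex), class = "gender_fit")
}

#' Predict from a sex-stratified model
#'
#' @param fit A `"gender_fit"`.
#' @param newx Feature vector or matrix.
#' @param sex Sex label(s) of the sample(s); must have been present at fit
#'   time.
#' @return Predicted age(s) in hours.
#' @export
predict_gender <- function(fit, newx, sex) {
  stopifnot(inherits(fit, "gender_fit"))
  if (is.null(dim(newx))) newx <- matrix(as.numeric(newx), nrow = 1L)
  sex <- rep_len(as.character(sex), nrow(newx))
  unseen <- setdiff(unique(sex), names(fit$by_sex))
  if (length(unseen) > 0L)
    stop(sprintf("no sub-model for sex '%s'", unseen[1]), call. = FALSE)
  out <- numeric(nrow(newx))
  for (s in unique(sex)) {
    idx <- sex == s
    out[idx] <- predict(fit$by_sex[[s]], newx[idx, , drop = FALSE])
  }
  out
}
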