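#' L1-regularized (Lasso) age regression on spectral bands
#'
#' Fits the penalized least-squares problem
#' \deqn{\min_{\beta_0,\beta}\;\frac{1}{2n}\sum_i (y_i-\beta_0-x_i^\top\beta)^2
#'   + \lambda \|\beta\|_1}
#' on per-band standardized features (the glmnet objective and scaling
#' convention), via [glmnet::glmnet()]. The absolute-value penalty drives
#' most band coefficients to exactly zero, so the fit doubles as a
#' wavelength-band selector. Coefficients are reported on the original
#' feature scale.
#'
#' The penalty weight is chosen by inner cross-validation whose folds group
#' whole subjects, never splitting one subject's recordings across folds —
#' within-subject correlation would otherwise leak into the selection. The
#' grid is log-spaced over `lambda_min_ratio * lambda_max .. lambda_max`,
#' where `lambda_max` is the smallest penalty that zeroes every coefficient.
#' Passing a fixed `lambda` (possibly 0, the ordinary-least-squares limit)
#' skips the inner CV.
#'
#' @param dataset A [normalize()]d `feature_dataset` with at least 2
#'   subjects and non-constant `y` (ages in hours).
#' @param lambda_grid Optional decreasing vector of penalty values; computed
#'   from the data when `NULL`.
#' @param inner_folds Number of subject-grouped inner CV folds (reduced to
#'   the subject count, with a warning, when there are fewer subjects).
#' @param lambda Optional fixed penalty; skips λ selection.
#' @param rule `"min"` (penalty minimizing inner-CV mean squared error) or
#'   `"1se"` (largest penalty within one standard error of that minimum).
#' @param n_lambda,lambda_min_ratio Grid size and lower end relative to
#'   `lambda_max`.
#' @param seed Seed for the fold assignment (the only randomness).
#' @param thresh Coordinate-descent convergence threshold passed to glmnet.
#' @return An object of class `"lasso_fit"`: intercept (hours),
#'   `coefficients` (length `n_bands`, hours per feature unit, original
#'   scale), `lambda`, `selected_bands` (indices of nonzero coefficients),
#'   `standardization` (per-band center/scale at fit time), `lambda_grid`,
#'   inner-CV curve (`cvm`) when λ was selected, and bookkeeping fields.
#' @export
fit_lasso <- function(dataset, lambda_grid = NULL, inner_folds = 5L,
                      lambda = NULL, rule = c("min", "1se"),
                      n_lambda = 100L, lambda_min_ratio = 1e-4,
                      seed = 1L, thresh = 1e-7) {
  stopifnot(inherits(dataset, "feature_dataset"))
  rule <- match.arg(rule)
  X <- dataset$X
  y <- dataset$y
  if (length(unique(y)) < 2L)
    stop("degenerate target: 'y' is constant", call. = FALSE)
  subjects <- unique(dataset$subject)
  if (is.null(lambda) && length(subjects) < 2L)
    stop("at least 2 subjects are required to select lambda", call. = FALSE)
  n <- nrow(X)
  center <- colMeans(X)
  scale_ <- sqrt(colMeans(sweep(X, 2, center)^2))  # glmnet's 1/n convention
  lmax <- lambda_max(X, y, center, scale_)
  if (!is.null(lambda)) {
    lambda <- as.numeric(lambda)
    stopifnot(length(lambda) == 1L, lambda >= 0)
    # glmnet needs a decreasing path to warm-start reliably down to small λ
    path <- if (lambda >= lmax) c(lmax * 1.001, lambda)
            else c(exp(seq(log(lmax), log(max(lambda, lmax * 1e-6)),
                           length.out = 50L)), lambda)
    path <- unique(sort(path, decreasing = TRUE))
    fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                          lambda = path, standardize = TRUE, thresh = thresh,
                          maxit = 10^7)
    k <- length(fit$lambda)
    beta <- as.numeric(fit$beta[, k])
    b0 <- as.numeric(fit$a0[k])
    cvm <- NULL
    grid_used <- path
  } else {
    grid_used <- if (is.null(lambda_grid))
      exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
    else sort(as.numeric(lambda_grid), decreasing = TRUE)
    foldid <- subject_folds(dataset$subject, inner_folds, seed)
    nf <- max(foldid)
    # explicit subject-grouped CV over the fixed grid (unlike cv.glmnet this
    # accepts 2 folds, which LOPO training sets with few subjects require)
    mse <- matrix(NA_real_, nf, length(grid_used))
    for (f in seq_len(nf)) {
      tr <- foldid != f
      fitf <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                             family = "gaussian", alpha = 1,
                             lambda = grid_used, standardize = TRUE,
                             thresh = thresh, maxit = 10^7)
      pred <- stats::predict(fitf, newx = X[!tr, , drop = FALSE])
      mse[f, seq_len(ncol(pred))] <- colMeans((pred - y[!tr])^2)
    }
    cvm <- colMeans(mse)
    ok <- which(is.finite(cvm))
    cvsd <- apply(mse, 2, stats::sd) / sqrt(nf)
    i_min <- ok[which.min(cvm[ok])]
    lambda <- if (rule == "min") grid_used[i_min]
    else max(grid_used[ok][cvm[ok] <= cvm[i_min] + cvsd[i_min]])
    fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                          lambda = grid_used, standardize = TRUE,
                          thresh = thresh, maxit = 10^7)
    k <- which.min(abs(fit$lambda - lambda))
    beta <- as.numeric(fit$beta[, k])
    b0 <- as.numeric(fit$a0[k])
  }
  structure(
    list(intercept = b0, coefficients = stats::setNames(beta, colnames(X)),
         lambda = lambda, selected_bands = which(beta != 0),
         standardization = list(center = center, scale = scale_),
         lambda_grid = grid_used, cvm = cvm, rule = rule,
         n_obs = n, n_subjects = length(subjects), method = dataset$method,
         grid = dataset$grid),
    class = "lasso_fit"
  )
}

# smallest penalty that zeroes every coefficient under glmnet's objective:
# max_j |<x_std_j, y - mean(y)>| / n (zero-variance bands contribute nothing)
lambda_max <- function(X, y, center = colMeans(X),
                       scale_ = sqrt(colMeans(sweep(X, 2, center)^2))) {
  ok <- scale_ > 0
  Xs <- sweep(sweep(X[, ok, drop = FALSE], 2, center[ok]), 2, scale_[ok], "/")
  max(abs(crossprod(Xs, y - mean(y)))) / nrow(X)
}

# deterministic subject-grouped fold assignment
subject_folds <- function(subject, k, seed) {
  subjects <- unique(subject)
  k_eff <- min(as.integer(k), length(subjects))
  if (k_eff < as.integer(k))
    warning(sprintf("reducing inner folds from %d to the subject count %d",
                    as.integer(k), k_eff), call. = FALSE)
  if (k_eff < 2L)
    stop("need at least 2 inner folds (2 subjects)", call. = FALSE)
  perm <- with_seed(derive_seed(seed, 104729L), sample.int(length(subjects)))
  fold_of_subject <- stats::setNames(rep_len(seq_len(k_eff),
                                             length(subjects))[order(perm)],
                                     subjects)
  unname(fold_of_subject[subject])
}

#' Predict hematoma age from a fitted Lasso model
#'
#' Returns \eqn{\beta_0 + x^\top\beta} in hours. Predictions are not clipped
#' to the observation window, so error statistics describe the unconstrained
#' model; negative or >21-day outputs are possible.
#'
#' @param object A `"lasso_fit"`.
#' @param newx Numeric feature vector of length `n_bands`, or a matrix with
#'   that many columns.
#' @param ... Unused.
#' @return Predicted age(s) in hours.
#' @export
predict.lasso_fit <- function(object, newx, ...) {
  if (is.null(dim(newx))) newx <- matrix(as.numeric(newx), nrow = 1L)
  if (ncol(newx) != length(object$coefficients))
    stop(sprintf("feature row has %d bands, fit expects %d",
                 ncol(newx), length(object$coefficients)), call. = FALSE)
  if (!all(is.finite(newx)))
    stop("non-finite feature values", call. = FALSE)
  drop(object$intercept + newx %*% object$coefficients)
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("lasso age model (%s features): lambda = %.4g, %d of %d bands selected\n",
              x$method %||% "?", x$lambda, length(x$selected_bands),
              length(x$coefficients)))
  if (length(x$selected_bands) > 0 && !is.null(x$grid)) {
    wl <- band_to_wavelength(x$selected_bands, x$grid)
    cat("  selected bands:",
        paste(sprintf("%d (%.0f nm)", x$selected_bands, wl), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a model fit to JSON
#'
#' Writes method, penalty, intercept, the nonzero coefficients keyed by band
#' index, the standardization vectors, and (for hierarchical fits) the gate
#' threshold — enough to re-apply the model elsewhere.
#'
#' @param fit A `"lasso_fit"`, `"hierarchical_fit"` or `"gender_fit"`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(fit_to_list(fit), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

fit_to_list <- function(fit) {
  if (inherits(fit, "lasso_fit")) {
    nz <- fit$selected_bands
    list(type = "lasso", method = fit$method, lambda = fit$lambda,
         intercept = fit$intercept,
         coefficients = as.list(stats::setNames(fit$coefficients[nz],
                                                as.character(nz))),
         standardization = fit$standardization,
         n_obs = fit$n_obs, n_subjects = fit$n_subjects, rule = fit$rule)
  } else if (inherits(fit, "hierarchical_fit")) {
    list(type = "hierarchical", threshold_hours = fit$threshold_hours,
         gate_variant = fit$gate_variant,
         gate = fit_to_list(fit$gate), young = fit_to_list(fit$young),
         old = fit_to_list(fit$old))
  } else if (inherits(fit, "gender_fit")) {
    list(type = "gender", by_sex = lapply(fit$by_sex, fit_to_list))
  } else stop("unknown fit class", call. = FALSE)
}
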