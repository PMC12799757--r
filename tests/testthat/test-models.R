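test_that("the penalty-free limit recovers a single-band linear law exactly", {
  ds <- linear_dataset(slope = 24, intercept = 100)
  fit <- fit_lasso(ds, lambda = 0, thresh = 1e-12)
  expect_equal(unname(fit$coefficients[3]), 24, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[-3]), rep(0, 4), tolerance = 1e-6)
  expect_equal(fit$intercept, 100, tolerance = 1e-6)
})

test_that("lambda = 0 coefficients match an ordinary-least-squares oracle", {
  ds <- dense_dataset()
  fit <- fit_lasso(ds, lambda = 0, thresh = 1e-13)
  ols <- stats::lm.fit(cbind(1, ds$X), ds$y)$coefficients
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients), unname(ols[-1]), tolerance = 1e-6)
})

test_that("full shrinkage yields the mean-only model and ignores constant bands", {
  ds <- dense_dataset()
  ds$X[, 3] <- 5  # constant band
  lmax <- hsibruise:::lambda_max(ds$X, ds$y)
  fit <- fit_lasso(ds, lambda = lmax * 1.01)
  expect_equal(fit$intercept, mean(ds$y), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients), rep(0, 5))
  expect_length(fit$selected_bands, 0)
  # a zero-variance band stays at zero for any positive penalty
  fit2 <- fit_lasso(ds, lambda = lmax / 50)
  expect_identical(unname(fit2$coefficients[3]), 0)
  # and the intercept-only model predicts mean(y) everywhere
  expect_equal(unname(predict(fit, ds$X[1:3, ])), rep(mean(ds$y), 3),
               tolerance = 1e-8)
})

test_that("prediction is the affine form and rejects bad input", {
  ds <- dense_dataset()
  fit <- fit_lasso(ds, lambda = 0)
  fit$intercept <- 48
  fit$coefficients[] <- 0
  fit$coefficients[2] <- 240
  x <- rep(0, 5); x[2] <- 0.5
  expect_equal(unname(predict(fit, x)), 168)
  expect_error(predict(fit, c(1, 2)), "bands")
  expect_error(predict(fit, c(x[-1], NaN)), "finite")
})

test_that("degenerate targets and too few subjects are refused", {
  ds <- dense_dataset()
  ds$y[] <- 100
  expect_error(fit_lasso(ds), "constant")
  ds2 <- dense_dataset()
  ds2$subject[] <- "S01"
  expect_error(fit_lasso(ds2), "2 subjects")
  ds3 <- dense_dataset(n_subjects = 3)
  expect_warning(fit_lasso(ds3, inner_folds = 5), "reducing inner folds")
})

test_that("the number of selected bands shrinks as the penalty grows", {
  recs <- small_cohort(seed = 77)
  ds <- normalize(recs, "divide")
  lmax <- hsibruise:::lambda_max(ds$X, ds$y)
  grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 12))
  sizes <- vapply(grid, function(l)
    length(fit_lasso(ds, lambda = l)$selected_bands), integer(1))
  # grid is ordered with decreasing penalty, so counts may only grow
  expect_true(all(diff(sizes) >= 0))
  expect_identical(sizes[1], 0L)
})

test_that("subject-grouped lambda selection is deterministic given the seed", {
  recs <- small_cohort(seed = 13)
  ds <- normalize(recs, "divide")
  f1 <- fit_lasso(ds, inner_folds = 4, seed = 99)
  f2 <- fit_lasso(ds, inner_folds = 4, seed = 99)
  expect_identical(f1$lambda, f2$lambda)
  expect_identical(f1$coefficients, f2$coefficients)
  # inner folds never split a subject
  folds <- hsibruise:::subject_folds(ds$subject, 4, 99)
  expect_true(all(tapply(folds, ds$subject,
                         function(f) length(unique(f))) == 1))
})

test_that("the day-7 gate routes to the matching branch, ties going old", {
  ds <- dense_dataset()
  mk <- function(b0) {
    f <- fit_lasso(ds, lambda = 0)
    f$intercept <- b0; f$coefficients[] <- 0
    f
  }
  hf <- structure(list(gate = mk(100), young = mk(50), old = mk(400),
                       threshold_hours = 168, gate_variant = "regression"),
                  class = "hierarchical_fit")
  x <- rep(0, 5)
  expect_equal(unname(predict(hf, x)), 50)    # gate 100 -> young branch
  hf$gate <- mk(168)
  expect_equal(unname(predict(hf, x)), 400)   # tie at 168 -> old branch
  hf$gate <- mk(400)
  expect_equal(unname(predict(hf, x)), 400)
})

test_that("hierarchical training strata split at 168 h with the boundary in both", {
  recs <- small_cohort(n_subjects = 5, n_male = 3, seed = 31)
  ds <- normalize(recs, "divide")
  # place one sample exactly on the boundary
  ds$y[which.min(abs(ds$y - 168))] <- 168
  hf <- fit_hierarchical(ds, inner_folds = 3, seed = 7)
  expect_s3_class(hf$young, "lasso_fit")
  expect_s3_class(hf$old, "lasso_fit")
  expect_identical(hf$young$n_obs, sum(ds$y <= 168))
  expect_identical(hf$old$n_obs, sum(ds$y >= 168))
  expect_identical(hf$young$n_obs + hf$old$n_obs, length(ds$y) + 1L)
  # routing consistency: when gate and truth agree, the branch predicts
  pred_all <- predict(hf, ds$X)
  g <- predict(hf$gate, ds$X)
  young_idx <- which(g < 168 & ds$y < 168)
  expect_equal(pred_all[young_idx],
               unname(predict(hf$young, ds$X[young_idx, , drop = FALSE])))
  # an empty stratum is named
  ds_young <- structure(ds, class = "feature_dataset")
  keep <- ds$y <= 100
  ds_young <- hsibruise:::subset_dataset(ds, which(keep))
  expect_error(fit_hierarchical(ds_young, inner_folds = 3), "'old'")
})

test_that("an L1 logistic gate is available and routes by class probability", {
  recs <- small_cohort(n_subjects = 5, n_male = 3, seed = 53)
  ds <- normalize(recs, "divide")
  hf <- fit_hierarchical(ds, inner_folds = 3, gate_variant = "logistic",
                         seed = 11)
  expect_s3_class(hf$gate, "logistic_gate")
  pred <- predict(hf, ds$X)
  expect_true(all(is.finite(pred)))
})

test_that("sex-stratified fits train only on their sex and route by label", {
  recs <- small_cohort(n_subjects = 6, n_male = 3, seed = 19)
  ds <- normalize(recs, "divide")
  gf <- fit_gender(ds, inner_folds = 3, seed = 5)
  expect_setequal(names(gf$by_sex), c("M", "F"))
  expect_identical(gf$by_sex$M$n_obs, sum(ds$sex == "M"))
  expect_identical(gf$by_sex$F$n_obs, sum(ds$sex == "F"))
  pm <- predict_gender(gf, ds$X[1, ], "M")
  expect_equal(unname(pm), unname(predict(gf$by_sex$M, ds$X[1, ])))
  expect_error(predict_gender(gf, ds$X[1, ], "X"), "no sub-model")
})

test_that("fits serialize to JSON with nonzero coefficients keyed by band", {
  ds <- dense_dataset()
  fit <- fit_lasso(ds, lambda = 0.5)
  path <- tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::read_json(path)
  expect_identical(back$type, "lasso")
  expect_equal(back$lambda, fit$lambda)
  expect_setequal(names(back$coefficients), as.character(fit$selected_bands))
})
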