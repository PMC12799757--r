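#' Build a model dataset from paired hematoma / skin spectra
#'
#' Produces the three analysis feature sets compared in the pipeline, all
#' defined per band from the hematoma spectrum `h` and the paired
#' adjacent-skin spectrum `s` of the same frame:
#'
#' * `raw`: `h` (no normalization),
#' * `subtract`: `h - s`,
#' * `divide`: `h / s`.
#'
#' Because both ROIs share the frame's illumination, a per-recording gain
#' `g > 0` multiplies `h` and `s` alike: `divide` features are exactly
#' invariant to `g`, while `raw` and `subtract` features scale with it.
#' This gain cancellation is why the ratio normalization is the robust
#' choice under varying lighting. Unaffected tissue maps to 1 under
#' `divide` and to 0 under `subtract`.
#'
#' Pre-injection baselines (`age_hours = NA`) are dropped; all other rows
#' keep their input order, and subject, sex and age labels pass through
#' unchanged.
#'
#' @param recordings List of [recording()] objects on one grid.
#' @param method `"raw"`, `"subtract"` or `"divide"`.
#' @param min_skin Smallest admissible `|s|` per band for `divide`
#'   (reflectance units). Calibrated skin reflectance over 400--1000 nm is
#'   never near zero, so a tiny value signals a broken ROI and is an error,
#'   not clamped.
#' @return An object of class `"feature_dataset"`: list with the feature
#'   matrix `X` (samples x bands, columns `band_0001..`), targets `y` in
#'   hours, `subject` and `sex` vectors, `method`, and the shared `grid`.
#' @export
normalize <- function(recordings, method = c("divide", "subtract", "raw"),
                      min_skin = 1e-6) {
  method <- match.arg(method)
  keep <- Filter(Negate(is_pre_injection), recordings)
  if (length(keep) == 0L)
    stop("no post-injection recordings to normalize", call. = FALSE)
  grid <- keep[[1]]$grid
  nb <- grid$n_bands
  X <- matrix(NA_real_, nrow = length(keep), ncol = nb,
              dimnames = list(NULL, band_cols(nb)))
  for (i in seq_along(keep)) {
    r <- keep[[i]]
    if (r$grid$n_bands != nb)
      stop("all recordings must share one wavelength grid", call. = FALSE)
    X[i, ] <- switch(method,
      raw = r$hematoma,
      subtract = r$hematoma - r$skin,
      divide = {
        bad <- which(abs(r$skin) < min_skin)
        if (length(bad) > 0L)
          stop(sprintf(
            "degenerate skin reference for subject %s at %g h: |skin| < %g in band %d",
            r$subject_id, r$age_hours, min_skin, bad[1]), call. = FALSE)
        r$hematoma / r$skin
      })
  }
  structure(
    list(X = X,
         y = vapply(keep, function(r) r$age_hours, numeric(1)),
         subject = vapply(keep, function(r) r$subject_id, character(1)),
         sex = vapply(keep, function(r) r$sex, character(1)),
         method = method, grid = grid),
    class = "feature_dataset"
  )
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("feature dataset: %d samples x %d bands, method '%s', %d subjects\n",
              nrow(x$X), ncol(x$X), x$method, length(unique(x$subject))))
  invisible(x)
}

# row subset preserving class and metadata
subset_dataset <- function(dataset, idx) {
  structure(
    list(X = dataset$X[idx, , drop = FALSE], y = dataset$y[idx],
         subject = dataset$subject[idx], sex = dataset$sex[idx],
         method = dataset$method, grid = dataset$grid),
    class = "feature_dataset"
  )
}
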