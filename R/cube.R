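#' Hyperspectral reflectance cube
#'
#' A rows x cols x bands array tied to a [wavelength_grid()]. Values are
#' reflectance relative to a white standard (unitless); values above 1 are
#' legitimate under deliberate overexposure and are never clipped.
#'
#' @param data Numeric array of shape rows x cols x n_bands, all finite.
#' @param grid The wavelength grid the third dimension refers to.
#' @return An object of class `"hypercube"`.
#' @export
hypercube <- function(data, grid = wavelength_grid()) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-d array (rows x cols x bands)", call. = FALSE)
  d <- dim(data)
  if (d[1] < 1L || d[2] < 1L)
    stop("cube must have at least one pixel", call. = FALSE)
  if (d[3] != grid$n_bands)
    stop(sprintf("cube has %d bands but the grid declares %d", d[3], grid$n_bands),
         call. = FALSE)
  if (!all(is.finite(data)))
    stop("cube contains non-finite values", call. = FALSE)
  structure(list(data = data, grid = grid), class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hypercube: %d x %d pixels, %d bands (%g-%g nm)\n",
              d[1], d[2], d[3], x$grid$lambda_min, x$grid$lambda_max))
  invisible(x)
}

#' White-reference calibration of raw sensor counts
#'
#' Converts raw digital counts to reflectance against a white standard
#' measured in the same frame: per pixel and band,
#' \eqn{R = (raw - dark) / (white - dark)}. A co-recorded white tile of known
#' flat reflectance makes recordings comparable across lighting conditions.
#' Reflectance above 1 (overexposed target relative to the tile) is retained.
#'
#' @param raw A [hypercube()] of raw counts.
#' @param white Numeric vector of white-reference counts per band.
#' @param dark Optional dark-frame counts per band; defaults to zero.
#' @return A calibrated [hypercube()] of reflectance.
#' @export
calibrate_reflectance <- function(raw, white, dark = NULL) {
  stopifnot(inherits(raw, "hypercube"))
  nb <- raw$grid$n_bands
  white <- as.numeric(white)
  if (length(white) != nb)
    stop(sprintf("white reference has %d bands, expected %d", length(white), nb),
         call. = FALSE)
  if (is.null(dark)) dark <- numeric(nb)
  dark <- as.numeric(dark)
  if (length(dark) != nb)
    stop(sprintf("dark reference has %d bands, expected %d", length(dark), nb),
         call. = FALSE)
  denom <- white - dark
  if (any(!is.finite(denom)) || any(denom <= 0)) {
    bad <- which(!(is.finite(denom) & denom > 0))
    stop(sprintf("white reference not above dark in band(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  out <- raw$data
  for (b in seq_len(nb)) out[, , b] <- (raw$data[, , b] - dark[b]) / denom[b]
  hypercube(out, raw$grid)
}

#' Mean ROI spectrum of a cube
#'
#' Arithmetic per-band mean over the pixels selected by a boolean mask, the
#' step that reduces an imaged region of interest to a single spectrum.
#'
#' @param cube A [hypercube()].
#' @param mask Logical matrix matching the cube's spatial shape, with at
#'   least one `TRUE` pixel.
#' @return Numeric vector of length `n_bands`.
#' @export
extract_mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (!is.matrix(mask) || !identical(dim(mask), d[1:2]))
    stop("mask shape does not match the cube's spatial shape", call. = FALSE)
  mask <- mask & !is.na(mask)
  if (!any(mask))
    stop("ROI mask selects no pixels", call. = FALSE)
  flat <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  colMeans(flat[as.vector(mask), , drop = FALSE])
}
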