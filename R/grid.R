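#' Wavelength grid of a hyperspectral sensor
#'
#' Defines the band-center convention used throughout the package: `n_bands`
#' centers spaced linearly between `lambda_min` and `lambda_max`, with the
#' first and last band sitting exactly on the endpoints, i.e.
#' \deqn{\lambda(b) = \lambda_{min} + (b-1)\,
#'   \frac{\lambda_{max}-\lambda_{min}}{n_{bands}-1}.}
#' The defaults describe a 204-band visible/near-infrared camera covering
#' 400--1000 nm (about 3 nm center spacing, ~7 nm optical resolution), the
#' configuration under which band 165 sits near 885 nm and bands 23--26 near
#' 470 nm.
#'
#' @param n_bands Number of spectral bands (integer, at least 2).
#' @param lambda_min,lambda_max Wavelengths of the first and last band
#'   centers, in nm.
#' @return An object of class `"wavelength_grid"`: a list with elements
#'   `n_bands`, `lambda_min`, `lambda_max` and the precomputed numeric vector
#'   `centers` (strictly increasing, length `n_bands`).
#' @examples
#' g <- wavelength_grid()
#' band_to_wavelength(165, g)   # ~884.7 nm
#' wavelength_to_band(470, g)   # 25
#' @export
wavelength_grid <- function(n_bands = 204L, lambda_min = 400, lambda_max = 1000) {
  n_bands <- as.integer(n_bands)
  if (is.na(n_bands) || n_bands < 2L)
    stop("'n_bands' must be an integer >= 2", call. = FALSE)
  if (!is.finite(lambda_min) || !is.finite(lambda_max) || lambda_min >= lambda_max)
    stop("'lambda_min' must be strictly less than 'lambda_max'", call. = FALSE)
  centers <- lambda_min + (seq_len(n_bands) - 1) *
    (lambda_max - lambda_min) / (n_bands - 1)
  structure(
    list(n_bands = n_bands, lambda_min = lambda_min, lambda_max = lambda_max,
         centers = centers),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("wavelength grid: %d bands, %g-%g nm (spacing %.3f nm)\n",
              x$n_bands, x$lambda_min, x$lambda_max,
              (x$lambda_max - x$lambda_min) / (x$n_bands - 1)))
  invisible(x)
}

#' Convert a 1-based band index to its center wavelength
#'
#' @param b Band index (1-based); may be a vector.
#' @param grid A [wavelength_grid()].
#' @return Center wavelength(s) in nm.
#' @export
band_to_wavelength <- function(b, grid = wavelength_grid()) {
  stopifnot(inherits(grid, "wavelength_grid"))
  b <- as.integer(b)
  if (any(is.na(b)) || any(b < 1L) || any(b > grid$n_bands))
    stop(sprintf("band index out of range 1..%d", grid$n_bands), call. = FALSE)
  grid$centers[b]
}

#' Find the band whose center is nearest a wavelength
#'
#' Ties between two equidistant centers are broken toward the lower index.
#'
#' @param nm Wavelength(s) in nm; must lie within the grid range.
#' @inheritParams band_to_wavelength
#' @return Band index (1-based).
#' @export
wavelength_to_band <- function(nm, grid = wavelength_grid()) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (any(!is.finite(nm)) || any(nm < grid$lambda_min) || any(nm > grid$lambda_max))
    stop(sprintf("wavelength out of range %g..%g nm",
                 grid$lambda_min, grid$lambda_max), call. = FALSE)
  vapply(nm, function(w) which.min(abs(grid$centers - w)), integer(1))
}
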