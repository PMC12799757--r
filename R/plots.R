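#' Band-trajectory panels
#'
#' Normalized intensity of selected wavelengths against hematoma age, one
#' line per subject — the view in which the biphasic ~470 nm course and the
#' early ~885 nm minimum are read off. Requires ggplot2.
#'
#' @param recordings List of [recording()]s.
#' @param wavelengths_nm Wavelengths to plot (nearest band is used).
#' @param method Normalization method, see [normalize()].
#' @param file Optional output path (png/pdf by extension); when `NULL` the
#'   ggplot object is returned unrendered.
#' @return A ggplot object, invisibly when written to file.
#' @export
plot_band_trajectories <- function(recordings, wavelengths_nm = c(470, 885),
                                   method = "divide", file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package", call. = FALSE)
  ds <- normalize(recordings, method)
  bands <- wavelength_to_band(wavelengths_nm, ds$grid)
  df <- do.call(rbind, lapply(seq_along(bands), function(i) {
    data.frame(subject_id = ds$subject, age_days = ds$y / 24,
               value = ds$X[, bands[i]],
               band = sprintf("band %d (%.0f nm)", bands[i],
                              band_to_wavelength(bands[i], ds$grid)),
               stringsAsFactors = FALSE)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = age_days, y = value,
                                        group = subject_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~band, scales = "free_y") +
    ggplot2::labs(x = "hematoma age [days]",
                  y = sprintf("%s-normalized reflectance", method)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 8, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Window-deviation bars
#'
#' Across-subject mean (+/- SD) of the per-subject mean absolute deviation,
#' split into the young (<= 7 d), old (> 7 d) and full windows, for one or
#' more cross-validation reports.
#'
#' @param reports A `"cv_report"` or list of them.
#' @param file Optional output path; when `NULL` the ggplot is returned.
#' @return A ggplot object, invisibly when written to file.
#' @export
plot_window_deviations <- function(reports, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package", call. = FALSE)
  if (inherits(reports, "cv_report")) reports <- list(reports)
  rows <- list()
  for (r in reports) {
    for (w in c("young", "old", "full")) {
      s <- r$window_stats[[w]]
      if (is.null(s)) next
      rows[[length(rows) + 1L]] <- data.frame(
        model = r$model_tag, window = w, M = s$M, SD = s$SD,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$window <- factor(df$window, levels = c("young", "old", "full"),
                      labels = c("≤ 7 d", "> 7 d", "full"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = window, y = M,
                                        fill = model)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = M - SD,
                                        ymax = M + SD),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = "true-age window",
                  y = "per-subject mean absolute deviation [days]") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}
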