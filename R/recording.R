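#' One timepoint's paired hematoma / adjacent-skin spectra
#'
#' The unit of observation of the study design: at each visit the hematoma
#' ROI and an unaffected skin ROI in close proximity are averaged to one
#' spectrum each, sharing the frame's illumination. A pre-injection baseline
#' image carries no age label (`age_hours = NA`) and is excluded from all
#' model datasets; the per-recording skin ROI, not the baseline image, is
#' the normalization reference.
#'
#' @param subject_id Subject identifier (string).
#' @param sex `"M"` or `"F"`.
#' @param age_hours Hematoma age in hours at recording time (non-negative),
#'   or `NA` for a pre-injection baseline.
#' @param hematoma,skin Numeric reflectance vectors on `grid`.
#' @param grid The shared [wavelength_grid()].
#' @return An object of class `"recording"`.
#' @export
recording <- function(subject_id, sex, age_hours, hematoma, skin,
                      grid = wavelength_grid()) {
  stopifnot(inherits(grid, "wavelength_grid"))
  sex <- as.character(sex)
  if (!sex %in% c("M", "F"))
    stop("'sex' must be \"M\" or \"F\"", call. = FALSE)
  if (!is.na(age_hours) && (!is.finite(age_hours) || age_hours < 0))
    stop("'age_hours' must be non-negative (or NA for pre-injection)",
         call. = FALSE)
  hematoma <- as.numeric(hematoma)
  skin <- as.numeric(skin)
  nb <- grid$n_bands
  if (length(hematoma) != nb || length(skin) != nb)
    stop(sprintf("hematoma and skin spectra must both have %d bands", nb),
         call. = FALSE)
  if (!all(is.finite(hematoma)) || !all(is.finite(skin)))
    stop("spectra must be finite", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), sex = sex,
         age_hours = as.numeric(age_hours),
         hematoma = hematoma, skin = skin, grid = grid),
    class = "recording"
  )
}

is_pre_injection <- function(rec) is.na(rec$age_hours)

#' Stable identifier of a recording within a dataset
#'
#' `"<subject_id>@<age_hours>h"`, with `"pre"` for the pre-injection
#' baseline. Used to name recordings in exclusion lists and logs.
#'
#' @param rec A [recording()].
#' @return A string key.
#' @export
recording_key <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (is_pre_injection(rec)) sprintf("%s@pre", rec$subject_id)
  else sprintf("%s@%gh", rec$subject_id, rec$age_hours)
}

band_cols <- function(n_bands) sprintf("band_%04d", seq_len(n_bands))

#' Write recordings to the long-format dataset CSV
#'
#' Two rows per recording (`roi = hematoma` then `roi = skin`) with columns
#' `subject_id, sex, age_hours, roi, band_0001..band_NNNN`. `age_hours` is
#' the empty string for pre-injection baselines. Values are written with 15
#' significant digits, so a write-read cycle reproduces them to double
#' precision.
#'
#' @param recordings List of [recording()] objects on one grid.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_dataset_csv <- function(recordings, path) {
  stopifnot(length(recordings) >= 1L)
  grid <- recordings[[1]]$grid
  nb <- grid$n_bands
  rows <- lapply(recordings, function(r) {
    stopifnot(inherits(r, "recording"))
    if (r$grid$n_bands != nb)
      stop("all recordings must share one wavelength grid", call. = FALSE)
    age <- if (is_pre_injection(r)) "" else format(r$age_hours, digits = 15)
    rbind(
      c(r$subject_id, r$sex, age, "hematoma", format(r$hematoma, digits = 15)),
      c(r$subject_id, r$sex, age, "skin",     format(r$skin,     digits = 15))
    )
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("subject_id", "sex", "age_hours", "roi", band_cols(nb))
  utils::write.csv(as.data.frame(m, stringsAsFactors = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the long-format dataset CSV back into recordings
#'
#' Hematoma and skin rows sharing `(subject_id, age_hours)` are paired into
#' one [recording()]. Unpaired rows, duplicated pairs, or a band count that
#' does not match the declared grid are schema errors.
#'
#' @param path CSV path as written by [write_dataset_csv()].
#' @param grid The [wavelength_grid()] the band columns refer to; its
#'   `n_bands` must match the file's band column count.
#' @return A list of [recording()] objects, in file order of the hematoma
#'   rows.
#' @export
read_dataset_csv <- function(path, grid = wavelength_grid()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character", sex = "character",
                                       roi = "character"))
  need <- c("subject_id", "sex", "age_hours", "roi")
  if (!all(need %in% names(df)))
    stop("dataset CSV missing required columns subject_id, sex, age_hours, roi",
         call. = FALSE)
  bcols <- grep("^band_[0-9]{4}$", names(df), value = TRUE)
  if (length(bcols) != grid$n_bands)
    stop(sprintf("dataset CSV has %d band columns but the grid declares %d",
                 length(bcols), grid$n_bands), call. = FALSE)
  bcols <- sort(bcols)
  if (!all(df$roi %in% c("hematoma", "skin")))
    stop("column 'roi' must be 'hematoma' or 'skin'", call. = FALSE)
  key <- paste(df$subject_id,
               ifelse(is.na(df$age_hours), "pre", format(df$age_hours, digits = 15)),
               sep = "|")
  out <- list()
  seen <- character(0)
  hem_idx <- which(df$roi == "hematoma")
  for (i in hem_idx) {
    k <- key[i]
    if (k %in% seen)
      stop(sprintf("duplicated hematoma/skin pair for '%s'", k), call. = FALSE)
    j <- which(df$roi == "skin" & key == k)
    if (length(j) == 0L)
      stop(sprintf("unpaired hematoma row: no skin row for '%s'", k), call. = FALSE)
    if (length(j) > 1L)
      stop(sprintf("duplicated skin row for '%s'", k), call. = FALSE)
    seen <- c(seen, k)
    out[[length(out) + 1L]] <- recording(
      df$subject_id[i], df$sex[i], df$age_hours[i],
      as.numeric(df[i, bcols]), as.numeric(df[j, bcols]), grid
    )
  }
  orphans <- setdiff(key[df$roi == "skin"], seen)
  if (length(orphans) > 0L)
    stop(sprintf("unpaired skin row(s): %s",
                 paste(utils::head(orphans, 3), collapse = ", ")), call. = FALSE)
  out
}
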