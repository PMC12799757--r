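# Forward model for study-shaped synthetic datasets: first-order chromophore
# kinetics (extravasated blood rising then clearing, its oxygenated fraction
# decaying, bilirubin appearing and resolving) composed with stylized
# Gaussian extinction spectra through a Beer-Lambert attenuation of a smooth
# skin baseline. The shapes are tuned to the qualitative phenomenology the
# analysis relies on -- a ~470 nm reflectance minimum between days 5 and 11
# driven by bilirubin and an early ~885 nm minimum around days 3-5 driven by
# total blood -- not to literature extinction tables.

#' Chromophore kinetics of a resolving hematoma
#'
#' Time courses (t in days) of the three drivers of bruise color change:
#' \deqn{blood(t) = b_0 (1 - e^{-t/\tau_{rise}}) e^{-t/\tau_{decay}}}
#' \deqn{oxy(t) = e^{-t/\tau_{oxy}}}
#' \deqn{bilirubin(t) = c_{bil} (e^{-t/\tau_{slow}} - e^{-t/\tau_{fast}})}
#' Blood pools over ~`tau_rise` days and is cleared on the `tau_decay`
#' scale, peaking at \eqn{\tau_{rise}\log(1+\tau_{decay}/\tau_{rise})}
#' (about 3.6 d at the defaults); its oxygenated fraction decays as
#' hemoglobin deoxygenates; bilirubin, the terminal heme-breakdown pigment,
#' rises with lag and resolves slowly, peaking at
#' \eqn{\log(\tau_{slow}/\tau_{fast})/(1/\tau_{fast}-1/\tau_{slow})}
#' (about 5.5 d). All courses vanish as the hematoma resolves to skin.
#'
#' @param b0 Peak-scale blood attenuation amplitude (unitless optical
#'   density at unit extinction).
#' @param tau_rise,tau_decay,tau_oxy,tau_fast,tau_slow Time constants in
#'   days; `tau_slow > tau_fast`.
#' @param c_bil Bilirubin attenuation amplitude (unitless).
#' @return An object of class `"chromophore_kinetics"`.
#' @export
chromophore_kinetics <- function(b0 = 0.55, tau_rise = 2.5, tau_decay = 8,
                                 tau_oxy = 2, c_bil = 0.25, tau_fast = 3,
                                 tau_slow = 12) {
  taus <- c(tau_rise = tau_rise, tau_decay = tau_decay, tau_oxy = tau_oxy,
            tau_fast = tau_fast, tau_slow = tau_slow)
  if (any(!is.finite(taus)) || any(taus <= 0))
    stop("all time constants must be positive", call. = FALSE)
  if (tau_slow <= tau_fast)
    stop("'tau_slow' must exceed 'tau_fast'", call. = FALSE)
  if (b0 < 0 || c_bil < 0)
    stop("amplitudes must be non-negative", call. = FALSE)
  structure(list(b0 = b0, tau_rise = tau_rise, tau_decay = tau_decay,
                 tau_oxy = tau_oxy, c_bil = c_bil, tau_fast = tau_fast,
                 tau_slow = tau_slow),
            class = "chromophore_kinetics")
}

#' Chromophore concentrations at a time point
#'
#' @param t Hematoma age in days (scalar or vector, non-negative).
#' @param kinetics A [chromophore_kinetics()].
#' @return List with numeric elements `blood`, `oxy_fraction`, `bilirubin`.
#' @export
timecourses <- function(t, kinetics = chromophore_kinetics()) {
  stopifnot(inherits(kinetics, "chromophore_kinetics"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be non-negative (days)", call. = FALSE)
  k <- kinetics
  list(
    blood = k$b0 * (1 - exp(-t / k$tau_rise)) * exp(-t / k$tau_decay),
    oxy_fraction = exp(-t / k$tau_oxy),
    bilirubin = k$c_bil * (exp(-t / k$tau_slow) - exp(-t / k$tau_fast))
  )
}

gaussian_bands <- function(lambda, centers, sigmas, heights) {
  out <- numeric(length(lambda))
  for (i in seq_along(centers))
    out <- out + heights[i] * exp(-((lambda - centers[i]) / sigmas[i])^2 / 2)
  out
}

#' Stylized skin/chromophore optics on a wavelength grid
#'
#' Per-band extinction curves as sums of Gaussian bands, peak-normalized to
#' 1: bilirubin at 465 nm (σ 45), oxyhemoglobin at 542 and 577 nm,
#' deoxyhemoglobin at 556 and 760 nm, plus one broad total-blood
#' near-infrared band at 900 nm (σ 120) shared by both hemoglobin species so
#' the ~885 nm attenuation tracks total blood content. The skin baseline
#' rises smoothly from 0.25 at 400 nm to 0.55 at 1000 nm. These are
#' documented modelling constants, not literature extinction coefficients.
#'
#' @param grid A [wavelength_grid()].
#' @param pathlength_scale Unitless scale multiplying all attenuations.
#' @return An object of class `"optical_model"` with per-band vectors
#'   `skin_baseline`, `eps_oxy`, `eps_deoxy`, `eps_bil`.
#' @export
optical_model <- function(grid = wavelength_grid(), pathlength_scale = 1) {
  stopifnot(inherits(grid, "wavelength_grid"))
  lam <- grid$centers
  s <- function(x) 1 / (1 + exp(-(x - 620) / 90))
  base <- 0.25 + 0.30 * (s(lam) - s(grid$lambda_min)) /
    (s(grid$lambda_max) - s(grid$lambda_min))
  structure(
    list(skin_baseline = base,
         eps_oxy = gaussian_bands(lam, c(542, 577, 900), c(25, 20, 120),
                                  c(1, 0.95, 0.55)),
         eps_deoxy = gaussian_bands(lam, c(556, 760, 900), c(30, 40, 120),
                                    c(1, 0.35, 0.55)),
         eps_bil = gaussian_bands(lam, 465, 45, 1),
         pathlength_scale = pathlength_scale, grid = grid),
    class = "optical_model"
  )
}

# Beer-Lambert optical density per band at age t (days)
attenuation <- function(t, optics, kinetics) {
  tc <- timecourses(t, kinetics)
  optics$pathlength_scale * (
    tc$blood * (tc$oxy_fraction * optics$eps_oxy +
                (1 - tc$oxy_fraction) * optics$eps_deoxy) +
    tc$bilirubin * optics$eps_bil
  )
}

#' Noise-free hematoma reflectance spectrum at a given age
#'
#' \deqn{R(\lambda,t) = skin(\lambda)\,f_{subj}\,
#'   e^{-A(\lambda,t)}}
#' where the attenuation `A` combines blood (split by oxygenated fraction
#' between the two hemoglobin extinction curves) and bilirubin. At `t = 0`
#' the spectrum equals the subject's skin spectrum; as the hematoma resolves
#' it returns to skin.
#'
#' @param t Age in days (scalar).
#' @param subject_factor Per-subject multiplicative intensity factor.
#' @param optics An [optical_model()].
#' @param kinetics A [chromophore_kinetics()].
#' @return Numeric reflectance vector on the optics' grid.
#' @export
hematoma_reflectance <- function(t, subject_factor = 1,
                                 optics = optical_model(),
                                 kinetics = chromophore_kinetics()) {
  stopifnot(inherits(optics, "optical_model"))
  optics$skin_baseline * subject_factor * exp(-attenuation(t, optics, kinetics))
}

#' Noise-free skin-divided band trajectory
#'
#' The value the divide normalization recovers in the noise-free limit:
#' `exp(-A(band, t))`, independent of subject factor and illumination gain.
#' Useful for reading off where a band's reflectance minimum falls.
#'
#' @param t_days Vector of ages in days.
#' @param band Band index (1-based).
#' @inheritParams hematoma_reflectance
#' @return Numeric vector of hematoma/skin ratios along `t_days`.
#' @export
divide_trajectory <- function(t_days, band, optics = optical_model(),
                              kinetics = chromophore_kinetics()) {
  vapply(t_days, function(t) exp(-attenuation(t, optics, kinetics)[band]),
         numeric(1))
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults mirror the study design being emulated: 25 subjects (15 male),
#' recordings daily on days 0--7 then every 48 h to day 21 (15 post-
#' injection timepoints), visit times deviating from the nominal schedule by
#' up to ±2 h, lognormal per-subject intensity variability, a lognormal
#' per-recording illumination gain shared by the hematoma and skin ROIs of
#' one frame, and 1% relative per-band measurement noise.
#'
#' @param n_subjects,n_male Cohort size and number of male subjects.
#' @param schedule_days Strictly increasing acquisition days starting at 0.
#' @param time_jitter_hours Half-width of the uniform visit-time jitter (h);
#'   applied consistently to the generation time and the age label.
#' @param subject_intensity_sd Lognormal σ of the per-subject factor.
#' @param gain_sd Lognormal σ of the per-recording illumination gain.
#' @param noise_sd Relative per-band Gaussian noise SD.
#' @param seed Master seed; each subject draws from a derived sub-stream, so
#'   enlarging the cohort leaves existing subjects unchanged.
#' @param grid,kinetics,optics Forward-model components.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_subjects = 25L, n_male = 15L,
                             schedule_days = c(0:7, seq(9, 21, by = 2)),
                             time_jitter_hours = 2, subject_intensity_sd = 0.3,
                             gain_sd = 0.15, noise_sd = 0.01, seed = 1L,
                             grid = wavelength_grid(),
                             kinetics = chromophore_kinetics(),
                             optics = optical_model(grid)) {
  n_subjects <- as.integer(n_subjects); n_male <- as.integer(n_male)
  if (is.na(n_subjects) || n_subjects < 1L)
    stop("invalid config field 'n_subjects'", call. = FALSE)
  if (is.na(n_male) || n_male < 0L || n_male > n_subjects)
    stop("invalid config field 'n_male' (must be 0..n_subjects)", call. = FALSE)
  if (length(schedule_days) < 1L || schedule_days[1] != 0 ||
      is.unsorted(schedule_days, strictly = TRUE))
    stop("invalid config field 'schedule_days' (strictly increasing, starting at 0)",
         call. = FALSE)
  for (f in c("time_jitter_hours", "subject_intensity_sd", "gain_sd", "noise_sd")) {
    v <- get(f)
    if (!is.finite(v) || v < 0)
      stop(sprintf("invalid config field '%s'", f), call. = FALSE)
  }
  structure(
    list(n_subjects = n_subjects, n_male = n_male,
         schedule_days = schedule_days,
         time_jitter_hours = time_jitter_hours,
         subject_intensity_sd = subject_intensity_sd,
         gain_sd = gain_sd, noise_sd = noise_sd, seed = as.integer(seed),
         grid = grid, kinetics = kinetics, optics = optics),
    class = "generator_config"
  )
}

#' Generate a synthetic study cohort
#'
#' For each subject: one pre-injection baseline recording (skin only, no age
#' label) and one recording per schedule point. Both ROI spectra of a frame
#' share that frame's illumination gain and carry independent per-band
#' relative Gaussian noise. Deterministic given the config seed.
#'
#' @param config A [generator_config()].
#' @return List of [recording()]s (pre-injection first within each subject).
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  nb <- config$grid$n_bands
  out <- vector("list",
                config$n_subjects * (length(config$schedule_days) + 1L))
  pos <- 1L
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", i)
    sex <- if (i <= config$n_male) "M" else "F"
    with_seed(derive_seed(config$seed, i), {
      subject_factor <- exp(stats::rnorm(1, 0, config$subject_intensity_sd))
      skin_true <- config$optics$skin_baseline * subject_factor
      make_frame <- function(age_days_or_na) {
        g <- exp(stats::rnorm(1, 0, config$gain_sd))
        if (is.na(age_days_or_na)) {
          hem_true <- skin_true
          age_hours <- NA_real_
        } else {
          jit <- stats::runif(1, -config$time_jitter_hours,
                              config$time_jitter_hours)
          age_hours <- max(0, age_days_or_na * 24 + jit)
          hem_true <- hematoma_reflectance(age_hours / 24, subject_factor,
                                           config$optics, config$kinetics)
        }
        hem <- hem_true * g * (1 + stats::rnorm(nb, 0, config$noise_sd))
        skin <- skin_true * g * (1 + stats::rnorm(nb, 0, config$noise_sd))
        recording(sid, sex, age_hours, hem, skin, config$grid)
      }
      out[[pos]] <- make_frame(NA_real_)
      pos <- pos + 1L
      for (d in config$schedule_days) {
        out[[pos]] <- make_frame(d)
        pos <- pos + 1L
      }
    })
  }
  out
}

#' Render a recording as an imaged cube with ROI masks
#'
#' Places the hematoma spectrum inside a centered disk and the skin spectrum
#' outside it, optionally with per-pixel relative noise, and returns masks
#' such that [extract_mean_spectrum()] recovers the recording's spectra
#' (exactly when `noise_sd = 0`). The skin mask keeps a 2-pixel guard ring
#' around the disk. Exercises the imaging path (ENVI I/O, calibration
#' geometry) end to end.
#'
#' @param rec A [recording()].
#' @param shape Integer `c(rows, cols)` of the frame.
#' @param disk_radius Hematoma disk radius in pixels; the disk must fit in
#'   the frame.
#' @param noise_sd Relative per-pixel, per-band Gaussian noise SD.
#' @param seed Seed for the pixel noise.
#' @return List with elements `cube` ([hypercube()]), `hematoma_mask`,
#'   `skin_mask` (logical matrices).
#' @export
render_cube <- function(rec, shape = c(48L, 48L), disk_radius = 10,
                        noise_sd = 0, seed = 1L) {
  stopifnot(inherits(rec, "recording"))
  shape <- as.integer(shape)
  if (disk_radius <= 0 || 2 * disk_radius + 4 > min(shape))
    stop(sprintf("disk of radius %g does not fit a %d x %d frame (needs a 2-pixel guard)",
                 disk_radius, shape[1], shape[2]), call. = FALSE)
  cy <- (shape[1] + 1) / 2; cx <- (shape[2] + 1) / 2
  d2 <- outer((seq_len(shape[1]) - cy)^2, (seq_len(shape[2]) - cx)^2, `+`)
  hem_mask <- d2 <= disk_radius^2
  skin_mask <- d2 > (disk_radius + 2)^2
  nb <- rec$grid$n_bands
  arr <- array(NA_real_, dim = c(shape[1], shape[2], nb))
  for (b in seq_len(nb))
    arr[, , b] <- ifelse(hem_mask, rec$hematoma[b], rec$skin[b])
  if (noise_sd > 0)
    arr <- with_seed(derive_seed(seed, 813L),
                     arr * (1 + stats::rnorm(length(arr), 0, noise_sd)))
  list(cube = hypercube(arr, rec$grid),
       hematoma_mask = hem_mask, skin_mask = skin_mask)
}
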