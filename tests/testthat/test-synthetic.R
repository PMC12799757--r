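test_that("chromophore timecourses honor initial conditions, limits and maxima", {
  k <- chromophore_kinetics()
  tc0 <- timecourses(0, k)
  expect_equal(tc0$blood, 0)
  expect_equal(tc0$bilirubin, 0)
  expect_equal(tc0$oxy_fraction, 1)
  tcinf <- timecourses(1e4, k)
  expect_lt(tcinf$blood, 1e-12)
  expect_lt(abs(tcinf$bilirubin), 1e-12)
  expect_lt(tcinf$oxy_fraction, 1e-12)
  expect_true(all(timecourses(seq(0, 30, 0.5), k)$bilirubin >= 0))
  # closed-form argmax positions, cross-checked by dense grid search
  tt <- seq(0, 30, by = 1e-3)
  tc <- timecourses(tt, k)
  t_blood <- k$tau_rise * log(1 + k$tau_decay / k$tau_rise)
  t_bil <- log(k$tau_slow / k$tau_fast) / (1 / k$tau_fast - 1 / k$tau_slow)
  expect_equal(tt[which.max(tc$blood)], t_blood, tolerance = 2e-3)
  expect_equal(tt[which.max(tc$bilirubin)], t_bil, tolerance = 2e-3)
  expect_equal(t_blood, 3.5877, tolerance = 1e-4)
  expect_equal(t_bil, 5.5452, tolerance = 1e-4)
  expect_error(timecourses(-1, k), "non-negative")
  expect_error(chromophore_kinetics(tau_fast = 5, tau_slow = 4), "tau_slow")
})

test_that("hematoma reflectance starts at skin and resolves back within 5%", {
  opt <- optical_model()
  kin <- chromophore_kinetics()
  expect_equal(hematoma_reflectance(0, 1.3, opt, kin),
               opt$skin_baseline * 1.3)
  r21 <- hematoma_reflectance(21, 1, opt, kin)
  expect_true(all(abs(r21 / opt$skin_baseline - 1) < 0.05))
  expect_true(all(opt$skin_baseline > 0))
  expect_true(all(opt$eps_oxy >= 0 & opt$eps_deoxy >= 0 & opt$eps_bil >= 0))
})

test_that("divide-normalized minima land in the reported day windows", {
  g <- wavelength_grid()
  opt <- optical_model(g)
  kin <- chromophore_kinetics()
  t <- seq(0, 21, by = 0.25)
  b470 <- wavelength_to_band(470, g)
  b885 <- wavelength_to_band(885, g)
  t470 <- t[which.min(divide_trajectory(t, b470, opt, kin))]
  t885 <- t[which.min(divide_trajectory(t, b885, opt, kin))]
  expect_gte(t470, 5); expect_lte(t470, 11)
  expect_gte(t885, 3); expect_lte(t885, 5)
  # the 885 nm course recovers monotonically toward skin after its minimum
  tail_ <- divide_trajectory(seq(t885, 21, by = 0.5), b885, opt, kin)
  expect_true(all(diff(tail_) > 0))
})

test_that("hematoma-to-skin spectral distance eventually shrinks monotonically", {
  opt <- optical_model()
  kin <- chromophore_kinetics()
  t <- seq(6, 21, by = 0.5)  # past both attenuation peaks
  d <- vapply(t, function(ti)
    sqrt(sum((hematoma_reflectance(ti, 1, opt, kin) - opt$skin_baseline)^2)),
    numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("the default cohort has the study shape: 25 subjects x 15 timepoints", {
  cfg <- generator_config(seed = 123)
  expect_identical(cfg$n_subjects, 25L)
  expect_identical(cfg$n_male, 15L)
  expect_length(cfg$schedule_days, 15)
  recs <- generate_dataset(cfg)
  post <- Filter(function(r) !is.na(r$age_hours), recs)
  pre <- Filter(function(r) is.na(r$age_hours), recs)
  expect_length(post, 375)
  expect_length(pre, 25)
  sex <- vapply(recs, `[[`, "", "sex")
  sid <- vapply(recs, `[[`, "", "subject_id")
  expect_identical(length(unique(sid[sex == "M"])), 15L)
  expect_identical(length(unique(sid[sex == "F"])), 10L)
  ages <- vapply(post, `[[`, 1, "age_hours")
  expect_true(all(ages >= 0 & ages <= 21 * 24 + 2))
  # jitter keeps every visit within 2 h of its nominal schedule slot
  nominal <- rep(cfg$schedule_days * 24, times = 25)
  expect_true(all(abs(sort(ages) - sort(nominal)) <= 2 + 1e-9))
})

test_that("generation is deterministic and subjects have independent streams", {
  a <- generate_dataset(generator_config(n_subjects = 3, n_male = 2, seed = 5))
  b <- generate_dataset(generator_config(n_subjects = 3, n_male = 2, seed = 5))
  expect_identical(a, b)
  # enlarging the cohort must not perturb existing subjects
  big <- generate_dataset(generator_config(n_subjects = 5, n_male = 2, seed = 5))
  expect_identical(big[seq_along(a)], a)
  # a different seed changes the draws
  c_ <- generate_dataset(generator_config(n_subjects = 3, n_male = 2, seed = 6))
  expect_false(identical(a, c_))
})

test_that("the per-recording gain hits both ROIs while divide features ignore it", {
  base <- generator_config(n_subjects = 2, n_male = 1, time_jitter_hours = 0,
                           noise_sd = 0, gain_sd = 0, seed = 8)
  gained <- generator_config(n_subjects = 2, n_male = 1, time_jitter_hours = 0,
                             noise_sd = 0, gain_sd = 0.3, seed = 8)
  r0 <- generate_dataset(base)
  r1 <- generate_dataset(gained)
  d0 <- normalize(r0, "divide"); d1 <- normalize(r1, "divide")
  expect_equal(d1$X, d0$X, tolerance = 1e-12)
  raw0 <- normalize(r0, "raw"); raw1 <- normalize(r1, "raw")
  expect_gt(max(abs(raw1$X - raw0$X)), 1e-3)
})

test_that("invalid generator fields are rejected by name", {
  expect_error(generator_config(n_male = 30), "n_male")
  expect_error(generator_config(schedule_days = c(1, 2)), "schedule_days")
  expect_error(generator_config(schedule_days = c(0, 2, 2)), "schedule_days")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
})

test_that("rendered cubes reproduce the recording under the returned masks", {
  recs <- small_cohort(n_subjects = 1, schedule = c(0, 5), seed = 4)
  rec <- recs[[3]]
  rc <- render_cube(rec, shape = c(40, 40), disk_radius = 8)
  expect_equal(extract_mean_spectrum(rc$cube, rc$hematoma_mask), rec$hematoma)
  expect_equal(extract_mean_spectrum(rc$cube, rc$skin_mask), rec$skin)
  expect_false(any(rc$hematoma_mask & rc$skin_mask))
  # with pixel noise the recovery holds to the noise scale
  rcn <- render_cube(rec, shape = c(40, 40), disk_radius = 8,
                     noise_sd = 0.01, seed = 2)
  expect_equal(extract_mean_spectrum(rcn$cube, rcn$hematoma_mask),
               rec$hematoma, tolerance = 0.01)
  expect_error(render_cube(rec, shape = c(16, 16), disk_radius = 8),
               "does not fit")
})
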