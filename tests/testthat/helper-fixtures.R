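# Small deterministic fixtures built in code.

# compact synthetic cohort for fast model tests
small_cohort <- function(n_subjects = 4, n_male = ceiling(n_subjects / 2),
                         schedule = c(0:7, seq(9, 21, by = 2)),
                         noise_sd = 0.01, gain_sd = 0.15, jitter = 2,
                         seed = 42) {
  generate_dataset(generator_config(
    n_subjects = n_subjects, n_male = n_male, schedule_days = schedule,
    time_jitter_hours = jitter, gain_sd = gain_sd, noise_sd = noise_sd,
    seed = seed))
}

# hand-built recording on a tiny grid
toy_recording <- function(h, s, subject = "S01", sex = "M", age = 24) {
  g <- wavelength_grid(length(h), 400, 1000)
  recording(subject, sex, age, h, s, g)
}

# feature dataset with a known linear signal in one band:
# y = slope * x[, band] + intercept, all other bands constant zero
linear_dataset <- function(n = 120, n_bands = 5, band = 3, slope = 24,
                           intercept = 100, n_subjects = 6, seed = 11) {
  set.seed(seed)
  X <- matrix(0, n, n_bands, dimnames = list(NULL, sprintf("band_%04d", 1:n_bands)))
  X[, band] <- runif(n, 0, 10)
  y <- slope * X[, band] + intercept
  structure(list(X = X, y = y,
                 subject = sprintf("S%02d", rep_len(seq_len(n_subjects), n)),
                 sex = rep_len(c("M", "F"), n), method = "raw",
                 grid = wavelength_grid(n_bands, 400, 1000)),
            class = "feature_dataset")
}

# well-conditioned multi-band regression problem (n >> p) for OLS checks
dense_dataset <- function(n = 200, n_bands = 5, n_subjects = 8, seed = 5) {
  set.seed(seed)
  X <- matrix(rnorm(n * n_bands), n, n_bands,
              dimnames = list(NULL, sprintf("band_%04d", 1:n_bands)))
  beta <- c(10, -6, 0, 3, 1)
  y <- drop(50 + X %*% beta + rnorm(n, 0, 2))
  structure(list(X = X, y = y,
                 subject = sprintf("S%02d", rep_len(seq_len(n_subjects), n)),
                 sex = rep_len(c("M", "F"), n), method = "raw",
                 grid = wavelength_grid(n_bands, 400, 1000)),
            class = "feature_dataset")
}
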