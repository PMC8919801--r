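# Shared fixtures, built in code. Heavy objects are memoised so several
# test files can reuse them without regenerating.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# a noiseless 2 Hz, 15 s recording: 30 exact parabolic cycles
clean_recording <- function() {
  memo("clean_recording", generate_tapping_recording(
    phenotype_params(tap_rate_hz = 2, period_cv = 0, amp_cv = 0,
                     amp_slope = 0),
    seed = 42))
}

# its tapping signal without filtering (exact parabolic cycles preserved)
clean_signal <- function() {
  memo("clean_signal", preprocess_recording(
    clean_recording()$recording,
    preprocess_config(lowpass_hz = NULL, outlier_threshold = NULL)))
}

# hand-built landmark recording from explicit index/thumb coordinates
make_recording <- function(ix, iy, tx, ty, fs = 30, conf = NULL) {
  n <- length(ix)
  if (is.null(conf)) conf <- rep(1, n)
  structure(list(
    fs = fs, hand = "dominant", subject_id = "T1", session_id = 1L,
    segment = c(1L, n),
    landmarks = data.frame(
      frame = rep(seq_len(n), 3),
      landmark = rep(c("index_tip", "thumb_tip", "wrist"), each = n),
      x = c(ix, tx, rep(0, n)), y = c(iy, ty, rep(0, n)),
      confidence = rep(conf, 3), stringsAsFactors = FALSE)
  ), class = "landmark_recording")
}

# hand-built tapping signal (bypasses preprocessing entirely)
make_signal <- function(amplitude, fs = 30) {
  structure(list(fs = fs, t = (seq_along(amplitude) - 1) / fs,
                 amplitude = amplitude,
                 velocity = numeric(length(amplitude)),
                 acceleration = numeric(length(amplitude)),
                 jerk = numeric(length(amplitude)),
                 qc = list()), class = "tapping_signal")
}

# hand-built alternating event sequence from peak/trough vectors
make_events <- function(peak_t, peak_a, trough_t, trough_a) {
  structure(list(peak_t = peak_t, peak_a = peak_a,
                 trough_t = trough_t, trough_a = trough_a),
            class = "tap_events")
}

# small mixed cohort reused by model and pipeline tests
small_cohort <- function() {
  memo("small_cohort", generate_cohort(
    cohort_spec(n_ataxia = 16, n_parkinsonism = 0, n_control = 16,
                seed = 11)))
}

small_cohort_features <- function() {
  memo("small_cohort_features", cohort_features(small_cohort(), "canonical"))
}

# independent brute-force leave-one-out cubic oracle: same neighbour
# rule, but fitted with lm() on a cubic polynomial basis
oracle_loo_deviance <- function(y) {
  n <- length(y)
  valid <- which(is.finite(y))
  dev <- rep(NA_real_, n)
  for (i in valid) {
    nb <- valid[valid != i]
    nb <- nb[order(abs(nb - i), nb)][1:4]
    df <- data.frame(x = nb - i, y = y[nb])
    fit <- lm(y ~ x + I(x^2) + I(x^3), data = df)
    dev[i] <- abs(y[i] - predict(fit, data.frame(x = 0)))
  }
  dev
}
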