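#' Index-thumb distance series from a landmark recording
#'
#' Per-frame Euclidean distance between the index fingertip and the thumb
#' tip. Frames where either landmark is missing, or has confidence below
#' `conf_floor`, are missing (`NA`) in the output.
#'
#' @param rec A `landmark_recording` (see [generate_tapping_recording()]
#'   or [read_landmark_csv()]).
#' @param conf_floor Confidence below this value is treated as missing.
#' @return Numeric vector of distances in pixels, `NA` where missing.
#' @export
compute_distance_series <- function(rec, conf_floor = 0.1) {
  lm <- rec$landmarks
  idx <- lm[lm$landmark == "index_tip", ]
  thb <- lm[lm$landmark == "thumb_tip", ]
  frames <- sort(unique(lm$frame))
  idx <- idx[match(frames, idx$frame), ]
  thb <- thb[match(frames, thb$frame), ]
  d <- sqrt((idx$x - thb$x)^2 + (idx$y - thb$y)^2)
  bad <- !is.finite(d) |
    (!is.na(idx$confidence) & idx$confidence < conf_floor) |
    (!is.na(thb$confidence) & thb$confidence < conf_floor)
  d[bad] <- NA_real_
  if (mean(!is.na(d)) < 0.5) {
    tapkin_error(sprintf(
      "index/thumb landmarks present for only %.0f%% of frames (need >= 50%%)",
      100 * mean(!is.na(d))), "tapkin_insufficient_data")
  }
  d
}

# Leave-one-out cubic estimate of each sample from its 4 nearest valid
# neighbours. Fast stencil for fully observed interiors; a generic local
# polynomial fit (exact Lagrange through 4 points) elsewhere.
loo_cubic_estimate <- function(y) {
  n <- length(y)
  est <- rep(NA_real_, n)
  valid <- which(is.finite(y))
  if (length(valid) < 5) {
    tapkin_error("need at least 8 samples (5 valid) for leave-one-out screening",
                 "tapkin_insufficient_data")
  }
  # fast symmetric stencil wherever the i-2..i+2 window is fully observed;
  # generic nearest-neighbour fit at edges and around missing samples
  v <- is.finite(y)
  i <- 3:(n - 2)
  ok <- i[v[i] & v[i - 2] & v[i - 1] & v[i + 1] & v[i + 2]]
  est[ok] <- (-y[ok - 2] + 4 * y[ok - 1] + 4 * y[ok + 1] - y[ok + 2]) / 6
  todo <- setdiff(valid, ok)
  for (i in todo) est[i] <- loo_est_one(y, valid, i)
  est
}

# cubic through the 4 nearest valid neighbours of i (i held out),
# evaluated at i; exact Lagrange form
loo_est_one <- function(y, valid, i) {
  nb <- valid[valid != i]
  if (length(nb) < 4) return(NA_real_)
  nb <- nb[order(abs(nb - i), nb)][1:4]
  xs <- nb - i                         # centre for conditioning
  v <- 0
  for (j in 1:4) {
    others <- xs[-j]
    v <- v + y[nb[j]] * prod(-others) / prod(xs[j] - others)
  }
  v
}

#' Leave-one-out cubic outlier screening
#'
#' Each sample is held out in turn and re-estimated by the cubic
#' polynomial through its four nearest valid neighbours; the absolute
#' difference between the observed and re-estimated value is the
#' sample's outlier deviance. The threshold is `threshold` times the
#' median deviance of the series (with a floating-point floor so an
#' analytically smooth series is never flagged). Masking proceeds one
#' sample at a time, worst first, among the first-pass suspects: after
#' a sample is removed, the deviances of the remaining suspects near it
#' are re-estimated without it, so a large spike does not drag its
#' neighbours into the mask — but re-estimation never recruits samples
#' that passed the first screen. Boundary samples use one-sided
#' neighbour sets.
#'
#' @param series Numeric vector, possibly with `NA`.
#' @param threshold Robust threshold in multiples of the median absolute
#'   deviance.
#' @return List with `deviance` (the first-pass per-sample deviance,
#'   `NA` at missing samples), `mask` (logical, `TRUE` = flagged
#'   outlier) and `series` with flagged samples set to `NA`.
#' @export
#' @examples
#' y <- sin(seq(0, 4 * pi, length.out = 100))
#' y[50] <- y[50] + 10
#' which(detect_outliers(y)$mask)
detect_outliers <- function(series, threshold = 6) {
  n <- length(series)
  if (sum(is.finite(series)) < 8) {
    tapkin_error("series too short for outlier screening (need >= 8 valid samples)",
                 "tapkin_insufficient_data")
  }
  est <- loo_cubic_estimate(series)
  dev0 <- abs(series - est)
  med <- median(dev0, na.rm = TRUE)
  floor_dev <- sqrt(.Machine$double.eps) * diff(range(series, na.rm = TRUE))
  cut <- max(threshold * med, floor_dev)

  # masking is confined to first-pass suspects: removing a sample and
  # re-estimating its neighbours may clear a suspect (a spike inflates
  # its neighbours' first-pass deviances) but never recruits new ones
  work <- series
  dev <- dev0
  mask <- rep(FALSE, n)
  cand <- which(!is.na(dev0) & dev0 > cut)
  while (length(cand) && sum(is.finite(work)) > 5) {
    j <- cand[which.max(dev[cand])]
    if (!is.finite(dev[j]) || dev[j] <= cut) break
    mask[j] <- TRUE
    work[j] <- NA_real_
    cand <- setdiff(cand, j)
    valid <- which(is.finite(work))
    for (i in cand[abs(cand - j) <= 6]) {
      dev[i] <- abs(work[i] - loo_est_one(work, valid, i))
    }
  }
  out <- series
  out[mask] <- NA_real_
  list(deviance = dev0, mask = mask, series = out)
}

# fit the exact polynomial (degree length(xi)-1) through (xi, yi),
# evaluated at x; xi need not be uniform
lagrange_eval <- function(xi, yi, x) {
  v <- numeric(length(x))
  for (j in seq_along(xi)) {
    others <- xi[-j]
    lj <- rep(yi[j], length(x))
    for (o in others) lj <- lj * (x - o) / (xi[j] - o)
    v <- v + lj
  }
  v
}

#' Fill short gaps by local cubic interpolation
#'
#' Missing runs up to `max_gap_s` long are filled with the cubic through
#' the four nearest valid samples (two on each side where available).
#' Longer interior gaps remain missing and are flagged; leading and
#' trailing missing runs are never filled.
#'
#' @param series Numeric vector with `NA` gaps.
#' @param fs Sampling rate (Hz).
#' @param max_gap_s Longest gap that is filled, in seconds.
#' @return List with `series` (gaps filled), `n_interpolated`,
#'   `n_unfilled` (interior missing samples left unfilled),
#'   `unrecoverable` (logical: any interior gap too long to fill) and
#'   `edge_missing` (count of leading/trailing missing samples).
#' @export
interpolate_gaps <- function(series, fs, max_gap_s = 0.5) {
  n <- length(series)
  valid <- which(is.finite(series))
  if (length(valid) == 0) {
    tapkin_error("series is entirely missing", "tapkin_insufficient_data")
  }
  max_len <- floor(max_gap_s * fs)
  out <- series
  n_interp <- 0L
  n_unfilled <- 0L
  unrec <- FALSE
  first_v <- valid[1]; last_v <- valid[length(valid)]
  miss <- which(!is.finite(series))
  miss <- miss[miss > first_v & miss < last_v]   # interior only
  if (length(miss)) {
    runs <- split(miss, cumsum(c(1, diff(miss) != 1)))
    for (r in runs) {
      if (length(r) > max_len) {
        unrec <- TRUE
        n_unfilled <- n_unfilled + length(r)
        next
      }
      left <- tail(valid[valid < r[1]], 2)
      right <- head(valid[valid > r[length(r)]], 2)
      nb <- c(left, right)
      if (length(nb) < 2) {
        unrec <- TRUE
        n_unfilled <- n_unfilled + length(r)
        next
      }
      out[r] <- lagrange_eval(nb, series[nb], r)
      n_interp <- n_interp + length(r)
    }
  }
  list(series = out, n_interpolated = n_interp, n_unfilled = n_unfilled,
       unrecoverable = unrec,
       edge_missing = (first_v - 1L) + (n - last_v))
}

# FIR low-pass taps: linear-phase window design, normalised to exact DC
# gain 1
fir_lowpass_taps <- function(order, w) {
  b <- signal::fir1(order, w)
  as.numeric(b) / sum(b)
}

# zero-phase filtering with mirror padding to suppress edge transients
filtfilt_padded <- function(b, x) {
  n <- length(x)
  pad <- min(n - 1, 3 * length(b))
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(b, 1, c(front, x, back))
  y[(pad + 1):(pad + n)]
}

#' Downsample a series to 30 Hz
#'
#' 60 Hz input is anti-alias filtered (zero-phase FIR, cutoff at the new
#' Nyquist) and decimated by two; 30 Hz input is returned unchanged.
#'
#' @param series Numeric vector, no missing samples.
#' @param fs_in Input sampling rate, 30 or 60 Hz.
#' @return Series at 30 Hz (length `ceiling(n / 2)` for 60 Hz input).
#' @export
resample_to_30 <- function(series, fs_in) {
  if (!fs_in %in% c(30, 60)) {
    tapkin_error(sprintf("unsupported sampling rate %s (expected 30 or 60 Hz)",
                         fs_in), "tapkin_unsupported_rate")
  }
  if (fs_in == 30) return(series)
  if (anyNA(series)) {
    tapkin_error("resampling requires a gap-free series",
                 "tapkin_insufficient_data")
  }
  b <- fir_lowpass_taps(60, 0.5)
  y <- filtfilt_padded(b, series)
  y[seq(1, length(y), by = 2)]
}

#' Zero-phase FIR low-pass at 10 Hz
#'
#' Linear-phase windowed FIR (order about two seconds of samples),
#' applied forward and backward for zero phase; DC gain exactly 1.
#'
#' @param series Numeric vector, no missing samples.
#' @param fs Sampling rate (Hz).
#' @param cutoff_hz Cutoff frequency (Hz).
#' @param order Filter order; default two seconds of samples.
#' @return Filtered series, same length as the input.
#' @export
lowpass_10hz <- function(series, fs = 30, cutoff_hz = 10,
                         order = round(2 * fs)) {
  if (anyNA(series)) {
    tapkin_error("filtering requires a gap-free series",
                 "tapkin_insufficient_data")
  }
  if (length(series) < 3 * (order + 1)) {
    tapkin_error(sprintf("series too short to filter (need >= %d samples)",
                         3 * (order + 1)), "tapkin_insufficient_data")
  }
  b <- fir_lowpass_taps(order, cutoff_hz / (fs / 2))
  filtfilt_padded(b, series)
}

#' Z-score a series
#'
#' Removes the amplitude scale set by the hand-camera distance: the
#' output has mean 0 and (sample) standard deviation 1.
#'
#' @param series Numeric vector without missing values.
#' @return Z-scored series.
#' @export
zscore <- function(series) {
  s <- sd(series)
  if (!is.finite(s) || s == 0) {
    tapkin_error("series has zero variance (constant distance means no tapping)",
                 "tapkin_degenerate_signal")
  }
  (series - mean(series)) / s
}

# central finite differences, one-sided at the edges, scaled by fs
finite_diff <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

#' Preprocessing configuration
#'
#' @param conf_floor Landmark confidence below this is treated as missing.
#' @param outlier_threshold Robust threshold for [detect_outliers()];
#'   `NULL` disables outlier screening.
#' @param max_gap_s Longest missing gap filled by interpolation (s).
#' @param lowpass_hz Low-pass cutoff in Hz; `NULL` disables filtering.
#' @param auto_trim If `TRUE` and the recording has no task-segment
#'   annotation, trim to the longest active window (rolling 1 s amplitude
#'   range above 25% of the global range).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(conf_floor = 0.1, outlier_threshold = 6,
                              max_gap_s = 0.5, lowpass_hz = 10,
                              auto_trim = TRUE) {
  structure(list(conf_floor = conf_floor,
                 outlier_threshold = outlier_threshold,
                 max_gap_s = max_gap_s, lowpass_hz = lowpass_hz,
                 auto_trim = auto_trim), class = "preprocess_config")
}

# longest window whose rolling 1 s amplitude range exceeds 25% of the
# global range; used only when no segment annotation is present
auto_trim_segment <- function(d, fs) {
  n <- length(d)
  w <- max(2L, round(fs))
  rng <- vapply(seq_len(n - w + 1L), function(i) {
    seg <- d[i:(i + w - 1L)]
    if (all(is.na(seg))) 0 else diff(range(seg, na.rm = TRUE))
  }, numeric(1))
  active <- rng > 0.25 * diff(range(d, na.rm = TRUE))
  if (!any(active)) return(c(1L, n))
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- which(runs$values)[which.max(runs$lengths[runs$values])]
  c(starts[k], min(n, ends[k] + w - 1L))
}

#' Preprocess a landmark recording into a tapping signal
#'
#' Runs the full conditioning chain: trim to the task segment, compute
#' the index-thumb distance, screen outliers by leave-one-out cubic
#' re-estimation, fill short gaps by cubic interpolation, resample to
#' 30 Hz, low-pass filter at 10 Hz (zero-phase FIR), z-score, and
#' compute the first three time derivatives (velocity, acceleration,
#' jerk) by central finite differences. Quality-control on raw frames
#' precedes normalisation so that spikes cannot corrupt the scale
#' estimate.
#'
#' @param rec A `landmark_recording`.
#' @param config A [preprocess_config()].
#' @return A `tapping_signal`: `fs` (30), `t`, `amplitude`, `velocity`,
#'   `acceleration`, `jerk`, and a `qc` list (`outlier_count`,
#'   `interpolated_count`, `unrecoverable_gap`, `edge_missing`,
#'   `n_missing_input`).
#' @export
preprocess_recording <- function(rec, config = preprocess_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, tapkin_error = function(e) {
      tapkin_error(sprintf("[%s] %s", name, conditionMessage(e)), class(e)[1])
    })
  }
  d <- stage("distance", compute_distance_series(rec, config$conf_floor))
  seg <- rec$segment
  if (is.null(seg)) {
    seg <- if (config$auto_trim) auto_trim_segment(d, rec$fs) else
      tapkin_error("no task segment annotation and auto_trim disabled",
                   "tapkin_parameter_error")
  }
  d <- d[seg[1]:seg[2]]
  n_missing_input <- sum(!is.finite(d))

  outlier_count <- 0L
  if (!is.null(config$outlier_threshold)) {
    sc <- stage("outliers", detect_outliers(d, config$outlier_threshold))
    outlier_count <- sum(sc$mask)
    d <- sc$series
  }
  gi <- stage("gaps", interpolate_gaps(d, rec$fs, config$max_gap_s))
  d <- gi$series
  # leading/trailing missing runs are dropped, not invented
  keep <- range(which(is.finite(d)))
  d <- d[keep[1]:keep[2]]
  if (anyNA(d)) {
    tapkin_error(sprintf(
      "[gaps] unrecoverable gap longer than %.2f s remains in the task segment",
      config$max_gap_s), "tapkin_unrecoverable_gap")
  }
  d <- stage("resample", resample_to_30(d, rec$fs))
  fs <- 30
  if (!is.null(config$lowpass_hz)) {
    d <- stage("filter", lowpass_10hz(d, fs, config$lowpass_hz))
  }
  a <- stage("zscore", zscore(d))
  v <- finite_diff(a, fs)
  acc <- finite_diff(v, fs)
  jrk <- finite_diff(acc, fs)

  structure(list(
    fs = fs, t = (seq_along(a) - 1) / fs,
    amplitude = a, velocity = v, acceleration = acc, jerk = jrk,
    qc = list(outlier_count = outlier_count,
              interpolated_count = gi$n_interpolated,
              unrecoverable_gap = gi$unrecoverable,
              edge_missing = gi$edge_missing,
              n_missing_input = n_missing_input)
  ), class = "tapping_signal")
}

#' Construct a tapping signal directly from an amplitude series
#'
#' Convenience constructor for analyses that start from an already clean
#' distance trace (for example a generator's noiseless ground truth):
#' z-scores the series and computes the three derivatives, with no
#' quality control or filtering.
#'
#' @param amplitude Numeric amplitude series without missing values.
#' @param fs Sampling rate (Hz).
#' @return A `tapping_signal`.
#' @export
tapping_signal_from_series <- function(amplitude, fs = 30) {
  a <- zscore(amplitude)
  v <- finite_diff(a, fs)
  acc <- finite_diff(v, fs)
  jrk <- finite_diff(acc, fs)
  structure(list(
    fs = fs, t = (seq_along(a) - 1) / fs, amplitude = a, velocity = v,
    acceleration = acc, jerk = jrk,
    qc = list(outlier_count = 0L, interpolated_count = 0L,
              unrecoverable_gap = FALSE, edge_missing = 0L,
              n_missing_input = 0L)
  ), class = "tapping_signal")
}

#' @export
print.tapping_signal <- function(x, ...) {
  cat("<tapping_signal> ", length(x$amplitude), " samples @ ", x$fs,
      " Hz; outliers removed: ", x$qc$outlier_count,
      ", samples interpolated: ", x$qc$interpolated_count, "\n", sep = "")
  invisible(x)
}
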