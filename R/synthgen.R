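#' Phenotype parameters for synthetic finger tapping
#'
#' Bundles the generative parameters of one synthetic tapping recording:
#' tap rate, cycle-period and peak-amplitude variability, amplitude
#' decrement, landmark tracking noise, dropout and spike-outlier rates.
#' These axes mirror the clinically meaningful dimensions of tapping
#' impairment (rate, rhythm, amplitude dynamics) that the downstream
#' features are designed to measure.
#'
#' @param tap_rate_hz Mean tap frequency (Hz), > 0.
#' @param period_cv Coefficient of variation of the cycle period (>= 0).
#' @param amp_cv Coefficient of variation of the peak amplitude (>= 0).
#' @param amp_slope Fractional amplitude change per second (1/s); negative
#'   values model amplitude decrement.
#' @param base_amp_px Mean peak index-thumb separation in pixels.
#' @param jitter_sd_px Per-frame Gaussian landmark noise SD (pixels).
#' @param dropout_prob Per-frame probability that a missing-sample gap starts.
#' @param dropout_mean_len_s Mean gap length in seconds.
#' @param outlier_prob Per-frame probability of a spike outlier on the
#'   index fingertip.
#' @param outlier_mag_px Spike magnitude in pixels.
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate, 30 or 60 Hz.
#'
#' @return An object of class `phenotype_params`.
#' @seealso [preset_params()] for the built-in group presets.
#' @export
#' @examples
#' p <- phenotype_params(tap_rate_hz = 2, period_cv = 0, amp_cv = 0)
phenotype_params <- function(tap_rate_hz = 3, period_cv = 0.05, amp_cv = 0.08,
                             amp_slope = 0, base_amp_px = 120,
                             jitter_sd_px = 0, dropout_prob = 0,
                             dropout_mean_len_s = 0.1, outlier_prob = 0,
                             outlier_mag_px = 40, duration_s = 15, fs = 30) {
  check_scalar(tap_rate_hz, "tap_rate_hz", lower = 0, strict_lower = TRUE)
  check_scalar(period_cv, "period_cv", lower = 0)
  check_scalar(amp_cv, "amp_cv", lower = 0)
  check_scalar(amp_slope, "amp_slope")
  check_scalar(base_amp_px, "base_amp_px", lower = 0, strict_lower = TRUE)
  check_scalar(jitter_sd_px, "jitter_sd_px", lower = 0)
  check_scalar(dropout_prob, "dropout_prob", lower = 0, upper = 1 - 1e-12)
  check_scalar(dropout_mean_len_s, "dropout_mean_len_s", lower = 0,
               strict_lower = TRUE)
  check_scalar(outlier_prob, "outlier_prob", lower = 0, upper = 1 - 1e-12)
  check_scalar(outlier_mag_px, "outlier_mag_px", lower = 0)
  check_scalar(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_scalar(fs, "fs", allowed = c(30, 60))
  structure(list(
    tap_rate_hz = tap_rate_hz, period_cv = period_cv, amp_cv = amp_cv,
    amp_slope = amp_slope, base_amp_px = base_amp_px,
    jitter_sd_px = jitter_sd_px, dropout_prob = dropout_prob,
    dropout_mean_len_s = dropout_mean_len_s, outlier_prob = outlier_prob,
    outlier_mag_px = outlier_mag_px, duration_s = duration_s, fs = fs
  ), class = "phenotype_params")
}

#' Built-in phenotype presets
#'
#' Group presets encoding the qualitative directions reported for each
#' phenotype: ataxia taps more slowly with markedly more variable periods
#' and amplitudes; parkinsonism shows amplitude decrement over the trial
#' with mildly elevated variability; controls tap fast and regularly.
#' Magnitudes are package defaults chosen to be plausible for a seated
#' 15 s tapping trial filmed at 30 frames/s; they are configurable and
#' are not calibrated to any clinical cohort.
#'
#' @param group One of `"control"`, `"ataxia"`, `"parkinsonism"`.
#' @param ... Overrides passed on to [phenotype_params()].
#' @return A `phenotype_params` object.
#' @export
preset_params <- function(group = c("control", "ataxia", "parkinsonism"), ...) {
  group <- match.arg(group)
  base <- switch(group,
    control      = list(tap_rate_hz = 3.0, period_cv = 0.05, amp_cv = 0.08,
                        amp_slope = 0),
    ataxia       = list(tap_rate_hz = 1.8, period_cv = 0.25, amp_cv = 0.25,
                        amp_slope = 0),
    parkinsonism = list(tap_rate_hz = 2.8, period_cv = 0.10, amp_cv = 0.12,
                        amp_slope = -0.03)
  )
  noise <- list(jitter_sd_px = 2, dropout_prob = 0.01,
                dropout_mean_len_s = 0.1, outlier_prob = 0.005,
                outlier_mag_px = 40)
  args <- utils::modifyList(c(base, noise), list(...))
  do.call(phenotype_params, args)
}

# Fixed scene geometry: thumb anchored mid-frame of a 960x540 image, the
# index fingertip moves away from it along a fixed unit direction, the
# wrist sits at a constant offset.
.scene <- list(
  thumb = c(480, 270),
  dir   = c(0.6, -0.8),
  wrist_offset = c(-40, 60)
)

#' Generate one synthetic tapping recording
#'
#' Builds a landmark recording as a chain of tap cycles. Cycle `k` has
#' period `T_k = (1/tap_rate_hz) * max(0.2, 1 + period_cv * e_k)` and peak
#' amplitude `A_k = base_amp_px * (1 + amp_slope * t_k) * max(0.1, 1 +
#' amp_cv * n_k)` with standard-normal `e_k`, `n_k` (`t_k` = cycle start
#' time). Within a cycle with normalised time `tau` in `[0, 1]` the
#' index-thumb distance is the downward parabola `A_k * 4 * tau * (1 -
#' tau)`, zero at the troughs and maximal mid-cycle, so every cycle is
#' exactly quadratic in normalised time. The thumb and wrist are fixed;
#' the index fingertip is placed at the current distance along a fixed
#' direction. Gaussian jitter, geometric-length dropouts and spike
#' outliers are then applied to the landmark coordinates.
#'
#' @param params A [phenotype_params()] object.
#' @param seed Integer seed; the recording is deterministic given
#'   `(params, seed)`.
#' @param hand `"dominant"` or `"nondominant"` (metadata only).
#' @param subject_id,session_id Metadata strings.
#' @param group Optional group label; stored and used to anchor the true
#'   severity (controls have severity exactly 0, see
#'   [severity_from_params()]).
#'
#' @return A list with components `recording` (a `landmark_recording`:
#'   `fs`, `hand`, `subject_id`, `session_id`, `segment`, and `landmarks`,
#'   a long data frame with columns frame, landmark, x, y, confidence) and
#'   `truth` (a `ground_truth`: noiseless `amplitude` trace, true cycle
#'   `periods` and `peak_amps`, `cycle_starts`, frames affected by
#'   `outlier_frames`/`dropout_frames`, and `severity`).
#' @export
#' @examples
#' r <- generate_tapping_recording(phenotype_params(tap_rate_hz = 2,
#'   period_cv = 0, amp_cv = 0), seed = 1)
#' length(r$truth$periods)
generate_tapping_recording <- function(params, seed, hand = "dominant",
                                       subject_id = "S1", session_id = 1L,
                                       group = "ataxia") {
  if (!inherits(params, "phenotype_params")) {
    params <- do.call(phenotype_params, as.list(params))
  }
  with_seed(seed, {
    n <- floor(params$duration_s * params$fs)
    t <- (seq_len(n) - 1) / params$fs

    # cycle periods and peak amplitudes; truncated-normal multipliers keep
    # both strictly positive at high CV
    mean_T <- 1 / params$tap_rate_hz
    n_cyc_max <- ceiling(params$duration_s / (0.2 * mean_T)) + 2L
    eps <- rnorm(n_cyc_max)
    periods <- mean_T * pmax(0.2, 1 + params$period_cv * eps)
    starts <- cumsum(c(0, periods))
    n_cyc <- which(starts >= params$duration_s)[1] - 1L
    periods <- periods[seq_len(n_cyc)]
    starts <- starts[seq_len(n_cyc)]
    eta <- rnorm(n_cyc)
    amps <- params$base_amp_px * pmax(0.05, 1 + params$amp_slope * starts) *
      pmax(0.1, 1 + params$amp_cv * eta)

    k <- findInterval(t, starts)
    tau <- (t - starts[k]) / periods[k]
    dist_true <- amps[k] * 4 * tau * (1 - tau)

    complete <- (starts + periods) <= params$duration_s + 1e-9

    # landmark placement
    ix <- .scene$thumb[1] + dist_true * .scene$dir[1]
    iy <- .scene$thumb[2] + dist_true * .scene$dir[2]
    tx <- rep(.scene$thumb[1], n); ty <- rep(.scene$thumb[2], n)
    wx <- rep(.scene$thumb[1] + .scene$wrist_offset[1], n)
    wy <- rep(.scene$thumb[2] + .scene$wrist_offset[2], n)

    # spike outliers: index fingertip displaced along the tapping axis
    out_frames <- integer(0)
    if (params$outlier_prob > 0) {
      out_frames <- which(runif(n) < params$outlier_prob)
      if (length(out_frames)) {
        sgn <- sample(c(-1, 1), length(out_frames), replace = TRUE)
        ix[out_frames] <- ix[out_frames] +
          sgn * params$outlier_mag_px * .scene$dir[1]
        iy[out_frames] <- iy[out_frames] +
          sgn * params$outlier_mag_px * .scene$dir[2]
      }
    }

    # jitter on every coordinate of every landmark
    if (params$jitter_sd_px > 0) {
      jit <- matrix(rnorm(6 * n, sd = params$jitter_sd_px), ncol = 6)
      ix <- ix + jit[, 1]; iy <- iy + jit[, 2]
      tx <- tx + jit[, 3]; ty <- ty + jit[, 4]
      wx <- wx + jit[, 5]; wy <- wy + jit[, 6]
    }

    # dropouts: geometric-length gaps where all landmarks go missing
    drop_frames <- integer(0)
    if (params$dropout_prob > 0) {
      gap_starts <- which(runif(n) < params$dropout_prob)
      mean_len <- max(1, params$dropout_mean_len_s * params$fs)
      for (g in gap_starts) {
        len <- 1L + rgeom(1, 1 / mean_len)
        drop_frames <- c(drop_frames, g:min(n, g + len - 1L))
      }
      drop_frames <- sort(unique(drop_frames))
      ix[drop_frames] <- NA_real_; iy[drop_frames] <- NA_real_
      tx[drop_frames] <- NA_real_; ty[drop_frames] <- NA_real_
      wx[drop_frames] <- NA_real_; wy[drop_frames] <- NA_real_
    }

    conf <- rep(1, n); conf[drop_frames] <- 0
    frames <- seq_len(n)
    landmarks <- data.frame(
      frame = rep(frames, 3),
      landmark = rep(c("index_tip", "thumb_tip", "wrist"), each = n),
      x = c(ix, tx, wx), y = c(iy, ty, wy),
      confidence = rep(conf, 3),
      stringsAsFactors = FALSE
    )

    recording <- structure(list(
      fs = params$fs, hand = hand, subject_id = subject_id,
      session_id = session_id, segment = c(1L, n), landmarks = landmarks
    ), class = "landmark_recording")

    truth <- structure(list(
      amplitude = dist_true, t = t,
      periods = periods[complete], peak_amps = amps[complete],
      cycle_starts = starts[complete],
      outlier_frames = out_frames, dropout_frames = drop_frames,
      severity = severity_from_params(params, group)
    ), class = "ground_truth")

    list(recording = recording, truth = truth)
  })
}

#' Map generative parameters to a severity scalar
#'
#' Deterministic monotone map from the pathological parameter axes to a
#' severity score in `[0, 1]`: severity increases with period variability,
#' amplitude variability, and the tap-rate deficit relative to a healthy
#' reference rate. Controls are anchored at exactly zero, matching the
#' convention of assigning zero clinical arm scores to unaffected
#' participants.
#'
#' @param params A [phenotype_params()] object.
#' @param group Group label; `"control"` returns exactly 0.
#' @param coefs Named coefficients `period_cv`, `amp_cv`, `rate_deficit`
#'   and the healthy reference rate `ref_rate_hz`.
#' @return Severity in `[0, 1]`.
#' @export
severity_from_params <- function(params, group = "ataxia",
                                 coefs = c(period_cv = 0.6, amp_cv = 0.3,
                                           rate_deficit = 0.45,
                                           ref_rate_hz = 3)) {
  if (identical(group, "control")) return(0)
  deficit <- max(0, (coefs[["ref_rate_hz"]] - params$tap_rate_hz) /
                   coefs[["ref_rate_hz"]])
  clip01(coefs[["period_cv"]] * params$period_cv +
           coefs[["amp_cv"]] * params$amp_cv +
           coefs[["rate_deficit"]] * deficit)
}

#' Specification of a synthetic cohort
#'
#' Describes a cohort of recordings across the three groups: per-group
#' recording counts (both hands are generated for every session), the
#' phenotype presets and their between-subject spread, the fraction of
#' recordings that are repeat visits, per-group age distributions, and
#' the severity-map coefficients. Default counts match a cohort of 169
#' ataxia, 74 parkinsonism and 58 control videos.
#'
#' @param n_ataxia,n_parkinsonism,n_control Recordings per group (per hand).
#' @param group_params Named list of `phenotype_params` per group.
#' @param rate_sd Between-subject SD of tap rate (Hz).
#' @param cv_rel_sd Between-subject log-normal relative SD applied to
#'   `period_cv` and `amp_cv`.
#' @param slope_sd Between-subject SD of `amp_slope` (1/s).
#' @param repeat_fraction Fraction of recordings that are second visits of
#'   an already-seen subject, in `[0, 0.5)`.
#' @param hand_asymmetry Multiplier on `period_cv`/`amp_cv` for the
#'   nondominant hand.
#' @param ages Named list of `c(mean, sd, min, max)` per group.
#' @param severity_coefs Passed to [severity_from_params()].
#' @param hands Which hands to generate per session.
#' @param seed Master seed for the whole cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ataxia = 169, n_parkinsonism = 74, n_control = 58,
                        group_params = list(
                          ataxia = preset_params("ataxia"),
                          parkinsonism = preset_params("parkinsonism"),
                          control = preset_params("control")),
                        rate_sd = 0.3, cv_rel_sd = 0.3, slope_sd = 0.01,
                        repeat_fraction = 0.2, hand_asymmetry = 1.1,
                        ages = list(ataxia = c(49, 22.4, 5, 82),
                                    parkinsonism = c(67, 7.7, 45, 85),
                                    control = c(30, 20.2, 4, 86)),
                        severity_coefs = c(period_cv = 0.6, amp_cv = 0.3,
                                           rate_deficit = 0.45,
                                           ref_rate_hz = 3),
                        hands = c("dominant", "nondominant"),
                        seed = 1L) {
  check_scalar(n_ataxia, "n_ataxia", lower = 0)
  check_scalar(n_parkinsonism, "n_parkinsonism", lower = 0)
  check_scalar(n_control, "n_control", lower = 0)
  check_scalar(repeat_fraction, "repeat_fraction", lower = 0,
               upper = 0.5 - 1e-12)
  structure(list(
    counts = c(ataxia = n_ataxia, parkinsonism = n_parkinsonism,
               control = n_control),
    group_params = group_params, rate_sd = rate_sd, cv_rel_sd = cv_rel_sd,
    slope_sd = slope_sd, repeat_fraction = repeat_fraction,
    hand_asymmetry = hand_asymmetry, ages = ages,
    severity_coefs = severity_coefs, hands = hands, seed = seed
  ), class = "cohort_spec")
}

# round to the 0.5-step grid of a clinical arm item
round_half <- function(x) round(x * 2) / 2

#' Generate a synthetic cohort
#'
#' Draws subject-level phenotype parameters around the group presets,
#' assigns repeat visits, ages and clinical-score labels, and generates
#' the landmark recordings for every session and hand. Clinical labels
#' are produced from the generative severity: ataxia arm scores on a
#' 0-4 scale in 0.5 steps, a parkinsonism arm composite on a 0-12
#' integer scale, and total scores on the native 0-30 / 0-108 scales.
#' Reproducible bit-for-bit from the master seed.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort_dataset` list: `recordings` and `truths` (named by
#'   recording id), `manifest` (one row per recording), `sessions` (one
#'   row per session with both hands' labels) and the originating `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  if (sum(spec$counts) == 0) {
    tapkin_error("cohort spec requests zero recordings", "tapkin_empty_dataset")
  }

  plan <- with_seed(spec$seed, {
    rows <- list()
    for (g in names(spec$counts)) {
      n_rec <- spec$counts[[g]]
      if (n_rec == 0) next
      n_rep <- min(floor(spec$repeat_fraction * n_rec), n_rec %/% 2)
      n_subj <- n_rec - n_rep
      prefix <- toupper(substr(g, 1, 3))
      subj_ids <- sprintf("%s%03d", prefix, seq_len(n_subj))
      repeated <- if (n_rep > 0) sample(subj_ids, n_rep) else character(0)

      gp <- spec$group_params[[g]]
      a <- spec$ages[[g]]
      for (i in seq_len(n_subj)) {
        age <- min(a[4], max(a[3], rnorm(1, a[1], a[2])))
        rate <- max(0.5, rnorm(1, gp$tap_rate_hz, spec$rate_sd))
        pcv <- gp$period_cv * exp(rnorm(1, 0, spec$cv_rel_sd))
        acv <- gp$amp_cv * exp(rnorm(1, 0, spec$cv_rel_sd))
        slope <- rnorm(1, gp$amp_slope, spec$slope_sd)
        n_sess <- if (subj_ids[i] %in% repeated) 2L else 1L
        for (s in seq_len(n_sess)) {
          rows[[length(rows) + 1L]] <- list(
            subject_id = subj_ids[i], session_id = s, group = g, age = age,
            rate = rate, period_cv = pcv, amp_cv = acv, slope = slope)
        }
      }
    }
    rows
  })

  recordings <- list(); truths <- list()
  manifest <- list(); sessions <- list()
  counter <- 0L
  for (row in plan) {
    counter <- counter + 1L
    sess_key <- sprintf("%s_s%d", row$subject_id, row$session_id)
    gp <- spec$group_params[[row$group]]
    hand_sev <- c(dominant = NA_real_, nondominant = NA_real_)
    hand_bars <- hand_sev; hand_updrs <- hand_sev; hand_common <- hand_sev

    for (h in spec$hands) {
      asym <- if (h == "nondominant") spec$hand_asymmetry else 1
      hp <- phenotype_params(
        tap_rate_hz = row$rate, period_cv = row$period_cv * asym,
        amp_cv = row$amp_cv * asym, amp_slope = row$slope,
        base_amp_px = gp$base_amp_px, jitter_sd_px = gp$jitter_sd_px,
        dropout_prob = gp$dropout_prob,
        dropout_mean_len_s = gp$dropout_mean_len_s,
        outlier_prob = gp$outlier_prob, outlier_mag_px = gp$outlier_mag_px,
        duration_s = gp$duration_s, fs = gp$fs)
      sev <- severity_from_params(hp, row$group, spec$severity_coefs)
      rec_seed <- child_seed(spec$seed, counter * 4L +
                               match(h, c("dominant", "nondominant")))
      gen <- generate_tapping_recording(hp, rec_seed, hand = h,
                                        subject_id = row$subject_id,
                                        session_id = row$session_id,
                                        group = row$group)
      gen$truth$severity <- sev
      rec_id <- sprintf("%s_%s", sess_key, h)
      recordings[[rec_id]] <- gen$recording
      truths[[rec_id]] <- gen$truth

      bars_arm <- if (row$group == "ataxia") {
        min(4, round_half(sev * 4))
      } else 0
      updrs_arm <- if (row$group == "parkinsonism") {
        min(12, round(sev * 12))
      } else 0
      common <- common_arm_score(bars_arm = bars_arm,
                                 updrs_arm_sum = updrs_arm,
                                 group = row$group)
      hand_sev[h] <- sev; hand_bars[h] <- bars_arm
      hand_updrs[h] <- updrs_arm; hand_common[h] <- common

      manifest[[length(manifest) + 1L]] <- data.frame(
        recording_id = rec_id, subject_id = row$subject_id,
        session_id = row$session_id, hand = h, group = row$group,
        age = row$age, severity_true = sev, bars_arm = bars_arm,
        updrs_arm = updrs_arm, common_arm = common,
        stringsAsFactors = FALSE)
    }

    sev_mean <- mean(hand_sev, na.rm = TRUE)
    total_noise <- with_seed(child_seed(spec$seed, counter * 4L + 3L),
                             rnorm(2))
    bars_total <- if (row$group == "ataxia") {
      min(30, max(0, round(sev_mean * 24 + 2 * total_noise[1])))
    } else 0
    updrs_total <- if (row$group == "parkinsonism") {
      min(108, max(0, round(sev_mean * 51 + 5 * total_noise[2])))
    } else 0
    score_total <- switch(row$group,
      ataxia = bars_total / 30, parkinsonism = updrs_total / 108, control = 0)

    sessions[[length(sessions) + 1L]] <- data.frame(
      session_key = sess_key, subject_id = row$subject_id,
      session_id = row$session_id, group = row$group, age = row$age,
      severity_dominant = hand_sev[["dominant"]],
      severity_nondominant = hand_sev[["nondominant"]],
      common_arm_dominant = hand_common[["dominant"]],
      common_arm_nondominant = hand_common[["nondominant"]],
      bars_total = bars_total, updrs_total = updrs_total,
      score_total = score_total, stringsAsFactors = FALSE)
  }

  structure(list(
    recordings = recordings, truths = truths,
    manifest = do.call(rbind, manifest),
    sessions = do.call(rbind, sessions),
    spec = spec
  ), class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  tab <- table(x$manifest$group[!duplicated(x$manifest$recording_id)])
  cat("<cohort_dataset> ", length(x$recordings), " recordings, ",
      length(unique(x$manifest$subject_id)), " subjects\n", sep = "")
  print(tab)
  invisible(x)
}
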