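test_that("event detection finds the true taps of a clean signal", {
  sig <- clean_signal()
  ev <- detect_events(sig)
  expect_length(ev$peak_t, 30)
  expect_length(ev$trough_t, 29)
  # strict alternation: peak, trough, peak, ...
  expect_true(all(ev$peak_t[-length(ev$peak_t)] < ev$trough_t))
  expect_true(all(ev$trough_t < ev$peak_t[-1]))
  expect_true(all(ev$peak_a[-length(ev$peak_a)] > ev$trough_a))
  expect_true(all(ev$peak_a[-1] > ev$trough_a))
  # constant signal has no events
  expect_error(detect_events(make_signal(rep(0.5, 450))),
               class = "tapkin_too_few_events")
})

test_that("a pure 2 Hz cosine yields 0.5 s trough-to-trough periods", {
  fs <- 30
  t <- seq(0, 15 - 1 / fs, by = 1 / fs)
  sig <- tapping_signal_from_series(cos(2 * pi * 2 * t), fs)
  ev <- detect_events(sig)
  expect_true(all(abs(diff(ev$trough_t) - 0.5) <= 1 / fs + 1e-12))
})

test_that("event alternation holds across random noisy signals", {
  withr::with_seed(77, {
    for (i in 1:200) {
      rate <- runif(1, 1, 4)
      p <- phenotype_params(tap_rate_hz = rate,
                            period_cv = runif(1, 0, 0.3),
                            amp_cv = runif(1, 0, 0.3),
                            amp_slope = runif(1, -0.03, 0))
      g <- generate_tapping_recording(p, seed = 1000 + i)
      sig <- tapping_signal_from_series(
        g$truth$amplitude + rnorm(length(g$truth$amplitude),
                                  sd = 0.02 * p$base_amp_px))
      ev <- tryCatch(detect_events(sig),
                     tapkin_error = function(e) NULL)
      if (is.null(ev)) next
      m <- length(ev$peak_t)
      expect_true(all(diff(c(rbind(ev$peak_t[-m], ev$trough_t),
                             ev$peak_t[m])) > 0))
      expect_true(all(ev$peak_a[-m] > ev$trough_a) &&
                    all(ev$peak_a[-1] > ev$trough_a))
    }
  })
})

test_that("the 11 summary measures follow their definitions", {
  m <- summary_measures(c(1, 2, 3, 4))
  expect_equal(unname(m[c("mean", "max", "min", "median", "range", "iqr")]),
               c(2.5, 4, 1, 2.5, 3, 1.5))
  expect_equal(unname(m["p10"]), 1.3)
  expect_equal(unname(m["p90"]), 3.7)
  cm <- summary_measures(rep(2, 10))
  expect_equal(unname(cm[c("std", "range", "iqr", "ent")]), c(0, 0, 0, 0))
  expect_error(summary_measures(3), class = "tapkin_insufficient_data")
})

test_that("histogram entropy equals an independent oracle", {
  withr::with_seed(4, {
    x <- runif(10000)
    got <- unname(summary_measures(x)["ent"])
    # independent binning oracle
    cuts <- cut(x, breaks = seq(min(x), max(x), length.out = 17),
                include.lowest = TRUE, right = FALSE)
    p <- as.numeric(table(cuts)) / length(x)
    p <- p[p > 0]
    expect_equal(got, -sum(p * log(p)), tolerance = 1e-12)
    expect_lt(abs(got - log(16)), 0.02 * log(16))
  })
})

test_that("TS family reflects the z-scored signal and its spectrum", {
  sig <- clean_signal()
  f <- ts_family(sig)
  expect_length(f, 45)
  expect_equal(unname(f["ts.amp.mean"]), 0, tolerance = 1e-9)
  expect_equal(unname(f["ts.amp.std"]), 1, tolerance = 1e-9)
  expect_equal(unname(f["ts.spectral_peak_hz"]), 2, tolerance = 0.25)
  expect_length(ts_family(sig, spectral_peak = FALSE), 44)
})

test_that("event families handle constant and linearly drifting peaks", {
  tt <- seq(0, 10, by = 0.5)
  ev <- make_events(peak_t = tt, peak_a = rep(2, length(tt)),
                    trough_t = tt[-1] - 0.25,
                    trough_a = rep(0, length(tt) - 1))
  f <- event_family(ev, "peaks")
  expect_length(f, 45)
  expect_equal(unname(f["pk.slope"]), 0)
  expect_true(all(f[grep("^pk\\.d[123]\\.", names(f))] == 0))
  # peaks decaying as 1 - 0.05 t recover the slope exactly
  ev2 <- make_events(peak_t = tt, peak_a = 1 - 0.05 * tt,
                     trough_t = tt[-1] - 0.25,
                     trough_a = rep(0, length(tt) - 1))
  expect_equal(unname(event_family(ev2, "peaks")["pk.slope"]), -0.05,
               tolerance = 1e-6)
  expect_length(event_family(ev, "troughs", max_deriv = 2), 34)
  few <- make_events(peak_t = c(0, 1), peak_a = c(1, 1),
                     trough_t = 0.5, trough_a = 0)
  expect_error(event_family(few, "peaks"),
               class = "tapkin_insufficient_data")
})

test_that("amplitude variability propagates to peak-amplitude spread", {
  n_larger <- 0L
  for (i in 1:40) {
    hi <- generate_tapping_recording(
      phenotype_params(tap_rate_hz = 2, amp_cv = 0.3), seed = 200 + i)
    lo <- generate_tapping_recording(
      phenotype_params(tap_rate_hz = 2, amp_cv = 0.05), seed = 200 + i)
    sd_of <- function(g) {
      sig <- tapping_signal_from_series(g$truth$amplitude)
      sd(detect_events(sig)$peak_a)
    }
    if (sd_of(hi) > sd_of(lo)) n_larger <- n_larger + 1L
  }
  expect_gte(n_larger, 38)
})

test_that("peak-to-trough features match a brute-force pairing oracle", {
  sig <- clean_signal()
  ev <- detect_events(sig)
  f <- pkth_family(ev)
  expect_lt(abs(unname(f["pkth.dt.mean"]) - 0.25), 1 / 30 + 1e-9)
  expect_equal(unname(f["pkth.dt.std"]), 0, tolerance = 1e-9)
  expect_equal(unname(f["pkth.damp.std"]), 0, tolerance = 1e-6)
  # randomised events against an independent pairing loop
  withr::with_seed(12, {
    m <- 10
    pt <- cumsum(runif(m, 0.3, 0.6))
    tt <- pt[-m] + runif(m - 1, 0.05, 0.2)
    ev2 <- make_events(pt, runif(m, 1, 2), tt, runif(m - 1, -1, 0))
    f2 <- pkth_family(ev2)
    dts <- c(); das <- c()
    for (i in seq_len(m - 1)) {
      dts <- c(dts, tt[i] - pt[i])
      das <- c(das, ev2$peak_a[i] - ev2$trough_a[i])
    }
    expect_equal(unname(f2), c(mean(dts), sd(dts), median(dts),
                               mean(das), sd(das), median(das)))
  })
  expect_error(pkth_family(make_events(c(0, 1), c(1, 1), 0.5, 0)),
               class = "tapkin_insufficient_data")
})

test_that("quadratic cycle fits recover exact parabolas", {
  # one cycle sampled from 4*tau*(1-tau): coefficients (-4, 4, 0)
  fs <- 30
  t <- seq(0, 3, by = 1 / fs)
  tau_all <- (t %% 1)
  sig <- make_signal(4 * tau_all * (1 - tau_all), fs)
  ev <- make_events(peak_t = c(0.5, 1.5, 2.5), peak_a = rep(1, 3),
                    trough_t = c(0, 1, 2, 3), trough_a = rep(0, 4))
  res <- thth_family(sig, ev)
  expect_equal(res$fits$a, rep(-4, 3), tolerance = 1e-9)
  expect_equal(res$fits$b, rep(4, 3), tolerance = 1e-9)
  expect_equal(res$fits$c, rep(0, 3), tolerance = 1e-9)
  expect_lt(max(res$fits$rss), 1e-18)
  expect_equal(unname(res$features["thth.a.std"]), 0, tolerance = 1e-9)
})

test_that("generator cycles are exactly quadratic end to end", {
  sig <- clean_signal()
  ev <- detect_events(sig)
  res <- thth_family(sig, ev)
  expect_lt(max(res$fits$rss), 1e-9)
  expect_lt(sd(res$fits$a), 1e-6)
  expect_equal(mean(res$fits$duration), 0.5, tolerance = 1e-9)
})

test_that("cycle fits agree with an independent least-squares oracle", {
  withr::with_seed(33, {
    fs <- 30
    t <- seq(0, 5, by = 1 / fs)
    sig <- make_signal(rnorm(length(t)), fs)
    tt <- c(0, 1, 2.5, 3.4, 5)
    ev <- make_events(peak_t = c(0.5, 1.7, 3, 4), peak_a = rep(1, 4),
                      trough_t = tt, trough_a = rep(0, 5))
    res <- thth_family(sig, ev)
    for (i in seq_len(4)) {
      span <- (round(tt[i] * fs) + 1):(round(tt[i + 1] * fs) + 1)
      tau <- (t[span] - tt[i]) / (tt[i + 1] - tt[i])
      fit <- lm(sig$amplitude[span] ~ tau + I(tau^2))
      expect_equal(res$fits$a[i], unname(coef(fit)[3]), tolerance = 1e-8)
      expect_equal(res$fits$b[i], unname(coef(fit)[2]), tolerance = 1e-8)
      expect_equal(res$fits$c[i], unname(coef(fit)[1]), tolerance = 1e-8)
    }
  })
})

test_that("the feature inventory is complete, named, finite and stable", {
  sig <- clean_signal()
  f <- extract_features(sig, sig, "canonical")
  expect_false(any(duplicated(names(f))))
  expect_true(all(is.finite(f)))
  man <- attr(f, "manifest")
  expect_equal(man$total, length(f))
  expect_equal(sum(unlist(man$per_family)), man$total)
  # per-hand canonical inventory: 44+1 TS, 45 Pk, 45 Th, 6 PkTh, 3 Th-Th
  expect_equal(unlist(man$per_family_per_hand),
               c(TS = 45, Pk = 45, Th = 45, PkTh = 6, ThTh = 3))
  f2 <- extract_features(sig, sig, "canonical")
  expect_identical(f, f2)
  # single-hand mode halves the inventory
  f1 <- extract_features(sig, profile = "canonical")
  expect_length(f1, length(f) / 2)
})

test_that("the paper-total profile reconciles to 256 features", {
  sig <- clean_signal()
  f <- extract_features(sig, sig, "paper-total")
  expect_length(f, 256)
  man <- attr(f, "manifest")
  expect_equal(man$total, 256)
  expect_equal(unlist(man$per_family_per_hand),
               c(TS = 45, Pk = 34, Th = 34, PkTh = 6, ThTh = 9))
})

test_that("family tags are parsed from feature names", {
  expect_equal(feature_family_of(c("d.ts.amp.mean", "nd.pk.slope",
                                   "d.thth.a.std", "nd.pkth.dt.mean",
                                   "d.th.d2.iqr")),
               c("TS", "Pk", "ThTh", "PkTh", "Th"))
})
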