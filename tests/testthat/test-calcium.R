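make_tone <- function(freq, dur_s, fs = 2000, amp = 1) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq * t)
}

test_that("smoothing preserves the passband and kills the stopband", {
  fs <- 2000
  slow <- calcium_trace(make_tone(0.5, 60, fs), fs)
  sm <- smooth_trace(slow)
  expect_equal(sm$sampling_rate, 60)
  # deep in the passband: amplitude preserved within 1%
  expect_gt(max(sm$values), 0.99)
  expect_lt(max(abs(sm$values)), 1.01)
  # 100 Hz is beyond the stopband: attenuated by >= 40 dB in steady state
  # (the first/last second carry the usual zero-phase boundary transient)
  fast <- calcium_trace(make_tone(100, 60, fs), fs)
  smf <- smooth_trace(fast)
  nn <- length(smf$values)
  expect_lt(max(abs(smf$values[61:(nn - 60)])) / 1, 10^(-40 / 20))
  # the designed response itself is identically 0 beyond the stopband
  H <- function(f) ifelse(f <= 20, 1, ifelse(f >= 40, 0,
                                             0.5 * (1 + cos(pi * (f - 20) / 20))))
  expect_equal(H(100), 0)
  expect_lt(H(39), 0.01)
  # constant in, constant out
  const <- smooth_trace(calcium_trace(rep(3.5, fs * 10), fs))
  expect_equal(const$values, rep(3.5, length(const$values)), tolerance = 1e-9)
  expect_error(smooth_trace(calcium_trace(rnorm(100), 100)), "too low")
})

test_that("segment cropping follows the 2-min / 12-min schedule", {
  fs <- 60
  full <- calcium_trace(rnorm(fs * 21600), fs)
  segs <- crop_segments(full)
  expect_length(segs, 30)
  expect_true(all(lengths(segs) == 120 * fs))
  # 24-min trace -> 2 segments, with a warning
  short <- calcium_trace(rnorm(fs * 24 * 60), fs)
  expect_warning(segs2 <- crop_segments(short), "shorter")
  expect_length(segs2, 2)
  # brute-force index check: segments start at i*period and never overlap
  vals <- seq_len(fs * 21600)
  idx <- crop_segments(calcium_trace(vals, fs))
  starts <- vapply(idx, `[`, 0, 1)
  expect_equal(starts, (0:29) * 720 * fs + 1)
  ends <- vapply(idx, function(s) s[length(s)], 0)
  expect_true(all(ends - starts + 1 == 120 * fs))
  expect_true(all(starts[-1] > ends[-30]))
})

test_that("band powers concentrate, nest, and satisfy Parseval", {
  fs <- 60; n <- 7200   # one 2-min segment at 60 Hz
  t <- (0:(n - 1)) / fs
  tone <- sin(2 * pi * 0.5 * t)
  bp <- band_power(tone, fs)
  expect_gt(bp[["0.1-1"]] / sum(bp[c("0.1-1", "1-20")]), 0.99)
  # equal-amplitude tones at 2 and 10 Hz: band(1-4) = band(1-20)/2 within 2%
  two <- sin(2 * pi * 2 * t) + sin(2 * pi * 10 * t)
  bp2 <- band_power(two, fs)
  expect_equal(bp2[["1-4"]], bp2[["1-20"]] / 2, tolerance = 0.02)
  # white noise: total one-sided power matches the variance (Parseval)
  set.seed(51)
  x <- rnorm(n)
  bpn <- band_power(x, fs, bands = list(all = c(0, fs / 2 + 1)))
  expect_equal(bpn[["all"]], mean((x - mean(x))^2), tolerance = 1e-10)
  # nesting inequality and time-reversal invariance on random segments
  for (i in 1:20) {
    seg <- rnorm(600) + sin(2 * pi * 3 * (1:600) / fs)
    b <- band_power(seg, fs)
    expect_lte(b[["1-4"]], b[["1-20"]] + 1e-12)
    expect_equal(band_power(rev(seg), fs), b, tolerance = 1e-9)
  }
})

test_that("per-animal averaging equals independent recomputation", {
  fs <- 60
  set.seed(52)
  tr <- calcium_trace(rnorm(fs * 24 * 60), fs, animal_id = "r1",
                      condition = "ISO")
  tab <- suppressWarnings(trace_band_powers(tr, smooth = FALSE))
  expect_equal(nrow(tab), 2)
  avg <- animal_band_means(tab)
  expect_equal(avg$n_segments, 2)
  expect_equal(avg[["0.1-1"]], mean(tab[["0.1-1"]]))
  expect_equal(avg[["1-20"]], (tab[["1-20"]][1] + tab[["1-20"]][2]) / 2)
  # identical segments -> mean equals each segment
  tab2 <- tab; tab2[2, c("0.1-1", "1-4", "1-20")] <- tab[1, c("0.1-1", "1-4", "1-20")]
  expect_equal(animal_band_means(tab2)[["1-4"]], tab[["1-4"]][1])
})

test_that("slow-envelope traces carry more low-band power than persistent ones", {
  # ISO-like: burst-suppression envelope below 1 Hz; MED-like: persistent
  # faster activity; equal variance
  fs <- 2000; dur <- 120
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  iso <- sin(2 * pi * 0.4 * t)
  med <- sin(2 * pi * 3 * t) + 0.5 * sin(2 * pi * 8 * t)
  iso <- iso / sd(iso); med <- med / sd(med)
  bp_iso <- band_power(smooth_trace(calcium_trace(iso, fs))$values, 60)
  bp_med <- band_power(smooth_trace(calcium_trace(med, fs))$values, 60)
  expect_gt(bp_iso[["0.1-1"]], bp_med[["0.1-1"]])
  expect_gt(bp_med[["1-4"]], bp_iso[["1-4"]])
})
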