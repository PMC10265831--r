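# Calcium-trace band-power analysis: zero-phase lowpass smoothing with
# resampling to 60 Hz, periodic 2-min cropping, periodogram band sums for
# 0.1-1, 1-4 and 1-20 Hz, and per-animal averaging.

#' Construct a calcium trace
#'
#' @param values Fluorescence samples (single channel).
#' @param sampling_rate Sampling rate in Hz (native recordings: 2000).
#' @param animal_id,condition Metadata.
#' @return A `calcium_trace` object.
#' @export
calcium_trace <- function(values, sampling_rate, animal_id = "",
                          condition = "") {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  structure(list(values = as.numeric(values),
                 sampling_rate = as.numeric(sampling_rate),
                 animal_id = animal_id, condition = condition),
            class = "calcium_trace")
}

#' Read a calcium trace from CSV
#'
#' Input columns: `time_s`, `value`; the sampling rate is taken from the
#' time column unless given.
#'
#' @param path CSV file.
#' @param sampling_rate Override for the sampling rate (Hz).
#' @param animal_id,condition Metadata.
#' @return A [calcium_trace()].
#' @export
read_calcium_trace <- function(path, sampling_rate = NULL, animal_id = "",
                               condition = "") {
  tab <- utils::read.csv(path)
  if (is.null(sampling_rate)) {
    sampling_rate <- 1 / stats::median(diff(tab$time_s))
  }
  calcium_trace(tab$value, sampling_rate, animal_id, condition)
}

#' Zero-phase lowpass smoothing and resampling to 60 Hz
#'
#' The trace is filtered with a zero-phase frequency-domain lowpass
#' (unit gain up to `passband` Hz, raised-cosine roll-off to zero at
#' `stopband` Hz) and then resampled to `target_rate` by linear
#' interpolation. The trace is reflection-padded by one second on each side
#' before the FFT to suppress circular wrap-around. Zero phase means band
#' powers are unaffected by filter delay. As with any zero-phase filter, the
#' first and last second of the output can carry a boundary transient when
#' the trace holds strong out-of-band power at its edges.
#'
#' @param trace A [calcium_trace()] with rate >= `2 * target_rate`.
#' @param passband Passband edge (Hz).
#' @param stopband Stopband edge (Hz); fully attenuated above this.
#' @param target_rate Output sampling rate (Hz).
#' @return A [calcium_trace()] at `target_rate`.
#' @export
smooth_trace <- function(trace, passband = 20, stopband = 40,
                         target_rate = 60) {
  fs <- trace$sampling_rate
  if (fs < 2 * target_rate) stop("sampling rate too low: need >= ",
                                 2 * target_rate, " Hz")
  if (fs <= 2 * stopband) stop("sampling rate must exceed twice the stopband")
  x <- trace$values
  n0 <- length(x)
  pad <- min(n0 - 1L, as.integer(round(fs)))
  # reflection pads, tapered to the trace mean at the outer ends so the
  # circular FFT boundary is continuous (a jump there would leak
  # low-frequency power through the passband)
  mu <- mean(x)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(pad) - 1L) / pad))
  front <- mu + (rev(x[2:(pad + 1L)]) - mu) * ramp
  back <- mu + (rev(x[(n0 - pad):(n0 - 1L)]) - mu) * rev(ramp)
  xp <- c(front, x, back)
  n <- length(xp)
  freq <- (seq_len(n) - 1L) / n * fs
  freq <- pmin(freq, fs - freq)            # two-sided frequency axis
  H <- ifelse(freq <= passband, 1,
              ifelse(freq >= stopband, 0,
                     0.5 * (1 + cos(pi * (freq - passband) /
                                      (stopband - passband)))))
  xf <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / n
  xf <- xf[(pad + 1L):(pad + n0)]
  t_in <- (seq_len(n0) - 1L) / fs
  t_out <- seq(0, t_in[n0], by = 1 / target_rate)
  y <- stats::approx(t_in, xf, xout = t_out)$y
  calcium_trace(y, target_rate, trace$animal_id, trace$condition)
}

#' Crop periodic 2-min segments from a trace
#'
#' Segment `i` (starting at 0) begins at `i * period` and lasts
#' `segment_len`; segments are emitted while they fit inside the trace, up
#' to `total / period`. The default schedule (2-min segment every 12 min
#' over 6 h) yields exactly 30 segments.
#'
#' @param trace A [calcium_trace()] (typically the smoothed 60 Hz trace).
#' @param segment_len Segment length in seconds (default 120).
#' @param period Segment period in seconds (default 720).
#' @param total Scheduled total duration in seconds (default 21600 = 6 h).
#' @return List of numeric vectors (one per segment). A warning is issued
#'   when the trace is shorter than the schedule.
#' @export
crop_segments <- function(trace, segment_len = 120, period = 720,
                          total = 21600) {
  fs <- trace$sampling_rate
  n <- length(trace$values)
  len <- as.integer(round(segment_len * fs))
  n_sched <- as.integer(floor(total / period))
  segs <- list()
  for (i in seq_len(n_sched) - 1L) {
    start <- as.integer(round(i * period * fs)) + 1L
    if (start + len - 1L > n) break
    segs[[length(segs) + 1L]] <- trace$values[start:(start + len - 1L)]
  }
  if (length(segs) < n_sched) {
    warning("trace shorter than schedule: ", length(segs), " of ", n_sched,
            " segments")
  }
  segs
}

#' Periodogram band powers of one segment
#'
#' The segment is mean-detrended and a plain (untapered) periodogram is
#' computed; one-sided spectral values are summed over every bin whose
#' center frequency lies in `[lo, hi)`. Total power over all bins
#' approximates the signal variance (Parseval).
#'
#' @param segment Numeric vector of samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param bands Named list of `c(lo, hi)` band edges in Hz.
#' @return Named numeric vector of band powers.
#' @export
band_power <- function(segment, sampling_rate,
                       bands = list(`0.1-1` = c(0.1, 1),
                                    `1-4` = c(1, 4),
                                    `1-20` = c(1, 20))) {
  x <- segment - mean(segment)
  n <- length(x)
  X <- stats::fft(x)
  kmax <- floor(n / 2)
  k <- seq_len(kmax)
  p <- 2 * Mod(X[k + 1L])^2 / n^2
  if (n %% 2 == 0) p[kmax] <- p[kmax] / 2   # Nyquist bin is not doubled
  f <- k * sampling_rate / n
  vapply(bands, function(b) sum(p[f >= b[1] & f < b[2]]), numeric(1))
}

#' Band powers for every segment of a trace
#'
#' @param trace A native-rate [calcium_trace()].
#' @param ... Passed to [crop_segments()].
#' @param bands Passed to [band_power()].
#' @param smooth Apply [smooth_trace()] first (default TRUE)?
#' @return Data frame: one row per segment with `animal_id`, `condition`,
#'   `segment`, and one column per band.
#' @export
trace_band_powers <- function(trace, ..., bands = list(`0.1-1` = c(0.1, 1),
                                                       `1-4` = c(1, 4),
                                                       `1-20` = c(1, 20)),
                              smooth = TRUE) {
  tr <- if (smooth) smooth_trace(trace) else trace
  segs <- crop_segments(tr, ...)
  if (!length(segs)) stop("no complete segments in trace")
  pw <- t(vapply(segs, band_power, numeric(length(bands)),
                 sampling_rate = tr$sampling_rate, bands = bands))
  out <- data.frame(animal_id = trace$animal_id, condition = trace$condition,
                    segment = seq_along(segs), stringsAsFactors = FALSE)
  cbind(out, as.data.frame(pw))
}

#' Per-animal mean band powers
#'
#' Arithmetic mean of each band across an animal's segments.
#'
#' @param band_table Data frame from [trace_band_powers()] (possibly several
#'   animals row-bound together).
#' @return Data frame with one row per (animal_id, condition).
#' @export
animal_band_means <- function(band_table) {
  bands <- setdiff(names(band_table), c("animal_id", "condition", "segment"))
  key <- interaction(band_table$animal_id, band_table$condition, drop = TRUE)
  out <- do.call(rbind, lapply(split(band_table, key), function(d) {
    cbind(data.frame(animal_id = d$animal_id[1], condition = d$condition[1],
                     n_segments = nrow(d), stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(d[bands])), check.names = FALSE))
  }))
  rownames(out) <- NULL
  out
}
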