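# Region-wise TSC parameterization: arrival time, peak, AUC and
# mono-exponential decay rate, with the discard rules used for reporting.

#' Arrival time of a time signal curve
#'
#' The earliest sample time followed by at least three successive strict
#' increases (`v[i+1] > v[i]`, `v[i+2] > v[i+1]`, `v[i+3] > v[i+2]`).
#' "Increased" is strictly greater; no noise band is applied.
#'
#' @param tsc A [time_signal_curve()] with >= 4 samples.
#' @return Arrival time in minutes, or `NA` if no qualifying point exists.
#' @export
arrival_time <- function(tsc) {
  v <- tsc$values
  up <- diff(v) > 0
  n <- length(up)
  for (i in seq_len(n - 2L)) {
    if (up[i] && up[i + 1L] && up[i + 2L]) return(tsc$times[i])
  }
  NA_real_
}

#' Peak of a time signal curve
#'
#' Global maximum value and its time; ties resolve to the earliest time.
#'
#' @param tsc A [time_signal_curve()].
#' @return List with `t_max` (min) and `S_max` (percent).
#' @export
tsc_peak <- function(tsc) {
  i <- which.max(tsc$values)
  list(t_max = tsc$times[i], S_max = tsc$values[i])
}

#' Area under a time signal curve
#'
#' Trapezoidal integral of the curve over `[0, t_end]` on the native grid.
#' With `strict = TRUE` (default) `t_end` must not exceed the last sample;
#' otherwise integration stops at the last sample.
#'
#' @param tsc A [time_signal_curve()].
#' @param t_end Upper limit in minutes (default 360 = 6 h).
#' @param strict Error when `t_end` lies beyond the last sample?
#' @return AUC in percent * minutes.
#' @export
tsc_auc <- function(tsc, t_end = 360, strict = TRUE) {
  tt <- tsc$times; vv <- tsc$values
  last <- tt[length(tt)]
  if (t_end > last) {
    if (strict) stop("t_end (", t_end, ") beyond last sample (", last, ")")
    t_end <- last
  }
  keep <- tt < t_end
  if (t_end > tt[1] && !t_end %in% tt) {
    v_end <- stats::approx(tt, vv, xout = t_end)$y
    tt <- c(tt[keep], t_end); vv <- c(vv[keep], v_end)
  } else {
    keep <- tt <= t_end
    tt <- tt[keep]; vv <- vv[keep]
  }
  lo <- tt >= 0
  trapz(tt[lo], vv[lo])
}

#' Mono-exponential decay fit of a TSC tail
#'
#' Fits `a * exp(-b * t)` by unweighted least squares to the samples with
#' `t >= t_max + 90` minutes; `t` is absolute acquisition time, so `a` is
#' window-dependent while `b` is not. The fit is discarded
#' (`decay_valid = FALSE`) when the peak falls less than 90 min before the
#' end of acquisition, fewer than `min_points` samples lie in the window, or
#' the fitted rate `b` is not positive. Since the model is linear in `a`
#' given `b`, `a` is profiled out in closed form and the fit reduces to a
#' 1-D minimization over `b`; negative trial rates are searched so that a
#' rising tail is detected (and then discarded) rather than clipped.
#'
#' @param tsc A [time_signal_curve()].
#' @param gap Minutes between the peak and the start of the fit window
#'   (default 90).
#' @param min_points Minimum samples required in the window.
#' @return List with `a`, `b`, `decay_valid`, `fit_window`, `reason`.
#' @export
fit_decay <- function(tsc, gap = 90, min_points = 3L) {
  pk <- tsc_peak(tsc)
  t_end <- tsc$times[length(tsc$times)]
  invalid <- function(reason) {
    list(a = NA_real_, b = NA_real_, decay_valid = FALSE,
         fit_window = c(pk$t_max + gap, t_end), reason = reason)
  }
  if (pk$t_max > t_end - gap) return(invalid("peak too close to end of acquisition"))
  sel <- tsc$times >= pk$t_max + gap
  tt <- tsc$times[sel]; vv <- tsc$values[sel]
  if (length(tt) < min_points) return(invalid("too few samples in fit window"))
  # profile out the amplitude: for fixed b, a*(b) = <v,e> / <e,e>
  a_of_b <- function(b) {
    e <- exp(-b * (tt - tt[1]))       # shifted to keep exp() in range
    sum(vv * e) / sum(e * e)
  }
  sse_b <- function(b) {
    e <- exp(-b * (tt - tt[1]))
    a <- sum(vv * e) / sum(e * e)
    sum((vv - a * e)^2)
  }
  opt <- try(stats::optimize(sse_b, interval = c(-0.2, 1), tol = 1e-10),
             silent = TRUE)
  if (inherits(opt, "try-error")) return(invalid("optimizer failure"))
  b <- opt$minimum
  a <- a_of_b(b) * exp(b * tt[1])     # undo the time shift
  if (!is.finite(a)) return(invalid("degenerate amplitude"))
  if (!is.finite(b) || b <= 0) return(invalid("fitted decay rate not positive"))
  list(a = a, b = b, decay_valid = TRUE,
       fit_window = c(pk$t_max + gap, t_end), reason = "")
}

#' Full kinetic parameterization of a time signal curve
#'
#' Computes arrival time, peak time/value, AUC over `[0, t_end]` and the
#' tail decay fit in one call.
#'
#' @param tsc A [time_signal_curve()].
#' @param t_end AUC upper limit in minutes.
#' @param strict Passed to [tsc_auc()].
#' @return A one-row data frame: `label`, `condition`, `animal_id`, `t_a`,
#'   `t_max`, `S_max`, `AUC`, `a`, `b`, `decay_valid`.
#' @export
tsc_parameters <- function(tsc, t_end = 360, strict = FALSE) {
  pk <- tsc_peak(tsc)
  dec <- fit_decay(tsc)
  data.frame(label = tsc$label, condition = tsc$condition,
             animal_id = tsc$animal_id,
             t_a = arrival_time(tsc), t_max = pk$t_max, S_max = pk$S_max,
             AUC = tsc_auc(tsc, t_end = t_end, strict = strict),
             a = dec$a, b = dec$b, decay_valid = dec$decay_valid,
             stringsAsFactors = FALSE)
}

#' Parameter table for a set of curves
#'
#' @param tscs List of [time_signal_curve()].
#' @inheritParams tsc_parameters
#' @return Data frame with one row per curve.
#' @export
tsc_parameter_table <- function(tscs, t_end = 360, strict = FALSE) {
  do.call(rbind, lapply(tscs, tsc_parameters, t_end = t_end, strict = strict))
}
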