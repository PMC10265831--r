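# Synthetic cohorts with planted kinetic ground truth.
#
# The generator emulates the phenomenology of cisterna-magna tracer studies:
# a delayed rise to a peak followed by slow decay in the outer compartment
# (gamma-variate input), an inner compartment driven by first-order exchange
# dI_in/dt = k1 I_out - k2 I_in, additive Gaussian noise on percent-change
# values, and per-animal jitter. Everything is deterministic under a seed.

#' Default acquisition time grid
#'
#' 40 frames spanning 6 h from the pre-contrast baseline at t = 0.
#'
#' @param n_frames Number of frames.
#' @param t_end End of acquisition in minutes.
#' @return Numeric vector of frame times (minutes).
#' @export
default_time_grid <- function(n_frames = 40L, t_end = 360) {
  seq(0, t_end, length.out = n_frames)
}

#' Gamma-variate tracer input curve
#'
#' `value(t) = A * ((t - t0) / (alpha * tau))^alpha * exp(alpha - (t - t0)/tau)`
#' for `t > t0`, else 0. The curve peaks at exactly `A` at `t = t0 + alpha*tau`.
#'
#' @param t0 Onset delay (min), >= 0.
#' @param A Peak amplitude (percent change), > 0.
#' @param alpha Shape parameter, > 0.
#' @param tau Timescale (min), > 0.
#' @param times Sample times (minutes).
#' @param label,condition,animal_id Curve metadata.
#' @return A [time_signal_curve()].
#' @export
gamma_variate_input <- function(t0, A, alpha, tau, times, label = "outer",
                                condition = "", animal_id = "") {
  stopifnot(t0 >= 0, A > 0, alpha > 0, tau > 0)
  dt <- times - t0
  v <- ifelse(dt > 0, A * (dt / (alpha * tau))^alpha * exp(alpha - dt / tau), 0)
  time_signal_curve(times, v, label = label, condition = condition,
                    animal_id = animal_id)
}

#' Inner-compartment curve from an outer curve by first-order exchange
#'
#' Integrates `dI_in/dt = k1 * I_out - k2 * I_in`, `I_in(t_1) = 0`, with
#' classical 4th-order Runge-Kutta on a uniform internal grid refined at
#' least `refine` times finer than the TSC sampling; the forcing is linearly
#' interpolated between TSC samples. The solution is then sampled back at the
#' TSC times.
#'
#' @param I_out Outer-compartment [time_signal_curve()].
#' @param k1 Outer-to-inner exchange rate (1/min), >= 0.
#' @param k2 Inner-to-outer exchange rate (1/min), >= 0.
#' @param refine Internal grid refinement factor (>= 10 recommended).
#' @param label Label for the returned curve.
#' @return A [time_signal_curve()] sampled at `I_out$times`.
#' @export
generate_inner_from_outer <- function(I_out, k1, k2, refine = 10L,
                                      label = "inner") {
  stopifnot(k1 >= 0, k2 >= 0, refine >= 1)
  tt <- I_out$times
  h <- min(diff(tt)) / refine
  grid <- seq(tt[1], tt[length(tt)], by = h)
  if (grid[length(grid)] < tt[length(tt)]) grid <- c(grid, tt[length(tt)])
  f_out <- stats::approxfun(tt, I_out$values, rule = 2)
  deriv <- function(t, y) k1 * f_out(t) - k2 * y
  y <- numeric(length(grid)); y[1] <- 0
  for (i in seq_len(length(grid) - 1L)) {
    hi <- grid[i + 1L] - grid[i]
    t <- grid[i]
    k_1 <- deriv(t, y[i])
    k_2 <- deriv(t + hi / 2, y[i] + hi / 2 * k_1)
    k_3 <- deriv(t + hi / 2, y[i] + hi / 2 * k_2)
    k_4 <- deriv(t + hi, y[i] + hi * k_3)
    y[i + 1L] <- y[i] + hi / 6 * (k_1 + 2 * k_2 + 2 * k_3 + k_4)
  }
  vals <- stats::approx(grid, y, xout = tt)$y
  time_signal_curve(tt, vals, label = label, condition = I_out$condition,
                    animal_id = I_out$animal_id)
}

#' Per-animal synthetic specification
#'
#' @param condition Condition tag (e.g. "MED").
#' @param t0,A,alpha,tau Gamma-variate input parameters (see
#'   [gamma_variate_input()]).
#' @param k1,k2 Planted exchange rates (1/min).
#' @param noise_sd Additive Gaussian noise SD in percent-change units.
#' @param animal_id Identifier.
#' @return An `animal_spec` list.
#' @export
animal_spec <- function(condition, t0, A, alpha, tau, k1, k2,
                        noise_sd = 0.5, animal_id = "") {
  stopifnot(t0 >= 0, A > 0, alpha > 0, tau > 0, k1 >= 0, k2 >= 0,
            noise_sd >= 0)
  structure(list(condition = condition, t0 = t0, A = A, alpha = alpha,
                 tau = tau, k1 = k1, k2 = k2, noise_sd = noise_sd,
                 animal_id = animal_id),
            class = "animal_spec")
}

#' Condition presets for the synthetic generator
#'
#' Illustrative presets mirroring the qualitative ordering of the anesthetic
#' regimens: MED arrives early with high amplitude and fast exchange,
#' ISO+MED is similar with a smaller inner-to-outer rate, ISO and the
#' acetazolamide (AZE) variants arrive late with low amplitude and small
#' tracer volumes. The numeric values are the generator's own stated world,
#' not measured data.
#'
#' @return Named list of parameter lists.
#' @export
condition_presets <- function() {
  list(
    MED         = list(t0 = 10, A = 30, alpha = 2, tau = 35, k1 = 0.020, k2 = 0.016),
    ISO_MED     = list(t0 = 12, A = 25, alpha = 2, tau = 40, k1 = 0.020, k2 = 0.015),
    ISO         = list(t0 = 30, A = 8,  alpha = 2, tau = 60, k1 = 0.010, k2 = 0.004),
    MED_AZE     = list(t0 = 40, A = 12, alpha = 2, tau = 50, k1 = 0.015, k2 = 0.008),
    ISO_AZE     = list(t0 = 45, A = 6,  alpha = 2, tau = 60, k1 = 0.010, k2 = 0.004),
    ISO_MED_AZE = list(t0 = 45, A = 5,  alpha = 2, tau = 65, k1 = 0.008, k2 = 0.004)
  )
}

#' Build the animal specs for one synthetic condition group
#'
#' Per-animal multiplicative jitter (lognormal, sd `jitter_sd` on the log
#' scale) is applied to amplitude and rates so animals differ while the
#' group stays centered on the preset.
#'
#' @param condition Preset name (see [condition_presets()]) or a list with
#'   fields t0, A, alpha, tau, k1, k2.
#' @param n Number of animals.
#' @param noise_sd Additive noise SD (percent-change units).
#' @param jitter_sd Log-scale SD of per-animal parameter jitter.
#' @param seed Integer seed; animal i uses sub-seed `seed + i`.
#' @return List of [animal_spec()].
#' @export
cohort_specs <- function(condition, n = 8L, noise_sd = 0.5, jitter_sd = 0.05,
                         seed = 1L) {
  p <- if (is.character(condition)) {
    preset <- condition_presets()[[condition]]
    if (is.null(preset)) stop("unknown condition preset: ", condition)
    preset
  } else condition
  tag <- if (is.character(condition)) condition else "custom"
  lapply(seq_len(n), function(i) {
    set.seed(as.integer(seed) + i)
    j <- exp(stats::rnorm(3, 0, jitter_sd))
    animal_spec(tag, t0 = p$t0, A = p$A * j[1], alpha = p$alpha, tau = p$tau,
                k1 = p$k1 * j[2], k2 = p$k2 * j[3], noise_sd = noise_sd,
                animal_id = sprintf("%s_%02d", tag, i))
  })
}

#' Generate a synthetic cohort of outer/inner curve pairs
#'
#' For each animal: the noise-free outer curve is the gamma-variate input;
#' the noise-free inner curve is generated from the noise-free outer by
#' first-order exchange with the planted rates; independent Gaussian noise
#' is then added to each. Deterministic under `seed` (animal i draws from
#' sub-seed `seed + 1000 + i`).
#'
#' @param specs List of [animal_spec()].
#' @param times Shared acquisition time grid (minutes).
#' @param seed Integer root seed.
#' @return A `synthetic_cohort`: list with `specs`, `animals` (each holding
#'   `outer`, `inner`, and the noise-free `outer0`, `inner0`), `times`, `seed`.
#' @export
generate_cohort <- function(specs, times = default_time_grid(), seed = 1L) {
  if (length(specs) < 1L) stop("need at least one animal spec")
  animals <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    outer0 <- gamma_variate_input(sp$t0, sp$A, sp$alpha, sp$tau, times,
                                  label = "outer", condition = sp$condition,
                                  animal_id = sp$animal_id)
    inner0 <- generate_inner_from_outer(outer0, sp$k1, sp$k2)
    set.seed(as.integer(seed) + 1000L + i)
    outer <- outer0; inner <- inner0
    if (sp$noise_sd > 0) {
      outer$values <- outer0$values + stats::rnorm(length(times), 0, sp$noise_sd)
      inner$values <- inner0$values + stats::rnorm(length(times), 0, sp$noise_sd)
    }
    list(spec = sp, outer = outer, inner = inner,
         outer0 = outer0, inner0 = inner0)
  })
  structure(list(specs = specs, animals = animals, times = times,
                 seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' Planted net exchange ratio of a synthetic animal
#'
#' Computed from the noise-free curves and planted rates:
#' `k2 * integral(I_in) / (k1 * integral(I_out))`.
#'
#' @param animal One element of a [generate_cohort()] `animals` list.
#' @return The planted NER.
#' @export
planted_ner <- function(animal) {
  sp <- animal$spec
  v_out <- trapz(animal$outer0$times, animal$outer0$values)
  v_in <- trapz(animal$inner0$times, animal$inner0$values)
  (sp$k2 * v_in) / (sp$k1 * v_out)
}

#' Build a cubic shell phantom with planted compartment curves
#'
#' A cubic region of edge `cube_edge` sits centered in a padded background
#' volume. Its outer shell of erosion depth `outer_thickness` carries
#' `baseline + I_out(t)` raw intensity; the remaining core carries
#' `baseline + I_in(t)`; background stays at `baseline`. With baseline 100,
#' percent-change normalization recovers the planted curves exactly.
#'
#' @param outer_thickness Shell thickness in voxels (6-connected erosion
#'   depth), >= 1.
#' @param cube_edge Region edge length in voxels; must exceed
#'   `2 * outer_thickness`.
#' @param I_out,I_in Planted [time_signal_curve()]s on a shared grid.
#' @param times Frame times; defaults to `I_out$times`.
#' @param baseline Raw baseline intensity (default 100).
#' @param noise_sd Optional voxel-wise Gaussian raw-intensity noise SD.
#' @param pad Background padding in voxels on each side.
#' @return List with `dyn` ([dynamic4d()]) and `lab` ([label_volume()]);
#'   region id is 1.
#' @export
build_shell_phantom <- function(outer_thickness, cube_edge, I_out, I_in,
                                times = I_out$times, baseline = 100,
                                noise_sd = 0, pad = 2L) {
  if (cube_edge <= 2 * outer_thickness) {
    stop("cube_edge must exceed twice the outer thickness")
  }
  n <- cube_edge + 2L * pad
  vox <- array(0L, dim = c(n, n, n))
  idx <- (pad + 1L):(pad + cube_edge)
  vox[idx, idx, idx] <- 1L
  lab <- label_volume(vox, lookup = c(`1` = "phantom_region"))
  region <- vox == 1L
  inner <- erode_mask(region, outer_thickness)
  outer <- region & !inner
  nt <- length(times)
  frames <- array(baseline, dim = c(n, n, n, nt))
  for (t in seq_len(nt)) {
    fr <- frames[, , , t]
    fr[outer] <- baseline + I_out$values[t]
    fr[inner] <- baseline + I_in$values[t]
    frames[, , , t] <- fr
  }
  if (noise_sd > 0) {
    frames <- frames + array(stats::rnorm(length(frames), 0, noise_sd),
                             dim = dim(frames))
    frames[, , , 1] <- baseline  # keep the baseline frame clean and positive
  }
  list(dyn = dynamic4d(frames, times, baseline_index = 1L), lab = lab)
}
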