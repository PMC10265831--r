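# Apparent diffusion coefficient estimation and percent-change ROI
# statistics (subarachnoid volume, aqueductal-flow surrogate, vessel signal).

#' Mono-exponential ADC fit
#'
#' Fits `S(b) = S0 * exp(-b * ADC)` across b-values. The default estimator
#' is a log-domain linear regression weighted by `S^2`, which matches the
#' nonlinear least-squares solution to first order and is exact on
#' noise-free data; `method = "nls"` runs the unweighted nonlinear fit.
#' With exactly two b-values both reduce to the closed form
#' `ADC = log(S1/S2) / (b2 - b1)`.
#'
#' @param b_values Diffusion weightings (s/mm^2), strictly increasing,
#'   length >= 2. The study's full scheme is
#'   `c(10, 200, 400, 600, 800, 1000, 1200, 1400, 1500)`.
#' @param signals Mean ROI signal per b-value; all > 0.
#' @param method "loglin" (default) or "nls".
#' @return List with `ADC` (mm^2/s), `S0`, and `valid` (FALSE when the
#'   fitted ADC is negative).
#' @export
fit_adc <- function(b_values, signals, method = c("loglin", "nls")) {
  method <- match.arg(method)
  if (length(b_values) < 2L || length(b_values) != length(signals)) {
    stop("need matching b_values and signals, at least 2")
  }
  if (any(diff(b_values) <= 0)) stop("b_values must be strictly increasing")
  if (any(signals <= 0)) stop("signals must be positive")
  if (method == "loglin" || length(b_values) == 2L) {
    w <- signals^2
    fitc <- stats::lm.wfit(cbind(1, b_values), log(signals), w)$coefficients
    s0 <- exp(fitc[1]); adc <- -fitc[2]
  } else {
    start <- fit_adc(b_values, signals, method = "loglin")
    fit <- stats::nls(signals ~ S0 * exp(-b_values * ADC),
                      start = list(S0 = start$S0, ADC = start$ADC),
                      control = stats::nls.control(maxiter = 200,
                                                   scaleOffset = 1))
    cf <- stats::coef(fit)
    s0 <- cf[["S0"]]; adc <- cf[["ADC"]]
  }
  list(ADC = unname(adc), S0 = unname(s0), valid = unname(adc) >= 0)
}

#' Aqueductal flow surrogate from a single diffusion shell
#'
#' Per-voxel pseudo-ADC `log(S_ref / S_b) / b` averaged over the ROI. In
#' flowing CSF the attenuation mixes diffusion and flow dephasing, so the
#' value is a flow-sensitized magnitude surrogate, not a pure diffusion
#' coefficient, and carries no directional information.
#'
#' @param S_ref Reference (b ~ 0) signal: scalar, vector, or 3D array.
#' @param S_b Diffusion-weighted signal at `b`, same shape as `S_ref` (or
#'   `S_ref` scalar).
#' @param b Diffusion weighting of `S_b` (s/mm^2), > 0.
#' @param roi Optional logical mask selecting ROI voxels.
#' @return List with `pseudo_ADC` (ROI mean, mm^2/s) and `per_voxel`.
#' @export
aqueduct_flow_surrogate <- function(S_ref, S_b, b = 1000, roi = NULL) {
  if (b <= 0) stop("b must be positive")
  if (length(S_ref) == 1L) S_ref <- rep(S_ref, length(S_b))
  if (!is.null(roi)) {
    S_ref <- S_ref[roi]; S_b <- S_b[roi]
  }
  if (any(S_ref <= 0) || any(S_b <= 0)) stop("signals must be positive")
  pv <- log(as.numeric(S_ref) / as.numeric(S_b)) / b
  list(pseudo_ADC = mean(pv), per_voxel = pv)
}

#' Percent change from a baseline-condition value
#'
#' `100 * (value - baseline) / baseline`, the study's convention with the
#' ISO condition as the initial value.
#'
#' @param baseline Baseline (initial condition) value, > 0.
#' @param value Value under the condition of interest.
#' @return List with `baseline_value`, `condition_value`, `percent_change`.
#' @export
percent_change <- function(baseline, value) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  list(baseline_value = baseline, condition_value = value,
       percent_change = 100 * (value - baseline) / baseline)
}
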