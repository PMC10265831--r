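#' Trapezoidal integral on an arbitrary grid
#'
#' @param x Strictly increasing sample locations.
#' @param y Sample values.
#' @return The trapezoid-rule integral of `y` over `x`.
#' @export
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Euclidean (L2) norm of a numeric vector
#' @param x Numeric vector.
#' @return `sqrt(sum(x^2))`.
#' @export
l2norm <- function(x) sqrt(sum(x^2))

#' Significance stars for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `""` otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of annotations.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}
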