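# Shell-mask compartment geometry: split a brain region into a closed outer
# envelope of uniform voxel thickness and the enclosed inner rest, and
# aggregate their signal curves.

shift_mask <- function(m, axis, by) {
  # shift a 3D logical array along one axis, padding with FALSE
  d <- dim(m)
  out <- array(FALSE, dim = d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  sx <- ix; sx[[axis]] <- src
  dx <- ix; dx[[axis]] <- dst
  out[dx[[1]], dx[[2]], dx[[3]]] <- m[sx[[1]], sx[[2]], sx[[3]]]
  out
}

erode_once <- function(m, connectivity = 6L) {
  out <- m
  for (axis in 1:3) {
    out <- out & shift_mask(m, axis, 1L) & shift_mask(m, axis, -1L)
  }
  if (connectivity >= 18L) {
    for (a in 1:2) for (b in (a + 1):3) for (s1 in c(-1L, 1L)) for (s2 in c(-1L, 1L)) {
      out <- out & shift_mask(shift_mask(m, a, s1), b, s2)
    }
  }
  if (connectivity == 26L) {
    for (s1 in c(-1L, 1L)) for (s2 in c(-1L, 1L)) for (s3 in c(-1L, 1L)) {
      out <- out & shift_mask(shift_mask(shift_mask(m, 1, s1), 2, s2), 3, s3)
    }
  }
  out
}

#' Morphological erosion of a 3D mask
#'
#' Erodes `s` times with the face-neighbor (6-connected) structuring element
#' by default. Voxels outside the image are background, so surfaces touching
#' the volume border peel like any other surface.
#'
#' @param mask 3D logical array.
#' @param s Number of erosion passes, >= 0.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full cube).
#' @return Eroded 3D logical array.
#' @export
erode_mask <- function(mask, s, connectivity = 6L) {
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  if (s < 0) stop("s must be >= 0")
  out <- mask
  for (i in seq_len(s)) out <- erode_once(out, connectivity)
  out
}

#' Split a region into outer-shell and inner compartments
#'
#' The inner compartment is the region mask eroded `s` times; the outer
#' compartment is the remainder, a closed envelope of uniform thickness `s`
#' voxels that completely surrounds the inner compartment.
#'
#' @param lab A [label_volume()].
#' @param region_id Region to split.
#' @param s Outer-envelope thickness in voxels, >= 1.
#' @param connectivity Structuring-element connectivity (default 6).
#' @return List with `outer_mask`, `inner_mask` (3D logical), voxel counts
#'   `n_outer`, `n_inner`, `region_id`, `s`, and `degenerate` (TRUE when the
#'   erosion exhausted the region).
#' @export
split_region <- function(lab, region_id, s, connectivity = 6L) {
  if (s < 1) stop("s must be >= 1")
  region <- lab$voxels == region_id
  if (!any(region)) stop("region ", region_id, " is empty")
  inner <- erode_mask(region, s, connectivity)
  outer <- region & !inner
  list(region_id = region_id, s = as.integer(s),
       outer_mask = outer, inner_mask = inner,
       n_outer = sum(outer), n_inner = sum(inner),
       degenerate = !any(inner))
}

mask_aggregate_tsc <- function(dyn, mask, how = c("sum", "mean"), label,
                               condition = "", animal_id = "") {
  how <- match.arg(how)
  nt <- dim(dyn$frames)[4]
  fr <- matrix(dyn$frames, ncol = nt)[as.vector(mask), , drop = FALSE]
  bl <- fr[, dyn$baseline_index]
  if (any(bl <= 0)) stop("nonpositive voxel baseline inside mask")
  pct <- 100 * sweep(sweep(fr, 1, bl, "-"), 1, bl, "/")
  vals <- if (how == "sum") colSums(pct) else colMeans(pct)
  time_signal_curve(dyn$times, vals, label = label, condition = condition,
                    animal_id = animal_id)
}

#' Aggregate compartment curves over a split region
#'
#' Each voxel is normalized to percent change from its own baseline frame and
#' the normalized signals are summed over every voxel of each compartment
#' (aggregation by sum is the model's convention; `how = "mean"` is available
#' for region-style curves).
#'
#' @param dyn A [dynamic4d()] on the same grid as the masks.
#' @param split Result of [split_region()].
#' @param how "sum" (default) or "mean".
#' @param condition,animal_id Metadata for the curves.
#' @return A `compartment_pair`: the `split` fields plus `I_out`, `I_in`
#'   ([time_signal_curve()]s) and `usable` (FALSE when the inner compartment
#'   is empty).
#' @export
compartment_curves <- function(dyn, split, how = "sum", condition = "",
                               animal_id = "") {
  I_out <- mask_aggregate_tsc(dyn, split$outer_mask, how, label = "outer",
                              condition = condition, animal_id = animal_id)
  I_in <- if (split$degenerate) NULL else {
    mask_aggregate_tsc(dyn, split$inner_mask, how, label = "inner",
                       condition = condition, animal_id = animal_id)
  }
  structure(c(split, list(I_out = I_out, I_in = I_in,
                          usable = !split$degenerate)),
            class = "compartment_pair")
}

#' Wrap two curves as a compartment pair
#'
#' For curve-level workflows (no voxel data), e.g. synthetic cohorts.
#'
#' @param I_out,I_in Outer and inner [time_signal_curve()]s on one grid.
#' @param s Nominal thickness tag.
#' @return A `compartment_pair`.
#' @export
curve_pair <- function(I_out, I_in, s = NA_integer_) {
  stopifnot(identical(I_out$times, I_in$times))
  structure(list(region_id = NA_integer_, s = s, outer_mask = NULL,
                 inner_mask = NULL, n_outer = NA_integer_,
                 n_inner = NA_integer_, degenerate = FALSE,
                 I_out = I_out, I_in = I_in, usable = TRUE),
            class = "compartment_pair")
}
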