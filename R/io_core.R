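# Core containers: label volumes, 4D dynamics, time signal curves, and the
# TSV round-trip formats shared by the whole pipeline.

#' Construct a label volume
#'
#' An atlas-style 3D integer label image. Label 0 is background; any other id
#' addresses a brain region, optionally named through `lookup`.
#'
#' @param voxels 3D array of nonnegative integer region ids.
#' @param voxel_size Physical voxel edge lengths in mm (length 3).
#' @param lookup Named character vector mapping region id (name of element)
#'   to region name. May be empty.
#' @return A `label_volume` object.
#' @export
label_volume <- function(voxels, voxel_size = c(1, 1, 1), lookup = character()) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (any(voxels < 0) || any(voxels != round(voxels))) {
    stop("labels must be nonnegative integers")
  }
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("voxel_size must be 3 positive lengths (mm)")
  }
  structure(
    list(voxels = array(as.integer(round(voxels)), dim = dim(voxels)),
         voxel_size = as.numeric(voxel_size),
         lookup = lookup),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  ids <- setdiff(sort(unique(as.vector(x$voxels))), 0L)
  cat("label_volume:", paste(dim(x$voxels), collapse = " x "),
      "voxels,", length(ids), "region(s)\n")
  invisible(x)
}

#' Region name lookup
#'
#' @param lab A [label_volume()].
#' @param region_id Integer region id present in the volume.
#' @return The region name.
#' @export
region_name <- function(lab, region_id) {
  key <- as.character(region_id)
  if (!key %in% names(lab$lookup)) {
    stop("region id ", region_id, " not present in lookup")
  }
  unname(lab$lookup[key])
}

#' Read a label volume from NIfTI
#'
#' @param path NIfTI file with integer-valued voxels.
#' @param lookup_path Optional TSV with columns `region_id`, `region_name`.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, lookup_path = NULL) {
  img <- read_nifti(path)
  if (any(img != round(img))) stop("label image is not integer-valued: ", path)
  lookup <- character()
  if (!is.null(lookup_path)) {
    tab <- utils::read.delim(lookup_path, stringsAsFactors = FALSE)
    lookup <- stats::setNames(as.character(tab$region_name),
                              as.character(tab$region_id))
  }
  label_volume(img, voxel_size = attr(img, "pixdim"), lookup = lookup)
}

#' Write a label volume to NIfTI
#'
#' @param lab A [label_volume()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @param lookup_path Optional path for the region lookup TSV.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(lab, path, lookup_path = NULL) {
  write_nifti(lab$voxels, path, pixdim = lab$voxel_size, datatype = 8L)
  if (!is.null(lookup_path) && length(lab$lookup)) {
    utils::write.table(
      data.frame(region_id = names(lab$lookup), region_name = unname(lab$lookup)),
      lookup_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Construct a 4D dynamic series
#'
#' @param frames 4D array (x, y, z, frame) of signal intensities.
#' @param times Acquisition midpoint of each frame in minutes, strictly
#'   increasing, one per frame.
#' @param baseline_index 1-based index of the pre-contrast baseline frame.
#' @param voxel_size Voxel edge lengths in mm.
#' @return A `dynamic4d` object.
#' @export
dynamic4d <- function(frames, times, baseline_index = 1L, voxel_size = c(1, 1, 1)) {
  if (length(dim(frames)) != 4L) stop("frames must be a 4D array")
  nt <- dim(frames)[4]
  if (length(times) != nt) stop("times length must equal frame count")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (baseline_index < 1L || baseline_index > nt) stop("baseline_index out of range")
  structure(
    list(frames = frames, times = as.numeric(times),
         baseline_index = as.integer(baseline_index),
         voxel_size = as.numeric(voxel_size)),
    class = "dynamic4d"
  )
}

#' Read a 4D dynamic series from NIfTI
#'
#' Frame times are not part of the NIfTI subset used here and must be given.
#'
#' @param path 4D NIfTI file.
#' @inheritParams dynamic4d
#' @return A [dynamic4d()].
#' @export
read_dynamic4d <- function(path, times, baseline_index = 1L) {
  img <- read_nifti(path)
  if (length(dim(img)) != 4L) stop("expected a 4D image: ", path)
  dynamic4d(img, times, baseline_index, voxel_size = attr(img, "pixdim"))
}

#' Construct a time signal curve
#'
#' Holds a sampled region or compartment signal in percent change from the
#' pre-contrast baseline on a strictly increasing time grid (minutes).
#'
#' @param times Sample times in minutes, strictly increasing, length >= 4.
#' @param values Percent signal change from baseline, same length.
#' @param label Region or compartment identifier.
#' @param condition Anesthetic-regimen tag.
#' @param animal_id Optional animal identifier.
#' @return A `time_signal_curve` object.
#' @export
time_signal_curve <- function(times, values, label = "", condition = "",
                              animal_id = "") {
  if (length(times) != length(values)) stop("times and values must match")
  if (length(times) < 4L) stop("a TSC needs at least 4 samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(
    list(times = as.numeric(times), values = as.numeric(values),
         label = as.character(label), condition = as.character(condition),
         animal_id = as.character(animal_id)),
    class = "time_signal_curve"
  )
}

#' @export
print.time_signal_curve <- function(x, ...) {
  cat(sprintf("time_signal_curve '%s' [%s]: %d samples, t in [%g, %g] min\n",
              x$label, x$condition, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Percent-change normalization to baseline
#'
#' Converts raw intensities to percent change from the baseline sample:
#' `100 * (raw - raw[baseline_index]) / raw[baseline_index]`. The baseline
#' sample maps to exactly 0.
#'
#' @param raw Numeric vector of raw intensities.
#' @param baseline_index 1-based index of the baseline sample.
#' @return Percent-change values, same length as `raw`.
#' @export
normalize_to_baseline <- function(raw, baseline_index = 1L) {
  bl <- raw[baseline_index]
  if (is.na(bl) || bl <= 0) stop("baseline intensity must be positive")
  100 * (raw - bl) / bl
}

#' Extract a region-wise time signal curve
#'
#' Per frame, the mean raw intensity over the voxels of `region_id` is taken
#' and the resulting series is normalized to percent change from the baseline
#' frame.
#'
#' @param dyn A [dynamic4d()].
#' @param lab A [label_volume()] co-registered with `dyn`.
#' @param region_id Region id with at least one voxel.
#' @param label,condition,animal_id Metadata passed to the returned curve.
#' @return A [time_signal_curve()].
#' @export
extract_region_tsc <- function(dyn, lab, region_id, label = NULL,
                               condition = "", animal_id = "") {
  mask <- lab$voxels == region_id
  n <- sum(mask)
  if (n == 0L) stop("region ", region_id, " has no voxels")
  nt <- dim(dyn$frames)[4]
  fr <- matrix(dyn$frames, ncol = nt)
  raw <- colMeans(fr[as.vector(mask), , drop = FALSE])
  if (is.null(label)) {
    label <- if (as.character(region_id) %in% names(lab$lookup)) {
      lab$lookup[[as.character(region_id)]]
    } else as.character(region_id)
  }
  time_signal_curve(dyn$times, normalize_to_baseline(raw, dyn$baseline_index),
                    label = label, condition = condition, animal_id = animal_id)
}

#' Write time signal curves to TSV
#'
#' On-disk format: one header line, columns `time_min`, `value_pct`, `label`,
#' `condition`, `animal_id`.
#'
#' @param tscs A [time_signal_curve()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsc_table <- function(tscs, path) {
  if (inherits(tscs, "time_signal_curve")) tscs <- list(tscs)
  rows <- do.call(rbind, lapply(tscs, function(x) {
    data.frame(time_min = x$times, value_pct = x$values, label = x$label,
               condition = x$condition, animal_id = x$animal_id,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read time signal curves from TSV
#'
#' @param path TSV written by [write_tsc_table()].
#' @return A list of [time_signal_curve()], one per unique
#'   (label, condition, animal_id) triple, in order of first appearance.
#' @export
read_tsc_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(time_min = "numeric",
                                          value_pct = "numeric",
                                          label = "character",
                                          condition = "character",
                                          animal_id = "character"))
  key <- paste(tab$label, tab$condition, tab$animal_id, sep = "\r")
  lapply(split(tab, factor(key, levels = unique(key))), function(d) {
    time_signal_curve(d$time_min, d$value_pct, label = d$label[1],
                      condition = d$condition[1], animal_id = d$animal_id[1])
  })
}
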