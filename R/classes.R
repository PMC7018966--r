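## Core S3 containers shared by the spread and morpho pipelines.

CELL_TYPES <- c("inflammatory", "fibroblastic", "endocardial", "undefined")

#' Maximal-voltage amplitude map
#'
#' A 2D image of maximal membrane-voltage amplitude (arbitrary fluorescence
#' units) together with its pixel pitch. This is the substrate of the
#' decay-constant pipeline: amplitudes are binned and regressed against
#' radial distance from the stimulating electrode.
#'
#' @param values numeric matrix of amplitudes (a.u.); must be finite and
#'   non-negative.
#' @param pixel_pitch pixel size in mm/pixel.
#' @return An object of class `amplitude_map` with fields `values` and
#'   `pixel_pitch`.
#' @export
amplitude_map <- function(values, pixel_pitch) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (any(!is.finite(values))) stopf("amplitude map contains non-finite values")
  if (any(values < 0)) stopf("amplitude map contains negative values")
  assert_scalar_pos(pixel_pitch, "pixel_pitch")
  structure(list(values = values, pixel_pitch = pixel_pitch),
            class = "amplitude_map")
}

#' @export
print.amplitude_map <- function(x, ...) {
  cat(sprintf("<amplitude_map> %d x %d px, pitch %.4g mm/px, range [%.4g, %.4g] a.u.\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voltage-imaging movie
#'
#' A stack of fluorescence frames (time, row, col) from optical mapping of a
#' Langendorff-perfused heart stained with a voltage-sensitive dye.
#'
#' @param frames 3D numeric array, dimensions (t, row, col).
#' @param frame_rate acquisition rate in frames/s.
#' @param pixel_pitch pixel size in mm/pixel.
#' @return An object of class `voltage_movie`.
#' @export
voltage_movie <- function(frames, frame_rate, pixel_pitch) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stopf("'frames' must be a 3D array (t, row, col)")
  assert_scalar_pos(frame_rate, "frame_rate")
  assert_scalar_pos(pixel_pitch, "pixel_pitch")
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_pitch = pixel_pitch), class = "voltage_movie")
}

#' @export
print.voltage_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<voltage_movie> %d frames of %d x %d px @ %g fps, pitch %.4g mm/px\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_pitch))
  invisible(x)
}

#' Region annotation for the passive-spread analysis
#'
#' Holds the scar outline, the electrode center and (optionally) a manually
#' selected uninjured-myocardium region, all in image coordinates. The
#' electrode center is a continuous (row, col) position; it must lie outside
#' the scar because current is injected into uninjured myocardium adjacent
#' to the scar.
#'
#' @param scar_mask logical matrix marking scar pixels.
#' @param electrode_center numeric length-2 (row, col), continuous pixel
#'   coordinates (1-based pixel centers).
#' @param uninjured_mask optional logical matrix, same shape, disjoint from
#'   the scar.
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(scar_mask, electrode_center,
                              uninjured_mask = NULL) {
  if (!is.logical(scar_mask) || !is.matrix(scar_mask))
    stopf("'scar_mask' must be a logical matrix")
  if (length(electrode_center) != 2L || any(!is.finite(electrode_center)))
    stopf("'electrode_center' must be finite (row, col)")
  er <- round(electrode_center[1]); ec <- round(electrode_center[2])
  if (er >= 1 && er <= nrow(scar_mask) && ec >= 1 && ec <= ncol(scar_mask) &&
      isTRUE(scar_mask[er, ec]))
    stopf("electrode_center lies inside scar_mask")
  if (!is.null(uninjured_mask)) {
    if (!identical(dim(uninjured_mask), dim(scar_mask)))
      stopf("uninjured_mask shape differs from scar_mask")
    if (any(uninjured_mask & scar_mask))
      stopf("uninjured_mask overlaps scar_mask")
  }
  structure(list(scar_mask = scar_mask,
                 electrode_center = as.numeric(electrode_center),
                 uninjured_mask = uninjured_mask),
            class = "region_annotation")
}

#' Labeled 3D voxel volume
#'
#' The substrate of all EM morphometrics: an integer label per voxel
#' (0 = extracellular matrix / background), an anisotropic voxel pitch in
#' nm, and a label-to-cell-type table. Serial block-face SEM stacks are
#' strongly anisotropic (here e.g. 6.3 x 6.3 nm pixels, 80 nm sections), so
#' every derived area/volume weights voxel faces by orientation.
#'
#' @param labels 3D integer array, dimensions (z, y, x); values >= 0.
#' @param voxel_pitch numeric length-3 (dz, dy, dx) in nm.
#' @param type_table named character vector mapping label -> cell type
#'   (one of inflammatory, fibroblastic, endocardial, undefined). Labels
#'   absent from the table default to "undefined".
#' @param nucleus_table optional named logical vector, label -> whether a
#'   nucleus is visible within the imaged block.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, voxel_pitch, type_table = NULL,
                           nucleus_table = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stopf("'labels' must be a 3D array (z, y, x)")
  if (any(labels < 0)) stopf("labels must be >= 0")
  if (!is.numeric(voxel_pitch) || length(voxel_pitch) != 3L ||
      any(!is.finite(voxel_pitch)) || any(voxel_pitch <= 0))
    stopf("'voxel_pitch' must be three positive pitches (dz, dy, dx) in nm")
  storage.mode(labels) <- "integer"
  present <- sort(unique(as.vector(labels)))
  present <- present[present > 0L]
  tt <- rep("undefined", length(present))
  names(tt) <- as.character(present)
  if (!is.null(type_table)) {
    type_table <- unlist(type_table)
    bad <- setdiff(unique(type_table), CELL_TYPES)
    if (length(bad))
      stopf("unknown cell type(s): %s", paste(bad, collapse = ", "))
    keep <- intersect(names(type_table), names(tt))
    tt[keep] <- type_table[keep]
    extra <- setdiff(names(type_table), names(tt))
    if (length(extra))
      attr(tt, "absent_labels") <- as.integer(extra)
  }
  if (!is.null(nucleus_table)) nucleus_table <- unlist(nucleus_table)
  structure(list(labels = labels, voxel_pitch = as.numeric(voxel_pitch),
                 type_table = tt, nucleus_table = nucleus_table),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels (z,y,x), pitch (%g, %g, %g) nm, %d cells\n",
              d[1], d[2], d[3], x$voxel_pitch[1], x$voxel_pitch[2],
              x$voxel_pitch[3], length(x$type_table)))
  invisible(x)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> DC = %.4g mm, v_edge = %.4g a.u., R^2 = %.4f, converged: %s\n",
              x$decay_constant, x$v_edge, x$r_squared, x$converged))
  if (!is.null(x$bins))
    cat(sprintf("  fitted on %d bins (%d pixels)\n", nrow(x$bins),
                sum(x$bins$pixel_count)))
  invisible(x)
}
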