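## Synthetic voltage maps and movies with known ground truth.
##
## The observation model mirrors optical mapping of passive electrotonic
## spread: a current pulse is injected by an electrode adjacent to a scar and
## the maximal sub-threshold voltage deflection decays with distance, with a
## region-specific space constant lambda.

#' Specification of a synthetic tissue sheet
#'
#' Describes a 2D tissue sheet imaged from above: grid geometry, electrode
#' position, a scar region, region-specific space constants, edge amplitude,
#' additive Gaussian noise, and the generative mode.
#'
#' @param grid_shape integer (rows, cols) in pixels.
#' @param pixel_pitch mm per pixel (the reference acquisition used 0.0928).
#' @param electrode_center continuous (row, col) pixel coordinates.
#' @param scar_mask logical matrix marking the scar; must not contain the
#'   electrode center.
#' @param lambda_scar space constant of the scar, mm.
#' @param lambda_uninjured space constant of uninjured myocardium, mm.
#' @param v_edge amplitude (a.u.) at the region edge nearest the electrode.
#' @param noise_sd additive i.i.d. Gaussian noise SD per pixel (a.u.).
#' @param mode `"pure_exponential"` (closed-form decay law) or
#'   `"cable_steady_state"` (finite-difference solve of the steady-state
#'   cable equation `lambda^2 * laplacian(V) - V = -source` on the sheet).
#' @param uninjured_mask optional logical matrix; when present it provides
#'   the distance reference (edge) for the uninjured decay law.
#' @param seed integer RNG seed; identical specs and seeds give bit-identical
#'   outputs.
#' @return An object of class `sheet_spec`.
#' @export
sheet_spec <- function(grid_shape, pixel_pitch, electrode_center, scar_mask,
                       lambda_scar, lambda_uninjured, v_edge = 10,
                       noise_sd = 0,
                       mode = c("pure_exponential", "cable_steady_state"),
                       uninjured_mask = NULL, seed = 1L) {
  mode <- match.arg(mode)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 3L))
    stopf("'grid_shape' must be (rows, cols), each >= 3")
  assert_scalar_pos(pixel_pitch, "pixel_pitch")
  assert_scalar_pos(lambda_scar, "lambda_scar")
  assert_scalar_pos(lambda_uninjured, "lambda_uninjured")
  assert_scalar_pos(v_edge, "v_edge")
  if (!is.numeric(noise_sd) || noise_sd < 0) stopf("'noise_sd' must be >= 0")
  if (!identical(dim(scar_mask), grid_shape) &&
      !identical(dim(scar_mask), as.integer(grid_shape)))
    stopf("scar_mask shape must equal grid_shape")
  ## region_annotation enforces disjointness and the electrode placement
  ann <- region_annotation(scar_mask, electrode_center, uninjured_mask)
  structure(list(grid_shape = grid_shape, pixel_pitch = pixel_pitch,
                 electrode_center = ann$electrode_center,
                 scar_mask = ann$scar_mask,
                 uninjured_mask = ann$uninjured_mask,
                 lambda_scar = lambda_scar,
                 lambda_uninjured = lambda_uninjured,
                 v_edge = v_edge, noise_sd = noise_sd, mode = mode,
                 seed = as.integer(seed)),
            class = "sheet_spec")
}

#' Annular-sector mask
#'
#' Convenience builder for scar-like regions: the set of pixels whose
#' electrode distance lies in `[r_min, r_max]` mm and whose azimuth from the
#' center is within `half_angle_deg` of `axis_angle_deg`.
#'
#' @param grid_shape (rows, cols).
#' @param center (row, col) continuous pixel coordinates of the electrode.
#' @param r_min,r_max radial limits in mm.
#' @param half_angle_deg half-opening angle of the sector, degrees.
#' @param pixel_pitch mm per pixel.
#' @param axis_angle_deg direction of the sector axis, degrees (0 = +row).
#' @return Logical matrix.
#' @export
sector_mask <- function(grid_shape, center, r_min, r_max, half_angle_deg,
                        pixel_pitch, axis_angle_deg = 0) {
  g <- coord_grids(grid_shape)
  r <- sqrt((g$row - center[1])^2 + (g$col - center[2])^2) * pixel_pitch
  ang <- atan2(g$col - center[2], g$row - center[1]) * 180 / pi
  dang <- ((ang - axis_angle_deg + 180) %% 360) - 180
  r >= r_min & r <= r_max & abs(dang) <= half_angle_deg
}

new_ground_truth <- function(...) structure(list(...), class = "ground_truth")

#' Generate a synthetic maximal-amplitude map
#'
#' In `pure_exponential` mode each scar pixel gets
#' `v_edge * exp(-(r - r_edge_scar)/lambda_scar)` where `r` is the Euclidean
#' distance (mm) from the electrode center to the pixel center and
#' `r_edge_scar` is the minimum `r` over the scar mask; all other pixels get
#' the uninjured law (referenced to the uninjured mask's edge when that mask
#' is present, else to the electrode). In `cable_steady_state` mode the map
#' is the steady-state solution of the cable equation on the sheet with a
#' region-dependent space constant, a single-pixel current source at the
#' electrode and V = 0 at the border, scaled so its maximum equals `v_edge`.
#' Additive Gaussian noise (SD `noise_sd`) is applied last, truncated at 0
#' so the result remains a valid amplitude map.
#'
#' @param spec a [sheet_spec()].
#' @return A list with elements `map` ([amplitude_map]) and `truth`
#'   (`ground_truth` record: true lambdas, v_edge, noise_sd, seed, mode and
#'   any generation warnings).
#' @export
generate_amplitude_map <- function(spec) {
  stopifnot(inherits(spec, "sheet_spec"))
  if (!any(spec$scar_mask)) stopf("scar_mask is empty")
  warnings <- character()
  if (min(spec$lambda_scar, spec$lambda_uninjured) < spec$pixel_pitch)
    warnings <- c(warnings,
                  "space constant smaller than one pixel pitch; map is undersampled")

  r <- pixel_distances_mm(spec$grid_shape, spec$electrode_center,
                          spec$pixel_pitch)
  if (spec$mode == "pure_exponential") {
    r_edge_scar <- min(r[spec$scar_mask])
    r_edge_unj <- if (!is.null(spec$uninjured_mask) && any(spec$uninjured_mask))
      min(r[spec$uninjured_mask]) else 0
    vals <- spec$v_edge * exp(-(r - r_edge_unj) / spec$lambda_uninjured)
    vals[spec$scar_mask] <-
      spec$v_edge * exp(-(r[spec$scar_mask] - r_edge_scar) / spec$lambda_scar)
  } else {
    vals <- cable_sheet_solve(spec)
    vals <- vals * (spec$v_edge / max(vals))
  }
  if (spec$noise_sd > 0) {
    vals <- with_seed(spec$seed,
                      vals + matrix(rnorm(length(vals), sd = spec$noise_sd),
                                    nrow(vals), ncol(vals)))
  }
  vals[vals < 0] <- 0
  truth <- new_ground_truth(
    lambda_scar = spec$lambda_scar, lambda_uninjured = spec$lambda_uninjured,
    v_edge = spec$v_edge, noise_sd = spec$noise_sd, seed = spec$seed,
    mode = spec$mode, warnings = warnings)
  list(map = amplitude_map(vals, spec$pixel_pitch), truth = truth)
}

## 5-point finite-difference solve of lambda^2 * laplacian(V) - V = -s with
## Dirichlet V = 0 outside the sheet and a unit source at the pixel nearest
## the electrode center. lambda varies by region (scar vs elsewhere).
cable_sheet_solve <- function(spec) {
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  h <- spec$pixel_pitch
  lam2 <- matrix(spec$lambda_uninjured^2, nr, nc)
  lam2[spec$scar_mask] <- spec$lambda_scar^2
  n <- nr * nc
  idx <- matrix(seq_len(n), nr, nc)
  coef_c <- lam2 / h^2

  ii <- list(); jj <- list(); xx <- list()
  push <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  ## neighbor couplings (missing neighbors are V = 0, so simply dropped)
  push(as.vector(idx[-1, ]), as.vector(idx[-nr, ]), as.vector(coef_c[-1, ]))
  push(as.vector(idx[-nr, ]), as.vector(idx[-1, ]), as.vector(coef_c[-nr, ]))
  push(as.vector(idx[, -1]), as.vector(idx[, -nc]), as.vector(coef_c[, -1]))
  push(as.vector(idx[, -nc]), as.vector(idx[, -1]), as.vector(coef_c[, -nc]))
  push(seq_len(n), seq_len(n), as.vector(-4 * coef_c - 1))
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  b <- numeric(n)
  src <- c(min(max(round(spec$electrode_center[1]), 1), nr),
           min(max(round(spec$electrode_center[2]), 1), nc))
  b[idx[src[1], src[2]]] <- -1
  v <- as.numeric(Matrix::solve(A, b))
  matrix(v, nr, nc)
}

#' Generate a synthetic voltage movie
#'
#' Emulates pulsed current injection during optical mapping: baseline frames
#' carry amplitude 0 plus noise; frames inside the pulse window carry the
#' [generate_amplitude_map()] image plus noise. Applying
#' [compute_amplitude_map()] with the same windows recovers the map (exactly
#' when `noise_sd = 0`).
#'
#' @param spec a [sheet_spec()].
#' @param frames total number of frames.
#' @param pulse_window integer (start, end): 0-based, half-open frame window
#'   of the pulse, i.e. frames `start .. end-1` carry the pulse.
#' @param frame_rate frames per second (metadata only; default 1000).
#' @return A list with elements `movie` ([voltage_movie]) and `truth`.
#' @export
generate_voltage_movie <- function(spec, frames, pulse_window,
                                   frame_rate = 1000) {
  stopifnot(inherits(spec, "sheet_spec"))
  if (!is_count(frames)) stopf("'frames' must be a positive integer")
  pw <- as.integer(pulse_window)
  if (length(pw) != 2L || pw[1] < 0 || pw[2] <= pw[1] || pw[2] > frames)
    stopf("pulse_window must satisfy 0 <= start < end <= frames")
  noise_free <- spec
  noise_free$noise_sd <- 0
  gen <- generate_amplitude_map(noise_free)
  base <- gen$map$values
  nr <- nrow(base); nc <- ncol(base)
  arr <- with_seed(spec$seed, {
    a <- array(0, dim = c(frames, nr, nc))
    for (t in (pw[1] + 1L):pw[2]) a[t, , ] <- base
    if (spec$noise_sd > 0)
      a <- a + array(rnorm(length(a), sd = spec$noise_sd), dim = dim(a))
    a
  })
  truth <- gen$truth
  truth$noise_sd <- spec$noise_sd
  truth$pulse_window <- pw
  truth$frames <- as.integer(frames)
  list(movie = voltage_movie(arr, frame_rate, spec$pixel_pitch),
       truth = truth)
}
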