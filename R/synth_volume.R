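## Synthetic labeled EM volumes with known ground truth.
##
## Emulates a segmented serial block-face SEM stack: an integer label per
## voxel (0 = extracellular matrix), strongly anisotropic voxel pitch, cells
## of prescribed shape/size/placement, optional required face contacts, and
## an optional target cellular volume fraction reached by packing random
## filler cells (spheres and flattened, sheet-like ellipsoids).

#' Prescribe a single synthetic cell
#'
#' @param cell_type one of `"inflammatory"`, `"fibroblastic"`,
#'   `"endocardial"`, `"undefined"`.
#' @param shape `"sphere"`, `"ellipsoid"`, `"box"` or `"sheet"` (a sheet is
#'   a box that is thin along one axis; the caller chooses the extents).
#' @param size nm: a single radius for spheres; semi-axes (z, y, x) for
#'   ellipsoids; full extents (z, y, x) for boxes and sheets.
#' @param center continuous (z, y, x) position in voxel units (voxel `k`
#'   has coordinate `k`).
#' @return A `cell_prescription` list.
#' @export
cell_prescription <- function(cell_type, shape, size, center) {
  shape <- match.arg(shape, c("sphere", "ellipsoid", "box", "sheet"))
  cell_type <- match.arg(cell_type, CELL_TYPES)
  if (shape == "sphere") {
    if (length(size) != 1L || size <= 0) stopf("sphere size is one radius (nm)")
  } else if (length(size) != 3L || any(size <= 0)) {
    stopf("'%s' size must be three positive extents/semi-axes (z, y, x) nm", shape)
  }
  if (length(center) != 3L) stopf("'center' must be (z, y, x) in voxels")
  structure(list(cell_type = cell_type, shape = shape,
                 size = as.numeric(size), center = as.numeric(center)),
            class = "cell_prescription")
}

#' Specification of a synthetic labeled volume
#'
#' @param grid_shape integer (z, y, x) voxel counts.
#' @param voxel_pitch (dz, dy, dx) in nm; the reference stack used
#'   (80, 6.3, 6.3).
#' @param cells list of [cell_prescription()]s, placed greedily in order and
#'   labeled 1, 2, ... Overlaps are errors, not silent displacement.
#' @param target_cell_fraction optional fraction in `[0, 1]`; random filler
#'   cells are added until the non-background voxel fraction is within 0.5
#'   percentage points of this target.
#' @param contact_plan list of length-2 vectors `(a, b)` of labels required
#'   to share at least one voxel face; realized shared-face areas are
#'   recorded exactly in the ground truth.
#' @param seed integer RNG seed.
#' @return An object of class `volume_spec`.
#' @export
volume_spec <- function(grid_shape, voxel_pitch, cells = list(),
                        target_cell_fraction = NULL, contact_plan = list(),
                        seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 2L))
    stopf("'grid_shape' must be (z, y, x), each >= 2")
  if (length(voxel_pitch) != 3L || any(voxel_pitch <= 0))
    stopf("'voxel_pitch' must be three positive pitches (dz, dy, dx) nm")
  if (!is.null(target_cell_fraction)) {
    if (!is.numeric(target_cell_fraction) || target_cell_fraction < 0 ||
        target_cell_fraction > 1)
      stopf("'target_cell_fraction' must lie in [0, 1]")
  }
  for (cp in cells) stopifnot(inherits(cp, "cell_prescription"))
  for (p in contact_plan)
    if (length(p) != 2L || any(p < 1)) stopf("contact_plan entries are label pairs")
  structure(list(grid_shape = grid_shape, voxel_pitch = as.numeric(voxel_pitch),
                 cells = cells, target_cell_fraction = target_cell_fraction,
                 contact_plan = contact_plan, seed = as.integer(seed)),
            class = "volume_spec")
}

## Rasterize one cell onto its bounding subbox. Returns NULL when the ideal
## bounding box does not fit in the grid (caller decides error vs reject).
rasterize_cell <- function(dims, pitch, shape, size, center) {
  half <- switch(shape,
                 sphere = rep(size, 3) / pitch,
                 ellipsoid = size / pitch,
                 box = , sheet = (size / 2) / pitch)
  lo <- ceiling(center - half - 1e-9)
  hi <- floor(center + half + 1e-9)
  if (any(lo < 1) || any(hi > dims)) return(NULL)
  zc <- (lo[1]:hi[1] - center[1]) * pitch[1]
  yc <- (lo[2]:hi[2] - center[2]) * pitch[2]
  xc <- (lo[3]:hi[3] - center[3]) * pitch[3]
  eps <- 1e-9
  mask <- switch(shape,
    sphere = outer(outer(zc^2, yc^2, "+"), xc^2, "+") <= size^2 * (1 + eps),
    ellipsoid = outer(outer((zc / size[1])^2, (yc / size[2])^2, "+"),
                      (xc / size[3])^2, "+") <= 1 + eps,
    outer(outer(abs(zc) <= size[1] / 2 + eps, abs(yc) <= size[2] / 2 + eps, "&"),
          abs(xc) <= size[3] / 2 + eps, "&"))
  list(lo = lo, hi = hi, mask = mask, n = sum(mask))
}

## Exact shared-face area (um^2) between labels a and b, restricted to their
## joint bounding box. Direct slab-by-slab face enumeration.
pair_contact_area <- function(labels, pitch, a, b) {
  hit <- labels == a | labels == b
  if (!any(hit)) return(0)
  w <- which(hit, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - 1L, 1L)
  hi <- pmin(apply(w, 2, max) + 1L, dim(labels))
  sub <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(sub)
  face_nm2 <- c(pitch[2] * pitch[3], pitch[1] * pitch[3], pitch[1] * pitch[2])
  area <- 0
  if (d[1] > 1) {
    s1 <- sub[-d[1], , , drop = FALSE]; s2 <- sub[-1, , , drop = FALSE]
    area <- area + sum((s1 == a & s2 == b) | (s1 == b & s2 == a)) * face_nm2[1]
  }
  if (d[2] > 1) {
    s1 <- sub[, -d[2], , drop = FALSE]; s2 <- sub[, -1, , drop = FALSE]
    area <- area + sum((s1 == a & s2 == b) | (s1 == b & s2 == a)) * face_nm2[2]
  }
  if (d[3] > 1) {
    s1 <- sub[, , -d[3], drop = FALSE]; s2 <- sub[, , -1, drop = FALSE]
    area <- area + sum((s1 == a & s2 == b) | (s1 == b & s2 == a)) * face_nm2[3]
  }
  area / 1e6
}

#' Generate a synthetic labeled volume
#'
#' Places the prescribed cells greedily in order (overlap or not fitting is
#' an error naming the offending labels), verifies every pair in the contact
#' plan actually shares voxel faces, then (optionally) packs random filler
#' cells — spheres and flattened sheet-like ellipsoids of shrinking size —
#' until the realized cellular volume fraction is within 0.5 percentage
#' points of `target_cell_fraction`.
#'
#' @param spec a [volume_spec()].
#' @return A list with elements `volume` ([labeled_volume]) and `truth`
#'   (`ground_truth`: exact per-cell voxel counts and volumes, exact
#'   shared-face areas for every planned pair, realized cell fraction, seed).
#' @export
generate_labeled_volume <- function(spec) {
  stopifnot(inherits(spec, "volume_spec"))
  dims <- spec$grid_shape
  pitch <- spec$voxel_pitch
  labels <- array(0L, dim = dims)
  types <- character()

  for (i in seq_along(spec$cells)) {
    cp <- spec$cells[[i]]
    ras <- rasterize_cell(dims, pitch, cp$shape, cp$size, cp$center)
    if (is.null(ras))
      stopf("prescribed cell %d (%s) does not fit inside the grid", i, cp$shape)
    if (ras$n == 0L) stopf("prescribed cell %d rasterizes to zero voxels", i)
    sub <- labels[ras$lo[1]:ras$hi[1], ras$lo[2]:ras$hi[2],
                  ras$lo[3]:ras$hi[3], drop = FALSE]
    clash <- unique(sub[ras$mask & sub != 0L])
    if (length(clash))
      stopf("cell %d overlaps previously placed cell(s): %s", i,
            paste(sort(clash), collapse = ", "))
    sub[ras$mask] <- i
    labels[ras$lo[1]:ras$hi[1], ras$lo[2]:ras$hi[2],
           ras$lo[3]:ras$hi[3]] <- sub
    types[as.character(i)] <- cp$cell_type
  }

  ## verify the contact plan against the realized volume
  plan_areas <- NULL
  if (length(spec$contact_plan)) {
    plan_areas <- data.frame(
      label_a = integer(), label_b = integer(), area_um2 = numeric())
    missing <- character()
    for (p in spec$contact_plan) {
      a <- min(p); b <- max(p)
      ar <- pair_contact_area(labels, pitch, a, b)
      if (ar <= 0) missing <- c(missing, sprintf("(%d, %d)", a, b))
      plan_areas <- rbind(plan_areas,
                          data.frame(label_a = a, label_b = b, area_um2 = ar))
    }
    if (length(missing))
      stopf("contact plan infeasible; pairs with no shared faces: %s",
            paste(missing, collapse = ", "))
  }

  warnings <- character()
  n_total <- prod(dims)
  if (!is.null(spec$target_cell_fraction)) {
    target <- spec$target_cell_fraction
    tol <- 0.002             # stricter than the 0.005 contract, by construction
    cur <- sum(labels != 0L)
    if (cur / n_total > target + tol)
      stopf("prescribed cells already exceed target_cell_fraction (%.4f > %.4f)",
            cur / n_total, target)
    fill <- with_seed(spec$seed,
                      pack_filler_cells(labels, types, dims, pitch, cur,
                                        target, tol))
    labels <- fill$labels; types <- fill$types
  }

  counts <- tabulate(labels[labels != 0L], nbins = max(labels, 1L))
  frac <- sum(counts) / n_total
  truth <- new_ground_truth(
    voxel_counts = counts,
    volumes_um3 = counts * prod(pitch) / 1e9,
    contact_areas = plan_areas,
    cell_fraction = frac,
    seed = spec$seed,
    warnings = warnings)
  vol <- labeled_volume(labels, pitch, type_table = types)
  list(volume = vol, truth = truth)
}

## Random sequential packing with a shrinking size schedule. Acceptance is
## guarded so the realized fraction lands in [target - tol, target + tol].
pack_filler_cells <- function(labels, types, dims, pitch, cur, target, tol) {
  n_total <- prod(dims)
  lo_n <- (target - tol) * n_total
  hi_n <- (target + tol) * n_total
  radius <- min(dims * pitch) / 4
  fails <- 0L
  iter <- 0L
  next_label <- if (length(types)) max(as.integer(names(types))) + 1L else 1L
  while (cur < lo_n) {
    iter <- iter + 1L
    if (iter > 50000L)
      stopf("filler packing did not reach target_cell_fraction")
    if (fails >= 40L) {
      radius <- radius * 0.75
      fails <- 0L
      if (radius < max(pitch) / 4)
        stopf("filler packing stalled before reaching target_cell_fraction")
    }
    is_sheet <- stats::runif(1) < 0.25
    if (is_sheet) {
      ax <- sample.int(3L, 1L)
      size <- rep(radius * 1.3, 3)
      size[ax] <- max(radius / 6, 1.2 * pitch[ax])
      shape <- "ellipsoid"            # flattened ellipsoid = sheet-like cell
      half <- size / pitch
    } else {
      shape <- "sphere"; size <- radius; half <- rep(radius, 3) / pitch
    }
    center <- 1 + half + stats::runif(3) * pmax(dims - 1 - 2 * half, 0)
    if (any(center - half < 1 - 1e-9) || any(center + half > dims + 1e-9)) {
      fails <- fails + 1L; next
    }
    ras <- rasterize_cell(dims, pitch, shape, size, center)
    if (is.null(ras) || ras$n == 0L) { fails <- fails + 1L; next }
    if (cur + ras$n > hi_n) { fails <- fails + 1L; next }   # would overshoot
    sub <- labels[ras$lo[1]:ras$hi[1], ras$lo[2]:ras$hi[2],
                  ras$lo[3]:ras$hi[3], drop = FALSE]
    if (any(sub[ras$mask] != 0L)) { fails <- fails + 1L; next }
    sub[ras$mask] <- next_label
    labels[ras$lo[1]:ras$hi[1], ras$lo[2]:ras$hi[2],
           ras$lo[3]:ras$hi[3]] <- sub
    types[as.character(next_label)] <-
      sample(c("inflammatory", "fibroblastic", "endocardial"), 1L)
    next_label <- next_label + 1L
    cur <- cur + ras$n
    fails <- 0L
  }
  list(labels = labels, types = types)
}
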