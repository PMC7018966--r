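## Morphometrics of labeled EM volumes: per-cell volumes and surface areas,
## intercellular contact interfaces, the cell-contact network, and per-type
## summaries. All areas are sums of voxel-face areas weighted by orientation
## (the voxel pitch is anisotropic), reported in um^2; volumes in um^3.

face_areas_um2 <- function(pitch) {
  ## face normal to z spans dy*dx, to y spans dz*dx, to x spans dz*dy (nm^2)
  c(z = pitch[2] * pitch[3], y = pitch[1] * pitch[3],
    x = pitch[1] * pitch[2]) / 1e6
}

#' Physical volume of a stack
#'
#' For a [labeled_volume], the product of the three physical extents
#' (voxel count x pitch per axis), in cubic micrometers. A numeric length-3
#' vector is interpreted directly as extents in micrometers, so printed
#' stack dimensions can be checked without materializing a voxel array.
#'
#' @param x a [labeled_volume] or numeric length-3 extents (um).
#' @return Volume in um^3.
#' @export
stack_volume <- function(x) UseMethod("stack_volume")

#' @export
stack_volume.labeled_volume <- function(x) {
  prod(dim(x$labels) * x$voxel_pitch) / 1e9
}

#' @export
stack_volume.numeric <- function(x) {
  if (length(x) != 3L || any(x <= 0)) stopf("extents must be three positive um values")
  prod(x)
}

## Per-label face tallies against different-valued neighbors, plus boundary
## faces. Shared infrastructure for surface areas.
label_face_tally <- function(labels, pitch) {
  d <- dim(labels)
  nlab <- max(labels)
  fa <- face_areas_um2(pitch)
  surf <- numeric(nlab)
  boundary <- logical(nlab)
  add <- function(vals, area) {
    vals <- vals[vals > 0L]
    if (length(vals)) {
      t <- tabulate(vals, nbins = nlab)
      surf <<- surf + t * area
    }
  }
  for (ax in 1:3) {
    n <- d[ax]
    s1 <- switch(ax, labels[-n, , , drop = FALSE], labels[, -n, , drop = FALSE],
                 labels[, , -n, drop = FALSE])
    s2 <- switch(ax, labels[-1, , , drop = FALSE], labels[, -1, , drop = FALSE],
                 labels[, , -1, drop = FALSE])
    diff <- s1 != s2
    add(s1[diff], fa[ax])
    add(s2[diff], fa[ax])
    ## faces on the stack boundary are counted (cells cut by the block edge)
    first <- switch(ax, labels[1, , ], labels[, 1, ], labels[, , 1])
    last <- switch(ax, labels[n, , ], labels[, n, ], labels[, , n])
    add(first, fa[ax]); add(last, fa[ax])
    b <- unique(c(first[first > 0L], last[last > 0L]))
    boundary[b] <- TRUE
  }
  list(surface_um2 = surf, touches_boundary = boundary)
}

#' Per-cell morphometrics
#'
#' One record per nonzero label: exact voxel count and volume, voxel-face
#' surface area (faces against background, other cells, or the stack
#' boundary, each weighted by its anisotropic face area), whether the cell
#' touches the stack boundary, and (when a nucleus table is present)
#' whether a nucleus is visible in the block. Cells cut by the block edge
#' are kept but flagged, mirroring common practice with EM blocks where not
#' every nucleus is contained.
#'
#' @param vol a [labeled_volume].
#' @return A `data.frame` (one row per cell): `label`, `cell_type`,
#'   `voxel_count`, `volume_um3`, `surface_area_um2`, `touches_boundary`,
#'   `has_nucleus`.
#' @export
cell_morphometrics <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  labels <- vol$labels
  nlab <- max(labels)
  if (nlab == 0L) stopf("volume contains no cells (all background)")
  counts <- tabulate(labels[labels != 0L], nbins = nlab)
  present <- which(counts > 0L)
  tally <- label_face_tally(labels, vol$voxel_pitch)
  absent <- setdiff(as.integer(names(vol$type_table)), present)
  if (length(absent))
    warnf("label(s) %s present in type_table but absent from volume",
          paste(absent, collapse = ", "))
  tt <- vol$type_table
  ctype <- unname(tt[as.character(present)])
  ctype[is.na(ctype)] <- "undefined"
  nuc <- if (!is.null(vol$nucleus_table))
    unname(vol$nucleus_table[as.character(present)]) else rep(NA, length(present))
  out <- data.frame(
    label = present,
    cell_type = ctype,
    voxel_count = counts[present],
    volume_um3 = counts[present] * prod(vol$voxel_pitch) / 1e9,
    surface_area_um2 = tally$surface_um2[present],
    touches_boundary = tally$touches_boundary[present],
    has_nucleus = nuc,
    stringsAsFactors = FALSE)
  if (length(absent)) attr(out, "absent_labels") <- absent
  out
}

## all 6-connected face adjacencies between distinct nonzero labels, as a
## face table: lower-voxel coordinates, axis, and the two labels.
collect_shared_faces <- function(labels) {
  d <- dim(labels)
  res <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]
    s1 <- switch(ax, labels[-n, , , drop = FALSE], labels[, -n, , drop = FALSE],
                 labels[, , -n, drop = FALSE])
    s2 <- switch(ax, labels[-1, , , drop = FALSE], labels[, -1, , drop = FALSE],
                 labels[, , -1, drop = FALSE])
    sel <- which(s1 > 0L & s2 > 0L & s1 != s2)
    if (!length(sel)) next
    dd <- dim(s1)
    coord <- arrayInd(sel, dd)
    res[[ax]] <- data.frame(z = coord[, 1], y = coord[, 2], x = coord[, 3],
                            axis = ax, lab1 = s1[sel], lab2 = s2[sel])
  }
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}

## Connected components of one interface's face set. Two faces are connected
## when their a-side voxels are equal or 6-adjacent AND their b-side voxels
## are equal or 6-adjacent.
interface_patch_count <- function(faces) {
  n <- nrow(faces)
  if (n <= 1L) return(n)
  ## voxel coords on the a side (lower label side) and b side
  av <- cbind(faces$z, faces$y, faces$x)
  bv <- av
  for (i in seq_len(n)) bv[i, faces$axis[i]] <- bv[i, faces$axis[i]] + 1L
  swap <- faces$lab1 > faces$lab2
  tmp <- av[swap, , drop = FALSE]
  av[swap, ] <- bv[swap, , drop = FALSE]
  bv[swap, ] <- tmp
  adj6 <- function(p, q) sum(abs(p - q)) <= 1L     # equal or 6-adjacent
  edges <- list(); k <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (adj6(av[i, ], av[j, ]) && adj6(bv[i, ], bv[j, ])) {
      k <- k + 1L; edges[[k]] <- c(i, j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (k) g <- igraph::add_edges(g, unlist(edges))
  as.integer(igraph::components(g)$no)
}

#' Detect intercellular contact interfaces
#'
#' Exhaustively enumerates all 6-connected voxel-face adjacencies between
#' distinct nonzero labels. In voxel terms this is the operational
#' definition of an intercellular contact: directly apposed voxels of two
#' different cells with no background between them. Each face contributes
#' the area implied by the voxel pitch and the face orientation; diagonal
#' (edge/corner) adjacency contributes no area.
#'
#' @param vol a [labeled_volume].
#' @param patches logical; also report the number of connected patches per
#'   interface (can be slow on very large interfaces; the area and face
#'   count never depend on it).
#' @return A `data.frame` with `label_a < label_b`, `shared_face_count`,
#'   `area_um2` and (when `patches`) `patch_count`, one row per unordered
#'   cell pair in contact.
#' @export
detect_contacts <- function(vol, patches = TRUE) {
  stopifnot(inherits(vol, "labeled_volume"))
  faces <- collect_shared_faces(vol$labels)
  fa <- face_areas_um2(vol$voxel_pitch)
  empty <- data.frame(label_a = integer(), label_b = integer(),
                      shared_face_count = integer(), area_um2 = numeric())
  if (patches) empty$patch_count <- integer()
  if (is.null(faces) || !nrow(faces)) return(empty)
  a <- pmin(faces$lab1, faces$lab2)
  b <- pmax(faces$lab1, faces$lab2)
  key <- paste(a, b)
  area <- fa[faces$axis]
  agg_n <- tapply(area, key, length)
  agg_a <- tapply(area, key, sum)
  ks <- names(agg_n)
  parts <- do.call(rbind, strsplit(ks, " "))
  out <- data.frame(label_a = as.integer(parts[, 1]),
                    label_b = as.integer(parts[, 2]),
                    shared_face_count = as.integer(agg_n),
                    area_um2 = as.numeric(agg_a))
  if (patches) {
    out$patch_count <- vapply(ks, function(k)
      interface_patch_count(faces[key == k, , drop = FALSE]), integer(1))
  }
  o <- order(out$label_a, out$label_b)
  rownames(out) <- NULL
  out[o, , drop = FALSE]
}

#' Build the cell-contact network
#'
#' Nodes are cells (carrying their morphometrics), edges are contact
#' interfaces (carrying shared-face area and patch count). The node degree
#' is the number of interfacing cells.
#'
#' @param cells output of [cell_morphometrics()].
#' @param contacts output of [detect_contacts()].
#' @return An object of class `contact_graph`: list with the `igraph`
#'   object (`graph`) and the two tables (`cells`, `contacts`).
#' @export
build_contact_graph <- function(cells, contacts) {
  if (!nrow(cells)) stopf("no cells to build a graph from")
  unknown <- setdiff(unique(c(contacts$label_a, contacts$label_b)), cells$label)
  if (length(unknown))
    stopf("contact edge references unknown label(s): %s",
          paste(unknown, collapse = ", "))
  if (any(contacts$label_a == contacts$label_b)) stopf("self-contact edge")
  verts <- data.frame(name = as.character(cells$label), cells,
                      stringsAsFactors = FALSE)
  edges <- if (nrow(contacts))
    data.frame(from = as.character(contacts$label_a),
               to = as.character(contacts$label_b),
               contacts[, setdiff(names(contacts), c("label_a", "label_b")),
                        drop = FALSE])
  else data.frame(from = character(), to = character())
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
  structure(list(graph = g, cells = cells, contacts = contacts),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> %d cells, %d contact interfaces, total contact area %.4g um^2\n",
              nrow(x$cells), nrow(x$contacts), sum(x$contacts$area_um2)))
  invisible(x)
}

#' Summarize the contact network by cell type
#'
#' Per cell type: cell count, total and mean cell volume, volume fraction of
#' the stack, mean number of interfacing cells per cell (node degree), mean
#' contact area per interface (over interface incidences of cells of that
#' type), and the mean ratio of a cell's total contact area to its surface
#' area. These are the quantities used to compare inflammatory,
#' fibroblastic and endocardial populations.
#'
#' @param graph a [build_contact_graph()] result.
#' @param vol the originating [labeled_volume] (for the stack volume).
#' @return A `data.frame`, one row per cell type present.
#' @export
summarize_by_type <- function(graph, vol) {
  stopifnot(inherits(graph, "contact_graph"), inherits(vol, "labeled_volume"))
  cells <- graph$cells
  contacts <- graph$contacts
  if (!nrow(cells)) stopf("empty graph")
  total_um3 <- stack_volume(vol)
  deg <- igraph::degree(graph$graph)
  deg <- deg[as.character(cells$label)]
  ## per-cell incident contact area
  inc_area <- vapply(cells$label, function(l)
    sum(contacts$area_um2[contacts$label_a == l | contacts$label_b == l]),
    numeric(1))
  types_present <- intersect(CELL_TYPES, unique(cells$cell_type))
  skipped <- setdiff(CELL_TYPES, types_present)
  if (length(skipped))
    message("types with zero cells omitted: ", paste(skipped, collapse = ", "))
  rows <- lapply(types_present, function(tp) {
    sel <- cells$cell_type == tp
    labs <- cells$label[sel]
    inc_edges <- contacts[contacts$label_a %in% labs |
                          contacts$label_b %in% labs, , drop = FALSE]
    ## per-incidence mean: an interface between two cells of this type is
    ## seen from both cells
    inc_from <- c(contacts$area_um2[contacts$label_a %in% labs],
                  contacts$area_um2[contacts$label_b %in% labs])
    data.frame(
      cell_type = tp,
      n_cells = sum(sel),
      total_volume_um3 = sum(cells$volume_um3[sel]),
      mean_volume_um3 = mean(cells$volume_um3[sel]),
      volume_fraction = sum(cells$volume_um3[sel]) / total_um3,
      mean_interfacing_cells = mean(deg[sel]),
      mean_area_per_interface_um2 =
        if (length(inc_from)) mean(inc_from) else 0,
      mean_relative_contact_area =
        mean(inc_area[sel] / cells$surface_area_um2[sel]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cellular volume fraction of a labeled volume
#'
#' Fraction of voxels occupied by cells (nonzero labels), with a per-type
#' breakdown that sums exactly to the total.
#'
#' @param vol a [labeled_volume].
#' @return A list with `total` (fraction in `[0, 1]`) and `by_type` (named
#'   numeric vector of per-type fractions).
#' @export
cell_volume_fraction <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  labels <- vol$labels
  n <- length(labels)
  nz <- labels[labels != 0L]
  if (!length(nz)) return(list(total = 0, by_type = numeric()))
  counts <- tabulate(nz, nbins = max(nz))
  present <- which(counts > 0L)
  tp <- unname(vol$type_table[as.character(present)])
  tp[is.na(tp)] <- "undefined"
  by_type <- tapply(counts[present] / n, tp, sum)
  list(total = length(nz) / n, by_type = c(by_type))
}
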