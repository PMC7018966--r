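## Readers/writers: multi-page TIFF payloads with JSON sidecars carrying all
## physical metadata (TIFF tags are not trusted for pitch or frame rate).
## The sidecar of `foo.tif` is `foo.tif.json`.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

read_sidecar <- function(path, required = character()) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stopf("sidecar not found: %s", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in required)
    if (is.null(meta[[f]])) stopf("sidecar %s is missing field '%s'", sp, f)
  meta
}

truth_to_list <- function(truth) {
  if (is.null(truth)) return(NULL)
  unclass(truth)
}

#' Write / read a voltage movie as multi-page TIFF + JSON sidecar
#'
#' Pages are frames in time order; pixels row-major; samples 64-bit float.
#' The sidecar carries frame rate, pixel pitch, optional electrode center,
#' masks (run-length encoded) and ground truth.
#'
#' @param movie a [voltage_movie].
#' @param path output TIFF path.
#' @param annotation optional [region_annotation] stored alongside.
#' @param truth optional `ground_truth` record.
#' @return `path` invisibly (writer); a list with `movie`, `annotation`,
#'   `truth` (reader).
#' @export
write_voltage_movie <- function(movie, path, annotation = NULL, truth = NULL) {
  stopifnot(inherits(movie, "voltage_movie"))
  nt <- dim(movie$frames)[1]
  pages <- lapply(seq_len(nt), function(t) movie$frames[t, , ])
  write_tiff_pages(path, pages, sample = "float")
  meta <- list(kind = "voltage_movie",
               frame_rate = movie$frame_rate,
               pixel_pitch_mm = movie$pixel_pitch,
               ground_truth = truth_to_list(truth))
  if (!is.null(annotation)) meta <- c(meta, annotation_to_list(annotation))
  write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_voltage_movie
#' @export
read_voltage_movie <- function(path) {
  meta <- read_sidecar(path, required = c("frame_rate", "pixel_pitch_mm"))
  pages <- read_tiff_pages(path)
  nt <- length(pages)
  arr <- array(0, dim = c(nt, nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_len(nt)) arr[t, , ] <- pages[[t]]
  list(movie = voltage_movie(arr, meta$frame_rate, meta$pixel_pitch_mm),
       annotation = annotation_from_meta(meta),
       truth = meta$ground_truth)
}

#' Write / read an amplitude map as single-page TIFF + JSON sidecar
#'
#' @param map an [amplitude_map].
#' @param path output TIFF path.
#' @param annotation optional [region_annotation].
#' @param truth optional `ground_truth` record.
#' @return `path` invisibly (writer); list with `map`, `annotation`,
#'   `truth` (reader).
#' @export
write_amplitude_map <- function(map, path, annotation = NULL, truth = NULL) {
  stopifnot(inherits(map, "amplitude_map"))
  write_tiff_pages(path, list(map$values), sample = "float")
  meta <- list(kind = "amplitude_map",
               pixel_pitch_mm = map$pixel_pitch,
               ground_truth = truth_to_list(truth))
  if (!is.null(annotation)) meta <- c(meta, annotation_to_list(annotation))
  write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_amplitude_map
#' @export
read_amplitude_map <- function(path) {
  meta <- read_sidecar(path, required = "pixel_pitch_mm")
  pages <- read_tiff_pages(path)
  if (length(pages) != 1L) stopf("amplitude map TIFF must have one page")
  list(map = amplitude_map(pages[[1]], meta$pixel_pitch_mm),
       annotation = annotation_from_meta(meta),
       truth = meta$ground_truth)
}

#' Write / read a labeled volume as multi-page TIFF + JSON sidecar
#'
#' Pages are z slices (rows = y, cols = x), unsigned integer samples. The
#' sidecar carries the voxel pitch in nm, the label-to-type table, the
#' optional nucleus table and ground truth.
#'
#' @param vol a [labeled_volume].
#' @param path output TIFF path.
#' @param truth optional `ground_truth`.
#' @return `path` invisibly (writer); list with `volume`, `truth` (reader).
#' @export
write_labeled_volume <- function(vol, path, truth = NULL) {
  stopifnot(inherits(vol, "labeled_volume"))
  nz <- dim(vol$labels)[1]
  pages <- lapply(seq_len(nz), function(z) vol$labels[z, , ])
  write_tiff_pages(path, pages, sample = "uint")
  write_sidecar(path, list(
    kind = "labeled_volume",
    voxel_pitch_nm = vol$voxel_pitch,
    type_table = as.list(vol$type_table),
    nucleus_table = if (!is.null(vol$nucleus_table))
      as.list(vol$nucleus_table) else NULL,
    ground_truth = truth_to_list(truth)))
  invisible(path)
}

#' @rdname write_labeled_volume
#' @export
read_labeled_volume <- function(path) {
  meta <- read_sidecar(path, required = "voxel_pitch_nm")
  pages <- read_tiff_pages(path)
  nz <- length(pages)
  arr <- array(0L, dim = c(nz, nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_len(nz)) arr[z, , ] <- as.integer(pages[[z]])
  tt <- unlist(meta$type_table)
  present <- unique(arr[arr != 0L])
  untyped <- setdiff(present, as.integer(names(tt) %||% character()))
  if (length(untyped))
    warnf("label(s) %s absent from type_table; loaded as \"undefined\"",
          paste(sort(untyped), collapse = ", "))
  vol <- labeled_volume(arr, meta$voxel_pitch_nm, type_table = tt,
                        nucleus_table = unlist(meta$nucleus_table))
  list(volume = vol, truth = meta$ground_truth)
}

annotation_to_list <- function(annotation) {
  stopifnot(inherits(annotation, "region_annotation"))
  list(electrode_center = annotation$electrode_center,
       scar_mask = mask_rle_encode(annotation$scar_mask),
       uninjured_mask = if (!is.null(annotation$uninjured_mask))
         mask_rle_encode(annotation$uninjured_mask) else NULL)
}

annotation_from_meta <- function(meta) {
  if (is.null(meta$scar_mask) || is.null(meta$electrode_center)) return(NULL)
  region_annotation(
    scar_mask = mask_rle_decode(meta$scar_mask),
    electrode_center = as.numeric(meta$electrode_center),
    uninjured_mask = if (!is.null(meta$uninjured_mask))
      mask_rle_decode(meta$uninjured_mask) else NULL)
}

#' Write / read a region annotation as JSON
#'
#' Masks are run-length encoded over their row-major flattening.
#'
#' @param annotation a [region_annotation].
#' @param path JSON path.
#' @return `path` invisibly (writer); a [region_annotation] (reader).
#' @export
write_annotation_json <- function(annotation, path) {
  jsonlite::write_json(annotation_to_list(annotation), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_annotation_json
#' @export
read_annotation_json <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("scar_mask", "electrode_center"))
    if (is.null(meta[[f]])) stopf("annotation %s is missing field '%s'", path, f)
  annotation_from_meta(meta)
}

#' Serialize a decay fit to JSON
#'
#' @param fit a `decay_fit`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_decay_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "decay_fit"))
  out <- unclass(fit)
  out$bins <- as.data.frame(out$bins)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows", pretty = TRUE)
  invisible(path)
}
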