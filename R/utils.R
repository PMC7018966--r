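#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm nls optim rnorm sd runif
#' @importFrom utils write.csv read.csv packageVersion modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == trunc(x)

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("'%s' must be a single positive finite number", name)
  invisible(x)
}

## Encode a logical matrix as run lengths over its row-major flattening.
## Row-major matches the pixel order of the TIFF pages we write.
mask_rle_encode <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  flat <- as.vector(t(mask))
  r <- rle(flat)
  list(shape = dim(mask), order = "row-major",
       first = as.integer(r$values[1]), lengths = as.integer(r$lengths))
}

mask_rle_decode <- function(enc) {
  for (f in c("shape", "first", "lengths"))
    if (is.null(enc[[f]])) stopf("mask RLE record is missing field '%s'", f)
  n <- length(enc$lengths)
  vals <- rep(c(enc$first == 1, enc$first != 1), length.out = n)
  flat <- inverse.rle(structure(list(lengths = as.integer(enc$lengths),
                                     values = vals), class = "rle"))
  shape <- as.integer(enc$shape)
  if (length(flat) != prod(shape))
    stopf("mask RLE lengths sum to %d but shape implies %d pixels",
          length(flat), prod(shape))
  matrix(flat, nrow = shape[1], ncol = shape[2], byrow = TRUE)
}

## Matrices of row/column coordinates (1-based pixel centers).
coord_grids <- function(shape) {
  list(row = matrix(seq_len(shape[1]), shape[1], shape[2]),
       col = matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE))
}

## Euclidean distance (in mm) from every pixel center to `center` (row, col).
pixel_distances_mm <- function(shape, center, pixel_pitch) {
  g <- coord_grids(shape)
  sqrt((g$row - center[1])^2 + (g$col - center[2])^2) * pixel_pitch
}
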