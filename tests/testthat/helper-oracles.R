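# Independent brute-force oracles. Deliberately written as plain voxel/pixel
# loops so they share no code path with the package implementations.

# O(N*6) face scan: per-label surface areas (boundary faces included) and
# per-pair contact areas, in um^2. Feasible on volumes <= 32^3.
bf_face_scan <- function(labels, pitch) {
  d <- dim(labels)
  fa <- c(pitch[2] * pitch[3], pitch[1] * pitch[3], pitch[1] * pitch[2]) / 1e6
  nlab <- max(labels)
  surf <- numeric(nlab)
  contacts <- list()
  step <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    v <- labels[z, y, x]
    for (ax in 1:3) {
      nb <- c(z, y, x) + step[[ax]]
      w <- if (nb[ax] > d[ax]) -1L else labels[nb[1], nb[2], nb[3]]
      # forward face
      if (w == -1L) {                       # stack boundary (far side)
        if (v > 0) surf[v] <- surf[v] + fa[ax]
      } else if (v != w) {
        if (v > 0) surf[v] <- surf[v] + fa[ax]
        if (w > 0) surf[w] <- surf[w] + fa[ax]
        if (v > 0 && w > 0) {
          key <- paste(min(v, w), max(v, w))
          contacts[[key]] <- (contacts[[key]] %||% 0) + fa[ax]
        }
      }
      # near-side stack boundary
      if (c(z, y, x)[ax] == 1L && v > 0) surf[v] <- surf[v] + fa[ax]
    }
  }
  ct <- if (length(contacts)) {
    parts <- do.call(rbind, strsplit(names(contacts), " "))
    o <- order(as.integer(parts[, 1]), as.integer(parts[, 2]))
    data.frame(label_a = as.integer(parts[, 1])[o],
               label_b = as.integer(parts[, 2])[o],
               area_um2 = unlist(contacts, use.names = FALSE)[o])
  } else data.frame(label_a = integer(), label_b = integer(),
                    area_um2 = numeric())
  list(surface_um2 = surf, contacts = ct)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# voxel-center-in-sphere count, independent of the package rasterizer
bf_sphere_count <- function(dims, center, radius_vox) {
  n <- 0L
  for (z in 1:dims[1]) for (y in 1:dims[2]) for (x in 1:dims[3])
    if ((z - center[1])^2 + (y - center[2])^2 + (x - center[3])^2 <=
        radius_vox^2) n <- n + 1L
  n
}

# per-pixel equal-width bin assignment by explicit comparison
bf_bin_assign <- function(A, n_bins) {
  lo <- min(A); hi <- max(A)
  width <- (hi - lo) / n_bins
  out <- integer(length(A))
  for (i in seq_along(A)) {
    k <- 1L
    while (k < n_bins && A[i] >= lo + k * width) k <- k + 1L
    out[i] <- n_bins + 1L - k          # 1 = highest-amplitude bin
  }
  out
}

# effective exponential decay constant of the cable far field K0(r/lambda)
# sampled on r in [2 lambda, 4 lambda] -- the derived oracle for the 2D
# sheet solver (closed-form modified Bessel far field).
bf_k0_effective_dc <- function(lambda) {
  r <- seq(2 * lambda, 4 * lambda, length.out = 200)
  A <- besselK(r / lambda, 0)
  d <- r - min(r)
  st <- coef(lm(log(A) ~ d))
  fit <- nls(A ~ v * exp(-d / dc),
             start = list(v = exp(unname(st[1])), dc = -1 / unname(st[2])))
  unname(coef(fit)[["dc"]])
}
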