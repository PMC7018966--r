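## The passive-spread pipeline: voltage movie -> maximal amplitude map ->
## region masking -> equal-width amplitude bins -> edge-referenced radial
## distances -> single-exponential least squares -> group summaries.

#' Maximal-amplitude map from a voltage movie
#'
#' Per pixel: the maximum over the pulse window minus the mean over the
#' baseline window, clipped at 0. Windows are 0-based and half-open
#' (`c(start, end)` covers frames `start .. end-1`), matching
#' [generate_voltage_movie()]. The baseline defaults to all frames before
#' pulse onset.
#'
#' @param movie a [voltage_movie].
#' @param pulse_window integer (start, end), 0-based half-open.
#' @param baseline_window integer (start, end), 0-based half-open, disjoint
#'   from the pulse window; default `c(0, pulse_start)`.
#' @return An [amplitude_map].
#' @export
compute_amplitude_map <- function(movie, pulse_window, baseline_window = NULL) {
  stopifnot(inherits(movie, "voltage_movie"))
  nt <- dim(movie$frames)[1]
  pw <- as.integer(pulse_window)
  if (length(pw) != 2L || pw[1] < 0 || pw[2] <= pw[1] || pw[2] > nt)
    stopf("pulse_window must satisfy 0 <= start < end <= n_frames")
  if (is.null(baseline_window)) baseline_window <- c(0L, pw[1])
  bw <- as.integer(baseline_window)
  if (length(bw) != 2L || bw[1] < 0 || bw[2] <= bw[1] || bw[2] > nt)
    stopf("baseline_window must be a nonempty (start, end) within the movie")
  if (max(pw[1], bw[1]) < min(pw[2], bw[2]))
    stopf("pulse and baseline windows must be disjoint")
  pulse <- movie$frames[(pw[1] + 1L):pw[2], , , drop = FALSE]
  base <- movie$frames[(bw[1] + 1L):bw[2], , , drop = FALSE]
  mx <- apply(pulse, c(2, 3), max)
  mn <- apply(base, c(2, 3), mean)
  vals <- mx - mn
  vals[vals < 0] <- 0
  amplitude_map(vals, movie$pixel_pitch)
}

#' Edge-referenced radial distances over a mask
#'
#' Distances are measured radially from the electrode center to pixel
#' centers; 0 mm corresponds to the edge of the region closest to the
#' electrode, i.e. `d(p) = ||p - electrode|| * pitch - r_edge` with `r_edge`
#' the minimum electrode distance over the mask. The minimum of `d` over
#' the mask is exactly 0.
#'
#' @param mask logical matrix (nonempty).
#' @param electrode_center continuous (row, col).
#' @param pixel_pitch mm per pixel.
#' @return Numeric matrix of distances (mm) over the mask, `NA` elsewhere;
#'   attribute `r_edge_mm` holds the subtracted edge distance.
#' @export
radial_distances <- function(mask, electrode_center, pixel_pitch) {
  if (!any(mask)) stopf("mask is empty")
  r <- pixel_distances_mm(dim(mask), electrode_center, pixel_pitch)
  r_edge <- min(r[mask])
  d <- r - r_edge
  d[!mask] <- NA_real_
  attr(d, "r_edge_mm") <- r_edge
  d
}

#' Equal-width amplitude bins over a region
#'
#' Splits the `[min, max]` range of in-mask amplitudes into `n_bins`
#' equal-width intervals ("each bin contains the same number of amplitude
#' levels"); bin 1 is the highest-amplitude bin, nearest the electrode.
#' Every in-mask pixel belongs to exactly one bin. Bins holding fewer than
#' `min_pixels` pixels are merged into their lower-amplitude neighbor (the
#' lowest bin merges upward) and the receiving bin is flagged.
#'
#' @param map an [amplitude_map].
#' @param mask logical matrix (nonempty), same shape as the map.
#' @param electrode_center continuous (row, col) — needed for the bins'
#'   mean edge-referenced distances.
#' @param n_bins number of bins (>= 2; default 5).
#' @param min_pixels minimum bin occupancy before merging (default 5).
#' @return A `data.frame` of class `amplitude_bins`: `index`, `amp_low`,
#'   `amp_high`, `mean_amplitude`, `mean_distance_mm`, `pixel_count`,
#'   `merged`.
#' @export
bin_amplitudes <- function(map, mask, electrode_center, n_bins = 5,
                           min_pixels = 5) {
  stopifnot(inherits(map, "amplitude_map"))
  if (!identical(dim(mask), dim(map$values))) stopf("mask shape mismatch")
  if (!any(mask)) stopf("mask is empty")
  if (!is_count(n_bins) || n_bins < 2) stopf("n_bins must be >= 2")
  n_bins <- as.integer(n_bins)
  A <- map$values[mask]
  rng <- range(A)
  if (rng[1] == rng[2]) stopf("constant amplitude over mask; cannot bin")
  d <- radial_distances(mask, electrode_center, map$pixel_pitch)[mask]
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  lowbin <- findInterval(A, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  idx <- n_bins + 1L - lowbin              # 1 = highest-amplitude bin
  bins <- data.frame(
    index = seq_len(n_bins),
    amp_low = rev(breaks[-(n_bins + 1)]),
    amp_high = rev(breaks[-1]),
    mean_amplitude = as.numeric(tapply(A, factor(idx, levels = seq_len(n_bins)), mean)),
    mean_distance_mm = as.numeric(tapply(d, factor(idx, levels = seq_len(n_bins)), mean)),
    pixel_count = as.integer(table(factor(idx, levels = seq_len(n_bins)))),
    merged = FALSE)
  ## merge under-filled bins into their lower-amplitude neighbor
  member <- split(seq_along(A), factor(idx, levels = seq_len(n_bins)))
  i <- 1L
  while (i <= nrow(bins)) {
    if (bins$pixel_count[i] < min_pixels && nrow(bins) > 1L) {
      recv <- if (i < nrow(bins)) i + 1L else i - 1L
      px <- c(member[[i]], member[[recv]])
      member[[recv]] <- px
      bins$amp_low[recv] <- min(bins$amp_low[c(i, recv)])
      bins$amp_high[recv] <- max(bins$amp_high[c(i, recv)])
      bins$mean_amplitude[recv] <- mean(A[px])
      bins$mean_distance_mm[recv] <- mean(d[px])
      bins$pixel_count[recv] <- length(px)
      bins$merged[recv] <- TRUE
      bins <- bins[-i, , drop = FALSE]
      member[[i]] <- NULL
      ## do not advance: the receiving bin shifted into position i
    } else i <- i + 1L
  }
  bins$index <- seq_len(nrow(bins))
  rownames(bins) <- NULL
  class(bins) <- c("amplitude_bins", "data.frame")
  attr(bins, "n_bins_requested") <- as.integer(n_bins)
  attr(bins, "pixel_bin") <- idx
  bins
}

#' Single-exponential decay fit
#'
#' Nonlinear least squares of `mean_amplitude = v_edge * exp(-d / DC)` over
#' the bins' (mean distance, mean amplitude) points, initialized from the
#' log-linear fit. By construction the fitted curve at one decay constant
#' equals `v_edge / e` (about 37% of the edge amplitude) — the operational
#' definition of the tissue decay constant.
#'
#' @param bins an `amplitude_bins` table (or any data.frame with
#'   `mean_distance_mm`, `mean_amplitude`, optionally `pixel_count`).
#' @param max_dc declare non-convergence when the fitted DC exceeds this
#'   value (mm); default `Inf`. The pipeline passes the field diagonal.
#' @return An object of class `decay_fit`: `v_edge`, `decay_constant` (mm),
#'   `bins`, `rss`, `r_squared`, `converged`, `diagnostics`.
#' @export
fit_exponential <- function(bins, max_dc = Inf) {
  d <- bins$mean_distance_mm
  A <- bins$mean_amplitude
  keep <- is.finite(d) & is.finite(A)
  d <- d[keep]; A <- A[keep]
  if (length(d) < 3L) stopf("need >= 3 usable bins for the exponential fit")
  if (length(unique(round(d, 12))) < 3L)
    stopf("need >= 3 distinct mean distances for the exponential fit")
  pos <- A > 0
  if (sum(pos) < 3L) stopf("need >= 3 bins with positive amplitude")
  ll <- coef(lm(log(A[pos]) ~ d[pos]))
  if (!is.finite(ll[2]) || ll[2] >= 0)
    start <- list(v = max(A), dc = max(d) / 2)
  else
    start <- list(v = exp(unname(ll[1])), dc = -1 / unname(ll[2]))
  rss_fun <- function(p) sum((A - p[1] * exp(-d / p[2]))^2)
  converged <- TRUE
  note <- ""
  start_rss <- rss_fun(c(start$v, start$dc))
  if (start_rss <= 1e-24 * sum(A^2)) {
    ## log-linear start already interpolates (noise-free fixtures); NLS has
    ## nothing to improve and would fail on zero residuals
    est <- c(start$v, start$dc)
  } else {
    fit <- tryCatch(
      nls(A ~ v * exp(-d / dc), start = start, algorithm = "port",
          lower = c(v = 0, dc = 1e-9),
          control = list(maxiter = 200, warnOnly = FALSE)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      opt <- optim(c(start$v, start$dc), rss_fun, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12))
      est <- opt$par
      converged <- opt$convergence == 0 && est[2] > 0
      note <- sprintf("nls failed (%s); Nelder-Mead fallback", conditionMessage(fit))
    } else {
      est <- coef(fit)[c("v", "dc")]
    }
  }
  est <- unname(est)
  rss <- rss_fun(est)
  tss <- sum((A - mean(A))^2)
  if (est[2] > max_dc) {
    converged <- FALSE
    note <- paste(note, sprintf("fitted DC %.3g exceeds field width %.3g",
                                est[2], max_dc))
  }
  structure(list(v_edge = est[1], decay_constant = est[2],
                 bins = as.data.frame(bins)[keep, , drop = FALSE],
                 rss = rss,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 converged = converged,
                 diagnostics = trimws(note)),
            class = "decay_fit")
}

#' Construct (or validate) the matched uninjured region
#'
#' The uninjured comparison region must have the same size and the same
#' minimum electrode distance as the scar. When the annotation already
#' carries an uninjured mask this op validates it (pixel count within 2%,
#' disjoint from the scar, minimum electrode distance within half a pixel)
#' and returns it. Otherwise the scar mask is rotated about the electrode
#' center, in `angle_step_deg` increments, until a copy is found that does
#' not overlap the scar (with a 2-pixel margin) and stays in the field.
#'
#' @param map an [amplitude_map] (provides the grid and pixel pitch).
#' @param annotation a [region_annotation].
#' @param angle_step_deg rotation search step (default 5 degrees).
#' @param margin_px dilation margin around the scar (default 2 px).
#' @param area_tol relative pixel-count tolerance (default 0.02).
#' @return Logical mask of the matched region.
#' @export
select_matched_uninjured_region <- function(map, annotation,
                                            angle_step_deg = 5,
                                            margin_px = 2, area_tol = 0.02) {
  stopifnot(inherits(map, "amplitude_map"), inherits(annotation, "region_annotation"))
  scar <- annotation$scar_mask
  if (!any(scar)) stopf("scar mask is empty")
  ec <- annotation$electrode_center
  shape <- dim(scar)
  r <- pixel_distances_mm(shape, ec, map$pixel_pitch)
  r_edge_scar <- min(r[scar])
  n_scar <- sum(scar)
  validate <- function(mask, what) {
    if (abs(sum(mask) - n_scar) / n_scar > area_tol)
      stopf("%s pixel count differs from scar by more than %.0f%%",
            what, 100 * area_tol)
    if (any(mask & scar)) stopf("%s overlaps the scar", what)
    if (abs(min(r[mask]) - r_edge_scar) > 0.5 * map$pixel_pitch)
      stopf("%s minimum electrode distance does not match the scar's", what)
    mask
  }
  if (!is.null(annotation$uninjured_mask))
    return(validate(annotation$uninjured_mask, "annotated uninjured region"))

  ## dilate the scar by the margin
  dil <- scar
  for (dr in -margin_px:margin_px) for (dc in -margin_px:margin_px) {
    if (dr == 0 && dc == 0) next
    src_r <- seq_len(shape[1]) - dr; src_c <- seq_len(shape[2]) - dc
    ok_r <- src_r >= 1 & src_r <= shape[1]; ok_c <- src_c >= 1 & src_c <= shape[2]
    sh <- matrix(FALSE, shape[1], shape[2])
    sh[ok_r, ok_c] <- scar[src_r[ok_r], src_c[ok_c]]
    dil <- dil | sh
  }
  px <- which(scar, arr.ind = TRUE)
  pr <- px[, 1] - ec[1]; pc <- px[, 2] - ec[2]
  for (ang in seq(angle_step_deg, 360 - angle_step_deg, by = angle_step_deg)) {
    th <- ang * pi / 180
    nr <- round(ec[1] + pr * cos(th) - pc * sin(th))
    nc <- round(ec[2] + pr * sin(th) + pc * cos(th))
    if (any(nr < 1 | nr > shape[1] | nc < 1 | nc > shape[2])) next
    cand <- matrix(FALSE, shape[1], shape[2])
    cand[cbind(nr, nc)] <- TRUE
    if (any(cand & dil)) next
    if (abs(sum(cand) - n_scar) / n_scar > area_tol) next
    if (abs(min(r[cand]) - r_edge_scar) > 0.5 * map$pixel_pitch) next
    attr(cand, "rotation_deg") <- ang
    return(cand)
  }
  stopf("no non-overlapping rotation of the scar mask found; annotate the uninjured region manually")
}

#' End-to-end tissue decay constant
#'
#' Composition of the pipeline: (movie -> amplitude map ->) region mask ->
#' equal-width amplitude bins -> edge-referenced distances -> single
#' exponential fit. Deterministic for fixed input.
#'
#' @param x an [amplitude_map] or [voltage_movie].
#' @param annotation a [region_annotation].
#' @param region `"scar"` or `"uninjured"`. For `"uninjured"` the
#'   annotation's mask is used when present, otherwise a matched region is
#'   constructed by [select_matched_uninjured_region()].
#' @param n_bins number of amplitude bins (default 5).
#' @param pulse_window,baseline_window frame windows, required when `x` is
#'   a movie (see [compute_amplitude_map()]).
#' @param min_pixels minimum bin occupancy (default 5).
#' @return A `decay_fit` (with the region and bins recorded).
#' @export
pipeline_decay_constant <- function(x, annotation,
                                    region = c("scar", "uninjured"),
                                    n_bins = 5, pulse_window = NULL,
                                    baseline_window = NULL, min_pixels = 5) {
  region <- match.arg(region)
  stopifnot(inherits(annotation, "region_annotation"))
  map <- if (inherits(x, "voltage_movie")) {
    if (is.null(pulse_window)) stopf("pulse_window is required for a movie input")
    compute_amplitude_map(x, pulse_window, baseline_window)
  } else if (inherits(x, "amplitude_map")) x
  else stopf("'x' must be an amplitude_map or voltage_movie")
  mask <- if (region == "scar") annotation$scar_mask
  else annotation$uninjured_mask %||%
    select_matched_uninjured_region(map, annotation)
  bins <- bin_amplitudes(map, mask, annotation$electrode_center,
                         n_bins = n_bins, min_pixels = min_pixels)
  field_mm <- sqrt(sum((dim(map$values))^2)) * map$pixel_pitch
  fit <- fit_exponential(bins, max_dc = field_mm)
  fit$region <- region
  fit$n_bins <- as.integer(n_bins)
  fit
}

#' Per-group decay-constant summary
#'
#' @param values numeric vector of per-heart decay constants (mm).
#' @param label group label (e.g. `"bmpCTL"`).
#' @return A `group_summary` list: `label`, `values`, `n`, `mean`, `sem`.
#' @export
group_summary <- function(values, label) {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values)))
    stopf("group '%s' needs finite decay constants", label)
  structure(list(label = as.character(label), values = values,
                 n = length(values), mean = mean(values),
                 sem = if (length(values) > 1) sd(values) / sqrt(length(values))
                       else NA_real_),
            class = "group_summary")
}

#' Normalize group means to the control group
#'
#' Each group's normalized mean is its mean divided by the control group's
#' mean (control becomes exactly 1); the percent change vs control is also
#' attached.
#'
#' @param groups list of [group_summary()] objects.
#' @param control_label label of the control group.
#' @return The list of groups, each gaining `normalized_mean` and
#'   `percent_change` fields.
#' @export
normalize_to_control <- function(groups, control_label) {
  labs <- vapply(groups, `[[`, character(1), "label")
  ci <- match(control_label, labs)
  if (is.na(ci)) stopf("control group '%s' not found", control_label)
  cm <- groups[[ci]]$mean
  if (!is.finite(cm) || cm == 0) stopf("control group mean is zero")
  lapply(groups, function(g) {
    g$normalized_mean <- g$mean / cm
    g$percent_change <- 100 * (g$mean - cm) / cm
    g
  })
}

#' Percent decrease of a group mean relative to control
#'
#' `100 * (control - group) / control`.
#'
#' @param group_mean,control_mean numeric scalars; `control_mean > 0`.
#' @return Percent decrease (negative when the group mean exceeds control).
#' @export
percent_decrease <- function(group_mean, control_mean) {
  if (!is.numeric(control_mean) || control_mean <= 0)
    stopf("control_mean must be > 0")
  100 * (control_mean - group_mean) / control_mean
}
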