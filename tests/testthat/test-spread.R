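test_that("compute_amplitude_map: exactness, clipping and noise behavior", {
  fx <- ref_sheet()
  gen <- generate_voltage_movie(fx$spec, frames = 40, pulse_window = c(10, 30))
  map0 <- generate_amplitude_map(fx$spec)$map
  expect_identical(compute_amplitude_map(gen$movie, c(10, 30))$values,
                   map0$values)
  # constant movie -> all-zero map (clipped at 0)
  const <- voltage_movie(array(3, dim = c(20, 8, 8)), 1000, 0.1)
  expect_true(all(compute_amplitude_map(const, c(10, 20))$values == 0))
  expect_error(compute_amplitude_map(const, c(5, 5)), "pulse_window")
  expect_error(compute_amplitude_map(const, c(5, 15), c(10, 20)), "disjoint")

  # Monte-Carlo bound: max over n pulse frames of N(A, sigma) biases the map
  # upward by about sigma*E[max of n] and stays within a max-of-n envelope
  sigma <- 0.3
  fxn <- ref_sheet(noise_sd = sigma, seed = 13L)
  mv <- generate_voltage_movie(fxn$spec, frames = 40, pulse_window = c(10, 30))
  rec <- compute_amplitude_map(mv$movie, c(10, 30))
  err <- rec$values - map0$values
  expect_lt(max(abs(err)), 5 * sigma)
  expect_gt(median(err[fx$scar]), 0.5 * sigma)   # positive max-of-n bias
  expect_lt(median(err[fx$scar]), 3.0 * sigma)
})

test_that("radial distances are edge-referenced and translation invariant", {
  mask <- matrix(FALSE, 30, 30)
  mask[15, 15] <- TRUE
  d <- radial_distances(mask, c(3.2, 7.9), 0.1)
  expect_equal(d[15, 15], 0)                      # single pixel: edge is itself
  # pixels at 10 and 20 px from the electrode, pitch 0.0928 mm
  mask2 <- matrix(FALSE, 5, 30)
  mask2[3, c(13, 23)] <- TRUE
  d2 <- radial_distances(mask2, c(3, 3), 0.0928)
  expect_equal(sort(d2[mask2]), c(0, 0.928))
  expect_equal(attr(d2, "r_edge_mm"), 10 * 0.0928)
  # translating the whole scene leaves distances unchanged
  mask3 <- matrix(FALSE, 10, 40)
  mask3[3 + 2, c(13, 23) + 4] <- TRUE
  d3 <- radial_distances(mask3, c(3 + 2, 3 + 4), 0.0928)
  expect_equal(sort(d3[mask3]), sort(d2[mask2]))
  expect_error(radial_distances(matrix(FALSE, 3, 3), c(1, 1), 0.1), "empty")
})

test_that("equal-width binning partitions the mask and matches brute force", {
  set.seed(2)
  vals <- matrix(runif(400, 0, 100), 20, 20)
  vals[1, 1] <- 0; vals[20, 20] <- 100           # pin the range
  map <- amplitude_map(vals, 0.1)
  mask <- matrix(TRUE, 20, 20)
  bins <- bin_amplitudes(map, mask, c(-5, 10), n_bins = 5, min_pixels = 1)
  expect_equal(bins$amp_high[1], 100)
  expect_equal(bins$amp_low[5], 0)
  expect_equal(bins$amp_low, c(80, 60, 40, 20, 0))
  expect_equal(sum(bins$pixel_count), sum(mask))  # partition
  expect_identical(attr(bins, "pixel_bin"), bf_bin_assign(vals[mask], 5L))

  # monotone law: mean amplitudes strictly decrease with bin index
  fx <- ref_sheet()
  m <- generate_amplitude_map(fx$spec)$map
  b2 <- bin_amplitudes(m, fx$scar, fx$ec, n_bins = 5)
  expect_true(all(diff(b2$mean_amplitude) < 0))
  expect_true(all(diff(b2$mean_distance_mm) > 0))

  expect_error(bin_amplitudes(amplitude_map(matrix(1, 4, 4), 0.1),
                              matrix(TRUE, 4, 4), c(1, 1)), "constant")
})

test_that("under-filled bins merge into their lower-amplitude neighbor", {
  # one extreme outlier pixel forces an under-filled top bin
  vals <- matrix(1, 10, 10)
  vals[2:9, 2:9] <- seq(0, 10, length.out = 64)
  vals[5, 5] <- 100
  map <- amplitude_map(vals, 0.1)
  bins <- bin_amplitudes(map, matrix(TRUE, 10, 10), c(0, 0), n_bins = 5,
                         min_pixels = 5)
  expect_lt(nrow(bins), 5)
  expect_true(any(bins$merged))
  expect_equal(sum(bins$pixel_count), 100)
  expect_equal(bins$index, seq_len(nrow(bins)))
})

test_that("exponential fit recovers exact parameters and self-consistency", {
  for (tc in list(c(10, 0.48), c(7, 0.57))) {
    d <- seq(0, 2, by = 0.25)
    pts <- data.frame(mean_distance_mm = d,
                      mean_amplitude = tc[1] * exp(-d / tc[2]))
    fit <- fit_exponential(pts)
    expect_true(fit$converged)
    expect_equal(fit$decay_constant, tc[2], tolerance = 1e-6)
    expect_equal(fit$v_edge, tc[1], tolerance = 1e-6)
    # definitional: amplitude at one decay constant is v_edge/e
    expect_equal(fit$v_edge * exp(-fit$decay_constant / fit$decay_constant),
                 fit$v_edge * exp(-1), tolerance = 1e-12)
  }
  # noisy points still converge with sensible diagnostics
  set.seed(4)
  d <- seq(0, 2, by = 0.2)
  pts <- data.frame(mean_distance_mm = d,
                    mean_amplitude = 10 * exp(-d / 0.5) + rnorm(length(d), 0, 0.1))
  fit <- fit_exponential(pts)
  expect_true(fit$converged)
  expect_equal(fit$decay_constant, 0.5, tolerance = 0.15)
  expect_gt(fit$r_squared, 0.98)
  # degenerate distances refuse to fit
  bad <- data.frame(mean_distance_mm = c(0, 0, 1),
                    mean_amplitude = c(10, 10, 5))
  expect_error(fit_exponential(bad), "distinct mean distances")
  # a DC beyond the stated field width is flagged, never silent
  flat <- data.frame(mean_distance_mm = c(0, 0.5, 1),
                     mean_amplitude = c(10, 9.99, 9.98))
  f2 <- fit_exponential(flat, max_dc = 2)
  expect_false(f2$converged)
  expect_match(f2$diagnostics, "field width")
})

test_that("matched uninjured region mirrors the scar geometry", {
  fx <- ref_sheet()
  map <- generate_amplitude_map(fx$spec)$map
  unj <- select_matched_uninjured_region(map, fx$ann)
  expect_lt(abs(sum(unj) - sum(fx$scar)) / sum(fx$scar), 0.02)
  expect_false(any(unj & fx$scar))
  r <- sqrt(outer((1:110 - fx$ec[1])^2, (1:110 - fx$ec[2])^2, "+")) * fx$pitch
  expect_lt(abs(min(r[unj]) - min(r[fx$scar])), 0.5 * fx$pitch + 1e-12)

  # a valid hand annotation is validated and passed through
  fx2 <- ref_sheet(uninjured_mask = unj)
  expect_identical(select_matched_uninjured_region(map, fx2$ann), unj)
  # an annotation of the wrong size is rejected
  small <- unj; small[which(small)[1:200]] <- FALSE
  fx3 <- ref_sheet(uninjured_mask = small)
  expect_error(select_matched_uninjured_region(map, fx3$ann), "pixel count")

  # a full-field scar admits no rotation
  full <- matrix(TRUE, 40, 40); full[1, 1] <- FALSE
  ann <- region_annotation(full, c(1, 1))
  m2 <- amplitude_map(matrix(1:1600 / 1600, 40, 40), 0.1)
  expect_error(select_matched_uninjured_region(m2, ann), "manual")
})

test_that("pipeline recovers ground-truth decay constants", {
  fx <- ref_sheet(lambda_scar = 0.48, lambda_uninjured = 0.57)
  map <- generate_amplitude_map(fx$spec)$map
  fit <- pipeline_decay_constant(map, fx$ann, "scar", n_bins = 5)
  expect_lt(abs(fit$decay_constant - 0.48) / 0.48, 0.05)
  # identical scar/uninjured space constants give matching DCs
  sym <- ref_sheet(lambda_scar = 0.5, lambda_uninjured = 0.5)
  msym <- generate_amplitude_map(sym$spec)$map
  f1 <- pipeline_decay_constant(msym, sym$ann, "scar")
  f2 <- pipeline_decay_constant(msym, sym$ann, "uninjured")
  expect_lt(abs(f1$decay_constant - f2$decay_constant) / f1$decay_constant, 0.05)
  # movie input composes the same way
  mv <- generate_voltage_movie(fx$spec, frames = 30, pulse_window = c(10, 25))
  fmv <- pipeline_decay_constant(mv$movie, fx$ann, "scar",
                                 pulse_window = c(10, 25))
  expect_equal(fmv$decay_constant, fit$decay_constant, tolerance = 1e-12)
})

test_that("pipeline equivariances: amplitude scale and pixel pitch", {
  fx <- ref_sheet()
  map <- generate_amplitude_map(fx$spec)$map
  fit <- pipeline_decay_constant(map, fx$ann, "scar")
  scaled <- amplitude_map(map$values * 3.7, map$pixel_pitch)
  fs <- pipeline_decay_constant(scaled, fx$ann, "scar")
  expect_equal(fs$decay_constant, fit$decay_constant, tolerance = 1e-9)
  expect_equal(fs$v_edge, 3.7 * fit$v_edge, tolerance = 1e-9)
  # doubling the pixel pitch doubles the decay constant exactly
  wide <- amplitude_map(map$values, 2 * map$pixel_pitch)
  fw <- pipeline_decay_constant(wide, fx$ann, "scar")
  expect_equal(fw$decay_constant, 2 * fit$decay_constant, tolerance = 1e-9)
})

test_that("parameter recovery holds across a space-constant grid", {
  errs <- vapply(seq(0.2, 1.0, by = 0.1), function(l) {
    fx <- ref_sheet(lambda_scar = l)
    fit <- pipeline_decay_constant(generate_amplitude_map(fx$spec)$map,
                                   fx$ann, "scar", n_bins = 5)
    abs(fit$decay_constant - l) / l
  }, numeric(1))
  expect_lte(median(errs), 0.05)
})

test_that("noisy maps recover the decay constant within 15% across seeds", {
  errs <- vapply(1:20, function(s) {
    fx <- ref_sheet(lambda_scar = 0.48, noise_sd = 0.2, seed = s)
    fit <- pipeline_decay_constant(generate_amplitude_map(fx$spec)$map,
                                   fx$ann, "scar", n_bins = 5)
    abs(fit$decay_constant - 0.48) / 0.48
  }, numeric(1))
  expect_true(all(errs < 0.15))
})

test_that("group summaries normalize to control and report percent decrease", {
  g <- normalize_to_control(list(group_summary(c(0.5, 0.5), "ctl"),
                                 group_summary(c(0.25, 0.25), "ko")), "ctl")
  expect_equal(vapply(g, `[[`, numeric(1), "normalized_mean"), c(1.0, 0.5))
  solo <- normalize_to_control(list(group_summary(c(0.4, 0.6), "only")), "only")
  expect_equal(solo[[1]]$normalized_mean, 1.0)
  expect_error(normalize_to_control(list(group_summary(0.5, "a")), "b"),
               "not found")
  expect_error(normalize_to_control(list(group_summary(c(0, 0), "z")), "z"),
               "zero")

  g2 <- normalize_to_control(list(group_summary(rep(0.48, 3), "ctl"),
                                  group_summary(rep(0.30, 3), "ko")), "ctl")
  expect_equal(g2[[2]]$normalized_mean, 0.625)
  expect_equal(percent_decrease(0.30, 0.48), 37.5)
  expect_equal(percent_decrease(0.42, 0.42), 0)
  expect_equal(round(percent_decrease(0.404, 0.57), 1), 29.1)
  expect_error(percent_decrease(0.3, 0), "control_mean")
  # SEM is sd/sqrt(n)
  gs <- group_summary(c(0.4, 0.5, 0.6), "x")
  expect_equal(gs$sem, sd(c(0.4, 0.5, 0.6)) / sqrt(3))
})
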