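test_that("stack_volume computes physical volume exactly", {
  vol <- labeled_volume(array(0L, dim = c(1, 1, 1)), c(1000, 1000, 1000))
  expect_equal(stack_volume(vol), 1)
  # 384 slices at 80 nm give a 30.72 um z extent
  vol384 <- labeled_volume(array(0L, dim = c(384, 2, 2)), c(80, 500, 500))
  expect_equal(stack_volume(vol384), 30.72 * (2 * 0.5) * (2 * 0.5))
  expect_error(stack_volume(c(-1, 2, 3)), "positive")
})

test_that("cell morphometrics: cube volumes and orientation-weighted surfaces", {
  mk <- function(pitch) {
    labels <- array(0L, dim = c(12, 12, 12))
    labels[2:11, 2:11, 2:11] <- 1L
    labeled_volume(labels, pitch, type_table = c("1" = "inflammatory"))
  }
  iso <- cell_morphometrics(mk(c(1000, 1000, 1000)))
  expect_equal(iso$volume_um3, 1000)
  expect_equal(iso$surface_area_um2, 600)
  expect_false(iso$touches_boundary)

  aniso <- cell_morphometrics(mk(c(80, 6.3, 6.3)))
  expect_equal(aniso$volume_um3, 1000 * 80 * 6.3 * 6.3 / 1e9)
  expect_equal(aniso$surface_area_um2,
               (2 * 100 * 6.3 * 6.3 + 2 * 100 * 80 * 6.3 + 2 * 100 * 80 * 6.3) / 1e6)
})

test_that("adjacent cells both count the shared wall; boundary faces count", {
  gen <- generate_labeled_volume(two_box_spec(pitch = c(1000, 1000, 1000)))
  cm <- cell_morphometrics(gen$volume)
  expect_equal(cm$surface_area_um2, c(600, 600))     # shared wall included
  # a full-field slab touches the boundary and its cut faces are counted
  labels <- array(1L, dim = c(2, 5, 5))
  slab <- labeled_volume(labels, c(1000, 1000, 1000))
  cm2 <- cell_morphometrics(slab)
  expect_true(cm2$touches_boundary)
  expect_equal(cm2$surface_area_um2, 2 * 25 + 4 * 10)
})

test_that("detect_contacts: full-face interface, gap, and patch counts", {
  gen <- generate_labeled_volume(two_box_spec(pitch = c(1000, 1000, 1000)))
  ct <- detect_contacts(gen$volume)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$shared_face_count, 100L)
  expect_equal(ct$area_um2, 100)
  expect_equal(ct$patch_count, 1L)

  # separate the boxes by a 1-voxel background gap: no interfaces
  labels <- gen$volume$labels
  gap <- labels
  gap[labels == 2L] <- 0L
  gap[13:22, 1:10, 1:10] <- gen$volume$labels[12:21, 1:10, 1:10]
  vol_gap <- labeled_volume(gap, c(1000, 1000, 1000))
  expect_equal(nrow(detect_contacts(vol_gap)), 0L)

  # two disjoint contact spots between the same pair: one edge, two patches
  labels <- array(0L, dim = c(2, 7, 3))
  labels[1, , ] <- 1L
  labels[2, c(1, 2, 6, 7), ] <- 2L
  vol2 <- labeled_volume(labels, c(1000, 1000, 1000))
  ct2 <- detect_contacts(vol2)
  expect_equal(nrow(ct2), 1L)
  expect_equal(ct2$patch_count, 2L)
  expect_equal(ct2$shared_face_count, 12L)
})

test_that("contacts and surfaces match the brute-force face scan exactly", {
  for (seed in c(11L, 12L)) {
    vol <- random_volume(c(16L, 16L, 16L), n_labels = 4L, seed = seed)
    bf <- bf_face_scan(vol$labels, vol$voxel_pitch)
    cm <- cell_morphometrics(vol)
    expect_equal(cm$surface_area_um2, bf$surface_um2[cm$label])
    ct <- detect_contacts(vol, patches = FALSE)
    expect_equal(ct[c("label_a", "label_b", "area_um2")],
                 bf$contacts, ignore_attr = TRUE)
  }
})

test_that("relabeling permutes records but preserves all measurements", {
  vol <- random_volume(c(12L, 12L, 12L), n_labels = 4L, seed = 21L)
  perm <- c(3L, 1L, 4L, 2L)                      # label i -> perm[i]
  relab <- vol$labels
  relab[vol$labels > 0L] <- perm[vol$labels[vol$labels > 0L]]
  vol2 <- labeled_volume(relab, vol$voxel_pitch,
                         type_table = setNames(vol$type_table, perm[as.integer(names(vol$type_table))]))
  cm1 <- cell_morphometrics(vol)
  cm2 <- cell_morphometrics(vol2)
  expect_equal(cm2$volume_um3[match(perm[cm1$label], cm2$label)],
               cm1$volume_um3)
  expect_equal(sort(cm1$surface_area_um2), sort(cm2$surface_area_um2))
  ct1 <- detect_contacts(vol, patches = FALSE)
  ct2 <- detect_contacts(vol2, patches = FALSE)
  expect_equal(sort(ct1$area_um2), sort(ct2$area_um2))
  g1 <- build_contact_graph(cm1, ct1)
  g2 <- build_contact_graph(cm2, ct2)
  expect_true(igraph::isomorphic(g1$graph, g2$graph))
})

test_that("volume conservation: cell volumes plus background equal the stack", {
  vol <- random_volume(c(14L, 14L, 14L), n_labels = 4L, seed = 31L)
  cm <- cell_morphometrics(vol)
  bg <- sum(vol$labels == 0L) * prod(vol$voxel_pitch) / 1e9
  expect_equal(sum(cm$volume_um3) + bg, stack_volume(vol),
               tolerance = 1e-12)
  # fraction breakdown is consistent too
  cf <- cell_volume_fraction(vol)
  expect_equal(sum(cf$by_type), cf$total, tolerance = 1e-12)
})

test_that("contact graph has the expected topology", {
  cells <- data.frame(label = 1:3, cell_type = "inflammatory",
                      voxel_count = 10, volume_um3 = 1,
                      surface_area_um2 = 6, touches_boundary = FALSE,
                      has_nucleus = NA)
  tri <- data.frame(label_a = c(1L, 1L, 2L), label_b = c(2L, 3L, 3L),
                    shared_face_count = 1L, area_um2 = 0.5)
  g <- build_contact_graph(cells, tri)
  expect_equal(unname(igraph::degree(g$graph)), c(2, 2, 2))
  chain <- tri[1:2, ]
  chain$label_a <- c(1L, 2L); chain$label_b <- c(2L, 3L)
  g2 <- build_contact_graph(cells, chain)
  expect_equal(unname(igraph::degree(g2$graph)[as.character(1:3)]), c(1, 2, 1))
  bad <- tri; bad$label_b[1] <- 9L
  expect_error(build_contact_graph(cells, bad), "unknown label")
})

test_that("type summary: touching unit cubes and degenerate inputs", {
  labels <- array(0L, dim = c(3, 2, 1))
  labels[1, 1, 1] <- 1L; labels[2, 1, 1] <- 2L
  vol <- labeled_volume(labels, c(1000, 1000, 1000),
                        type_table = c("1" = "inflammatory", "2" = "inflammatory"))
  cm <- cell_morphometrics(vol)
  ct <- detect_contacts(vol)
  g <- build_contact_graph(cm, ct)
  expect_message(ts <- summarize_by_type(g, vol), "omitted")
  expect_equal(ts$n_cells, 2L)
  expect_equal(ts$mean_interfacing_cells, 1)
  expect_equal(ts$mean_relative_contact_area, 1 / 6)
  expect_equal(ts$mean_area_per_interface_um2, 1)
  expect_equal(ts$volume_fraction, 2 / 6)

  empty <- labeled_volume(array(0L, dim = c(3, 3, 3)), c(1000, 1000, 1000))
  expect_error(cell_morphometrics(empty), "no cells")
  expect_equal(cell_volume_fraction(empty)$total, 0)
  full <- labeled_volume(array(1L, dim = c(3, 3, 3)), c(1000, 1000, 1000))
  expect_equal(cell_volume_fraction(full)$total, 1)
})

test_that("per-type contact-area ratio tracks the planned geometry", {
  # type-1 pair shares a 10x10 face; type-2 pair a 3x3 face patch
  pitch <- c(100, 100, 100)
  labels <- array(0L, dim = c(22, 14, 14))
  labels[2:11, 2:11, 2:11] <- 1L
  labels[12:21, 2:11, 2:11] <- 2L
  labels[1, 5:7, 5:7] <- 3L               # small cap touching cell 1
  vol <- labeled_volume(labels, pitch,
                        type_table = c("1" = "inflammatory",
                                       "2" = "inflammatory",
                                       "3" = "fibroblastic"))
  g <- build_contact_graph(cell_morphometrics(vol), detect_contacts(vol))
  suppressMessages(ts <- summarize_by_type(g, vol))
  infl <- ts[ts$cell_type == "inflammatory", ]
  fib <- ts[ts$cell_type == "fibroblastic", ]
  # inflammatory incidences: 100-face interface twice + 9-face once;
  # fibroblastic: the 9-face interface only
  expect_equal(infl$mean_area_per_interface_um2 / fib$mean_area_per_interface_um2,
               mean(c(1, 1, 0.09)) / 0.09)
})

test_that("morphometrics flags type-table labels absent from the volume", {
  labels <- array(0L, dim = c(4, 4, 4)); labels[2, 2, 2] <- 1L
  vol <- labeled_volume(labels, c(1000, 1000, 1000))
  vol$type_table <- c("1" = "inflammatory", "7" = "endocardial")
  expect_warning(cm <- cell_morphometrics(vol), "absent from volume")
  expect_equal(attr(cm, "absent_labels"), 7L)
  expect_equal(nrow(cm), 1L)
})
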