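# Shared fixtures: the reference sector-scar sheet (electrode-to-scar
# distance 2 mm, 0.0928 mm/px, as in the imaged hearts) and small volumes.

ref_sheet <- function(lambda_scar = 0.48, lambda_uninjured = 0.57,
                      noise_sd = 0, seed = 1L, pitch = 0.0928,
                      uninjured_mask = NULL, mode = "pure_exponential") {
  shape <- c(110L, 110L)
  ec <- c(55.5, 55.5)
  scar <- sector_mask(shape, ec, 2, 3.5, 40, pitch)
  spec <- sheet_spec(shape, pitch, ec, scar, lambda_scar = lambda_scar,
                     lambda_uninjured = lambda_uninjured, v_edge = 10,
                     noise_sd = noise_sd, mode = mode,
                     uninjured_mask = uninjured_mask, seed = seed)
  list(spec = spec, ann = region_annotation(scar, ec, uninjured_mask),
       shape = shape, ec = ec, pitch = pitch, scar = scar)
}

# two 10x10x10-voxel boxes sharing one full 10x10 face; `normal` picks the
# contact-plane normal axis (1 = z, 3 = x)
two_box_spec <- function(pitch = c(80, 6.3, 6.3), normal = 1) {
  ext <- 10 * pitch
  c1 <- c(5.5, 5.5, 5.5)
  c2 <- c1; c2[normal] <- 15.5
  dims <- rep(12L, 3); dims[normal] <- 22L
  volume_spec(dims, pitch,
              cells = list(
                cell_prescription("inflammatory", "box", ext, c1),
                cell_prescription("fibroblastic", "box", ext, c2)),
              contact_plan = list(c(1, 2)))
}

# small random multi-label volume for oracle-equivalence tests
random_volume <- function(dims = c(16L, 16L, 16L), n_labels = 4L, seed = 11L,
                          pitch = c(80, 6.3, 6.3)) {
  set.seed(seed)
  labels <- array(sample(0:n_labels, prod(dims), replace = TRUE,
                         prob = c(0.5, rep(0.5 / n_labels, n_labels))),
                  dim = dims)
  labeled_volume(labels, pitch,
                 type_table = setNames(
                   rep(c("inflammatory", "fibroblastic", "endocardial"),
                       length.out = n_labels),
                   as.character(1:n_labels)))
}
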