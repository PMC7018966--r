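# scartools

Quantitative analysis of cardiac scar electrophysiology and ultrastructure.

Healed myocardial scar contains non-myocyte cells (macrophages, fibroblasts,
endocardial cells) that form physical networks capable of passively
conducting electrical current. `scartools` implements, as tested reusable R
code, the two pipelines used to quantify this:

1. **Passive-spread pipeline** (optical mapping). Voltage-imaging movies of
   sub-threshold current injection are reduced to maximal-amplitude maps;
   a region of interest (scar, or a size- and distance-matched uninjured
   region) is partitioned into equal-width amplitude bins; bin mean
   amplitudes are regressed on edge-referenced radial distance by a single
   exponential

   V(d) = V_edge · exp(−d/λ),

   and the **tissue decay constant** λ (mm) — the distance at which the
   amplitude falls to 1/e ≈ 37% of the edge amplitude — summarizes the
   tissue's electrotonic coupling. Group summaries report mean ± SEM,
   normalization to a control group, and percent change.

2. **Morphometrics pipeline** (serial block-face SEM). A labeled voxel
   volume with anisotropic pitch (e.g. 6.3 × 6.3 nm pixels, 80 nm sections)
   yields per-cell volumes and surface areas, intercellular contact
   interfaces (6-connected shared voxel faces, orientation-weighted areas),
   the cell-contact network (an igraph), and per-cell-type summaries.

A **synthetic-data module** generates both input kinds — radially decaying
amplitude maps (closed-form exponential or a finite-difference cable-equation
solve) and packed multi-cell label volumes — together with exact ground
truth, so every stage is testable without any external data.

## Worked example

```r
library(scartools)

## a synthetic heart: sector scar starting 2 mm from the electrode,
## 0.0928 mm/px, ground-truth space constants 0.48 (scar) / 0.57 mm
shape <- c(110L, 110L); ec <- c(55.5, 55.5); pitch <- 0.0928
scar  <- sector_mask(shape, ec, r_min = 2, r_max = 3.5,
                     half_angle_deg = 40, pixel_pitch = pitch)
spec  <- sheet_spec(shape, pitch, ec, scar,
                    lambda_scar = 0.48, lambda_uninjured = 0.57)
map   <- generate_amplitude_map(spec)$map
ann   <- region_annotation(scar, ec)

fit <- pipeline_decay_constant(map, ann, region = "scar", n_bins = 5)
fit
#> <decay_fit> DC = 0.4899 mm, v_edge = 9.975 a.u., R^2 = 0.9998, converged: TRUE
#>   fitted on 5 bins (668 pixels)
```

The recovered decay constant 0.4899 mm sits within 2.1% of the 0.48 mm
ground truth; the residual bias comes from fitting five aggregated bin
points, which is the protocol the package models (see the methods vignette).

```r
## morphometrics on a synthetic EM volume packed to 35.2% cellularity
vspec <- volume_spec(c(128L, 256L, 256L), c(80, 6.3, 6.3),
                     target_cell_fraction = 0.352, seed = 1L)
vol <- generate_labeled_volume(vspec)$volume
cell_volume_fraction(vol)$total
#> [1] 0.3500062

cells    <- cell_morphometrics(vol)
contacts <- detect_contacts(vol, patches = FALSE)
graph    <- build_contact_graph(cells, contacts)
graph
#> <contact_graph> 1258 cells, 1086 contact interfaces, total contact area 4.755 um^2
```

A command-line surface wraps the same pipelines
(`simulate-map`, `simulate-volume`, `amplitude-map`, `decay-constant`,
`morphometrics`, `group-summary`):

```sh
Rscript -e 'quit(status = scartools::run_cli(commandArgs(TRUE)))' \
  simulate-map --config map.json --out out/
```

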