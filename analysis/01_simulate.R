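#!/usr/bin/env Rscript
# Generate the synthetic study: every acquisition type the pipeline
# consumes, with ground truth, written under scratch/data/. Later scripts
# read these files back, so the whole workflow exercises the package's
# file formats as well as its estimators.

suppressMessages(library(confinemetry))

data_dir <- "scratch/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
seed0 <- 20260930L

## Single-molecule TIRF movies of two SLBs (40 Hz, 200 frames), one at
## moderate and one at higher pMHC density; D = 1.16 um^2/s as measured
## for freely diffusing pMHC on an intact bilayer.
for (i in 1:2) {
  dens <- c(0.1, 0.3)[i]
  p <- sim_params(field_size = c(12.8, 12.8), n_frames = 200,
                  seed = seed0 + i)
  movie <- gen_sm_movie(p, density = dens, D = 1.16,
                        immobile_fraction = 0.01)
  write_stack(movie$stack, file.path(data_dir, sprintf("slb%d.tif", i)))
  write_table_tsv(movie$truth$tracks,
                  file.path(data_dir, sprintf("slb%d_truth.tsv", i)))
  cat(sprintf("SLB %d: density %.2f um^-2 -> %d molecules\n",
              i, movie$truth$density, movie$truth$n_initial))
}

## Fura-2 confinement experiment: pre- and post-confinement recordings of
## nine T-cells; confinement raises sectional area 120 -> 180 um^2 and
## the Ca2+ ratio by 0.3.
set.seed(seed0)
n_cells <- 9
grid <- expand.grid(ix = 1:3, iy = 1:3)
base_ratio <- 1.0 + rnorm(n_cells, 0, 0.02)
base_area <- 120 + rnorm(n_cells, 0, 4)
post_area <- base_area + 60 + rnorm(n_cells, 0, 4)
# slow random-walk motility around each grid anchor (a few um/min),
# small enough that neighbouring cells never touch
mk_cells <- function(areas, ratios) lapply(seq_len(n_cells), function(i)
  list(traj = data.frame(frame = 1:20,
                         x = grid$ix[i] * 24 + cumsum(rnorm(20, 0, 0.15)),
                         y = grid$iy[i] * 24 + cumsum(rnorm(20, 0, 0.15))),
       area = rep(areas[i], 20), ratio = rep(ratios[i], 20)))
for (stage in c("pre", "post")) {
  p <- sim_params(field_size = c(96, 96), pixel_size = 0.5, n_frames = 20,
                  background_level = 100, noise_sd = 2,
                  seed = seed0 + match(stage, c("pre", "post")) * 10L)
  fura <- gen_fura_stack(p, if (stage == "pre")
    mk_cells(base_area, base_ratio) else
    mk_cells(post_area, base_ratio + 0.3))
  write_stack(fura$stack, file.path(data_dir,
                                    sprintf("fura_%s.tif", stage)))
  write_table_tsv(fura$truth, file.path(data_dir,
                                        sprintf("fura_%s_truth.tsv", stage)))
}
cat("Fura-2 recordings written (area step 120 -> 180, ratio step +0.3)\n")

## Membrane-stained z-stacks at the two spacer-bead confinement heights.
for (h in c(6, 4))
  write_stack(gen_confined_zstack(h, z_step = 0.5, membrane_sigma = 0.4),
              file.path(data_dir, sprintf("zstack_%dum.tif", h)))

## Immunostained fields for the four conditions (rest/act, -/+ confinement)
## with pErk levels reflecting activation and the confinement effects.
perk_levels <- c(rest_unconf = 300, rest_conf = 380, act_unconf = 600,
                 act_conf = 560)
for (i in seq_along(perk_levels)) {
  per_cell <- rnorm(8, perk_levels[i], 40)   # cell-to-cell variability
  im <- gen_immuno_image(8, nucleus_radius = 3.5, cell_radius = 7,
                         perk_level = per_cell, noise_sd = 5,
                         seed = seed0 + 100L + i)
  write_stack(im$stack, file.path(data_dir,
    sprintf("immuno_%s.tif", names(perk_levels)[i])))
}
cat("Immunostain fields written for", length(perk_levels), "conditions\n")

## Membrane deflection profiles at six pressures, 6.5 um/mbar apex slope.
profs <- gen_deflection_profiles(6.5, c(25, 50, 100, 150, 200, 250),
                                 noise_sd = 5, seed = seed0)
write_table_tsv(do.call(rbind, profs),
                file.path(data_dir, "deflection_profiles.tsv"))
cat("Deflection profiles written\n")
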