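#!/usr/bin/env Rscript
# Actuator-membrane mechanics and confinement-geometry validation:
# even-polynomial fits of the deflection profiles, arc-length engineering
# strain per pressure, deflection-pressure linearity with the gap-height
# resolution per 0.1 mbar controller step, and cell heights from the
# membrane-stained z-stacks.

suppressMessages(library(confinemetry))

cfg <- pipeline_defaults()$mech
data_dir <- "scratch/data"
dir.create("results", showWarnings = FALSE)

profs <- read_table_tsv(file.path(data_dir, "deflection_profiles.tsv"))
rows <- lapply(split(profs, profs$pressure), function(pr) {
  fit <- fit_profile(pr, order = cfg$profile_order)
  a <- max(abs(pr$x_mm))
  s <- arc_strain(fit, a)
  data.frame(pressure = pr$pressure[1], apex = fit$apex,
             strain = s$strain, arc_length_mm = s$arc_length)
})
mech <- do.call(rbind, rows)
mech <- mech[order(mech$pressure), ]
pl <- pressure_linearity(mech$pressure, mech$apex,
                         controller_step = cfg$controller_step)
cat(sprintf(
  "deflection slope %.3f um/mbar (R^2 %.4f) -> %.3f um per 0.1 mbar step\n",
  pl$slope, pl$r_squared, pl$resolution))
cat(sprintf("strain at %d mbar: %.2f%%\n", max(mech$pressure),
            100 * mech$strain[which.max(mech$pressure)]))
write_table_tsv(mech, "results/mechanics_profiles.tsv")
write_table_tsv(data.frame(slope = pl$slope, intercept = pl$intercept,
                           resolution = pl$resolution,
                           r_squared = pl$r_squared),
                "results/mechanics_linearity.tsv")

heights <- lapply(c(6, 4), function(h) {
  st <- read_stack(file.path(data_dir, sprintf("zstack_%dum.tif", h)))
  est <- cell_height_from_zstack(st, peak_floor = cfg$peak_floor)
  cat(sprintf("z-stack preset %d um: measured %.2f um (%s)\n",
              h, est$height, est$method))
  data.frame(preset = h, height = est$height, method = est$method)
})
write_table_tsv(do.call(rbind, heights), "results/confinement_heights.tsv")
cat("wrote results/mechanics_*.tsv, confinement_heights.tsv\n")
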