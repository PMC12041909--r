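test_that("identical parameters and seed give bit-identical movies", {
  p <- sim_params(field_size = c(6.4, 6.4), n_frames = 10, seed = 11)
  a <- gen_sm_movie(p, density = 0.3, D = 0.5)
  b <- gen_sm_movie(p, density = 0.3, D = 0.5)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$tracks, b$truth$tracks)
})

test_that("empty field gives background-only stack and empty truth", {
  p <- sim_params(field_size = c(6.4, 6.4), n_frames = 5,
                  background_level = 100, noise_sd = 0, seed = 2)
  out <- gen_sm_movie(p, density = 0, D = 1)
  expect_equal(unique(as.numeric(out$stack$data)), 100)
  expect_equal(nrow(out$truth$tracks), 0L)
})

test_that("frozen dynamics: D = 0 and no bleaching keeps coordinates fixed", {
  p <- sim_params(field_size = c(6.4, 6.4), n_frames = 8, bleach_rate = 0,
                  seed = 3)
  out <- gen_sm_movie(p, density = 0.5, D = 0)
  tr <- out$truth$tracks
  for (id in unique(tr$id)) {
    expect_equal(length(unique(tr$x[tr$id == id])), 1L)
    expect_equal(length(unique(tr$y[tr$id == id])), 1L)
  }
  expect_equal(nrow(tr), out$truth$n_initial * 8L)
})

test_that("initial molecule count is Poisson with mean density x area", {
  # Monte-Carlo over seeds against the Poisson mean; 3 SE band
  density <- 0.5; area <- 6.4 * 6.4
  n0 <- vapply(1:100, function(s) {
    p <- sim_params(field_size = c(6.4, 6.4), n_frames = 1, seed = s)
    gen_sm_movie(p, density = density, D = 0)$truth$n_initial
  }, 0)
  lambda <- density * area
  se <- sqrt(lambda / 100)
  expect_lt(abs(mean(n0) - lambda), 3 * se)
})

test_that("photon accounting: frame totals equal unbleached brightness", {
  p <- sim_params(field_size = c(9.6, 9.6), n_frames = 20,
                  background_level = 0, noise_sd = 0, bleach_rate = 0.1,
                  seed = 5)
  out <- gen_sm_movie(p, density = 0.4, D = 1)
  mol <- out$truth$molecules
  for (f in c(1L, 5L, 20L)) {
    expected <- sum(mol$brightness[mol$bleach_frame >= f])
    got <- sum(out$stack$data[, , f])
    expect_lt(abs(got - expected), 1e-3 * max(expected, 1))
  }
})

test_that("trajectory step variance matches 2 D / frame_rate", {
  p <- sim_params(field_size = c(6.4, 6.4), n_frames = 150,
                  bleach_rate = 0, noise_sd = 0, seed = 6)
  D <- 0.05  # small steps so boundary reflections are negligible
  out <- gen_sm_movie(p, density = 2, D = D)
  tr <- out$truth$tracks
  steps <- unlist(lapply(split(tr, tr$id), function(d) {
    d <- d[order(d$frame), ]
    c(diff(d$x), diff(d$y))
  }))
  expect_gt(length(steps), 2e4)
  v <- mean(steps^2)
  truth <- 2 * D / p$frame_rate
  se <- sqrt(2 / length(steps)) * truth  # SE of a variance estimate
  expect_lt(abs(v - truth), 3 * se)
})

test_that("fura phantom: unit ratio makes the channels equal on the cell", {
  p <- sim_params(field_size = c(12.8, 12.8), pixel_size = 0.2,
                  n_frames = 3, background_level = 0, noise_sd = 0,
                  seed = 1)
  cells <- list(list(traj = data.frame(frame = 1:3, x = 6.4, y = 6.4),
                     area = rep(20, 3), ratio = rep(1, 3)))
  out <- gen_fura_stack(p, cells)
  expect_equal(out$stack$data[, , , 1], out$stack$data[, , , 2])
})

test_that("fura phantom: rendered disk area matches the area curve", {
  p <- sim_params(field_size = c(25.6, 25.6), pixel_size = 0.2,
                  n_frames = 1, background_level = 0, noise_sd = 0,
                  seed = 1)
  cells <- list(list(traj = data.frame(frame = 1, x = 12.8, y = 12.8),
                     area = 100, ratio = 1.5))
  out <- gen_fura_stack(p, cells)
  mask <- out$stack$data[, , 1, 2] > 0
  px_area <- sum(mask) * p$pixel_size^2
  # pixelized disk: allow a one-pixel ring around the circumference
  ring <- 2 * pi * sqrt(100 / pi) * p$pixel_size
  expect_lt(abs(px_area - 100), ring)
})

test_that("fura phantom with no cells is background only", {
  p <- sim_params(field_size = c(6.4, 6.4), pixel_size = 0.2, n_frames = 2,
                  background_level = 50, noise_sd = 0, seed = 1)
  out <- gen_fura_stack(p, list())
  expect_equal(unique(as.numeric(out$stack$data)), 50)
  expect_equal(nrow(out$truth), 0L)
})

test_that("fura ratio fidelity: noiseless output reproduces the curve", {
  p <- sim_params(field_size = c(12.8, 12.8), pixel_size = 0.2,
                  n_frames = 4, background_level = 100, noise_sd = 0,
                  seed = 1)
  curve <- c(1.0, 1.1, 1.25, 1.4)
  cells <- list(list(traj = data.frame(frame = 1:4, x = 6.4, y = 6.4),
                     area = rep(30, 4), ratio = curve))
  out <- gen_fura_stack(p, cells)
  rs <- make_sum_ratio(out$stack, B340 = 100, B380 = 100)
  for (f in 1:4) {
    vals <- rs$ratio[, , f][rs$valid[, , f]]
    expect_lt(max(abs(vals - curve[f]) / curve[f]), 1e-6)
  }
})

test_that("overlapping cells are reported", {
  p <- sim_params(field_size = c(12.8, 12.8), pixel_size = 0.2,
                  n_frames = 1, noise_sd = 0, seed = 1)
  cells <- list(
    list(traj = data.frame(frame = 1, x = 6.0, y = 6.4), area = 50,
         ratio = 1),
    list(traj = data.frame(frame = 1, x = 7.0, y = 6.4), area = 50,
         ratio = 2))
  expect_warning(out <- gen_fura_stack(p, cells), "overlap")
  expect_equal(attr(out$truth, "overlap_frames"), 1L)
})

test_that("confined z-stack phantom has two lamellae the height apart", {
  for (h in c(6, 4)) {
    st <- gen_confined_zstack(h, z_step = 0.5, membrane_sigma = 0.4)
    nz <- n_frames(st)
    mid <- round(dim(st$data)[1] / 2)
    prof <- st$data[mid, mid, ]
    peaks <- which(diff(sign(diff(prof))) < 0) + 1L
    peaks <- peaks[prof[peaks] > 0.3 * max(prof)]
    expect_equal(length(peaks), 2L)
    expect_equal((peaks[2] - peaks[1]) * st$z_step, h, tolerance = 0.13)
  }
})

test_that("delta-sigma limit concentrates intensity in two slices", {
  st <- gen_confined_zstack(6, z_step = 0.5, membrane_sigma = 0,
                            lateral_radius = 3)
  mid <- round(dim(st$data)[1] / 2)
  prof <- st$data[mid, mid, ]
  expect_equal(sum(prof > 0), 2L)
})

test_that("too-shallow phantom is rejected", {
  expect_error(gen_confined_zstack(0.9, z_step = 0.5), "degenerate")
})

test_that("immunostain phantom: disk areas and intensity levels", {
  out <- gen_immuno_image(3, nucleus_radius = 3, cell_radius = 8,
                          perk_level = 500, seed = 4)
  perk <- out$stack$data[, , 1, 2]
  lab <- EBImage::bwlabel(perk > 250)
  expect_equal(max(lab), 3L)
  areas <- tabulate(lab[lab > 0]) * out$stack$pixel_size^2
  expect_true(all(abs(areas - pi * 64) / (pi * 64) < 0.05))
  expect_equal(unique(perk[perk > 0]), 500)
})

test_that("immunostain phantom guards", {
  blank <- gen_immuno_image(0, seed = 1)
  expect_true(all(blank$stack$data == 0))
  expect_error(gen_immuno_image(200, field_size = c(40, 40), seed = 1),
               "placement failed")
  expect_error(gen_immuno_image(2, nucleus_radius = 9, cell_radius = 8),
               "nucleus_radius")
})

test_that("deflection profiles: apex height, linearity, flat limit", {
  pr <- gen_deflection_profiles(6.5, c(100, 200), noise_sd = 0)
  apex1 <- max(pr[[1]]$z_um); apex2 <- max(pr[[2]]$z_um)
  expect_equal(apex2, 1300)
  expect_equal(apex2 / apex1, 2)
  tiny <- gen_deflection_profiles(6.5, 1e-9, noise_sd = 0)
  expect_lt(max(abs(tiny[[1]]$z_um)), 1e-6)
})

test_that("deflection shape must vanish at the rim with unit apex", {
  expect_error(gen_deflection_profiles(6.5, 100, shape_coef = c(1, -0.5)),
               "rim")
  expect_error(gen_deflection_profiles(6.5, 100, shape_coef = c(2, -2)),
               "unit apex")
})

test_that("brownian track generator: step statistics and determinism", {
  tr <- gen_brownian_tracks(50, 100, step_sd = 0.2, seed = 9)
  expect_identical(tr, gen_brownian_tracks(50, 100, step_sd = 0.2, seed = 9))
  steps <- unlist(lapply(split(tr, tr$track), function(d)
    c(diff(d$x), diff(d$y))))
  expect_lt(abs(stats::sd(steps) - 0.2) / 0.2, 0.02)
})
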