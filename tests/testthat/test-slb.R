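test_that("a single noiseless spot is localized with correct size and brightness", {
  frame <- oracle_spot_frame(32, 32, cx_px = 14.3, cy_px = 17.7,
                             sigma = 1.0, mass = 1000)
  st <- image_stack(array(frame, c(32, 32, 1)), pixel_size = 0.16,
                    frame_interval = 0.025)
  locs <- localize_spots(st, detection_threshold = 30)
  expect_equal(nrow(locs), 1L)
  expect_lt(abs(locs$x_px - 14.3), 0.05)
  expect_lt(abs(locs$y_px - 17.7), 0.05)
  expect_true(locs$size > 0.95 && locs$size < 1.05)
  expect_true(locs$brightness > 950 && locs$brightness < 1050)
})

test_that("a blank frame yields no localizations", {
  st <- image_stack(array(100, c(32, 32, 1)), pixel_size = 0.16)
  expect_equal(nrow(localize_spots(st, detection_threshold = 30)), 0L)
})

test_that("two spots 10 px apart are both recovered near truth", {
  frame <- oracle_spot_frame(40, 40, 12.5, 20.5, 1.0, 1000) +
    oracle_spot_frame(40, 40, 22.5, 20.5, 1.0, 800)
  st <- image_stack(array(frame, c(40, 40, 1)), pixel_size = 0.16)
  locs <- localize_spots(st, detection_threshold = 30)
  expect_equal(nrow(locs), 2L)
  locs <- locs[order(locs$x_px), ]
  expect_lt(abs(locs$x_px[1] - 12.5), 0.5)
  expect_lt(abs(locs$x_px[2] - 22.5), 0.5)
})

test_that("saturated spots are flagged and not fitted", {
  frame <- oracle_spot_frame(32, 32, 16.5, 16.5, 1.0, 1e6)
  st <- image_stack(array(frame, c(32, 32, 1)), pixel_size = 0.16)
  locs <- localize_spots(st, detection_threshold = 30, saturation = 65535)
  expect_equal(nrow(locs), 0L)
  expect_equal(attr(locs, "n_saturated"), 1L)
})

test_that("size filter keeps only signals strictly inside the bounds", {
  locs <- data.frame(frame = 1L, x = 1:3, y = 1:3, x_px = 1:3, y_px = 1:3,
                     brightness = 1000, size = c(0.5, 1.0, 1.3), bg = 0)
  out <- filter_spots(locs, field_area = 1, frames = 1L,
                      density_threshold = 10)
  expect_equal(out$locs$size, 1.0)
})

test_that("first qualifying frame follows the per-frame density", {
  # 100 spots/frame in frames 1-5 (0.10 um^-2 at 1000 um^2), 80 afterwards
  locs <- do.call(rbind, lapply(1:8, function(f) {
    n <- if (f <= 5) 100 else 80
    data.frame(frame = f, x = 0, y = 0, x_px = 0, y_px = 0,
               brightness = 1000, size = 1.0, bg = 0)[rep(1, n), ]
  }))
  out <- filter_spots(locs, field_area = 1000, frames = 1:8)
  expect_equal(out$first_qualifying_frame, 6L)
  expect_true(all(out$locs$frame >= 6L))
  expect_error(filter_spots(locs, field_area = 1000, frames = 1:8,
                            density_threshold = 0.01),
               "never below threshold")
  empty <- locs[0, ]
  expect_error(filter_spots(empty, field_area = 1000), "empty")
})

test_that("single-molecule brightness is the interval mean", {
  locs <- data.frame(frame = c(5, 6, 7, 40), x = 0, y = 0, x_px = 0,
                     y_px = 0, brightness = c(900, 1000, 1100, 9999),
                     size = 1, bg = 0)
  expect_equal(as.numeric(single_molecule_brightness(locs, 5, 10)), 1000)
  expect_error(single_molecule_brightness(locs, 100, 10), "no localizations")
})

test_that("density estimate equals brightness per area over molecule brightness", {
  # 50 molecules of brightness 1000 on 100 um^2, background 0
  frame <- matrix(0, 50, 50)
  frame[cbind(sample(10:40, 50, TRUE), sample(10:40, 50, TRUE))] <- 0
  ps <- 0.2  # 50 px * 0.2 = 10 um => 100 um^2
  set.seed(2)
  for (k in 1:50)
    frame <- frame + oracle_spot_frame(50, 50, runif(1, 10, 40),
                                       runif(1, 10, 40), 1.0, 1000)
  st <- image_stack(array(frame, c(50, 50, 1)), pixel_size = ps)
  de <- estimate_density(st, single_molecule_brightness = 1000,
                         background = 0)
  expect_equal(de$mean_brightness_per_um2, 500, tolerance = 1e-3)
  expect_equal(de$rho, 0.5, tolerance = 1e-3)
  # scale invariance: doubling all brightnesses and the reference
  st2 <- image_stack(array(2 * frame, c(50, 50, 1)), pixel_size = ps)
  de2 <- estimate_density(st2, single_molecule_brightness = 2000,
                          background = 0)
  expect_equal(de2$rho, de$rho, tolerance = 1e-12)
  # blank field
  blank <- image_stack(array(0, c(50, 50, 1)), pixel_size = ps)
  expect_equal(estimate_density(blank, 1000, background = 0)$rho, 0)
  expect_error(estimate_density(st, 0, background = 0), "positive")
})

test_that("linking keeps a slowly moving molecule on one track", {
  locs <- data.frame(frame = 1:20, x = 0.16 * (1:20) * 0.5, y = 0.16 * 10,
                     x_px = (1:20) * 0.5, y_px = 10, brightness = 1000,
                     size = 1, bg = 0)
  tr <- link_molecules(locs, search_radius = 6)
  expect_equal(length(unique(tr$track)), 1L)
  expect_equal(nrow(tr), 20L)
})

test_that("a displacement beyond the search radius splits the track", {
  xpx <- c(1, 2, 3, 10, 11)  # 7 px jump with radius 6
  locs <- data.frame(frame = 1:5, x = 0.16 * xpx, y = 0.16 * 5,
                     x_px = xpx, y_px = 5, brightness = 1000, size = 1,
                     bg = 0)
  tr <- link_molecules(locs, search_radius = 6)
  expect_equal(length(unique(tr$track)), 2L)
})

test_that("well-separated molecules never swap identity", {
  set.seed(7)
  x1 <- cumsum(c(5, rnorm(19, 0, 0.5)))
  x2 <- cumsum(c(40, rnorm(19, 0, 0.5)))
  locs <- rbind(
    data.frame(frame = 1:20, x = 0.16 * x1, y = 0.16 * 5, x_px = x1,
               y_px = 5, brightness = 1000, size = 1, bg = 0),
    data.frame(frame = 1:20, x = 0.16 * x2, y = 0.16 * 5, x_px = x2,
               y_px = 5, brightness = 1000, size = 1, bg = 0))
  tr <- link_molecules(locs, search_radius = 6)
  expect_equal(length(unique(tr$track)), 2L)
  for (id in unique(tr$track)) {
    xs <- tr$x_px[tr$track == id]
    expect_true(all(xs < 25) || all(xs > 25))
  }
})

test_that("linking reproduces generator tracks up to relabeling", {
  # perfect localizations straight from the generator truth isolate the
  # linker from detection effects
  p <- sim_params(field_size = c(12.8, 12.8), n_frames = 40,
                  noise_sd = 0, bleach_rate = 0.05, seed = 23)
  out <- gen_sm_movie(p, density = 0.05, D = 0.3)
  truth <- out$truth$tracks
  # fixture validity: molecules stay well separated in every frame
  mind <- min(vapply(split(truth, truth$frame), function(d)
    if (nrow(d) < 2) Inf else min(stats::dist(cbind(d$x, d$y))), 0))
  expect_gt(mind / p$pixel_size, 2)
  locs <- data.frame(frame = truth$frame, x = truth$x, y = truth$y,
                     x_px = truth$x / p$pixel_size,
                     y_px = truth$y / p$pixel_size,
                     brightness = 1000, size = 1, bg = 0)
  tr <- link_molecules(locs, search_radius = 6)
  tr$truth_id <- truth$id[match(paste(tr$frame, tr$x_px),
                                paste(truth$frame,
                                      truth$x / p$pixel_size))]
  # the recovered partition equals the truth partition up to relabeling
  purity <- vapply(split(tr$truth_id, tr$track),
                   function(v) length(unique(v)), 0L)
  frag <- vapply(split(tr$track, tr$truth_id),
                 function(v) length(unique(v)), 0L)
  expect_true(all(purity == 1L))
  expect_true(all(frag == 1L))
})

test_that("image-based localization and linking never mix identities", {
  p <- sim_params(field_size = c(12.8, 12.8), n_frames = 40,
                  noise_sd = 0, bleach_rate = 0.05, seed = 23)
  out <- gen_sm_movie(p, density = 0.05, D = 0.3)
  locs <- localize_spots(out$stack, detection_threshold = 30)
  fl <- filter_spots(locs, field_area = field_area_um2(out$stack),
                     frames = seq_len(n_frames(out$stack)))
  tr <- link_molecules(fl$locs)
  truth <- out$truth$tracks
  assign_truth <- function(i) {
    cand <- truth[truth$frame == tr$frame[i], ]
    cand$id[which.min((cand$x - tr$x[i])^2 + (cand$y - tr$y[i])^2)]
  }
  tr$truth_id <- vapply(seq_len(nrow(tr)), assign_truth, 0L)
  purity <- vapply(split(tr$truth_id, tr$track),
                   function(v) length(unique(v)), 0L)
  expect_true(all(purity == 1L))
})

test_that("all-static tracks give zero diffusion and zero mobile fraction", {
  tr <- do.call(rbind, lapply(1:12, function(i)
    data.frame(track = i, frame = 1:10, x = i, y = i)))
  mm <- molecule_diffusion(tr, frame_interval = 0.025)
  expect_equal(mm$D, 0)
  expect_equal(mm$mobile_fraction, 0)
})

test_that("diffusion estimator is consistent across seeds and D values", {
  dt <- 0.025
  for (D in c(0.1, 0.5, 1.16)) {
    est <- vapply(1:20, function(s) {
      tr <- gen_brownian_tracks(60, 20, step_sd = sqrt(2 * D * dt),
                                frame_interval = dt, seed = 100 + s)
      molecule_diffusion(tr, frame_interval = dt)$D
    }, 0)
    se <- stats::sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - D), 3 * se + 1e-12)
  }
})

test_that("MSD curve is non-negative and excludes the zero lag", {
  tr <- gen_brownian_tracks(20, 15, step_sd = 0.2, seed = 5)
  mm <- molecule_diffusion(tr, frame_interval = 0.025)
  expect_true(all(mm$msd$msd >= 0))
  expect_true(all(mm$msd$lag_s > 0))
})
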