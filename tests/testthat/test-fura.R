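test_that("sum and ratio stacks follow the background-corrected arithmetic", {
  a340 <- image_stack(array(200, c(4, 4, 2)), pixel_size = 0.5)
  a380 <- image_stack(array(100, c(4, 4, 2)), pixel_size = 0.5)
  rs <- make_sum_ratio(a340, a380, B340 = 50, B380 = 50)
  expect_equal(unique(as.numeric(rs$sum)), 300)
  expect_equal(unique(as.numeric(rs$ratio)), 3.0)
  # identity when channels are equal and background zero
  rs2 <- make_sum_ratio(a380, a380, B340 = 0, B380 = 0)
  expect_equal(unique(as.numeric(rs2$ratio)), 1.0)
})

test_that("zero denominator pixels are masked invalid, not infinite", {
  a340 <- image_stack(array(200, c(4, 4, 1)), pixel_size = 0.5)
  a380 <- image_stack(array(50, c(4, 4, 1)), pixel_size = 0.5)
  rs <- make_sum_ratio(a340, a380, B340 = 50, B380 = 50)
  expect_true(all(!rs$valid))
  expect_true(all(is.na(rs$ratio)))
  bad <- image_stack(array(100, c(5, 4, 1)), pixel_size = 0.5)
  expect_error(make_sum_ratio(a340, bad, 0, 0), "different shapes")
})

test_that("ratio stack is invariant under a common channel gain", {
  p <- sim_params(field_size = c(12.8, 12.8), pixel_size = 0.2,
                  n_frames = 2, background_level = 100, noise_sd = 0,
                  seed = 3)
  cells <- make_grid_cells(1, 2, 12.8, area = 40, ratio = 1.3)
  out <- gen_fura_stack(p, cells)
  rs1 <- make_sum_ratio(out$stack, B340 = 100, B380 = 100)
  gained <- out$stack
  gained$data <- gained$data * 2.5
  rs2 <- make_sum_ratio(gained, B340 = 250, B380 = 250)
  expect_equal(rs2$ratio, rs1$ratio, tolerance = 1e-12)
})

test_that("segmentation recovers well-separated disks and their areas", {
  p <- sim_params(field_size = c(51.2, 51.2), pixel_size = 0.4,
                  n_frames = 1, background_level = 100, noise_sd = 0,
                  seed = 5)
  cells <- make_grid_cells(3, 1, 51.2, area = 100, ratio = 1.2)
  out <- gen_fura_stack(p, cells)
  rs <- make_sum_ratio(out$stack, B340 = 100, B380 = 100)
  mask <- segment_cells(rs$sum[, , 1], pixel_size = 0.4)
  expect_equal(max(mask), 3L)
  areas <- tabulate(mask[mask > 0]) * 0.4^2
  expect_true(all(abs(areas - 100) / 100 < 0.05))
})

test_that("a blank frame segments to zero labels", {
  expect_equal(max(segment_cells(matrix(0, 64, 64), pixel_size = 0.4)), 0L)
})

test_that("watershed separates touching disks with distinct maxima", {
  ps <- 0.4
  m1 <- confinemetry:::disk_mask(96, 96, 15, 19.2, 6, ps)
  m2 <- confinemetry:::disk_mask(96, 96, 26.5, 19.2, 6, ps)
  img <- matrix(0, 96, 96); img[m1 | m2] <- 1000
  mask <- segment_cells(img, pixel_size = ps)
  expect_equal(max(mask), 2L)
})

test_that("segmentation count matches truth across seeds", {
  for (s in 1:10) {
    p <- sim_params(field_size = c(51.2, 51.2), pixel_size = 0.4,
                    n_frames = 1, background_level = 100, noise_sd = 2,
                    seed = s)
    cells <- make_grid_cells(4, 1, 51.2, area = 80, ratio = 1.1,
                             jitter_um = 2, seed = s)
    out <- gen_fura_stack(p, cells)
    rs <- make_sum_ratio(out$stack, B340 = 100, B380 = 100)
    mask <- segment_cells(rs$sum[, , 1], pixel_size = 0.4)
    expect_equal(max(mask), 4L)
  }
})

test_that("a static cell is tracked as one id with constant area and exact ratio", {
  p <- sim_params(field_size = c(25.6, 25.6), pixel_size = 0.4,
                  n_frames = 6, background_level = 100, noise_sd = 0,
                  seed = 6)
  cells <- list(list(traj = data.frame(frame = 1:6, x = 12.8, y = 12.8),
                     area = rep(100, 6), ratio = rep(1.4, 6)))
  out <- gen_fura_stack(p, cells)
  rs <- make_sum_ratio(out$stack, B340 = 100, B380 = 100)
  series <- track_cells(rs)
  expect_equal(unique(series$cell), 1L)
  expect_equal(nrow(series), 6L)
  expect_equal(length(unique(series$area)), 1L)
  expect_equal(series$ratio, rep(1.4, 6), tolerance = 1e-9)
  expect_lt(abs(series$area[1] - 100) / 100, 0.05)
})

test_that("identity is preserved for a moving cell and separated pairs", {
  p <- sim_params(field_size = c(51.2, 51.2), pixel_size = 0.4,
                  n_frames = 8, background_level = 100, noise_sd = 0,
                  seed = 7)
  traj1 <- data.frame(frame = 1:8, x = 10 + 2 * (0:7), y = 12)
  traj2 <- data.frame(frame = 1:8, x = 10 + 2 * (0:7), y = 38)
  cells <- list(list(traj = traj1, area = rep(80, 8), ratio = rep(1, 8)),
                list(traj = traj2, area = rep(80, 8), ratio = rep(2, 8)))
  out <- gen_fura_stack(p, cells)
  rs <- make_sum_ratio(out$stack, B340 = 100, B380 = 100)
  series <- track_cells(rs, max_displacement = 15)
  expect_equal(length(unique(series$cell)), 2L)
  counts <- table(series$cell)
  expect_true(all(counts == 8))
  # ratio identifies the cells: each track must keep one constant ratio
  for (id in unique(series$cell))
    expect_lt(diff(range(series$ratio[series$cell == id])), 1e-6)
})

test_that("recordings join by proximity and unmatched cells are flagged", {
  mk <- function(xs, frames) {
    do.call(rbind, lapply(seq_along(xs), function(i)
      data.frame(cell = i, frame = frames, x = xs[i], y = 10,
                 area = 100, ratio = 1, border = FALSE)))
  }
  pre <- mk(c(10, 30, 50), 1:5)
  post <- mk(c(10.5, 30.2), 1:4)   # third cell left during the gap
  joined <- join_recordings(pre, post, match_limit = 25)
  expect_equal(attr(joined, "join_index"), 6L)
  expect_equal(sort(unique(joined$cell[joined$recording == "post"])),
               c(1L, 2L))
  expect_true(all(joined$matched[joined$recording == "post"]))
  expect_equal(max(joined$frame), 9L)
  # a post cell with no pre partner gets a fresh id and a flag
  post2 <- mk(c(10.5, 90), 1:4)
  joined2 <- join_recordings(pre, post2, match_limit = 25)
  newcell <- joined2[joined2$recording == "post" & !joined2$matched, ]
  expect_equal(unique(newcell$x), 90)
  expect_equal(unique(newcell$cell), 4L)
})

test_that("window means recover a step and exclude absent cells", {
  ser <- rbind(
    data.frame(cell = 1, frame = 1:10, x = 0, y = 0,
               area = c(rep(120, 5), rep(180, 5)),
               ratio = c(rep(1, 5), rep(2, 5)), border = FALSE),
    data.frame(cell = 2, frame = 1:5, x = 0, y = 0, area = 100,
               ratio = 1, border = FALSE))
  wm <- window_means(ser, pre_window = c(1, 5), post_window = c(6, 10))
  expect_equal(nrow(wm), 1L)
  expect_equal(attr(wm, "n_excluded"), 1L)
  expect_equal(wm$area_pre, 120)
  expect_equal(wm$area_post, 180)
  expect_equal(wm$ratio_pre, 1)
  expect_equal(wm$ratio_post, 2)
  expect_error(window_means(ser, c(1, 6), c(6, 10)), "non-overlapping")
  expect_error(window_means(ser, c(1, 5), c(50, 60)), "no observations")
})

test_that("per-frame cell areas never exceed the field area", {
  p <- sim_params(field_size = c(51.2, 51.2), pixel_size = 0.4,
                  n_frames = 3, background_level = 100, noise_sd = 2,
                  seed = 9)
  cells <- make_grid_cells(2, 3, 51.2, area = 120, ratio = 1.2, seed = 9)
  out <- gen_fura_stack(p, cells)
  rs <- make_sum_ratio(out$stack, B340 = 100, B380 = 100)
  series <- track_cells(rs)
  per_frame <- tapply(series$area, series$frame, sum)
  expect_true(all(per_frame <= 25.6^2))
})
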