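#' Simulation parameters for synthetic acquisitions
#'
#' Bundles the acquisition geometry and camera model shared by the synthetic
#' generators. Defaults follow the TIRF single-molecule acquisition settings
#' the pipeline targets: 200 frames at 40 Hz; the camera pixel size is not a
#' published quantity, so the default of 0.16 um/px (a typical 100x/EMCCD
#' combination) is configurable.
#'
#' @param field_size field of view in micrometres, `c(width, height)`.
#' @param pixel_size um per pixel (> 0).
#' @param frame_rate frames per second (> 0).
#' @param n_frames number of frames (>= 1).
#' @param psf_sigma Gaussian PSF sigma in pixels (> 0).
#' @param mean_molecule_brightness mean integrated counts per molecule.
#' @param brightness_cv coefficient of variation of per-molecule brightness.
#' @param bleach_rate per-frame irreversible bleaching probability in [0, 1].
#' @param background_level constant background in counts per pixel.
#' @param noise_sd Gaussian read-noise standard deviation in counts.
#' @param seed integer seed; identical parameters give bit-identical output.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(field_size = c(25.6, 25.6), pixel_size = 0.16,
                       frame_rate = 40, n_frames = 200, psf_sigma = 1.0,
                       mean_molecule_brightness = 1000, brightness_cv = 0.1,
                       bleach_rate = 0.02, background_level = 100,
                       noise_sd = 5, seed = 1L) {
  stopifnot(length(field_size) == 2L, all(field_size > 0), pixel_size > 0,
            frame_rate > 0, n_frames >= 1, psf_sigma > 0,
            mean_molecule_brightness > 0, brightness_cv >= 0,
            background_level >= 0, noise_sd >= 0)
  if (!is.finite(bleach_rate) || bleach_rate < 0 || bleach_rate > 1)
    stop("bleach_rate must lie in [0, 1]")
  structure(list(field_size = as.numeric(field_size),
                 pixel_size = pixel_size, frame_rate = frame_rate,
                 n_frames = as.integer(n_frames), psf_sigma = psf_sigma,
                 mean_molecule_brightness = mean_molecule_brightness,
                 brightness_cv = brightness_cv, bleach_rate = bleach_rate,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Fold an out-of-range 1-based pixel index back into [1, n] by reflection at
# the image border (mirror about the pixel grid edges). Keeps photon mass in
# the field, consistent with the reflecting boundaries used for motion.
fold_index <- function(i, n) {
  i <- (i - 1L) %% (2L * n)
  ifelse(i >= n, 2L * n - 1L - i, i) + 1L
}

# Add one integrated-Gaussian spot to an image (matrix, [y, x]).
# x_um/y_um are physical coordinates; mass is the integrated brightness in
# counts. The PSF is integrated exactly over each pixel (not point sampled)
# within a +/- 5 sigma window, and mass falling outside the field is folded
# back by reflection so total intensity is conserved.
render_spot <- function(img, x_um, y_um, sigma_px, mass, pixel_size) {
  nx <- ncol(img); ny <- nrow(img)
  cx <- x_um / pixel_size   # position in pixel-edge coordinates
  cy <- y_um / pixel_size
  w <- ceiling(5 * sigma_px) + 1L
  jj <- (floor(cx) - w):(floor(cx) + w)     # candidate columns (1-based)
  ii <- (floor(cy) - w):(floor(cy) + w)
  mx <- stats::pnorm(jj, cx, sigma_px) - stats::pnorm(jj - 1, cx, sigma_px)
  my <- stats::pnorm(ii, cy, sigma_px) - stats::pnorm(ii - 1, cy, sigma_px)
  fj <- fold_index(jj, nx); fi <- fold_index(ii, ny)
  mxf <- rowsum(mx, fj); myf <- rowsum(my, fi)
  uc <- as.integer(rownames(mxf)); ur <- as.integer(rownames(myf))
  img[ur, uc] <- img[ur, uc] + mass * (myf %*% t(mxf))
  img
}

# Reflect positions into [0, L] (specular walls at the field edges).
reflect_into <- function(p, L) {
  p <- p %% (2 * L)
  ifelse(p > L, 2 * L - p, p)
}

#' Simulate a single-molecule TIRF movie of an SLB
#'
#' Generates a movie of fluorescently labelled molecules diffusing on a
#' supported lipid bilayer, with known ground truth. The initial molecule
#' count is Poisson with mean `density x field area`; a fraction of
#' molecules is immobile, the rest take 2D Brownian steps with per-axis
#' variance `2 D / frame_rate`, reflected at the field edges. Each molecule
#' bleaches irreversibly with probability `bleach_rate` per frame, so later
#' frames are sparse enough for single-molecule analysis. Per-molecule
#' brightness is drawn once from a log-normal with the configured mean and
#' CV and stays constant until bleaching. Spots are rendered as integrated
#' 2D Gaussians plus constant background and Gaussian read noise.
#'
#' @param params a [sim_params()] object.
#' @param density molecule surface density in um^-2 (>= 0).
#' @param D diffusion coefficient in um^2/s (>= 0, finite).
#' @param immobile_fraction fraction of molecules that never move, in [0, 1].
#' @return A list with `stack` (an [image_stack()]) and `truth`, a list with
#'   `tracks` (data frame: id, frame, x, y in um), `molecules` (id,
#'   brightness, mobile, bleach_frame), `density` (realized initial count /
#'   area), `D`, and `n_initial`.
#' @export
gen_sm_movie <- function(params, density, D, immobile_fraction = 0) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.finite(D) || D < 0) stop("D must be finite and non-negative")
  if (density < 0) stop("density must be non-negative")
  if (immobile_fraction < 0 || immobile_fraction > 1)
    stop("immobile_fraction must lie in [0, 1]")
  set.seed(params$seed)
  L <- params$field_size
  area <- prod(L)
  nx <- round(L[1] / params$pixel_size)
  ny <- round(L[2] / params$pixel_size)
  n0 <- stats::rpois(1L, density * area)
  nf <- params$n_frames

  mol <- data.frame(id = integer(0), brightness = numeric(0),
                    mobile = logical(0), bleach_frame = integer(0))
  tracks <- data.frame(id = integer(0), frame = integer(0),
                       x = numeric(0), y = numeric(0))
  pos <- NULL
  if (n0 > 0) {
    x0 <- stats::runif(n0, 0, L[1])
    y0 <- stats::runif(n0, 0, L[2])
    mobile <- stats::runif(n0) >= immobile_fraction
    cv <- params$brightness_cv
    if (cv > 0) {
      sdl <- sqrt(log(1 + cv^2))
      bri <- stats::rlnorm(n0, log(params$mean_molecule_brightness) -
                               sdl^2 / 2, sdl)
    } else bri <- rep(params$mean_molecule_brightness, n0)
    # last visible frame: geometric survival, bleach tested after each frame
    if (params$bleach_rate > 0)
      last <- pmin(stats::rgeom(n0, params$bleach_rate) + 1L, nf)
    else last <- rep(nf, n0)
    mol <- data.frame(id = seq_len(n0), brightness = bri, mobile = mobile,
                      bleach_frame = last)
    step_sd <- sqrt(2 * D / params$frame_rate)
    xs <- matrix(NA_real_, n0, nf); ys <- matrix(NA_real_, n0, nf)
    xs[, 1] <- x0; ys[, 1] <- y0
    if (nf > 1) for (f in 2:nf) {
      dx <- ifelse(mobile, stats::rnorm(n0, 0, step_sd), 0)
      dy <- ifelse(mobile, stats::rnorm(n0, 0, step_sd), 0)
      xs[, f] <- reflect_into(xs[, f - 1] + dx, L[1])
      ys[, f] <- reflect_into(ys[, f - 1] + dy, L[2])
    }
    keep <- which(outer(last, seq_len(nf), `>=`), arr.ind = TRUE)
    keep <- keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
    tracks <- data.frame(id = keep[, 1], frame = keep[, 2],
                         x = xs[cbind(keep[, 1], keep[, 2])],
                         y = ys[cbind(keep[, 1], keep[, 2])])
    pos <- list(xs = xs, ys = ys)
  }

  arr <- array(params$background_level, c(ny, nx, nf))
  if (n0 > 0) for (f in seq_len(nf)) {
    alive <- which(mol$bleach_frame >= f)
    img <- arr[, , f]
    for (m in alive)
      img <- render_spot(img, pos$xs[m, f], pos$ys[m, f],
                         params$psf_sigma, mol$brightness[m],
                         params$pixel_size)
    arr[, , f] <- img
  }
  if (params$noise_sd > 0)
    arr <- arr + stats::rnorm(length(arr), 0, params$noise_sd)

  stack <- image_stack(arr, pixel_size = params$pixel_size,
                       frame_interval = 1 / params$frame_rate)
  list(stack = stack,
       truth = list(tracks = tracks, molecules = mol,
                    density = n0 / area, D = D, n_initial = n0))
}

disk_mask <- function(nx, ny, cx_um, cy_um, radius_um, pixel_size) {
  xc <- (seq_len(nx) - 0.5) * pixel_size
  yc <- (seq_len(ny) - 0.5) * pixel_size
  outer(yc, xc, function(y, x) (x - cx_um)^2 + (y - cy_um)^2 <= radius_um^2)
}

#' Simulate a dual-excitation Fura-2 stack
#'
#' Renders motile cells as disks into a two-channel (340 nm / 380 nm
#' excitation) stack such that the background-corrected ratio
#' `(I340 - B) / (I380 - B)` equals each cell's prescribed ratio curve at
#' every cell pixel, and the disk area follows the prescribed area curve.
#' Both channels share geometry exactly, as for sequential dual-excitation
#' imaging of the same dye.
#'
#' @param params a [sim_params()]; `mean_molecule_brightness` sets the
#'   380-channel cell amplitude above background.
#' @param cells list of cells, each a list with `traj` (data frame `frame`,
#'   `x`, `y` in um), `area` (um^2 per frame of `traj`) and `ratio`
#'   (dimensionless per frame, strictly positive).
#' @return List with `stack` (4D [image_stack()], channels "340", "380") and
#'   `truth` (data frame: cell, frame, x, y, area, ratio, plus an
#'   `overlap_frames` attribute listing frames where rendered cells touched).
#' @export
gen_fura_stack <- function(params, cells) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  L <- params$field_size
  nx <- round(L[1] / params$pixel_size)
  ny <- round(L[2] / params$pixel_size)
  nf <- params$n_frames
  B <- params$background_level
  A <- params$mean_molecule_brightness
  arr <- array(B, c(ny, nx, nf, 2L))
  truth <- list(); overlap <- integer(0)
  claimed <- array(0L, c(ny, nx))
  for (f in seq_len(nf)) {
    claimed[] <- 0L
    i340 <- arr[, , f, 1L]; i380 <- arr[, , f, 2L]
    for (ci in seq_along(cells)) {
      cell <- cells[[ci]]
      row <- match(f, cell$traj$frame)
      if (is.na(row)) next
      ratio <- cell$ratio[row]; area <- cell$area[row]
      if (!is.finite(ratio) || ratio <= 0)
        stop("ratio curves must be strictly positive")
      cx <- cell$traj$x[row]; cy <- cell$traj$y[row]
      if (cx < 0 || cx > L[1] || cy < 0 || cy > L[2])
        stop("cell trajectory leaves the field of view")
      r <- sqrt(area / pi)
      m <- disk_mask(nx, ny, cx, cy, r, params$pixel_size)
      i380[m] <- i380[m] + A
      i340[m] <- i340[m] + ratio * A
      claimed[m] <- claimed[m] + 1L
      truth[[length(truth) + 1L]] <-
        data.frame(cell = ci, frame = f, x = cx, y = cy,
                   area = area, ratio = ratio)
    }
    if (any(claimed > 1L)) overlap <- c(overlap, f)
    arr[, , f, 1L] <- i340; arr[, , f, 2L] <- i380
  }
  if (length(overlap))
    warning("cells overlap in frame(s) ", paste(overlap, collapse = ", "))
  if (params$noise_sd > 0)
    arr <- arr + stats::rnorm(length(arr), 0, params$noise_sd)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(cell = integer(0), frame = integer(0), x = numeric(0),
               y = numeric(0), area = numeric(0), ratio = numeric(0))
  attr(truth, "overlap_frames") <- unique(overlap)
  stack <- image_stack(arr, pixel_size = params$pixel_size,
                       frame_interval = 1 / params$frame_rate,
                       channels = c("340", "380"))
  list(stack = stack, truth = truth)
}

#' Simulate a membrane-stained confined-cell z-stack
#'
#' Phantom of a membrane-stained cell squeezed between two surfaces: two
#' bright lamellae (the top and bottom plasma membranes) separated by the
#' confinement height, each with a Gaussian axial profile integrated over
#' the slice thickness, plus a dim lateral membrane shell connecting them.
#' The z range covers both lamellae with margin.
#'
#' @param height confinement height (lamella separation) in um (> 0).
#' @param z_step axial sampling step in um (default 0.5, the acquisition
#'   step the pipeline targets).
#' @param membrane_sigma axial Gaussian sigma of each lamella in um.
#' @param lateral_radius cell radius in the imaging plane, um.
#' @param pixel_size lateral um/px.
#' @param amplitude peak lamella brightness scale in counts.
#' @return An [image_stack()] whose frame dimension is z (slice i at
#'   `z = (i-1) * z_step`), with a `true_height` attribute.
#' @export
gen_confined_zstack <- function(height, z_step = 0.5, membrane_sigma = 0.4,
                                lateral_radius = 6, pixel_size = 0.16,
                                amplitude = 1000) {
  stopifnot(height > 0, z_step > 0, membrane_sigma >= 0, lateral_radius > 0)
  if (height < 2 * z_step)
    stop("degenerate phantom: height must be at least 2 z-steps")
  margin <- max(4 * membrane_sigma, 2 * z_step) + 0.5
  z_bot <- margin
  z_top <- margin + height
  zs <- seq(0, z_top + margin, by = z_step)
  nx <- ceiling((2 * lateral_radius + 4) / pixel_size)
  ny <- nx
  cx <- nx * pixel_size / 2; cy <- ny * pixel_size / 2
  inner <- disk_mask(nx, ny, cx, cy, lateral_radius, pixel_size)
  shell <- disk_mask(nx, ny, cx, cy, lateral_radius + 0.4, pixel_size) &
    !disk_mask(nx, ny, cx, cy, lateral_radius - 0.4, pixel_size)
  # lamella mass integrated over each slice so the delta-sigma limit puts
  # all intensity into the slices containing the lamellae
  slice_mass <- function(z0) {
    if (membrane_sigma > 0)
      stats::pnorm(zs + z_step / 2, z0, membrane_sigma) -
        stats::pnorm(zs - z_step / 2, z0, membrane_sigma)
    else as.numeric(abs(zs - z0) <= z_step / 2)
  }
  lam <- slice_mass(z_bot) + slice_mass(z_top)
  side <- as.numeric(zs >= z_bot & zs <= z_top)
  arr <- array(0, c(ny, nx, length(zs)))
  for (k in seq_along(zs)) {
    img <- matrix(0, ny, nx)
    img[inner] <- amplitude * lam[k]
    img[shell] <- img[shell] + 0.15 * amplitude * side[k]
    arr[, , k] <- img
  }
  st <- image_stack(arr, pixel_size = pixel_size, z_step = z_step)
  attr(st, "true_height") <- height
  st
}

#' Simulate a two-channel immunostain image (nucleus + pErk1/2)
#'
#' Non-overlapping cells placed by rejection sampling: channel 1 carries
#' nuclear-stain disks, channel 2 phospho-Erk1/2 disks of the full cell
#' footprint at a uniform level plus optional noise. Nuclei are concentric
#' with their cells.
#'
#' @param n_cells number of cells (>= 0).
#' @param nucleus_radius,cell_radius radii in um; nucleus must be smaller.
#' @param perk_level pErk channel level in counts (scalar or per cell).
#' @param seed integer seed.
#' @param field_size field in um.
#' @param pixel_size um/px (default 0.22, a 20x confocal acquisition).
#' @param nucleus_level nuclear channel level in counts.
#' @param noise_sd Gaussian noise sd in counts.
#' @return List with `stack` (channels "dapi", "perk") and `truth`
#'   (data frame: cell, x, y, nucleus_radius, cell_radius, perk_level).
#' @export
gen_immuno_image <- function(n_cells, nucleus_radius = 3, cell_radius = 8,
                             perk_level = 500, seed = 1L,
                             field_size = c(110, 110), pixel_size = 0.22,
                             nucleus_level = 800, noise_sd = 0) {
  stopifnot(n_cells >= 0, nucleus_radius > 0, cell_radius > 0)
  if (nucleus_radius >= cell_radius)
    stop("nucleus_radius must be smaller than cell_radius")
  set.seed(seed)
  perk_level <- rep_len(perk_level, max(n_cells, 1L))
  nx <- round(field_size[1] / pixel_size)
  ny <- round(field_size[2] / pixel_size)
  margin <- cell_radius + 1
  xs <- numeric(0); ys <- numeric(0); tries <- 0L
  while (length(xs) < n_cells) {
    if (tries > 5000L)
      stop("placement failed: field too small for ", n_cells, " cells")
    tries <- tries + 1L
    x <- stats::runif(1, margin, field_size[1] - margin)
    y <- stats::runif(1, margin, field_size[2] - margin)
    if (all(sqrt((xs - x)^2 + (ys - y)^2) > 2 * cell_radius + 1)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  dapi <- matrix(0, ny, nx); perk <- matrix(0, ny, nx)
  for (i in seq_len(n_cells)) {
    dapi[disk_mask(nx, ny, xs[i], ys[i], nucleus_radius, pixel_size)] <-
      nucleus_level
    perk[disk_mask(nx, ny, xs[i], ys[i], cell_radius, pixel_size)] <-
      perk_level[i]
  }
  arr <- array(0, c(ny, nx, 1L, 2L))
  arr[, , 1L, 1L] <- dapi; arr[, , 1L, 2L] <- perk
  if (noise_sd > 0) arr <- arr + stats::rnorm(length(arr), 0, noise_sd)
  truth <- data.frame(cell = seq_len(n_cells), x = xs[seq_len(n_cells)],
                      y = ys[seq_len(n_cells)],
                      nucleus_radius = rep_len(nucleus_radius, n_cells),
                      cell_radius = rep_len(cell_radius, n_cells),
                      perk_level = perk_level[seq_len(n_cells)])
  list(stack = image_stack(arr, pixel_size = pixel_size,
                           channels = c("dapi", "perk")),
       truth = truth)
}

eval_even_poly <- function(coef, u) {
  # coef are coefficients of u^0, u^2, u^4, ...
  p <- 0
  for (k in seq_along(coef)) p <- p + coef[k] * u^(2 * (k - 1))
  p
}

#' Simulate membrane deflection profiles at several pressures
#'
#' Profiles of an elastic membrane bulging under pressure: apex height is
#' linear in pressure with the given slope, the radial shape is an even
#' polynomial normalized to unit apex that vanishes at the rim.
#'
#' @param slope apex deflection per pressure, um/mbar.
#' @param pressures applied pressures in mbar (all > 0).
#' @param shape_coef coefficients of the even polynomial shape in
#'   `u = x / half_width` (powers 0, 2, 4, ...); must satisfy shape(0) = 1
#'   and shape(1) = 0. Default is the parabola `1 - u^2`.
#' @param half_width membrane half width in mm.
#' @param noise_sd measurement noise sd in um.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param n_points samples across the profile.
#' @return A list of data frames (`x_mm`, `z_um`, `pressure`), one per
#'   pressure.
#' @export
gen_deflection_profiles <- function(slope, pressures, shape_coef = c(1, -1),
                                    half_width = 5, noise_sd = 0, seed = 1L,
                                    n_points = 201) {
  stopifnot(all(pressures > 0), half_width > 0, n_points >= 3)
  if (abs(eval_even_poly(shape_coef, 0) - 1) > 1e-9)
    stop("invalid shape: shape(0) must equal 1 (unit apex)")
  if (abs(eval_even_poly(shape_coef, 1)) > 1e-9)
    stop("invalid shape: shape must vanish at the rim (shape(1) = 0)")
  set.seed(seed)
  x <- seq(-half_width, half_width, length.out = n_points)
  shp <- eval_even_poly(shape_coef, x / half_width)
  lapply(pressures, function(p) {
    z <- slope * p * shp
    if (noise_sd > 0) z <- z + stats::rnorm(length(z), 0, noise_sd)
    data.frame(x_mm = x, z_um = z, pressure = p)
  })
}

#' Simulate Brownian trajectories with optional drift
#'
#' Trajectory-level ground truth for estimator studies, bypassing image
#' rendering: each track takes 2D Gaussian steps of the given per-axis
#' standard deviation, optionally superimposed on directed motion at a
#' constant speed in a random per-track direction, with optional
#' localization noise added to every position.
#'
#' @param n_tracks number of trajectories.
#' @param n_steps steps per trajectory (scalar or vector, recycled).
#' @param step_sd per-axis Brownian step standard deviation, um; equals
#'   `sqrt(2 D frame_interval)` for diffusion coefficient D.
#' @param frame_interval frame interval in seconds.
#' @param speed directed-motion speed, um/s (0 for pure diffusion).
#' @param loc_noise_sd localization noise per axis, um (the positional
#'   accuracy PA of the MSD model).
#' @param seed integer seed.
#' @return Data frame of class `track_table`: `track`, `frame`, `x`, `y`.
#' @export
gen_brownian_tracks <- function(n_tracks, n_steps, step_sd,
                                frame_interval = 1, speed = 0,
                                loc_noise_sd = 0, seed = 1L) {
  stopifnot(n_tracks >= 1, all(n_steps >= 1), step_sd >= 0, speed >= 0,
            loc_noise_sd >= 0, frame_interval > 0)
  set.seed(seed)
  len <- rep_len(n_steps, n_tracks)
  out <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    n <- len[i] + 1L
    theta <- stats::runif(1, 0, 2 * pi)
    vx <- speed * cos(theta) * frame_interval
    vy <- speed * sin(theta) * frame_interval
    x <- cumsum(c(0, stats::rnorm(len[i], vx, step_sd)))
    y <- cumsum(c(0, stats::rnorm(len[i], vy, step_sd)))
    if (loc_noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, loc_noise_sd)
      y <- y + stats::rnorm(n, 0, loc_noise_sd)
    }
    out[[i]] <- data.frame(track = i, frame = seq_len(n), x = x, y = y)
  }
  out <- do.call(rbind, out)
  class(out) <- c("track_table", "data.frame")
  out
}
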