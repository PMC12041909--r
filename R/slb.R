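#' Localize single-molecule spots by Gaussian fitting
#'
#' Finds candidate local maxima above a count threshold in every frame and
#' refines each by least-squares fitting of an integrated 2D Gaussian
#' (pixel-integrated, matching how the spots are formed), yielding
#' sub-pixel position, integrated brightness, size (the Gaussian sigma in
#' pixels) and local background. Candidates closer than 1 px after
#' refinement are merged keeping the brighter. Saturated candidates (any
#' pixel at or above `saturation`) are flagged and not fitted; their count
#' is returned in the `n_saturated` attribute.
#'
#' @param stack single-channel [image_stack()] movie with calibration.
#' @param detection_threshold counts above the frame median a local maximum
#'   must reach to become a candidate.
#' @param frames frame indices to process (default all).
#' @param fit_halfwidth half width of the square fit window in px; the
#'   default 2 (a 5 x 5 window) suits sigma ~ 1 px spots and keeps
#'   neighbouring signals out of the window (the integrated model accounts
#'   for the window truncation).
#' @param saturation saturation level in counts.
#' @return Data frame (class `localization_table`): `frame`, `x`, `y` (um),
#'   `x_px`, `y_px` (pixel-edge units), `brightness` (integrated counts),
#'   `size` (sigma, px), `bg` (counts/px).
#' @export
localize_spots <- function(stack, detection_threshold, frames = NULL,
                           fit_halfwidth = 2L, saturation = Inf) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(frames)) frames <- seq_len(n_frames(stack))
  out <- vector("list", length(frames))
  n_sat <- 0L
  for (k in seq_along(frames)) {
    f <- frames[k]
    img <- get_frame(stack, f)
    cand <- local_maxima(img, stats::median(img) + detection_threshold)
    if (nrow(cand) == 0L) next
    rows <- vector("list", nrow(cand))
    for (s in seq_len(nrow(cand))) {
      fit <- fit_gaussian_spot(img, cand[s, 1L], cand[s, 2L],
                               fit_halfwidth, saturation)
      if (is.null(fit)) next
      if (identical(fit, "saturated")) { n_sat <- n_sat + 1L; next }
      rows[[s]] <- fit
    }
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (!length(rows)) next
    loc <- do.call(rbind, rows)
    loc <- merge_close_spots(loc, 1.0)
    out[[k]] <- data.frame(frame = f,
                           x = loc[, "x_px"] * stack$pixel_size,
                           y = loc[, "y_px"] * stack$pixel_size,
                           x_px = loc[, "x_px"], y_px = loc[, "y_px"],
                           brightness = loc[, "brightness"],
                           size = loc[, "size"], bg = loc[, "bg"])
  }
  out <- out[!vapply(out, is.null, TRUE)]
  locs <- if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
               x_px = numeric(0), y_px = numeric(0),
               brightness = numeric(0), size = numeric(0), bg = numeric(0))
  rownames(locs) <- NULL
  attr(locs, "n_saturated") <- n_sat
  class(locs) <- c("localization_table", "data.frame")
  locs
}

# 8-neighbour strict local maxima above an absolute threshold.
# Returns a 2-column matrix (row, col).
local_maxima <- function(img, threshold) {
  ny <- nrow(img); nx <- ncol(img)
  if (ny < 3L || nx < 3L) return(matrix(integer(0), 0, 2))
  core <- img[2:(ny - 1), 2:(nx - 1)]
  is_max <- core > threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- img[(2 + di):(ny - 1 + di), (2 + dj):(nx - 1 + dj)]
    is_max <- is_max & (core >= nb) & !(core == nb & (di < 0 | (di == 0 & dj < 0)))
  }
  w <- which(is_max, arr.ind = TRUE)
  w + 1L
}

# Integrated-Gaussian least-squares refinement of one candidate.
# Returns a named numeric vector, NULL if the fit is unusable, or the
# string "saturated".
fit_gaussian_spot <- function(img, row, col, hw, saturation) {
  ny <- nrow(img); nx <- ncol(img)
  r0 <- max(1L, row - hw); r1 <- min(ny, row + hw)
  c0 <- max(1L, col - hw); c1 <- min(nx, col + hw)
  win <- img[r0:r1, c0:c1]
  if (any(win >= saturation)) return("saturated")
  off0 <- min(win)
  mass0 <- sum(win - off0)
  if (mass0 <= 0) return(NULL)
  # pixel-edge coordinates of window pixels
  cols <- c0:c1; rows <- r0:r1
  npx <- length(win)
  # variable projection: for given (cx, cy, sigma) the best mass and offset
  # are a linear least-squares solve, so only 3 nonlinear parameters remain
  lin_solve <- function(p) {
    cx <- p[1]; cy <- p[2]; sg <- exp(p[3])
    mx <- stats::pnorm(cols, cx, sg) - stats::pnorm(cols - 1, cx, sg)
    my <- stats::pnorm(rows, cy, sg) - stats::pnorm(rows - 1, cy, sg)
    g <- as.numeric(my %*% t(mx))
    sg1 <- sum(g); sgg <- sum(g * g)
    det <- sgg * npx - sg1 * sg1
    if (det <= 0) return(NULL)
    sy <- sum(win); sgy <- sum(g * win)
    mass <- (sgy * npx - sg1 * sy) / det
    off <- (sy - mass * sg1) / npx
    list(g = g, mass = mass, off = off)
  }
  obj <- function(p) {
    ls <- lin_solve(p)
    if (is.null(ls)) return(sum((win - mean(win))^2))
    sum((as.numeric(win) - ls$off - ls$mass * ls$g)^2)
  }
  p0 <- c(col - 0.5, row - 0.5, 0)
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12))
  p <- opt$par
  sg <- exp(p[3])
  ls <- lin_solve(p)
  if (is.null(ls) || !is.finite(sg) || sg <= 0 ||
      sg > 2 * (2 * hw + 1) || ls$mass <= 0) return(NULL)
  # reject fits that wandered out of the window
  if (p[1] < c0 - 1.5 || p[1] > c1 + 0.5 ||
      p[2] < r0 - 1.5 || p[2] > r1 + 0.5) return(NULL)
  c(x_px = unname(p[1]), y_px = unname(p[2]), brightness = ls$mass,
    size = unname(sg), bg = ls$off)
}

merge_close_spots <- function(loc, min_dist_px) {
  if (nrow(loc) <= 1L) return(loc)
  ord <- order(loc[, "brightness"], decreasing = TRUE)
  loc <- loc[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(loc))
  for (i in seq_len(nrow(loc))) {
    if (!keep[i]) next
    if (i < nrow(loc)) {
      j <- (i + 1):nrow(loc)
      d <- sqrt((loc[j, "x_px"] - loc[i, "x_px"])^2 +
                (loc[j, "y_px"] - loc[i, "y_px"])^2)
      keep[j[d < min_dist_px]] <- FALSE
    }
  }
  loc[keep, , drop = FALSE]
}

#' Filter localizations by spot size and single-molecule density
#'
#' Applies the size filter (Gaussian sigma strictly inside `size_bounds`,
#' default 0.75--1.25 px) and determines the first frame at which the
#' per-frame localization density has dropped to or below
#' `density_threshold` (default 0.09 um^-2), the point from which spots are
#' well separated enough for single-molecule statistics. Frames before the
#' first qualifying frame are excluded from the returned table.
#'
#' @param locs a `localization_table`.
#' @param size_bounds exclusive sigma bounds in px.
#' @param density_threshold localization density threshold in um^-2.
#' @param field_area field of view area in um^2.
#' @param frames full frame range of the movie (default inferred from
#'   `locs`); frames without localizations count as zero density.
#' @return List with `locs` (size-filtered, from the first qualifying frame
#'   on), `first_qualifying_frame`, and `density_per_frame` (data frame
#'   `frame`, `density`).
#' @export
filter_spots <- function(locs, size_bounds = c(0.75, 1.25),
                         density_threshold = 0.09, field_area,
                         frames = NULL) {
  stopifnot(field_area > 0, length(size_bounds) == 2L)
  sized <- locs[locs$size > size_bounds[1] & locs$size < size_bounds[2], ,
                drop = FALSE]
  if (is.null(frames)) {
    if (nrow(locs) == 0L) stop("empty localization table and no frame range")
    frames <- seq(min(locs$frame), max(locs$frame))
  }
  counts <- vapply(frames, function(f) sum(sized$frame == f), 0)
  dens <- data.frame(frame = frames, density = counts / field_area)
  qual <- which(dens$density <= density_threshold)
  if (!length(qual))
    stop("density never below threshold (", density_threshold, " um^-2)")
  fqf <- frames[qual[1]]
  out <- sized[sized$frame >= fqf, , drop = FALSE]
  rownames(out) <- NULL
  list(locs = out, first_qualifying_frame = fqf, density_per_frame = dens)
}

#' Mean single-molecule brightness over a frame interval
#'
#' Mean integrated brightness of filtered localizations in the interval of
#' `interval` frames starting at the first qualifying frame, where
#' bleaching has separated the signals into individual molecules. Spots
#' with another localization closer than `isolation_radius` in the same
#' frame are excluded: a neighbour inside the fit window inflates the
#' fitted mass, which would bias the brightness reference of the density
#' estimate.
#'
#' @param locs filtered `localization_table`.
#' @param first_qualifying_frame interval start (frame index).
#' @param interval interval length in frames (default 10).
#' @param isolation_radius minimum same-frame neighbour distance in px
#'   (0, the default, disables the isolation filter).
#' @return Mean brightness in counts; number of molecules used is attached
#'   as attribute `n`.
#' @export
single_molecule_brightness <- function(locs, first_qualifying_frame,
                                       interval = 10L,
                                       isolation_radius = 0) {
  sel <- locs$frame >= first_qualifying_frame &
    locs$frame < first_qualifying_frame + interval
  if (!any(sel)) stop("no localizations in the brightness interval")
  sub <- locs[sel, , drop = FALSE]
  if (isolation_radius > 0 && nrow(sub) > 1L) {
    iso <- unlist(lapply(split(seq_len(nrow(sub)), sub$frame),
                         function(ix) {
      if (length(ix) == 1L) return(ix)
      d <- as.matrix(stats::dist(cbind(sub$x_px[ix], sub$y_px[ix])))
      diag(d) <- Inf
      ix[apply(d, 1, min) >= isolation_radius]
    }))
    if (length(iso)) sub <- sub[iso, , drop = FALSE]
  }
  out <- mean(sub$brightness)
  attr(out, "n") <- nrow(sub)
  out
}

#' Estimate molecule surface density by brightness normalization
#'
#' The density of labelled molecules on the bilayer is the
#' background-corrected mean brightness per square micrometre of the first
#' frame divided by the mean brightness of an individual molecule. This
#' works at densities far above the single-molecule regime because it only
#' needs total intensity, not resolvable spots.
#'
#' @param stack single-channel [image_stack()].
#' @param single_molecule_brightness counts per molecule (> 0).
#' @param background counts per pixel; if `NULL`, the median of `roi` when
#'   given, else the 1st percentile of the first frame.
#' @param frame frame to measure (default 1, before bleaching).
#' @param roi optional logical matrix marking a molecule-free region used
#'   for background estimation.
#' @return List of class `density_estimate`: `rho` (um^-2),
#'   `mean_brightness_per_um2`, `single_molecule_brightness`, `background`,
#'   `frame`.
#' @export
estimate_density <- function(stack, single_molecule_brightness,
                             background = NULL, frame = 1L, roi = NULL) {
  if (!is.finite(single_molecule_brightness) ||
      single_molecule_brightness <= 0)
    stop("single_molecule_brightness must be positive")
  img <- get_frame(stack, frame)
  if (is.null(background)) {
    background <- if (!is.null(roi)) stats::median(img[roi])
                  else stats::quantile(img, 0.01, names = FALSE)
  }
  mb <- mean(img - background) / stack$pixel_size^2
  if (mb < 0) {
    warning("negative background-corrected brightness clipped at 0")
    mb <- 0
  }
  structure(list(rho = mb / single_molecule_brightness,
                 mean_brightness_per_um2 = mb,
                 single_molecule_brightness = single_molecule_brightness,
                 background = background, frame = frame),
            class = "density_estimate")
}

#' Link localizations into trajectories
#'
#' Frame-to-frame assignment between consecutive frames: candidate pairs
#' within `search_radius` (px) are assigned in order of increasing
#' displacement (each localization used once), unmatched localizations
#' start new tracks. No gap closing.
#'
#' @param locs filtered `localization_table` with `x_px`, `y_px` columns.
#' @param search_radius maximum frame-to-frame displacement in px
#'   (default 6).
#' @return Data frame (class `track_table`): `track`, `frame`, `x`, `y`
#'   (um), `x_px`, `y_px`.
#' @export
link_molecules <- function(locs, search_radius = 6) {
  cols <- c("track", "frame", "x", "y", "x_px", "y_px")
  if (nrow(locs) == 0L) {
    out <- data.frame(track = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0), x_px = numeric(0),
                      y_px = numeric(0))
    class(out) <- c("track_table", "data.frame")
    return(out)
  }
  locs <- locs[order(locs$frame), , drop = FALSE]
  frames <- sort(unique(locs$frame))
  idx <- split(seq_len(nrow(locs)), locs$frame)
  track_id <- integer(nrow(locs))
  next_id <- 1L
  first <- idx[[as.character(frames[1])]]
  track_id[first] <- seq_len(length(first))
  next_id <- length(first) + 1L
  for (k in seq_along(frames)[-1]) {
    cur <- idx[[as.character(frames[k])]]
    prev <- if (frames[k] - frames[k - 1] == 1L)
      idx[[as.character(frames[k - 1])]] else integer(0)
    assigned_prev <- logical(length(prev))
    assigned_cur <- logical(length(cur))
    if (length(prev) && length(cur)) {
      d <- outer(locs$x_px[prev], locs$x_px[cur], `-`)^2 +
           outer(locs$y_px[prev], locs$y_px[cur], `-`)^2
      cand <- which(d <= search_radius^2, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1L]; j <- cand[r, 2L]
          if (!assigned_prev[i] && !assigned_cur[j]) {
            track_id[cur[j]] <- track_id[prev[i]]
            assigned_prev[i] <- TRUE; assigned_cur[j] <- TRUE
          }
        }
      }
    }
    for (j in which(!assigned_cur)) {
      track_id[cur[j]] <- next_id
      next_id <- next_id + 1L
    }
  }
  out <- data.frame(track = track_id, frame = locs$frame,
                    x = locs$x, y = locs$y,
                    x_px = locs$x_px, y_px = locs$y_px)
  out <- out[order(out$track, out$frame), cols]
  rownames(out) <- NULL
  class(out) <- c("track_table", "data.frame")
  out
}

#' Molecular diffusion and mobile fraction from trajectories
#'
#' Ensemble mean squared displacement over all trajectories with at least
#' `min_steps` steps, and the diffusion coefficient from a weighted linear
#' fit `MSD(t) = 4 D t + c` over the first `n_fit_lags` lag times (weights
#' proportional to the number of contributing displacement pairs; the
#' intercept c absorbs localization error and is constrained
#' non-negative). The mobile fraction is the fraction of retained tracks
#' whose individual diffusion coefficient exceeds `immobile_cutoff`.
#'
#' @param tracks a `track_table` (x, y in um).
#' @param min_steps minimum number of steps per retained track (default 5).
#' @param frame_interval frame interval in seconds.
#' @param max_lag largest lag (frames) in the reported MSD curve.
#' @param n_fit_lags number of lags used in the D fit (default 5).
#' @param immobile_cutoff per-track D below which a track counts as
#'   immobile, um^2/s.
#' @return List of class `molecule_mobility`: `D` (um^2/s),
#'   `mobile_fraction`, `n_tracks`, `msd` (data frame `lag_s`, `msd`,
#'   `n_pairs`), `intercept`, `low_sample` flag.
#' @export
molecule_diffusion <- function(tracks, min_steps = 5L, frame_interval,
                               max_lag = 10L, n_fit_lags = 5L,
                               immobile_cutoff = 0.01) {
  stopifnot(frame_interval > 0)
  comp <- msd_components(tracks, max_lag)
  len <- comp$n_points
  keep <- len >= min_steps + 1L
  if (!any(keep)) stop("no tracks with at least ", min_steps, " steps")
  ss <- comp$ss[keep, , drop = FALSE]
  np <- comp$n_pairs[keep, , drop = FALSE]
  n_tracks <- sum(keep)
  low_sample <- n_tracks < 10L
  if (low_sample) warning("fewer than 10 retained tracks")
  tot_n <- colSums(np)
  lags <- which(tot_n > 0)
  msd <- colSums(ss)[lags] / tot_n[lags]
  t_lag <- lags * frame_interval
  nf <- min(n_fit_lags, length(lags))
  A <- cbind(4 * t_lag[seq_len(nf)], 1)
  w <- sqrt(tot_n[lags][seq_len(nf)])
  fit <- pracma::lsqnonneg(A * w, msd[seq_len(nf)] * w)
  # per-track D for the mobile fraction: slope of the track's own MSD
  d_track <- vapply(seq_len(n_tracks), function(i) {
    li <- which(np[i, ] > 0)
    li <- li[seq_len(min(n_fit_lags, length(li)))]
    m <- ss[i, li] / np[i, li]
    tt <- li * frame_interval
    if (length(li) < 2L) return(m[1] / (4 * tt[1]))
    stats::coef(stats::lm(m ~ tt))[2] / 4
  }, 0)
  structure(list(D = fit$x[1], intercept = fit$x[2],
                 mobile_fraction = mean(d_track > immobile_cutoff),
                 n_tracks = n_tracks,
                 msd = data.frame(lag_s = t_lag, msd = msd,
                                  n_pairs = tot_n[lags]),
                 low_sample = low_sample),
            class = "molecule_mobility")
}

#' Average density estimates over image series of one SLB
#'
#' Each bilayer is typically imaged as several series; the per-SLB antigen
#' density is the mean of the per-series estimates.
#'
#' @param estimates list of `density_estimate` objects.
#' @return Mean density in um^-2.
#' @export
average_density <- function(estimates) {
  mean(vapply(estimates, function(e) e$rho, 0))
}
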