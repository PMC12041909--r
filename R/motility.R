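# Per-track sums of squared displacements by lag (overlapping pairs).
# Returns ss and n_pairs matrices [track, lag] plus per-track point counts,
# so pooled MSDs and bootstrap re-pooling are cheap re-aggregations.
msd_components <- function(tracks, max_lag) {
  ids <- unique(tracks$track)
  ss <- matrix(0, length(ids), max_lag)
  np <- matrix(0L, length(ids), max_lag)
  n_points <- integer(length(ids))
  by_id <- split(tracks[c("frame", "x", "y")], tracks$track)
  by_id <- by_id[as.character(ids)]
  for (i in seq_along(ids)) {
    tr <- by_id[[i]]
    ord <- order(tr$frame)
    x <- tr$x[ord]; y <- tr$y[ord]
    n <- length(x)
    n_points[i] <- n
    for (lag in seq_len(min(n - 1L, max_lag))) {
      dx <- x[(1 + lag):n] - x[1:(n - lag)]
      dy <- y[(1 + lag):n] - y[1:(n - lag)]
      ss[i, lag] <- sum(dx * dx + dy * dy)
      np[i, lag] <- n - lag
    }
  }
  list(ids = ids, ss = ss, n_pairs = np, n_points = n_points)
}

#' Pooled mean squared displacement
#'
#' Pools all trajectories of a condition into one ensemble MSD curve:
#' `MSD(lag)` is the mean over all tracks and all start frames (overlapping
#' pairs) of the squared displacement at that lag.
#'
#' @param tracks a `track_table` (columns `track`, `frame`, `x`, `y`; x, y
#'   in um).
#' @param max_lag largest lag in frames; truncated with a warning if no
#'   track is long enough to reach it.
#' @param frame_interval frame interval in seconds.
#' @return Data frame of class `msd_curve`: `lag_s`, `msd` (um^2),
#'   `n_pairs`.
#' @export
pooled_msd <- function(tracks, max_lag, frame_interval) {
  stopifnot(nrow(tracks) > 0, frame_interval > 0, max_lag >= 1)
  comp <- msd_components(tracks, max_lag)
  tot_n <- colSums(comp$n_pairs)
  if (any(tot_n == 0)) {
    warning("max_lag exceeds the longest track; curve truncated")
  }
  lags <- which(tot_n > 0)
  if (!length(lags)) stop("no displacement pairs (all tracks length 1)")
  out <- data.frame(lag_s = lags * frame_interval,
                    msd = colSums(comp$ss)[lags] / tot_n[lags],
                    n_pairs = tot_n[lags])
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit the diffusion-plus-directed-motion MSD model
#'
#' Weighted least-squares fit of `MSD(t) = 4 D t + V^2 t^2 + 4 PA^2`, where
#' D is the diffusion coefficient, V the global movement speed and PA the
#' positional accuracy. The model is linear in (D, V^2, PA^2), which are
#' constrained non-negative; weights are proportional to the number of
#' contributing displacement pairs per lag.
#'
#' @param msd an `msd_curve` with at least 3 lags.
#' @return List of class `motility_fit`: `D` (um^2/s), `V` (um/s), `PA`
#'   (um), `residual` (root weighted mean squared residual), `n_lags`.
#' @export
fit_motility <- function(msd) {
  if (nrow(msd) < 3L) stop("need at least 3 lags to fit the MSD model")
  if (length(unique(msd$lag_s)) < 3L)
    stop("singular design: fewer than 3 distinct lags")
  t <- msd$lag_s
  A <- cbind(4 * t, t^2, 4)
  w <- sqrt(msd$n_pairs / sum(msd$n_pairs))
  fit <- pracma::lsqnonneg(A * w, msd$msd * w)
  res <- (A %*% fit$x - msd$msd) * w
  structure(list(D = fit$x[1], V = sqrt(fit$x[2]), PA = sqrt(fit$x[3]),
                 residual = sqrt(mean(res^2)), n_lags = nrow(msd)),
            class = "motility_fit")
}

#' @export
print.motility_fit <- function(x, ...) {
  cat(sprintf("MSD fit: D = %.4g um^2/s, V = %.4g um/s, PA = %.4g um (%d lags)\n",
              x$D, x$V, x$PA, x$n_lags))
  invisible(x)
}

#' Bootstrap uncertainties for the motility fit
#'
#' Resamples whole trajectories with replacement, re-pools the MSD and
#' refits the diffusion-plus-drift model; reports the standard deviation of
#' each parameter over replicates. Deterministic for a given seed.
#'
#' @param tracks a `track_table`.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param max_lag largest lag in frames for the pooled curve.
#' @param frame_interval frame interval in seconds.
#' @return List: `sd_D`, `sd_V`, `sd_PA`, `n_boot`, `low_sample` flag
#'   (fewer than 5 tracks), and `replicates` (n_boot x 3 matrix).
#' @export
bootstrap_fit <- function(tracks, n_boot = 1000L, seed = 1L, max_lag,
                          frame_interval) {
  set.seed(seed)
  comp <- msd_components(tracks, max_lag)
  n <- length(comp$ids)
  low_sample <- n < 5L
  if (low_sample) warning("fewer than 5 tracks for bootstrapping")
  reps <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, c("D", "V", "PA")))
  for (b in seq_len(n_boot)) {
    pick <- sample.int(n, n, replace = TRUE)
    tot_n <- colSums(comp$n_pairs[pick, , drop = FALSE])
    lags <- which(tot_n > 0)
    if (length(lags) < 3L) next
    msd <- data.frame(
      lag_s = lags * frame_interval,
      msd = colSums(comp$ss[pick, , drop = FALSE])[lags] / tot_n[lags],
      n_pairs = tot_n[lags])
    fit <- fit_motility(msd)
    reps[b, ] <- c(fit$D, fit$V, fit$PA)
  }
  list(sd_D = stats::sd(reps[, 1], na.rm = TRUE),
       sd_V = stats::sd(reps[, 2], na.rm = TRUE),
       sd_PA = stats::sd(reps[, 3], na.rm = TRUE),
       n_boot = n_boot, low_sample = low_sample, replicates = reps)
}

#' Per-cell local velocity and directional persistence
#'
#' Average local velocity: frame-to-frame speeds smoothed with a centred
#' sliding window, then averaged over the track, reported in um/min.
#' Directional persistence: net displacement divided by total path length
#' (1 for a straight track, 0 in the limit of a closed path); defined as 0
#' for a track of zero path length.
#'
#' @param track data frame for a single cell (`frame`, `x`, `y` in um).
#' @param window sliding-window width in frames (>= 1).
#' @param frame_interval frame interval in seconds.
#' @return List of class `cell_kinematics`: `velocity` (um/min),
#'   `persistence` (in `[0, 1]`), `n_steps`.
#' @export
cell_kinematics <- function(track, window = 3L, frame_interval) {
  ord <- order(track$frame)
  x <- track$x[ord]; y <- track$y[ord]
  n <- length(x)
  if (n < 2L) stop("track must have at least 2 points")
  if (window < 1L || window > n - 1L)
    stop("window must lie between 1 and the number of steps")
  steps <- sqrt(diff(x)^2 + diff(y)^2)
  speeds <- steps / frame_interval                   # um/s
  sm <- as.numeric(stats::filter(speeds, rep(1 / window, window),
                                 sides = 2))
  vel <- mean(sm, na.rm = TRUE) * 60
  path <- sum(steps)
  net <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  persistence <- if (path > 0) net / path else 0
  structure(list(velocity = vel, persistence = persistence,
                 n_steps = n - 1L),
            class = "cell_kinematics")
}
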