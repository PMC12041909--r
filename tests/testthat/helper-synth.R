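# Build a set of well-separated synthetic cells on a jittered grid for the
# Fura-2 phantoms: returns the `cells` list gen_fura_stack() expects.
make_grid_cells <- function(n, n_frames, field, area, ratio,
                            jitter_um = 0, seed = 1) {
  set.seed(seed)
  per_side <- ceiling(sqrt(n))
  pitch <- field / (per_side + 1)
  centers <- expand.grid(ix = seq_len(per_side), iy = seq_len(per_side))
  centers <- centers[seq_len(n), ]
  lapply(seq_len(n), function(i) {
    x0 <- centers$ix[i] * pitch + stats::runif(1, -jitter_um, jitter_um)
    y0 <- centers$iy[i] * pitch + stats::runif(1, -jitter_um, jitter_um)
    list(traj = data.frame(frame = seq_len(n_frames), x = x0, y = y0),
         area = rep_len(area, n_frames),
         ratio = rep_len(ratio, n_frames))
  })
}

# Render one integrated-Gaussian spot into a zero matrix, written out
# independently of the package's renderer (pixel i integrates the normal
# density over [i-1, i] in pixel-edge units).
oracle_spot_frame <- function(ny, nx, cx_px, cy_px, sigma, mass) {
  mx <- stats::pnorm(seq_len(nx), cx_px, sigma) -
    stats::pnorm(seq_len(nx) - 1, cx_px, sigma)
  my <- stats::pnorm(seq_len(ny), cy_px, sigma) -
    stats::pnorm(seq_len(ny) - 1, cy_px, sigma)
  mass * (my %*% t(mx))
}
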