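#' Cell height from a membrane-stained z-stack
#'
#' Extracts the axial intensity profile through the cell centroid and
#' estimates the confinement height as the distance between the two
#' outermost local maxima (the top and bottom plasma membranes), each
#' refined by 3-point parabolic interpolation for sub-z-step precision.
#' When the maxima have merged into a single peak the full width at half
#' maximum of the envelope is used instead; a single peak narrower than two
#' z-steps is unresolvable.
#'
#' @param stack z-calibrated [image_stack()] (slice i at
#'   `z = (i - 1) * z_step`).
#' @param peak_floor fraction of the profile maximum below which local
#'   maxima are ignored (suppresses ripple from the lateral shell).
#' @return List of class `height_estimate`: `height` (um), `method`
#'   ("peak-to-peak" or "fwhm"), `z_step`, `uncertainty` (um, at least half
#'   a z-step), `profile` (data frame `z`, `intensity`).
#' @export
cell_height_from_zstack <- function(stack, peak_floor = 0.3) {
  stopifnot(inherits(stack, "image_stack"), is.finite(stack$z_step),
            stack$z_step > 0)
  nz <- n_frames(stack)
  proj <- apply(stack$data, c(1, 2), max)
  tot <- sum(proj)
  if (tot <= 0) stop("empty stack")
  ci <- round(sum(row(proj) * proj) / tot)
  cj <- round(sum(col(proj) * proj) / tot)
  ri <- max(1, ci - 1):min(nrow(proj), ci + 1)
  rj <- max(1, cj - 1):min(ncol(proj), cj + 1)
  prof <- vapply(seq_len(nz), function(k)
    mean(stack$data[ri, rj, k]), 0)
  zs <- (seq_len(nz) - 1) * stack$z_step

  floor_level <- peak_floor * max(prof)
  peaks <- which(diff(sign(diff(prof))) < 0) + 1L
  peaks <- peaks[prof[peaks] > floor_level]
  refine <- function(i) {
    if (i <= 1L || i >= nz) return(zs[i])
    y0 <- prof[i - 1]; y1 <- prof[i]; y2 <- prof[i + 1]
    den <- y0 - 2 * y1 + y2
    off <- if (den != 0) 0.5 * (y0 - y2) / den else 0
    zs[i] + off * stack$z_step
  }
  if (length(peaks) >= 2L) {
    z_lo <- refine(peaks[1]); z_hi <- refine(peaks[length(peaks)])
    h <- z_hi - z_lo
    method <- "peak-to-peak"
  } else if (length(peaks) == 1L) {
    half <- max(prof) / 2
    above <- which(prof >= half)
    cross <- function(i0, i1) {
      # linear interpolation of the half-max crossing between slices
      zs[i0] + (half - prof[i0]) / (prof[i1] - prof[i0]) * (zs[i1] - zs[i0])
    }
    lo <- above[1]; hi <- above[length(above)]
    z_lo <- if (lo > 1L) cross(lo - 1L, lo) else zs[lo]
    z_hi <- if (hi < nz) cross(hi + 1L, hi) else zs[hi]
    h <- z_hi - z_lo
    method <- "fwhm"
    if (h < 2 * stack$z_step)
      stop("unresolvable height: single peak narrower than 2 z-steps")
  } else stop("no axial intensity peak found")
  structure(list(height = h, method = method, z_step = stack$z_step,
                 uncertainty = max(stack$z_step / 2, 0),
                 profile = data.frame(z = zs, intensity = prof)),
            class = "height_estimate")
}

#' Fit a membrane deflection profile with an even polynomial
#'
#' Least-squares fit of the radial deflection profile with a polynomial of
#' even powers only (the profile is symmetric about the apex), default
#' order 12. Positions are rescaled to the profile half-width internally
#' for numerical conditioning. Rank-deficient designs are refitted at a
#' reduced order with a warning.
#'
#' @param profile data frame with `x_mm` (lateral position, centred at the
#'   apex) and `z_um` (height).
#' @param order even polynomial order, at most 12.
#' @return List of class `profile_fit`: `coef` (powers 0, 2, ... of
#'   `x / scale`), `scale` (mm), `apex` (um), `order`, `fun(x)` and
#'   `deriv(x)` evaluating height (um) and slope (um/mm) at `x` (mm).
#' @export
fit_profile <- function(profile, order = 12L) {
  stopifnot(order %% 2 == 0, order >= 2, order <= 12)
  x <- profile$x_mm; z <- profile$z_um
  if (length(x) < order + 1)
    stop("need at least order + 1 samples")
  scale <- max(abs(x))
  if (scale == 0) stop("degenerate profile: all positions identical")
  u <- x / scale
  repeat {
    powers <- seq(0, order, by = 2)
    X <- outer(u, powers, `^`)
    fit <- stats::lm.fit(X, z)
    if (fit$rank == ncol(X)) break
    order <- order - 2L
    warning("rank-deficient design; order reduced to ", order)
    if (order < 2L) stop("profile cannot support even a quadratic fit")
  }
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  f <- function(xx) eval_even_poly(cf, xx / scale)
  df <- function(xx) {
    uu <- xx / scale
    d <- 0
    for (k in seq_along(cf)[-1])
      d <- d + cf[k] * (2 * (k - 1)) * uu^(2 * (k - 1) - 1)
    d / scale
  }
  structure(list(coef = unname(cf), scale = scale, apex = unname(cf[1]),
                 order = order, fun = f, deriv = df),
            class = "profile_fit")
}

#' Arc-length engineering strain of a deflected membrane
#'
#' The membrane starts flat; under pressure its radial section becomes the
#' fitted profile. The engineering strain is
#' `(arc length - chord) / chord` over `[-a, a]`, with the arc length
#' computed by adaptive quadrature of `sqrt(1 + z'(x)^2)` to 1e-9 relative
#' tolerance.
#'
#' @param fit a `profile_fit` (or any list with a `deriv(x)` element).
#' @param a half width in mm (> 0).
#' @param z_scale factor converting the profile's height unit to the
#'   lateral unit (default `1e-3`: heights in um, positions in mm).
#' @return List: `strain` (dimensionless), `arc_length` and `chord` in mm.
#' @export
arc_strain <- function(fit, a, z_scale = 1e-3) {
  if (!is.numeric(a) || a <= 0) stop("half width a must be positive")
  integrand <- function(x) sqrt(1 + (fit$deriv(x) * z_scale)^2)
  L <- stats::integrate(integrand, -a, a, rel.tol = 1e-9,
                        subdivisions = 500L)$value
  list(strain = (L - 2 * a) / (2 * a), arc_length = L, chord = 2 * a)
}

#' Deflection-pressure linearity and gap-height resolution
#'
#' Ordinary least-squares line through (pressure, apex height). The
#' gap-height resolution is the slope times the pressure-controller step
#' (0.1 mbar): the smallest achievable change of the confinement gap.
#'
#' @param pressures pressures in mbar (at least 2 distinct).
#' @param apex_heights maximum deflections in um.
#' @param controller_step pressure controller resolution in mbar.
#' @return List of class `pressure_fit`: `slope` (um/mbar), `intercept`
#'   (um), `resolution` (um per controller step), `r_squared`.
#' @export
pressure_linearity <- function(pressures, apex_heights,
                               controller_step = 0.1) {
  if (length(unique(pressures)) < 2L)
    stop("need at least two distinct pressures")
  fit <- stats::lm(apex_heights ~ pressures)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((apex_heights - mean(apex_heights))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 resolution = unname(stats::coef(fit)[2]) * controller_step,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1),
            class = "pressure_fit")
}

#' Expected confinement gap from levelled topography
#'
#' Levels a topography map so the designated reference region (the actuator
#' surface that contacts the carrier) has zero mean height, then reports
#' the gap between a reference plane at `offset` and the levelled surface
#' inside the confining disc footprint, together with the coplanarity
#' (max - min gap across the footprint).
#'
#' @param height_map numeric matrix of surface heights (um).
#' @param ref_mask logical matrix: the reference (levelling) region.
#' @param footprint_mask logical matrix: the confining disc footprint.
#' @param offset height of the opposing surface above the reference plane
#'   (um).
#' @return List: `gap_map` (um, `NA` outside the footprint), `min_gap`,
#'   `max_gap`, `mean_gap`, `coplanarity`.
#' @export
expected_gap <- function(height_map, ref_mask, footprint_mask, offset) {
  if (!any(ref_mask)) stop("reference region is empty")
  if (!any(footprint_mask)) stop("footprint region is empty")
  levelled <- height_map - mean(height_map[ref_mask])
  gap <- offset - levelled
  vals <- gap[footprint_mask]
  gm <- matrix(NA_real_, nrow(height_map), ncol(height_map))
  gm[footprint_mask] <- gap[footprint_mask]
  list(gap_map = gm, min_gap = min(vals), max_gap = max(vals),
       mean_gap = mean(vals), coplanarity = max(vals) - min(vals))
}
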