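#' Build Fura-2 sum and ratio stacks
#'
#' The sum stack (`I340 + I380`) carries total dye signal and is what cells
#' are segmented and tracked on; the ratio stack
#' `(I340 - B340) / (I380 - B380)` is the calcium readout. Pixels whose
#' background-corrected denominator is not strictly positive are masked
#' invalid rather than producing infinities.
#'
#' @param stack340,stack380 single-channel [image_stack()]s of the 340 nm
#'   and 380 nm excitation emissions, co-registered and of equal shape.
#'   Alternatively `stack340` may be a two-channel stack with channels
#'   "340" and "380" and `stack380` omitted.
#' @param B340,B380 per-channel constant backgrounds in counts.
#' @return List of class `ratio_stacks`: `sum` and `ratio` arrays
#'   `[y, x, frame]` (ratio is `NA` where invalid), `valid` logical array,
#'   `pixel_size`, `frame_interval`.
#' @export
make_sum_ratio <- function(stack340, stack380 = NULL, B340, B380) {
  if (is.null(stack380)) {
    a340 <- stack340$data[, , , match("340", stack340$channels)]
    a380 <- stack340$data[, , , match("380", stack340$channels)]
    ps <- stack340$pixel_size; fi <- stack340$frame_interval
  } else {
    if (!identical(dim(stack340$data), dim(stack380$data)))
      stop("channel stacks have different shapes")
    a340 <- stack340$data; a380 <- stack380$data
    ps <- stack340$pixel_size; fi <- stack340$frame_interval
  }
  if (length(dim(a340)) == 2L) {
    a340 <- array(a340, c(dim(a340), 1L))
    a380 <- array(a380, c(dim(a380), 1L))
  }
  den <- a380 - B380
  valid <- den > 0
  ratio <- array(NA_real_, dim(a340))
  ratio[valid] <- (a340[valid] - B340) / den[valid]
  structure(list(sum = a340 + a380, ratio = ratio, valid = valid,
                 pixel_size = ps, frame_interval = fi),
            class = "ratio_stacks")
}

#' Segment cells in a single frame
#'
#' Standard fluorescence-footprint segmentation: Gaussian smoothing, global
#' Otsu threshold, hole filling, watershed split on the distance-transform
#' maxima, and removal of objects below `min_area`. Labels are consecutive
#' positive integers.
#'
#' @param frame numeric matrix (one frame, e.g. of the Fura-2 sum stack).
#' @param pixel_size um/px.
#' @param min_area smallest retained object, um^2 (default 20).
#' @param smooth_sigma Gaussian smoothing sigma in px (default 1).
#' @param watershed_tolerance minimum distance-map depth separating two
#'   objects (px).
#' @return Integer label matrix (0 = background).
#' @export
segment_cells <- function(frame, pixel_size, min_area = 20,
                          smooth_sigma = 1, watershed_tolerance = 1) {
  rng <- range(frame)
  if (diff(rng) == 0) return(matrix(0L, nrow(frame), ncol(frame)))
  norm <- (frame - rng[1]) / diff(rng)
  sm <- EBImage::gblur(norm, sigma = smooth_sigma)
  sm <- pmin(pmax(sm, 0), 1)
  th <- EBImage::otsu(EBImage::Image(sm))
  bw <- sm > th
  bw <- EBImage::fillHull(EBImage::Image(bw)) > 0
  if (!any(bw)) return(matrix(0L, nrow(frame), ncol(frame)))
  dm <- EBImage::distmap(EBImage::Image(bw))
  lab <- EBImage::imageData(EBImage::watershed(dm,
                                               tolerance = watershed_tolerance))
  min_px <- min_area / pixel_size^2
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts >= min_px)
  out <- matrix(0L, nrow(frame), ncol(frame))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

# Per-label centroid (um), area (um^2) and border contact for one mask.
label_properties <- function(mask, pixel_size) {
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs))
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0), border = logical(0)))
  ny <- nrow(mask); nx <- ncol(mask)
  res <- lapply(labs, function(l) {
    w <- which(mask == l, arr.ind = TRUE)
    data.frame(label = l,
               x = (mean(w[, 2]) - 0.5) * pixel_size,
               y = (mean(w[, 1]) - 0.5) * pixel_size,
               area = nrow(w) * pixel_size^2,
               border = any(w[, 1] %in% c(1L, ny) | w[, 2] %in% c(1L, nx)))
  })
  do.call(rbind, res)
}

#' Segment and track cells through a Fura-2 recording
#'
#' Segments every frame of the sum stack, links cell identities between
#' consecutive frames by greedy nearest-centroid matching up to
#' `max_displacement`, and emits per cell and frame the sectional cell area
#' (segmented footprint times pixel area) and the Ca2+ ratio (mean of the
#' ratio stack over the cell's valid segmented pixels). Cells touching the
#' image border are flagged: their sectional area is censored by the field
#' edge.
#'
#' @param ratio a `ratio_stacks` object from [make_sum_ratio()].
#' @param max_displacement largest frame-to-frame centroid displacement for
#'   identity linking, um (default 15).
#' @param min_area,smooth_sigma,watershed_tolerance passed to
#'   [segment_cells()].
#' @return Data frame of class `cell_time_series`: `cell`, `frame`, `x`,
#'   `y` (um), `area` (um^2), `ratio`, `border`.
#' @export
track_cells <- function(ratio, max_displacement = 15, min_area = 20,
                        smooth_sigma = 1, watershed_tolerance = 1) {
  stopifnot(inherits(ratio, "ratio_stacks"))
  nf <- dim(ratio$sum)[3]
  ps <- ratio$pixel_size
  rows <- list(); prev <- NULL; next_id <- 1L
  for (f in seq_len(nf)) {
    mask <- segment_cells(ratio$sum[, , f], ps, min_area = min_area,
                          smooth_sigma = smooth_sigma,
                          watershed_tolerance = watershed_tolerance)
    props <- label_properties(mask, ps)
    if (nrow(props) == 0L) { prev <- NULL; next }
    props$cell <- NA_integer_
    if (!is.null(prev) && nrow(prev)) {
      d <- sqrt(outer(prev$x, props$x, `-`)^2 +
                outer(prev$y, props$y, `-`)^2)
      cand <- which(d <= max_displacement, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        used_p <- logical(nrow(prev)); used_c <- logical(nrow(props))
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1L]; j <- cand[r, 2L]
          if (!used_p[i] && !used_c[j]) {
            props$cell[j] <- prev$cell[i]
            used_p[i] <- TRUE; used_c[j] <- TRUE
          }
        }
      }
    }
    for (j in which(is.na(props$cell))) {
      props$cell[j] <- next_id; next_id <- next_id + 1L
    }
    rfr <- ratio$ratio[, , f]; vfr <- ratio$valid[, , f]
    props$ratio <- vapply(props$label, function(l) {
      px <- mask == l & vfr
      if (any(px)) mean(rfr[px]) else NA_real_
    }, 0)
    props$frame <- f
    rows[[f]] <- props[c("cell", "frame", "x", "y", "area", "ratio",
                         "border")]
    prev <- props
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = integer(0), frame = integer(0), x = numeric(0),
               y = numeric(0), area = numeric(0), ratio = numeric(0),
               border = logical(0))
  out <- out[order(out$cell, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("cell_time_series", "data.frame")
  out
}

#' Join pre- and post-confinement recordings
#'
#' A confinement experiment consists of two recordings of the same field
#' separated by the actuator-application gap. Cells are matched across the
#' gap by centroid proximity (last pre-confinement position vs first
#' post-confinement position, greedy by distance, ties broken by lower cell
#' id); matched cells keep their pre-recording id, unmatched cells are
#' retained and flagged. Post-recording frames are renumbered to continue
#' the pre recording, and the join index (first post frame) is attached.
#'
#' @param pre,post `cell_time_series` from the two recordings.
#' @param match_limit largest centroid displacement across the gap, um
#'   (default 25).
#' @return A `cell_time_series` with extra columns `recording`
#'   ("pre"/"post") and `matched`, and attribute `join_index`.
#' @export
join_recordings <- function(pre, post, match_limit = 25) {
  join_index <- if (nrow(pre)) max(pre$frame) + 1L else 1L
  pre$recording <- "pre"; pre$matched <- TRUE
  last_pre <- do.call(rbind, lapply(split(pre, pre$cell), function(d)
    d[which.max(d$frame), ]))
  first_post <- do.call(rbind, lapply(split(post, post$cell), function(d)
    d[which.min(d$frame), ]))
  map <- rep(NA_integer_, if (nrow(post)) max(post$cell) else 0L)
  if (!is.null(last_pre) && !is.null(first_post) &&
      nrow(last_pre) && nrow(first_post)) {
    last_pre <- last_pre[order(last_pre$cell), ]
    first_post <- first_post[order(first_post$cell), ]
    d <- sqrt(outer(last_pre$x, first_post$x, `-`)^2 +
              outer(last_pre$y, first_post$y, `-`)^2)
    cand <- which(d <= match_limit, arr.ind = TRUE)
    if (nrow(cand)) {
      # ascending distance; ties broken by lower pre then post cell id
      cand <- cand[order(d[cand], last_pre$cell[cand[, 1]],
                         first_post$cell[cand[, 2]]), , drop = FALSE]
      used_a <- logical(nrow(last_pre)); used_b <- logical(nrow(first_post))
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1L]; j <- cand[r, 2L]
        if (!used_a[i] && !used_b[j]) {
          map[first_post$cell[j]] <- last_pre$cell[i]
          used_a[i] <- TRUE; used_b[j] <- TRUE
        }
      }
    }
  }
  next_id <- if (nrow(pre)) max(pre$cell) + 1L else 1L
  post$matched <- !is.na(map[post$cell])
  new_ids <- map
  for (cid in unique(post$cell)) if (is.na(new_ids[cid])) {
    new_ids[cid] <- next_id; next_id <- next_id + 1L
  }
  post$cell <- new_ids[post$cell]
  post$frame <- post$frame - min(post$frame) + join_index
  post$recording <- "post"
  out <- rbind(pre, post)
  out <- out[order(out$cell, out$frame), ]
  rownames(out) <- NULL
  attr(out, "join_index") <- join_index
  class(out) <- c("cell_time_series", "data.frame")
  out
}

#' Pre/post-confinement window means per cell
#'
#' Compares each cell's mean sectional area and Ca2+ ratio between a
#' pre-confinement and a post-confinement frame window. Cells absent from
#' either window are excluded and counted in the `n_excluded` attribute.
#'
#' @param series a `cell_time_series` (typically joined).
#' @param pre_window,post_window `c(first_frame, last_frame)`, inclusive and
#'   non-overlapping; the pre window must end before the post window starts.
#' @return Data frame: `cell`, `area_pre`, `area_post`, `ratio_pre`,
#'   `ratio_post`, with attribute `n_excluded`.
#' @export
window_means <- function(series, pre_window, post_window) {
  stopifnot(length(pre_window) == 2L, length(post_window) == 2L)
  if (pre_window[2] >= post_window[1])
    stop("windows must be non-overlapping with pre before post")
  in_win <- function(f, w) f >= w[1] & f <= w[2]
  if (!any(in_win(series$frame, pre_window)))
    stop("pre window contains no observations")
  if (!any(in_win(series$frame, post_window)))
    stop("post window contains no observations")
  res <- lapply(split(series, series$cell), function(d) {
    a <- d[in_win(d$frame, pre_window), ]
    b <- d[in_win(d$frame, post_window), ]
    if (nrow(a) == 0L || nrow(b) == 0L) return(NULL)
    data.frame(cell = d$cell[1],
               area_pre = mean(a$area), area_post = mean(b$area),
               ratio_pre = mean(a$ratio, na.rm = TRUE),
               ratio_post = mean(b$ratio, na.rm = TRUE))
  })
  excluded <- sum(vapply(res, is.null, TRUE))
  res <- res[!vapply(res, is.null, TRUE)]
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(cell = integer(0), area_pre = numeric(0),
               area_post = numeric(0), ratio_pre = numeric(0),
               ratio_post = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  out
}
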