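#' Calibrated image stack
#'
#' The common container for all pixel data in the pipeline: a numeric array
#' indexed `[y, x, frame]` (single channel) or `[y, x, frame, channel]`
#' (multi-channel), together with the physical calibration that every
#' downstream computation in physical units requires.
#'
#' The coordinate convention is: pixel `[i, j]` (1-based row `i` = y,
#' column `j` = x) has its centre at physical position
#' `((j - 0.5) * pixel_size, (i - 0.5) * pixel_size)` micrometres, origin at
#' the top-left image corner.
#'
#' @param data numeric array, `[y, x, frame]` or `[y, x, frame, channel]`.
#' @param pixel_size lateral pixel size in micrometres per pixel (> 0).
#' @param frame_interval time between frames in seconds (`NA` for z-stacks).
#' @param z_step axial step in micrometres for z-stacks (`NA` otherwise).
#' @param channels character vector of channel labels; length must match the
#'   4th dimension when present.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size, frame_interval = NA_real_,
                        z_step = NA_real_, channels = NULL) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3- or 4-dimensional array")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/px)")
  nd <- length(dim(data))
  if (nd == 4L) {
    if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[4L]))
    if (length(channels) != dim(data)[4L])
      stop("`channels` length must match the channel dimension")
  } else if (is.null(channels)) {
    channels <- "ch1"
  }
  structure(
    list(data = data, pixel_size = pixel_size,
         frame_interval = frame_interval, z_step = z_step,
         channels = as.character(channels)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d px, %d frames, %d channel(s)\n",
              d[2L], d[1L], d[3L], if (length(d) == 4L) d[4L] else 1L))
  cat(sprintf("  pixel size %.4g um/px", x$pixel_size))
  if (is.finite(x$frame_interval))
    cat(sprintf(", frame interval %.4g s", x$frame_interval))
  if (is.finite(x$z_step)) cat(sprintf(", z step %.4g um", x$z_step))
  cat("\n")
  invisible(x)
}

#' Number of frames in a stack
#' @param stack an `image_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$data)[3L]

#' Extract one frame as a matrix
#'
#' @param stack an `image_stack`.
#' @param frame 1-based frame (or z-slice) index.
#' @param channel 1-based channel index or channel label.
#' @return Numeric matrix `[y, x]`.
#' @export
get_frame <- function(stack, frame, channel = 1L) {
  if (is.character(channel)) {
    channel <- match(channel, stack$channels)
    if (is.na(channel)) stop("unknown channel label")
  }
  if (length(dim(stack$data)) == 4L) stack$data[, , frame, channel]
  else stack$data[, , frame]
}

#' Field of view size in micrometres
#' @param stack an `image_stack`.
#' @return `c(width_um, height_um)`.
#' @export
field_size_um <- function(stack) {
  d <- dim(stack$data)
  c(d[2L], d[1L]) * stack$pixel_size
}

#' Physical field area of a stack in square micrometres
#' @param stack an `image_stack`.
#' @return Area in um^2.
#' @export
field_area_um2 <- function(stack) prod(field_size_um(stack))

sidecar_path <- function(path) paste0(path, ".meta.txt")

#' Write an image stack to multi-page TIFF
#'
#' One TIFF file per channel (the channel label is appended to the file stem
#' for multi-channel stacks) plus a plain-text sidecar carrying the physical
#' calibration (`pixel_size_um`, `frame_interval_s`, `z_step_um`,
#' `channels`). Pixel values are stored as 16-bit unsigned integers; values
#' are clipped to [0, 65535] and rounded, so the round trip is lossless for
#' integer-valued data in range.
#'
#' @param stack an `image_stack`.
#' @param path output path of the (first) TIFF file.
#' @return Invisibly, the character vector of files written.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  nch <- if (length(d) == 4L) d[4L] else 1L
  paths <- character(nch)
  for (ch in seq_len(nch)) {
    p <- if (nch == 1L) path else
      sub("(\\.[^.]+)$", sprintf("_%s\\1", stack$channels[ch]), path)
    pages <- lapply(seq_len(d[3L]), function(f) {
      m <- get_frame(stack, f, ch)
      pmin(pmax(round(m), 0), 65535) / 65535
    })
    tiff::writeTIFF(pages, p, bits.per.sample = 16L, compression = "none")
    paths[ch] <- p
  }
  meta <- c(sprintf("pixel_size_um=%.12g", stack$pixel_size),
            sprintf("frame_interval_s=%.12g", stack$frame_interval),
            sprintf("z_step_um=%.12g", stack$z_step),
            paste0("channels=", paste(stack$channels, collapse = ",")))
  writeLines(meta, sidecar_path(path))
  invisible(c(paths, sidecar_path(path)))
}

#' Read a multi-page TIFF stack with calibration
#'
#' Calibration comes from the sidecar written by [write_stack()], or must be
#' passed explicitly; reading without any calibration is an error, never a
#' silent assumption.
#'
#' @param path TIFF file path (single channel; read channels separately and
#'   combine for multi-channel data).
#' @param pixel_size,frame_interval,z_step explicit calibration overriding or
#'   replacing the sidecar.
#' @return An `image_stack` with integer-valued pixel data.
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL,
                       z_step = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("malformed stack: pages have inconsistent shapes")
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    kv <- strsplit(readLines(sp), "=", fixed = TRUE)
    meta <- stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
  }
  num <- function(key, override) {
    if (!is.null(override)) return(override)
    v <- meta[[key]]
    if (is.null(v) || identical(v, "NA")) return(NULL)
    as.numeric(v)
  }
  ps <- num("pixel_size_um", pixel_size)
  if (is.null(ps))
    stop("calibration missing: no sidecar metadata for ", path,
         " and no explicit pixel_size given")
  fi <- num("frame_interval_s", frame_interval)
  zs <- num("z_step_um", z_step)
  ch <- if (!is.null(meta$channels)) strsplit(meta$channels, ",")[[1]][1]
        else NULL
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]]
  image_stack(arr, pixel_size = ps,
              frame_interval = if (is.null(fi)) NA_real_ else fi,
              z_step = if (is.null(zs)) NA_real_ else zs,
              channels = ch)
}

#' Write a data frame as a tab-delimited table
#'
#' Header row, tab separators, decimal points regardless of locale; numeric
#' values are written with 12 significant digits so a round trip through
#' [read_table_tsv()] is lossless at that precision.
#'
#' @param table a data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_table_tsv <- function(table, path) {
  if (anyDuplicated(names(table)))
    stop("duplicated column names in table")
  fmt <- table
  for (j in seq_along(fmt))
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.12g", fmt[[j]])
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tab-delimited table written by [write_table_tsv()]
#'
#' @param path file path.
#' @param numeric_cols optional character vector of columns that must parse
#'   as numbers; a non-numeric cell raises an error naming row and column.
#' @return A data frame.
#' @export
read_table_tsv <- function(path, numeric_cols = NULL) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header))
    stop("duplicated header names in ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  for (col in names(tab)) {
    vals <- tab[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) & !is.na(vals) & nzchar(vals))
    if (!is.null(numeric_cols) && col %in% numeric_cols && length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   vals[bad[1]], bad[1], col))
    if (length(bad) == 0L && length(vals)) tab[[col]] <- num
    if (length(vals) == 0L && (is.null(numeric_cols) ||
                               col %in% numeric_cols))
      tab[[col]] <- numeric(0)
  }
  tab
}
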