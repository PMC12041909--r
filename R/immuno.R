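#' Segment one immunostain channel
#'
#' Applies the same smoothing / Otsu / watershed recipe used for Fura-2 sum
#' images (see [segment_cells()]) to a single confocal channel and reports
#' per-label sectional areas in physical units.
#'
#' @param image numeric matrix, one calibrated channel.
#' @param pixel_size um/px (0.22 um for the 20x confocal acquisition this
#'   pipeline targets).
#' @param min_area smallest retained object, um^2.
#' @return List: `mask` (integer label matrix) and `areas` (data frame
#'   `label`, `area`, `x`, `y`, `border`).
#' @export
segment_channel <- function(image, pixel_size, min_area = 20) {
  mask <- segment_cells(image, pixel_size, min_area = min_area)
  list(mask = mask, areas = label_properties(mask, pixel_size))
}

#' Quantify pErk1/2 per cell with nucleus pairing
#'
#' Measures the mean phospho-Erk1/2 intensity within each cell footprint
#' (segmented from the pErk channel itself) and pairs every nucleus to the
#' cell whose footprint contains the nucleus centroid. Nuclei whose
#' centroid lies outside every cell are reported unpaired (`cell = NA`).
#'
#' @param perk_image numeric matrix, the pErk1/2 channel.
#' @param cell_mask integer label mask from segmenting `perk_image`.
#' @param nucleus_mask optional integer label mask of the nuclear channel.
#' @param pixel_size um/px.
#' @return Data frame (class `immuno_record`): `cell`, `cell_area` (um^2),
#'   `perk_mean` (counts), `nucleus`, `nucleus_area` (um^2; `NA` where no
#'   nucleus paired). Unpaired nuclei appear as rows with `cell = NA`.
#' @export
measure_perk <- function(perk_image, cell_mask, nucleus_mask = NULL,
                         pixel_size) {
  cells <- label_properties(cell_mask, pixel_size)
  rec <- if (nrow(cells)) data.frame(
    cell = cells$label,
    cell_area = cells$area,
    perk_mean = vapply(cells$label, function(l)
      mean(perk_image[cell_mask == l]), 0),
    nucleus = NA_integer_, nucleus_area = NA_real_)
  else data.frame(cell = integer(0), cell_area = numeric(0),
                  perk_mean = numeric(0), nucleus = integer(0),
                  nucleus_area = numeric(0))
  if (!is.null(nucleus_mask)) {
    nuc <- label_properties(nucleus_mask, pixel_size)
    for (i in seq_len(nrow(nuc))) {
      # nucleus centroid back to pixel indices for containment lookup
      ci <- pmin(pmax(round(nuc$y[i] / pixel_size + 0.5), 1L),
                 nrow(cell_mask))
      cj <- pmin(pmax(round(nuc$x[i] / pixel_size + 0.5), 1L),
                 ncol(cell_mask))
      owner <- cell_mask[ci, cj]
      if (owner > 0 && is.na(rec$nucleus[match(owner, rec$cell)])) {
        k <- match(owner, rec$cell)
        rec$nucleus[k] <- nuc$label[i]
        rec$nucleus_area[k] <- nuc$area[i]
      } else {
        rec <- rbind(rec, data.frame(cell = NA_integer_,
                                     cell_area = NA_real_,
                                     perk_mean = NA_real_,
                                     nucleus = nuc$label[i],
                                     nucleus_area = nuc$area[i]))
      }
    }
  }
  rownames(rec) <- NULL
  class(rec) <- c("immuno_record", "data.frame")
  rec
}
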