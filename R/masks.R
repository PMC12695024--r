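#' Construct an ROI pixel mask
#'
#' An ROI (region of interest) is the pixel footprint of one putative neuron
#' in one session's segmentation. Pixels are 0-based integer `(row, col)`
#' coordinates. The centroid is the unweighted mean of the pixel coordinates;
#' the median pixel is the coordinate-wise median (used for grid-based
#' candidate selection).
#'
#' @param roi_id 0-based integer index of the ROI within its session.
#' @param pixels n x 2 integer matrix with columns `(row, col)`, 0-based.
#' @param weights optional per-pixel nonnegative weights (same length as
#'   rows of `pixels`); carried through but ignored by spatial matching.
#' @param cell_probability optional classifier probability in `[0, 1]`.
#' @param shape optional `(H, W)` image shape used to bound-check pixels.
#' @param out_of_bounds logical flag set by [warp_mask()] when the whole
#'   mask mapped outside the field of view.
#' @return An object of class `roi_mask` with fields `roi_id`, `pixels`,
#'   `weights`, `centroid`, `median_pixel`, `cell_probability`.
#' @export
roi_mask <- function(roi_id, pixels, weights = NULL, cell_probability = NULL,
                     shape = NULL, out_of_bounds = FALSE) {
  pixels <- base::matrix(as.integer(pixels), ncol = 2L,
                         dimnames = list(NULL, c("row", "col")))
  empty <- nrow(pixels) == 0L
  if (!empty) {
    if (anyDuplicated(pixels))
      td_validation_error(sprintf("ROI %d has duplicate pixels", roi_id))
    if (any(pixels < 0L))
      td_validation_error(sprintf("ROI %d has negative pixel coordinates", roi_id))
    if (!is.null(shape) &&
        (any(pixels[, 1] >= shape[1]) || any(pixels[, 2] >= shape[2])))
      td_validation_error(sprintf(
        "ROI %d has pixels outside the %dx%d image bounds", roi_id,
        shape[1], shape[2]))
  } else if (!out_of_bounds) {
    td_validation_error(sprintf("ROI %d has no pixels", roi_id))
  }
  if (!is.null(weights)) {
    if (length(weights) != nrow(pixels))
      td_validation_error(sprintf(
        "ROI %d: %d weights for %d pixels", roi_id, length(weights),
        nrow(pixels)))
    if (any(weights < 0))
      td_validation_error(sprintf("ROI %d has negative weights", roi_id))
  }
  structure(list(
    roi_id = as.integer(roi_id),
    pixels = pixels,
    weights = weights,
    centroid = if (empty) c(NA_real_, NA_real_) else colMeans(pixels),
    median_pixel = if (empty) c(NA_integer_, NA_integer_) else
      apply(pixels, 2, function(v) as.integer(median(v))),
    cell_probability = cell_probability,
    shape = if (is.null(shape)) NULL else as.integer(shape),
    out_of_bounds = out_of_bounds
  ), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> id=%d  %d px  centroid=(%.1f, %.1f)%s\n",
              x$roi_id, nrow(x$pixels), x$centroid[1], x$centroid[2],
              if (x$out_of_bounds) "  [out of bounds]" else ""))
  invisible(x)
}

# encode (row, col) pairs as single integers for fast set operations;
# valid while both coordinates are < 2^15
pixel_keys <- function(pixels) {
  pixels[, 1] * 32768L + pixels[, 2]
}

#' Masks from an integer label image
#'
#' Converts a label image (0 = background, `k` = ROI `k - 1`) into a list of
#' [roi_mask()] objects ordered by label.
#'
#' @param labels integer matrix; label `k` produces the mask with
#'   `roi_id = k - 1`.
#' @param cell_probability optional vector of classifier probabilities, one
#'   per label.
#' @return List of `roi_mask` objects.
#' @export
masks_from_labels <- function(labels, cell_probability = NULL) {
  labs <- sort(unique(labels[labels > 0]))
  if (length(labs) == 0L) return(list())
  if (!identical(as.integer(labs), seq_along(labs)))
    td_validation_error("label image must use consecutive labels 1..K")
  shape <- dim(labels)
  lapply(labs, function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    roi_mask(k - 1L, cbind(idx[, 1] - 1L, idx[, 2] - 1L),
             cell_probability = if (is.null(cell_probability)) NULL else
               cell_probability[k],
             shape = shape)
  })
}

# inverse: render masks as a label image (roi_id k -> label k+1);
# overlapping pixels keep the highest label drawn last
masks_to_labels <- function(masks, shape) {
  lab <- base::matrix(0L, shape[1], shape[2])
  for (m in masks) {
    if (nrow(m$pixels) == 0L) next
    lab[m$pixels[, 1] + 1L + shape[1] * m$pixels[, 2]] <- m$roi_id + 1L
  }
  lab
}
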