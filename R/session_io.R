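#' Session loading options
#'
#' @param cell_prob_threshold ROIs with a classifier `cell_probability`
#'   below this value are excluded at load time (with their trace rows),
#'   mirroring the usual segmentation-curation default of 0.5. ROIs without
#'   a probability are always kept.
#' @param verbose emit an INFO message per load/filter decision.
#' @return A list of class `load_control`.
#' @export
load_control <- function(cell_prob_threshold = 0.5, verbose = TRUE) {
  structure(list(cell_prob_threshold = cell_prob_threshold,
                 verbose = verbose), class = "load_control")
}

td_log <- function(verbose, ...) {
  if (verbose) message("INFO: ", sprintf(...))
}

#' Construct and validate a session record
#'
#' One imaging day: the mean field-of-view image(s), the ROI masks, and the
#' baseline-corrected fluorescence trace matrix (dF/F).
#'
#' @param rois list of [roi_mask()] objects, ordered so that mask `k`
#'   corresponds to trace row `k`.
#' @param traces numeric matrix, `n_rois x n_frames`.
#' @param mean_image_functional 2-D numeric matrix (H x W).
#' @param mean_image_anatomical optional 2-D matrix of the same shape.
#' @param session_index 0-based ordinal of the session.
#' @param day_label free-text label (e.g. `"P8"`).
#' @param frame_rate acquisition rate in Hz.
#' @param pixel_size_um optional pixel size in micrometres.
#' @return An object of class `session_record`.
#' @export
session_record <- function(rois, traces, mean_image_functional,
                           mean_image_anatomical = NULL,
                           session_index = 0L, day_label = NULL,
                           frame_rate = 30, pixel_size_um = NULL) {
  traces <- as.matrix(traces)
  shape <- dim(mean_image_functional)
  if (length(shape) != 2L)
    td_validation_error("mean_image_functional must be a 2-D matrix")
  if (!is.null(mean_image_anatomical) &&
      !identical(dim(mean_image_anatomical), shape))
    td_validation_error("anatomical and functional mean images differ in shape")
  if (length(rois) != nrow(traces))
    td_validation_error(sprintf(
      "session %s: %d ROIs but %d trace rows",
      day_label %||% session_index, length(rois), nrow(traces)))
  if (frame_rate <= 0) td_validation_error("frame_rate must be positive")
  for (m in rois) {
    if (nrow(m$pixels) > 0L &&
        (any(m$pixels[, 1] >= shape[1]) || any(m$pixels[, 2] >= shape[2])))
      td_validation_error(sprintf(
        "session %s: ROI %d has pixels outside the %dx%d image",
        day_label %||% session_index, m$roi_id, shape[1], shape[2]))
  }
  structure(list(session_index = as.integer(session_index),
                 day_label = day_label %||% paste0("s", session_index),
                 mean_image_functional = mean_image_functional,
                 mean_image_anatomical = mean_image_anatomical,
                 rois = rois, traces = traces,
                 frame_rate = frame_rate, pixel_size_um = pixel_size_um,
                 shape = as.integer(shape)),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s: %dx%d FOV, %d ROIs, %d frames @ %g Hz%s\n",
              x$day_label, x$shape[1], x$shape[2], length(x$rois),
              ncol(x$traces), x$frame_rate,
              if (is.null(x$mean_image_anatomical)) "" else
                " (+anatomical channel)"))
  invisible(x)
}

#' Load one session from a directory
#'
#' Expects the package's canonical on-disk layout:
#' \describe{
#'   \item{`mean_image_functional.tif`}{required grayscale TIFF.}
#'   \item{`mean_image_anatomical.tif`}{optional second channel.}
#'   \item{`roi_pixels.csv`}{`roi_id,row,col[,weight]` pixel table
#'     (0-based), or alternatively `roi_labels.tif`, an integer label image
#'     with 0 = background.}
#'   \item{`traces.csv`}{headerless `n_rois x n_frames` matrix.}
#'   \item{`iscell.csv`}{optional `roi_id,cell_probability` table.}
#'   \item{`session.json`}{optional metadata: `day_label`, `frame_rate`,
#'     `pixel_size_um`, `session_index`.}
#' }
#' ROIs with `cell_probability` below the configured threshold are excluded
#' together with their trace rows; surviving ROIs are re-indexed 0..m-1 in
#' their original order so that mask `k` still pairs with trace row `k`.
#'
#' @param path session directory.
#' @param config a [load_control()] list.
#' @return A validated [session_record()].
#' @export
load_session <- function(path, config = load_control()) {
  need <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p)) td_load_error(sprintf("missing file: %s", p))
    p
  }
  img_f <- read_image_tiff(need("mean_image_functional.tif"))
  img_a <- NULL
  if (file.exists(file.path(path, "mean_image_anatomical.tif")))
    img_a <- read_image_tiff(file.path(path, "mean_image_anatomical.tif"))

  meta <- list()
  if (file.exists(file.path(path, "session.json")))
    meta <- jsonlite::read_json(file.path(path, "session.json"),
                                simplifyVector = TRUE)

  probs_tab <- NULL
  if (file.exists(file.path(path, "iscell.csv")))
    probs_tab <- utils::read.csv(file.path(path, "iscell.csv"))

  if (file.exists(file.path(path, "roi_pixels.csv"))) {
    tab <- utils::read.csv(file.path(path, "roi_pixels.csv"))
    ids <- sort(unique(tab$roi_id))
    if (!identical(as.integer(ids), seq_along(ids) - 1L))
      td_validation_error("roi_pixels.csv: roi_id must be consecutive 0..m-1")
    rois <- lapply(ids, function(k) {
      sub <- tab[tab$roi_id == k, , drop = FALSE]
      roi_mask(k, cbind(sub$row, sub$col),
               weights = if ("weight" %in% names(tab)) sub$weight else NULL,
               shape = dim(img_f))
    })
  } else if (file.exists(file.path(path, "roi_labels.tif"))) {
    lab <- round(read_image_tiff(file.path(path, "roi_labels.tif"),
                                 as_integer = TRUE))
    rois <- masks_from_labels(lab)
  } else {
    td_load_error(sprintf(
      "missing file: %s (no roi_pixels.csv or roi_labels.tif)", path))
  }

  if (!is.null(probs_tab)) {
    for (i in seq_along(rois)) {
      hit <- match(rois[[i]]$roi_id, probs_tab$roi_id)
      if (!is.na(hit))
        rois[[i]]$cell_probability <- probs_tab$cell_probability[hit]
    }
  }

  traces <- as.matrix(data.table::fread(need("traces.csv"), header = FALSE))
  dimnames(traces) <- NULL
  if (nrow(traces) != length(rois))
    td_validation_error(sprintf(
      "%s: %d trace rows for %d ROIs", path, nrow(traces), length(rois)))

  # probability filter: drop ROI + trace row together, then re-index
  prob <- vapply(rois, function(m) m$cell_probability %||% 1.0, numeric(1))
  keep <- prob >= config$cell_prob_threshold
  if (any(!keep)) {
    td_log(config$verbose,
           "%s: excluded %d/%d ROIs below cell probability %.2f (ids: %s)",
           path, sum(!keep), length(keep), config$cell_prob_threshold,
           paste(which(!keep) - 1L, collapse = ", "))
    rois <- rois[keep]
    traces <- traces[keep, , drop = FALSE]
    for (i in seq_along(rois)) rois[[i]]$roi_id <- i - 1L
  }
  td_log(config$verbose, "%s: loaded %d ROIs, %d frames", path,
         length(rois), ncol(traces))

  session_record(rois, traces, img_f, img_a,
                 session_index = meta$session_index %||% 0L,
                 day_label = meta$day_label,
                 frame_rate = meta$frame_rate %||% 30,
                 pixel_size_um = meta$pixel_size_um)
}

read_image_tiff <- function(path, as_integer = FALSE) {
  img <- tiff::readTIFF(path, as.is = as_integer)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Load an ordered series of sessions
#'
#' @param paths ordered character vector of >= 2 session directories.
#' @param config a [load_control()] list.
#' @return A list of [session_record()] ordered as given, with
#'   `session_index` set to 0..N-1. Fails on mismatched image dimensions or
#'   channel availability across sessions.
#' @export
load_dataset <- function(paths, config = load_control()) {
  if (length(paths) < 2L)
    td_usage_error("need at least 2 sessions to track")
  sessions <- lapply(paths, load_session, config = config)
  shape <- sessions[[1]]$shape
  has_anat <- !is.null(sessions[[1]]$mean_image_anatomical)
  for (i in seq_along(sessions)) {
    sessions[[i]]$session_index <- i - 1L
    if (!identical(sessions[[i]]$shape, shape))
      td_validation_error(sprintf(
        "session %s is %dx%d but session %s is %dx%d",
        paths[i], sessions[[i]]$shape[1], sessions[[i]]$shape[2],
        paths[1], shape[1], shape[2]))
    if (!identical(!is.null(sessions[[i]]$mean_image_anatomical), has_anat))
      td_validation_error(sprintf(
        "session %s differs in anatomical-channel availability", paths[i]))
  }
  sessions
}

#' Write one session in the canonical on-disk layout
#'
#' Inverse of [load_session()]; used by the synthetic generator and by
#' tests. Images are rescaled to `[0, 1]` for TIFF storage.
#'
#' @param session a [session_record()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_tiff01 <- function(img, file)
    tiff::writeTIFF(pmin(pmax(
      (img - min(img)) / max(max(img) - min(img), 1e-12), 0), 1),
      file.path(path, file), bits.per.sample = 32L)
  write_tiff01(session$mean_image_functional, "mean_image_functional.tif")
  if (!is.null(session$mean_image_anatomical))
    write_tiff01(session$mean_image_anatomical, "mean_image_anatomical.tif")
  px <- do.call(rbind, lapply(session$rois, function(m)
    data.frame(roi_id = m$roi_id, row = m$pixels[, 1], col = m$pixels[, 2])))
  utils::write.csv(px, file.path(path, "roi_pixels.csv"), row.names = FALSE)
  data.table::fwrite(data.table::as.data.table(session$traces),
                     file.path(path, "traces.csv"), col.names = FALSE)
  jsonlite::write_json(list(day_label = session$day_label,
                            frame_rate = session$frame_rate,
                            pixel_size_um = session$pixel_size_um,
                            session_index = session$session_index),
                       file.path(path, "session.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
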