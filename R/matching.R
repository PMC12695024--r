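#' Intersection over union of two ROI masks
#'
#' `|A ∩ B| / |A ∪ B|` on binary pixel occupancy (per-pixel weights are a
#' segmentation artifact and are ignored). Both masks must live in the same
#' coordinate frame. By convention an empty mask yields 0.
#'
#' @param a,b [roi_mask()] objects.
#' @return Scalar in `[0, 1]`; symmetric in its arguments.
#' @export
compute_iou <- function(a, b) {
  na <- nrow(a$pixels); nb <- nrow(b$pixels)
  if (na == 0L || nb == 0L) return(0)
  inter <- sum(pixel_keys(a$pixels) %in% pixel_keys(b$pixels))
  inter / (na + nb - inter)
}

#' Build the match cost matrix between two sessions' ROI sets
#'
#' Entry `[i, j] = 1 - IoU(ref_i, mov_j)` where the moving-session masks
#' have already been warped into the reference frame. Computed for all pairs
#' at once through sparse pixel-occupancy incidence matrices, so the cost of
#' a session pair scales with total mask area rather than with the number of
#' ROI pairs. Masks that warped entirely out of bounds give full-cost
#' (1.0) rows/columns.
#'
#' @param ref_rois list of [roi_mask()] in the reference session.
#' @param warped_mov_rois list of [roi_mask()] already expressed in the
#'   reference frame (output of [warp_mask()]).
#' @param shape `(H, W)` of the reference frame; inferred from the masks'
#'   `shape` field when omitted.
#' @return An object of class `cost_matrix` with field `values`
#'   (`m_ref x m_mov`, entries in `[0, 1]`).
#' @export
build_cost_matrix <- function(ref_rois, warped_mov_rois, shape = NULL) {
  if (is.null(shape)) {
    for (m in c(ref_rois, warped_mov_rois))
      if (!is.null(m$shape)) { shape <- m$shape; break }
    if (is.null(shape))
      td_usage_error("shape must be given when masks carry no shape")
  }
  m_ref <- length(ref_rois); m_mov <- length(warped_mov_rois)
  if (m_ref == 0L || m_mov == 0L) {
    values <- base::matrix(numeric(), m_ref, m_mov)
  } else {
    inc <- function(rois) {
      sizes <- vapply(rois, function(m) nrow(m$pixels), integer(1))
      px <- do.call(rbind, lapply(rois, `[[`, "pixels"))
      if (is.null(px)) px <- base::matrix(integer(), 0, 2)
      Matrix::sparseMatrix(
        i = px[, 1] + 1L + shape[1] * px[, 2],
        j = rep.int(seq_along(rois), sizes),
        x = 1, dims = c(shape[1] * shape[2], length(rois)))
    }
    A <- inc(ref_rois); B <- inc(warped_mov_rois)
    inter <- as.matrix(Matrix::crossprod(A, B))
    sizes_a <- Matrix::colSums(A); sizes_b <- Matrix::colSums(B)
    union <- outer(sizes_a, sizes_b, `+`) - inter
    iou <- ifelse(union > 0, inter / union, 0)
    values <- 1 - iou
  }
  structure(list(values = values,
                 ref_session = NA_integer_, mov_session = NA_integer_),
            class = "cost_matrix")
}

#' Globally optimal one-to-one ROI assignment
#'
#' Solves the linear sum assignment problem on a (possibly rectangular)
#' cost matrix: a partial one-to-one assignment of rows to columns of size
#' `min(m_ref, m_mov)` minimising total cost -- equivalently maximising the
#' summed IoU across all matches. Output is deterministic for identical
#' input.
#'
#' @param cost a [build_cost_matrix()] result or a plain numeric matrix.
#' @return Integer matrix with columns `ref`, `mov` (0-based ROI indices),
#'   one row per assigned pair, ordered by `ref`.
#' @export
assign_matches <- function(cost) {
  values <- if (inherits(cost, "cost_matrix")) cost$values else as.matrix(cost)
  if (nrow(values) == 0L || ncol(values) == 0L)
    return(base::matrix(integer(), 0, 2, dimnames = list(NULL, c("ref", "mov"))))
  if (!all(is.finite(values)))
    td_validation_error("cost matrix must be finite")
  if (nrow(values) <= ncol(values)) {
    sol <- as.integer(clue::solve_LSAP(values))
    pairs <- cbind(ref = seq_len(nrow(values)) - 1L, mov = sol - 1L)
  } else {
    sol <- as.integer(clue::solve_LSAP(t(values)))
    pairs <- cbind(ref = sol - 1L, mov = seq_len(ncol(values)) - 1L)
    pairs <- pairs[order(pairs[, "ref"]), , drop = FALSE]
  }
  pairs
}

#' Otsu's threshold on a set of match-quality values
#'
#' Histogram threshold maximising the between-class variance, computed on a
#' fixed `n_bins`-bin histogram over `[0, 1]`. Candidate thresholds are the
#' interior bin edges; when several candidates tie (every split of an empty
#' gap between the two modes scores identically), the middle of the tied
#' run is returned, placing the threshold centrally in the gap. Used to
#' separate the bimodal IoU distribution of assigned matches into putative
#' true (high-IoU) and false (low-IoU) matches.
#'
#' @param values numeric vector in `[0, 1]` (the assigned pairs' IoUs).
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold, or `NA` (with attribute `degenerate = TRUE`) when
#'   fewer than 2 values or a zero value range make thresholding
#'   meaningless; callers fall back to a configured floor.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  degenerate <- structure(NA_real_, degenerate = TRUE)
  if (length(values) < 2L || diff(range(values)) < .Machine$double.eps)
    return(degenerate)
  if (any(values < 0) || any(values > 1))
    td_validation_error("otsu_threshold expects values in [0, 1]")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(values, edges,
                                            rightmost.closed = TRUE), 1L),
                          n_bins), nbins = n_bins)
  p <- counts / sum(counts)
  centres <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w1 <- cumsum(p)                       # class weight below edge k+1
  m1 <- cumsum(p * centres)
  mu <- m1[n_bins]
  # between-class variance at each interior edge (threshold = edges[k+1])
  w2 <- 1 - w1
  valid <- w1 > 0 & w2 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu * w1[valid] - m1[valid])^2 / (w1[valid] * w2[valid])
  if (!any(is.finite(sigma_b))) return(degenerate)
  best <- which(sigma_b == max(sigma_b))
  k <- best[ceiling(length(best) / 2)]  # middle of the tied run
  edges[k + 1L]
}

#' Otsu threshold with a unimodality guard
#'
#' Applies [otsu_threshold()] and then checks that the class *below* the
#' split actually looks like false matches. Otsu assumes a bimodal
#' histogram -- true matches overlapping strongly versus false matches
#' overlapping barely -- but when (almost) every assigned pair is a true
#' match the IoU distribution is unimodal and the raw Otsu threshold
#' would slice the good mode in half. False matches pair up different
#' cells, so their IoU clusters near zero; if the mean IoU of the
#' rejected class exceeds `max_reject_iou` the split is cutting through
#' true matches instead, and the threshold is declared degenerate (`NA`;
#' the caller falls back to the floor).
#'
#' @param values assigned pairs' IoU values.
#' @param n_bins histogram bins for [otsu_threshold()].
#' @param max_reject_iou largest mean IoU the rejected class may have for
#'   the split to be trusted (default 0.3).
#' @return Threshold, or `NA` with attribute `degenerate` when the sample
#'   is degenerate or unimodal; attribute `reject_mean_iou` records the
#'   rejected class's mean actually measured.
#' @export
guarded_otsu_threshold <- function(values, n_bins = 256L,
                                   max_reject_iou = 0.3) {
  theta <- otsu_threshold(values, n_bins = n_bins)
  if (is.na(theta)) return(theta)
  lo_mean <- mean(values[values < theta])
  if (is.nan(lo_mean)) lo_mean <- 0
  if (lo_mean > max_reject_iou)
    return(structure(NA_real_, degenerate = TRUE,
                     reject_mean_iou = lo_mean))
  structure(theta, reject_mean_iou = lo_mean)
}

#' Accept or reject assigned matches by IoU threshold
#'
#' A pair is accepted iff its IoU is at least `max(threshold, floor)`; a
#' degenerate (`NA`) threshold falls back to the floor alone. Both accepted
#' and rejected pairs are retained for diagnostics.
#'
#' @param assignment integer matrix with columns `ref`, `mov` from
#'   [assign_matches()].
#' @param ious per-pair IoU values (same order as `assignment` rows).
#' @param threshold Otsu threshold (possibly `NA`).
#' @param floor minimum acceptable IoU guarding the unimodal/degenerate
#'   case (default 0.10).
#' @return An object of class `match_set`: data frame `pairs` with columns
#'   `ref`, `mov`, `iou`, `accepted`, plus `threshold` (effective),
#'   `theta_otsu` and `floor`.
#' @export
filter_matches <- function(assignment, ious, threshold, floor = 0.10) {
  if (NROW(assignment) != length(ious))
    td_validation_error("one IoU value per assigned pair is required")
  eff <- if (is.na(threshold)) floor else max(threshold, floor)
  pairs <- data.frame(ref = as.integer(assignment[, 1]),
                      mov = as.integer(assignment[, 2]),
                      iou = as.numeric(ious))
  pairs$accepted <- pairs$iou >= eff
  structure(list(pairs = pairs, threshold = eff,
                 theta_otsu = as.numeric(threshold), floor = floor),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf(
    "<match_set> %d pairs, %d accepted (threshold %.3f, otsu %s)\n",
    nrow(x$pairs), sum(x$pairs$accepted), x$threshold,
    if (is.na(x$theta_otsu)) "degenerate" else sprintf("%.3f", x$theta_otsu)))
  invisible(x)
}

#' Tracking pipeline options
#'
#' @param channel which mean image drives registration: `"anatomical"` (a
#'   sparse structural marker, the baseline choice) or `"functional"`
#'   (dense calcium-indicator signal). An error is raised if the chosen
#'   channel is missing in any session.
#' @param mode `"affine"` (models growth: scale and shear on top of shift
#'   and rotation) or `"rigid"` (ablation).
#' @param iou_floor minimum IoU for an accepted match (default 0.10),
#'   guarding the case where the IoU distribution is not bimodal and Otsu
#'   thresholding degenerates.
#' @param n_bins histogram bins for Otsu (default 256).
#' @param max_reject_iou largest mean IoU the Otsu-rejected class may
#'   have for the automatic threshold to be trusted (see
#'   [guarded_otsu_threshold()]); above it the floor alone applies.
#' @param seed_new_tracks also open new tracks at later sessions for
#'   unmatched ROIs (extension; default off, matching first-day seeding).
#' @param registration a [reg_control()] list.
#' @param verbose emit INFO messages per session pair.
#' @return A list of class `track_control`.
#' @export
track_control <- function(channel = c("anatomical", "functional"),
                          mode = c("affine", "rigid"), iou_floor = 0.10,
                          n_bins = 256L, max_reject_iou = 0.3,
                          seed_new_tracks = FALSE,
                          registration = reg_control(), verbose = TRUE) {
  structure(list(channel = match.arg(channel), mode = match.arg(mode),
                 iou_floor = iou_floor, n_bins = as.integer(n_bins),
                 max_reject_iou = max_reject_iou,
                 seed_new_tracks = seed_new_tracks,
                 registration = registration, verbose = verbose),
            class = "track_control")
}

session_channel <- function(session, channel) {
  img <- if (channel == "anatomical") session$mean_image_anatomical
         else session$mean_image_functional
  if (is.null(img))
    td_validation_error(sprintf(
      "session %s has no %s channel", session$day_label, channel))
  img
}

#' Track cells sequentially across all sessions
#'
#' The full pipeline. For each consecutive pair `(s_k, s_{k+1})`: the mean
#' image of `s_{k+1}` is registered onto `s_k` (affine by default), all
#' `s_{k+1}` ROI masks are warped into the `s_k` frame, a `1 - IoU` cost
#' matrix is built, matches are assigned by linear sum assignment, an Otsu
#' threshold computed on the assigned pairs' IoU distribution rejects
#' low-overlap (putative false) matches, and tracks -- seeded one per ROI of
#' the first session -- are extended by the accepted matches. A track with
#' no accepted match at some step is terminated and never resumes. Pairs
#' are registered independently; transforms are never chained, which avoids
#' accumulating registration error across the series.
#'
#' @param sessions list of >= 2 validated [session_record()].
#' @param config a [track_control()] list.
#' @return A list with elements `track_table` ([track_table()]),
#'   `match_sets` (per-pair [filter_matches()] results), `transforms`
#'   (per-pair [affine_transform()]), and `report` (per-session ROI counts
#'   and per-pair acceptance summary, suitable for JSON serialisation).
#' @export
link_sessions <- function(sessions, config = track_control()) {
  if (length(sessions) < 2L)
    td_usage_error("need at least 2 sessions to track")
  n <- length(sessions)
  labels <- vapply(sessions, `[[`, "", "day_label")
  n_rois0 <- length(sessions[[1]]$rois)
  entries <- base::matrix(-1L, n_rois0, n)
  entries[, 1] <- seq_len(n_rois0) - 1L
  current <- entries[, 1]               # live ROI id per track, -1 if dead
  track_of_roi <- seq_len(n_rois0)      # track row owning each live ref ROI
  match_sets <- vector("list", n - 1L)
  transforms <- vector("list", n - 1L)
  pair_report <- vector("list", n - 1L)

  for (k in seq_len(n - 1L)) {
    ref <- sessions[[k]]; mov <- sessions[[k + 1L]]
    tf <- estimate_transform(session_channel(ref, config$channel),
                             session_channel(mov, config$channel),
                             mode = config$mode,
                             control = config$registration,
                             fixed_session = ref$session_index,
                             moving_session = mov$session_index)
    warped <- lapply(mov$rois, warp_mask, transform = tf,
                     out_shape = ref$shape)
    cost <- build_cost_matrix(ref$rois, warped, shape = ref$shape)
    assignment <- assign_matches(cost)
    ious <- 1 - cost$values[cbind(assignment[, 1] + 1L,
                                  assignment[, 2] + 1L)]
    theta <- guarded_otsu_threshold(ious, n_bins = config$n_bins,
                                    max_reject_iou = config$max_reject_iou)
    ms <- filter_matches(assignment, ious, theta, floor = config$iou_floor)
    match_sets[[k]] <- ms
    transforms[[k]] <- tf

    acc <- ms$pairs[ms$pairs$accepted, , drop = FALSE]
    nxt <- rep(-1L, length(current))
    alive <- which(current >= 0L)
    hit <- match(current[alive], acc$ref)
    nxt[alive[!is.na(hit)]] <- acc$mov[hit[!is.na(hit)]]
    terminated <- sum(current >= 0L) - sum(nxt >= 0L)
    td_log(config$verbose,
           "pair %s->%s: NCC %.3f, %d/%d matches accepted (thr %.3f), %d tracks terminated",
           labels[k], labels[k + 1L], tf$registration_metric_value,
           nrow(acc), nrow(ms$pairs), ms$threshold, terminated)

    if (config$seed_new_tracks) {
      new_rois <- setdiff(seq_len(length(mov$rois)) - 1L, acc$mov)
      if (length(new_rois)) {
        add <- base::matrix(-1L, length(new_rois), n)
        add[, k + 1L] <- new_rois
        entries <- rbind(entries, add)
        nxt <- c(nxt, new_rois)
        current <- c(current, rep(-1L, length(new_rois)))
      }
    }
    current <- nxt
    entries[, k + 1L] <- current
    pair_report[[k]] <- list(
      pair = paste0(labels[k], "->", labels[k + 1L]),
      ncc = tf$registration_metric_value, converged = tf$converged,
      n_assigned = nrow(ms$pairs), n_accepted = nrow(acc),
      threshold = ms$threshold, theta_otsu = ms$theta_otsu,
      n_terminated = terminated)
  }

  tbl <- track_table(entries, labels, seed_session = 0L,
                     strict_seed = !config$seed_new_tracks)
  report <- list(
    n_sessions = n, session_labels = labels,
    n_rois = vapply(sessions, function(s) length(s$rois), integer(1)),
    n_tracks = nrow(entries),
    n_complete = sum(complete_tracks(tbl)),
    channel = config$channel, mode = config$mode,
    iou_floor = config$iou_floor, pairs = pair_report)
  list(track_table = tbl, match_sets = match_sets, transforms = transforms,
       report = report)
}
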