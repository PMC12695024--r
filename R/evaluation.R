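#' Construct a ground-truth track set
#'
#' Ground truth contains only full-length tracks (cells detected and
#' manually tracked across every session); there are no sentinels. Each
#' row's first-session entry must be one of the candidate seeds originally
#' selected for annotation.
#'
#' @param entries integer matrix (`T_gt x n_sessions`) of 0-based ROI
#'   indices, no sentinels.
#' @param candidate_seeds 0-based first-session ROI indices selected for
#'   annotation (defaults to the first column).
#' @param session_labels optional day labels.
#' @return An object of class `ground_truth_tracks`.
#' @export
ground_truth_tracks <- function(entries, candidate_seeds = NULL,
                                session_labels = NULL) {
  entries <- base::matrix(as.integer(entries), nrow = NROW(entries))
  if (any(entries < 0L))
    td_validation_error("ground truth must contain only full-length tracks")
  for (s in seq_len(ncol(entries)))
    if (anyDuplicated(entries[, s]))
      td_validation_error(sprintf(
        "ground truth column %d assigns one ROI to several tracks", s))
  if (is.null(candidate_seeds)) candidate_seeds <- entries[, 1]
  if (nrow(entries) > 0L && !all(entries[, 1] %in% candidate_seeds))
    td_validation_error("every ground-truth track must start at a candidate seed")
  structure(list(entries = entries,
                 candidate_seeds = as.integer(candidate_seeds),
                 session_labels = session_labels),
            class = "ground_truth_tracks")
}

#' Select annotation candidates on a regular grid
#'
#' Lays `rows x cols` equidistant points over the field of view (interior
#' grid, excluding the borders) and picks, for each point, the ROI whose
#' median pixel is nearest in Euclidean distance. Duplicates are collapsed
#' (an ROI nearest to two points is listed once), so the result may be
#' shorter than `rows * cols`. Ties break to the lowest ROI index. The
#' default 8x8 grid yields up to 64 candidates for manual annotation.
#'
#' @param session a [session_record()] with at least one ROI.
#' @param grid integer `(rows, cols)`.
#' @return Integer vector of 0-based ROI indices, in grid-point order.
#' @export
select_grid_candidates <- function(session, grid = c(8L, 8L)) {
  if (length(session$rois) == 0L)
    td_usage_error("session has no ROIs to select from")
  H <- session$shape[1]; W <- session$shape[2]
  rws <- seq(0, H - 1, length.out = grid[1] + 2L)[seq_len(grid[1]) + 1L]
  cls <- seq(0, W - 1, length.out = grid[2] + 2L)[seq_len(grid[2]) + 1L]
  pts <- as.matrix(expand.grid(row = rws, col = cls))
  med <- t(vapply(session$rois, `[[`, numeric(2), "median_pixel"))
  picked <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d <- (med[, 1] - pts[i, 1])^2 + (med[, 2] - pts[i, 2])^2
    picked[i] <- which.min(d) - 1L      # which.min ties -> lowest index
  }
  unique(picked)
}

#' Complete-tracks (CT) score against ground truth
#'
#' `CT = 2 * T_rc / (T_c + T_gt)`: the F1 score over perfectly
#' reconstructed full-length tracks. A predicted track is perfectly
#' reconstructed iff its ROI index equals the ground-truth row at *every*
#' session -- there is no partial credit, so the metric rewards perfect
#' matches and penalises every kind of mismatch. Predicted tracks are first
#' restricted to those seeded at the annotation candidates; `T_c` counts
#' the sentinel-free (complete) tracks among them, so an early-terminated
#' prediction is a false negative but not a false positive.
#'
#' @param gt a [ground_truth_tracks()].
#' @param pred a [track_table()] with the same session count.
#' @param prop_correct also compute the per-horizon proportion-correct
#'   curve (see [prop_correct_curve()]).
#' @return An object of class `evaluation_report` with fields `T_rc`,
#'   `T_c`, `T_gt`, `ct`, and (optionally) `prop_correct`.
#' @export
compute_ct <- function(gt, pred, prop_correct = TRUE) {
  if (ncol(gt$entries) != ncol(pred$entries))
    td_validation_error(sprintf(
      "ground truth has %d sessions, prediction %d",
      ncol(gt$entries), ncol(pred$entries)))
  seeded <- pred$entries[pred$entries[, 1] %in% gt$candidate_seeds, ,
                         drop = FALSE]
  complete <- seeded[rowSums(seeded < 0L) == 0L, , drop = FALSE]
  T_c <- nrow(complete)
  T_gt <- nrow(gt$entries)
  key <- function(m) apply(m, 1, paste, collapse = ",")
  T_rc <- if (T_gt > 0L && T_c > 0L)
    sum(key(gt$entries) %in% key(complete)) else 0L
  ct <- if (T_c + T_gt > 0L) 2 * T_rc / (T_c + T_gt) else NA_real_
  out <- structure(list(T_rc = as.integer(T_rc), T_c = T_c, T_gt = T_gt,
                        ct = ct, prop_correct = NULL),
                   class = "evaluation_report")
  if (prop_correct) out$prop_correct <- prop_correct_curve(gt, pred)
  out
}

#' Proportion of correctly reconstructed tracks per time span
#'
#' For each horizon `s` (the first `s` sessions, `s = 2 .. n_sessions`),
#' the fraction of ground-truth tracks whose prediction matches exactly on
#' those sessions. The denominator is fixed at `T_gt` (full-length ground
#' truth), so the curve is agnostic to false positives at shorter spans and
#' non-increasing in the horizon; its final value equals `T_rc / T_gt`.
#'
#' @inheritParams compute_ct
#' @return Named numeric vector of fractions for horizons `2..n_sessions`.
#' @export
prop_correct_curve <- function(gt, pred) {
  if (ncol(gt$entries) != ncol(pred$entries))
    td_validation_error(sprintf(
      "ground truth has %d sessions, prediction %d",
      ncol(gt$entries), ncol(pred$entries)))
  n_sessions <- ncol(gt$entries)
  T_gt <- nrow(gt$entries)
  out <- setNames(numeric(n_sessions - 1L),
                  paste0("h", seq(2L, n_sessions)))
  if (T_gt == 0L) return(out)
  # per-session uniqueness makes the first-session entry a track key
  hit <- match(gt$entries[, 1], pred$entries[, 1])
  for (s in seq(2L, n_sessions)) {
    ok <- !is.na(hit) &
      rowSums(gt$entries[, 1:s, drop = FALSE] ==
                pred$entries[hit, 1:s, drop = FALSE], na.rm = FALSE) == s
    ok[is.na(ok)] <- FALSE
    out[s - 1L] <- sum(ok) / T_gt
  }
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> CT = %.3f (T_rc=%d, T_c=%d, T_gt=%d)\n",
              x$ct, x$T_rc, x$T_c, x$T_gt))
  if (!is.null(x$prop_correct))
    cat("  prop. correct:",
        paste(sprintf("%.2f", x$prop_correct), collapse = " "), "\n")
  invisible(x)
}
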