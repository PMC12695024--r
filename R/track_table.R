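#' Construct and validate a track table
#'
#' The pipeline's main output: a `n_tracks x n_sessions` integer matrix of
#' per-session 0-based ROI indices, with the sentinel -1 meaning "absent".
#' Within a session (column) each ROI index may appear at most once; tracks
#' terminate but never resume (once -1, always -1); every track carries at
#' least one real entry, and by default a real entry at the seed session.
#'
#' @param entries integer matrix (tracks x sessions), sentinel -1.
#' @param session_labels character vector of day labels, one per column.
#' @param seed_session 0-based index where tracks originate (default 0).
#' @param strict_seed require a non-sentinel entry at `seed_session` for
#'   every track (relaxed when later-session seeding is enabled).
#' @return An object of class `track_table`.
#' @export
track_table <- function(entries, session_labels = NULL, seed_session = 0L,
                        strict_seed = TRUE) {
  entries <- base::matrix(as.integer(entries), nrow = NROW(entries),
                          ncol = NCOL(entries))
  n_sessions <- ncol(entries)
  if (is.null(session_labels)) session_labels <- paste0("s", seq_len(n_sessions) - 1L)
  if (length(session_labels) != n_sessions)
    td_validation_error("one session label per column is required")
  if (nrow(entries) > 0L) {
    if (any(is.na(entries)) || any(entries < -1L))
      td_validation_error("track entries must be ROI indices >= 0 or -1")
    for (s in seq_len(n_sessions)) {
      ids <- entries[entries[, s] >= 0L, s]
      if (anyDuplicated(ids))
        td_validation_error(sprintf(
          "session %s: ROI index %d assigned to more than one track",
          session_labels[s], ids[duplicated(ids)][1]))
    }
    for (k in seq_len(nrow(entries))) {
      real <- which(entries[k, ] >= 0L)
      if (length(real) == 0L)
        td_validation_error(sprintf("track %d has no entries", k - 1L))
      if (!identical(real, seq(min(real), max(real))))
        td_validation_error(sprintf(
          "track %d resumes after termination", k - 1L))
      if (strict_seed && entries[k, seed_session + 1L] < 0L)
        td_validation_error(sprintf(
          "track %d has no entry at seed session %d", k - 1L, seed_session))
    }
  }
  structure(list(entries = entries, session_labels = session_labels,
                 seed_session = as.integer(seed_session)),
            class = "track_table")
}

#' @export
print.track_table <- function(x, ...) {
  complete <- if (nrow(x$entries)) sum(rowSums(x$entries < 0L) == 0L) else 0L
  cat(sprintf("<track_table> %d tracks x %d sessions (%d complete)\n",
              nrow(x$entries), ncol(x$entries), complete))
  invisible(x)
}

# logical vector: which tracks have no sentinel
complete_tracks <- function(table) {
  if (nrow(table$entries) == 0L) return(logical(0))
  rowSums(table$entries < 0L) == 0L
}

#' Persist a track table as CSV
#'
#' Header `track_id,<label_0>,...,<label_N>`; body is integer ROI indices
#' with -1 for "absent". The round trip through [read_track_table()] is
#' bit-exact.
#'
#' @param table a [track_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(table, path) {
  header <- paste(c("track_id", table$session_labels), collapse = ",")
  body <- if (nrow(table$entries) > 0L)
    apply(cbind(seq_len(nrow(table$entries)) - 1L, table$entries), 1,
          paste, collapse = ",")
  else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a track table from CSV
#'
#' @param path file written by [write_track_table()].
#' @param seed_session,strict_seed passed to [track_table()] validation.
#' @return A validated [track_table()]. Ragged rows or non-integer cells
#'   raise a parse error naming the offending line; duplicate ROI indices
#'   within a session raise a validation error.
#' @export
read_track_table <- function(path, seed_session = 0L, strict_seed = TRUE) {
  if (!file.exists(path)) td_load_error(sprintf("missing file: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0L) td_stop(sprintf("%s: empty file", path), "parse")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "track_id")
    td_stop(sprintf("%s: line 1: expected header 'track_id,<labels...>'",
                    path), "parse")
  labels <- header[-1]
  n_col <- length(header)
  rows <- vector("list", length(lines) - 1L)
  for (i in seq_along(rows)) {
    cells <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    if (length(cells) != n_col)
      td_stop(sprintf("%s: line %d: %d fields, expected %d", path, i + 1L,
                      length(cells), n_col), "parse")
    vals <- suppressWarnings(as.numeric(cells))
    if (any(is.na(vals)) || any(vals != round(vals)))
      td_stop(sprintf("%s: line %d: non-integer cell", path, i + 1L), "parse")
    rows[[i]] <- as.integer(vals[-1])
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    base::matrix(integer(), 0L, length(labels))
  track_table(entries, labels, seed_session = seed_session,
              strict_seed = strict_seed)
}

#' Assemble aligned traces for tracked cells
#'
#' Restricts a track table to complete (sentinel-free) tracks and gathers,
#' for every session, the trace matrix and centroids of the tracked cells in
#' identical row order: row `k` is the same putative cell in every session.
#' This cross-day alignment is what enables longitudinal analyses of the
#' same neurons.
#'
#' @param table a [track_table()] with one column per session.
#' @param sessions list of [session_record()].
#' @param complete_only keep only sentinel-free tracks (default). With
#'   `FALSE`, all tracks are kept and absent entries yield `NA` trace rows.
#' @return An object of class `tracked_dataset` with fields `track_table`
#'   (the restriction), `traces` (per-session aligned matrices), and
#'   `centroids` (per-session aligned `(row, col)` matrices in each
#'   session's native frame).
#' @export
extract_tracked_traces <- function(table, sessions, complete_only = TRUE) {
  if (ncol(table$entries) != length(sessions))
    td_validation_error(sprintf(
      "track table has %d sessions but %d records supplied",
      ncol(table$entries), length(sessions)))
  keep <- if (complete_only) complete_tracks(table) else
    rep(TRUE, nrow(table$entries))
  entries <- table$entries[keep, , drop = FALSE]
  for (s in seq_along(sessions)) {
    m <- length(sessions[[s]]$rois)
    bad <- which(entries[, s] >= m)
    if (length(bad))
      td_validation_error(sprintf(
        "track %d, session %s: ROI index %d out of range (%d ROIs)",
        which(keep)[bad[1]] - 1L, table$session_labels[s],
        entries[bad[1], s], m))
  }
  traces <- lapply(seq_along(sessions), function(s) {
    out <- base::matrix(NA_real_, nrow(entries), ncol(sessions[[s]]$traces))
    real <- entries[, s] >= 0L
    out[real, ] <- sessions[[s]]$traces[entries[real, s] + 1L, , drop = FALSE]
    out
  })
  centroids <- lapply(seq_along(sessions), function(s) {
    out <- base::matrix(NA_real_, nrow(entries), 2L,
                        dimnames = list(NULL, c("row", "col")))
    real <- which(entries[, s] >= 0L)
    for (k in real)
      out[k, ] <- sessions[[s]]$rois[[entries[k, s] + 1L]]$centroid
    out
  })
  structure(list(
    track_table = track_table(entries, table$session_labels,
                              seed_session = table$seed_session,
                              strict_seed = FALSE),
    traces = setNames(traces, table$session_labels),
    centroids = setNames(centroids, table$session_labels),
    frame_rate = sessions[[1]]$frame_rate,
    pixel_size_um = sessions[[1]]$pixel_size_um),
    class = "tracked_dataset")
}

#' @export
print.tracked_dataset <- function(x, ...) {
  cat(sprintf("<tracked_dataset> %d tracked cells x %d sessions\n",
              nrow(x$track_table$entries), length(x$traces)))
  invisible(x)
}
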