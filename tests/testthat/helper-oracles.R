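# Independent oracles used across the suite. These are deliberately naive
# implementations (enumeration, exhaustive scans, direct rendering) kept
# separate from the package's own code paths.

# brute-force linear sum assignment: enumerate all partial injections of
# the smaller dimension into the larger, return the minimal total cost
brute_force_lsap <- function(cost) {
  m <- nrow(cost); n <- ncol(cost)
  transposed <- m > n
  if (transposed) { cost <- t(cost); tmp <- m; m <- n; n <- tmp }
  best <- Inf
  cols <- seq_len(n)
  rec <- function(row, used, total) {
    if (total >= best) return()
    if (row > m) { best <<- total; return() }
    for (j in cols[!used]) {
      used[j] <- TRUE
      rec(row + 1L, used, total + cost[row, j])
      used[j] <- FALSE
    }
  }
  rec(1L, logical(n), 0)
  best
}

# exhaustive Otsu scan over interior edges of a fixed [0,1] histogram,
# same tie rule as the package documents (middle of the tied run)
otsu_scan <- function(values, n_bins = 256L) {
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  centres <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  best_sigma <- -Inf; best_ks <- integer(0)
  for (k in seq_len(n_bins - 1L)) {
    lo <- values[bin <= k]; hi <- values[bin > k]
    if (!length(lo) || !length(hi)) next
    n1 <- sum(bin <= k); n2 <- sum(bin > k)
    w1 <- n1 / length(values); w2 <- n2 / length(values)
    mu1 <- sum(centres[bin[bin <= k]]) / n1
    mu2 <- sum(centres[bin[bin > k]]) / n2
    sigma <- w1 * w2 * (mu1 - mu2)^2
    if (sigma > best_sigma + 1e-15) { best_sigma <- sigma; best_ks <- k }
    else if (abs(sigma - best_sigma) <= 1e-15) best_ks <- c(best_ks, k)
  }
  if (!length(best_ks)) return(NA_real_)
  edges[best_ks[ceiling(length(best_ks) / 2)] + 1L]
}

# independent Gaussian-blob renderer: sum of anisotropic Gaussians on the
# full pixel grid (no bounding boxes, no shared code with the package)
oracle_render <- function(cells, H, W) {
  img <- matrix(0, H, W)
  rows <- matrix(0:(H - 1), H, W)
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  q <- sqrt(2 * log(2))
  for (i in seq_len(nrow(cells))) {
    s1 <- cells$r_major[i] / q; s2 <- cells$r_minor[i] / q
    dr <- rows - cells$row[i]; dc <- cols - cells$col[i]
    co <- cos(cells$orientation[i]); si <- sin(cells$orientation[i])
    u <- (dr * co + dc * si) / s1
    v <- (-dr * si + dc * co) / s2
    img <- img + cells$peak[i] * exp(-(u^2 + v^2) / 2)
  }
  img
}

# random textured cell field for registration tests, plus its planted
# moving counterpart under scale/rotation/shift about the FOV centre
planted_pair <- function(seed, H = 192L, W = 192L, n_cells = 60L,
                         scale = 1, rot_deg = 0, shift = c(0, 0)) {
  set.seed(seed)
  cells <- data.frame(
    row = runif(n_cells, 8, H - 9), col = runif(n_cells, 8, W - 9),
    r_major = runif(n_cells, 3, 5), r_minor = runif(n_cells, 3, 5),
    orientation = runif(n_cells, 0, pi), peak = runif(n_cells, 0.5, 1))
  ref <- oracle_render(cells, H, W) +
    matrix(rnorm(H * W, 0, 0.03), H, W)
  th <- rot_deg * pi / 180
  A <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  C <- c((W - 1) / 2, (H - 1) / 2)
  t_vec <- shift + C - A %*% C
  truth <- affine_transform(cbind(A, t_vec))   # moving -> reference
  inv <- invert_transform(truth)
  mov_xy <- apply_transform(inv, cbind(cells$col, cells$row))
  mov_cells <- cells
  mov_cells$col <- mov_xy[, 1]; mov_cells$row <- mov_xy[, 2]
  mov_cells$r_major <- cells$r_major / scale
  mov_cells$r_minor <- cells$r_minor / scale
  mov_cells$orientation <- cells$orientation - th
  set.seed(seed + 1000L)
  mov <- oracle_render(mov_cells, H, W) + matrix(rnorm(H * W, 0, 0.03), H, W)
  list(ref = ref, mov = mov, truth = truth, shape = c(H, W))
}

# small hand-made mask
mk_mask <- function(id, px, shape = c(16L, 16L), ...) {
  roi_mask(id, matrix(as.integer(px), ncol = 2, byrow = TRUE),
           shape = shape, ...)
}

# toy session with square 2x2 cells at given (row, col) corners
toy_session <- function(corners, n_frames = 50L, shape = c(32L, 32L),
                        session_index = 0L, day_label = NULL, seed = 1L) {
  rois <- lapply(seq_len(nrow(corners)), function(i) {
    r <- corners[i, 1]; c <- corners[i, 2]
    mk_mask(i - 1L, c(r, c, r, c + 1L, r + 1L, c, r + 1L, c + 1L),
            shape = shape)
  })
  img <- matrix(0.1, shape[1], shape[2])
  for (m in rois) img[m$pixels + 1L] <- 1
  set.seed(seed)
  img <- img + matrix(rnorm(prod(shape), 0, 0.02), shape[1], shape[2])
  traces <- matrix(rnorm(length(rois) * n_frames), length(rois), n_frames)
  session_record(rois, traces, img, session_index = session_index,
                 day_label = day_label, frame_rate = 30)
}

# brute-force CT via row-tuple set intersection (evaluation oracle)
brute_force_ct <- function(gt_entries, pred_entries, seeds) {
  keyed <- function(m) apply(m, 1, paste, collapse = "|")
  pred <- pred_entries[pred_entries[, 1] %in% seeds, , drop = FALSE]
  pred <- pred[apply(pred, 1, function(r) all(r >= 0)), , drop = FALSE]
  T_rc <- length(intersect(keyed(gt_entries), keyed(pred)))
  2 * T_rc / (nrow(pred) + nrow(gt_entries))
}

pixel_strings <- function(px) paste(px[, 1], px[, 2])

# run the matching half of the pipeline with the generator's true
# transforms (bypassing registration); isolates matching from
# registration error
link_with_true_transforms <- function(ds, iou_floor = 0.10) {
  sessions <- ds$sessions
  tfs <- ds$ground_truth$transforms
  n <- length(sessions)
  n0 <- length(sessions[[1]]$rois)
  entries <- matrix(-1L, n0, n)
  entries[, 1] <- seq_len(n0) - 1L
  current <- entries[, 1]
  for (k in seq_len(n - 1L)) {
    warped <- lapply(sessions[[k + 1L]]$rois, warp_mask,
                     transform = tfs[[k]],
                     out_shape = sessions[[k]]$shape)
    cost <- build_cost_matrix(sessions[[k]]$rois, warped,
                              shape = sessions[[k]]$shape)
    a <- assign_matches(cost)
    ious <- 1 - cost$values[cbind(a[, 1] + 1L, a[, 2] + 1L)]
    ms <- filter_matches(a, ious, guarded_otsu_threshold(ious),
                         floor = iou_floor)
    acc <- ms$pairs[ms$pairs$accepted, , drop = FALSE]
    nxt <- rep(-1L, n0)
    alive <- which(current >= 0L)
    hit <- match(current[alive], acc$ref)
    nxt[alive[!is.na(hit)]] <- acc$mov[hit[!is.na(hit)]]
    current <- nxt
    entries[, k + 1L] <- current
  }
  track_table(entries, vapply(sessions, `[[`, "", "day_label"))
}
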