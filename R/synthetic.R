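# run expr under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a synthetic multi-session dataset
#'
#' Defines the study conditions the generator emulates: elliptical cells in
#' a field of view undergoing per-day affine growth (isotropic scaling
#' about the FOV centre, default 2.5 %/day -- compounding to roughly 15 %
#' over six day-steps, the growth scale reported for the second postnatal
#' week), small day-to-day rotation/translation jitter, independent
#' per-cell-per-day detection dropout, plus population activity with early
#' global synchrony transitioning to decorrelated, motion-coupled dynamics.
#'
#' @param n_cells number of cells in the catalogue.
#' @param n_sessions number of imaging days (>= 2).
#' @param fov_shape `(H, W)` in pixels.
#' @param growth per-day isotropic scale factor about the FOV centre.
#' @param rot_jitter_deg,trans_jitter_px uniform per-day jitter ranges.
#' @param dropout per-cell-per-day detection failure probability.
#' @param permanent_loss per-cell-per-day probability of permanent
#'   disappearance (emulating cell death; default 0).
#' @param noise_sd Gaussian noise sd added to mean images.
#' @param background mean-image background level.
#' @param radius_range,aspect_range,peak_range cell geometry/intensity
#'   ranges (half-peak footprint radius in px, axis ratio, peak intensity).
#' @param min_distance minimum centre-to-centre distance at placement (px).
#' @param margin placement margin from the FOV border (px).
#' @param anatomical_fraction fraction of cells bright in the sparse
#'   anatomical channel.
#' @param pixel_size_um pixel size (720 um / 512 px by default).
#' @param frame_rate imaging rate (Hz).
#' @param n_frames frames per session.
#' @param transition_session 0-based day index at which population activity
#'   switches from the synchronous to the motion-coupled regime.
#' @param private_rate per-cell private event rate (events/min).
#' @param sync_rate global synchronous-event rate on early days
#'   (events/min).
#' @param sync_prob probability that a cell joins a global event.
#' @param coupled_fraction fraction of cells motion-coupled on late days.
#' @param coupling_gain multiplicative motion modulation of coupled cells'
#'   rates.
#' @param calcium_tau exponential calcium-kernel decay (s).
#' @param trace_noise_sd Gaussian noise sd on traces.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 300L, n_sessions = 7L,
                           fov_shape = c(512L, 512L), growth = 1.025,
                           rot_jitter_deg = 1, trans_jitter_px = 2,
                           dropout = 0.05, permanent_loss = 0,
                           noise_sd = 0.05, background = 0.1,
                           radius_range = c(3, 5),
                           aspect_range = c(1, 1.4),
                           peak_range = c(0.5, 1),
                           min_distance = 14, margin = 8,
                           anatomical_fraction = 0.3,
                           pixel_size_um = 720 / 512,
                           frame_rate = 30, n_frames = 3000L,
                           transition_session = 3L,
                           private_rate = 2, sync_rate = 6,
                           sync_prob = 0.8, coupled_fraction = 0.4,
                           coupling_gain = 2, calcium_tau = 0.3,
                           trace_noise_sd = 0.05) {
  if (growth <= 0) td_validation_error("growth factor must be positive")
  if (dropout < 0 || dropout >= 1)
    td_validation_error("dropout must be in [0, 1)")
  if (n_sessions < 2L) td_validation_error("need at least 2 sessions")
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Place a catalogue of synthetic cells in the field of view
#'
#' Seeded rejection sampling of non-overlapping elliptical cells: centres
#' at least `min_distance` apart and `margin` pixels from the border, radii,
#' axis ratios, orientations and peak intensities drawn uniformly from the
#' spec's ranges. The catalogue order is the canonical ground-truth cell
#' identity.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_scene`: data frame `cells` with
#'   columns `row`, `col`, `r_major`, `r_minor`, `orientation`, `peak`,
#'   `anatomical`, plus `fov_shape`.
#' @export
generate_scene <- function(spec, seed = 0L) {
  H <- spec$fov_shape[1]; W <- spec$fov_shape[2]
  cells <- with_seed(seed, {
    centres <- base::matrix(numeric(), 0, 2)
    attempts <- 0L
    while (nrow(centres) < spec$n_cells) {
      attempts <- attempts + 1L
      if (attempts > 200L * max(spec$n_cells, 1L))
        td_stop(sprintf(
          "could not place %d cells with min distance %.1f px; use fewer cells or a larger FOV",
          spec$n_cells, spec$min_distance), "placement")
      p <- c(runif(1, spec$margin, H - 1 - spec$margin),
             runif(1, spec$margin, W - 1 - spec$margin))
      if (nrow(centres) == 0L ||
          min(sqrt((centres[, 1] - p[1])^2 + (centres[, 2] - p[2])^2)) >=
            spec$min_distance)
        centres <- rbind(centres, p)
    }
    n <- nrow(centres)
    r <- runif(n, spec$radius_range[1], spec$radius_range[2])
    aspect <- runif(n, spec$aspect_range[1], spec$aspect_range[2])
    data.frame(row = centres[, 1], col = centres[, 2],
               r_major = r * sqrt(aspect), r_minor = r / sqrt(aspect),
               orientation = runif(n, 0, pi),
               peak = runif(n, spec$peak_range[1], spec$peak_range[2]),
               anatomical = seq_len(n) <= round(spec$anatomical_fraction * n))
  })
  if (spec$n_cells == 0L)
    cells <- cells[integer(0), , drop = FALSE]
  structure(list(cells = cells, fov_shape = c(H, W)),
            class = "synthetic_scene")
}

# half-peak Mahalanobis radius of a Gaussian blob: exp(-q^2/2) = 1/2
HALF_PEAK_MAHA <- sqrt(2 * log(2))

# render one Gaussian cell into img (in place via return); returns the
# updated image and the cell's half-peak footprint pixels (0-based)
render_cell <- function(img, row0, col0, r_major, r_minor, orientation,
                        peak, want_mask = FALSE) {
  H <- nrow(img); W <- ncol(img)
  s1 <- r_major / HALF_PEAK_MAHA; s2 <- r_minor / HALF_PEAK_MAHA
  ext <- ceiling(3 * max(s1, s2))
  if (floor(row0 - ext) > H - 1L || ceiling(row0 + ext) < 0L ||
      floor(col0 - ext) > W - 1L || ceiling(col0 + ext) < 0L)
    return(list(img = img, mask = base::matrix(integer(), 0, 2)))
  rr <- max(0L, floor(row0 - ext)):min(H - 1L, ceiling(row0 + ext))
  cc <- max(0L, floor(col0 - ext)):min(W - 1L, ceiling(col0 + ext))
  dr <- outer(rr - row0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - col0)
  co <- cos(orientation); si <- sin(orientation)
  u <- (dr * co + dc * si) / s1
  v <- (-dr * si + dc * co) / s2
  q2 <- u^2 + v^2
  blob <- peak * exp(-q2 / 2)
  img[rr + 1L, cc + 1L] <- img[rr + 1L, cc + 1L] + blob
  mask <- NULL
  if (want_mask) {
    idx <- which(q2 <= HALF_PEAK_MAHA^2, arr.ind = TRUE)
    mask <- cbind(rr[idx[, 1]], cc[idx[, 2]])
  }
  list(img = img, mask = mask)
}

# per-day global transform: p -> C + R(theta_d) g^d (p - C) + t_d
day_transform <- function(day, growth, theta, trans, centre) {
  A <- base::matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)),
                    2, 2) * growth^day
  affine_transform(cbind(A, c(trans[1], trans[2]) + centre - A %*% centre))
}

#' Render the multi-session dataset from a cell catalogue
#'
#' Applies the per-day growth + jitter affine to the catalogue, renders the
#' functional (all cells) and anatomical (sparse bright subset) mean
#' images with Gaussian noise, derives ROI masks as the half-peak
#' footprints of the *noiseless* detected cells, applies per-cell-per-day
#' detection dropout (the cell stays visible in the mean image -- only its
#' ROI and trace are missing, emulating a segmentation failure), and fills
#' the traces via [generate_population_activity()]. Cells whose footprint
#' leaves the FOV are absent that day. Ground truth records every
#' correspondence, presence flag and true pairwise transform.
#'
#' @param scene a [generate_scene()] result.
#' @param spec the matching [synthetic_spec()].
#' @param seed integer RNG seed.
#' @return A list with `sessions` (list of [session_record()]) and
#'   `ground_truth` (class `synthetic_ground_truth`): fields `tracks`
#'   ([ground_truth_tracks()] over cells present on all days),
#'   `roi_index` (cells x sessions, -1 when absent), `presence`,
#'   `transforms` (true pairwise, moving `s_{k+1}` to reference `s_k`),
#'   `motion` (per-day traces), `coupling_weights`, `coupled_sessions`.
#' @export
render_sessions <- function(scene, spec, seed = 0L) {
  n_cells <- nrow(scene$cells)
  n_days <- spec$n_sessions
  H <- scene$fov_shape[1]; W <- scene$fov_shape[2]
  centre <- c((W - 1) / 2, (H - 1) / 2)   # (x, y)

  geom <- with_seed(seed + 1L, list(
    theta = c(0, runif(n_days - 1L, -1, 1) * spec$rot_jitter_deg * pi / 180),
    trans = rbind(c(0, 0),
                  base::matrix(runif(2L * (n_days - 1L), -1, 1) *
                                 spec$trans_jitter_px, ncol = 2)),
    dropped = base::matrix(runif(n_cells * n_days) < spec$dropout,
                           n_cells, n_days),
    lost = base::matrix(runif(n_cells * n_days) < spec$permanent_loss,
                        n_cells, n_days),
    img_noise_seeds = sample.int(.Machine$integer.max %/% 2L, n_days)))
  # permanent loss: once lost, lost forever (day 0 cells always start alive)
  lost <- geom$lost
  if (n_days > 1L) for (d in 2:n_days) lost[, d] <- lost[, d] | lost[, d - 1L]
  lost[, 1] <- FALSE

  day_tf <- lapply(seq_len(n_days) - 1L, function(d)
    day_transform(d, spec$growth, geom$theta[d + 1L],
                  geom$trans[d + 1L, ], centre))
  pair_tf <- if (n_days > 1L)
    lapply(seq_len(n_days - 1L), function(k)
      compose_transforms(day_tf[[k]], invert_transform(day_tf[[k + 1L]])))
  else list()

  presence <- base::matrix(FALSE, n_cells, n_days)
  roi_index <- base::matrix(-1L, n_cells, n_days)
  sessions <- vector("list", n_days)
  day_rois <- vector("list", n_days)
  images <- vector("list", n_days)

  for (d in seq_len(n_days)) {
    func <- base::matrix(spec$background, H, W)
    anat <- base::matrix(0, H, W)
    masks <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      if (lost[i, d]) next
      cell <- scene$cells[i, ]
      ctr <- apply_transform(day_tf[[d]], cbind(cell$col, cell$row))
      g <- spec$growth^(d - 1L)
      want <- !geom$dropped[i, d]
      res <- render_cell(func, ctr[2], ctr[1],
                         cell$r_major * g, cell$r_minor * g,
                         cell$orientation + geom$theta[d],
                         cell$peak, want_mask = want)
      func <- res$img
      if (cell$anatomical)
        anat <- render_cell(anat, ctr[2], ctr[1],
                            cell$r_major * g, cell$r_minor * g,
                            cell$orientation + geom$theta[d],
                            cell$peak)$img
      if (want && nrow(res$mask) > 0L) {
        presence[i, d] <- TRUE
        masks[[i]] <- res$mask
      }
    }
    present <- which(presence[, d])
    roi_index[present, d] <- seq_along(present) - 1L
    day_rois[[d]] <- lapply(seq_along(present), function(j)
      roi_mask(j - 1L, masks[[present[j]]], shape = c(H, W)))
    images[[d]] <- with_seed(geom$img_noise_seeds[d], list(
      func = func + base::matrix(rnorm(H * W, 0, spec$noise_sd), H, W),
      anat = anat + base::matrix(rnorm(H * W, 0, spec$noise_sd), H, W)))
  }

  gt_rows <- which(rowSums(presence) == n_days)
  gt <- structure(list(
    tracks = ground_truth_tracks(
      roi_index[gt_rows, , drop = FALSE],
      session_labels = paste0("day", seq_len(n_days) - 1L)),
    roi_index = roi_index, presence = presence,
    transforms = pair_tf, day_transforms = day_tf,
    scene = scene, motion = NULL, coupling_weights = NULL,
    coupled_sessions = which(seq_len(n_days) - 1L >=
                               spec$transition_session)),
    class = "synthetic_ground_truth")

  act <- generate_population_activity(gt, spec, seed + 2L)
  gt$motion <- act$motion
  gt$coupling_weights <- act$coupling_weights

  for (d in seq_len(n_days)) {
    sessions[[d]] <- session_record(
      rois = day_rois[[d]], traces = act$traces[[d]],
      mean_image_functional = images[[d]]$func,
      mean_image_anatomical = images[[d]]$anat,
      session_index = d - 1L, day_label = paste0("day", d - 1L),
      frame_rate = spec$frame_rate, pixel_size_um = spec$pixel_size_um)
  }
  list(sessions = sessions, ground_truth = gt)
}

#' Generate population activity and motion traces
#'
#' Per cell and day, spikes are private Poisson events plus, on early days,
#' global synchronous events shared across cells, and, on late days,
#' events whose rate is modulated by a simulated motion trace through
#' per-cell coupling weights (weights are fixed across days, emulating a
#' stable representation once it emerges). Spike trains are convolved with
#' an exponential calcium kernel and Gaussian noise is added. The motion
#' trace is a rectified, smoothed Gaussian process.
#'
#' @param ground_truth a `synthetic_ground_truth` (presence flags are
#'   used to shape the per-day trace matrices).
#' @param spec the matching [synthetic_spec()].
#' @param seed integer RNG seed.
#' @return List with `traces` (per-day `n_present x n_frames` matrices),
#'   `motion` (per-day vectors, length `n_frames`), `coupling_weights`
#'   (per-cell, 0 for uncoupled cells).
#' @export
generate_population_activity <- function(ground_truth, spec, seed = 0L) {
  presence <- ground_truth$presence
  n_cells <- nrow(presence); n_days <- ncol(presence)
  fr <- spec$frame_rate; T_ <- spec$n_frames
  kern <- exp(-(seq_len(ceiling(5 * spec$calcium_tau * fr)) - 1L) /
                (spec$calcium_tau * fr))
  with_seed(seed, {
    w <- numeric(n_cells)
    coupled <- if (n_cells > 0L)
      sample.int(n_cells, round(spec$coupled_fraction * n_cells)) else integer(0)
    w[coupled] <- runif(length(coupled), 0.5, 1.5) * spec$coupling_gain
    motion <- vector("list", n_days)
    traces <- vector("list", n_days)
    gauss <- dnorm(seq(-2, 2, length.out = 2L * fr + 1L))
    gauss <- gauss / sum(gauss)
    for (d in seq_len(n_days)) {
      # rectified smoothed Gaussian process, ~1 s correlation length
      pad <- length(gauss)
      z <- stats::convolve(rnorm(T_ + 2L * pad), rev(gauss), type = "open")
      z <- z[pad + (seq_len(T_))]
      z <- z / max(sd(z), 1e-12)
      motion[[d]] <- pmax(z, 0)
      late <- (d - 1L) >= spec$transition_session
      sync_events <- if (!late)
        runif(T_) < spec$sync_rate / 60 / fr else rep(FALSE, T_)
      present <- which(presence[, d])
      tr <- base::matrix(0, length(present), T_)
      for (j in seq_along(present)) {
        i <- present[j]
        rate <- rep(spec$private_rate / 60 / fr, T_)
        if (late && w[i] > 0) rate <- rate * (1 + w[i] * motion[[d]])
        spikes <- rpois(T_, rate)
        if (!late) spikes <- spikes + (sync_events &
                                         runif(T_) < spec$sync_prob)
        amp <- spikes * runif(T_, 0.8, 1.2)
        s <- stats::convolve(amp, rev(kern), type = "open")
        tr[j, ] <- s[seq_len(T_)] + rnorm(T_, 0, spec$trace_noise_sd)
      }
      traces[[d]] <- tr
    }
    list(traces = traces, motion = motion, coupling_weights = w)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: [generate_scene()] then [render_sessions()].
#' Identical spec and seed give bit-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer master seed.
#' @return As [render_sessions()].
#' @export
simulate_dataset <- function(spec = synthetic_spec(), seed = 0L) {
  render_sessions(generate_scene(spec, seed), spec, seed)
}

#' Write a synthetic dataset in the canonical on-disk layout
#'
#' Emits one directory per session (see [write_session()]) plus
#' `ground_truth.csv` (track-table dialect), `true_transforms.csv`
#' (`pair,a11,a12,a13,a21,a22,a23`) and `motion.csv` (frames x days).
#'
#' @param dataset a [simulate_dataset()] result.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (d in seq_along(dataset$sessions))
    write_session(dataset$sessions[[d]],
                  file.path(path, sprintf("day%d", d - 1L)))
  gt <- dataset$ground_truth
  write_track_table(
    track_table(gt$tracks$entries, gt$tracks$session_labels),
    file.path(path, "ground_truth.csv"))
  tf <- do.call(rbind, lapply(seq_along(gt$transforms), function(k) {
    m <- gt$transforms[[k]]$matrix
    data.frame(pair = sprintf("day%d->day%d", k, k - 1L),
               a11 = m[1, 1], a12 = m[1, 2], a13 = m[1, 3],
               a21 = m[2, 1], a22 = m[2, 2], a23 = m[2, 3])
  }))
  utils::write.csv(tf, file.path(path, "true_transforms.csv"),
                   row.names = FALSE)
  mo <- as.data.frame(do.call(cbind, gt$motion))
  names(mo) <- paste0("day", seq_along(gt$motion) - 1L)
  utils::write.csv(mo, file.path(path, "motion.csv"), row.names = FALSE)
  invisible(path)
}
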