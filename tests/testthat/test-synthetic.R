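small_spec <- function(...) {
  synthetic_spec(n_cells = 40L, n_sessions = 3L, fov_shape = c(128L, 128L),
                 min_distance = 14, n_frames = 200L, ...)
}

test_that("scene generation respects placement constraints and seeds", {
  spec <- small_spec()
  sc <- generate_scene(spec, seed = 3)
  expect_equal(nrow(sc$cells), 40L)
  d <- as.matrix(dist(sc$cells[, c("row", "col")]))
  diag(d) <- Inf
  expect_gte(min(d), spec$min_distance)
  expect_true(all(sc$cells$row >= spec$margin &
                    sc$cells$row <= 127 - spec$margin))
  # determinism and the empty catalogue
  expect_identical(generate_scene(spec, seed = 3), sc)
  sc0 <- generate_scene(synthetic_spec(n_cells = 0L, n_sessions = 2L,
                                       fov_shape = c(64L, 64L)), seed = 1)
  expect_equal(nrow(sc0$cells), 0L)
  # an impossible packing fails with advice
  expect_error(generate_scene(
    synthetic_spec(n_cells = 500L, fov_shape = c(64L, 64L),
                   min_distance = 20), seed = 1), "fewer cells")
})

test_that("rendering is deterministic and internally consistent", {
  spec <- small_spec()
  a <- simulate_dataset(spec, seed = 5)
  b <- simulate_dataset(spec, seed = 5)
  expect_identical(a$sessions[[2]]$mean_image_functional,
                   b$sessions[[2]]$mean_image_functional)
  expect_identical(a$sessions[[3]]$traces, b$sessions[[3]]$traces)
  gt <- a$ground_truth
  for (d in seq_along(a$sessions)) {
    s <- a$sessions[[d]]
    expect_equal(length(s$rois), sum(gt$presence[, d]))
    expect_equal(nrow(s$traces), length(s$rois))
    # every present cell has exactly one ROI index that day
    ids <- gt$roi_index[gt$presence[, d], d]
    expect_setequal(ids, seq_along(ids) - 1L)
  }
  # ground-truth tracks cover exactly the cells present every day
  expect_equal(nrow(gt$tracks$entries), sum(rowSums(gt$presence) == 3L))
})

test_that("degenerate spec collapses to identical sessions with CT = 1", {
  spec <- synthetic_spec(n_cells = 30L, n_sessions = 3L,
                         fov_shape = c(128L, 128L), growth = 1,
                         rot_jitter_deg = 0, trans_jitter_px = 0,
                         dropout = 0, noise_sd = 0, min_distance = 14,
                         n_frames = 100L)
  ds <- simulate_dataset(spec, seed = 2)
  expect_identical(ds$sessions[[1]]$mean_image_functional,
                   ds$sessions[[2]]$mean_image_functional)
  expect_identical(
    lapply(ds$sessions[[1]]$rois, `[[`, "pixels"),
    lapply(ds$sessions[[3]]$rois, `[[`, "pixels"))
  res <- link_with_true_transforms(ds)
  expect_equal(compute_ct(ds$ground_truth$tracks, res)$ct, 1.0)
})

test_that("planted growth appears in pairwise distances and transforms", {
  spec <- synthetic_spec(n_cells = 120L, n_sessions = 7L, dropout = 0,
                         n_frames = 60L)
  ds <- simulate_dataset(spec, seed = 13)
  gt <- ds$ground_truth
  tracked <- extract_tracked_traces(
    track_table(gt$tracks$entries, gt$tracks$session_labels), ds$sessions)
  growth <- pairwise_distance_growth(tracked)
  expect_equal(growth[7], 1.025^6, tolerance = 0.01)
  # the true pairwise transform's linear part has determinant 1/g^2
  for (k in seq_along(gt$transforms))
    expect_equal(det(gt$transforms[[k]]$matrix[, 1:2]), 1 / 1.025^2,
                 tolerance = 1e-10)
})

test_that("dropout thins detections at the binomial rate", {
  spec <- synthetic_spec(n_cells = 100L, n_sessions = 2L, dropout = 0.5,
                         fov_shape = c(256L, 256L), min_distance = 14,
                         n_frames = 60L)
  ds <- simulate_dataset(spec, seed = 23)
  n1 <- length(ds$sessions[[2]]$rois)
  # binomial(100, 0.5): within 3 sigma of the mean
  expect_gt(n1, 50 - 3 * 5); expect_lt(n1, 50 + 3 * 5)
})

test_that("population activity follows its regime parameters", {
  # pure private Poisson: no synchrony, no coupling
  spec <- synthetic_spec(n_cells = 30L, n_sessions = 2L,
                         fov_shape = c(128L, 128L), min_distance = 14,
                         n_frames = 3000L, dropout = 0,
                         sync_rate = 0, coupled_fraction = 0,
                         private_rate = 6, trace_noise_sd = 0.02)
  ds <- simulate_dataset(spec, seed = 31)
  # expected 6 events/min over 100 s -> lambda = 10 per cell
  rates <- vapply(seq_len(30), function(i)
    event_rate(ds$sessions[[1]]$traces[i, ], frame_rate = 30), numeric(1))
  lambda <- 10
  expect_lt(abs(mean(rates) * 100 / 60 - lambda), 3 * sqrt(lambda / 30))
  # early synchrony beats late decorrelation in mean pairwise correlation
  spec2 <- synthetic_spec(n_cells = 30L, n_sessions = 2L,
                          fov_shape = c(128L, 128L), min_distance = 14,
                          n_frames = 2000L, dropout = 0,
                          transition_session = 1L)
  ds2 <- simulate_dataset(spec2, seed = 37)
  mean_offdiag <- function(m) {
    v <- pairwise_fc(m)$values; mean(v[upper.tri(v)], na.rm = TRUE)
  }
  expect_gt(mean_offdiag(ds2$sessions[[1]]$traces),
            mean_offdiag(ds2$sessions[[2]]$traces))
})

test_that("a dataset written to disk reloads identically", {
  spec <- synthetic_spec(n_cells = 12L, n_sessions = 2L,
                         fov_shape = c(64L, 64L), min_distance = 12,
                         n_frames = 40L)
  ds <- simulate_dataset(spec, seed = 41)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  expect_true(file.exists(file.path(dir, "true_transforms.csv")))
  loaded <- suppressMessages(
    load_dataset(file.path(dir, c("day0", "day1"))))
  expect_equal(length(loaded[[1]]$rois), length(ds$sessions[[1]]$rois))
  expect_equal(loaded[[2]]$traces, ds$sessions[[2]]$traces,
               tolerance = 1e-6)
  gt_back <- read_track_table(file.path(dir, "ground_truth.csv"))
  expect_identical(gt_back$entries, ds$ground_truth$tracks$entries)
})
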