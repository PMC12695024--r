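test_that("IoU matches hand-enumerated pixel sets", {
  a <- mk_mask(0L, c(0, 0, 0, 1, 1, 0))
  b <- mk_mask(1L, c(0, 1, 1, 0, 1, 1))
  expect_equal(compute_iou(a, b), 0.5)   # |∩| = 2, |∪| = 4
  expect_equal(compute_iou(b, a), 0.5)
  expect_equal(compute_iou(a, a), 1.0)
  far <- mk_mask(2L, c(9, 9, 9, 10))
  expect_equal(compute_iou(a, far), 0.0)
  empty <- roi_mask(3L, matrix(integer(), 0, 2), out_of_bounds = TRUE)
  expect_equal(compute_iou(a, empty), 0.0)
})

test_that("cost matrices enumerate 1 - IoU for all pairs", {
  a1 <- mk_mask(0L, c(0, 0, 0, 1, 1, 0))
  a2 <- mk_mask(1L, c(9, 9, 9, 10))
  b1 <- mk_mask(0L, c(0, 1, 1, 0, 1, 1))
  b2 <- mk_mask(1L, c(12, 12, 12, 13))
  cm <- build_cost_matrix(list(a1, a2), list(b1, b2))
  expect_equal(cm$values,
               rbind(c(0.5, 1), c(1, 1)))      # a2/b2 disjoint everywhere
  single <- build_cost_matrix(list(a1), list(a1))
  expect_equal(single$values, matrix(0, 1, 1))
  expect_equal(dim(build_cost_matrix(list(), list(b1, b2),
                                     shape = c(16, 16))$values), c(0L, 2L))
  # empty warped mask -> full-cost column
  empty <- roi_mask(5L, matrix(integer(), 0, 2), out_of_bounds = TRUE)
  cm2 <- build_cost_matrix(list(a1, a2), list(empty), shape = c(16, 16))
  expect_equal(cm2$values, matrix(1, 2, 1))
})

test_that("assignment solves hand-checkable cases", {
  pairs <- assign_matches(rbind(c(0.1, 0.9), c(0.9, 0.2)))
  expect_equal(pairs, cbind(ref = 0:1, mov = 0:1))
  # zero-diagonal square -> diagonal assignment
  z <- matrix(0.7, 4, 4); diag(z) <- 0
  expect_equal(assign_matches(z)[, "mov"], 0:3)
  # 2 rows x 1 column: only the cheaper row is assigned
  tall <- assign_matches(matrix(c(0.3, 0.1), 2, 1))
  expect_equal(tall, cbind(ref = 1L, mov = 0L))
  expect_equal(nrow(assign_matches(matrix(numeric(), 0, 3))), 0L)
})

test_that("assignment total cost equals brute-force enumeration exactly", {
  set.seed(501)
  for (rep in 1:200) {
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    cost <- matrix(round(runif(m * n), 3), m, n)
    pairs <- assign_matches(cost)
    expect_equal(nrow(pairs), min(m, n))
    expect_false(anyDuplicated(pairs[, 1]) > 0)
    expect_false(anyDuplicated(pairs[, 2]) > 0)
    total <- sum(cost[pairs + 1L])
    expect_equal(total, brute_force_lsap(cost), tolerance = 1e-12)
  }
})

test_that("otsu threshold separates the planted bimodal example", {
  th <- otsu_threshold(c(0.05, 0.06, 0.07, 0.75, 0.80, 0.85))
  expect_gt(th, 0.07); expect_lte(th, 0.75)
  th2 <- otsu_threshold(c(0.1, 0.9))
  expect_gt(th2, 0.1); expect_lte(th2, 0.9)
  deg <- otsu_threshold(rep(0.4, 5))
  expect_true(is.na(deg))
  expect_true(attr(deg, "degenerate"))
  expect_true(is.na(otsu_threshold(0.3)))
})

test_that("otsu equals the exhaustive between-class-variance scan", {
  set.seed(601)
  for (rep in 1:100) {
    n_lo <- sample(5:40, 1); n_hi <- sample(5:40, 1)
    vals <- pmin(pmax(c(rnorm(n_lo, 0.08, 0.04), rnorm(n_hi, 0.8, 0.08)),
                      0), 1)
    expect_identical(as.numeric(otsu_threshold(vals)), otsu_scan(vals))
  }
})

test_that("the guard rejects splits whose low class is not false-like", {
  set.seed(605)
  # bimodal: false matches near zero, true matches high -> split trusted
  bimodal <- c(runif(20, 0, 0.1), runif(80, 0.7, 0.95))
  th <- guarded_otsu_threshold(bimodal)
  expect_false(is.na(th))
  expect_identical(as.numeric(th), as.numeric(otsu_threshold(bimodal)))
  # unimodal true matches: any split cuts high-IoU pairs -> degenerate
  unimodal <- runif(100, 0.6, 0.95)
  g <- guarded_otsu_threshold(unimodal)
  expect_true(is.na(g))
  expect_true(attr(g, "degenerate"))
  expect_gt(attr(g, "reject_mean_iou"), 0.3)
})

test_that("match filtering honours threshold, floor and degeneracy", {
  a <- cbind(ref = 0:1, mov = c(3L, 1L))
  ms <- filter_matches(a, c(0.8, 0.05), threshold = 0.4, floor = 0.1)
  expect_equal(ms$pairs$accepted, c(TRUE, FALSE))
  expect_equal(ms$threshold, 0.4)
  # degenerate otsu falls back to the floor
  ms2 <- filter_matches(a, c(0.5, 0.05), threshold = NA_real_, floor = 0.1)
  expect_equal(ms2$pairs$accepted, c(TRUE, FALSE))
  expect_equal(ms2$threshold, 0.1)
  ms3 <- filter_matches(a, c(0.8, 0.7), threshold = 0.4, floor = 0.1)
  expect_true(all(ms3$pairs$accepted))
})

test_that("byte-identical sessions track perfectly end to end", {
  s <- toy_session(cbind(c(4L, 10L, 20L, 26L), c(4L, 22L, 8L, 25L)))
  s2 <- s; s2$session_index <- 1L; s2$day_label <- "d1"
  res <- link_sessions(list(s, s2), track_control(channel = "functional",
                                                  verbose = FALSE))
  expect_equal(res$track_table$entries, cbind(0:3, 0:3))
  expect_true(all(res$match_sets[[1]]$pairs$iou == 1))
  expect_equal(sum(trackdev:::complete_tracks(res$track_table)), 4L)
})

test_that("tracks terminate on dropout and never resume", {
  spec <- synthetic_spec(n_cells = 60L, n_sessions = 4L,
                         fov_shape = c(160L, 160L), min_distance = 14,
                         dropout = 0.15, n_frames = 120L)
  ds <- simulate_dataset(spec, seed = 9)
  # bypass registration with the true transforms: isolates matching
  res <- link_with_true_transforms(ds)
  tbl <- res$entries
  for (k in seq_len(nrow(tbl))) {
    real <- which(tbl[k, ] >= 0L)
    expect_identical(real, seq(min(real), max(real)))
  }
  # one-to-one per column
  for (s in seq_len(ncol(tbl)))
    expect_false(anyDuplicated(tbl[tbl[, s] >= 0L, s]) > 0)
})

test_that("complete-track count degrades monotonically with dropout", {
  counts <- vapply(c(0, 0.15, 0.3), function(p) {
    spec <- synthetic_spec(n_cells = 60L, n_sessions = 4L,
                           fov_shape = c(160L, 160L), min_distance = 14,
                           dropout = p, n_frames = 120L)
    ds <- simulate_dataset(spec, seed = 17)
    tbl <- link_with_true_transforms(ds)
    sum(rowSums(tbl$entries < 0L) == 0L)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # zero dropout with true transforms is the geometry oracle: CT = 1
  spec0 <- synthetic_spec(n_cells = 60L, n_sessions = 4L,
                          fov_shape = c(160L, 160L), min_distance = 14,
                          dropout = 0, n_frames = 120L)
  ds0 <- simulate_dataset(spec0, seed = 17)
  tbl0 <- link_with_true_transforms(ds0)
  expect_equal(compute_ct(ds0$ground_truth$tracks, tbl0)$ct, 1.0)
})
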