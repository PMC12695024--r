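test_that("motion energy reproduces hand arithmetic", {
  const <- array(0.5, c(4, 4, 5))
  expect_equal(motion_energy(const)$values, rep(0, 4))
  f <- array(0, c(2, 2, 2)); f[, , 2] <- 1
  expect_equal(motion_energy(f)$values, 4)  # 4 pixels x 1^2
  g <- array(0, c(3, 3, 2)); g[2, 2, 2] <- 3
  expect_equal(motion_energy(g)$values, 9)
  expect_error(motion_energy(array(0, c(2, 2, 1))), ">= 2")
})

test_that("event detection counts planted transients exactly", {
  expect_equal(event_rate(rep(0, 1800)), 0)
  # 1 minute at 30 Hz with 4 well-separated transients, amplitude 10x the
  # noise floor
  set.seed(91)
  tr <- rnorm(1800, 0, 0.02)
  tau <- 9  # frames
  onsets <- c(200, 600, 1100, 1500)
  for (o in onsets)
    tr[o:1800] <- tr[o:1800] + 0.8 * exp(-(seq(o, 1800) - o) / tau)
  det <- detect_events(tr, frame_rate = 30)
  expect_equal(length(det$events), 4L)
  expect_equal(det$rate, 4.0)
  # a threshold above the transient amplitude silences the detector
  expect_equal(event_rate(tr, k_sd = 50), 0)
  # zero-variance trace is a no-event case, not an error
  expect_equal(detect_events(rep(1, 100))$rate, 0)
})

test_that("planted transients are recovered exactly across rates", {
  # well above noise, >= 1 s apart: counts match the construction exactly
  set.seed(92)
  for (n_events in c(2, 6, 10)) {
    tr <- rnorm(3600, 0, 0.02)
    onsets <- seq(100, 3300, length.out = n_events)
    for (o in onsets)
      tr[o:3600] <- tr[o:3600] + 1.0 * exp(-(seq(o, 3600) - o) / 9)
    expect_equal(length(detect_events(tr, 30)$events), n_events)
  }
})

test_that("pairwise FC behaves like Pearson correlation with flags", {
  set.seed(93)
  base <- rnorm(500)
  tr <- rbind(base, base, -base, rnorm(500))
  fc <- pairwise_fc(tr)
  expect_equal(fc$values[1, 2], 1)
  expect_equal(fc$values[1, 3], -1)
  expect_lt(abs(fc$values[1, 4]), 0.15)
  expect_equal(fc$values, t(fc$values))
  # zero-variance row flagged and NA
  tr2 <- rbind(rnorm(100), rep(1, 100), rnorm(100))
  fc2 <- pairwise_fc(tr2)
  expect_false(fc2$valid[2])
  expect_true(all(is.na(fc2$values[2, ])))
})

test_that("distance profile recovers a planted exponential intercept", {
  set.seed(94)
  n <- 40
  cent <- cbind(runif(n, 0, 200), runif(n, 0, 200))
  dmat <- as.matrix(dist(cent))
  # correlations generated exactly from the model at each pair's bin centre
  bin_centre <- function(d) (floor(d / 30) + 0.5) * 30
  vals <- 0.6 * exp(-bin_centre(dmat) / 50) + 0.1
  diag(vals) <- 1
  fc <- structure(list(values = vals, valid = rep(TRUE, n),
                       centroids = cent), class = "fc_matrix")
  prof <- distance_profile(fc, pixel_size_um = 1)
  expect_equal(prof$neighbor_correlation, 0.7, tolerance = 1e-3)
  expect_equal(unname(prof$fit["lambda"]), 50, tolerance = 1e-2)
  # constant correlations: a ~ 0, intercept ~ the constant
  vals_c <- matrix(0.25, n, n); diag(vals_c) <- 1
  fc_c <- structure(list(values = vals_c, valid = rep(TRUE, n),
                         centroids = cent), class = "fc_matrix")
  prof_c <- distance_profile(fc_c, pixel_size_um = 1)
  expect_equal(prof_c$neighbor_correlation, 0.25, tolerance = 1e-6)
  # single occupied bin: warning, no fit
  tight <- structure(list(values = vals_c[1:5, 1:5],
                          valid = rep(TRUE, 5),
                          centroids = cent[1:5, ] / 40),
                     class = "fc_matrix")
  expect_warning(pr <- distance_profile(tight, pixel_size_um = 1),
                 "fit skipped")
  expect_true(is.na(pr$neighbor_correlation))
})

test_that("FC similarity is a correlation over strict upper triangles", {
  set.seed(95)
  n <- 50
  V <- cor(matrix(rnorm(40 * n), 40, n))
  fa <- structure(list(values = V, valid = rep(TRUE, n)),
                  class = "fc_matrix")
  expect_equal(fc_similarity(fa, fa), 1.0)
  neg <- -V; diag(neg) <- 1
  fb <- structure(list(values = neg, valid = rep(TRUE, n)),
                  class = "fc_matrix")
  expect_equal(fc_similarity(fa, fb), -1.0)
  expect_equal(fc_similarity(fa, fb), fc_similarity(fb, fa))
  # independent random symmetric matrices decorrelate (1225 pairs)
  W <- cor(matrix(rnorm(40 * n), 40, n))
  fw <- structure(list(values = W, valid = rep(TRUE, n)),
                  class = "fc_matrix")
  expect_lt(abs(fc_similarity(fa, fw)), 0.15)
  expect_error(fc_similarity(fa, structure(list(
    values = V[1:10, 1:10], valid = rep(TRUE, 10)), class = "fc_matrix")),
    "dimension")
})

test_that("within-session similarity reflects population structure", {
  set.seed(96)
  n <- 30; T_ <- 2000; k <- 4
  L <- matrix(rnorm(n * k), n, k)
  z <- matrix(rnorm(k * T_), k, T_)
  structured <- L %*% z + matrix(rnorm(n * T_, 0, 0.2), n, T_)
  expect_gt(within_session_similarity(structured), 0.9)
  noise <- matrix(rnorm(n * T_), n, T_)
  expect_lt(abs(within_session_similarity(noise)), 0.2)
  # duplicated half gives exactly 1
  half <- matrix(rnorm(n * 500), n, 500)
  expect_equal(within_session_similarity(cbind(half, half)), 1.0)
})

test_that("similarity matrices expose two-regime block structure", {
  set.seed(97)
  n <- 30; T_ <- 1500; k <- 5
  LA <- matrix(rnorm(n * k), n, k); LB <- matrix(rnorm(n * k), n, k)
  mk_day <- function(L) L %*% matrix(rnorm(k * T_), k, T_) +
    matrix(rnorm(n * T_, 0, 0.3), n, T_)
  traces <- list(d0 = mk_day(LA), d1 = mk_day(LA),
                 d2 = mk_day(LB), d3 = mk_day(LB))
  tracked <- structure(list(traces = traces), class = "tracked_dataset")
  sm <- similarity_matrix(tracked)
  expect_equal(dim(sm$values), c(4L, 4L))
  expect_equal(sm$values, t(sm$values))
  within_block <- c(sm$values[1, 2], sm$values[3, 4])
  cross_block <- c(sm$values[1, 3], sm$values[1, 4],
                   sm$values[2, 3], sm$values[2, 4])
  expect_gt(mean(within_block) - mean(cross_block), 0.3)
  # identical traces every day: everything is 1
  same <- structure(list(traces = list(a = traces$d0, b = traces$d0)),
                    class = "tracked_dataset")
  expect_equal(similarity_matrix(same)$values,
               matrix(c(similarity_matrix(same)$values[1, 1], 1, 1,
                        similarity_matrix(same)$values[2, 2]), 2, 2),
               tolerance = 1e-12)
  expect_equal(similarity_matrix(same)$values[1, 2], 1.0)
})

test_that("dimensionality counts principal components as the rank oracle", {
  set.seed(98)
  sig <- rnorm(800)
  copies <- matrix(rep(sig, 10), 10, byrow = TRUE)
  expect_equal(dimensionality(copies), 1L)
  # 10 equal-variance orthogonal latents spread over many neurons:
  # eigenvalues equal, so 9 components reach exactly 90 %
  k <- 10; T_ <- 1000
  z <- qr.Q(qr(matrix(rnorm(T_ * k), T_, k)))          # orthonormal in time
  mix <- qr.Q(qr(matrix(rnorm(40 * 40), 40, 40)))[, 1:k]  # orthonormal mixing
  pop <- mix %*% t(z)
  expect_equal(dimensionality(pop), 9L)
  # isotropic noise keeps nearly the full spectrum
  iso <- matrix(rnorm(20 * 20000), 20, 20000)
  expect_gte(dimensionality(iso), 18L)
  expect_error(dimensionality(matrix(1, 5, 100)), "zero-variance")
  # oracle: eigen-spectrum computed directly
  m <- matrix(rnorm(15 * 400), 15, 400) * sqrt(seq(4, 0.1, length.out = 15))
  ev <- eigen(cov(t(m - rowMeans(m))), only.values = TRUE)$values
  oracle <- which(cumsum(ev) / sum(ev) >= 0.9)[1]
  expect_equal(dimensionality(m), oracle)
})

test_that("PC1 tracks motion when the population is motion-driven", {
  set.seed(99)
  motion <- pmax(stats::filter(rnorm(1200), rep(0.2, 5), sides = 2), 0)
  motion[is.na(motion)] <- 0
  pop <- matrix(rep(as.numeric(motion), 25), 25, byrow = TRUE) +
    matrix(rnorm(25 * 1200, 0, 0.01), 25, 1200)
  r <- pc1_motion_correlation(pop, as.numeric(motion))
  expect_gte(r$abs_r, 0.99)
  null_pop <- matrix(rnorm(25 * 1200), 25, 1200)
  expect_lt(pc1_motion_correlation(null_pop, as.numeric(motion))$abs_r, 0.2)
  expect_error(pc1_motion_correlation(pop, rep(1, 1200)), "zero variance")
})

test_that("sigmoid transition fitting recovers planted parameters", {
  days <- 8:14
  y <- 0.2 + (0.8 - 0.2) / (1 + exp(2 * (days - 11)))
  fit <- fit_transition(y, days, upper_limit = 0.8)
  expect_true(fit$converged)
  expect_equal(fit$transition_age, 11, tolerance = 0.05)
  expect_equal(fit$k, 2, tolerance = 0.05)
  expect_equal(fit$b, 0.2, tolerance = 0.01)
  # transition time against the closed-form logistic: the inner extrema of
  # the 4th derivative solve d5 = 0; locate them from the analytic
  # expression independently
  expr4 <- quote(0.2 + 0.6 / (1 + exp(2 * (t - 11))))
  for (i in 1:4) expr4 <- stats::D(expr4, "t")
  d4 <- function(t) eval(expr4, list(t = t))
  # y'''' vanishes at t0 and symmetrically at t0 +/- u; the inner extrema
  # flanking t0 sit between those zeros
  zero_right <- stats::uniroot(d4, c(11.05, 13))$root
  inner_left <- stats::optimize(function(t) -abs(d4(t)),
                                c(2 * 11 - zero_right + 1e-3, 11 - 1e-3))
  expect_equal(fit$transition_time, 2 * (11 - inner_left$minimum),
               tolerance = 0.05)
  # flat input fails honestly
  expect_false(fit_transition(rep(0.5, 7), days, 0.8)$converged)
})

test_that("noisy transition fits stay within half a day (median)", {
  days <- 8:14
  clean <- 0.2 + 0.6 / (1 + exp(2 * (days - 11)))
  set.seed(101)
  err <- replicate(20, {
    fit <- fit_transition(clean + rnorm(7, 0, 0.05), days, upper_limit = 0.8)
    abs(fit$transition_age - 11)
  })
  expect_lte(median(err), 0.5)
})
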