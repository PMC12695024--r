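#' Motion energy from a behaviour video
#'
#' For each pair of consecutive frames, the pixel-wise difference is
#' squared and summed across pixels, giving one nonnegative scalar per
#' frame transition -- a proxy for the animal's global movement/arousal.
#'
#' @param frames 3-D array `H x W x T` or list of `T` matrices, `T >= 2`.
#' @param frame_rate acquisition rate (Hz), carried on the result.
#' @return An object of class `motion_trace`: `values` of length `T - 1`
#'   and `frame_rate`.
#' @export
motion_energy <- function(frames, frame_rate = 30) {
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) != 3L || dim(frames)[3] < 2L)
    td_usage_error("motion_energy needs a stack of >= 2 equally sized frames")
  T_ <- dim(frames)[3]
  vals <- vapply(seq_len(T_ - 1L), function(t)
    sum((frames[, , t + 1L] - frames[, , t])^2), numeric(1))
  structure(list(values = vals, frame_rate = frame_rate),
            class = "motion_trace")
}

# non-overlapping boxcar mean; trailing remainder dropped
bin_trace <- function(x, bin = 10L) {
  if (bin <= 1L) return(as.numeric(x))
  n <- (length(x) %/% bin) * bin
  if (n == 0L) td_usage_error("trace shorter than one bin")
  colMeans(base::matrix(x[seq_len(n)], nrow = bin))
}

bin_rows <- function(m, bin = 10L) {
  t(apply(m, 1, bin_trace, bin = bin))
}

# topographic prominence of local maxima (same convention as the usual
# signal-processing definition: drop to the lowest point on the higher
# side bounded by the nearest taller sample)
local_peaks <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1L)]
    taller_l <- which(left > h)
    lmin <- min(x[(if (length(taller_l)) max(taller_l) else 1L):p])
    right <- x[(p + 1L):length(x)]
    taller_r <- which(right > h)
    rmin <- min(x[p:(p + (if (length(taller_r)) min(taller_r) else
      length(right)))])
    h - min(max(lmin, rmin), h)
  }, numeric(1))
}

#' Detect calcium events in a dF/F trace
#'
#' The trace is lightly denoised by non-overlapping boxcar averaging
#' (`bin` frames), then local maxima with height and prominence of at
#' least `k_sd` standard deviations of the binned trace are counted as
#' events.
#'
#' @param trace numeric dF/F series, length >= `bin`.
#' @param frame_rate acquisition rate (Hz).
#' @param bin boxcar width in frames (default 10).
#' @param k_sd height/prominence threshold in binned-trace SDs (default 1).
#' @return List with `events` (0-based indices into the *binned* trace),
#'   `rate` (events per minute), `binned` (the denoised trace), and
#'   `threshold`.
#' @export
detect_events <- function(trace, frame_rate = 30, bin = 10L, k_sd = 1) {
  b <- bin_trace(trace, bin)
  s <- sd(b)
  duration_min <- length(trace) / frame_rate / 60
  if (!is.finite(s) || s == 0)
    return(list(events = integer(0), rate = 0, binned = b, threshold = NA_real_))
  thr <- k_sd * s
  pk <- local_peaks(b)
  pk <- pk[b[pk] >= thr]
  if (length(pk)) pk <- pk[peak_prominence(b, pk) >= thr]
  list(events = pk - 1L, rate = length(pk) / duration_min, binned = b,
       threshold = thr)
}

#' Calcium event rate (events per minute)
#'
#' @inheritParams detect_events
#' @return Scalar events/minute.
#' @export
event_rate <- function(trace, frame_rate = 30, bin = 10L, k_sd = 1) {
  detect_events(trace, frame_rate, bin, k_sd)$rate
}

#' Pairwise functional connectivity matrix
#'
#' Pearson correlation between the full traces of all neuron pairs.
#' Zero-variance rows yield `NA` entries (flagged and excluded from
#' downstream similarity computations); the diagonal is 1 for valid rows.
#'
#' @param traces `n x T` matrix (`n >= 2`, `T >= 3`).
#' @param centroids optional `n x 2` `(row, col)` centroid matrix carried
#'   along for distance profiles.
#' @return Object of class `fc_matrix` with fields `values` (symmetric
#'   `n x n`), `valid` (logical per neuron), `centroids`.
#' @export
pairwise_fc <- function(traces, centroids = NULL) {
  traces <- as.matrix(traces)
  if (nrow(traces) < 2L || ncol(traces) < 3L)
    td_usage_error("pairwise_fc needs >= 2 neurons and >= 3 frames")
  valid <- apply(traces, 1, sd) > 0
  vals <- suppressWarnings(cor(t(traces)))
  vals[!valid, ] <- NA_real_
  vals[, !valid] <- NA_real_
  diag(vals)[valid] <- 1
  structure(list(values = vals, valid = valid, centroids = centroids),
            class = "fc_matrix")
}

#' Pairwise correlation as a function of anatomical distance
#'
#' Bins all neuron pairs by centroid distance (default 30-um bins),
#' averages the correlation per bin, and fits `a * exp(-d / lambda) + c`
#' to the binned curve by least squares. The correlation of neighbouring
#' neurons is read off as the intercept of the fit (its value at zero
#' distance, `a + c`).
#'
#' @param fc an [pairwise_fc()] result with centroids.
#' @param pixel_size_um pixel size; when `NULL` the bins are in pixels
#'   (with a warning) using `bin_um` as a pixel width.
#' @param bin_um bin width in micrometres (default 30).
#' @return List with `distance` (bin centres), `correlation` (bin means),
#'   `n_pairs`, `fit` (coefficients `a`, `lambda`, `c` or `NULL`),
#'   `neighbor_correlation` (`a + c`, `NA` without a fit).
#' @export
distance_profile <- function(fc, pixel_size_um = NULL, bin_um = 30) {
  if (is.null(fc$centroids))
    td_usage_error("distance_profile needs centroids on the FC matrix")
  scale <- pixel_size_um
  if (is.null(scale)) {
    warning("pixel size unknown; distance bins are in pixels", call. = FALSE)
    scale <- 1
  }
  n <- nrow(fc$values)
  ut <- which(upper.tri(fc$values), arr.ind = TRUE)
  d <- sqrt((fc$centroids[ut[, 1], 1] - fc$centroids[ut[, 2], 1])^2 +
              (fc$centroids[ut[, 1], 2] - fc$centroids[ut[, 2], 2])^2) * scale
  r <- fc$values[ut]
  keep <- is.finite(r)
  d <- d[keep]; r <- r[keep]
  bins <- floor(d / bin_um)
  agg <- tapply(r, bins, mean)
  centres <- (as.numeric(names(agg)) + 0.5) * bin_um
  counts <- as.integer(table(bins))
  fit <- NULL; intercept <- NA_real_
  if (length(agg) < 3L) {
    warning("fewer than 3 occupied distance bins; exponential fit skipped",
            call. = FALSE)
  } else if (sd(agg) < 1e-10) {
    # distance-independent correlations: the decay term is absent and the
    # intercept is the constant itself
    fit <- c(a = 0, lambda = NA_real_, c = mean(agg))
    intercept <- mean(agg)
  } else {
    df <- data.frame(d = centres, r = as.numeric(agg))
    start <- list(a = max(df$r) - min(df$r), lambda = max(df$d) / 3,
                  c = min(df$r))
    fit_try <- tryCatch(
      minpack.lm::nlsLM(r ~ a * exp(-d / lambda) + c, data = df,
                        start = start,
                        lower = c(-Inf, 1e-6, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit_try)) {
      fit <- coef(fit_try)
      intercept <- unname(fit["a"] + fit["c"])
    } else {
      warning("exponential fit did not converge", call. = FALSE)
    }
  }
  list(distance = centres, correlation = as.numeric(agg), n_pairs = counts,
       fit = fit, neighbor_correlation = intercept)
}

#' Functional-connectivity similarity between two sessions
#'
#' Pearson correlation over the strict upper triangles of two FC matrices
#' computed on the same tracked neuron set in identical order. The unit
#' diagonal is excluded (it would inflate the correlation); entries
#' undefined in either matrix (zero-variance neurons) are excluded
#' pairwise.
#'
#' @param fc_a,fc_b [pairwise_fc()] results of equal dimension.
#' @return Pearson r in `[-1, 1]`; symmetric in its arguments.
#' @export
fc_similarity <- function(fc_a, fc_b) {
  if (!identical(dim(fc_a$values), dim(fc_b$values)))
    td_validation_error("FC matrices must have the same dimension")
  if (nrow(fc_a$values) < 3L)
    td_usage_error("fc_similarity needs at least 3 neurons")
  ut <- upper.tri(fc_a$values)
  a <- fc_a$values[ut]; b <- fc_b$values[ut]
  keep <- is.finite(a) & is.finite(b)
  if (sum(keep) < 2L) return(NA_real_)
  cor(a[keep], b[keep])
}

#' Within-session (split-half) FC similarity
#'
#' FC similarity between the FC matrices of the first and second half of a
#' single session's recording -- the noise ceiling used as the reference
#' (fixed upper asymptote) when fitting the across-day transition.
#'
#' @param traces `n x T` matrix, `T >= 6`.
#' @return Pearson r.
#' @export
within_session_similarity <- function(traces) {
  traces <- as.matrix(traces)
  T_ <- ncol(traces)
  if (T_ < 6L) td_usage_error("need at least 6 frames to split in halves")
  h <- T_ %/% 2L
  fc_similarity(pairwise_fc(traces[, seq_len(h), drop = FALSE]),
                pairwise_fc(traces[, (h + 1L):T_, drop = FALSE]))
}

#' Across-day FC similarity matrix for tracked neurons
#'
#' Off-diagonal entries are the FC similarity between pairs of days
#' computed on the aligned (tracked) population; diagonal entries are each
#' day's within-session split-half similarity.
#'
#' @param tracked a [extract_tracked_traces()] result.
#' @return Object of class `similarity_matrix`: `values` (`n_days x
#'   n_days`), `day_labels`.
#' @export
similarity_matrix <- function(tracked) {
  n_days <- length(tracked$traces)
  fcs <- lapply(tracked$traces, pairwise_fc)
  vals <- base::matrix(NA_real_, n_days, n_days)
  for (d in seq_len(n_days)) {
    vals[d, d] <- within_session_similarity(tracked$traces[[d]])
    if (d < n_days) for (e in seq(d + 1L, n_days)) {
      vals[d, e] <- vals[e, d] <- fc_similarity(fcs[[d]], fcs[[e]])
    }
  }
  structure(list(values = vals,
                 day_labels = names(tracked$traces) %||%
                   paste0("s", seq_len(n_days) - 1L)),
            class = "similarity_matrix")
}

#' Mean pairwise-distance growth curve of tracked cells
#'
#' Mean over all tracked cell pairs of the centroid distance, per day,
#' normalised to the first day. Under isotropic tissue growth this ratio
#' recovers the cumulative scale factor irrespective of rotation or
#' translation, and is the quantitative growth readout for longitudinal
#' recordings.
#'
#' @param tracked a [extract_tracked_traces()] result (complete tracks).
#' @return Numeric vector, one value per day; first entry 1.
#' @export
pairwise_distance_growth <- function(tracked) {
  mean_dist <- vapply(tracked$centroids, function(cen) {
    cen <- cen[stats::complete.cases(cen), , drop = FALSE]
    if (nrow(cen) < 2L) return(NA_real_)
    mean(stats::dist(cen))
  }, numeric(1))
  unname(mean_dist / mean_dist[1])
}

#' Number of principal components explaining a variance fraction
#'
#' Mean-centres each neuron and returns the smallest number of principal
#' components of the neuron-by-time matrix whose cumulative explained
#' variance reaches `variance_fraction` (default 90 %) -- a simple
#' dimensionality measure of population activity.
#'
#' @param traces `n x T` matrix.
#' @param variance_fraction target cumulative fraction (default 0.90).
#' @return Integer number of components.
#' @export
dimensionality <- function(traces, variance_fraction = 0.90) {
  traces <- as.matrix(traces)
  if (nrow(traces) < 2L) td_usage_error("need >= 2 neurons")
  if (ncol(traces) <= nrow(traces))
    warning("fewer frames than neurons; spectrum estimates are unstable",
            call. = FALSE)
  centred <- traces - rowMeans(traces)
  if (all(abs(centred) < .Machine$double.eps))
    td_usage_error("zero-variance data has no principal components")
  ev <- svd(centred, nu = 0, nv = 0)$d^2
  frac <- cumsum(ev) / sum(ev)
  which(frac >= variance_fraction - 1e-10)[1]
}

#' Correlation between the leading population component and motion
#'
#' Pearson correlation between the first principal-component time course
#' of the population and the motion trace. PC1 is oriented so that the sum
#' of its neuron loadings is nonnegative; the absolute correlation is also
#' returned since the sign convention is arbitrary.
#'
#' @param traces `n x T` matrix.
#' @param motion numeric motion values, length `T` (already aligned).
#' @param bin optional boxcar width applied to both (default 1, none).
#' @return List with `r` and `abs_r`.
#' @export
pc1_motion_correlation <- function(traces, motion, bin = 1L) {
  traces <- as.matrix(traces)
  if (length(motion) != ncol(traces))
    td_validation_error("motion and traces must share frame alignment")
  if (sd(motion) == 0) td_usage_error("motion trace has zero variance")
  if (bin > 1L) {
    traces <- bin_rows(traces, bin)
    motion <- bin_trace(motion, bin)
  }
  centred <- traces - rowMeans(traces)
  sv <- svd(centred, nu = 1, nv = 1)
  pc1 <- as.numeric(sv$v[, 1]) * sv$d[1]
  if (sum(sv$u[, 1]) < 0) pc1 <- -pc1
  r <- cor(pc1, motion)
  list(r = r, abs_r = abs(r))
}
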