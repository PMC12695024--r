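#' Prepare aligned design matrix and target for decoding
#'
#' Lightly denoises both the population traces and the motion trace by
#' averaging in non-overlapping bins of `bin` consecutive timestamps, and
#' arranges the result as a time-by-neurons design matrix `X` with the
#' time-aligned motion target `y`.
#'
#' @param traces `n x T` dF/F matrix.
#' @param motion numeric motion values of length `T` (equal frame rates
#'   are assumed, as with hardware-triggered simultaneous acquisition).
#' @param bin boxcar width (default 10).
#' @return List with `X` (`T/bin x n`) and `y` (length `T/bin`).
#' @export
prepare_decoding <- function(traces, motion, bin = 10L) {
  traces <- as.matrix(traces)
  if (length(motion) != ncol(traces))
    td_validation_error(sprintf(
      "motion has %d samples but traces have %d frames",
      length(motion), ncol(traces)))
  list(X = t(bin_rows(traces, bin)), y = bin_trace(motion, bin))
}

# closed-form ridge solve on standardised features:
# minimises ||y - X beta||^2 + lambda ||beta||^2
ridge_fit <- function(X, y, lambda, x_centre, x_scale) {
  Xs <- sweep(sweep(X, 2, x_centre), 2, x_scale, `/`)
  y_centre <- mean(y)
  p <- ncol(Xs)
  beta <- solve(crossprod(Xs) + lambda * diag(p), crossprod(Xs, y - y_centre))
  list(beta = as.numeric(beta), y_centre = y_centre,
       x_centre = x_centre, x_scale = x_scale, lambda = lambda)
}

ridge_predict <- function(model, X) {
  Xs <- sweep(sweep(X, 2, model$x_centre), 2, model$x_scale, `/`)
  as.numeric(Xs %*% model$beta) + model$y_centre
}

# R^2 on a test segment: 1 - SS_res / SS_tot about the segment mean
# (may be negative)
r_squared <- function(y, yhat) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / ss_tot
}

# split indices 1..n into k contiguous blocks (lengths differ by <= 1)
contiguous_folds <- function(n, k) {
  if (n < k) td_usage_error(sprintf("%d samples cannot form %d folds", n, k))
  split(seq_len(n), rep(seq_len(k), times = diff(round(seq(0, n, length.out = k + 1)))))
}

# feature standardisation statistics from a training subset; constant
# features get unit scale so they contribute nothing after centring
scale_stats <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < .Machine$double.eps] <- 1
  list(centre = ctr, scale = scl)
}

#' Ridge decoding with nested cross-validation
#'
#' Decodes motion from population activity with ridge regression (loss
#' `||y - X beta||^2 + lambda ||beta||^2`). Model performance and
#' regularisation strength are estimated by nested cross-validation on
#' contiguous temporal blocks (respecting the autocorrelation of both
#' signals): the outer loop reports held-out test R-squared, the inner
#' loop selects `lambda` by validation R-squared on splits of the
#' training data. Features are z-scored with training-fold statistics
#' only. The final model is refit on all data at the `lambda` selected by
#' an inner-style CV over the full series. Deterministic given the data.
#'
#' @param X time-by-neurons design matrix (from [prepare_decoding()]).
#' @param y motion target, same length.
#' @param outer_folds,inner_folds numbers of contiguous blocks (default 5).
#' @param lambda_grid candidate penalties (default 9 values log-spaced
#'   `1e-3 .. 1e5`).
#' @return Object of class `ridge_decoder`: `r2` (mean outer-fold test
#'   R-squared), `fold_r2`, `fold_lambda`, `lambda` (final selection),
#'   `model` (final fit with `beta`, standardisation statistics), `n`.
#' @export
nested_cv_ridge <- function(X, y, outer_folds = 5L, inner_folds = 5L,
                            lambda_grid = 10^seq(-3, 5, by = 1)) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n)
    td_validation_error("X and y must have the same number of samples")
  folds <- contiguous_folds(n, outer_folds)

  select_lambda <- function(idx) {
    inner <- contiguous_folds(length(idx), inner_folds)
    scores <- vapply(lambda_grid, function(lam) {
      mean(vapply(inner, function(v) {
        val <- idx[v]; trn <- setdiff(idx, val)
        st <- scale_stats(X[trn, , drop = FALSE])
        m <- ridge_fit(X[trn, , drop = FALSE], y[trn], lam,
                       st$centre, st$scale)
        r2 <- r_squared(y[val], ridge_predict(m, X[val, , drop = FALSE]))
        if (is.na(r2)) -Inf else r2
      }, numeric(1)))
    }, numeric(1))
    lambda_grid[which.max(scores)]    # ties -> smallest lambda
  }

  fold_r2 <- numeric(outer_folds)
  fold_lambda <- numeric(outer_folds)
  for (f in seq_len(outer_folds)) {
    test <- folds[[f]]; train <- setdiff(seq_len(n), test)
    lam <- select_lambda(train)
    st <- scale_stats(X[train, , drop = FALSE])
    m <- ridge_fit(X[train, , drop = FALSE], y[train], lam,
                   st$centre, st$scale)
    fold_r2[f] <- r_squared(y[test], ridge_predict(m, X[test, , drop = FALSE]))
    fold_lambda[f] <- lam
  }

  final_lambda <- select_lambda(seq_len(n))
  st <- scale_stats(X)
  final <- ridge_fit(X, y, final_lambda, st$centre, st$scale)
  structure(list(r2 = mean(fold_r2), fold_r2 = fold_r2,
                 fold_lambda = fold_lambda, lambda = final_lambda,
                 model = final, n = n),
            class = "ridge_decoder")
}

#' @export
print.ridge_decoder <- function(x, ...) {
  cat(sprintf("<ridge_decoder> CV R^2 = %.3f (lambda = %g, n = %d)\n",
              x$r2, x$lambda, x$n))
  invisible(x)
}

#' Cross-day decoding matrix over tracked neurons
#'
#' Fits one ridge decoder per day on the aligned (tracked) population and
#' evaluates every model on every day: entry `(d, d')` is the R-squared of
#' the day-`d` model predicting day-`d'` motion from day-`d'` aligned
#' activity, with day-`d` feature standardisation applied to the test
#' data. Diagonal entries are the same-day cross-validated values from
#' [nested_cv_ridge()] (never in-sample). Only possible because row `k`
#' of the aligned traces is the same cell on every day.
#'
#' @param tracked a [extract_tracked_traces()] result (complete tracks).
#' @param motions list of per-day motion traces (vectors of length
#'   `n_frames`, or `motion_trace` objects).
#' @param bin boxcar width for [prepare_decoding()] (default 10).
#' @param ... passed to [nested_cv_ridge()].
#' @return Object of class `cross_day_decoding`: `r2` (`n_days x n_days`
#'   matrix), `decoders` (per-day [nested_cv_ridge()] fits).
#' @export
cross_day_decode <- function(tracked, motions, bin = 10L, ...) {
  n_days <- length(tracked$traces)
  if (length(motions) != n_days)
    td_validation_error("one motion trace per day is required")
  prep <- lapply(seq_len(n_days), function(d) {
    mo <- motions[[d]]
    if (inherits(mo, "motion_trace")) mo <- mo$values
    prepare_decoding(tracked$traces[[d]], mo, bin = bin)
  })
  decoders <- lapply(prep, function(p) nested_cv_ridge(p$X, p$y, ...))
  r2 <- base::matrix(NA_real_, n_days, n_days,
                     dimnames = list(fit = names(tracked$traces),
                                     test = names(tracked$traces)))
  for (d in seq_len(n_days)) {
    for (e in seq_len(n_days)) {
      r2[d, e] <- if (d == e) decoders[[d]]$r2 else
        r_squared(prep[[e]]$y,
                  ridge_predict(decoders[[d]]$model, prep[[e]]$X))
    }
  }
  structure(list(r2 = r2, decoders = decoders),
            class = "cross_day_decoding")
}
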