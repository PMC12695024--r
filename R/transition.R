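#' Fit a sigmoid transition to FC similarity versus age
#'
#' Models the decay of FC similarity (reference day vs. every later day)
#' as a decreasing logistic
#' `y(t) = b + (U - b) / (1 + exp(k (t - t0)))` with the upper asymptote
#' `U` fixed to the reference day's within-session similarity and the
#' lower asymptote `b`, steepness `k > 0` and midpoint `t0` free. Fitting
#' is bounded least squares from a deterministic multi-start grid (`t0`
#' over the observed day range crossed with several steepness guesses),
#' keeping the best residual. The transition age is `t0` (the extremum of
#' the first derivative); the transition time is the width of the linear
#' portion, measured as the distance between the two fourth-derivative
#' extrema flanking `t0`, located numerically on a dense grid.
#'
#' @param similarities FC similarity values, one per day.
#' @param days day/age covariate (same length, >= 4 distinct values).
#' @param upper_limit fixed upper asymptote `U`.
#' @return Object of class `sigmoid_fit`: `b`, `U`, `k`, `t0`,
#'   `transition_age`, `transition_time`, `residual_norm`, `converged`.
#'   Flat or non-convergent input yields `converged = FALSE` with `NA`
#'   ages.
#' @export
fit_transition <- function(similarities, days, upper_limit) {
  if (length(similarities) != length(days))
    td_validation_error("one similarity value per day is required")
  if (length(unique(days)) < 4L)
    td_usage_error("need at least 4 days to fit a transition")
  failed <- structure(list(b = NA_real_, U = upper_limit, k = NA_real_,
                           t0 = NA_real_, transition_age = NA_real_,
                           transition_time = NA_real_,
                           residual_norm = NA_real_, converged = FALSE),
                      class = "sigmoid_fit")
  if (sd(similarities) < 1e-12) return(failed)
  df <- data.frame(t = as.numeric(days), y = as.numeric(similarities))
  span <- diff(range(df$t))
  best <- NULL
  for (t0_start in seq(min(df$t), max(df$t), length.out = 7L)) {
    for (k_start in c(0.5, 1, 2, 4) / max(span / 6, .Machine$double.eps)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ b + (upper_limit - b) / (1 + exp(k * (t - t0))), data = df,
          start = list(b = min(df$y), k = k_start, t0 = t0_start),
          lower = c(-Inf, 1e-6, min(df$t) - span),
          upper = c(upper_limit, Inf, max(df$t) + span),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rn <- sqrt(sum(stats::resid(fit)^2))
        if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
      }
    }
  }
  if (is.null(best)) return(failed)
  cf <- coef(best$fit)
  b <- unname(cf["b"]); k <- unname(cf["k"]); t0 <- unname(cf["t0"])

  # numerical fourth derivative of the fitted curve on a dense grid
  lo <- t0 - 8 / k; hi <- t0 + 8 / k
  grid <- seq(lo, hi, length.out = 4001L)
  h <- grid[2] - grid[1]
  yv <- b + (upper_limit - b) / (1 + exp(k * (grid - t0)))
  d4 <- yv
  for (i in 1:4) d4 <- diff(d4) / h
  tc <- grid[seq_along(d4)] + (h * 4) / 2     # centres of the 4th-diff stencil
  ext <- local_extrema(d4)
  t_left <- tc[ext][tc[ext] < t0]
  t_right <- tc[ext][tc[ext] > t0]
  transition_time <- if (length(t_left) && length(t_right))
    min(t_right) - max(t_left) else NA_real_

  structure(list(b = b, U = upper_limit, k = k, t0 = t0,
                 transition_age = t0, transition_time = transition_time,
                 residual_norm = best$rn, converged = TRUE),
            class = "sigmoid_fit")
}

# indices of interior local extrema (strict on one side)
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  core <- 2:(n - 1L)
  up <- x[core] > x[core - 1L] & x[core] >= x[core + 1L]
  dn <- x[core] < x[core - 1L] & x[core] <= x[core + 1L]
  core[up | dn]
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<sigmoid_fit> failed (flat or non-convergent input)\n")
  } else {
    cat(sprintf(
      "<sigmoid_fit> b=%.3f U=%.3f k=%.3f t0=%.2f  transition age %.2f, time %.2f\n",
      x$b, x$U, x$k, x$t0, x$transition_age, x$transition_time))
  }
  invisible(x)
}
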