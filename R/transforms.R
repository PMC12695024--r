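#' Construct a 2-D affine transform between two sessions' coordinate frames
#'
#' An `affine_transform` maps continuous coordinates `(x = col, y = row)` of
#' the *moving* session's frame into the *reference* (fixed) session's frame:
#' `p_ref = A %*% p_mov + t`, where `matrix = cbind(A, t)` is 2x3.
#'
#' @param matrix 2x3 numeric matrix `cbind(A, t)`.
#' @param mode `"affine"` or `"rigid"`. In rigid mode the linear part must be
#'   a pure rotation (orthonormal, determinant +1).
#' @param fixed_session,moving_session optional session indices (0-based).
#' @param metric_value optional final registration similarity (diagnostic).
#' @param converged logical diagnostic flag from the optimiser.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix, mode = c("affine", "rigid"),
                             fixed_session = NA_integer_,
                             moving_session = NA_integer_,
                             metric_value = NA_real_, converged = TRUE) {
  mode <- match.arg(mode)
  matrix <- base::matrix(as.numeric(matrix), 2L, 3L)
  if (!all(is.finite(matrix)))
    td_validation_error("affine matrix contains non-finite values")
  A <- matrix[, 1:2]
  if (abs(det(A)) <= 1e-8)
    td_validation_error("affine linear part is (near-)singular")
  if (mode == "rigid") {
    if (max(abs(crossprod(A) - diag(2))) > 1e-6 || det(A) < 0)
      td_validation_error(
        "rigid transform requires an orthonormal rotation with determinant +1")
  }
  structure(list(matrix = matrix, mode = mode,
                 fixed_session = fixed_session,
                 moving_session = moving_session,
                 registration_metric_value = metric_value,
                 converged = converged),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform> mode=%s", x$mode))
  if (!is.na(x$fixed_session))
    cat(sprintf("  pair %d<-%d", x$fixed_session, x$moving_session))
  if (!is.na(x$registration_metric_value))
    cat(sprintf("  NCC=%.4f", x$registration_metric_value))
  cat("\n")
  print(round(x$matrix, 5))
  invisible(x)
}

#' The identity transform
#'
#' @param mode `"affine"` or `"rigid"`.
#' @return An [affine_transform()] mapping every point to itself.
#' @export
identity_transform <- function(mode = "affine") {
  affine_transform(cbind(diag(2), c(0, 0)), mode = mode)
}

#' Apply an affine transform to (x, y) points
#'
#' @param transform an [affine_transform()].
#' @param xy n x 2 matrix of `(x = col, y = row)` coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, xy) {
  xy <- base::matrix(as.numeric(xy), ncol = 2L)
  A <- transform$matrix[, 1:2]
  t(A %*% t(xy) + transform$matrix[, 3])
}

#' Invert an affine transform
#'
#' @param transform an [affine_transform()].
#' @return The inverse transform (reference frame to moving frame).
#' @export
invert_transform <- function(transform) {
  A <- transform$matrix[, 1:2]
  Ainv <- solve(A)
  affine_transform(cbind(Ainv, -Ainv %*% transform$matrix[, 3]),
                   mode = transform$mode,
                   fixed_session = transform$moving_session,
                   moving_session = transform$fixed_session)
}

#' Compose two affine transforms
#'
#' `compose_transforms(f, g)` returns the transform applying `g` first and
#' then `f`, i.e. `p -> f(g(p))`.
#'
#' @param f,g [affine_transform()] objects.
#' @return The composed transform. Mode is `"rigid"` only if both are rigid.
#' @export
compose_transforms <- function(f, g) {
  Af <- f$matrix[, 1:2]; Ag <- g$matrix[, 1:2]
  A <- Af %*% Ag
  t <- Af %*% g$matrix[, 3] + f$matrix[, 3]
  mode <- if (f$mode == "rigid" && g$mode == "rigid") "rigid" else "affine"
  affine_transform(cbind(A, t), mode = mode)
}

#' Mean corner displacement between two transforms
#'
#' Maps the four corners of an `H x W` field of view through both transforms
#' and returns the mean Euclidean distance between the two images of the
#' corners, in pixels. Used as the registration-accuracy metric: it summarises
#' the worst-case geometric disagreement over the FOV.
#'
#' @param estimated,truth [affine_transform()] objects.
#' @param shape integer `(H, W)` of the field of view.
#' @return Mean corner displacement in pixels.
#' @export
corner_displacement <- function(estimated, truth, shape) {
  H <- shape[1]; W <- shape[2]
  corners <- cbind(x = c(0, W - 1, 0, W - 1), y = c(0, 0, H - 1, H - 1))
  d <- apply_transform(estimated, corners) - apply_transform(truth, corners)
  mean(sqrt(rowSums(d^2)))
}

# Build the 2x3 matrix from a geometric parameterisation about a centre
# point: A = R(theta) %*% [[sx, sh], [0, sy]], p -> C + A (p - C) + t.
# Rigid mode uses (tx, ty, theta) only. Angles in radians.
params_to_transform <- function(par, mode, centre) {
  if (mode == "rigid") {
    theta <- par[3]; sx <- 1; sy <- 1; sh <- 0
  } else {
    theta <- par[3]; sx <- exp(par[4]); sy <- exp(par[5]); sh <- par[6]
  }
  R <- base::matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  A <- R %*% base::matrix(c(sx, 0, sh, sy), 2, 2)
  t <- c(par[1], par[2]) + centre - A %*% centre
  cbind(A, t)
}
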