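#' Registration options
#'
#' Controls for [estimate_transform()]. The defaults implement a
#' multi-resolution (pyramid) optimisation of normalised cross-correlation
#' (NCC) between the two mean images: same-modality images across days make
#' NCC a robust similarity, and the pyramid lets the optimiser absorb large
#' displacements at coarse scale before refining at full resolution.
#' Optimisation uses Nelder-Mead from a deterministic identity
#' initialisation, so registration is reproducible bit-for-bit.
#'
#' @param pyramid integer downsampling factors, coarse to fine.
#' @param maxit iteration caps per pyramid level (recycled).
#' @param clip percentile pair used to rescale intensities to `[0, 1]`
#'   before registration (guards against day-to-day brightness drift).
#' @param min_overlap minimum fraction of the FOV that must remain in-bounds
#'   for a candidate transform; transforms below it are penalised.
#' @param reltol relative convergence tolerance of the optimiser.
#' @return A list of class `reg_control`.
#' @export
reg_control <- function(pyramid = c(4L, 2L, 1L), maxit = c(400L, 300L, 200L),
                        clip = c(0.01, 0.99), min_overlap = 0.25,
                        reltol = 1e-10) {
  structure(list(pyramid = as.integer(pyramid),
                 maxit = rep_len(as.integer(maxit), length(pyramid)),
                 clip = clip, min_overlap = min_overlap, reltol = reltol),
            class = "reg_control")
}

# percentile-clip and rescale an image to [0, 1]
normalize_image <- function(img, clip = c(0.01, 0.99)) {
  q <- quantile(img, clip, names = FALSE)
  if (q[2] <= q[1]) td_stop("image is (near-)constant", "degenerate_input")
  pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
}

# block-mean downsampling by integer factor (trailing remainder dropped)
downsample_image <- function(img, f) {
  if (f == 1L) return(img)
  H <- (nrow(img) %/% f) * f
  W <- (ncol(img) %/% f) * f
  img <- img[seq_len(H), seq_len(W), drop = FALSE]
  a <- array(img, c(f, H %/% f, f, W %/% f))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

# negative NCC of fixed vs moving-resampled-under-par, with a penalty when
# the in-bounds overlap drops below min_overlap
reg_objective <- function(par, mode, fixed, moving, centre, opts) {
  M <- params_to_transform(par, mode, centre)
  A <- M[, 1:2]
  d <- det(A)
  if (!is.finite(d) || abs(d) < 1e-8) return(10)
  Ainv <- solve(A)
  minv <- cbind(Ainv, -Ainv %*% M[, 3])
  w <- warp_image_bilinear(moving, minv, nrow(fixed), ncol(fixed), NA_real_)
  v <- ncc_masked(fixed, w)
  if (!is.finite(v[1])) return(10)
  -v[1] + 4 * max(0, opts$min_overlap - v[2])
}

#' Estimate the transform aligning one session's mean image onto another's
#'
#' Registers `moving` (session `s_{k+1}`) onto `reference` (session `s_k`):
#' the returned transform maps moving-frame coordinates into the reference
#' frame. Similarity is normalised cross-correlation optimised over a
#' three-level image pyramid with a deterministic identity initialisation,
#' in `"rigid"` mode over (shift, rotation) and in `"affine"` mode
#' additionally over scale and shear -- the degrees of freedom that model
#' day-to-day brain growth.
#'
#' @param reference,moving 2-D numeric matrices of identical shape.
#' @param mode `"affine"` (default) or `"rigid"`.
#' @param control a [reg_control()] list.
#' @param fixed_session,moving_session optional session indices recorded on
#'   the result.
#' @return An [affine_transform()] whose `registration_metric_value` is the
#'   final full-resolution NCC; `converged` is `FALSE` when the optimiser
#'   hit its iteration cap (a warning is raised and the best-found transform
#'   returned).
#' @export
estimate_transform <- function(reference, moving, mode = c("affine", "rigid"),
                               control = reg_control(),
                               fixed_session = NA_integer_,
                               moving_session = NA_integer_) {
  mode <- match.arg(mode)
  if (!identical(dim(reference), dim(moving)))
    td_validation_error("reference and moving images must share their shape")
  if (!all(is.finite(reference)) || !all(is.finite(moving)))
    td_validation_error("images must be finite")
  fixed_n <- normalize_image(reference, control$clip)
  moving_n <- normalize_image(moving, control$clip)

  npar <- if (mode == "rigid") 3L else 6L
  par <- numeric(npar)  # identity
  parscale <- c(1, 1, 0.01, 0.01, 0.01, 0.01)[seq_len(npar)]
  converged <- TRUE
  for (l in seq_along(control$pyramid)) {
    f <- control$pyramid[l]
    fx <- downsample_image(fixed_n, f)
    mv <- downsample_image(moving_n, f)
    centre <- c((ncol(fx) - 1) / 2, (nrow(fx) - 1) / 2)
    # translations live in level pixels: rescale from the previous level
    if (l > 1L) par[1:2] <- par[1:2] * control$pyramid[l - 1L] / f
    fit <- optim(par, reg_objective, mode = mode, fixed = fx, moving = mv,
                 centre = centre, opts = control, control = list(
                   maxit = control$maxit[l], reltol = control$reltol,
                   parscale = parscale),
                 method = "Nelder-Mead")
    par <- fit$par
    if (l == length(control$pyramid)) {
      # quasi-Newton polish at the finest level: Nelder-Mead stalls near
      # the optimum in 6 dimensions, numeric-gradient BFGS does not
      polish <- optim(par, reg_objective, mode = mode, fixed = fx,
                      moving = mv, centre = centre, opts = control,
                      method = "BFGS",
                      control = list(maxit = 100L, reltol = control$reltol,
                                     parscale = parscale,
                                     ndeps = rep(1e-4, npar)))
      if (polish$value <= fit$value) {
        par <- polish$par
        fit <- polish
      }
      # convergence is judged at the finest level only: iteration caps at
      # coarse levels are expected and harmless once the polish settles
      converged <- fit$convergence == 0L
    }
  }
  if (!converged)
    warning("registration optimiser hit its iteration cap; ",
            "returning best-found transform", call. = FALSE)
  centre <- c((ncol(fixed_n) - 1) / 2, (nrow(fixed_n) - 1) / 2)
  M <- params_to_transform(par, mode, centre)
  affine_transform(M, mode = mode, fixed_session = fixed_session,
                   moving_session = moving_session,
                   metric_value = -reg_objective(par, mode, fixed_n, moving_n,
                                                 centre, opts = control),
                   converged = converged)
}

#' Warp an ROI mask into the reference frame
#'
#' A reference-frame pixel belongs to the warped mask iff its inverse-mapped
#' location falls on a mask pixel under nearest-neighbour lookup, so warped
#' masks have no holes or fractional pixels. Pixels mapping outside
#' `out_shape` are dropped; a mask that maps entirely out of bounds is
#' returned empty with its `out_of_bounds` flag set (such cells have grown
#' out of the field of view). Per-pixel weights are not warped: matching
#' operates on binary occupancy.
#'
#' @param mask an [roi_mask()] in the moving session's frame.
#' @param transform [affine_transform()] mapping moving to reference frame.
#' @param out_shape integer `(H, W)` of the reference frame.
#' @return An [roi_mask()] in the reference frame (same `roi_id`).
#' @export
warp_mask <- function(mask, transform, out_shape) {
  inv <- invert_transform(transform)
  # forward-map the pixel corners to bound the candidate region
  xy <- cbind(mask$pixels[, 2], mask$pixels[, 1])
  fwd <- apply_transform(transform, xy)
  r0 <- max(0L, floor(min(fwd[, 2])) - 1L)
  r1 <- min(out_shape[1] - 1L, ceiling(max(fwd[, 2])) + 1L)
  c0 <- max(0L, floor(min(fwd[, 1])) - 1L)
  c1 <- min(out_shape[2] - 1L, ceiling(max(fwd[, 1])) + 1L)
  if (r1 < r0 || c1 < c0) {
    return(roi_mask(mask$roi_id, base::matrix(integer(), 0, 2),
                    cell_probability = mask$cell_probability,
                    shape = out_shape, out_of_bounds = TRUE))
  }
  cand <- as.matrix(expand.grid(row = r0:r1, col = c0:c1))
  src <- apply_transform(inv, cbind(cand[, 2], cand[, 1]))
  src_px <- cbind(round(src[, 2]), round(src[, 1]))  # nearest neighbour
  keep <- src_px[, 1] >= 0 & src_px[, 2] >= 0
  keys <- pixel_keys(mask$pixels)
  inside <- keep
  inside[keep] <- pixel_keys(src_px[keep, , drop = FALSE]) %in% keys
  px <- cand[inside, , drop = FALSE]
  roi_mask(mask$roi_id, px, cell_probability = mask$cell_probability,
           shape = out_shape, out_of_bounds = nrow(px) == 0L)
}

#' Warp an image into the reference frame
#'
#' Linear-interpolated resampling used for diagnostics and quality-control
#' overlays only (matching operates on warped masks, never warped images).
#' Out-of-bounds regions are filled with 0.
#'
#' @param image 2-D numeric matrix in the moving frame.
#' @param transform [affine_transform()] mapping moving to reference frame.
#' @param out_shape integer `(H, W)`; defaults to the input shape.
#' @return A numeric `out_shape` matrix.
#' @export
warp_image <- function(image, transform, out_shape = dim(image)) {
  inv <- invert_transform(transform)
  warp_image_bilinear(image, inv$matrix, out_shape[1], out_shape[2], 0)
}
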