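#' Rigid (Euclidean) frame transforms
#'
#' A rigid transform describes the motion of a frame relative to the
#' reference: a point at 0-based reference coordinates \eqn{X} appears in the
#' moving frame at \eqn{X' = R(\phi)(X - c) + c + t}, where \eqn{c} is the
#' image centre, \eqn{t = (tx, ty)} the shift in pixels and \eqn{\phi} the
#' rotation in degrees (counter-clockwise in the x-right / y-down pixel
#' frame). The rotation centre is the image centre: any fixed centre gives an
#' equivalent parameterisation, but one must be fixed for reporting.
#'
#' @param tx,ty shift in pixels along x (columns) and y (rows).
#' @param phi rotation in degrees; normalised to (-180, 180].
#' @return an object of class `rigid_transform`.
#' @examples
#' t1 <- rigid_transform(3, -1, 2)
#' t1
#' @export
rigid_transform <- function(tx = 0, ty = 0, phi = 0) {
  stopifnot(is.finite(tx), is.finite(ty), is.finite(phi))
  phi <- ((phi + 180) %% 360) - 180
  if (phi == -180) phi <- 180
  structure(list(tx = tx, ty = ty, phi = phi), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform: tx = %.4f px, ty = %.4f px, phi = %.4f deg\n",
              x$tx, x$ty, x$phi))
  invisible(x)
}

.is_identity <- function(tf, tol = 0)
  abs(tf$tx) <= tol && abs(tf$ty) <= tol && abs(tf$phi) <= tol

.rot2 <- function(phi_deg) {
  a <- phi_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

# Apply transform to 0-based point coordinates (n x 2 matrix or length-2).
.apply_tf <- function(tf, pts, centre) {
  pts <- matrix(pts, ncol = 2)
  R <- .rot2(tf$phi)
  sweep(t(R %*% t(sweep(pts, 2, centre))), 2,
        centre + c(tf$tx, tf$ty), `+`)
}

# Composition outer(inner(x)); rotation centres must agree.
.compose_tf <- function(outer, inner) {
  R1 <- .rot2(outer$phi)
  t2 <- c(inner$tx, inner$ty)
  tt <- as.vector(R1 %*% t2) + c(outer$tx, outer$ty)
  rigid_transform(tt[1], tt[2], outer$phi + inner$phi)
}

.invert_tf <- function(tf) {
  Rinv <- .rot2(-tf$phi)
  t <- -as.vector(Rinv %*% c(tf$tx, tf$ty))
  rigid_transform(t[1], t[2], -tf$phi)
}

.image_centre <- function(dim_hw) c((dim_hw[2] - 1) / 2, (dim_hw[1] - 1) / 2)

#' Least-squares rigid transform between two point sets
#'
#' Finds the shift and rotation (about the image centre) that carries the
#' reference points onto the current points with minimum total squared
#' distance, via the closed-form 2-D orthogonal Procrustes solution: centre
#' both point clouds, form the 2x2 cross-covariance, and read the rotation
#' angle off its polar decomposition. This solves the same least-squares
#' objective as a linearised Gauss-elimination fit in (cos phi, sin phi,
#' tx, ty), but enforces a true rotation exactly.
#'
#' @param ref_points,cur_points n x 2 matrices of 0-based (x, y) coordinates;
#'   `cur_points[j, ]` is where `ref_points[j, ]` moved to.
#' @param centre rotation centre (x, y); defaults to the centroid-free
#'   convention used across the package, the image centre, which callers
#'   supply via `dim_hw`.
#' @param dim_hw optional image dimensions `c(height, width)` from which the
#'   centre is computed when `centre` is missing.
#' @return a [rigid_transform()] `tf` with `cur ~ tf(ref)`.
#' @examples
#' ref <- cbind(runif(20, 0, 100), runif(20, 0, 100))
#' tf0 <- rigid_transform(3, -1, 2)
#' cur <- retreg:::.apply_tf(tf0, ref, centre = c(50, 50))
#' fit_rigid(ref, cur, centre = c(50, 50))
#' @export
fit_rigid <- function(ref_points, cur_points, centre = NULL, dim_hw = NULL) {
  ref_points <- matrix(as.numeric(ref_points), ncol = 2)
  cur_points <- matrix(as.numeric(cur_points), ncol = 2)
  n <- nrow(ref_points)
  if (nrow(cur_points) != n)
    stop("point sets must have the same length", call. = FALSE)
  if (n < 2)
    stop("insufficient points: at least 2 point pairs are required",
         call. = FALSE)
  if (all(abs(sweep(ref_points, 2, ref_points[1, ])) < 1e-12))
    stop("insufficient points: reference points are all coincident",
         call. = FALSE)
  if (is.null(centre)) {
    if (is.null(dim_hw))
      stop("either `centre` or `dim_hw` must be given", call. = FALSE)
    centre <- .image_centre(dim_hw)
  }
  a <- sweep(ref_points, 2, colMeans(ref_points))
  b <- sweep(cur_points, 2, colMeans(cur_points))
  # rotation from the polar decomposition of the 2x2 cross-covariance
  num <- sum(a[, 1] * b[, 2] - a[, 2] * b[, 1])
  den <- sum(a[, 1] * b[, 1] + a[, 2] * b[, 2])
  phi <- if (num == 0 && den == 0) 0 else atan2(num, den) * 180 / pi
  R <- .rot2(phi)
  mr <- colMeans(ref_points); mc <- colMeans(cur_points)
  t <- mc - as.vector(R %*% (mr - centre)) - centre
  rigid_transform(t[1], t[2], phi)
}

#' Resample a frame under a rigid transform
#'
#' Builds the registered view of a moving frame: the output at reference
#' coordinates \eqn{X} is the moving frame sampled bilinearly at
#' \eqn{tf(X)}. Pixels that map outside the moving frame are filled with 0
#' and reported in the validity mask.
#'
#' @param frame 2-D intensity matrix (the moving frame).
#' @param tf [rigid_transform()] mapping reference coordinates to moving
#'   coordinates.
#' @param mask optional logical validity mask of `frame` to carry through.
#' @return list with `image` (resampled matrix) and `mask` (logical matrix,
#'   TRUE where the sample was fully inside and, if given, inside `mask`).
#' @export
warp_rigid <- function(frame, tf, mask = NULL) {
  .assert_frame(frame)
  .warp_rigid_cpp(frame, tf$tx, tf$ty, tf$phi, mask)
}
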