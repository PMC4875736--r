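# Stage-2 registration: adaptive tracking points on the vessel tree,
# Lucas-Kanade displacement estimation, trackability feedback into the
# tracking-point probability map, and iterative rigid transform fitting.

.hessian <- function(frame) {
  gx <- .sobel_x(frame); gy <- .sobel_y(frame)
  list(gxx = .sobel_x(gx), gxy = .sobel_y(gx), gyy = .sobel_y(gy))
}

#' Hessian eigenvalue vessel map
#'
#' Per-pixel larger eigenvalue of the 2x2 Hessian (second derivatives
#' approximated by repeated Sobel operators). Blood vessels are darker than
#' the background (intensity valleys), so the second derivative across a
#' vessel is large and positive along its centreline. Negative values are
#' clipped to zero and the map is min-max normalised to [0, 1]; a constant
#' frame yields an all-zero map.
#'
#' @param frame preprocessed 2-D intensity matrix.
#' @return matrix in [0, 1], same shape; min 0 and max 1 unless constant.
#' @export
eigen_map <- function(frame) {
  .assert_frame(frame)
  h <- .hessian(frame)
  lam <- 0.5 * (h$gxx + h$gyy) +
    sqrt(0.25 * (h$gxx - h$gyy)^2 + h$gxy^2)
  lam[lam < 0] <- 0
  lo <- min(lam); hi <- max(lam)
  if (hi <= lo) return(lam * 0)
  (lam - lo) / (hi - lo)
}

# Binary erosion by a k-px square radius, separable and with doubling
# steps (erosion by k = composition of erosions summing to k per axis).
.erode <- function(mask, k) {
  out <- mask
  for (along in c(1L, 2L)) {
    left <- k
    d <- 1L
    while (left > 0L) {
      step <- min(d, left)
      out <- .erode_1d(out, step, along)
      left <- left - step
      d <- d * 2L
    }
  }
  out
}

# One-axis erosion by d pixels on each side (min filter of radius d).
.erode_1d <- function(m, d, along) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  if (along == 1L) {
    if (d >= h) return(m & FALSE)
    out[seq_len(h - d), ] <- out[seq_len(h - d), ] & m[d + seq_len(h - d), ]
    out[h - seq_len(d) + 1L, ] <- FALSE
    res <- out
    res[d + seq_len(h - d), ] <- res[d + seq_len(h - d), ] & out[seq_len(h - d), ]
    res[seq_len(d), ] <- FALSE
  } else {
    if (d >= w) return(m & FALSE)
    out[, seq_len(w - d)] <- out[, seq_len(w - d)] & m[, d + seq_len(w - d)]
    out[, w - seq_len(d) + 1L] <- FALSE
    res <- out
    res[, d + seq_len(w - d)] <- res[, d + seq_len(w - d)] & out[, seq_len(w - d)]
    res[, seq_len(d)] <- FALSE
  }
  res
}

# Eigen map restricted to a validity mask: the zero-filled borders of a
# warped frame create strong artificial second derivatives that would
# dominate the min-max normalisation and swamp the vessel signal, so the
# map is zeroed outside the mask eroded by the Hessian support before
# normalisation.
.masked_eigen_map <- function(frame, mask = NULL) {
  if (is.null(mask)) return(eigen_map(frame))
  h <- .hessian(frame)
  lam <- 0.5 * (h$gxx + h$gyy) + sqrt(0.25 * (h$gxx - h$gyy)^2 + h$gxy^2)
  lam[lam < 0] <- 0
  lam[!.erode(mask, 3L)] <- 0
  .renorm01(lam)
}

#' Tracking-point probability map
#'
#' Holds the evolving vessel probability map `lambda_bar` (in [0, 1]) that
#' accumulates per-frame eigen maps with exponential weighting, plus the
#' most recent trackability map.
#'
#' @param lambda_bar initial map, typically `eigen_map()` of the reference.
#' @param q exponential weight in (0, 1); values close to 1 damp the
#'   influence of any single (possibly distorted) frame.
#' @return object of class `tp_map`.
#' @export
tp_map <- function(lambda_bar, q = 0.9) {
  .assert_frame(lambda_bar, "lambda_bar")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  structure(list(lambda_bar = lambda_bar, q = q,
                 quality = lambda_bar * 0), class = "tp_map")
}

.renorm01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi <= lo) return(m * 0)
  (m - lo) / (hi - lo)
}

#' Exponentially weighted update of the probability map
#'
#' Accumulates the current frame's eigen map into the running map,
#' `lambda_bar <- q * lambda_bar + new_lambda`, then min-max renormalises
#' to [0, 1] (the normalisation is performed after every modification).
#' This suppresses the random part of the maps while reinforcing the static
#' vessel tree.
#'
#' @param map a [tp_map()].
#' @param new_lambda eigen map of the currently registered frame.
#' @return the updated `tp_map`.
#' @export
update_probability_map <- function(map, new_lambda) {
  stopifnot(inherits(map, "tp_map"))
  if (!all(dim(new_lambda) == dim(map$lambda_bar)))
    stop("map shapes differ", call. = FALSE)
  map$lambda_bar <- .renorm01(map$q * map$lambda_bar + new_lambda)
  map
}

# Kittler-Illingworth minimum-error threshold on a histogram of `values`.
# Assumes a two-Gaussian mixture; returns the threshold value, or the Otsu
# threshold when the criterion has no interior minimum.
.kittler_threshold <- function(values, bins = 256L) {
  values <- values[is.finite(values)]
  if (!length(values)) return(NA_real_)
  lo <- min(values); hi <- max(values)
  if (hi <= lo) return(lo)
  idx <- pmin(floor((values - lo) / (hi - lo) * bins), bins - 1L)
  cnt <- tabulate(idx + 1L, nbins = bins)
  centers <- lo + (seq_len(bins) - 0.5) / bins * (hi - lo)
  p <- cnt / sum(cnt)
  P1 <- cumsum(p); P2 <- 1 - P1
  m1 <- cumsum(p * centers) / pmax(P1, .Machine$double.eps)
  m2 <- (sum(p * centers) - cumsum(p * centers)) / pmax(P2, .Machine$double.eps)
  s1 <- cumsum(p * centers^2) / pmax(P1, .Machine$double.eps) - m1^2
  s2 <- (sum(p * centers^2) - cumsum(p * centers^2)) /
    pmax(P2, .Machine$double.eps) - m2^2
  vmin <- ((hi - lo) / bins)^2 / 12           # quantisation floor
  s1 <- pmax(s1, vmin); s2 <- pmax(s2, vmin)
  J <- 1 + 2 * (P1 * log(sqrt(s1)) + P2 * log(sqrt(s2))) -
    2 * (P1 * log(pmax(P1, .Machine$double.eps)) +
         P2 * log(pmax(P2, .Machine$double.eps)))
  valid <- which(P1 > 0.001 & P2 > 0.001)
  valid <- valid[valid > 1 & valid < bins]
  if (!length(valid)) return(.otsu_threshold(cnt, centers))
  t <- valid[which.min(J[valid])]
  # no interior minimum -> fall back to Otsu
  if (t == valid[1] && J[valid[1]] <= min(J[valid]) &&
      all(diff(J[valid]) >= 0)) return(.otsu_threshold(cnt, centers))
  centers[t]
}

.otsu_threshold <- function(cnt, centers) {
  p <- cnt / sum(cnt)
  P1 <- cumsum(p)
  mu <- cumsum(p * centers)
  muT <- mu[length(mu)]
  sb <- (muT * P1 - mu)^2 / pmax(P1 * (1 - P1), .Machine$double.eps)
  centers[which.max(sb)]
}

# Zhang-Suen thinning of a logical mask to a 1-px skeleton.
.skeletonize <- function(mask) {
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  h <- nrow(img); w <- ncol(img)
  rs <- seq_len(h) + 1L; cs <- seq_len(w) + 1L
  neigh <- function(p) list(
    P2 = p[rs - 1L, cs], P3 = p[rs - 1L, cs + 1L], P4 = p[rs, cs + 1L],
    P5 = p[rs + 1L, cs + 1L], P6 = p[rs + 1L, cs], P7 = p[rs + 1L, cs - 1L],
    P8 = p[rs, cs - 1L], P9 = p[rs - 1L, cs - 1L])
  subiter <- function(img, first) {
    p <- matrix(0L, h + 2L, w + 2L)
    p[rs, cs] <- img
    n <- neigh(p)
    B <- n$P2 + n$P3 + n$P4 + n$P5 + n$P6 + n$P7 + n$P8 + n$P9
    A <- (n$P2 == 0L & n$P3 == 1L) + (n$P3 == 0L & n$P4 == 1L) +
         (n$P4 == 0L & n$P5 == 1L) + (n$P5 == 0L & n$P6 == 1L) +
         (n$P6 == 0L & n$P7 == 1L) + (n$P7 == 0L & n$P8 == 1L) +
         (n$P8 == 0L & n$P9 == 1L) + (n$P9 == 0L & n$P2 == 1L)
    if (first) {
      c1 <- n$P2 * n$P4 * n$P6 == 0L; c2 <- n$P4 * n$P6 * n$P8 == 0L
    } else {
      c1 <- n$P2 * n$P4 * n$P8 == 0L; c2 <- n$P2 * n$P6 * n$P8 == 0L
    }
    del <- img == 1L & B >= 2L & B <= 6L & A == 1L & c1 & c2
    img[del] <- 0L
    list(img = img, changed = any(del))
  }
  repeat {
    s1 <- subiter(img, TRUE)
    s2 <- subiter(s1$img, FALSE)
    img <- s2$img
    if (!s1$changed && !s2$changed) break
  }
  img == 1L
}

#' Select tracking points from the probability map
#'
#' Binarises `lambda_bar` with the Kittler minimum-error threshold
#' (computed on the 256-bin histogram of its nonzero pixels), removes
#' connected components smaller than `min_area` pixels (segmented vessels
#' should form longer structures), skeletonises the remaining mask to the
#' vessel centrelines, and returns the skeleton pixels as tracking points,
#' uniformly subsampled to at most `max_points`.
#'
#' @param map a [tp_map()] or a plain `lambda_bar` matrix in [0, 1].
#' @param cfg a [retreg_config()] (`min_area`, `max_points`).
#' @return n x 2 matrix of 0-based (x, y) coordinates.
#' @export
select_tracking_points <- function(map, cfg = retreg_config()) {
  lb <- if (inherits(map, "tp_map")) map$lambda_bar else map
  .assert_frame(lb, "lambda_bar")
  nz <- lb[lb > 0]
  if (!length(nz)) stop("no tracking points", call. = FALSE)
  thr <- .kittler_threshold(nz, 256L)
  mask <- lb > thr
  if (!any(mask)) stop("no tracking points", call. = FALSE)
  lab <- EBImage::bwlabel(t(mask))      # EBImage indexes [x, y]
  areas <- tabulate(as.integer(lab))
  keep <- which(areas >= cfg$min_area)
  mask <- t(matrix(as.integer(lab) %in% keep, nrow(lab), ncol(lab)))
  if (!any(mask)) stop("no tracking points", call. = FALSE)
  skel <- .skeletonize(mask)
  idx <- which(skel)
  if (!length(idx)) stop("no tracking points", call. = FALSE)
  h <- nrow(skel)
  pts <- cbind(x = (idx - 1L) %/% h, y = (idx - 1L) %% h)
  if (nrow(pts) > cfg$max_points) {
    stride <- seq(1L, nrow(pts), length.out = cfg$max_points)
    pts <- pts[unique(round(stride)), , drop = FALSE]
  }
  pts
}

#' Lucas-Kanade displacement of tracking points
#'
#' For each tracking point, solves the 2x2 linear system given by the two
#' normal equations of the first-order expansion of the window SSD: with
#' temporal difference \eqn{D = g_i - g_r} and spatial gradients
#' \eqn{I_x, I_y} of the moving frame over the M x M window,
#' \deqn{\sum (D + I_x dx + I_y dy) I_x = 0, \quad
#'       \sum (D + I_x dx + I_y dy) I_y = 0.}
#' Points whose window leaves the image (or the validity mask) are skipped;
#' points with a singular or ill-conditioned structure matrix (aperture
#' problem, e.g. textureless regions) and points whose displacement exceeds
#' half the window are marked lost.
#'
#' @param reference,moving 2-D intensity matrices (preprocessed; the moving
#'   frame already coarse-aligned / warped).
#' @param points n x 2 matrix of 0-based (x, y) tracking points in
#'   reference coordinates.
#' @param window odd LK window size M (default 31).
#' @param mask optional logical validity mask of `moving`; windows touching
#'   invalid pixels are skipped.
#' @return data.frame with columns `x`, `y`, `dx`, `dy`, `lost`.
#' @export
lk_displacement <- function(reference, moving, points, window = 31L,
                            mask = NULL) {
  .assert_frame(reference, "reference"); .assert_frame(moving, "moving")
  stopifnot(all(dim(reference) == dim(moving)))
  points <- matrix(as.numeric(points), ncol = 2)
  h <- nrow(moving); w <- ncol(moving)
  hw <- (window - 1L) %/% 2L
  xs <- round(points[, 1]); ys <- round(points[, 2])
  out <- data.frame(x = points[, 1], y = points[, 2],
                    dx = NA_real_, dy = NA_real_, lost = TRUE)
  ok <- xs >= hw & xs <= w - 1L - hw & ys >= hw & ys <= h - 1L - hw
  if (!any(ok)) return(out)
  sol <- .lk_solve_cpp(reference, moving, as.integer(xs[ok]),
                       as.integer(ys[ok]), as.integer(window), mask)
  out$dx[ok] <- sol$dx
  out$dy[ok] <- sol$dy
  out$lost[ok] <- sol$lost
  out
}

#' Raw trackability score of tracked points
#'
#' Evaluates, at the solved displacement, the residual-weighted gradient
#' sum
#' \deqn{Q = \frac{1}{2 M^2} \sum_{(x,y) \in W}
#'   (D + I_x dx + I_y dy)(I_x + I_y),}
#' where the factor \eqn{M^2} normalises for window size (the sum runs over
#' one M x M window for each of the two directions). |Q| grows with the
#' misfit: a perfectly tracked point has zero residual and |Q| = 0.
#'
#' @inheritParams lk_displacement
#' @param tp data.frame from [lk_displacement()] (columns `x`, `y`, `dx`,
#'   `dy`, `lost`).
#' @return numeric vector of raw signed Q values (NA for lost points).
#' @export
trackability <- function(reference, moving, tp, window = 31L) {
  q <- rep(NA_real_, nrow(tp))
  use <- which(!tp$lost & !is.na(tp$dx))
  if (!length(use)) return(q)
  q[use] <- .lk_q_cpp(reference, moving,
                      as.integer(round(tp$x[use])),
                      as.integer(round(tp$y[use])),
                      tp$dx[use], tp$dy[use], as.integer(window))
  q
}

# Assemble per-point raw Q values into a normalised quality image:
# score = 1 - |Q| / max |Q| (1 = good), placed at the point pixels and
# spread spatially by a compact Gaussian kernel (support <= window/2, so
# the map stays zero outside the union of point windows).
.q_map <- function(dim_hw, tp, qraw, window, sigma) {
  qimg <- matrix(0, dim_hw[1], dim_hw[2])
  use <- which(!is.na(qraw))
  if (!length(use)) return(qimg)
  aq <- abs(qraw[use])
  score <- if (max(aq) > 0) 1 - aq / max(aq) else rep(1, length(aq))
  idx <- round(tp$y[use]) + 1L + dim_hw[1] * round(tp$x[use])
  qimg[idx] <- pmax(qimg[idx], score)
  radius <- min(ceiling(3 * sigma), (window - 1L) %/% 2L)
  qimg <- .gauss_sep(qimg, sigma, radius = radius)
  if (max(qimg) > 0) qimg <- qimg / max(qimg)
  qimg
}

#' Fine (stage-2) registration of one frame
#'
#' Iterates tracking-point selection, Lucas-Kanade displacement, rigid
#' least-squares fitting and rigid warping until the parameter change
#' between iterations falls below the tolerances (0.05 px for shifts, 2
#' degrees for rotation, by default) or the iteration cap is reached;
#' typical behaviour is convergence within a handful of iterations. If the
#' parameter change grows for 3 consecutive iterations, or too few valid
#' points remain, the frame is marked failed and the caller keeps the
#' stage-1 transform.
#'
#' After convergence the trackability map multiplies into the probability
#' map (`lambda_bar * (1 + Q)`, which raises only locations already above
#' zero), the registered frame's eigen map is accumulated with exponential
#' weighting, and the map is renormalised -- ready for the next frame.
#'
#' @param reference preprocessed reference frame.
#' @param moving preprocessed, coarse-aligned moving frame.
#' @param map a [tp_map()] carried along the sequence.
#' @param cfg a [retreg_config()].
#' @param mask optional validity mask of `moving` (from the coarse shift).
#' @param init optional [rigid_transform()] warm start (e.g. the previous
#'   frame's residual transform: fixational torsion is temporally
#'   persistent, so seeding the rotation saves iterations).
#' @return list with `tf` (residual [rigid_transform()] of the moving frame
#'   relative to the reference), `iterations`, `converged`, `failed`,
#'   `map` (updated [tp_map()]), `n_points`.
#' @export
fine_register_frame <- function(reference, moving, map,
                                cfg = retreg_config(), mask = NULL,
                                init = NULL) {
  stopifnot(inherits(map, "tp_map"))
  dim_hw <- dim(reference)
  points <- tryCatch(select_tracking_points(map, cfg),
                     error = function(e) NULL)
  fail <- function(reason) {
    lam <- .masked_eigen_map(moving, mask)
    list(tf = rigid_transform(), iterations = 0L, converged = FALSE,
         failed = TRUE, reason = reason,
         map = update_probability_map(map, lam), n_points = 0L)
  }
  if (is.null(points) || nrow(points) < 2) return(fail("no tracking points"))
  h <- dim_hw[1]; w <- dim_hw[2]
  hw <- (cfg$window - 1L) %/% 2L
  margin_ok <- points[, 1] >= hw & points[, 1] <= w - 1L - hw &
               points[, 2] >= hw & points[, 2] <= h - 1L - hw
  points <- points[margin_ok, , drop = FALSE]
  if (nrow(points) < 2) return(fail("no tracking points"))
  ptx <- as.integer(points[, 1]); pty <- as.integer(points[, 2])
  tf <- if (is.null(init)) rigid_transform() else init
  if (.is_identity(tf)) {
    warped <- moving; wmask <- mask
  } else {
    wr <- warp_rigid(moving, tf, mask)
    warped <- wr$image; wmask <- wr$mask
  }
  prev_resid <- Inf; n_grow <- 0L
  iterations <- 0L; converged <- FALSE; failed <- FALSE
  tp <- NULL
  while (iterations < cfg$max_iter) {
    iterations <- iterations + 1L
    sol <- .lk_solve_cpp(reference, warped, ptx, pty,
                         as.integer(cfg$window), wmask)
    tp <- data.frame(x = points[, 1], y = points[, 2],
                     dx = sol$dx, dy = sol$dy, lost = sol$lost)
    valid <- !tp$lost
    if (sum(valid) < 2) { failed <- TRUE; break }
    # residual point motion still to be explained by the transform
    resid <- median(sqrt(tp$dx[valid]^2 + tp$dy[valid]^2))
    dtf <- fit_rigid(points[valid, , drop = FALSE],
                     cbind(points[valid, 1] + tp$dx[valid],
                           points[valid, 2] + tp$dy[valid]),
                     dim_hw = dim_hw)
    tf <- .compose_tf(tf, dtf)
    wr <- warp_rigid(moving, tf, mask)
    warped <- wr$image; wmask <- wr$mask
    # parameter change expressed at the tracking points: the largest pixel
    # displacement the increment induces on any tracked point, so shift and
    # rotation changes share one scale
    moved <- .apply_tf(dtf, points[valid, , drop = FALSE], .image_centre(dim_hw))
    change <- max(sqrt((moved[, 1] - points[valid, 1])^2 +
                       (moved[, 2] - points[valid, 2])^2))
    if (change < cfg$tol_shift && abs(dtf$phi) < cfg$tol_rot) {
      converged <- TRUE; break
    }
    # divergence: the residual (not the increment, which can legitimately
    # grow while a large rotation is being recovered) grows repeatedly and
    # clearly; noise makes small non-monotonicity normal
    if (iterations > 2L && resid > prev_resid * 1.1)
      n_grow <- n_grow + 1L else n_grow <- 0L
    if (n_grow >= 4L) { failed <- TRUE; break }
    prev_resid <- resid
  }
  # a fit that ran out of iterations without shrinking the point motion to
  # subpixel scale, or drifted to an implausibly large residual transform,
  # is unreliable: fall back to the stage-1 result
  if (!failed && !converged && !is.null(tp)) {
    valid <- !tp$lost
    if (sum(valid) < 2 ||
        median(sqrt(tp$dx[valid]^2 + tp$dy[valid]^2)) > 1)
      failed <- TRUE
  }
  if (!failed &&
      (abs(tf$tx) > cfg$window || abs(tf$ty) > cfg$window ||
       abs(tf$phi) > 10)) failed <- TRUE
  if (failed) {
    lam <- .masked_eigen_map(moving, mask)
    return(list(tf = rigid_transform(), iterations = iterations,
                converged = FALSE, failed = TRUE, reason = "diverged",
                map = update_probability_map(map, lam),
                n_points = nrow(points)))
  }
  qraw <- trackability(reference, warped, tp, cfg$window)
  qimg <- .q_map(dim_hw, tp, qraw, cfg$window, cfg$q_sigma)
  map$quality <- qimg
  map$lambda_bar <- map$lambda_bar * (1 + qimg)
  map <- update_probability_map(map, .masked_eigen_map(warped, wmask))
  list(tf = tf, iterations = iterations, converged = converged,
       failed = FALSE, reason = NULL, map = map, n_points = nrow(points))
}
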