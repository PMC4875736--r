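# Synthetic retinal phantom: a static vessel tree (dark curvilinear valleys
# on a brighter background, Gaussian cross-section) with a brighter optic
# nerve head disc, moved rigidly per frame, degraded by additive Gaussian
# noise at a scripted SNR and by scheduled blur / blink artefacts. Every
# frame is rendered analytically at transformed coordinates, so the scripted
# transforms are exact ground truth with no interpolation error.

#' Phantom specification
#'
#' Describes the static scene: image size, vessel tree (polylines with
#' per-segment full width and darkness contrast), the bright optic nerve
#' head disc, the background level, and a rectangular homogeneous patch
#' used for SNR measurements (guaranteed structure-free in the unmoved
#' phantom). Vessels are defined in relative coordinates and scaled to the
#' image; widths are given in pixels at the nominal 640-wide geometry and
#' scale with the image width, capped to the modelled range [2, 21] px.
#'
#' @param image_size `c(height, width)` in pixels (nominal 480 x 640).
#' @param vessels list of vessel descriptors `list(pts = k x 2 matrix of
#'   relative (x, y) polyline vertices, width = px, contrast = depth)`;
#'   `NULL` for the built-in tree.
#' @param onh list `list(centre = c(x, y) relative, radius = relative to
#'   height, brightness = offset)`.
#' @param background background intensity level.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(480L, 640L), vessels = NULL,
                         onh = list(centre = c(0.42, 0.5), radius = 0.14,
                                    brightness = 0.16),
                         background = 0.55) {
  h <- image_size[1]; w <- image_size[2]
  if (is.null(vessels)) {
    seg <- function(..., width, contrast)
      list(pts = do.call(rbind, list(...)), width = width, contrast = contrast)
    vessels <- list(
      seg(c(0.04, 0.62), c(0.42, 0.50), c(0.95, 0.35), width = 14, contrast = 0.30),
      seg(c(0.04, 0.40), c(0.42, 0.53), c(0.92, 0.70), width = 10, contrast = 0.26),
      seg(c(0.42, 0.50), c(0.30, 0.26), c(0.22, 0.06), width = 7,  contrast = 0.22),
      seg(c(0.43, 0.52), c(0.55, 0.75), c(0.52, 0.95), width = 8,  contrast = 0.24),
      seg(c(0.28, 0.74), c(0.55, 0.82), c(0.78, 0.86), width = 5,  contrast = 0.18),
      seg(c(0.10, 0.12), c(0.30, 0.22), c(0.45, 0.30), width = 4,  contrast = 0.15),
      seg(c(0.58, 0.58), c(0.66, 0.45), c(0.64, 0.36), width = 4,  contrast = 0.14)
    )
  }
  scale_w <- w / 640
  vessels <- lapply(vessels, function(v) {
    v$width_px <- min(max(v$width * scale_w, 2), 21)
    v
  })
  for (v in vessels) {
    if (any(v$pts < 0) || any(v$pts > 1))
      stop("vessel outside image", call. = FALSE)
  }
  structure(list(
    image_size = as.integer(image_size), vessels = vessels, onh = onh,
    background = background,
    # homogeneous top-right patch, clear of vessels in the unmoved phantom
    snr_patch = c(round(0.70 * w), round(0.05 * h),
                  max(10L, round(0.20 * w)), max(10L, round(0.18 * h)))
  ), class = "phantom_spec")
}

# Distance from points (x, y) to segment a-b (all 0-based px, vectorised).
.seg_dist <- function(x, y, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  l2 <- vx^2 + vy^2
  if (l2 == 0) return(sqrt((x - a[1])^2 + (y - a[2])^2))
  t <- pmin(pmax(((x - a[1]) * vx + (y - a[2]) * vy) / l2, 0), 1)
  sqrt((x - a[1] - t * vx)^2 + (y - a[2] - t * vy)^2)
}

# Evaluate the phantom intensity field at arbitrary 0-based coordinates.
.phantom_field <- function(spec, x, y) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  val <- rep(spec$background, length(x))
  oc <- spec$onh$centre * c(w - 1, h - 1)
  orad <- spec$onh$radius * h
  d <- sqrt((x - oc[1])^2 + (y - oc[2])^2)
  val <- val + spec$onh$brightness / (1 + exp((d - orad) / 1.5))
  for (v in spec$vessels) {
    p <- v$pts %*% diag(c(w - 1, h - 1))
    sigma <- v$width_px / 4        # full width ~ +-2 sigma of the valley
    dmin <- NULL
    for (k in seq_len(nrow(p) - 1)) {
      dk <- .seg_dist(x, y, p[k, ], p[k + 1, ])
      dmin <- if (is.null(dmin)) dk else pmin(dmin, dk)
    }
    val <- val - v$contrast * exp(-dmin^2 / (2 * sigma^2))
  }
  .clip01(val)
}

#' Render the static phantom
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (h x w matrix) and `centrelines` (list of
#'   n x 2 matrices of 0-based (x, y) samples along each vessel centreline,
#'   1 px apart) for oracle use.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  xs <- rep(seq_len(w) - 1L, each = h)
  ys <- rep(seq_len(h) - 1L, times = w)
  img <- matrix(.phantom_field(spec, xs, ys), h, w)
  centrelines <- lapply(spec$vessels, function(v) {
    p <- v$pts %*% diag(c(w - 1, h - 1))
    out <- NULL
    for (k in seq_len(nrow(p) - 1)) {
      len <- sqrt(sum((p[k + 1, ] - p[k, ])^2))
      t <- seq(0, 1, length.out = max(2L, ceiling(len) + 1L))
      out <- rbind(out, cbind(p[k, 1] + t * (p[k + 1, 1] - p[k, 1]),
                              p[k, 2] + t * (p[k + 1, 2] - p[k, 2])))
    }
    colnames(out) <- c("x", "y")
    out
  })
  list(image = img, centrelines = centrelines)
}

#' Motion script for a synthetic sequence
#'
#' Draws per-frame rigid transforms emulating eye motion during single-spot
#' fixation: a slow first-order autoregressive drift around the fixation
#' point, interrupted by occasional saccadic jumps (probability 0.08 per
#' frame), with shifts truncated to `max_shift` pixels per axis and
#' rotations to `max_rot` degrees. Frame 0 starts at identity. An artefact
#' schedule and the noise level complete the script; all randomness is
#' governed by `seed`.
#'
#' @param n_frames number of frames (>= 2).
#' @param max_shift maximum |shift| per axis in pixels (<= 50).
#' @param max_rot maximum |rotation| in degrees (<= 5).
#' @param noise_snr_db additive-noise SNR in dB (20 log10(mean/sd) in a
#'   homogeneous region); the modelled acquisition sits around 19 dB.
#' @param artefacts list of per-frame artefact descriptors: `NULL` entries
#'   or `list(type = "blur", sigma = px)` / `list(type = "blink",
#'   fraction = saturated area fraction)`. Recycled with `NULL` if shorter
#'   than `n_frames`.
#' @param seed integer seed fixing all randomness.
#' @return object of class `motion_script` with element `transforms`
#'   (list of [rigid_transform()]).
#' @export
motion_script <- function(n_frames = 60L, max_shift = 30, max_rot = 3,
                          noise_snr_db = 19, artefacts = NULL, seed = 1L) {
  stopifnot(n_frames >= 2, abs(max_shift) <= 50, abs(max_rot) <= 5)
  set.seed(seed)
  transforms <- vector("list", n_frames)
  transforms[[1]] <- rigid_transform()
  pos <- c(0, 0); rot <- 0
  clamp <- function(v, lim) pmin(pmax(v, -lim), lim)
  for (i in seq_len(n_frames)[-1]) {
    pos <- 0.95 * pos + rnorm(2, 0, max_shift / 10)      # fixation drift
    sacc <- runif(1) < 0.08                               # saccade
    if (sacc) pos <- pos + rnorm(2, 0, max_shift / 2)
    pos <- clamp(pos, max_shift)
    # ocular torsion during fixation is far smaller than the translation:
    # slow sub-degree wander plus a small kick at saccades, bounded by
    # max_rot
    rot <- 0.9 * rot + rnorm(1, 0, max_rot / 10)
    if (sacc) rot <- rot + rnorm(1, 0, max_rot / 6)
    rot <- clamp(rot, max_rot)
    transforms[[i]] <- rigid_transform(pos[1], pos[2], rot)
  }
  sched <- vector("list", n_frames)
  if (!is.null(artefacts))
    for (i in seq_along(artefacts))
      if (i <= n_frames && !is.null(artefacts[[i]]))
        sched[[i]] <- artefacts[[i]]
  structure(list(transforms = transforms, artefacts = sched,
                 noise_snr_db = noise_snr_db, seed = as.integer(seed)),
            class = "motion_script")
}

#' Render a synthetic retinal sequence with ground truth
#'
#' Each frame is the phantom field evaluated at rigidly transformed
#' coordinates (analytic rendering: the scripted transform is exact ground
#' truth), followed by the scheduled artefact (Gaussian motion blur or a
#' bright blink/reflection disc saturating a given area fraction) and
#' additive white Gaussian noise scaled to the scripted SNR. Gaussian noise
#' is the simplest model consistent with the mean/sd SNR definition used.
#'
#' @param spec a [phantom_spec()].
#' @param script a [motion_script()].
#' @return list with `sequence` (a [frame_sequence()]), `truth` (the
#'   script's transforms), `centrelines`, `clean` (noise-free frames) and
#'   `snr_patch`.
#' @export
render_sequence <- function(spec, script) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(script, "motion_script"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  centre <- .image_centre(c(h, w))
  xs <- rep(seq_len(w) - 1L, each = h)
  ys <- rep(seq_len(h) - 1L, times = w)
  set.seed(script$seed + 1L)
  sigma_noise <- if (is.finite(script$noise_snr_db))
    spec$background / 10^(script$noise_snr_db / 20) else 0
  n <- length(script$transforms)
  frames <- vector("list", n)
  clean <- vector("list", n)
  for (i in seq_len(n)) {
    tf <- script$transforms[[i]]
    p <- if (.is_identity(tf)) cbind(xs, ys)
         else .apply_tf(.invert_tf(tf), cbind(xs, ys), centre)
    img <- matrix(.phantom_field(spec, p[, 1], p[, 2]), h, w)
    art <- script$artefacts[[i]]
    if (!is.null(art)) {
      if (art$type == "blur") {
        img <- .gauss_sep(img, art$sigma)
      } else if (art$type == "blink") {
        rad <- sqrt(art$fraction * h * w / pi)
        d <- sqrt((xs - centre[1])^2 + (ys - centre[2])^2)
        glare <- matrix(1 / (1 + exp((d - rad) / 2)), h, w)
        img <- img * (1 - glare) + glare
      } else stop("unknown artefact type: ", art$type, call. = FALSE)
    }
    clean[[i]] <- img
    if (sigma_noise > 0)
      img <- .clip01(img + matrix(rnorm(h * w, 0, sigma_noise), h, w))
    frames[[i]] <- img
  }
  ph <- render_phantom(spec)
  list(sequence = frame_sequence(frames, source = "synthetic"),
       truth = script$transforms,
       centrelines = ph$centrelines,
       clean = clean,
       snr_patch = spec$snr_patch)
}

#' Scripted transform of frame `i` relative to frame `r`
#'
#' Registration reports motion relative to its chosen reference frame,
#' while the script stores motion relative to the unmoved phantom; the two
#' are related by `T_i o T_r^{-1}`.
#'
#' @param truth list of scripted [rigid_transform()]s.
#' @param i,r 0-based frame indices (moving, reference).
#' @return a [rigid_transform()].
#' @export
true_relative_transform <- function(truth, i, r) {
  .compose_tf(truth[[i + 1L]], .invert_tf(truth[[r + 1L]]))
}
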