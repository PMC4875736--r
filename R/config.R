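#' Pipeline configuration
#'
#' Collects every tunable parameter of the registration pipeline with the
#' published defaults: 3x3 median window, 128 entropy bins, 31x31 LK window,
#' 0.05 px / 2 degree fine-stage stopping tolerances and 4x evaluation
#' upsampling. Unknown arguments are rejected by name so configuration typos
#' fail loudly.
#'
#' @param median_window odd median-filter window size in pixels.
#' @param clahe_clip CLAHE clip limit as a fraction of the uniform histogram
#'   height (normalised, skimage-style).
#' @param clahe_tiles integer CLAHE tile grid, `c(nx, ny)`.
#' @param entropy_bins histogram bins for the edge-image entropy.
#' @param quality_k distorted-frame threshold is `median(E) - quality_k *
#'   mad(E)`; the published procedure adjusts this threshold manually, the
#'   default is a robust automatic stand-in.
#' @param peak_warn_below coarse-stage correlation-peak height below which a
#'   low-confidence note is recorded.
#' @param q exponential weight of the tracking-point probability map
#'   (memory of roughly `1/(1-q)` frames); the method calls for a value
#'   close to 1.
#' @param window LK window size M (odd, pixels); 31 px spans the thickest
#'   vessels (about 21 px) plus the residual inter-frame motion.
#' @param min_area minimum connected-component area (px) kept in the
#'   tracking-point mask.
#' @param max_points cap on the number of skeleton tracking points (uniform
#'   subsampling along the skeleton).
#' @param tol_shift,tol_rot fine-stage convergence tolerances: iteration
#'   stops when the parameter change drops below `tol_shift` pixels for both
#'   shifts and `tol_rot` degrees for rotation.
#' @param max_iter hard cap on fine-stage iterations.
#' @param q_sigma standard deviation (px) of the Gaussian kernel that spreads
#'   the trackability score spatially; defaults to `window / 6`.
#' @param upsample evaluation profile upsampling factor.
#' @param n_sites default number of automatically proposed evaluation sites.
#' @param ... ignored; any named argument here is an unknown key and raises
#'   an error naming it.
#' @return a named list of class `retreg_config`.
#' @examples
#' cfg <- retreg_config(q = 0.95)
#' @export
retreg_config <- function(median_window = 3L,
                          clahe_clip = 0.01,
                          clahe_tiles = c(8L, 8L),
                          entropy_bins = 128L,
                          quality_k = 3,
                          peak_warn_below = 0.03,
                          q = 0.9,
                          window = 31L,
                          min_area = 20L,
                          max_points = 400L,
                          tol_shift = 0.05,
                          tol_rot = 2,
                          max_iter = 20L,
                          q_sigma = NULL,
                          upsample = 4L,
                          n_sites = 18L,
                          ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  if (median_window %% 2 != 1 || median_window < 1)
    stop("median_window must be an odd integer >= 1", call. = FALSE)
  if (clahe_clip <= 0) stop("clahe_clip must be > 0", call. = FALSE)
  if (entropy_bins < 2) stop("entropy_bins must be >= 2", call. = FALSE)
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  if (window %% 2 != 1 || window < 3)
    stop("window must be an odd integer >= 3", call. = FALSE)
  if (upsample < 1) stop("upsample must be >= 1", call. = FALSE)
  if (is.null(q_sigma)) q_sigma <- window / 6
  structure(list(
    median_window = as.integer(median_window),
    clahe_clip = clahe_clip,
    clahe_tiles = as.integer(clahe_tiles),
    entropy_bins = as.integer(entropy_bins),
    quality_k = quality_k,
    peak_warn_below = peak_warn_below,
    q = q,
    window = as.integer(window),
    min_area = as.integer(min_area),
    max_points = as.integer(max_points),
    tol_shift = tol_shift,
    tol_rot = tol_rot,
    max_iter = as.integer(max_iter),
    q_sigma = q_sigma,
    upsample = as.integer(upsample),
    n_sites = as.integer(n_sites)
  ), class = "retreg_config")
}

#' @export
print.retreg_config <- function(x, ...) {
  cat("retreg configuration:\n")
  for (k in names(x)) cat(sprintf("  %-15s %s\n", k, paste(x[[k]], collapse = " ")))
  invisible(x)
}
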