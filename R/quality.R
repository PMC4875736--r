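#' Sobel edge image of a frame
#'
#' Gradient magnitude from the horizontal and vertical Sobel responses,
#' computed on the CLAHE-enhanced frame. Blur (from eye movements) and
#' bright blink reflections both flatten this edge image, which is what the
#' entropy score detects.
#'
#' @param frame 2-D intensity matrix.
#' @param cfg a [retreg_config()] (CLAHE parameters).
#' @param enhance apply CLAHE before the gradient (the standard path);
#'   set FALSE to get the plain Sobel magnitude.
#' @return non-negative matrix, same shape.
#' @export
edge_image <- function(frame, cfg = retreg_config(), enhance = TRUE) {
  .assert_frame(frame)
  if (enhance) frame <- enhance_contrast(.clip01(frame), cfg)
  gx <- .sobel_x(frame)
  gy <- .sobel_y(frame)
  sqrt(gx^2 + gy^2)
}

#' Histogram entropy of an edge image
#'
#' Shannon entropy \eqn{E = -\sum_i p_i \log p_i} of the `n_bins`-bin
#' histogram of the edge image (natural log; the base only rescales E and
#' the frame ordering is base-invariant). Empty bins contribute zero, so
#' \eqn{0 \le E \le \log(n\_bins)}. A sharp frame has a wide tonal edge
#' distribution (high E); a blurred or reflection-saturated frame collapses
#' into a dominant peak (low E).
#'
#' @param frame edge image (output of [edge_image()]).
#' @param n_bins number of histogram bins (default 128).
#' @param range histogram range; defaults to `c(0, max(frame))`. When
#'   scoring a whole sequence the caller fixes one range for all frames so
#'   entropies are comparable.
#' @return scalar entropy (nats).
#' @export
frame_entropy <- function(frame, n_bins = 128L, range = NULL) {
  .assert_frame(frame)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (is.null(range)) range <- c(0, max(frame))
  if (range[2] <= range[1]) return(0)
  idx <- pmin(pmax(floor((as.vector(frame) - range[1]) /
                           (range[2] - range[1]) * n_bins), 0), n_bins - 1L)
  p <- tabulate(idx + 1L, nbins = n_bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Score frames and select the reference frame
#'
#' Computes the edge-image entropy of every frame (one histogram range per
#' sequence), takes the maximum-entropy frame as the reference (ties broken
#' to the lowest index) and flags frames whose entropy falls below
#' `median(E) - quality_k * mad(E)` as distorted (blur / blink). The
#' published procedure sets this threshold manually; the robust default
#' automates the same intent and is overridable via `threshold`.
#'
#' @param seq a [frame_sequence()] or list of frames.
#' @param cfg a [retreg_config()].
#' @param threshold optional explicit entropy threshold for flagging.
#' @return object of class `retreg_quality`: list with `entropy`,
#'   `reference_index` (0-based), `distorted` (logical), `threshold`.
#' @export
select_reference <- function(seq, cfg = retreg_config(), threshold = NULL) {
  frames <- if (inherits(seq, "frame_sequence")) seq$frames else seq
  if (length(frames) < 2)
    stop("need at least 2 frames to select a reference", call. = FALSE)
  edges <- lapply(frames, edge_image, cfg = cfg)
  emax <- max(vapply(edges, max, 0))
  ent <- vapply(edges, frame_entropy, 0,
                n_bins = cfg$entropy_bins, range = c(0, emax))
  if (is.null(threshold)) {
    m <- median(ent)
    threshold <- m - cfg$quality_k * mad(ent)
  }
  structure(list(
    entropy = ent,
    reference_index = which.max(ent) - 1L,
    distorted = ent < threshold,
    threshold = threshold
  ), class = "retreg_quality")
}

#' @export
print.retreg_quality <- function(x, ...) {
  cat(sprintf(
    "frame quality: %d frames, reference = frame %d (E = %.4f), %d distorted (threshold %.4f)\n",
    length(x$entropy), x$reference_index,
    x$entropy[x$reference_index + 1L], sum(x$distorted), x$threshold))
  invisible(x)
}
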