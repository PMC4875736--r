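#' Phase-correlation shift estimate between two frames
#'
#' Applies a separable Hanning window of the image size to both frames
#' (required because the DFT is periodic), forms the normalised cross-power
#' spectrum, inverse-transforms, and reads the integer shift off the global
#' maximum of the resulting correlation surface (a pure shift gives a Dirac
#' peak at the displacement). Peak coordinates at or past half the image
#' size wrap to negative shifts, so |shift| < size/2. No subpixel peak
#' interpolation is performed: subpixel refinement belongs to the fine
#' stage.
#'
#' The returned `(dx, dy)` is the displacement of the moving frame relative
#' to the reference; translating the moving frame by `(-dx, -dy)` aligns it.
#'
#' @param reference,moving 2-D intensity matrices of identical shape,
#'   already preprocessed (median-filtered and contrast-enhanced).
#' @param eps guard added to the spectrum magnitude before normalisation.
#' @return list with `dx`, `dy` (signed integer pixels) and `peak_value`
#'   (height of the correlation peak, a confidence signal).
#' @export
phase_correlate <- function(reference, moving, eps = 1e-12) {
  .assert_frame(reference, "reference"); .assert_frame(moving, "moving")
  if (!all(dim(reference) == dim(moving)))
    stop("reference and moving frames differ in shape", call. = FALSE)
  if (all(reference == 0) || all(moving == 0))
    stop("degenerate spectrum: all-zero image", call. = FALSE)
  h <- nrow(reference); w <- ncol(reference)
  win <- outer(.hanning(h), .hanning(w))
  f1 <- fft(reference * win)
  f2 <- fft(moving * win)
  cross <- f2 * Conj(f1)
  cross <- cross / (Mod(cross) + eps)
  corr <- Re(fft(cross, inverse = TRUE)) / length(cross)
  i <- which.max(corr)
  py <- (i - 1L) %% h
  px <- (i - 1L) %/% h
  list(dx = if (px >= w / 2) px - w else px,
       dy = if (py >= h / 2) py - h else py,
       peak_value = corr[i])
}

#' Coarse (stage-1) registration of a sequence
#'
#' Estimates the integer translation of every preprocessed frame against
#' the preprocessed reference by [phase_correlate()], then resamples each
#' frame by its integer shift (zero-filling exposed borders and carrying a
#' validity mask forward so the fine stage ignores invalid border pixels).
#' Distorted frames are still estimated; their correlation peak is
#' typically far below the sequence median and is reported as a confidence
#' signal.
#'
#' @param pre list of preprocessed frames.
#' @param reference_index 0-based index of the reference frame.
#' @param cfg a [retreg_config()].
#' @return list with per-frame `shifts` (list of `dx`, `dy`, `peak_value`),
#'   `aligned` (shifted preprocessed frames) and `masks` (validity masks).
#' @export
coarse_register <- function(pre, reference_index, cfg = retreg_config()) {
  n <- length(pre)
  if (reference_index < 0 || reference_index >= n)
    stop("reference_index out of range", call. = FALSE)
  ref <- pre[[reference_index + 1L]]
  shifts <- vector("list", n)
  aligned <- vector("list", n)
  masks <- vector("list", n)
  full <- matrix(TRUE, nrow(ref), ncol(ref))
  for (i in seq_len(n)) {
    if (i == reference_index + 1L) {
      shifts[[i]] <- list(dx = 0L, dy = 0L, peak_value = 1)
      aligned[[i]] <- pre[[i]]
      masks[[i]] <- full
    } else {
      s <- phase_correlate(ref, pre[[i]])
      sh <- .shift_zero(pre[[i]], -s$dx, -s$dy)
      shifts[[i]] <- s
      aligned[[i]] <- sh$image
      masks[[i]] <- sh$mask
    }
  }
  list(shifts = shifts, aligned = aligned, masks = masks)
}
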