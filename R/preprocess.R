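#' Median-filter noise suppression
#'
#' Applies the square median filter (default 3x3) used before both
#' registration stages. Median filtering raises the SNR of the homogeneous
#' retinal background while preserving vessel edges, which sharpens the
#' phase-correlation peak. Borders are handled by reflection padding so the
#' frame margins are not darkened (a dark border would bias the FFTs).
#'
#' @param frame 2-D intensity matrix.
#' @param cfg a [retreg_config()]; only `median_window` is used.
#' @return filtered matrix, same shape.
#' @export
denoise <- function(frame, cfg = retreg_config()) {
  .assert_frame(frame)
  w <- cfg$median_window
  if (w %% 2 != 1) stop("median window must be odd", call. = FALSE)
  if (w == 1) return(frame)
  if (w == 3) return(.median3(frame))
  # general odd window: reflect-pad and take running medians
  k <- (w - 1L) %/% 2L
  p <- .pad_reflect(frame, k)
  h <- nrow(frame); wd <- ncol(frame)
  out <- matrix(0, h, wd)
  for (r in seq_len(h)) for (c in seq_len(wd))
    out[r, c] <- median(p[r:(r + 2L * k), c:(c + 2L * k)])
  out
}

#' CLAHE contrast equalisation
#'
#' Contrast-limited adaptive histogram equalisation, applied to every frame
#' before registration and before the entropy score. It raises the local
#' contrast of blood vessels, on which both registration stages rely. The
#' clip limit is expressed as a fraction of the uniform histogram height;
#' the frame is reflect-padded to a tile-grid multiple and cropped back, so
#' any frame size is accepted.
#'
#' @param frame 2-D intensity matrix in [0, 1].
#' @param cfg a [retreg_config()]; uses `clahe_clip` and `clahe_tiles`.
#' @return equalised matrix in [0, 1], same shape.
#' @export
enhance_contrast <- function(frame, cfg = retreg_config()) {
  .assert_frame(frame)
  if (min(frame) < 0 || max(frame) > 1)
    stop("enhance_contrast expects intensities in [0, 1]", call. = FALSE)
  if (max(frame) - min(frame) < 1e-12) return(frame)  # no contrast to equalise
  nx <- cfg$clahe_tiles[1]; ny <- cfg$clahe_tiles[2]
  h <- nrow(frame); w <- ncol(frame)
  # pad to a multiple of the tile grid (EBImage requires exact tiling)
  ph <- ceiling(h / ny) * ny; pw <- ceiling(w / nx) * nx
  ri <- c(seq_len(h), h - seq_len(ph - h) + 1L)
  ci <- c(seq_len(w), w - seq_len(pw - w) + 1L)
  padded <- frame[ri, ci, drop = FALSE]
  bins <- 256L
  out <- EBImage::clahe(t(padded), nx = nx, ny = ny, bins = bins,
                        limit = max(cfg$clahe_clip * bins, 1), keep.range = TRUE)
  out <- t(out)[seq_len(h), seq_len(w), drop = FALSE]
  .clip01(out)
}

#' Full preprocessing of one frame
#'
#' Median filtering followed by CLAHE; this working copy drives every
#' estimation step, while the final geometric transform is applied to the
#' original frame so registered output keeps its true photometry.
#'
#' @inheritParams denoise
#' @return preprocessed matrix in [0, 1].
#' @export
preprocess_frame <- function(frame, cfg = retreg_config()) {
  enhance_contrast(.clip01(denoise(frame, cfg)), cfg)
}

#' Signal-to-noise ratio of a homogeneous patch
#'
#' SNR in dB as 20 log10(mean / sd) over a rectangular patch that is known
#' to be structure-free.
#'
#' @param frame 2-D intensity matrix.
#' @param patch integer vector `c(x, y, w, h)` (0-based top-left corner).
#' @return SNR in dB.
#' @export
measure_snr <- function(frame, patch) {
  v <- frame[patch[2] + seq_len(patch[4]), patch[1] + seq_len(patch[3])]
  s <- sd(v)
  if (s == 0) return(Inf)
  20 * log10(mean(v) / s)
}
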