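#' Frame sequence container
#'
#' An ordered stack of grayscale frames sharing one geometry, with
#' intensities held as doubles in [0, 1]. 8-bit sources are divided by 255;
#' the normalisation is affine and order-preserving, so intensity ranks are
#' unchanged. RGB frames are reduced to luminance (Rec. 601 weights
#' 0.299/0.587/0.114) -- the target device is monochrome, colour input is a
#' convenience.
#'
#' @param frames list of numeric matrices (identical dimensions) or a 3-D
#'   array sliced along the third dimension.
#' @param frame_rate frames per second, informational only.
#' @param source provenance string.
#' @return an object of class `frame_sequence`.
#' @examples
#' seq <- frame_sequence(replicate(3, matrix(runif(64 * 64), 64), simplify = FALSE))
#' length(seq$frames)
#' @export
frame_sequence <- function(frames, frame_rate = 25, source = "memory") {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (!is.list(frames) || length(frames) < 2)
    stop("a frame sequence needs at least 2 frames", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame shapes", call. = FALSE)
  frames <- lapply(frames, function(f) {
    .assert_frame(f)
    if (min(f) < 0 || max(f) > 1) {
      rng <- range(f)
      f <- if (rng[2] > rng[1]) (f - rng[1]) / (rng[2] - rng[1]) else f * 0
    }
    f
  })
  structure(list(frames = frames, frame_rate = frame_rate, source = source),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_sequence: %d frames of %d x %d px (%g fps) from %s\n",
              length(x$frames), d[1], d[2], x$frame_rate, x$source))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

.to_gray <- function(a) {
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3)
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    else a <- a[, , 1]
  }
  a
}

#' Read a retinal video sequence
#'
#' Reads a multi-page TIFF or a directory of numbered PNG frames into a
#' [frame_sequence()]. The format is inferred from the path unless
#' `format_hint` is given. AVI containers are not supported by this build;
#' convert to TIFF or a PNG directory first (e.g. with ffmpeg).
#'
#' @param path file (TIFF) or directory (PNGs) to read.
#' @param format_hint one of `"auto"`, `"tiff_stack"`, `"png_dir"`, `"avi"`.
#' @param frame_rate frames per second recorded in the returned object.
#' @return a [frame_sequence()].
#' @export
read_sequence <- function(path, format_hint = c("auto", "tiff_stack",
                                                "png_dir", "avi"),
                          frame_rate = 25) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file or directory", call. = FALSE)
  fmt <- format_hint
  if (fmt == "auto") {
    fmt <- if (dir.exists(path)) "png_dir"
           else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff_stack"
           else if (grepl("\\.avi$", path, ignore.case = TRUE)) "avi"
           else stop("cannot infer format of '", path,
                     "'; pass format_hint", call. = FALSE)
  }
  frames <- switch(fmt,
    tiff_stack = {
      pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                        error = function(e)
                          stop("cannot read '", path, "': ",
                               conditionMessage(e), call. = FALSE))
      lapply(pages, .to_gray)
    },
    png_dir = {
      files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
      if (!length(files))
        stop("cannot read '", path, "': no PNG files found", call. = FALSE)
      lapply(files, function(f) .to_gray(png::readPNG(f)))
    },
    avi = stop("AVI input is not supported by this build; convert '", path,
               "' to a multi-page TIFF or a PNG directory first",
               call. = FALSE)
  )
  if (length(frames) < 2)
    stop("degenerate input: '", path, "' holds fewer than 2 frames",
         call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame shapes in '", path, "'", call. = FALSE)
  frame_sequence(frames, frame_rate = frame_rate, source = path)
}

#' Write a frame sequence
#'
#' Writes a [frame_sequence()] as a multi-page TIFF or a directory of
#' zero-padded numbered PNGs. Both backends are lossless at the chosen bit
#' depth: with `bits = 8` the stored values are `round(v * 255) / 255`, so
#' inputs already quantised to `k/255` round-trip exactly.
#'
#' @param seq a [frame_sequence()].
#' @param path output file (`.tif`/`.tiff`) or directory.
#' @param format `"auto"`, `"tiff_stack"` or `"png_dir"`.
#' @param bits bits per sample for TIFF output (8, 16 or 32).
#' @export
write_sequence <- function(seq, path,
                           format = c("auto", "tiff_stack", "png_dir"),
                           bits = 8L) {
  stopifnot(inherits(seq, "frame_sequence"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      "tiff_stack" else "png_dir"
  if (format == "tiff_stack") {
    if (!dir.exists(dirname(path)))
      stop("cannot write '", path, "': parent directory does not exist",
           call. = FALSE)
    tiff::writeTIFF(lapply(seq$frames, .clip01), path,
                    bits.per.sample = as.integer(bits))
  } else {
    if (!dir.exists(path)) {
      ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop("cannot create directory '", path, "'", call. = FALSE)
    }
    nd <- max(4L, nchar(length(seq$frames)))
    for (i in seq_along(seq$frames))
      png::writePNG(.clip01(seq$frames[[i]]),
                    file.path(path, sprintf("frame_%0*d.png", nd, i)))
  }
  invisible(path)
}

#' Export per-frame registration transforms as CSV
#'
#' Writes the table `frame,tx_px,ty_px,phi_deg,entropy,excluded` with at
#' least 6 significant digits, one row per frame (0-based frame indices).
#' The per-frame shift and rotation double as an eye-movement trace during
#' fixation.
#'
#' @param result a `retreg` fit (from [register_sequence()]) or any list
#'   with elements `transforms` (list of [rigid_transform()]), `entropy`,
#'   `excluded_frames` and `reference_index`.
#' @param path output CSV path.
#' @export
export_transforms <- function(result, path) {
  tf <- result$transforms
  n <- length(tf)
  if (!n) stop("result carries no transforms", call. = FALSE)
  excl <- seq_len(n) - 1L
  excl <- excl %in% result$excluded_frames
  df <- data.frame(
    frame = seq_len(n) - 1L,
    tx_px = sprintf("%.8g", vapply(tf, `[[`, 0, "tx")),
    ty_px = sprintf("%.8g", vapply(tf, `[[`, 0, "ty")),
    phi_deg = sprintf("%.8g", vapply(tf, `[[`, 0, "phi")),
    entropy = sprintf("%.8g", result$entropy),
    excluded = as.integer(excl)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Re-import a transform table written by [export_transforms()]
#'
#' @param path CSV path.
#' @return data.frame with numeric columns `frame`, `tx_px`, `ty_px`,
#'   `phi_deg`, `entropy`, `excluded`.
#' @export
import_transforms <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "tx_px", "ty_px", "phi_deg", "entropy", "excluded")
  if (!all(need %in% names(df)))
    stop("'", path, "' is not a retreg transform table", call. = FALSE)
  df[need] <- lapply(df[need], as.numeric)
  df
}
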