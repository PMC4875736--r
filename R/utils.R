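# Low-level image helpers shared across the pipeline. Images are plain R
# matrices indexed [row, col] = [y+1, x+1]; all public coordinates are
# 0-based (x = column, y = row, origin at the top-left pixel centre).

.assert_frame <- function(frame, what = "frame") {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop(what, " must be a 2-D numeric matrix", call. = FALSE)
  if (!all(is.finite(frame)))
    stop(what, " must contain only finite values", call. = FALSE)
  invisible(frame)
}

# Reflect-pad a matrix by k pixels on every side (no edge duplication,
# "mirror" style: row 2 reflects to row 0).
.pad_reflect <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(rev(seq_len(k) + 1L), seq_len(h), h - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(w), w - seq_len(k))
  m[ri, ci, drop = FALSE]
}

# Replicate-pad (clamp to edge) by k pixels.
.pad_replicate <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(rep(1L, k), seq_len(h), rep(h, k))
  ci <- c(rep(1L, k), seq_len(w), rep(w, k))
  m[ri, ci, drop = FALSE]
}

# 3x3 convolution with an explicit kernel, reflection border.
# kern[i, j] multiplies the neighbour at (row offset i-2, col offset j-2).
.conv3 <- function(m, kern) {
  h <- nrow(m); w <- ncol(m)
  p <- .pad_reflect(m, 1L)
  out <- matrix(0, h, w)
  for (i in 1:3) for (j in 1:3) {
    if (kern[i, j] != 0)
      out <- out + kern[i, j] * p[(i - 1L) + seq_len(h), (j - 1L) + seq_len(w)]
  }
  out
}

# Sobel first-derivative kernels under the x = column convention.
.sobel_kx <- function() outer(c(1, 2, 1), c(-1, 0, 1))   # d/dx
.sobel_ky <- function() outer(c(-1, 0, 1), c(1, 2, 1))   # d/dy

.sobel_x <- function(m) .conv3(m, .sobel_kx())
.sobel_y <- function(m) .conv3(m, .sobel_ky())

# Central-difference gradients (replicate border), used by the LK solver.
.grad_central <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- .pad_replicate(m, 1L)
  gx <- (p[1L + seq_len(h), 2L + seq_len(w)] - p[1L + seq_len(h), seq_len(w)]) / 2
  gy <- (p[2L + seq_len(h), 1L + seq_len(w)] - p[seq_len(h), 1L + seq_len(w)]) / 2
  list(gx = gx, gy = gy)
}

# Vectorised median of the 9 values in each 3x3 neighbourhood
# (Paeth's 19-exchange sorting network), reflection border.
.median3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- .pad_reflect(m, 1L)
  v <- vector("list", 9L)
  n <- 1L
  for (i in 1:3) for (j in 1:3) {
    v[[n]] <- p[(i - 1L) + seq_len(h), (j - 1L) + seq_len(w)]
    n <- n + 1L
  }
  sw <- function(a, b) {
    lo <- pmin(v[[a]], v[[b]]); v[[b]] <<- pmax(v[[a]], v[[b]]); v[[a]] <<- lo
  }
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  v[[5]]
}

# 3x3 box (averaging) filter, reflection border.
.box3 <- function(m) .conv3(m, matrix(1 / 9, 3, 3))

# Separable Gaussian smoothing with a kernel truncated at `radius`
# (guarantees strictly compact support, unlike FFT-based blurs).
.gauss_sep <- function(m, sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(m)
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  p <- .pad_reflect(m, radius)
  tmp <- matrix(0, h, w + 2L * radius)
  for (i in seq_along(k))
    tmp <- tmp + k[i] * p[(i - 1L) + seq_len(h), , drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k))
    out <- out + k[i] * tmp[, (i - 1L) + seq_len(w), drop = FALSE]
  out
}

# Precompute bilinear gather indices and weights for 0-based positions
# (x, y) into an h x w matrix. Out-of-bounds positions get dummy indices
# and are reported in `inside`.
.bil_prep <- function(h, w, x, y) {
  inside <- (x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1)
  bad <- !inside
  if (any(bad)) { x[bad] <- 0; y[bad] <- 0 }
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- x0 + (x0 < w - 1); y1 <- y0 + (y0 < h - 1)
  list(i00 = y0 + 1 + h * x0, i10 = y0 + 1 + h * x1,
       i01 = y1 + 1 + h * x0, i11 = y1 + 1 + h * x1,
       w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy),
       w01 = (1 - fx) * fy, w11 = fx * fy, inside = inside)
}

.bil_apply <- function(m, p, fill = 0) {
  val <- p$w00 * m[p$i00] + p$w10 * m[p$i10] +
         p$w01 * m[p$i01] + p$w11 * m[p$i11]
  val[!p$inside] <- fill
  val
}

# Bilinear sampling of `m` at 0-based positions (x, y); outside -> fill.
# Returns list(values, inside) where inside marks fully in-bounds samples.
.bilinear <- function(m, x, y, fill = 0) {
  p <- .bil_prep(nrow(m), ncol(m), x, y)
  list(values = .bil_apply(m, p, fill), inside = p$inside)
}

# Separable Hanning window of length n (periodic endpoints at zero).
.hanning <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

# Integer cyclic roll: content moves by +dx columns, +dy rows.
.roll <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1L - dy) %% h) + 1L, ((seq_len(w) - 1L - dx) %% w) + 1L,
    drop = FALSE]
}

# Integer shift with zero fill; returns the shifted image and validity mask.
.shift_zero <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  mask <- matrix(FALSE, h, w)
  src_r <- seq_len(h) - dy; src_c <- seq_len(w) - dx
  rok <- src_r >= 1L & src_r <= h; cok <- src_c >= 1L & src_c <= w
  if (any(rok) && any(cok)) {
    out[rok, cok] <- m[src_r[rok], src_c[cok]]
    mask[rok, cok] <- TRUE
  }
  list(image = out, mask = mask)
}

.clip01 <- function(m) pmin(pmax(m, 0), 1)
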