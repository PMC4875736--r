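# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

small_spec <- function() phantom_spec(c(96L, 128L))

suite_spec <- function() phantom_spec(c(192L, 256L))

small_phantom <- function() fixture("small_phantom", render_phantom(small_spec()))

# cyclic roll used as an independent shift oracle (content moves +dx, +dy)
roll_img <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1L - dy) %% h) + 1L, ((seq_len(w) - 1L - dx) %% w) + 1L]
}

# analytic 2-D Gaussian blob sampled on the pixel grid (0-based centre)
gauss_blob <- function(h, w, cx, cy, sigma = 8) {
  xs <- rep(seq_len(w) - 1L, each = h)
  ys <- rep(seq_len(h) - 1L, times = w)
  matrix(exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2)), h, w)
}

# brute-force integer-shift normalised cross-correlation argmax (cyclic)
bf_shift_ncc <- function(ref, mov, max_shift) {
  best <- c(0, 0); bestv <- -Inf
  r0 <- ref - mean(ref)
  for (dx in -max_shift:max_shift) for (dy in -max_shift:max_shift) {
    m <- roll_img(mov, -dx, -dy)
    v <- sum(r0 * (m - mean(m)))
    if (v > bestv) { bestv <- v; best <- c(dx, dy) }
  }
  best
}

# brute-force SSD argmin displacement of a window around one point
bf_ssd_disp <- function(ref, mov, x, y, window, max_d = 5L) {
  hw <- (window - 1L) %/% 2L
  rows <- (y - hw):(y + hw) + 1L
  cols <- (x - hw):(x + hw) + 1L
  refw <- ref[rows, cols]
  best <- c(0, 0); bestv <- Inf
  for (dx in -max_d:max_d) for (dy in -max_d:max_d) {
    v <- sum((mov[rows + dy, cols + dx] - refw)^2)
    if (v < bestv) { bestv <- v; best <- c(dx, dy) }
  }
  best
}

# relative registration error of a fit against scripted ground truth:
# matrix with rows (translation error px, rotation error deg), reference
# frame column dropped
recovery_errors <- function(fit, truth) {
  r <- fit$reference_index
  err <- vapply(seq_along(truth) - 1L, function(i) {
    tt <- true_relative_transform(truth, i, r)
    est <- fit$transforms[[i + 1L]]
    c(sqrt((est$tx - tt$tx)^2 + (est$ty - tt$ty)^2), abs(est$phi - tt$phi))
  }, numeric(2))
  err[, -(r + 1L), drop = FALSE]
}

# smooth random blob field: a texture whose scale suits first-order LK
blob_field <- function(seed, h = 96, w = 128, smin = 5, smax = 9) {
  set.seed(seed)
  f <- matrix(0.4, h, w)
  for (k in 1:20) {
    cx <- runif(1, 12, w - 13); cy <- runif(1, 12, h - 13)
    s <- runif(1, smin, smax); a <- runif(1, -0.3, 0.3)
    f <- f + a * gauss_blob(h, w, cx, cy, s)
  }
  retreg:::.clip01(f)
}

# strongest corner-like point: argmax of the smaller structure-tensor
# eigenvalue (the classic trackability criterion), away from borders
best_corner <- function(f, margin = 22) {
  g <- retreg:::.grad_central(f)
  sxx <- retreg:::.gauss_sep(g$gx^2, 4)
  syy <- retreg:::.gauss_sep(g$gy^2, 4)
  sxy <- retreg:::.gauss_sep(g$gx * g$gy, 4)
  lmin <- (sxx + syy) / 2 - sqrt(((sxx - syy) / 2)^2 + sxy^2)
  lmin[1:margin, ] <- -1; lmin[(nrow(f) - margin):nrow(f), ] <- -1
  lmin[, 1:margin] <- -1; lmin[, (ncol(f) - margin):ncol(f)] <- -1
  i <- which.max(lmin)
  c((i - 1) %/% nrow(f), (i - 1) %% nrow(f))
}
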