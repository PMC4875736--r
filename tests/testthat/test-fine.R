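test_that("eigen map is zero on constants and peaks along a dark valley", {
  expect_equal(eigen_map(matrix(0.4, 20, 20)), matrix(0, 20, 20))
  # analytic Gaussian valley along row 40: the larger Hessian eigenvalue
  # of the cross-section profile peaks at the valley centre
  h <- 80; w <- 60
  ys <- matrix(rep(0:(h - 1), w), h, w)
  f <- 1 - 0.5 * exp(-(ys - 40)^2 / (2 * 3^2))
  m <- eigen_map(f)
  for (c in 5:(w - 5)) expect_equal(which.max(m[, c]), 41L)
  expect_equal(min(m), 0)
  expect_equal(max(m), 1)
})

test_that("probability-map updates renormalise, converge and attenuate transients", {
  set.seed(6)
  base <- matrix(0, 40, 40)
  base[15:17, 5:35] <- 0.5                      # persistent vessel
  m1 <- base; m1[30, 30] <- 1                   # transient artefact
  map <- tp_map(m1, q = 0.9)
  for (i in 1:9) map <- update_probability_map(map, base)
  got_ratio <- map$lambda_bar[30, 30] / map$lambda_bar[16, 20]
  # independent scalar oracle of the same recursion: geometric q-weighting
  # with min-max renormalisation each step (the background stays at zero,
  # so renormalisation is a pure rescaling)
  art <- 1; pers <- 0.5
  for (i in 1:9) {
    art <- 0.9 * art
    pers <- 0.9 * pers + 0.5
    m <- max(art, pers)
    art <- art / m; pers <- pers / m
  }
  expect_equal(got_ratio, art / pers, tolerance = 1e-10)
  expect_equal(range(map$lambda_bar), c(0, 1))
  # the transient started twice as strong as the vessel; now it is faint
  expect_lt(got_ratio, 0.2)

  # repeated identical input converges to that input's normalised form
  map2 <- tp_map(matrix(runif(100), 10, 10), q = 0.6)
  lam <- matrix(runif(100), 10, 10)
  for (i in 1:60) map2 <- update_probability_map(map2, lam)
  expect_equal(map2$lambda_bar, retreg:::.renorm01(lam), tolerance = 1e-6)

  # q -> 0 limit: the current frame dominates
  map3 <- tp_map(matrix(runif(100), 10, 10), q = 1e-9)
  map3 <- update_probability_map(map3, lam)
  expect_equal(map3$lambda_bar, retreg:::.renorm01(lam), tolerance = 1e-6)

  expect_error(update_probability_map(map2, matrix(0, 5, 5)), "shapes")
})

test_that("tracking points land on vessel centrelines and small fragments are dropped", {
  # phantom with one straight horizontal vessel of 9 px rendered width
  spec <- phantom_spec(c(96L, 128L),
                       vessels = list(list(pts = rbind(c(0.05, 0.5),
                                                       c(0.95, 0.5)),
                                           width = 45, contrast = 0.3)),
                       onh = list(centre = c(0.5, 0.5), radius = 1e-6,
                                  brightness = 0))
  expect_equal(spec$vessels[[1]]$width_px, 9)
  ph <- render_phantom(spec)
  pts <- select_tracking_points(tp_map(eigen_map(ph$image)))
  expect_gt(nrow(pts), 20)
  # away from the vessel end caps the skeleton follows the centreline
  core <- pts[pts[, 1] > 0.15 * 127 & pts[, 1] < 0.85 * 127, , drop = FALSE]
  expect_gt(nrow(core), 20)
  expect_true(all(abs(core[, 2] - 47.5) <= 1.5))

  expect_error(select_tracking_points(tp_map(matrix(0, 30, 30))),
               "no tracking points")

  # a 5-px fragment below the 20-px minimum area contributes no points
  lam <- matrix(0, 60, 80)
  set.seed(7)
  lam[sample(length(lam), 300)] <- runif(300, 0.05, 0.2)   # faint texture
  lam[29:31, 10:70] <- 0.95                                # long vessel
  lam[50, 74:78] <- 0.95                                   # short fragment
  pts <- select_tracking_points(tp_map(lam))
  expect_true(all(pts[, 2] >= 27 & pts[, 2] <= 32))
  expect_false(any(pts[, 2] == 50 & pts[, 1] >= 70))
})

test_that("LK displacement is exact at zero motion and subpixel-accurate on blobs", {
  ref <- gauss_blob(64, 64, 31.5, 31.5, 8) * 0.6 + 0.2
  pts <- cbind(c(31, 28, 35), c(31, 35, 28))
  same <- lk_displacement(ref, ref, pts, 31L)
  expect_true(all(!same$lost))
  expect_equal(same$dx, rep(0, 3), tolerance = 1e-12)
  expect_equal(same$dy, rep(0, 3), tolerance = 1e-12)
  # analytic translation by (0.5, -0.25): first-order LK on a smooth blob
  mov <- gauss_blob(64, 64, 31.5 + 0.5, 31.5 - 0.25, 8) * 0.6 + 0.2
  tp <- lk_displacement(ref, mov, pts, 31L)
  expect_true(all(abs(tp$dx - 0.5) < 0.1))
  expect_true(all(abs(tp$dy + 0.25) < 0.1))
  # textureless window: structure matrix singular -> lost
  flat <- matrix(0.5, 64, 64)
  expect_true(all(lk_displacement(flat, flat, pts, 31L)$lost))
  # window leaving the image: skipped
  out <- lk_displacement(ref, mov, cbind(2, 2), 31L)
  expect_true(out$lost[1])
  expect_true(is.na(out$dx[1]))
})

test_that("LK agrees with the brute-force SSD minimiser on integer shifts", {
  # smooth blob fields, tracked at their strongest corner point -- the
  # regime in which a single-level first-order tracker is meaningful
  for (k in 1:15) {
    f <- blob_field(k)
    set.seed(2000 + k)
    sh <- c(sample(-3:3, 1), sample(-3:3, 1))
    mov <- roll_img(f, sh[1], sh[2])
    p <- best_corner(f)
    tp <- lk_displacement(f, mov, rbind(p), 31L)
    expect_false(tp$lost[1])
    bf <- bf_ssd_disp(f, mov, p[1], p[2], 31L)
    expect_equal(bf, sh)                      # SSD oracle finds the shift
    expect_lte(abs(tp$dx[1] - bf[1]), 1)
    expect_lte(abs(tp$dy[1] - bf[2]), 1)
  }
})

test_that("trackability is zero at perfect alignment and grows off-optimum", {
  ref <- gauss_blob(64, 64, 31.5, 31.5, 8) * 0.6 + 0.2
  pts <- cbind(31, 31)
  tp <- lk_displacement(ref, ref, pts, 31L)
  q0 <- trackability(ref, ref, tp, 31L)
  expect_equal(abs(q0), 0, tolerance = 1e-12)
  # corrupting the displacement by +3 px strictly increases |Q|
  mov <- gauss_blob(64, 64, 32.5, 31.5, 8) * 0.6 + 0.2
  tp <- lk_displacement(ref, mov, pts, 31L)
  qopt <- abs(trackability(ref, mov, tp, 31L))
  tp_bad <- tp; tp_bad$dx <- tp$dx + 3
  qbad <- abs(trackability(ref, mov, tp_bad, 31L))
  expect_gt(qbad, qopt)
  # brute-force sweep: |Q| at the LK optimum is near the sweep minimum
  qs <- vapply(seq(-3, 3, by = 0.5), function(d) {
    tpd <- tp; tpd$dx <- tp$dx + d
    abs(trackability(ref, mov, tpd, 31L))
  }, 0)
  expect_lte(qopt, min(qs) + 1e-9)
})

test_that("quality map is zero outside the union of point windows", {
  tp <- data.frame(x = c(40, 55), y = c(30, 30), dx = c(0.1, 0.4),
                   dy = c(0, 0), lost = c(FALSE, FALSE))
  qimg <- retreg:::.q_map(c(60, 80), tp, c(0.1, 0.5), 31L, 31 / 6)
  expect_gt(qimg[31, 41], 0)          # the better point scores higher
  expect_gt(qimg[31, 41], qimg[31, 56])
  outside <- qimg
  outside[(30 - 15):(30 + 15) + 1, (40 - 15):(55 + 15) + 1] <- 0
  expect_equal(max(outside), 0)
})

test_that("fine registration recovers a known rigid motion and handles blinks", {
  spec <- small_spec()
  cfg <- retreg_config()
  tf_true <- rigid_transform(2.4, -1.7, 0.8)
  sc <- motion_script(2, max_shift = 1, max_rot = 0.1, noise_snr_db = 19,
                      seed = 71)
  sc$transforms[[2]] <- tf_true
  synth <- render_sequence(spec, sc)
  ref <- preprocess_frame(synth$sequence$frames[[1]], cfg)
  mov <- preprocess_frame(synth$sequence$frames[[2]], cfg)
  # stage 1 removes the integer part of the shift first, as in the pipeline
  co <- phase_correlate(ref, mov)
  sh <- retreg:::.shift_zero(mov, -co$dx, -co$dy)
  fr <- fine_register_frame(ref, sh$image, tp_map(eigen_map(ref)), cfg,
                            sh$mask)
  expect_false(fr$failed)
  total <- retreg:::.compose_tf(rigid_transform(co$dx, co$dy, 0), fr$tf)
  expect_lt(abs(total$tx - tf_true$tx), 0.5)
  expect_lt(abs(total$ty - tf_true$ty), 0.5)
  expect_lt(abs(total$phi - tf_true$phi), 0.5)
  expect_gte(fr$iterations, 2L)
  expect_lte(fr$iterations, 7L)

  # moving = reference converges immediately to the identity
  fr0 <- fine_register_frame(ref, ref, tp_map(eigen_map(ref)), cfg)
  expect_true(fr0$converged)
  expect_equal(fr0$iterations, 1L)
  expect_lt(max(abs(c(fr0$tf$tx, fr0$tf$ty, fr0$tf$phi))), 0.05)

  # a saturated blink frame fails gracefully (stage-1 transform kept)
  blink <- matrix(1, nrow(ref), ncol(ref))
  blink[1:20, ] <- ref[1:20, ]
  frb <- fine_register_frame(ref, blink, tp_map(eigen_map(ref)), cfg)
  expect_true(frb$failed)
  expect_equal(c(frb$tf$tx, frb$tf$ty, frb$tf$phi), c(0, 0, 0))
})

test_that("the probability map never grows where it was zero", {
  spec <- small_spec()
  sc <- motion_script(4, max_shift = 5, max_rot = 0.5, noise_snr_db = 19,
                      seed = 81)
  synth <- render_sequence(spec, sc)
  pre <- lapply(synth$sequence$frames, preprocess_frame)
  map <- tp_map(eigen_map(pre[[1]]))
  zero_before <- map$lambda_bar == 0
  lb <- map$lambda_bar
  qimg <- matrix(runif(length(lb)), nrow(lb))
  grown <- lb * (1 + qimg)
  expect_true(all(grown[zero_before] == 0))
  expect_true(all(grown[!zero_before] >= lb[!zero_before]))
  # and the full update keeps the map within [0, 1]
  for (i in 2:4) {
    fr <- fine_register_frame(pre[[1]], pre[[i]], map)
    map <- fr$map
    expect_true(min(map$lambda_bar) >= 0 && max(map$lambda_bar) <= 1)
  }
})
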