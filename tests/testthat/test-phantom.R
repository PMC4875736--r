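test_that("phantom rendering is deterministic with the documented geometry", {
  spec <- small_spec()
  p1 <- render_phantom(spec)
  p2 <- render_phantom(spec)
  expect_identical(p1$image, p2$image)
  expect_true(min(p1$image) >= 0 && max(p1$image) <= 1)
  # vessels are dark on a brighter background; the disc is brighter
  expect_lt(min(p1$image), spec$background - 0.1)
  expect_gt(max(p1$image), spec$background + 0.05)
  # rendered widths stay within the modelled 2-21 px range
  for (v in spec$vessels)
    expect_true(v$width_px >= 2 && v$width_px <= 21)
})

test_that("an empty vessel list renders background plus disc only", {
  spec <- phantom_spec(c(64L, 64L), vessels = list())
  img <- render_phantom(spec)$image
  expect_true(all(img >= spec$background - 1e-9))
  centre_val <- img[32, round(0.42 * 63) + 1]
  corner_val <- img[2, 60]
  expect_gt(centre_val, corner_val + 0.1)
})

test_that("a single horizontal vessel has its intensity minimum on the centreline", {
  spec <- phantom_spec(c(96L, 128L),
                       vessels = list(list(pts = rbind(c(0.1, 0.5),
                                                       c(0.9, 0.5)),
                                           width = 45, contrast = 0.3)),
                       onh = list(centre = c(0.5, 0.5), radius = 1e-6,
                                  brightness = 0))
  ph <- render_phantom(spec)
  y_true <- 0.5 * 95
  for (c in seq(20, 108, by = 8))
    expect_lt(abs((which.min(ph$image[, c]) - 1) - y_true), 1)
  # centreline samples returned for oracle use lie on the scripted line
  expect_true(all(abs(ph$centrelines[[1]][, "y"] - y_true) < 1e-9))
  expect_error(phantom_spec(c(64L, 64L),
                            vessels = list(list(pts = rbind(c(-0.2, 0.5),
                                                            c(0.5, 0.5)),
                                                width = 9, contrast = 0.2))),
               "outside image")
})

test_that("rendered sequences are seeded, reproducible and hit the scripted SNR", {
  spec <- small_spec()
  sc <- motion_script(4, max_shift = 10, max_rot = 1, seed = 12)
  a <- render_sequence(spec, sc)
  b <- render_sequence(spec, sc)
  for (i in 1:4) expect_identical(a$sequence$frames[[i]],
                                  b$sequence$frames[[i]])
  # identity script, zero noise: every frame equals the phantom
  sc0 <- motion_script(3, max_shift = 1e-9, max_rot = 1e-9,
                       noise_snr_db = Inf, seed = 1)
  for (i in 1:3) sc0$transforms[[i]] <- rigid_transform()
  clean <- render_sequence(spec, sc0)
  ph <- render_phantom(spec)$image
  for (i in 1:3) expect_equal(clean$sequence$frames[[i]], ph)
  # measured SNR within +-1 dB of the scripted 19 dB (identity frame)
  snrs <- vapply(1:20, function(s) {
    sy <- render_sequence(suite_spec(), motion_script(2, max_shift = 1e-9,
                                              max_rot = 1e-9,
                                              noise_snr_db = 19,
                                              seed = 300 + s))
    measure_snr(sy$sequence$frames[[1]], sy$snr_patch)
  }, 0)
  expect_true(all(abs(snrs - 19) <= 1))
})

test_that("motion scripts respect their bounds and seed determinism", {
  sc <- motion_script(200, max_shift = 30, max_rot = 3, seed = 99)
  tx <- vapply(sc$transforms, `[[`, 0, "tx")
  ty <- vapply(sc$transforms, `[[`, 0, "ty")
  ph <- vapply(sc$transforms, `[[`, 0, "phi")
  expect_true(all(abs(c(tx, ty)) <= 30))
  expect_true(all(abs(ph) <= 3))
  expect_true(any(abs(c(tx, ty)) > 10))   # saccades do occur
  sc2 <- motion_script(200, max_shift = 30, max_rot = 3, seed = 99)
  expect_identical(sc, sc2)
})

test_that("scripted transforms round-trip through noise-free registration", {
  spec <- small_spec()
  sc <- motion_script(6, max_shift = 10, max_rot = 1, noise_snr_db = Inf,
                      seed = 13)
  synth <- render_sequence(spec, sc)
  fit <- register_sequence(synth$sequence)
  err <- recovery_errors(fit, synth$truth)
  expect_lt(median(err[1, ]), 0.1)
  expect_lt(median(err[2, ]), 0.1)
})

test_that("artefact frames are reliably flagged by the entropy score", {
  spec <- small_spec()
  hits <- vapply(1:30, function(s) {
    sc <- motion_script(6, max_shift = 10, max_rot = 1, noise_snr_db = 19,
                        seed = 500 + s,
                        artefacts = list(NULL, NULL,
                                         list(type = "blur", sigma = 2),
                                         NULL,
                                         list(type = "blink",
                                              fraction = 0.5), NULL))
    q <- select_reference(render_sequence(spec, sc)$sequence)
    q$distorted[3] && q$distorted[5]
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
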