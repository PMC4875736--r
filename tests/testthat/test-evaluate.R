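test_that("profile extraction honours its sampling contract", {
  f <- matrix(0.5, 50, 60)
  site <- profile_site(c(10, 20), c(30, 20))
  p <- extract_profile(f, site)
  expect_length(p, 21)                       # ceiling(L) + 1 samples
  expect_equal(p, rep(0.5, 21))
  site2 <- profile_site(c(10, 10), c(20.4, 17.2))
  expect_length(extract_profile(f, site2),
                ceiling(sqrt(10.4^2 + 7.2^2)) + 1)
  expect_error(extract_profile(f, profile_site(c(-2, 5), c(10, 5))),
               "exits the image")
})

test_that("the profile minimum localises an analytic vessel crossing", {
  # vertical Gaussian valley centred at x = 25.3, crossed horizontally
  h <- 40; w <- 60
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  f <- 0.8 - 0.4 * exp(-(xs - 25.3)^2 / (2 * 2.5^2))
  site <- profile_site(c(10, 20), c(45, 20))
  p <- extract_profile(f, site)
  expect_lt(abs((which.min(p) - 1) + 10 - 25.3), 0.5 + 0.5)
  # ... and to subpixel on the upsampled grid
  up <- retreg:::.upsample_profile(p, 4L)
  expect_lt(abs((which.min(up) - 1) / 4 + 10 - 25.3), 0.3)
})

test_that("AME reproduces closed-form values on constructed fixtures", {
  # identical frames: zero error
  f <- small_phantom()$image
  site <- profile_site(c(30, 20), c(30, 75))
  expect_equal(as.numeric(site_ame(replicate(6, f, simplify = FALSE), site)),
               0)

  # two frames with minima 1 px apart: AME = 0.5 px regardless of where
  # the mean-profile minimum falls between them
  h <- 30; w <- 60
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  mk <- function(c0) 0.8 - 0.4 * exp(-(xs - c0)^2 / (2 * 2^2))
  site <- profile_site(c(5, 15), c(55, 15))
  ame <- site_ame(list(mk(30), mk(31)), site)
  expect_equal(as.numeric(ame), 0.5, tolerance = 1e-9)

  # known jitter: AME equals mean |offset - mean offset| up to the
  # quarter-pixel grid quantisation
  set.seed(23)
  offsets <- round(runif(10, -2, 2) * 4) / 4
  frames <- lapply(offsets, function(o) mk(30 + o))
  got <- as.numeric(site_ame(frames, site))
  oracle <- mean(abs(offsets - mean(offsets)))
  expect_lt(abs(got - oracle), 0.25 + 0.1 / 4)
  # quantisation: AME is a multiple of 1/(4N)
  expect_equal(got * 4 * 10, round(got * 4 * 10), tolerance = 1e-9)
})

test_that("AME is invariant to a constant intensity offset", {
  h <- 30; w <- 60
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  mk <- function(c0) 0.6 - 0.3 * exp(-(xs - c0)^2 / (2 * 2^2))
  site <- profile_site(c(5, 15), c(55, 15))
  frames <- lapply(c(29, 30.5, 31, 30), mk)
  a1 <- as.numeric(site_ame(frames, site))
  a2 <- as.numeric(site_ame(lapply(frames, `+`, 0.1), site))
  expect_equal(a1, a2)
})

test_that("region stratification, empty strata and exclusions behave", {
  h <- 40; w <- 60
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  mk <- function(c0) 0.8 - 0.4 * exp(-(xs - c0)^2 / (2 * 2^2))
  frames <- lapply(c(30, 30.5, 30.25, 29.75), mk)
  onh <- onh_region(c(30, 15), 12)
  sites <- list(profile_site(c(24, 15), c(36, 15)),   # inside the circle
                profile_site(c(24, 35), c(36, 35)))   # outside
  ev <- evaluate_registration(frames, sites, onh)
  expect_equal(ev$sites$region, c("inside_onh", "outside_onh"))
  expect_false(is.null(ev$test))

  # all sites inside: outside stratum reported absent, not zero
  ev2 <- evaluate_registration(frames, sites[1], onh)
  expect_null(ev2$regions$outside_onh)
  expect_false(is.null(ev2$regions$inside_onh))

  # excluded frames are removed before profiles are taken
  bad <- frames; bad[[2]] <- mk(45)
  ev3 <- evaluate_registration(bad, sites[2], onh, excluded = 1L)
  ev4 <- evaluate_registration(frames[-2], sites[2], onh)
  expect_equal(ev3$sites$ame, ev4$sites$ame)

  expect_error(evaluate_registration(frames, list(), onh), "empty site")
})

test_that("registration strictly reduces AME on a moving fixture", {
  spec <- small_spec()
  sc <- motion_script(8, max_shift = 12, max_rot = 1.5, noise_snr_db = 19,
                      seed = 91)
  synth <- render_sequence(spec, sc)
  fit <- register_sequence(synth$sequence)
  refp <- preprocess_frame(synth$sequence$frames[[fit$reference_index + 1]])
  sites <- auto_propose_sites(refp, 8)
  expect_gte(length(sites), 4)
  raw <- evaluate_registration(synth$sequence, sites)
  reg <- evaluate_registration(fitted(fit), sites,
                               excluded = fit$excluded_frames)
  expect_true(all(reg$sites$ame < raw$sites$ame))
})

test_that("automatic sites cross the vessel near-perpendicularly", {
  # one straight horizontal vessel: perpendicular means mostly vertical
  spec <- phantom_spec(c(96L, 128L),
                       vessels = list(list(pts = rbind(c(0.1, 0.5),
                                                       c(0.9, 0.5)),
                                           width = 45, contrast = 0.3)),
                       onh = list(centre = c(0.5, 0.5), radius = 1e-6,
                                  brightness = 0))
  ph <- render_phantom(spec)
  sites <- auto_propose_sites(ph$image, 6)
  expect_gte(length(sites), 3)
  for (s in sites) {
    d <- s$p2 - s$p1
    ang <- abs(atan2(d[2], d[1]) * 180 / pi)
    expect_lt(abs(ang - 90), 15)
  }
  # vessel-free constant image: empty list with a warning
  expect_warning(out <- auto_propose_sites(matrix(0.5, 60, 60), 5),
                 "no vessels|no sites")
  expect_length(out, 0)
})
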