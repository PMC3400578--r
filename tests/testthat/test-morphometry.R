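test_that("segmentation recovers the generator silhouette almost exactly", {
  fe <- generate_feather_image(preset_feather("wildtype", seed = 1))
  mask <- segment_feather(fe$image, fe$pixel_scale)
  jacc <- sum(mask & fe$mask) / sum(mask | fe$mask)
  expect_gte(jacc, 0.99)
})

test_that("segmentation errors and multi-component handling", {
  blank <- matrix(0.1, 50, 50)
  expect_error(segment_feather(blank, 0.1, method = 0.5),
               class = "NoObjectFound")
  two <- matrix(0, 60, 60)
  two[10:40, 10:20] <- 1      # 31 x 11
  two[50:55, 40:45] <- 1      # smaller blob
  expect_message(mask <- segment_feather(two, 0.1, method = 0.5),
                 "largest of 2")
  expect_true(all(which(mask) %in% which(two > 0.5)))
  expect_equal(sum(mask), 31 * 11)
})

test_that("fringes of a straight ribbon are parallel at the ribbon width", {
  mask <- straight_ribbon_mask(len_px = 400, width_px = 40)
  fr <- extract_fringes(mask)
  nn <- nearest_on_polyline(
    resample_polyline(fr$left, 0.3)[20:110, ],
    resample_polyline(fr$right, 0.3))
  # boundary pixel centres are inset by ~1 px overall relative to 40 px
  expect_true(all(abs(nn$dist / 0.1 - 39) <= 0.5 + 1e-9))
})

test_that("a pinched silhouette raises DegenerateWidth", {
  mask <- straight_ribbon_mask(len_px = 300, width_px = 30)
  mask[, 150:160] <- FALSE
  mask[27, 150:160] <- TRUE       # 1-px neck
  expect_error(extract_fringes(mask), class = "DegenerateWidth")
})

test_that("extracted fringes track the true edges to subpixel accuracy", {
  fe <- generate_feather_image(preset_feather("wildtype", seed = 6))
  mask <- segment_feather(fe$image, fe$pixel_scale)
  fr <- extract_fringes(mask, fe$pixel_scale)
  ed <- truth_edges(fe)
  px <- fe$pixel_scale
  for (side in c("left", "right")) {
    P <- resample_polyline(fr[[side]], 0.3)
    P <- P[10:(nrow(P) - 10), ]   # interior (caps are not edges)
    d1 <- max(directed_dist(P, ed$left))
    d2 <- max(directed_dist(P, ed$right))
    expect_lt(min(d1, d2) / px, 1.5)
  }
})

test_that("backbone of analytic fringes is the exact midcurve", {
  # straight ribbon, edges y = 0 and y = 4 mm
  x <- seq(0, 100, by = 0.5)
  fr <- rachis_fringes(cbind(x, rep(4, length(x))), cbind(x, rep(0, length(x))),
                       pixel_scale = 0.1)
  bb <- compute_backbone(fr)
  expect_true(all(abs(bb$y - 2) < 0.025))
  # annulus between radii 20 and 24 mm: midcurve radius 22
  ang <- seq(0, pi / 2, length.out = 300)
  fr2 <- rachis_fringes(cbind(20 * cos(ang), 20 * sin(ang)),
                        cbind(24 * cos(ang), 24 * sin(ang)))
  bb2 <- compute_backbone(fr2)
  r <- sqrt(bb2$x^2 + bb2$y^2)
  core <- bb2$s > 2 & bb2$s < max(bb2$s) - 2
  expect_true(all(abs(r[core] - 22) < 0.1))
})

test_that("crossing fringes are rejected", {
  x <- seq(0, 50, by = 0.5)
  up <- cbind(x, 2 - 4 * x / 50)     # crosses the other edge midway
  dn <- cbind(x, -2 + 4 * x / 50)
  expect_error(compute_backbone(rachis_fringes(up, dn)),
               class = "FringesCross")
})

test_that("image-derived backbone lies within a pixel of the true midline", {
  spec <- preset_feather("homozygous", seed = 8)
  spec$boundary_noise_px <- 0        # geometric accuracy, no edge jitter
  fe <- generate_feather_image(spec)
  mask <- segment_feather(fe$image, fe$pixel_scale)
  bb <- compute_backbone(extract_fringes(mask, fe$pixel_scale))
  P <- cbind(bb$x, bb$y)
  core <- bb$s > 0.05 * max(bb$s) & bb$s < 0.95 * max(bb$s)
  d <- directed_dist(P[core, ], cbind(fe$truth$x_mm, fe$truth$y_mm))
  expect_lt(max(d) / fe$pixel_scale, 1)
})

test_that("backbone smoothing behaves as a Gaussian arc-length filter", {
  x <- seq(0, 100, by = 0.1)
  straight <- structure(data.frame(x = x, y = rep(0, length(x)), s = x),
                        L_mm = 100, class = c("backbone", "data.frame"))
  sm <- smooth_backbone(straight, 3)
  expect_lt(max(abs(sm$y)), 1e-6)
  expect_lt(max(abs(range(sm$x) - c(0, 100))), 1e-3)
  # identity at zero smoothing
  expect_identical(smooth_backbone(straight, 0), straight)
  # 1-mm wavelength attenuated by >= 99% at sigma = 3 mm
  wig <- structure(data.frame(x = x, y = 0.25 * sin(2 * pi * x / 1), s = x),
                   L_mm = 100, class = c("backbone", "data.frame"))
  smw <- smooth_backbone(wig, 3)
  core <- smw$x > 10 & smw$x < 90
  expect_lt(max(abs(smw$y[core])), 0.25 * 0.01)
  # too-short curves are refused
  short <- structure(data.frame(x = x[x <= 5], y = 0 * x[x <= 5], s = x[x <= 5]),
                     L_mm = 5, class = c("backbone", "data.frame"))
  expect_error(smooth_backbone(short, 3), class = "TooShort")
})

test_that("tangent-angle profile recovers analytic angles", {
  s <- seq(0, 80, by = 0.1)
  line30 <- structure(data.frame(x = s * cos(pi / 6), y = s * sin(pi / 6), s = s),
                      L_mm = 80, class = c("backbone", "data.frame"))
  pr <- tangent_angle_profile(line30)
  expect_true(all(abs(pr$theta_deg - 30) < 0.01))
  expect_equal(length(pr$u), 512)
  # circular arc of radius 50 mm: d theta / ds = 180/(pi*50) deg/mm
  ang <- seq(0, 2, length.out = 2001)       # 100 mm of arc
  arc <- structure(data.frame(x = 50 * sin(ang), y = 50 * (1 - cos(ang)),
                              s = 50 * ang),
                   L_mm = 100, class = c("backbone", "data.frame"))
  pa <- tangent_angle_profile(arc)
  rate <- diff(pa$theta_deg) / (diff(pa$u) * pa$L_mm)
  core <- seq(round(0.1 * length(rate)), round(0.9 * length(rate)))
  expect_true(all(abs(rate[core] / (180 / (pi * 50)) - 1) < 0.02))
})

test_that("full-pipeline profile matches the kernel-matched reference within 2 degrees", {
  for (ph in c("wildtype", "krt75_mt")) {
    fe <- generate_feather_image(preset_feather(ph, seed = 12))
    pr <- measure_feather(fe)
    ref <- reference_profile(fe)
    expect_lt(profile_rms_diff(pr, ref, trim = 0.05), 2)
  }
})

test_that("kink detection finds planted steps and nothing else", {
  # constant-curvature arc below threshold: no calls
  arc <- make_profile(function(u) 120 * u, L = 100)     # 1.2 deg/mm
  expect_equal(nrow(detect_kinks(arc)), 0)
  # two 30-degree steps ramped over 1 mm at u = 0.3 and 0.7
  L <- 100
  step <- function(u, at) pmin(pmax((u - at) * L / 1 + 0.5, 0), 1)
  pr <- make_profile(function(u) 30 * step(u, 0.3) + 30 * step(u, 0.7), L = L)
  calls <- detect_kinks(pr)
  expect_equal(nrow(calls), 2)
  expect_lt(max(abs(calls$u_center - c(0.3, 0.7))), 0.02)
  expect_true(all(calls$angular_rate_deg_per_mm > 5))
  # an infinite threshold silences everything
  expect_equal(nrow(detect_kinks(pr, rate_threshold_deg_per_mm = Inf)), 0)
  # runs closer than the separation radius merge into one call
  pr2 <- make_profile(function(u) 30 * step(u, 0.50) + 30 * step(u, 0.51),
                      L = L)
  expect_equal(nrow(detect_kinks(pr2)), 1)
})
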