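test_that("feather rendering is a pure function of the spec and seed", {
  spec <- preset_feather("heterozygous", seed = 5)
  a <- generate_feather_image(spec)
  b <- generate_feather_image(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  spec2 <- preset_feather("heterozygous", seed = 6)
  expect_false(identical(generate_feather_image(spec2)$image, a$image))
})

test_that("constant-angle spec gives a constant ground-truth profile", {
  spec <- feather_spec(length_mm = 60,
                       theta_true = function(u) rep(30, length(u)),
                       boundary_noise_px = 0)
  u <- seq(0, 1, length.out = 101)
  expect_equal(feather_theta(spec, u), rep(30, 101))
  fe <- generate_feather_image(spec)
  expect_equal(unique(fe$truth$theta_deg), 30)
})

test_that("homozygous preset curves more strongly than wildtype", {
  mean_rate <- function(spec) {
    u <- seq(0, 1, length.out = 1001)
    th <- feather_theta(spec, u)
    mean(abs(diff(th) / (diff(u) * spec$length_mm)))
  }
  for (s in 1:5) {
    expect_gt(mean_rate(preset_feather("homozygous", seed = s)),
              mean_rate(preset_feather("wildtype", seed = s)))
  }
})

test_that("ground truth is self-consistent: integrating theta reproduces the backbone", {
  for (ph in c("wildtype", "homozygous", "krt75_mt")) {
    fe <- generate_feather_image(preset_feather(ph, seed = 2))
    tr <- fe$truth
    th <- tr$theta_deg * pi / 180
    n <- nrow(tr)
    dx <- diff(tr$s_mm) * (cos(th[-n]) + cos(th[-1])) / 2
    dy <- diff(tr$s_mm) * (sin(th[-n]) + sin(th[-1])) / 2
    x <- tr$x_mm[1] + cumsum(dx)
    y <- tr$y_mm[1] + cumsum(dy)
    err <- sqrt((x - tr$x_mm[-1])^2 + (y - tr$y_mm[-1])^2)
    expect_lt(max(err), 0.1)
  }
})

test_that("invalid feather specs are rejected", {
  expect_error(feather_spec(length_mm = -1), class = "InvalidSpec")
  expect_error(feather_spec(100, width_profile = function(u) u - 0.5),
               class = "InvalidSpec")
  expect_error(feather_spec(100, kinks = data.frame(u = 0, step_deg = 10,
                                                    ramp_mm = 1)),
               class = "InvalidSpec")
  expect_error(feather_spec(100, pixel_scale = 0), class = "InvalidSpec")
})

test_that("a canvas too small for the curve raises CanvasOverflow", {
  spec <- preset_feather("wildtype", seed = 1)
  expect_error(generate_feather_image(spec, canvas_px = c(50, 50)),
               class = "CanvasOverflow")
  big <- generate_feather_image(spec, canvas_px = c(2000, 2000))
  expect_identical(dim(big$image), c(2000L, 2000L))
})

test_that("barb texture stays outside the returned rachis mask", {
  spec <- preset_feather("wildtype", seed = 4)
  fe <- generate_feather_image(spec, barbs = TRUE)
  plain <- generate_feather_image(spec)
  expect_identical(fe$mask, plain$mask)
  expect_gt(sum(fe$image > 0.3), sum(plain$image > 0.3))  # barbs add texture
})
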