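#' Specify a synthetic feather
#'
#' A `feather_spec` fully determines a rendered feather: rachis length, width
#' taper, the ground-truth tangent-angle function \eqn{\theta_{true}(u)} on the
#' length-normalised coordinate \eqn{u = s/L}, a list of planted kinks
#' (localised angle steps), the raster scale, edge jitter, and the seed.
#'
#' The realised ground truth is
#' `theta_true(u) + sum of kink ramps`: each kink contributes a linear ramp of
#' `step_deg` degrees over `ramp_mm` millimetres of arc length centred at
#' `u_position`. Evaluate it with [feather_theta()].
#'
#' @param length_mm rachis length L in mm (> 0).
#' @param width_profile function of u in \[0,1\] giving rachis width in mm.
#' @param theta_true function of u giving the smooth part of the ground-truth
#'   tangent angle, degrees (arbitrary additive reference).
#' @param kinks data.frame with columns `u`, `step_deg`, `ramp_mm`; may have
#'   zero rows. Kink positions must lie strictly inside (0, 1).
#' @param pixel_scale mm per pixel (> 0).
#' @param boundary_noise_px standard deviation of edge jitter, in pixels.
#' @param seed integer seed; the spec plus seed fully determines the raster.
#' @return An object of class `feather_spec`.
#' @seealso [preset_feather()], [generate_feather_image()]
#' @export
feather_spec <- function(length_mm,
                         width_profile = function(u) 2.8 - 1.4 * u,
                         theta_true = function(u) rep(0, length(u)),
                         kinks = data.frame(u = numeric(), step_deg = numeric(),
                                            ramp_mm = numeric()),
                         pixel_scale = 0.15,
                         boundary_noise_px = 0.5,
                         seed = 1L) {
  fk_assert(is.numeric(length_mm) && length_mm > 0, "InvalidSpec",
            "length_mm must be > 0")
  fk_assert(is.function(width_profile) && is.function(theta_true),
            "InvalidSpec", "width_profile and theta_true must be functions")
  fk_assert(pixel_scale > 0, "InvalidSpec", "pixel_scale must be > 0")
  fk_assert(boundary_noise_px >= 0, "InvalidSpec",
            "boundary_noise_px must be >= 0")
  kinks <- as.data.frame(kinks)
  if (nrow(kinks)) {
    fk_assert(all(c("u", "step_deg", "ramp_mm") %in% names(kinks)),
              "InvalidSpec", "kinks needs columns u, step_deg, ramp_mm")
    fk_assert(all(kinks$u > 0 & kinks$u < 1), "InvalidSpec",
              "kink positions must lie strictly inside (0,1)")
    fk_assert(all(kinks$ramp_mm > 0), "InvalidSpec", "kink ramp_mm must be > 0")
  }
  wtest <- width_profile(seq(0, 1, length.out = 64))
  fk_assert(all(is.finite(wtest)) && all(wtest > 0), "InvalidSpec",
            "width_profile(u) must be positive on [0,1]")
  structure(list(length_mm = length_mm, width_profile = width_profile,
                 theta_true = theta_true, kinks = kinks,
                 pixel_scale = pixel_scale,
                 boundary_noise_px = boundary_noise_px,
                 seed = as.integer(seed)),
            class = "feather_spec")
}

#' Evaluate the ground-truth tangent angle of a feather spec
#'
#' Smooth component plus planted kink ramps, in degrees.
#'
#' @param spec a [feather_spec()].
#' @param u numeric vector in \[0,1\].
#' @return Numeric vector of angles (degrees).
#' @export
feather_theta <- function(spec, u) {
  th <- spec$theta_true(u)
  if (nrow(spec$kinks)) {
    s <- u * spec$length_mm
    for (i in seq_len(nrow(spec$kinks))) {
      k <- spec$kinks[i, ]
      ramp <- pmin(pmax((s - k$u * spec$length_mm) / k$ramp_mm + 0.5, 0), 1)
      th <- th + k$step_deg * ramp
    }
  }
  th
}

#' Phenotype presets for the feather generator
#'
#' Parameter tables qualitatively emulating four phenotype classes of a
#' feather-curvature mutant series: `"wildtype"` (gentle smooth bend, no
#' kinks), `"heterozygous"` (whole-rachis curvature plus several large kinks),
#' `"homozygous"` (dramatically increased smooth curvature, no kinks) and
#' `"krt75_mt"` (virally transduced mutant: irregular kinks, a severe distal
#' bend, and large feather-to-feather variability). The presets are
#' illustrative parameter choices, not fits to measured feathers; kink steps
#' are about 55--60 degrees over a 1-mm ramp so that they remain detectable
#' after 3-mm profile smoothing at the default 5 deg/mm kink threshold.
#'
#' Each preset draws a small number of smooth random bending components from
#' the seed (low-order sinusoids in u), so that replicate feathers of one
#' preset differ the way replicate real feathers do; the `krt75_mt` preset
#' uses much larger perturbation amplitudes, which is what makes its
#' profile dispersion exceed the wildtype's.
#'
#' @param phenotype one of `"wildtype"`, `"heterozygous"`, `"homozygous"`,
#'   `"krt75_mt"`.
#' @param seed integer seed for this feather.
#' @param pixel_scale mm per pixel.
#' @return A [feather_spec()].
#' @export
preset_feather <- function(phenotype = c("wildtype", "heterozygous",
                                         "homozygous", "krt75_mt"),
                           seed = 1L, pixel_scale = 0.15) {
  phenotype <- match.arg(phenotype)
  L <- 130
  pert_amp <- switch(phenotype,
                     wildtype = c(2, 1, 0.5),
                     heterozygous = c(3, 1.5, 0.8),
                     homozygous = c(3, 1.5, 0.8),
                     krt75_mt = c(15, 7, 4))
  a <- with_seed(child_seed(seed, paste0("preset-", phenotype)),
                 rnorm(3, 0, pert_amp))
  base <- switch(phenotype,
    wildtype = function(u) 25 * u^2,
    heterozygous = function(u) 60 * u^2,
    homozygous = function(u) 210 * u,
    krt75_mt = function(u) 40 * u^2 + 50 * pmax(u - 0.7, 0) / 0.3)
  theta_fun <- function(u) {
    base(u) + a[1] * sin(pi * u) + a[2] * sin(2 * pi * u) +
      a[3] * sin(3 * pi * u)
  }
  kinks <- switch(phenotype,
    wildtype = ,
    homozygous = data.frame(u = numeric(), step_deg = numeric(),
                            ramp_mm = numeric()),
    heterozygous = data.frame(u = c(0.30, 0.55, 0.80),
                              step_deg = c(60, -55, 55), ramp_mm = 1),
    krt75_mt = data.frame(u = c(0.35, 0.60), step_deg = c(60, -60),
                          ramp_mm = 1))
  feather_spec(length_mm = L, theta_true = theta_fun, kinks = kinks,
               pixel_scale = pixel_scale, seed = seed)
}

# pixel (row, col) <-> mm; row 1 is the image top.
px_to_mm <- function(row, col, nrow_img, pixel_scale) {
  list(x = (col - 0.5) * pixel_scale,
       y = (nrow_img - row + 0.5) * pixel_scale)
}

# correlated (Gaussian-smoothed) unit-sd noise along a 1-d grid
smooth_noise <- function(n, corr_samples) {
  z <- rnorm(n)
  if (corr_samples >= 1) {
    half <- ceiling(3 * corr_samples)
    k <- exp(-0.5 * ((-half:half) / corr_samples)^2)
    k <- k / sum(k)
    z <- as.numeric(stats::filter(c(rev(z[seq_len(half)]), z,
                                    rev(z[n - seq_len(half) + 1])),
                                  k, sides = 2))[half + seq_len(n)]
    s <- sd(z)
    if (s > 0) z <- z / s
  }
  z
}

#' Render a synthetic feather image with known ground truth
#'
#' Sweeps a ribbon of the specified width along the integral curve of the
#' ground-truth tangent angle, rasterises it at `pixel_scale` mm/px and
#' returns the grayscale image together with the exact silhouette mask and a
#' ground-truth table (u, s, x, y, theta). Edge jitter is applied as
#' correlated (about 1 mm) lateral and width perturbations of the ribbon with
#' the requested per-edge standard deviation. Identical spec (including seed)
#' gives a bitwise-identical raster.
#'
#' @param spec a [feather_spec()].
#' @param canvas_px optional `c(nrow, ncol)`; if the curve (plus margin) does
#'   not fit, a `CanvasOverflow` error is raised. Default: auto-sized.
#' @param barbs if `TRUE`, draws faint barb texture outside the rachis
#'   silhouette (the returned mask is the rachis only). Default off: the
#'   morphometry pipeline analyses the rachis alone.
#' @return An object of class `feather_image`: list with elements `image`
#'   (matrix in \[0,1\], rows = y from top), `mask` (logical matrix),
#'   `truth` (data.frame u, s_mm, x_mm, y_mm, theta_deg, for the ideal,
#'   jitter-free curve), `edges` (the rendered left/right edge polylines
#'   including jitter, in mm), `pixel_scale`, and `spec`.
#' @export
generate_feather_image <- function(spec, canvas_px = NULL, barbs = FALSE) {
  fk_assert(inherits(spec, "feather_spec"), "InvalidSpec",
            "spec must be a feather_spec")
  sc <- spec$pixel_scale
  L <- spec$length_mm
  ds <- sc / 3
  s <- seq(0, L, by = ds)
  u <- s / L
  th <- feather_theta(spec, u) * pi / 180
  # integral curve of the tangent angle (trapezoid rule)
  x <- cumsum(c(0, (cos(th[-1]) + cos(th[-length(th)])) / 2 * diff(s)))
  y <- cumsum(c(0, (sin(th[-1]) + sin(th[-length(th)])) / 2 * diff(s)))
  w <- spec$width_profile(u)
  fk_assert(all(w > 0), "InvalidSpec", "width_profile(u) must be positive")
  r <- w / 2

  # jitter perturbs the rendered edges only; the ground truth stays the
  # ideal curve
  xs <- x; ys <- y
  noise_mm <- spec$boundary_noise_px * sc
  if (noise_mm > 0) {
    corr <- 1 / ds   # ~1 mm correlation length
    jit <- with_seed(child_seed(spec$seed, "edge-jitter"), {
      nl <- smooth_noise(length(s), corr) * noise_mm
      nr <- smooth_noise(length(s), corr) * noise_mm
      list(nl = nl, nr = nr)
    })
    lat <- (jit$nl - jit$nr) / 2           # lateral centre shift
    r <- pmax(r + (jit$nl + jit$nr) / 2, 2 * sc)
    nx <- -sin(th); ny <- cos(th)          # unit normal
    xs <- x + lat * nx
    ys <- y + lat * ny
  }
  nx <- -sin(th); ny <- cos(th)

  margin <- max(r) + 5 * sc
  x0 <- min(xs) - margin; x1 <- max(xs) + margin
  y0 <- min(ys) - margin; y1 <- max(ys) + margin
  ncol_img <- ceiling((x1 - x0) / sc)
  nrow_img <- ceiling((y1 - y0) / sc)
  if (!is.null(canvas_px)) {
    fk_assert(nrow_img <= canvas_px[1] && ncol_img <= canvas_px[2],
              "CanvasOverflow",
              "curve needs %d x %d px but canvas is %d x %d",
              nrow_img, ncol_img, canvas_px[1], canvas_px[2])
    nrow_img <- canvas_px[1]; ncol_img <- canvas_px[2]
  }

  cx <- (xs - x0) / sc + 0.5               # pixel-centre coordinates
  cy <- nrow_img - (ys - y0) / sc + 0.5
  rpx <- r / sc

  mask <- matrix(FALSE, nrow_img, ncol_img)
  # disk templates cached per rounded radius
  templates <- new.env(parent = emptyenv())
  rkey <- sprintf("%.2f", round(rpx * 4) / 4)
  for (i in seq_along(s)) {
    key <- rkey[i]
    tpl <- templates[[key]]
    if (is.null(tpl)) {
      rr <- round(rpx[i] * 4) / 4
      d <- ceiling(rr)
      off <- expand.grid(dr = -d:d, dc = -d:d)
      off <- off[off$dr^2 + off$dc^2 <= rr^2, , drop = FALSE]
      tpl <- as.matrix(off)
      templates[[key]] <- tpl
    }
    pr <- round(cy[i]) + tpl[, 1]
    pc <- round(cx[i]) + tpl[, 2]
    keep <- pr >= 1 & pr <= nrow_img & pc >= 1 & pc <= ncol_img
    mask[cbind(pr[keep], pc[keep])] <- TRUE
  }

  img <- with_seed(child_seed(spec$seed, "intensity"), {
    im <- matrix(0.08 + rnorm(nrow_img * ncol_img, 0, 0.03),
                 nrow_img, ncol_img)
    im[mask] <- 0.85 + rnorm(sum(mask), 0, 0.03)
    im
  })
  if (barbs) {
    img <- with_seed(child_seed(spec$seed, "barbs"), {
      idx <- seq(1, length(s), by = max(1, round(1.5 / ds)))
      nxb <- -sin(th[idx]); nyb <- cos(th[idx])
      for (j in seq_along(idx)) {
        i <- idx[j]
        for (sgn in c(-1, 1)) {
          tt <- seq(rpx[i] + 1, rpx[i] + 12 + runif(1, 0, 8), by = 0.7)
          br <- round(cy[i] - sgn * nyb[j] * tt + cos(th[i]) * tt * 0.6)
          bc <- round(cx[i] + sgn * nxb[j] * tt + cos(th[i]) * tt * 0.0 +
                        sin(th[i]) * 0)
          keep <- br >= 1 & br <= nrow_img & bc >= 1 & bc <= ncol_img
          sel <- cbind(br[keep], bc[keep])
          img[sel] <- pmax(img[sel], 0.4)
        }
      }
      img
    })
  }
  img <- pmin(pmax(img, 0), 1)

  step <- max(1, round(0.1 / ds))          # truth table every ~0.1 mm
  ti <- unique(c(seq(1, length(s), by = step), length(s)))
  truth <- data.frame(u = u[ti], s_mm = s[ti],
                      x_mm = x[ti] - x0, y_mm = y[ti] - y0,
                      theta_deg = feather_theta(spec, u[ti]))
  # rendered edges (including jitter): the edge ground truth
  edges <- list(left = cbind(xs[ti] + r[ti] * nx[ti] - x0,
                             ys[ti] + r[ti] * ny[ti] - y0),
                right = cbind(xs[ti] - r[ti] * nx[ti] - x0,
                              ys[ti] - r[ti] * ny[ti] - y0))
  structure(list(image = img, mask = mask, truth = truth, edges = edges,
                 pixel_scale = sc, spec = spec),
            class = "feather_image")
}

#' @export
print.feather_image <- function(x, ...) {
  cat(sprintf("<feather_image> %d x %d px @ %.3f mm/px, L = %.1f mm, %d kinks\n",
              nrow(x$image), ncol(x$image), x$pixel_scale,
              x$spec$length_mm, nrow(x$spec$kinks)))
  invisible(x)
}
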