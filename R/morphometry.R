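#' Segment the feather silhouette from a grayscale image
#'
#' Thresholds the image (Otsu by default), keeps the largest connected
#' foreground component and fills holes. When more than one component is
#' present the smaller ones are discarded with a message.
#'
#' @param image numeric matrix in \[0,1\], rows = image rows from the top.
#' @param pixel_scale mm per pixel (> 0).
#' @param method threshold selection: `"otsu"` or a numeric cutoff in (0,1).
#' @return Logical mask matrix with attribute `pixel_scale`.
#' @export
segment_feather <- function(image, pixel_scale, method = "otsu") {
  fk_assert(is.matrix(image) && length(image) > 0, "InvalidSpec",
            "image must be a non-empty numeric matrix")
  fk_assert(is.numeric(pixel_scale) && pixel_scale > 0, "InvalidSpec",
            "pixel_scale must be > 0")
  thr <- if (identical(method, "otsu")) {
    EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  } else as.numeric(method)
  mask <- image > thr
  if (!any(mask)) fk_stop("NoObjectFound", "no foreground component found")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(tab) > 1)
    message(sprintf("segment_feather: keeping largest of %d components",
                    length(tab)))
  keep <- which.max(tab)
  mask <- EBImage::imageData(lab) == keep
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  dim(mask) <- dim(image)
  attr(mask, "pixel_scale") <- pixel_scale
  mask
}

#' Construct rachis fringes from two ordered polylines
#'
#' The two edges of the rachis as ordered (proximal to distal) polylines in mm
#' coordinates. Normally produced by [extract_fringes()]; exposed so that
#' analytic test cases (e.g. concentric arcs) can be built directly.
#'
#' @param left,right n x 2 matrices of (x, y) in mm, ordered proximal first.
#' @param pixel_scale mm per pixel of the source image (used for tolerances).
#' @return Object of class `rachis_fringes`.
#' @export
rachis_fringes <- function(left, right, pixel_scale = NA_real_) {
  left <- as.matrix(left); right <- as.matrix(right)
  fk_assert(ncol(left) == 2 && ncol(right) == 2 && nrow(left) >= 2 &&
              nrow(right) >= 2, "InvalidSpec",
            "fringes must be n x 2 matrices with n >= 2")
  structure(list(left = unname(left), right = unname(right),
                 pixel_scale = pixel_scale),
            class = "rachis_fringes")
}

#' Extract the two rachis fringes from a silhouette mask
#'
#' Traces the mask boundary, finds the two geodesically most distant points of
#' the silhouette (the proximal and distal tips), and splits the boundary
#' there into the two edge polylines. The proximal end is taken to be the end
#' with the larger mean width over its terminal 5% of length (the calamus);
#' if the two ends are within 2% of each other the end nearer the image
#' origin is used, deterministically.
#'
#' @param mask logical matrix from [segment_feather()] (single component).
#' @param pixel_scale mm per pixel; defaults to the mask's attribute.
#' @param rachis_region optional logical matrix restricting the analysis to a
#'   user-supplied rachis mask (intersected with `mask`).
#' @param strip_barbs if `TRUE`, applies a small morphological opening first
#'   to remove thin protruding structures (barbs) before edge tracing.
#' @param flip_orientation if `TRUE`, invert the automatic proximal/distal
#'   decision (manual override for unusual feathers).
#' @return A [rachis_fringes()] object.
#' @export
extract_fringes <- function(mask, pixel_scale = attr(mask, "pixel_scale"),
                            rachis_region = NULL, strip_barbs = FALSE,
                            flip_orientation = FALSE) {
  fk_assert(is.matrix(mask) && any(mask), "NoObjectFound", "empty mask")
  fk_assert(is.numeric(pixel_scale) && pixel_scale > 0, "InvalidSpec",
            "pixel_scale must be > 0")
  if (!is.null(rachis_region)) mask <- mask & rachis_region
  if (strip_barbs) {
    br <- EBImage::makeBrush(5, shape = "disc")
    mask <- EBImage::imageData(EBImage::opening(EBImage::Image(mask * 1),
                                                br)) > 0
  }
  storage.mode(mask) <- "logical"
  nr <- nrow(mask)

  D <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  dim(D) <- dim(mask)
  if (max(D) < 1) fk_stop("DegenerateWidth", "rachis narrower than 2 px")
  # pinch test: a <= 2 px neck (or an everywhere-thin mask) does not survive
  # a 1-px erosion as a single sizable component
  er <- EBImage::imageData(EBImage::erode(EBImage::Image(mask * 1),
                                          EBImage::makeBrush(3, "box")))
  if (!any(er > 0)) fk_stop("DegenerateWidth", "rachis narrower than 2 px")
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(er)))
  sizes <- tabulate(as.integer(lab))
  if (sum(sizes >= max(9, 0.01 * sum(mask))) > 1)
    fk_stop("DegenerateWidth", "rachis pinched to zero width")

  # geodesic endpoints on a downsampled mask (keeps >= ~3 px of width)
  f <- max(1L, floor(max(D) / 3))
  sm <- mask[seq(1, nr, by = f), seq(1, ncol(mask), by = f), drop = FALSE]
  start <- which(sm, arr.ind = TRUE)[1, ]
  d1 <- mask_bfs(sm, start)
  if (any(sm & is.na(d1)))
    fk_stop("DegenerateWidth",
            "rachis pinched below %d px: silhouette disconnects under downsampling", f)
  e1s <- bfs_farthest(d1)
  d2 <- mask_bfs(sm, e1s)
  e2s <- bfs_farthest(d2)
  if (max(d2, na.rm = TRUE) < 3)
    fk_stop("OrientationAmbiguous", "could not find two distinct silhouette tips")
  e1 <- (e1s - 1) * f + 1
  e2 <- (e2s - 1) * f + 1

  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  cont <- oc[[which.max(vapply(oc, nrow, 1L))]] + 1  # (row, col), 1-based
  i1 <- which.min((cont[, 1] - e1[1])^2 + (cont[, 2] - e1[2])^2)
  i2 <- which.min((cont[, 1] - e2[1])^2 + (cont[, 2] - e2[2])^2)
  if (i1 == i2) fk_stop("OrientationAmbiguous", "silhouette tips coincide")
  lo <- min(i1, i2); hi <- max(i1, i2)
  arc_a <- cont[lo:hi, , drop = FALSE]
  arc_b <- cont[c(hi:nrow(cont), 1:lo), , drop = FALSE]
  # orient both arcs from the e1 end to the e2 end
  if (lo != i1) arc_a <- arc_a[rev(seq_len(nrow(arc_a))), , drop = FALSE]
  db <- (arc_b[1, 1] - e1[1])^2 + (arc_b[1, 2] - e1[2])^2
  de <- (arc_b[nrow(arc_b), 1] - e1[1])^2 + (arc_b[nrow(arc_b), 2] - e1[2])^2
  if (de < db) arc_b <- arc_b[rev(seq_len(nrow(arc_b))), , drop = FALSE]

  # proximal end: larger mean width over the terminal 5% of geodesic length
  # (region means of the distance transform are proportional to local width)
  gmax <- max(d2, na.rm = TRUE)
  Dsm <- D[seq(1, nr, by = f), seq(1, ncol(mask), by = f), drop = FALSE]
  reg_e1 <- !is.na(d2) & d2 <= 0.05 * gmax      # d2 measures from e1
  reg_e2 <- !is.na(d2) & d2 >= 0.95 * gmax
  w_e1 <- mean(Dsm[reg_e1]); w_e2 <- mean(Dsm[reg_e2])
  flip <- if (abs(w_e1 - w_e2) > 0.02 * max(w_e1, w_e2)) {
    w_e2 > w_e1                               # arcs currently start at e1
  } else {
    (e2[1]^2 + e2[2]^2) < (e1[1]^2 + e1[2]^2)
  }
  if (flip_orientation) flip <- !flip
  if (flip) {
    arc_a <- arc_a[rev(seq_len(nrow(arc_a))), , drop = FALSE]
    arc_b <- arc_b[rev(seq_len(nrow(arc_b))), , drop = FALSE]
  }

  to_mm <- function(rc) {
    cbind((rc[, 2] - 0.5) * pixel_scale, (nr - rc[, 1] + 0.5) * pixel_scale)
  }
  fr <- rachis_fringes(to_mm(arc_a), to_mm(arc_b), pixel_scale)
  # silhouette tips (contour split points), proximal first: used by
  # compute_backbone to trim the rounded end caps
  tips <- rbind(cont[i1, ], cont[i2, ])
  if (flip) tips <- tips[2:1, , drop = FALSE]
  attr(fr, "tips") <- to_mm(tips)
  fr
}

#' Compute the rachis backbone as the curve equidistant to the two fringes
#'
#' Pairs each point of one fringe with its nearest point on the other and
#' takes midpoints, then refines each midpoint toward exact equidistance from
#' the two polylines. End caps (where the edge polylines wrap around the
#' tips) are trimmed by the local half width. The result is resampled to at
#' most `spacing_mm` point spacing.
#'
#' @param fringes a [rachis_fringes()] object.
#' @param spacing_mm maximum point spacing of the result (default 0.25 mm,
#'   i.e. within the 0.5-mm contract).
#' @return Object of class `backbone`: data.frame with columns `x`, `y`, `s`
#'   (mm) and attribute `L_mm`.
#' @export
compute_backbone <- function(fringes, spacing_mm = 0.25) {
  fk_assert(inherits(fringes, "rachis_fringes"), "InvalidSpec",
            "fringes must be a rachis_fringes object")
  fk_assert(spacing_mm > 0 && spacing_mm <= 0.5, "InvalidSpec",
            "spacing_mm must be in (0, 0.5]")
  Lf <- resample_polyline(fringes$left, spacing_mm)
  Rf <- resample_polyline(fringes$right, spacing_mm)
  nn <- nearest_on_polyline(Lf, Rf)
  width <- nn$dist
  tips <- attr(fringes, "tips")
  if (!is.null(tips)) {
    # image-derived fringes start/end on the rounded tip caps; the cap
    # contributes a quarter-circle of arc (pi/2 * half width) at each fringe
    # end, which must not take part in midline pairing
    sL <- cum_arclength(Lf); LL <- sL[length(sL)]
    w_prox <- width[which.min(abs(sL - min(4, LL / 4)))]
    w_dist <- width[which.min(abs(sL - (LL - min(4, LL / 4))))]
    # a cap-rim point lies within sqrt(2) * r of the tip, the straight fringe
    # beyond the tangency point does not; trimming at that distance starts
    # each fringe exactly at the axial position of the true midline end
    trim_fringe <- function(P) {
      dp <- sqrt((P[, 1] - tips[1, 1])^2 + (P[, 2] - tips[1, 2])^2)
      dd <- sqrt((P[, 1] - tips[2, 1])^2 + (P[, 2] - tips[2, 2])^2)
      keep <- dp >= 0.99 * sqrt(2) * w_prox / 2 &
        dd >= 0.99 * sqrt(2) * w_dist / 2
      if (sum(keep) >= 4) P[keep, , drop = FALSE] else P
    }
    Lf <- trim_fringe(Lf); Rf <- trim_fringe(Rf)
    nn <- nearest_on_polyline(Lf, Rf)
    width <- nn$dist
  }
  mid <- (Lf + nn$point) / 2
  # refine: true equidistant point between the two polylines
  for (it in 1:2) {
    a <- nearest_on_polyline(mid, Lf)
    b <- nearest_on_polyline(mid, Rf)
    mid <- (a$point + b$point) / 2
    width <- a$dist + b$dist
  }
  # fringes must stay on opposite sides: the signed offset direction from the
  # backbone to the left fringe may not flip sign along the curve
  a <- nearest_on_polyline(mid, Lf)
  tangent <- rbind(mid[2, ] - mid[1, ],
                   mid[-1, , drop = FALSE] - mid[-nrow(mid), , drop = FALSE])
  off <- a$point - mid
  side <- sign(tangent[, 1] * off[, 2] - tangent[, 2] * off[, 1])
  side <- side[is.finite(side) & side != 0]
  core <- side[seq(max(1, round(length(side) * 0.1)),
                   round(length(side) * 0.9))]
  if (length(core) && min(mean(core == 1), mean(core == -1)) > 0.2)
    fk_stop("FringesCross", "fringes cross: backbone side flips sign")

  # drop stalled points and any residual cap fragments (a midline point can
  # never lie nearer a silhouette tip than half the local width)
  keep <- c(TRUE, sqrt(rowSums(diff(mid)^2)) > spacing_mm * 0.1)
  mid <- mid[keep, , drop = FALSE]; width <- width[keep]
  if (!is.null(tips)) {
    s <- cum_arclength(mid)
    L <- s[length(s)]
    d_prox <- sqrt((mid[, 1] - tips[1, 1])^2 + (mid[, 2] - tips[1, 2])^2)
    d_dist <- sqrt((mid[, 1] - tips[2, 1])^2 + (mid[, 2] - tips[2, 2])^2)
    ends <- s <= 0.2 * L | s >= 0.8 * L
    keep <- !(ends & (d_prox < 0.9 * w_prox / 2 | d_dist < 0.9 * w_dist / 2))
    if (sum(keep) >= 4) { mid <- mid[keep, , drop = FALSE] }
  }

  mid <- resample_polyline(mid, spacing_mm)
  s <- cum_arclength(mid)
  structure(data.frame(x = mid[, 1], y = mid[, 2], s = s),
            L_mm = s[length(s)], class = c("backbone", "data.frame"))
}

#' Smooth a backbone along arc length with a Gaussian kernel
#'
#' The x and y coordinates, as functions of arc length s, are convolved with
#' a Gaussian of standard deviation `length_scale_mm`; the kernel is
#' renormalised where it is truncated at the ends. Arc length is recomputed
#' after smoothing. `length_scale_mm = 0` is the identity.
#'
#' @param backbone a `backbone` from [compute_backbone()].
#' @param length_scale_mm Gaussian sigma in mm (default 3, the scale used for
#'   rachis profiling).
#' @return A smoothed `backbone`.
#' @export
smooth_backbone <- function(backbone, length_scale_mm = 3) {
  fk_assert(inherits(backbone, "backbone"), "InvalidSpec",
            "backbone must be a backbone object")
  if (length_scale_mm == 0) return(backbone)
  fk_assert(length_scale_mm > 0, "InvalidSpec", "length_scale_mm must be >= 0")
  L <- attr(backbone, "L_mm")
  if (L <= 2 * length_scale_mm)
    fk_stop("TooShort", "backbone length %.1f mm must exceed twice the %.1f mm smoothing scale",
            L, length_scale_mm)
  ds <- min(0.1, length_scale_mm / 10)
  P <- resample_polyline(cbind(backbone$x, backbone$y), ds)
  s <- cum_arclength(P)
  # extend both ends linearly by 5 sigma so the truncated kernel does not
  # drag the endpoints inward and shorten the curve
  next_pts <- max(2, round(1 / ds))
  npad <- ceiling(5 * length_scale_mm / ds)
  t0 <- P[1, ] - P[next_pts, ]; t0 <- t0 / sqrt(sum(t0^2))
  t1 <- P[nrow(P), ] - P[nrow(P) - next_pts + 1, ]; t1 <- t1 / sqrt(sum(t1^2))
  pad0 <- P[rep(1, npad), ] + outer(ds * (npad:1), t0)
  pad1 <- P[rep(nrow(P), npad), ] + outer(ds * (1:npad), t1)
  Pe <- rbind(pad0, P, pad1)
  se <- c(s[1] - ds * (npad:1), s, s[length(s)] + ds * (1:npad))
  W <- exp(-0.5 * (outer(s, se, "-") / length_scale_mm)^2)
  W <- W / rowSums(W)
  sm <- W %*% Pe
  s2 <- cum_arclength(sm)
  structure(data.frame(x = sm[, 1], y = sm[, 2], s = s2),
            L_mm = s2[length(s2)], class = c("backbone", "data.frame"))
}

#' Construct a tangent-angle profile directly
#'
#' @param u grid on \[0,1\] (uniform).
#' @param theta_deg tangent angle per grid point, degrees (continuous).
#' @param L_mm total rachis length in mm.
#' @param meta optional list of metadata (source id, smoothing scale).
#' @return Object of class `theta_profile`.
#' @export
theta_profile <- function(u, theta_deg, L_mm, meta = list()) {
  fk_assert(length(u) == length(theta_deg) && length(u) >= 2, "InvalidSpec",
            "u and theta_deg must have equal length >= 2")
  fk_assert(L_mm > 0, "InvalidSpec", "L_mm must be > 0")
  structure(list(u = as.numeric(u), theta_deg = as.numeric(theta_deg),
                 L_mm = L_mm, meta = meta), class = "theta_profile")
}

#' @export
print.theta_profile <- function(x, ...) {
  cat(sprintf("<theta_profile> %d samples, L = %.1f mm, theta range [%.1f, %.1f] deg\n",
              length(x$u), x$L_mm, min(x$theta_deg), max(x$theta_deg)))
  invisible(x)
}

#' Tangent-angle profile theta(u) of a backbone
#'
#' At each arc-length position the tangent angle is the orientation of the
#' total-least-squares straight line fitted to the backbone points within a
#' centred window of `fit_window_mm` of arc length (truncated at the ends).
#' The orientation (defined modulo 180 degrees) is disambiguated by the local
#' direction of travel, unwrapped to a continuous function, and resampled on
#' a uniform grid of the length-normalised coordinate u = s/L. The additive
#' reference of theta is arbitrary (image-frame axes).
#'
#' @param backbone a (smoothed) `backbone` with at least 10 points.
#' @param fit_window_mm arc-length extent of the line-fit window (default 3).
#' @param n_grid number of uniform u samples (default 512).
#' @return A [theta_profile()].
#' @export
tangent_angle_profile <- function(backbone, fit_window_mm = 3, n_grid = 512) {
  fk_assert(inherits(backbone, "backbone"), "InvalidSpec",
            "backbone must be a backbone object")
  fk_assert(nrow(backbone) >= 10, "InvalidSpec",
            "backbone must have at least 10 points")
  ds <- min(0.1, fit_window_mm / 10)
  P <- resample_polyline(cbind(backbone$x, backbone$y), ds)
  s <- cum_arclength(P)
  n <- nrow(P)
  L <- s[n]
  half <- fit_window_mm / 2
  # windowed second moments via cumulative sums
  cx <- c(0, cumsum(P[, 1])); cy <- c(0, cumsum(P[, 2]))
  cxx <- c(0, cumsum(P[, 1]^2)); cyy <- c(0, cumsum(P[, 2]^2))
  cxy <- c(0, cumsum(P[, 1] * P[, 2]))
  i0 <- findInterval(s - half, s) + 1L
  i1 <- findInterval(s + half + 1e-12, s)
  m <- i1 - i0 + 1
  sx <- cx[i1 + 1] - cx[i0]; sy <- cy[i1 + 1] - cy[i0]
  sxx <- cxx[i1 + 1] - cxx[i0] - sx^2 / m
  syy <- cyy[i1 + 1] - cyy[i0] - sy^2 / m
  sxy <- cxy[i1 + 1] - cxy[i0] - sx * sy / m
  phi <- 0.5 * atan2(2 * sxy, sxx - syy)     # orientation mod pi
  # disambiguate direction with the window chord
  chord <- P[pmin(i1, n), ] - P[pmax(i0, 1), ]
  dotp <- cos(phi) * chord[, 1] + sin(phi) * chord[, 2]
  phi <- ifelse(dotp < 0, phi + pi, phi)
  th <- phi * 180 / pi
  # unwrap to continuity (nearest multiple of 360)
  dth <- diff(th)
  adj <- cumsum(c(0, -round(dth / 360) * 360))
  th <- th + adj
  if (any(abs(diff(th)) > 90))
    fk_stop("UnwrapFailure", "angle jump > 90 deg between neighbouring samples")
  ug <- seq(0, 1, length.out = n_grid)
  thg <- approx(s / L, th, xout = ug, rule = 2)$y
  theta_profile(ug, thg, L,
                meta = list(fit_window_mm = fit_window_mm, n_grid = n_grid))
}

#' Measure a feather image: silhouette to tangent-angle profile
#'
#' Convenience pipeline: [segment_feather()], [extract_fringes()],
#' [compute_backbone()], [smooth_backbone()], [tangent_angle_profile()].
#'
#' @param image numeric image matrix or a `feather_image` from the generator.
#' @param pixel_scale mm per pixel (taken from a `feather_image` if given).
#' @param length_scale_mm backbone smoothing sigma (default 3 mm).
#' @param fit_window_mm tangent line-fit window (default 3 mm).
#' @param n_grid number of u samples (default 512).
#' @param rachis_region,strip_barbs passed to [extract_fringes()].
#' @return A [theta_profile()].
#' @export
measure_feather <- function(image, pixel_scale = NULL, length_scale_mm = 3,
                            fit_window_mm = 3, n_grid = 512,
                            rachis_region = NULL, strip_barbs = FALSE) {
  if (inherits(image, "feather_image")) {
    if (is.null(pixel_scale)) pixel_scale <- image$pixel_scale
    image <- image$image
  }
  fk_assert(!is.null(pixel_scale), "InvalidSpec", "pixel_scale is required")
  mask <- segment_feather(image, pixel_scale)
  fr <- extract_fringes(mask, pixel_scale, rachis_region = rachis_region,
                        strip_barbs = strip_barbs)
  bb <- smooth_backbone(compute_backbone(fr), length_scale_mm)
  tangent_angle_profile(bb, fit_window_mm, n_grid)
}

#' Reference profile of a synthetic feather at the measurement scale
#'
#' Builds the profile an ideal measurement would produce from the generator's
#' exact ground-truth backbone: the true curve is smoothed with the same
#' Gaussian arc-length kernel and profiled with the same tangent-window fit as
#' the image pipeline. Validation of the image pipeline compares against this
#' kernel-matched reference, since an estimator operating at a 3-mm smoothing
#' scale is not expected to reproduce sub-kernel detail (e.g. the interior of
#' a 1-mm kink ramp).
#'
#' @param feather a `feather_image` from [generate_feather_image()].
#' @param length_scale_mm,fit_window_mm,n_grid as in [measure_feather()].
#' @return A [theta_profile()].
#' @export
reference_profile <- function(feather, length_scale_mm = 3, fit_window_mm = 3,
                              n_grid = 512) {
  fk_assert(inherits(feather, "feather_image"), "InvalidSpec",
            "feather must be a feather_image")
  tr <- feather$truth
  bb <- structure(data.frame(x = tr$x_mm, y = tr$y_mm, s = tr$s_mm),
                  L_mm = max(tr$s_mm), class = c("backbone", "data.frame"))
  bb <- smooth_backbone(bb, length_scale_mm)
  tangent_angle_profile(bb, fit_window_mm, n_grid)
}

#' RMS difference between two profiles modulo an additive constant
#'
#' Both profiles are compared on the grid of the first (linear interpolation),
#' after removing the best-fitting additive offset; an end margin can be
#' excluded. This is the comparison appropriate to tangent-angle profiles,
#' whose additive reference is arbitrary.
#'
#' @param p1,p2 [theta_profile()] objects.
#' @param trim fraction of each end to exclude (default 0.05).
#' @return RMS difference in degrees.
#' @export
profile_rms_diff <- function(p1, p2, trim = 0.05) {
  u <- p1$u
  keep <- u >= trim & u <= 1 - trim
  t2 <- approx(p2$u, p2$theta_deg, xout = u[keep], rule = 2)$y
  d <- p1$theta_deg[keep] - t2
  d <- d - mean(d)
  sqrt(mean(d^2))
}

#' Detect kinks in a tangent-angle profile
#'
#' A kink is a maximal run of grid samples where the absolute angular rate
#' |d theta / d s| exceeds `rate_threshold_deg_per_mm`. Runs separated by less
#' than `min_separation_mm` are merged; runs shorter than `min_extent_mm` are
#' discarded. Each surviving run yields one call at its rate-weighted
#' centroid.
#'
#' @param profile a [theta_profile()].
#' @param rate_threshold_deg_per_mm threshold on |d theta/ds| (default 5).
#' @param min_separation_mm merge radius between runs (default 2).
#' @param min_extent_mm minimum run extent (default 0.5).
#' @return data.frame of class `kink_calls` with columns `u_center`,
#'   `angular_rate_deg_per_mm` (peak rate in the run), `extent_mm`.
#' @export
detect_kinks <- function(profile, rate_threshold_deg_per_mm = 5,
                         min_separation_mm = 2, min_extent_mm = 0.5) {
  fk_assert(inherits(profile, "theta_profile"), "InvalidSpec",
            "profile must be a theta_profile")
  empty <- structure(data.frame(u_center = numeric(),
                                angular_rate_deg_per_mm = numeric(),
                                extent_mm = numeric()),
                     class = c("kink_calls", "data.frame"))
  u <- profile$u; th <- profile$theta_deg; L <- profile$L_mm
  ds <- diff(u) * L
  rate <- abs(diff(th) / ds)                 # at segment midpoints
  um <- (u[-1] + u[-length(u)]) / 2
  hot <- is.finite(rate) & rate > rate_threshold_deg_per_mm
  if (!any(hot)) return(empty)
  r <- rle(hot)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs with gaps below the separation radius
  if (nrow(runs) > 1) {
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      gap_mm <- (um[runs$start[i]] - um[merged$end[nrow(merged)]]) * L
      if (gap_mm < min_separation_mm) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else merged <- rbind(merged, runs[i, ])
    }
    runs <- merged
  }
  calls <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    idx <- runs$start[i]:runs$end[i]
    w <- rate[idx]
    data.frame(u_center = sum(um[idx] * w) / sum(w),
               angular_rate_deg_per_mm = max(w),
               extent_mm = (um[max(idx)] - um[min(idx)] + mean(diff(u))) * L)
  }))
  calls <- calls[calls$extent_mm >= min_extent_mm, , drop = FALSE]
  rownames(calls) <- NULL
  structure(calls, class = c("kink_calls", "data.frame"))
}
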