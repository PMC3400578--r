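# Group-level profile statistics. All comparisons operate modulo an additive
# constant, because theta carries an arbitrary reference.

common_grid <- function(profiles) {
  u <- profiles[[1]]$u
  for (p in profiles[-1]) {
    if (length(p$u) != length(u) || max(abs(p$u - u)) > 1e-9)
      fk_stop("GridMismatch", "profiles are not on a common u grid")
  }
  u
}

as_profile_list <- function(x) {
  if (inherits(x, "theta_profile")) list(x) else as.list(x)
}

#' Bilateral mirror-symmetry residual of two profile sets
#'
#' Feathers from opposite sides of the body are expected to be mirror images:
#' mirroring flips the sign of the tangent angle up to an additive constant,
#' so for per-side mean profiles the sum \eqn{\bar\theta_L(u) +
#' \bar\theta_R(u)} should be constant in u. The residual is the RMS over u of
#' that sum after removing its best-fitting constant; 0 means perfect mirror
#' symmetry.
#'
#' @param profiles_left,profiles_right a [theta_profile()] or list of them,
#'   all on one u grid.
#' @return Non-negative scalar, degrees.
#' @export
mirror_symmetry_residual <- function(profiles_left, profiles_right) {
  pl <- as_profile_list(profiles_left)
  pr <- as_profile_list(profiles_right)
  fk_assert(length(pl) >= 1 && length(pr) >= 1, "InsufficientData",
            "need at least one profile per side")
  common_grid(c(pl, pr))
  ml <- rowMeans(sapply(pl, `[[`, "theta_deg"))
  mr <- rowMeans(sapply(pr, `[[`, "theta_deg"))
  tot <- ml + mr
  tot <- tot - mean(tot)
  sqrt(mean(tot^2))
}

#' Across-feather dispersion of tangent-angle profiles
#'
#' Each profile is centred by its own mean (removing the arbitrary reference);
#' the dispersion is the mean over u of the across-profile standard deviation.
#' Converging profiles give values near 0; diverse ones give large values.
#'
#' @param profiles list of [theta_profile()] objects on one u grid (>= 2).
#' @return Non-negative scalar, degrees.
#' @export
profile_dispersion <- function(profiles) {
  profiles <- as_profile_list(profiles)
  if (length(profiles) < 2)
    fk_stop("InsufficientData", "need at least 2 profiles")
  common_grid(profiles)
  M <- sapply(profiles, `[[`, "theta_deg")
  M <- sweep(M, 2, colMeans(M))
  mean(apply(M, 1, sd))
}

#' Plot tangent-angle profiles theta(u)
#'
#' Publication-style line plot of one or more profiles on the
#' length-normalised coordinate, optionally shifted by arbitrary offsets for
#' clarity. Requires ggplot2.
#'
#' @param profiles a [theta_profile()] or list of them (optionally named).
#' @param offset_deg vertical shift between successive curves (default 0).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, offset_deg = 0) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_profiles requires the ggplot2 package")
  profiles <- as_profile_list(profiles)
  nm <- names(profiles)
  if (is.null(nm)) nm <- paste0("profile ", seq_along(profiles))
  df <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    data.frame(u = p$u, theta = p$theta_deg + (i - 1) * offset_deg,
               id = nm[i])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$theta,
                                   colour = .data$id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "u = s / L", y = expression(theta * " (deg)"),
                  colour = NULL) +
    ggplot2::theme_classic()
}
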