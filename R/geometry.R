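# Shared 2-d polyline utilities (mm coordinates).

polyline_arclength <- function(P) {
  if (nrow(P) < 2) return(0)
  sum(sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)))
}

cum_arclength <- function(P) {
  if (nrow(P) < 2) return(rep(0, nrow(P)))
  c(0, cumsum(sqrt(rowSums((P[-1, , drop = FALSE] -
                              P[-nrow(P), , drop = FALSE])^2))))
}

#' Resample an ordered polyline to equal arc-length spacing
#' @param P n x 2 matrix of (x, y) points.
#' @param spacing target point spacing (same units as P).
#' @return Resampled n' x 2 matrix.
#' @export
resample_polyline <- function(P, spacing) {
  s <- cum_arclength(P)
  L <- s[length(s)]
  if (L <= 0) return(P[1, , drop = FALSE])
  keep <- !duplicated(s)
  s <- s[keep]; P <- P[keep, , drop = FALSE]
  sg <- seq(0, L, length.out = max(2, ceiling(L / spacing) + 1))
  cbind(approx(s, P[, 1], xout = sg)$y, approx(s, P[, 2], xout = sg)$y)
}

#' Nearest points on a polyline
#'
#' For each query point, the closest point on (any segment of) a polyline.
#' Fully vectorised over segments.
#'
#' @param P m x 2 matrix of query points.
#' @param Q n x 2 polyline.
#' @return List with `point` (m x 2 foot points) and `dist` (m distances).
#' @export
nearest_on_polyline <- function(P, Q) {
  n <- nrow(Q)
  if (n == 1) {
    d <- sqrt((P[, 1] - Q[1, 1])^2 + (P[, 2] - Q[1, 2])^2)
    return(list(point = matrix(rep(Q[1, ], each = nrow(P)), ncol = 2), dist = d))
  }
  A <- Q[-n, , drop = FALSE]; B <- Q[-1, , drop = FALSE]
  ab <- B - A
  len2 <- pmax(rowSums(ab^2), .Machine$double.eps)
  # t[i, j]: projection parameter of P[i] on segment j
  tx <- outer(P[, 1], A[, 1], "-") * rep(ab[, 1], each = nrow(P))
  ty <- outer(P[, 2], A[, 2], "-") * rep(ab[, 2], each = nrow(P))
  tt <- pmin(pmax((tx + ty) / rep(len2, each = nrow(P)), 0), 1)
  fx <- rep(A[, 1], each = nrow(P)) + tt * rep(ab[, 1], each = nrow(P))
  fy <- rep(A[, 2], each = nrow(P)) + tt * rep(ab[, 2], each = nrow(P))
  d2 <- (fx - P[, 1])^2 + (fy - P[, 2])^2
  dim(d2) <- c(nrow(P), n - 1)
  j <- max.col(-d2, ties.method = "first")
  idx <- cbind(seq_len(nrow(P)), j)
  dim(fx) <- dim(fy) <- c(nrow(P), n - 1)
  list(point = cbind(fx[idx], fy[idx]), dist = sqrt(d2[idx]))
}

#' Directed distances from points to a polyline
#' @param P m x 2 matrix of points.
#' @param Q n x 2 polyline.
#' @return Vector of distances (their maximum is the directed Hausdorff
#'   distance from P to Q).
#' @export
directed_dist <- function(P, Q) nearest_on_polyline(P, Q)$dist

# vectorised BFS (8-connectivity) over a logical mask from a start pixel;
# returns integer distance matrix (NA = unreached)
mask_bfs <- function(mask, start_rc) {
  nr <- nrow(mask); nc <- ncol(mask)
  dist <- matrix(NA_integer_, nr, nc)
  fr <- start_rc[1]; fc <- start_rc[2]
  dist[fr, fc] <- 0L
  d <- 0L
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  while (length(fr)) {
    d <- d + 1L
    nrow_cand <- rep(fr, times = 8) + rep(dr, each = length(fr))
    ncol_cand <- rep(fc, times = 8) + rep(dc, each = length(fr))
    ok <- nrow_cand >= 1L & nrow_cand <= nr & ncol_cand >= 1L & ncol_cand <= nc
    nrow_cand <- nrow_cand[ok]; ncol_cand <- ncol_cand[ok]
    idx <- (ncol_cand - 1L) * nr + nrow_cand
    ok <- mask[idx] & is.na(dist[idx])
    idx <- unique(idx[ok])
    if (!length(idx)) break
    dist[idx] <- d
    fr <- ((idx - 1L) %% nr) + 1L
    fc <- ((idx - 1L) %/% nr) + 1L
  }
  dist
}

# farthest mask pixel from a BFS distance map
bfs_farthest <- function(dist) {
  i <- which.max(dist)  # NAs excluded by which.max
  c(((i - 1) %% nrow(dist)) + 1, ((i - 1) %/% nrow(dist)) + 1)
}
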