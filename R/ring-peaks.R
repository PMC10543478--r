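#' Ring-resolved peak detection by 2D local maxima
#'
#' Finds the concentric six-peak rings of a (population) autocorrelogram
#' directly from its 2D local maxima, rather than from the azimuthally
#' averaged profile: a lag bin is a peak if its value is positive, valid,
#' and maximal within a disc neighbourhood; peaks are then grouped into
#' rings by clustering their radii (a new ring starts where consecutive
#' sorted radii jump by more than \code{gap}). Rings of a hexagonal
#' lattice alternate orientation: ring 1 (radius \eqn{\lambda}) along the
#' lattice directions, ring 2 (radius \eqn{\sqrt 3 \lambda}) rotated 30
#' degrees.
#'
#' This resolves neighbouring rings (e.g. ring 2 at \eqn{\sqrt 3 \lambda}
#' and ring 3 at \eqn{2\lambda}) that blur together in the radial profile.
#'
#' @param corr A \code{gp_correlogram2d}.
#' @param neighborhood Disc radius (bins) a peak must dominate (default 6).
#' @param min_radius Radii below this (cm) are treated as the central peak
#'   and skipped (default 2 x neighborhood).
#' @param max_radius_frac Search cutoff as a fraction of the half-extent.
#' @param gap Radius jump (cm) that separates consecutive rings.
#' @param min_peaks Discard radius groups with fewer peaks (default 4; a
#'   complete interior ring has six).
#' @return List of rings, each with \code{radius} (mean peak radius, cm),
#'   \code{peaks} (k x 2 lag coordinates), \code{orientations} (axial
#'   directions, degrees in \[0, 180)), \code{values}.
#' @export
lattice_peaks_2d <- function(corr, neighborhood = 6L, min_radius = NULL,
                             max_radius_frac = 0.92, gap = 6,
                             min_peaks = 4L) {
  if (is.null(min_radius)) min_radius <- 2 * neighborhood * corr$bin_size
  v <- corr$values
  v[!corr$valid] <- -Inf
  nx <- nrow(v); ny <- ncol(v)
  # max filter over a disc neighbourhood via shifted pmax
  nb <- as.integer(neighborhood)
  mx <- matrix(-Inf, nx, ny)
  for (dx in -nb:nb) for (dy in -nb:nb) {
    if ((dx != 0 || dy != 0) && dx^2 + dy^2 <= nb^2) {
      sx <- max(1L, 1L + dx):min(nx, nx + dx)
      tx <- sx - dx
      sy <- max(1L, 1L + dy):min(ny, ny + dy)
      ty <- sy - dy
      mx[tx, ty] <- pmax(mx[tx, ty], v[sx, sy])
    }
  }
  rr <- sqrt(outer(corr$lag_x^2, corr$lag_y^2, "+"))
  cand <- which(is.finite(v) & v > 0 & v > mx &
                  rr > min_radius &
                  rr <= max_radius_frac * max(abs(corr$lag_x)))
  if (!length(cand)) return(list())
  px <- corr$lag_x[((cand - 1L) %% nx) + 1L]
  py <- corr$lag_y[((cand - 1L) %/% nx) + 1L]
  pr <- sqrt(px^2 + py^2)
  ord <- order(pr)
  px <- px[ord]; py <- py[ord]; pr <- pr[ord]; pv <- v[cand][ord]
  grp <- cumsum(c(1, diff(pr) > gap))
  rings <- list()
  for (g in unique(grp)) {
    sel <- grp == g
    if (sum(sel) < min_peaks) next
    rings[[length(rings) + 1L]] <- list(
      radius = mean(pr[sel]),
      peaks = cbind(px[sel], py[sel]),
      orientations = sort(unique(round(
        wrap180(atan2(py[sel], px[sel]) * 180 / pi), 4))),
      values = pv[sel])
  }
  rings
}
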