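#' Radial profile of a 2D correlogram
#'
#' \eqn{M(r)}: the mean autocorrelation along concentric circles of radius
#' r centered at zero lag, tabulated at 1-bin radii (a lag bin contributes
#' to the radius its center distance rounds to). Invalid lags are skipped.
#'
#' @param corr A \code{gp_correlogram2d}.
#' @return List with \code{r} (cm) and \code{M}; class
#'   \code{gp_radial_profile}.
#' @export
radial_profile <- function(corr) {
  rr <- sqrt(outer(corr$lag_x^2, corr$lag_y^2, "+"))
  ri <- as.integer(round(rr / corr$bin_size))
  ok <- corr$valid & !is.na(corr$values)
  sums <- rowsum(corr$values[ok], ri[ok])
  cnts <- rowsum(rep(1, sum(ok)), ri[ok])
  r <- as.integer(rownames(sums)) * corr$bin_size
  structure(list(r = r, M = as.numeric(sums / cnts),
                 half_extent = max(abs(corr$lag_x))),
            class = "gp_radial_profile")
}

#' Annulus containing the peak ring of a correlogram
#'
#' Determines the annulus that isolates a ring of six peaks from the
#' central peak. For a correlogram with clear hexagonal structure,
#' \eqn{M(r)} decreases from the origin to its minimum between the central
#' peak and the ring (\code{r_min} = the radius minimizing M over the
#' search range) and then rises to a maximum at the ring (\code{r_max} =
#' the radius maximizing M beyond \code{r_min}); the annulus spans
#' \code{r_min} to \code{r_max + (r_max - r_min)}. When no clear
#' minimum/maximum pair exists — no interior minimum followed by a
#' maximum, or a max-minus-min depth below 2\% of M(0) (six narrow peaks
#' spread over a full circle leave only a shallow bump in the azimuthal
#' mean, so the depth criterion must be permissive) — the fallback
#' \code{r_min} = 25 cm, \code{r_max} = 40 cm is used and flagged.
#'
#' The default search range stops at 60\% of the correlogram half-extent:
#' on annular-track data the track geometry itself contributes a strong
#' ring at a lag equal to the track diameter, which would otherwise
#' capture the argmax. On such data the minimum of M typically falls
#' beyond the (obscured) innermost ring, so the detected ring is the
#' second hexagonal ring — the behaviour expected of track recordings.
#'
#' @param M A [radial_profile()] (or a correlogram, profiled internally).
#' @param search_range Radii (cm) searched, \code{c(lo, hi)}; \code{NULL}
#'   for the default \code{(2*bin, 0.6*half_extent)}.
#' @return List of class \code{gp_annulus}: \code{r_min}, \code{r_max},
#'   \code{inner_radius}, \code{outer_radius}, \code{fallback_used}.
#' @export
annulus_bounds <- function(M, search_range = NULL) {
  if (inherits(M, "gp_correlogram2d")) M <- radial_profile(M)
  half <- M$half_extent
  if (is.null(search_range)) search_range <- c(2 * diff(M$r[1:2]), 0.6 * half)
  sel <- M$r > search_range[1] & M$r <= search_range[2]
  r <- M$r[sel]; v <- M$M[sel]
  ok <- FALSE
  if (length(v) >= 3L) {
    n <- length(v)
    i_min <- which.min(v)           # ties break to the smallest radius
    if (i_min < n) {
      after <- seq.int(i_min + 1L, n)
      i_max <- after[which.max(v[after])]
      depth <- v[i_max] - v[i_min]
      M0 <- M$M[M$r == 0]
      if (length(M0) && is.finite(M0) && depth >= 0.02 * abs(M0)) ok <- TRUE
    }
  }
  if (ok) {
    r_min <- r[i_min]; r_max <- r[i_max]; fb <- FALSE
  } else {
    r_min <- 25; r_max <- 40; fb <- TRUE
  }
  outer <- min(r_max + (r_max - r_min), half)
  structure(list(r_min = r_min, r_max = r_max, inner_radius = r_min,
                 outer_radius = outer, fallback_used = fb),
            class = "gp_annulus")
}

# Lag-bin coordinates and values inside an annulus of the correlogram.
annulus_bins <- function(corr, annulus) {
  lx <- rep(corr$lag_x, times = length(corr$lag_y))
  ly <- rep(corr$lag_y, each = length(corr$lag_x))
  rr <- sqrt(lx^2 + ly^2)
  sel <- rr >= annulus$inner_radius & rr <= annulus$outer_radius
  v <- as.vector(corr$values)
  v[!as.vector(corr$valid)] <- NA
  list(x = lx[sel], y = ly[sel], r = rr[sel],
       ang = wrap180(atan2(ly[sel], lx[sel]) * 180 / pi),
       values = v[sel])
}

#' Rotational autocorrelation of the extracted annulus
#'
#' Pearson correlation between the annulus of the correlogram and the same
#' annulus rotated by \code{angle} about zero lag. Rotated samples are
#' obtained by bilinear interpolation on the 1-cm lag grid; pairs whose
#' rotated point leaves the valid correlogram are dropped. For a perfect
#' hexagonal lattice the rotational autocorrelation is highest at 60 and
#' 120 degrees and lowest at 30, 90 and 150 degrees.
#'
#' @param corr A \code{gp_correlogram2d}.
#' @param annulus An [annulus_bounds()] result.
#' @param angle Rotation angle, degrees (may be a vector).
#' @return Numeric vector of correlations (NA where undefined, e.g. a
#'   constant annulus).
#' @export
rotational_autocorrelation <- function(corr, annulus, angle) {
  ab <- annulus_bins(corr, annulus)
  base <- ab$values
  vapply(angle, function(th) {
    ca <- cos(th * pi / 180); sa <- sin(th * pi / 180)
    xr <- ca * ab$x - sa * ab$y
    yr <- sa * ab$x + ca * ab$y
    rot <- bilinear_sample(corr$values, corr$lag_x, corr$lag_y, xr, yr)
    ok <- !is.na(base) & !is.na(rot)
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::sd(base[ok]) < 1e-12 || stats::sd(rot[ok]) < 1e-12)
      return(NA_real_)
    stats::cor(base[ok], rot[ok])
  }, numeric(1))
}

#' Gridness score of a correlogram
#'
#' The gridness score quantifies sixfold rotational symmetry: the annulus
#' containing the peak ring is extracted, its rotational autocorrelation
#' is evaluated at the five canonical angles, and the score is
#' \deqn{\min\{r(60°), r(120°)\} - \max\{r(30°), r(90°), r(150°)\}.}
#' Scores lie in \eqn{[-2, 2]}; positive values indicate hexagonal
#' structure, a radially symmetric annulus scores 0, and a square lattice
#' scores negative.
#'
#' @param corr A \code{gp_correlogram2d}.
#' @param annulus Optional [annulus_bounds()] override; determined from
#'   the correlogram when \code{NULL}.
#' @param profile If TRUE, also return the rotational autocorrelation
#'   profile in 3-degree steps (diagnostics).
#' @return The score (numeric; NA when undefined), with the annulus as
#'   attribute \code{"annulus"}; if \code{profile}, a list with
#'   \code{score}, \code{annulus}, \code{angles}, \code{rotcorr}.
#' @export
gridness_score <- function(corr, annulus = NULL, profile = FALSE) {
  if (is.null(annulus)) annulus <- annulus_bounds(corr)
  rc <- rotational_autocorrelation(corr, annulus, c(30, 60, 90, 120, 150))
  score <- if (anyNA(rc)) NA_real_ else
    min(rc[c(2, 4)]) - max(rc[c(1, 3, 5)])
  if (profile) {
    angs <- seq(3, 177, by = 3)
    return(list(score = score, annulus = annulus, angles = angs,
                rotcorr = rotational_autocorrelation(corr, annulus, angs)))
  }
  attr(score, "annulus") <- annulus
  score
}

#' Locate the three peaks of the upper half-annulus
#'
#' Iteratively finds the three lattice peaks on the upper half (0-180
#' degrees from the positive x-axis) of the extracted annulus: take the
#' bin with the maximum autocorrelation, exclude the sector within 35
#' degrees of it (angular distance taken modulo 180 degrees, using the
#' correlogram's point symmetry so exclusion wraps across 0/180), and
#' repeat twice. Peaks are bin-center argmaxes; ties go to the first bin
#' in raster order.
#'
#' @param corr A \code{gp_correlogram2d}.
#' @param annulus An [annulus_bounds()] result.
#' @param exclusion Half-width (degrees) of the sector excluded around
#'   each found peak.
#' @return 3 x 2 matrix of (x, y) lag coordinates (cm).
#' @export
locate_peaks <- function(corr, annulus, exclusion = 35) {
  ab <- annulus_bins(corr, annulus)
  upper <- ab$y > 0 | (abs(ab$y) < 1e-9 & ab$x > 0)
  x <- ab$x[upper]; y <- ab$y[upper]
  ang <- ab$ang[upper]; v <- ab$values[upper]
  peaks <- matrix(NA_real_, 3L, 2L)
  avail <- !is.na(v)
  for (k in 1:3) {
    if (!any(avail)) stop("annulus too narrow: exclusion emptied the sector")
    i <- which(avail)[which.max(v[avail])]
    peaks[k, ] <- c(x[i], y[i])
    avail <- avail & axial_diff(ang, ang[i]) > exclusion
  }
  peaks
}

#' Infer lattice spacing, orientations and gridness from a correlogram
#'
#' Locates the three peaks of the detected ring ([locate_peaks()]), infers
#' the grid spacing as the mean radial distance to the peaks and the three
#' orientation angles as the peak directions from the positive x-axis, and
#' attaches the gridness score. On annular-track data the central peak
#' often obscures the innermost ring, in which case the detected ring is
#' the second hexagonal ring — radius \eqn{\sqrt{3}\lambda}, rotated 30
#' degrees from the first — and the inferred values are to be interpreted
#' accordingly (see [locate_ring()] for ring-resolved measurement).
#'
#' @param corr A \code{gp_correlogram2d}.
#' @param annulus Optional annulus override.
#' @return List of class \code{gp_lattice_features}: \code{spacing} (cm),
#'   \code{orientations} (3 angles, degrees in \[0, 180), sorted),
#'   \code{gridness}, \code{peaks} (3 x 2, cm), \code{annulus}.
#' @export
infer_lattice <- function(corr, annulus = NULL) {
  if (is.null(annulus)) annulus <- annulus_bounds(corr)
  peaks <- locate_peaks(corr, annulus)
  radii <- sqrt(rowSums(peaks^2))
  orient <- sort(wrap180(atan2(peaks[, 2], peaks[, 1]) * 180 / pi))
  g <- gridness_score(corr, annulus = annulus)
  structure(
    list(spacing = mean(radii), orientations = orient,
         gridness = as.numeric(g), peaks = peaks, annulus = annulus),
    class = "gp_lattice_features"
  )
}

#' @export
print.gp_lattice_features <- function(x, ...) {
  cat(sprintf(
    "<lattice: spacing %.1f cm, orientations %s deg, gridness %.2f%s>\n",
    x$spacing, paste(sprintf("%.1f", x$orientations), collapse = "/"),
    x$gridness, if (x$annulus$fallback_used) " (fallback annulus)" else ""))
  invisible(x)
}

#' Ring-resolved peak measurement
#'
#' Identifies the k-th ring of six peaks from the local maxima of the
#' radial profile \eqn{M(r)} and measures its peaks: the annulus around
#' the k-th local maximum (bounded below by the preceding local minimum,
#' symmetric above) is extracted and the three upper-half peaks located.
#' Ring 1 of an ideal lattice sits at radius \eqn{\lambda}; ring 2 at
#' \eqn{\sqrt{3}\lambda}, rotated 30 degrees.
#'
#' @param corr A \code{gp_correlogram2d}.
#' @param ring Ring index (1 = innermost).
#' @param search_range Radii searched for profile extrema; default as in
#'   [annulus_bounds()] but extending to 85\% of the half-extent so outer
#'   rings stay reachable.
#' @param min_prominence Minimum rise of a profile local maximum over the
#'   preceding minimum, as a fraction of \eqn{M(0)} (default 0.01; the
#'   azimuthal mean of a six-peak ring is a shallow bump).
#' @return As [infer_lattice()], measured on the requested ring, plus
#'   \code{ring} and \code{ring_radius} (profile maximum position).
#' @export
locate_ring <- function(corr, ring = 1L, search_range = NULL,
                        min_prominence = 0.01) {
  M <- radial_profile(corr)
  if (is.null(search_range))
    search_range <- c(2 * diff(M$r[1:2]), 0.85 * M$half_extent)
  sel <- M$r > search_range[1] & M$r <= search_range[2]
  r <- M$r[sel]
  # 3-bin moving average suppresses bin-level wiggles in the profile
  v <- stats::filter(M$M[sel], rep(1 / 3, 3), sides = 2)
  v[c(1L, length(v))] <- M$M[sel][c(1L, length(v))]
  v <- as.numeric(v)
  n <- length(v)
  if (n < 3L) stop("profile too short")
  M0 <- abs(M$M[M$r == 0])
  mins <- which(v[2:(n - 1L)] < v[1:(n - 2L)] & v[2:(n - 1L)] <= v[3:n]) + 1L
  maxs <- which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n]) + 1L
  # keep maxima that rise by min_prominence over the preceding minimum
  rings <- list()
  for (im in maxs) {
    prev_min <- mins[mins < im]
    if (!length(prev_min)) next
    pm <- prev_min[length(prev_min)]
    nx <- mins[mins > im]
    if (v[im] - v[pm] >= min_prominence * M0)
      rings[[length(rings) + 1L]] <-
        c(i_min = pm, i_max = im, i_next = if (length(nx)) nx[1L] else NA)
  }
  if (length(rings) < ring)
    stop(sprintf("only %d ring(s) found in the radial profile", length(rings)))
  rg <- rings[[ring]]
  r_min <- r[rg[["i_min"]]]; r_max <- r[rg[["i_max"]]]
  # bound above by the next profile minimum (and by symmetry around the
  # ring) so neighbouring rings stay out of the peak search
  r_out <- r_max + (r_max - r_min)
  if (!is.na(rg[["i_next"]])) r_out <- min(r_out, r[rg[["i_next"]]])
  ann <- structure(
    list(r_min = r_min, r_max = r_max, inner_radius = r_min,
         outer_radius = min(r_out, M$half_extent),
         fallback_used = FALSE),
    class = "gp_annulus")
  out <- infer_lattice(corr, annulus = ann)
  out$ring <- ring
  out$ring_radius <- r_max
  out
}
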