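#' Environment geometry for an open arena or annular track
#'
#' Describes the circular environments used throughout the package: an open
#' circular arena, or an annular (circular) track obtained by removing an
#' inner disc from the arena. The geometry fixes the 1-cm binning grid that
#' rate maps and autocorrelograms live on: bin \code{(i, j)} covers the
#' half-open square \code{[origin + (i-1)*bin, origin + i*bin)} in each
#' coordinate, with the origin at the lower-left corner of the bounding
#' square of the environment.
#'
#' @param kind "arena" (full disc) or "track" (annulus).
#' @param outer_radius Outer radius in cm (arena radius, or track outer
#'   radius). The standard experimental geometry uses 75 cm.
#' @param inner_radius Inner radius in cm; 0 for an arena, 60 cm for the
#'   standard 15-cm-wide track.
#' @param center Environment center in cm, default \code{c(0, 0)}.
#' @param bin_size Spatial bin size in cm, default 1.
#'
#' @return An object of class \code{gp_geometry} with the occupancy mask
#'   (logical matrix, dim1 = x, dim2 = y), bin-center coordinate vectors
#'   \code{xs}, \code{ys} and the constructor arguments.
#' @export
#' @examples
#' arena <- geometry("arena", outer_radius = 75)
#' track <- geometry("track", outer_radius = 75, inner_radius = 60)
#' sum(track$mask) < sum(arena$mask)
geometry <- function(kind = c("arena", "track"), outer_radius = 75,
                     inner_radius = if (kind == "track") 60 else 0,
                     center = c(0, 0), bin_size = 1) {
  kind <- match.arg(kind)
  if (kind == "arena") inner_radius <- 0
  if (!(outer_radius > inner_radius && inner_radius >= 0))
    stop("need outer_radius > inner_radius >= 0")
  if (bin_size <= 0) stop("bin_size must be positive")
  n <- ceiling(2 * outer_radius / bin_size)
  origin <- center - n * bin_size / 2
  xs <- origin[1] + (seq_len(n) - 0.5) * bin_size
  ys <- origin[2] + (seq_len(n) - 0.5) * bin_size
  r <- sqrt(outer((xs - center[1])^2, (ys - center[2])^2, "+"))
  mask <- r >= inner_radius & r <= outer_radius
  structure(
    list(kind = kind, center = center, outer_radius = outer_radius,
         inner_radius = inner_radius, bin_size = bin_size,
         origin = origin, n = n, xs = xs, ys = ys, mask = mask),
    class = "gp_geometry"
  )
}

#' @export
print.gp_geometry <- function(x, ...) {
  cat(sprintf("<geometry: %s, outer %g cm, inner %g cm, %d x %d bins of %g cm>\n",
              x$kind, x$outer_radius, x$inner_radius, x$n, x$n, x$bin_size))
  invisible(x)
}

#' Is a point inside the environment?
#'
#' @param geom A [geometry()] object.
#' @param xy A two-column matrix (x, y) of positions in cm.
#' @return Logical vector.
#' @keywords internal
in_geometry <- function(geom, xy) {
  r <- sqrt((xy[, 1] - geom$center[1])^2 + (xy[, 2] - geom$center[2])^2)
  r >= geom$inner_radius & r <= geom$outer_radius
}
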