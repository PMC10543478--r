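#' Per-cell lattice features for module partitioning
#'
#' Assembles the feature table used to split grid cells into modules: each
#' cell's inferred spacing and three orientation angles, z-scored across
#' the cell set (columnwise).
#'
#' @param spacing Numeric vector of spacings (cm), one per cell.
#' @param orientations n x 3 matrix of orientation angles (degrees).
#' @param cell_id Optional cell identifiers.
#' @param circular If TRUE, each orientation angle is embedded as a point
#'   on the 60-degree-period circle (cosine and sine of angle * 6) before
#'   z-scoring, respecting the angles' circularity. The default (FALSE)
#'   z-scores the raw angles linearly, which is the convention matched by
#'   the rest of the analysis.
#' @return List of class \code{gp_cell_features} with \code{z_features}
#'   (matrix), \code{spacing}, \code{orientations}, \code{cell_id}.
#' @export
cell_features <- function(spacing, orientations, cell_id = NULL,
                          circular = FALSE) {
  orientations <- as.matrix(orientations)
  stopifnot(length(spacing) == nrow(orientations),
            ncol(orientations) == 3L)
  if (is.null(cell_id)) cell_id <- seq_along(spacing)
  raw <- if (circular) {
    th <- orientations * pi / 30  # 60-degree period onto the circle
    cbind(spacing, cos(th), sin(th))
  } else {
    cbind(spacing, orientations)
  }
  z <- scale(raw)
  z[, attr(z, "scaled:scale") == 0] <- 0   # constant feature -> all zeros
  structure(list(z_features = unclass(z)[, , drop = FALSE],
                 spacing = spacing, orientations = orientations,
                 cell_id = cell_id),
            class = "gp_cell_features")
}

#' Partition grid cells into modules by hierarchical clustering
#'
#' Agglomerative clustering with average linkage (the distance between two
#' clusters is the average Euclidean distance between all pairs across
#' them) on the z-scored spacing and orientation features. The tree is cut
#' at the smallest number of clusters such that exactly \code{n_modules}
#' of them have at least two members; cells in singleton clusters at that
#' cut are reported as outliers.
#'
#' @param features A [cell_features()] object.
#' @param n_modules Number of modules to recover (default 2).
#' @return List of class \code{gp_cluster_result}: \code{labels} (module
#'   id per cell, NA for outliers), \code{outliers} (indices),
#'   \code{merge_tree} (the \code{hclust} object), \code{heights}.
#' @export
cluster_modules <- function(features, n_modules = 2L) {
  z <- features$z_features
  n <- nrow(z)
  if (n < n_modules) stop("fewer cells than requested modules")
  d <- stats::dist(z)
  if (all(d < 1e-12) && n_modules > 1L)
    stop("all cells have identical features; cannot split into modules")
  h <- stats::hclust(d, method = "average")
  labels <- NULL
  for (k in seq.int(n_modules, n)) {
    cut <- stats::cutree(h, k = k)
    sizes <- table(cut)
    if (sum(sizes >= 2L) == n_modules) {
      big <- as.integer(names(sizes)[sizes >= 2L])
      labels <- rep(NA_integer_, n)
      for (j in seq_along(big)) labels[cut == big[j]] <- j
      break
    }
  }
  if (is.null(labels))
    stop(sprintf("no cut yields exactly %d non-singleton clusters", n_modules))
  structure(
    list(labels = labels, outliers = which(is.na(labels)),
         merge_tree = h, heights = h$height, cell_id = features$cell_id),
    class = "gp_cluster_result"
  )
}

#' @export
print.gp_cluster_result <- function(x, ...) {
  tab <- table(x$labels, useNA = "no")
  cat(sprintf("<modules: %s; %d outlier(s)>\n",
              paste(sprintf("%d cells", tab), collapse = " + "),
              length(x$outliers)))
  invisible(x)
}
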