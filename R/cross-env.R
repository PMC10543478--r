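#' Extract a normalized annulus rate vector from a rate map
#'
#' Flattens the rates in the annulus \code{r_in <= |x - center| <= r_out}
#' into a 1D vector in fixed raster order (x fastest), subtracts the mean
#' rate over visited annulus bins, and zeroes unvisited entries. This
#' normalization removes bias from uneven exploration when rate maps are
#' compared across environments on their shared annulus. With the standard
#' geometry the shared annulus is the track itself (radii 60 and 75 cm).
#'
#' @param map A [rate_map()].
#' @param center Annulus center, cm.
#' @param r_in,r_out Inner/outer radii, cm.
#' @param cell_id,environment_id Optional identifiers carried through.
#' @return List of class \code{gp_annulus_vector}: \code{values},
#'   \code{visited}, \code{cell_id}, \code{environment_id}.
#' @export
extract_annulus_vector <- function(map, center = c(0, 0), r_in = 60,
                                   r_out = 75, cell_id = NULL,
                                   environment_id = NULL) {
  co <- map_coords(map)
  rr <- sqrt(outer((co$xs - center[1])^2, (co$ys - center[2])^2, "+"))
  sel <- rr >= r_in & rr <= r_out
  if (!any(sel)) stop("empty annulus")
  v <- map$values[sel]
  vis <- map$visited[sel]
  if (any(vis)) v[vis] <- v[vis] - mean(v[vis])
  v[!vis] <- 0
  structure(list(values = v, visited = vis, cell_id = cell_id,
                 environment_id = environment_id),
            class = "gp_annulus_vector")
}

#' Same-cell vs cross-cell rate-map correlations across environments
#'
#' For every pair of environments, computes the Pearson correlation of
#' each cell's normalized annulus vector between the two environments
#' (same-cell coefficients) and of all ordered pairs of distinct cells
#' (cross-cell controls), then tests same-cell > cross-cell with a
#' right-tailed Mann-Whitney U (rank-sum) test. A significant result means
#' individual firing patterns are preserved between the environments; a
#' non-significant one is the signature of e.g. a lattice phase shift.
#'
#' @param vectors List of [extract_annulus_vector()] objects covering >= 2
#'   cells in >= 2 environments (all on the same annulus grid).
#' @return Data frame of class \code{gp_xenv_result}, one row per
#'   environment pair: \code{env_a}, \code{env_b}, \code{p_value}, plus
#'   attributes \code{same_cell} and \code{cross_cell} (named lists of
#'   coefficient vectors per pair).
#' @export
pairwise_environment_correlations <- function(vectors) {
  cells <- vapply(vectors, function(v) as.character(v$cell_id), character(1))
  envs <- vapply(vectors, function(v) as.character(v$environment_id),
                 character(1))
  if (length(unique(cells)) < 2L || length(unique(envs)) < 2L)
    stop("need >= 2 cells and >= 2 environments")
  getv <- function(cell, env) {
    i <- which(cells == cell & envs == env)
    if (length(i) != 1L) return(NULL)
    vectors[[i]]$values
  }
  safe_cor <- function(a, b) {
    if (is.null(a) || is.null(b)) return(NA_real_)
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
    stats::cor(a, b)
  }
  envs_u <- unique(envs)
  cells_u <- unique(cells)
  pairs <- utils::combn(envs_u, 2L)
  same_cell <- list(); cross_cell <- list(); pv <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    ea <- pairs[1L, j]; eb <- pairs[2L, j]
    same <- vapply(cells_u, function(cl)
      safe_cor(getv(cl, ea), getv(cl, eb)), numeric(1))
    cross <- as.vector(vapply(cells_u, function(c1)
      vapply(cells_u, function(c2)
        if (c1 == c2) NA_real_ else safe_cor(getv(c1, ea), getv(c2, eb)),
        numeric(1)), numeric(length(cells_u))))
    same <- same[!is.na(same)]; cross <- cross[!is.na(cross)]
    key <- paste(ea, eb, sep = ":")
    same_cell[[key]] <- same
    cross_cell[[key]] <- cross
    pv[j] <- if (length(same) && length(cross))
      suppressWarnings(     # ties fall back to the normal approximation
        stats::wilcox.test(same, cross, alternative = "greater")$p.value)
    else NA_real_
  }
  out <- data.frame(env_a = pairs[1L, ], env_b = pairs[2L, ], p_value = pv,
                    stringsAsFactors = FALSE)
  attr(out, "same_cell") <- same_cell
  attr(out, "cross_cell") <- cross_cell
  class(out) <- c("gp_xenv_result", class(out))
  out
}
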