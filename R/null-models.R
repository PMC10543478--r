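#' Detect firing fields as connected suprathreshold components
#'
#' Fields are 8-connected components of bins whose rate exceeds
#' \code{threshold} times the map maximum. Connectivity is resolved with
#' an adjacency graph over suprathreshold bins.
#'
#' @param map A [rate_map()].
#' @param threshold Fraction of the map maximum in \[0, 1).
#' @return List of class \code{gp_fields}: \code{labels} (integer matrix,
#'   0 = background), \code{n_fields}, \code{areas} (cm^2, by field) and
#'   \code{fields} (per-field lists with \code{ix}, \code{iy},
#'   \code{value} vectors).
#' @export
detect_fields <- function(map, threshold = 0) {
  stopifnot(threshold >= 0, threshold < 1)
  v <- map$values
  nx <- nrow(v); ny <- ncol(v)
  labels <- matrix(0L, nx, ny)
  mx <- max(v)
  if (mx <= 0) {
    return(structure(list(labels = labels, n_fields = 0L,
                          areas = numeric(0), fields = list()),
                     class = "gp_fields"))
  }
  on <- v > threshold * mx
  idx <- which(on)
  # 8-neighbour edges between suprathreshold bins
  ix <- ((idx - 1L) %% nx) + 1L
  iy <- ((idx - 1L) %/% nx) + 1L
  pos <- matrix(0L, nx, ny)
  pos[idx] <- seq_along(idx)
  edges <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    jx <- ix + d[1L]; jy <- iy + d[2L]
    okn <- jx >= 1L & jx <= nx & jy >= 1L & jy <= ny
    nb <- integer(length(idx))
    nb[okn] <- pos[cbind(jx[okn], jy[okn])]
    keep <- nb > 0L
    if (any(keep))
      edges <- rbind(edges, cbind(seq_along(idx)[keep], nb[keep]))
  }
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_along(idx), seq_along(idx))), directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(idx)]
  labels[idx] <- as.integer(comp)
  n <- max(comp)
  ord <- order(comp)
  bounds <- c(0L, cumsum(tabulate(comp, n)))
  fields <- lapply(seq_len(n), function(k) {
    sel <- ord[(bounds[k] + 1L):bounds[k + 1L]]
    list(ix = ix[sel], iy = iy[sel], value = v[idx[sel]])
  })
  areas <- vapply(fields, function(f) length(f$ix), integer(1)) *
    map$bin_size^2
  structure(list(labels = labels, n_fields = n, areas = areas,
                 fields = fields),
            class = "gp_fields")
}

#' Field-shuffled surrogate rate map
#'
#' Builds a control rate map with the same non-spatial statistics as the
#' source: its firing fields (connected suprathreshold components) are
#' relocated uniformly at random inside the same environment without any
#' two fields overlapping (or touching, so that re-detection on the
#' control recovers exactly the same fields), largest first. Detection
#' starts at threshold 0;
#' whenever a field exceeds \code{max_area} or a placement cannot be found
#' within the attempt budget, the detection threshold is raised by
#' \code{threshold_step} of the map maximum and the whole procedure
#' restarts. Finally the subthreshold pixel values are randomly assigned
#' to the remaining zero-activity bins of the environment, so the value
#' multiset of the control matches the source exactly.
#'
#' @param map A [rate_map()].
#' @param geom The [geometry()] the map lives in.
#' @param seed Integer seed.
#' @param max_area Largest allowed field, cm^2. The standard constraints
#'   are 1000 (arena) and 500 (track); the default picks by geometry kind.
#' @param threshold_step Escalation step, fraction of the map maximum
#'   (default 0.01).
#' @param attempts Uniform placement draws per field before escalating.
#' @param plan Optional [shuffle_plan()] carrying memoised field
#'   detections for this map (used by [gridness_significance()] to avoid
#'   re-detecting the same fields in every replicate).
#' @return List of class \code{gp_shuffle_control}: \code{control_map},
#'   \code{final_threshold} (fraction), \code{n_fields},
#'   \code{field_areas}.
#' @export
shuffle_fields <- function(map, geom, seed = NULL,
                           max_area = if (geom$kind == "track") 500 else 1000,
                           threshold_step = 0.01, attempts = 1000L,
                           plan = NULL) {
  mx <- max(map$values)
  nx <- nrow(map$values); ny <- ncol(map$values)
  if (mx <= 0) {
    return(structure(list(control_map = map, final_threshold = 0,
                          n_fields = 0L, field_areas = numeric(0)),
                     class = "gp_shuffle_control"))
  }
  mask_idx <- which(geom$mask)
  if (is.null(plan)) plan <- shuffle_plan(map, max_area, threshold_step)
  with_seed_(seed, {
    thr <- plan$start_threshold
    repeat {
      if (thr >= 1) stop("environment too small to place all fields")
      fl <- plan$get_fields(thr)
      if (fl$n_fields == 0L || any(fl$areas > max_area)) {
        thr <- thr + threshold_step
        next
      }
      ord <- order(fl$areas, decreasing = TRUE)
      # `occupied` additionally blocks the 8-neighbourhood of every placed
      # field: two fields that merely touch would merge into a single
      # connected component, breaking the field-count conservation
      occupied <- !geom$mask          # outside environment counts occupied
      ctrl <- matrix(0, nx, ny)
      filled <- matrix(FALSE, nx, ny) # actual field pixels (no halo)
      placed_all <- TRUE
      for (k in ord) {
        f <- fl$fields[[k]]
        rx <- f$ix - min(f$ix); ry <- f$iy - min(f$iy)
        rel <- ry * nx + rx              # linear offsets of the field shape
        done <- FALSE
        anchors <- mask_idx[sample.int(length(mask_idx), attempts,
                                       replace = TRUE)]
        ax_all <- ((anchors - 1L) %% nx) + 1L
        ay_all <- ((anchors - 1L) %/% nx) + 1L
        keep <- ax_all + max(rx) <= nx & ay_all + max(ry) <= ny
        anchors <- anchors[keep]
        # scan anchors in vectorized chunks (growing geometrically: easy
        # placements exit after a tiny chunk, hard ones ramp up quickly);
        # a subsampled pixel prefilter rejects most colliding anchors
        # before the full-shape check
        rel_sub <- if (length(rel) > 16L)
          rel[seq.int(1L, length(rel), by = 8L)] else rel
        chunk <- 8L
        i0 <- 1L
        while (!done && i0 <= length(anchors)) {
          anc <- anchors[i0:min(i0 + chunk - 1L, length(anchors))]
          pre <- rowSums(matrix(occupied[as.vector(outer(anc, rel_sub, "+"))],
                                nrow = length(anc))) == 0
          for (a in anc[pre]) {
            cells <- a + rel
            if (any(occupied[cells])) next
            ctrl[cells] <- f$value
            filled[cells] <- TRUE
            px <- ((cells - 1L) %% nx) + 1L
            py <- ((cells - 1L) %/% nx) + 1L
            for (ddx in -1:1) for (ddy in -1:1) {
              qx <- px + ddx; qy <- py + ddy
              okq <- qx >= 1L & qx <= nx & qy >= 1L & qy <= ny
              occupied[cbind(qx[okq], qy[okq])] <- TRUE
            }
            done <- TRUE
            break
          }
          i0 <- i0 + chunk
          chunk <- min(chunk * 2L, 512L)
        }
        if (!done) { placed_all <- FALSE; break }
      }
      if (placed_all) break
      thr <- thr + threshold_step
    }
    # redistribute subthreshold values over the free environment bins
    sub_idx <- which(map$visited & fl$labels == 0L)
    free <- which(geom$mask & !filled)
    sub_vals <- map$values[sub_idx]
    if (length(sub_vals) > length(free))
      stop("internal error: fewer free bins than subthreshold pixels")
    dest <- free[sample.int(length(free), length(sub_vals))]
    ctrl[dest] <- sub_vals
    structure(
      list(control_map = rate_map(ctrl, geom$mask, origin = map$origin,
                                  bin_size = map$bin_size),
           final_threshold = thr, n_fields = fl$n_fields,
           field_areas = fl$areas[ord]),
      class = "gp_shuffle_control")
  })
}

#' Precomputed field-detection ladder for repeated shuffles of one map
#'
#' Field detection at a given threshold is deterministic, and the first
#' threshold on the escalation ladder whose fields all satisfy the area
#' constraint can be found by bisection (component areas only shrink as
#' the threshold rises). This object memoises both, so repeated
#' [shuffle_fields()] replicates of the same map (as in
#' [gridness_significance()]) only redo the stochastic placement.
#'
#' @param map A [rate_map()].
#' @param max_area Largest allowed field, cm^2.
#' @param threshold_step Escalation step (fraction of the map maximum).
#' @return An environment with \code{get_fields(thr)} and
#'   \code{start_threshold}.
#' @export
shuffle_plan <- function(map, max_area, threshold_step = 0.01) {
  cache <- new.env(parent = emptyenv())
  get_fields <- function(thr) {
    key <- sprintf("t%.6f", thr)
    if (is.null(cache[[key]])) cache[[key]] <- detect_fields(map, thr)
    cache[[key]]
  }
  area_ok <- function(thr) {
    fl <- get_fields(thr)
    fl$n_fields > 0L && all(fl$areas <= max_area)
  }
  n_steps <- ceiling(1 / threshold_step)
  lo <- 0L; hi <- n_steps - 1L
  if (!area_ok(hi * threshold_step))
    stop("environment too small to place all fields")
  if (area_ok(0)) hi <- 0L else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (area_ok(mid * threshold_step)) hi <- mid else lo <- mid
    }
  }
  env <- new.env(parent = emptyenv())
  env$get_fields <- get_fields
  env$start_threshold <- hi * threshold_step
  env
}

#' Shuffle spike times uniformly over the session
#'
#' The temporal null model for linearized-track analysis: the spike count
#' is preserved and times are redrawn i.i.d. uniform over the session,
#' destroying any spatial organization of firing.
#'
#' @param spikes A [spike_train()].
#' @param session_bounds Length-2 numeric, session start/end (s).
#' @param seed Integer seed.
#' @return A [spike_train()].
#' @export
shuffle_spikes_time <- function(spikes, session_bounds, seed = NULL) {
  n <- length(spikes$spike_times)
  with_seed_(seed, {
    spike_train(sort(stats::runif(n, session_bounds[1], session_bounds[2])))
  })
}

#' Permutation significance of a population gridness score
#'
#' For each of \code{n_controls} replicates, every cell's rate map is
#' field-shuffled ([shuffle_fields()]), the population autocorrelation of
#' the controls is computed and its gridness score recorded. The p-value
#' is the plain fraction of control scores greater than or equal to the
#' observed population gridness (so p may be exactly 0). Replicates with
#' undefined gridness are redrawn.
#'
#' @param observed_maps List of [rate_map()]s (one per cell).
#' @param geom Their [geometry()].
#' @param n_controls Number of shuffle replicates (1000 in the full
#'   analysis; reduce for quick checks).
#' @param seed Integer seed; replicate k uses a child seed derived from
#'   it, so results are bit-reproducible.
#' @param mode Autocorrelation mode passed to [autocorrelation_2d()].
#' @return List of class \code{gp_significance}: \code{observed},
#'   \code{control_scores}, \code{p_value}, \code{n_controls}.
#' @export
gridness_significance <- function(observed_maps, geom, n_controls = 1000L,
                                  seed = NULL, mode = "zero_fill_pearson") {
  stopifnot(length(observed_maps) >= 1L)
  obs_corr <- population_autocorrelation(
    lapply(observed_maps, autocorrelation_2d, mode = mode))
  observed <- as.numeric(gridness_score(obs_corr))
  max_area <- if (geom$kind == "track") 500 else 1000
  plans <- lapply(observed_maps, shuffle_plan, max_area = max_area)
  control_scores <- numeric(n_controls)
  draw <- 0L
  for (k in seq_len(n_controls)) {
    repeat {
      draw <- draw + 1L
      sc <- control_population_score(observed_maps, geom,
                                     child_seed(seed, draw), mode, plans)
      if (!is.na(sc)) break
      if (draw > n_controls * 10L + 100L)
        stop("too many replicates with undefined gridness")
      message("replicate with undefined gridness redrawn")
    }
    control_scores[k] <- sc
  }
  p <- mean(control_scores >= observed)
  structure(list(observed = observed, control_scores = control_scores,
                 p_value = p, n_controls = n_controls),
            class = "gp_significance")
}

# One shuffle replicate: shuffle every map, sum autocorrelograms, score.
control_population_score <- function(maps, geom, seed, mode, plans = NULL) {
  ctrls <- lapply(seq_along(maps), function(i)
    shuffle_fields(maps[[i]], geom, seed = child_seed(seed, i),
                   plan = plans[[i]])$control_map)
  pc <- population_autocorrelation(
    lapply(ctrls, autocorrelation_2d, mode = mode))
  as.numeric(gridness_score(pc))
}

#' @export
print.gp_significance <- function(x, ...) {
  cat(sprintf("<gridness significance: observed %.3f, p = %.3f (%d controls)>\n",
              x$observed, x$p_value, x$n_controls))
  invisible(x)
}

#' Joint significance of a pair of gridness scores
#'
#' Compares an observed pair of gridness scores (e.g. the light and dark
#' track conditions) against matched control pairs by simultaneous
#' dominance: p is the fraction of control pairs whose components are both
#' greater than or equal to the corresponding observed components
#' (inclusive at equality).
#'
#' @param observed_pair Length-2 numeric.
#' @param control_pairs Two-column matrix (or data frame) of control score
#'   pairs from matched shuffle replicates.
#' @return The p-value (plain fraction).
#' @export
joint_significance <- function(observed_pair, control_pairs) {
  cp <- as.matrix(control_pairs)
  stopifnot(length(observed_pair) == 2L, ncol(cp) == 2L)
  mean(cp[, 1] >= observed_pair[1] & cp[, 2] >= observed_pair[2])
}
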