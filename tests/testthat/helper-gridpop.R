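# Shared fixtures and independent oracles for the test suite.
# Expensive simulated populations are cached across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

std_arena <- function() fixture("arena", geometry("arena", 75))
std_track <- function() fixture("track", geometry("track", 75, 60))

# 20-cell comodular module (spacing 45, orientation 14.9) and its maps
std_module_maps <- function() {
  fixture("std_maps", {
    mod <- make_module(20, seed = 42)
    arena_maps <- lapply(mod, ideal_rate_map, geom = std_arena())
    track_maps <- lapply(arena_maps, slice_to_track, track = std_track())
    list(module = mod, arena = arena_maps, track = track_maps)
  })
}

std_pop_corr <- function(env = c("arena", "track"),
                         mode = "zero_fill_pearson") {
  env <- match.arg(env)
  key <- paste0("pop_", env, "_", mode)
  fixture(key, population_autocorrelation(
    lapply(std_module_maps()[[env]], autocorrelation_2d, mode = mode)))
}

# Small compact-field maps (truncated ideal lattices): fields are isolated
# blobs already at zero threshold, as for typical recorded grid cells.
compact_maps <- function(n_cells = 4, seed = 1, geom = geometry("arena", 20),
                         spacing = 14, orient = 20, cut = 0.3) {
  mod <- make_module(n_cells, spacing_mean = spacing, orient_mean = orient,
                     seed = seed)
  lapply(mod, function(p) {
    m <- ideal_rate_map(p, geom)
    v <- m$values
    v[v < cut * max(v)] <- 0
    rate_map(v, m$visited, origin = m$origin, bin_size = m$bin_size)
  })
}

# --- independent oracles ----------------------------------------------------

# Brute-force 2D autocorrelation by explicit lag loops (the reference the
# FFT implementation must reproduce).
bf_autocorr2 <- function(map, mode, min_overlap = 20L) {
  a <- map$values
  vis <- map$visited
  nx <- nrow(a); ny <- ncol(a)
  out <- matrix(NA_real_, 2 * nx - 1, 2 * ny - 1)
  for (dx in -(nx - 1):(nx - 1)) for (dy in -(ny - 1):(ny - 1)) {
    i <- max(1, 1 - dx):min(nx, nx - dx)
    j <- max(1, 1 - dy):min(ny, ny - dy)
    A <- a[i, j, drop = FALSE]
    B <- a[i + dx, j + dy, drop = FALSE]
    if (mode == "raw") {
      out[dx + nx, dy + ny] <- sum(A * B)
      next
    }
    if (mode == "masked_pearson") {
      keep <- vis[i, j, drop = FALSE] & vis[i + dx, j + dy, drop = FALSE]
      if (sum(keep) < min_overlap) next
      A <- A[keep]; B <- B[keep]
    }
    A <- as.vector(A); B <- as.vector(B)
    if (length(A) >= 2 && stats::sd(A) > 1e-10 && stats::sd(B) > 1e-10)
      out[dx + nx, dy + ny] <- stats::cor(A, B)
  }
  out
}

# Brute-force agglomerative average-linkage merge heights.
bf_average_linkage_heights <- function(z) {
  d <- as.matrix(stats::dist(z))
  clusters <- as.list(seq_len(nrow(z)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < bd) { bd <- dij; best <- c(j, i) }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Brute-force 8-connected component count by flood fill.
bf_flood_count <- function(on) {
  nx <- nrow(on); ny <- ncol(on)
  seen <- matrix(FALSE, nx, ny)
  n <- 0L
  for (s in which(on & !seen)) {
    if (seen[s]) next
    n <- n + 1L
    stack <- s
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[cur]) next
      seen[cur] <- TRUE
      ci <- ((cur - 1) %% nx) + 1
      cj <- ((cur - 1) %/% nx) + 1
      for (di in -1:1) for (dj in -1:1) {
        ii <- ci + di; jj <- cj + dj
        if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny) {
          nb <- ii + (jj - 1) * nx
          if (on[nb] && !seen[nb]) stack <- c(stack, nb)
        }
      }
    }
  }
  n
}

# Exact right-tailed rank-sum p-value by enumeration of all group
# assignments (small samples, no ties).
bf_ranksum_p <- function(same, cross) {
  all_v <- c(same, cross)
  n <- length(same)
  w_obs <- sum(rank(all_v)[seq_len(n)])
  combs <- utils::combn(length(all_v), n)
  ranks <- rank(all_v)
  ws <- apply(combs, 2, function(ix) sum(ranks[ix]))
  mean(ws >= w_obs)
}

# Angular gaps between the six peaks of a ring (degrees, sorted).
ring_gaps <- function(orientations) {
  six <- sort(c(orientations, orientations + 180) %% 360)
  diff(c(six, six[1] + 360))
}
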