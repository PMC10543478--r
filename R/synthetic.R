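#' Generative lattice parameters for one simulated grid cell
#'
#' @param spacing Lattice spacing \eqn{\lambda} in cm (nearest-neighbour
#'   distance between firing-field centers); must be positive.
#' @param orientation Lattice orientation \eqn{\theta} in degrees; reduced
#'   modulo 60 (hexagonal symmetry).
#' @param phase 2D spatial offset of the lattice in cm.
#' @param peak_rate Firing rate at field centers, Hz. The value used for
#'   simulations is configurable; 10 Hz is a typical peak rate for grid
#'   cells and is the default.
#' @return An object of class \code{gp_grid_params}.
#' @export
#' @examples
#' grid_params(spacing = 45, orientation = 14.9)
grid_params <- function(spacing = 45, orientation = 14.9, phase = c(0, 0),
                        peak_rate = 10) {
  if (spacing <= 0) stop("spacing must be positive")
  if (peak_rate <= 0) stop("peak_rate must be positive")
  structure(
    list(spacing = spacing, orientation = orientation %% 60,
         phase = as.numeric(phase), peak_rate = peak_rate),
    class = "gp_grid_params"
  )
}

#' Ideal hexagonal grid-cell rate map
#'
#' Builds the idealistic rate map of a grid cell as the sum of three 2D
#' sinusoidal gratings whose stripe directions are \eqn{\theta},
#' \eqn{\theta + 60°} and \eqn{\theta + 120°} (wavevectors perpendicular to
#' the stripes, magnitude \eqn{4\pi / (\sqrt{3}\lambda)}). The summed
#' gratings range over \eqn{[-1.5, 3]} and are rescaled affinely to
#' \eqn{[0, \code{peak_rate}]}; field centers form a hexagonal lattice with
#' nearest-neighbour distance \eqn{\lambda} along the directions
#' \eqn{\theta + 60k°}. Rates outside the environment mask are zero.
#'
#' @param params A [grid_params()] object.
#' @param geom A [geometry()] object.
#' @return A [rate_map()].
#' @export
#' @examples
#' m <- ideal_rate_map(grid_params(45, 14.9), geometry("arena", 75))
#' range(m$values)
ideal_rate_map <- function(params, geom) {
  if (params$spacing > 2 * geom$outer_radius)
    warning("spacing exceeds the environment diameter; no full field lattice fits")
  k <- 4 * pi / (sqrt(3) * params$spacing)
  ang <- (params$orientation + c(30, 90, 150)) * pi / 180
  xs <- geom$xs - params$phase[1]
  ys <- geom$ys - params$phase[2]
  g <- matrix(0, geom$n, geom$n)
  for (a in ang) {
    kx <- k * cos(a); ky <- k * sin(a)
    g <- g + cos(outer(kx * xs, ky * ys, "+"))
  }
  vals <- (g + 1.5) / 4.5 * params$peak_rate
  vals[!geom$mask] <- 0
  rate_map(vals, geom$mask, origin = geom$origin, bin_size = geom$bin_size)
}

#' Generate a module of comodular grid cells
#'
#' Draws \code{n_cells} parameter sets sharing (up to optional normal
#' variability) a common spacing and orientation, with spatial phases
#' uniform over one lattice unit cell — the generative definition of a grid
#' module. The standard module of the simulations has spacing 45 cm and
#' orientation 14.9°; realistic variability is sd 5 cm and 3°.
#'
#' @param n_cells Number of cells (>= 1).
#' @param spacing_mean,spacing_sd Normal distribution of spacings (cm).
#' @param orient_mean,orient_sd Normal distribution of orientations (deg).
#' @param peak_rate Peak firing rate (Hz) given to every cell.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return List of [grid_params()] objects.
#' @export
#' @examples
#' mod <- make_module(20, seed = 1)
#' length(mod)
make_module <- function(n_cells, spacing_mean = 45, spacing_sd = 0,
                        orient_mean = 14.9, orient_sd = 0,
                        peak_rate = 10, seed = NULL) {
  stopifnot(n_cells >= 1, spacing_sd >= 0, orient_sd >= 0)
  with_seed_(seed, {
    lapply(seq_len(n_cells), function(i) {
      sp <- max(stats::rnorm(1, spacing_mean, spacing_sd), 1e-6)
      th <- stats::rnorm(1, orient_mean, orient_sd)
      # uniform over the unit-cell parallelogram spanned by the two
      # lattice basis vectors => uniform over phases
      ab <- stats::runif(2)
      v1 <- sp * c(cos(th * pi / 180), sin(th * pi / 180))
      v2 <- sp * c(cos((th + 60) * pi / 180), sin((th + 60) * pi / 180))
      grid_params(spacing = sp, orientation = th,
                  phase = ab[1] * v1 + ab[2] * v2, peak_rate = peak_rate)
    })
  })
}

#' Restrict a rate map to an annular track
#'
#' Grid-cell responses on the circular track are modelled as the
#' corresponding slice of the full-arena hexagonal lattice: rates outside
#' the track mask are zeroed and marked unvisited, rates inside are kept.
#'
#' @param map A [rate_map()] covering (at least) the track extent.
#' @param track A [geometry()] whose mask selects the track.
#' @return A [rate_map()] on the same grid as \code{map}.
#' @export
slice_to_track <- function(map, track) {
  co <- map_coords(map)
  xy <- cbind(rep(co$xs, times = length(co$ys)),
              rep(co$ys, each = length(co$xs)))
  inside <- matrix(in_geometry(track, xy), nrow(map$values))
  keep <- inside & map$visited
  if (!any(inside)) stop("track geometry does not intersect the map extent")
  vals <- map$values
  vals[!keep] <- 0
  rate_map(vals, keep, origin = map$origin, bin_size = map$bin_size)
}

#' Synthetic trajectory inside an environment
#'
#' Generates a plausible exploratory path: a smooth random walk with
#' reflecting boundaries in the arena, or a noisy angular progression with
#' occasional direction reversals on the track (animals on real circular
#' tracks are typically permitted to turn around; the default reversal
#' probability is 0.001 per time step).
#'
#' @param geom A [geometry()] object.
#' @param duration Session length in seconds.
#' @param speed Mean running speed, cm/s (default 15).
#' @param dt Sampling interval, s (default 0.02, i.e. 50 Hz tracking).
#' @param reversal_prob Per-step probability of reversing running direction
#'   on the track.
#' @param seed Integer seed.
#' @return An object of class \code{gp_trajectory}: \code{times} (s) and
#'   \code{positions} (n x 2 matrix, cm).
#' @export
synth_trajectory <- function(geom, duration, speed = 15, dt = 0.02,
                             reversal_prob = 0.001, seed = NULL) {
  if (duration <= 0) stop("duration must be positive")
  n <- max(1L, ceiling(duration / dt))
  times <- (seq_len(n) - 1) * dt
  with_seed_(seed, {
    if (geom$kind == "arena") {
      pos <- matrix(0, n, 2)
      pos[1, ] <- geom$center
      head_ang <- stats::runif(1, 0, 2 * pi)
      step <- speed * dt
      rmax <- geom$outer_radius - geom$bin_size
      for (i in seq_len(n - 1L)) {
        head_ang <- head_ang + stats::rnorm(1, 0, 1.2) * sqrt(dt)
        cand <- pos[i, ] + step * c(cos(head_ang), sin(head_ang))
        if (sqrt(sum((cand - geom$center)^2)) > rmax) {
          # turn towards the center and retry
          head_ang <- atan2(geom$center[2] - pos[i, 2],
                            geom$center[1] - pos[i, 1]) +
            stats::rnorm(1, 0, 0.5)
          cand <- pos[i, ] + step * c(cos(head_ang), sin(head_ang))
          if (sqrt(sum((cand - geom$center)^2)) > rmax) cand <- pos[i, ]
        }
        pos[i + 1L, ] <- cand
      }
    } else {
      r_mid <- (geom$inner_radius + geom$outer_radius) / 2
      half_w <- (geom$outer_radius - geom$inner_radius) / 2
      phi <- numeric(n); rad <- numeric(n)
      phi[1] <- stats::runif(1, 0, 2 * pi)
      rad[1] <- r_mid
      dir <- sample(c(-1, 1), 1)
      for (i in seq_len(n - 1L)) {
        if (stats::runif(1) < reversal_prob) dir <- -dir
        dphi <- dir * speed * dt / rad[i] * (1 + stats::rnorm(1, 0, 0.15))
        phi[i + 1L] <- phi[i] + dphi
        rad[i + 1L] <- r_mid +
          max(min(rad[i] - r_mid + stats::rnorm(1, 0, 0.35 * sqrt(dt) * half_w),
                  half_w), -half_w)
      }
      pos <- cbind(geom$center[1] + rad * cos(phi),
                   geom$center[2] + rad * sin(phi))
    }
    structure(list(times = times, positions = pos), class = "gp_trajectory")
  })
}

#' @export
print.gp_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d samples over %.1f s>\n",
              length(x$times), diff(range(x$times))))
  invisible(x)
}

#' Inhomogeneous Poisson spikes from a rate map along a trajectory
#'
#' Emits spikes as an inhomogeneous Poisson process whose intensity is the
#' rate-map value at the animal's current position (nearest bin, held
#' constant within each tracking interval). Spike counts per interval are
#' Poisson with mean rate x dt; spike times are placed uniformly within the
#' interval.
#'
#' @param map A [rate_map()] (or a function \code{f(x, y)} returning Hz).
#' @param traj A [synth_trajectory()] (or compatible) trajectory.
#' @param seed Integer seed.
#' @return An object of class \code{gp_spike_train} with sorted
#'   \code{spike_times} (s).
#' @export
spikes_from_rate <- function(map, traj, seed = NULL) {
  n <- length(traj$times)
  if (n < 2L) stop("trajectory too short for spike generation")
  dts <- diff(traj$times)
  if (is.function(map)) {
    rates <- map(traj$positions[, 1], traj$positions[, 2])
  } else {
    ix <- pmin(pmax(round((traj$positions[, 1] - map$origin[1]) / map$bin_size + 0.5), 1),
               nrow(map$values))
    iy <- pmin(pmax(round((traj$positions[, 2] - map$origin[2]) / map$bin_size + 0.5), 1),
               ncol(map$values))
    rates <- map$values[cbind(ix, iy)]
  }
  if (any(rates < 0, na.rm = TRUE)) stop("negative rates")
  rates[is.na(rates)] <- 0
  with_seed_(seed, {
    counts <- stats::rpois(n - 1L, rates[-n] * dts)
    idx <- rep.int(seq_len(n - 1L), counts)
    st <- traj$times[idx] + stats::runif(length(idx)) * dts[idx]
    spike_train(sort(st))
  })
}

#' Construct a spike-train object
#'
#' @param spike_times Nondecreasing numeric vector of spike times (s).
#' @return An object of class \code{gp_spike_train}.
#' @export
spike_train <- function(spike_times) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) stop("spike times must be nondecreasing")
  structure(list(spike_times = spike_times), class = "gp_spike_train")
}

#' @export
print.gp_spike_train <- function(x, ...) {
  cat(sprintf("<spike train: %d spikes>\n", length(x$spike_times)))
  invisible(x)
}
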