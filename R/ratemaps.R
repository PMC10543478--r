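#' Occupancy-normalized smoothed rate map
#'
#' Estimates the average firing rate at every position as the ratio of a
#' Gaussian-smoothed spike-position density to the Gaussian-smoothed
#' occupancy time:
#' \deqn{\lambda(x) = \frac{\sum_i g((s_i - x)/\sigma)}
#'                         {\int_0^T g((y(t) - x)/\sigma)\,dt},}
#' where \eqn{s_i} is the animal's position at the i-th spike, \eqn{y(t)}
#' the trajectory and \eqn{g} an (unnormalized) Gaussian kernel with
#' smoothing factor \eqn{\sigma} = 3 cm by default. The time integral is a
#' Riemann sum over trajectory samples with \eqn{\Delta t} equal to the
#' median inter-sample interval; spike positions are linear interpolations
#' of the trajectory at spike times. Positions are accumulated on the 1-cm
#' bin grid before smoothing. Bins farther than \code{unvisited_radius}
#' from every trajectory sample are marked unvisited and set to 0.
#'
#' @param traj Trajectory (\code{times}, \code{positions}).
#' @param spikes A [spike_train()]; all spikes must fall inside the
#'   trajectory's time range.
#' @param geom A [geometry()] defining the bin grid.
#' @param sigma Gaussian smoothing factor, cm (default 3).
#' @param unvisited_radius Distance (cm) beyond which a bin counts as
#'   unvisited (default 3).
#' @return A [rate_map()].
#' @export
average_rate_map <- function(traj, spikes, geom, sigma = 3,
                             unvisited_radius = 3) {
  n <- length(traj$times)
  if (n == 0L) stop("empty trajectory")
  st <- spikes$spike_times
  if (length(st) &&
      (min(st) < traj$times[1] || max(st) > traj$times[n]))
    stop("spike outside the trajectory time range")
  dt <- if (n > 1L) stats::median(diff(traj$times)) else 1

  bin_ix <- function(x, o) pmin(pmax(
    as.integer(floor((x - o) / geom$bin_size)) + 1L, 1L), geom$n)
  acc <- function(xy, w) {
    m <- matrix(0, geom$n, geom$n)
    idx <- bin_ix(xy[, 1], geom$origin[1]) +
      (bin_ix(xy[, 2], geom$origin[2]) - 1L) * geom$n
    s <- rowsum(w, idx)
    m[as.integer(rownames(s))] <- s
    m
  }

  occ <- acc(traj$positions, rep(dt, n))
  if (length(st)) {
    sx <- stats::approx(traj$times, traj$positions[, 1], st, rule = 2)$y
    sy <- stats::approx(traj$times, traj$positions[, 2], st, rule = 2)$y
    spk <- acc(cbind(sx, sy), rep(1, length(st)))
  } else {
    spk <- matrix(0, geom$n, geom$n)
  }

  # truncated Gaussian kernel on the bin grid (constant factor cancels)
  half <- ceiling(4 * sigma / geom$bin_size)
  off <- (-half:half) * geom$bin_size
  K <- exp(-outer(off^2, off^2, "+") / (2 * sigma^2))
  num <- conv2_same(spk, K)
  den <- conv2_same(occ, K)

  # visited = within unvisited_radius of some occupied bin (disc dilation)
  rad <- ceiling(unvisited_radius / geom$bin_size)
  disc <- (outer(((-rad:rad) * geom$bin_size)^2,
                 ((-rad:rad) * geom$bin_size)^2, "+") <= unvisited_radius^2) * 1
  visited <- conv2_same((occ > 0) * 1, disc) > 0.5

  vals <- matrix(0, geom$n, geom$n)
  ok <- visited & den > 0
  vals[ok] <- pmax(num[ok], 0) / den[ok]   # clamp FFT roundoff
  rate_map(vals, visited, origin = geom$origin, bin_size = geom$bin_size)
}

# "same"-size 2D convolution with a centered symmetric kernel, via FFT
# cross-correlation (kernel symmetry makes conv == xcorr).
conv2_same <- function(a, K) {
  nx <- nrow(a); ny <- ncol(a)
  hx <- (nrow(K) - 1L) %/% 2L; hy <- (ncol(K) - 1L) %/% 2L
  ap <- matrix(0, nx + 2L * hx, ny + 2L * hy)
  ap[hx + seq_len(nx), hy + seq_len(ny)] <- a
  P1 <- stats::nextn(nrow(ap) + nrow(K) - 1L, c(2L, 3L))
  P2 <- stats::nextn(ncol(ap) + ncol(K) - 1L, c(2L, 3L))
  Kp <- matrix(0, P1, P2); Kp[seq_len(nrow(K)), seq_len(ncol(K))] <- K
  Ap <- matrix(0, P1, P2); Ap[seq_len(nrow(ap)), seq_len(ncol(ap))] <- ap
  S <- Re(stats::fft(Conj(stats::fft(Kp)) * stats::fft(Ap), inverse = TRUE)) /
    (P1 * P2)
  # S[d1+1, d2+1] = sum_u K(u) ap(u + d); d = (i-1, j-1) centers K on bin (i,j)
  S[seq_len(nx), seq_len(ny)]
}

#' Linearize a circular-track session
#'
#' Maps a trajectory on an annular track to a 1D coordinate: the cumulative
#' signed angular distance travelled from the starting position, times a
#' reference radius, positive for clockwise motion by default. Spikes and
#' timestamps are sorted into 1-cm bins; the rate in a bin is the number of
#' spikes divided by the number of timestamps in that bin, divided by the
#' time step. A lap-stable cell's activity then repeats with period equal
#' to the track circumference (2 pi x \code{radius_convention}; 471 cm at
#' the outer radius of 75 cm).
#'
#' @param traj Trajectory on an annular track.
#' @param spikes A [spike_train()].
#' @param center Track center, cm.
#' @param radius_convention Radius (cm) converting angle to arc length. The
#'   outer radius (75 cm) is the default convention; the track midline
#'   (67.5 cm, circumference 424 cm) is an equally defensible choice and is
#'   supported by passing it here.
#' @param clockwise_positive Sign convention for travelled distance.
#' @param bin_size Linear bin size, cm (default 1).
#' @return An object of class \code{gp_linear_rate_map}: \code{bin_edges}
#'   (cm), \code{rates} (Hz), \code{visited}, and \code{circumference} (cm).
#' @export
linearize <- function(traj, spikes, center = c(0, 0),
                      radius_convention = 75, clockwise_positive = TRUE,
                      bin_size = 1) {
  dx <- traj$positions[, 1] - center[1]
  dy <- traj$positions[, 2] - center[2]
  r <- sqrt(dx^2 + dy^2)
  if (any(r < 1e-9)) stop("trajectory passes through the track center")
  ang <- atan2(dy, dx)
  d <- diff(ang)
  d <- (d + pi) %% (2 * pi) - pi           # unwrap to (-pi, pi]
  sgn <- if (clockwise_positive) -1 else 1
  lin <- c(0, cumsum(sgn * d)) * radius_convention
  n <- length(traj$times)
  dt <- if (n > 1L) stats::median(diff(traj$times)) else 1
  st <- spikes$spike_times
  slin <- if (length(st))
    stats::approx(traj$times, lin, st, rule = 2)$y else numeric(0)

  lo <- floor(min(lin) / bin_size) * bin_size
  hi <- ceiling(max(lin) / bin_size + 1e-9) * bin_size
  edges <- seq(lo, hi, by = bin_size)
  if (length(edges) < 2L) edges <- c(lo, lo + bin_size)
  occ <- graphics::hist(lin, breaks = edges, plot = FALSE)$counts
  spk <- if (length(slin))
    graphics::hist(pmin(pmax(slin, lo), hi), breaks = edges, plot = FALSE)$counts
  else rep(0L, length(occ))
  rates <- rep(0, length(occ))
  visited <- occ > 0
  rates[visited] <- spk[visited] / occ[visited] / dt
  structure(
    list(bin_edges = edges, rates = rates, visited = visited,
         circumference = 2 * pi * radius_convention,
         total_distance = lin[n]),
    class = "gp_linear_rate_map"
  )
}

#' @export
print.gp_linear_rate_map <- function(x, ...) {
  cat(sprintf("<linear rate map: %d bins, circumference %.0f cm>\n",
              length(x$rates), x$circumference))
  invisible(x)
}
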