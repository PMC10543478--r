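#' 2D spatial autocorrelogram of a rate map
#'
#' For every integer-bin spatial lag \eqn{\Delta}, computes the Pearson
#' correlation between the rate map and its \eqn{\Delta}-shifted copy over
#' the window where the two copies overlap. Three modes are supported:
#' \describe{
#'   \item{\code{zero_fill_pearson} (default)}{unvisited bins enter the
#'     correlation as rate 0 and the window is the full square extent of
#'     the map. This is the behaviour implied by setting unvisited rates to
#'     zero before correlating, and it reproduces the geometric signature
#'     of an annular track (central peak plus an outer ring at the track
#'     diameter) in the correlogram.}
#'   \item{\code{masked_pearson}}{only bins visited in both shifted copies
#'     are correlated; lags with fewer than 20 overlapping bins are marked
#'     invalid. Provided for sensitivity analysis.}
#'   \item{\code{raw}}{the unnormalized sliding inner product.}
#' }
#' Lags with zero variance in either copy are marked invalid (\code{NA}
#' value with \code{valid = FALSE}), not NaN-propagated. Computation uses
#' zero-padded FFTs and agrees with an explicit double loop to better than
#' 1e-9.
#'
#' @param map A [rate_map()].
#' @param mode Correlation mode, see above.
#' @param min_overlap Minimum overlapping bin count for a valid lag in
#'   \code{masked_pearson} mode.
#' @return An object of class \code{gp_correlogram2d}: \code{values} matrix
#'   over lags, \code{valid} matrix, lag coordinate vectors \code{lag_x},
#'   \code{lag_y} (cm), \code{bin_size}, \code{mode} and \code{n_cells} (1).
#' @export
#' @examples
#' g <- geometry("arena", 30)
#' ac <- autocorrelation_2d(ideal_rate_map(grid_params(20, 10), g))
#' ac$values[ac$lag_x == 0, ac$lag_y == 0]  # 1 at zero lag
autocorrelation_2d <- function(map,
                               mode = c("zero_fill_pearson",
                                        "masked_pearson", "raw"),
                               min_overlap = 20L) {
  mode <- match.arg(mode)
  a <- map$values
  nx <- nrow(a); ny <- ncol(a)
  plan <- xcorr2_plan(nx, ny)
  rot <- function(z) z[nrow(z):1, ncol(z):1]
  if (mode == "raw") {
    vals <- xcorr2_fft(a, a, plan = plan)
    vals <- (vals + rot(vals)) / 2  # enforce exact point symmetry
    valid <- matrix(TRUE, nrow(vals), ncol(vals))
  } else {
    ip <- function(f1, f2)
      Re(stats::fft(Conj(f1) * f2, inverse = TRUE))[plan$idx1, plan$idx2] /
      (plan$P1 * plan$P2)
    if (mode == "zero_fill_pearson") {
      # overlap windows are rectangles: window counts and sliding sums come
      # from closed forms / summed-area tables, leaving one FFT pair (sxy)
      fa <- padded_fft(a, plan)
      sxy <- ip(fa, fa)
      dx <- -(nx - 1L):(nx - 1L); dy <- -(ny - 1L):(ny - 1L)
      n_tau <- outer(nx - abs(dx), ny - abs(dy))
      sat <- function(z) {
        S <- matrix(0, nx + 1L, ny + 1L)
        S[-1L, -1L] <- apply(apply(z, 2L, cumsum), 1L, cumsum) |> t()
        r1 <- pmax(1L, 1L - dx); r2 <- pmin(nx, nx - dx)
        c1 <- pmax(1L, 1L - dy); c2 <- pmin(ny, ny - dy)
        S[r2 + 1L, c2 + 1L] - S[r1, c2 + 1L] - S[r2 + 1L, c1] + S[r1, c1]
      }
      sx <- sat(a)
      sxx <- sat(a * a)
    } else {
      m <- map$visited * 1
      a <- a * m
      fm <- padded_fft(m, plan)
      fa <- padded_fft(a, plan)
      fa2 <- padded_fft(a * a, plan)
      n_tau <- ip(fm, fm)
      sxy <- ip(fa, fa)
      sx <- ip(fa, fm)      # sum of a over overlap, unshifted copy
      sxx <- ip(fa2, fm)
    }
    # shifted-copy sums are the point reflections of the unshifted ones
    sy <- rot(sx); syy <- rot(sxx)
    n_tau <- round(n_tau)
    vx <- n_tau * sxx - sx^2
    vy <- n_tau * syy - sy^2
    tol <- 1e-8 * max(abs(a))^2 * max(n_tau)
    valid <- n_tau >= max(2L, if (mode == "masked_pearson") min_overlap else 2L) &
      vx > tol & vy > tol
    vals <- matrix(NA_real_, nrow(n_tau), ncol(n_tau))
    vals[valid] <- (n_tau[valid] * sxy[valid] - sx[valid] * sy[valid]) /
      sqrt(vx[valid] * vy[valid])
    valid <- valid & rot(valid)  # keep the lag set point-symmetric
    vals[!valid] <- NA_real_
    vals[valid] <- ((vals + rot(vals)) / 2)[valid]
  }
  structure(
    list(values = vals, valid = valid,
         lag_x = (-(nx - 1L):(nx - 1L)) * map$bin_size,
         lag_y = (-(ny - 1L):(ny - 1L)) * map$bin_size,
         bin_size = map$bin_size, mode = mode, n_cells = 1L),
    class = "gp_correlogram2d"
  )
}

#' @export
print.gp_correlogram2d <- function(x, ...) {
  cat(sprintf("<2D correlogram: %d x %d lags, mode %s, %d cell(s)>\n",
              nrow(x$values), ncol(x$values), x$mode, x$n_cells))
  invisible(x)
}

#' Population autocorrelation: sum of correlograms across comodular cells
#'
#' The population autocorrelation is the elementwise sum of the individual
#' autocorrelograms of all cells in a module. Because the autocorrelation
#' of a hexagonal lattice is independent of its spatial phase, partial
#' per-cell patterns (as arise on an undersampled annular track, where each
#' cell's visible fields depend on its phase) superpose into the complete
#' six-peak lattice even when no individual correlogram shows it.
#' Individual correlograms are summed as-is, without renormalization, so a
#' cell with more surviving structure contributes proportionally more. A
#' lag is valid in the sum if it is valid in at least one input, and the
#' sum runs over the valid inputs at that lag.
#'
#' @param corrs List of correlograms (all 2D or all 1D) sharing lag grid
#'   and mode.
#' @return A correlogram of the same class with \code{n_cells} equal to the
#'   total cell count.
#' @export
population_autocorrelation <- function(corrs) {
  stopifnot(length(corrs) >= 1L)
  first <- corrs[[1L]]
  is2d <- inherits(first, "gp_correlogram2d")
  if (!is2d && !inherits(first, "gp_correlogram1d"))
    stop("inputs must be correlogram objects")
  for (cc in corrs[-1L]) {
    if (!identical(class(cc), class(first)) ||
        !identical(cc$mode, first$mode) ||
        !identical(dim(cc$values), dim(first$values)) ||
        !isTRUE(all.equal(if (is2d) cc$lag_x else cc$lags,
                          if (is2d) first$lag_x else first$lags)))
      stop("correlograms do not share lag grid and mode")
  }
  acc <- array(0, dim = dim(first$values) %||% length(first$values))
  anyv <- array(FALSE, dim = dim(acc))
  for (cc in corrs) {
    v <- cc$values
    ok <- cc$valid & !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    anyv <- anyv | ok
  }
  acc[!anyv] <- NA_real_
  out <- first
  out$values <- if (is2d) matrix(acc, nrow(first$values)) else as.numeric(acc)
  out$valid <- if (is2d) matrix(anyv, nrow(first$values)) else as.logical(anyv)
  out$n_cells <- sum(vapply(corrs, function(cc) cc$n_cells, integer(1)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' 1D autocorrelation of a linearized rate profile
#'
#' Pearson autocorrelation of the linearized firing-rate vector over
#' overlapping bins at every 1-bin lag. For a cell whose fields are stable
#' across laps of a circular track, the profile repeats with period equal
#' to the circumference, producing a peak at that lag; the population
#' version (elementwise sum across cells, via
#' [population_autocorrelation()]) amplifies the circumference peak shared
#' by all cells while idiosyncratic per-cell peaks wash out.
#'
#' @param lin A [linearize()] output.
#' @param mode \code{"zero_fill_pearson"} (unvisited bins as rate 0,
#'   default) or \code{"masked_pearson"}.
#' @param min_overlap Minimum overlap (bins) for a valid lag.
#' @return An object of class \code{gp_correlogram1d}: \code{lags} (cm),
#'   \code{values}, \code{valid}, \code{mode}, \code{n_cells}.
#' @export
autocorrelation_1d <- function(lin,
                               mode = c("zero_fill_pearson", "masked_pearson"),
                               min_overlap = 20L) {
  mode <- match.arg(mode)
  a <- lin$rates
  n <- length(a)
  if (n < 2L) stop("need at least 2 bins")
  if (all(a == 0)) {
    return(structure(
      list(lags = (-(n - 1L):(n - 1L)) * diff(lin$bin_edges[1:2]),
           values = rep(NA_real_, 2L * n - 1L),
           valid = rep(FALSE, 2L * n - 1L),
           mode = mode, n_cells = 1L),
      class = "gp_correlogram1d"
    ))
  }
  m <- if (mode == "masked_pearson") lin$visited * 1 else rep(1, n)
  a <- a * m
  n_tau <- round(xcorr1_fft(m, m))
  sxy <- xcorr1_fft(a, a)
  sx <- xcorr1_fft(a, m)
  sxx <- xcorr1_fft(a * a, m)
  sy <- rev(sx); syy <- rev(sxx)
  vx <- n_tau * sxx - sx^2
  vy <- n_tau * syy - sy^2
  tol <- 1e-8 * max(abs(a))^2 * max(n_tau)
  valid <- n_tau >= max(2L, if (mode == "masked_pearson") min_overlap else 2L) &
    vx > tol & vy > tol
  vals <- rep(NA_real_, length(n_tau))
  vals[valid] <- (n_tau[valid] * sxy[valid] - sx[valid] * sy[valid]) /
    sqrt(vx[valid] * vy[valid])
  structure(
    list(lags = (-(n - 1L):(n - 1L)) * diff(lin$bin_edges[1:2]),
         values = vals, valid = valid, mode = mode, n_cells = 1L),
    class = "gp_correlogram1d"
  )
}

#' @export
print.gp_correlogram1d <- function(x, ...) {
  cat(sprintf("<1D correlogram: %d lags, %d cell(s)>\n",
              length(x$values), x$n_cells))
  invisible(x)
}

#' First prominent non-central peak of a 1D correlogram
#'
#' Scans positive lags beyond \code{min_lag} for local maxima (strictly
#' greater than every value within \code{window} bins) and returns the lag
#' of the first one whose height is at least \code{min_height_frac} of the
#' tallest such maximum. Used to read off the lap-repeat (circumference)
#' peak from a population 1D autocorrelation.
#'
#' @param corr A \code{gp_correlogram1d}.
#' @param min_lag Smallest lag (cm) considered, to skip the central peak.
#' @param window Half-width (bins) of the local-maximum neighbourhood.
#' @param min_height_frac Prominence criterion relative to the tallest
#'   non-central peak.
#' @return Lag in cm (NA if no peak qualifies).
#' @export
first_prominent_peak <- function(corr, min_lag = 25, window = 10L,
                                 min_height_frac = 0.5) {
  lag <- corr$lags
  v <- corr$values
  v[!corr$valid] <- NA
  cand <- which(lag >= min_lag & !is.na(v))
  is_max <- vapply(cand, function(i) {
    lo <- max(1L, i - window); hi <- min(length(v), i + window)
    w <- v[lo:hi]
    all(v[i] >= w, na.rm = TRUE) && sum(!is.na(w)) > 1L
  }, logical(1))
  cand <- cand[is_max]
  if (!length(cand)) return(NA_real_)
  thr <- min_height_frac * max(v[cand])
  cand <- cand[v[cand] >= thr]
  lag[cand[1L]]
}
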