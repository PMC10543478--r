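# Internal numerical helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random state; seed = NULL means "use the current stream".
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic child seed, kept inside 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483587L)
}

# Full (non-circular) 2D cross-correlation by zero-padded FFT:
#   out[dx + nx, dy + ny] = sum_x a(x) * b(x + d),  d = (dx, dy),
# for dx in -(nx-1)..(nx-1), dy likewise. `fb` may carry a precomputed
# fft(B) so population loops reuse transforms of static arrays.
xcorr2_fft <- function(a, b = NULL, fb = NULL, plan = NULL) {
  nx <- nrow(a); ny <- ncol(a)
  if (is.null(plan)) plan <- xcorr2_plan(nx, ny)
  A <- matrix(0, plan$P1, plan$P2)
  A[seq_len(nx), seq_len(ny)] <- a
  fa <- stats::fft(A)
  if (is.null(fb)) {
    B <- matrix(0, plan$P1, plan$P2)
    B[seq_len(nrow(b)), seq_len(ncol(b))] <- b
    fb <- stats::fft(B)
  }
  S <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / (plan$P1 * plan$P2)
  S[plan$idx1, plan$idx2]
}

# Padding geometry for xcorr2_fft on nx-by-ny inputs.
xcorr2_plan <- function(nx, ny) {
  P1 <- stats::nextn(2L * nx - 1L, c(2L, 3L))
  P2 <- stats::nextn(2L * ny - 1L, c(2L, 3L))
  list(
    nx = nx, ny = ny, P1 = P1, P2 = P2,
    idx1 = ((-(nx - 1L):(nx - 1L)) %% P1) + 1L,
    idx2 = ((-(ny - 1L):(ny - 1L)) %% P2) + 1L
  )
}

# fft of a zero-padded matrix under a plan (for caching static factors).
padded_fft <- function(a, plan) {
  A <- matrix(0, plan$P1, plan$P2)
  A[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  stats::fft(A)
}

# 1D analogue of xcorr2_fft.
xcorr1_fft <- function(a, b) {
  n <- length(a); m <- length(b)
  stopifnot(n == m)
  P <- stats::nextn(2L * n - 1L, c(2L, 3L))
  A <- c(a, rep(0, P - n)); B <- c(b, rep(0, P - m))
  S <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE)) / P
  S[((-(n - 1L):(n - 1L)) %% P) + 1L]
}

# Bilinear sampling of matrix Z (dim1 = x, dim2 = y) on the uniform grid
# with cell (i, j) at (xs[i], ys[j]); NA cells poison any interpolated
# value that touches them; points outside the grid return NA. Vectorized
# direct indexing (hot path of the rotational autocorrelation).
bilinear_sample <- function(Z, xs, ys, xp, yp) {
  dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]
  fx <- (xp - xs[1]) / dx
  fy <- (yp - ys[1]) / dy
  i0 <- floor(fx); j0 <- floor(fy)
  wx <- fx - i0; wy <- fy - j0
  nx <- length(xs); ny <- length(ys)
  ok <- i0 >= 0 & i0 <= nx - 2L & j0 >= 0 & j0 <= ny - 2L
  out <- rep(NA_real_, length(xp))
  if (!any(ok)) return(out)
  i0 <- i0[ok] + 1L; j0 <- j0[ok] + 1L
  wx <- wx[ok]; wy <- wy[ok]
  v00 <- Z[cbind(i0, j0)]
  v10 <- Z[cbind(i0 + 1L, j0)]
  v01 <- Z[cbind(i0, j0 + 1L)]
  v11 <- Z[cbind(i0 + 1L, j0 + 1L)]
  out[ok] <- v00 * (1 - wx) * (1 - wy) + v10 * wx * (1 - wy) +
    v01 * (1 - wx) * wy + v11 * wx * wy
  out  # any NA corner propagates NA through the arithmetic
}

# Wrap angles (degrees) into [0, 180): direction of an axial (point-symmetric)
# feature such as an autocorrelogram peak.
wrap180 <- function(a) ((a %% 180) + 180) %% 180

# Smallest angular separation between two axial directions (degrees, <= 90).
axial_diff <- function(a, b) {
  d <- abs(wrap180(a) - wrap180(b))
  pmin(d, 180 - d)
}
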