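test_that("ideal rate maps span [0, peak_rate] and are lattice-periodic", {
  g <- geometry("arena", 60)
  p <- grid_params(30, 21, peak_rate = 8)
  m <- ideal_rate_map(p, g)
  expect_true(all(m$values >= 0))
  expect_true(all(m$values <= 8 + 1e-9))
  expect_equal(max(m$values), 8, tolerance = 1e-3)

  # shifting the phase by any lattice vector leaves the map unchanged
  th <- p$orientation * pi / 180
  v1 <- p$spacing * c(cos(th), sin(th))
  v2 <- p$spacing * c(cos(th + pi / 3), sin(th + pi / 3))
  for (v in list(v1, v2, 2 * v1 - v2)) {
    p2 <- grid_params(30, 21, phase = v, peak_rate = 8)
    expect_equal(ideal_rate_map(p2, g)$values, m$values, tolerance = 1e-9)
  }

  expect_error(ideal_rate_map(grid_params(-3, 0), g))
  expect_warning(ideal_rate_map(grid_params(500, 0), g), "spacing")
})

test_that("field centers form a hexagonal lattice with the requested spacing", {
  big <- geometry("arena", 150)
  m <- ideal_rate_map(grid_params(45, 14.9), big)
  v <- m$values
  nx <- nrow(v)
  # brute-force local maxima away from the rim, deduplicated by strictness
  lm <- NULL
  for (i in 2:(nx - 1)) for (j in 2:(nx - 1)) {
    nb <- v[(i - 1):(i + 1), (j - 1):(j + 1)]
    nb[2, 2] <- -Inf
    if (m$visited[i, j] && v[i, j] > max(nb) && v[i, j] > 0.8 * max(v) &&
        sqrt(big$xs[i]^2 + big$ys[j]^2) < 125)
      lm <- rbind(lm, c(big$xs[i], big$ys[j]))
  }
  d <- as.matrix(dist(lm))
  diag(d) <- Inf
  expect_gt(nrow(lm), 20)
  expect_lt(abs(mean(apply(d, 1, min)) - 45), 1)
})

test_that("make_module draws reproducible comodular parameter sets", {
  m1 <- make_module(20, seed = 5)
  m2 <- make_module(20, seed = 5)
  expect_identical(m1, m2)
  expect_length(make_module(1, seed = 1), 1)

  # zero sds: cells identical except phase
  sp <- vapply(m1, function(p) p$spacing, numeric(1))
  th <- vapply(m1, function(p) p$orientation, numeric(1))
  ph <- t(vapply(m1, function(p) p$phase, numeric(2)))
  expect_true(all(sp == sp[1]) && all(th == th[1]))
  expect_gt(nrow(unique(ph)), 15)

  big <- make_module(2000, spacing_mean = 45, spacing_sd = 5, seed = 9)
  expect_lt(abs(mean(vapply(big, function(p) p$spacing, numeric(1))) - 45), 0.5)
})

test_that("slice_to_track restricts rates to the annulus and conserves mass", {
  arena <- std_arena(); track <- std_track()
  m <- ideal_rate_map(grid_params(45, 14.9), arena)
  s <- slice_to_track(m, track)
  # identity slice: "track" equal to the full arena
  expect_equal(slice_to_track(m, arena)$values, m$values)
  # nonzero rate confined to the annulus
  co <- expand.grid(x = arena$xs, y = arena$ys)
  r <- sqrt(co$x^2 + co$y^2)
  on <- matrix(r >= 60 & r <= 75, arena$n)
  expect_true(all(s$values[!on] == 0))
  # integral of slice equals integral of original over the annulus
  expect_equal(sum(s$values), sum(m$values[on & m$visited]))
  far <- geometry("track", outer_radius = 20, inner_radius = 10,
                  center = c(500, 500))
  expect_error(slice_to_track(m, far), "intersect")
})

test_that("synthetic trajectories stay inside the environment", {
  arena <- geometry("arena", 40)
  tr <- synth_trajectory(arena, duration = 60, speed = 20, seed = 3)
  r <- sqrt(rowSums(tr$positions^2))
  expect_true(all(r <= 40 + 1e-9))
  expect_gte(length(synth_trajectory(arena, 0.1, seed = 1)$times), 1)
  # step lengths average near speed * dt
  steps <- sqrt(rowSums(diff(tr$positions)^2))
  expect_lt(abs(mean(steps) - 20 * 0.02), 0.5 * 20 * 0.02)

  track <- std_track()
  tt <- synth_trajectory(track, duration = 120, speed = 15, seed = 4)
  rt <- sqrt(rowSums(tt$positions^2))
  expect_true(all(rt >= 60 - 1e-9 & rt <= 75 + 1e-9))
})

test_that("a long track session occupies the full annulus", {
  track <- std_track()
  tr <- synth_trajectory(track, duration = 4800, speed = 18, dt = 0.05,
                         seed = 8)
  ix <- pmin(pmax(floor(tr$positions[, 1] - track$origin[1]) + 1, 1), track$n)
  iy <- pmin(pmax(floor(tr$positions[, 2] - track$origin[2]) + 1, 1), track$n)
  occ <- matrix(FALSE, track$n, track$n)
  occ[cbind(ix, iy)] <- TRUE
  expect_gte(mean(occ[track$mask]), 0.999)
})

test_that("Poisson spike generation matches its intensity", {
  arena <- geometry("arena", 40)
  tr <- synth_trajectory(arena, duration = 400, speed = 20, seed = 11)
  expect_length(
    spikes_from_rate(function(x, y) rep(0, length(x)), tr, seed = 1)$spike_times,
    0)
  # constant rate: total count within 3 sd of rT
  r0 <- 6
  sp <- spikes_from_rate(function(x, y) rep(r0, length(x)), tr, seed = 2)
  Tdur <- max(tr$times)
  expect_lt(abs(length(sp$spike_times) - r0 * Tdur), 3 * sqrt(r0 * Tdur))
  expect_identical(sp, spikes_from_rate(function(x, y) rep(r0, length(x)),
                                        tr, seed = 2))

  # time-rescaled inter-spike intervals are Exp(1)
  m <- ideal_rate_map(grid_params(25, 10, peak_rate = 20), arena)
  s <- spikes_from_rate(m, tr, seed = 4)
  ix <- pmin(pmax(round(tr$positions[, 1] - m$origin[1] + 0.5), 1), arena$n)
  iy <- pmin(pmax(round(tr$positions[, 2] - m$origin[2] + 0.5), 1), arena$n)
  rate_t <- m$values[cbind(ix, iy)]
  Lam <- c(0, cumsum(rate_t[-length(rate_t)] * diff(tr$times)))
  Ls <- approx(tr$times, Lam, s$spike_times)$y
  expect_gt(stats::ks.test(diff(Ls), "pexp", 1)$p.value, 0.01)
})

test_that("estimated rate maps recover the generative map", {
  arena <- geometry("arena", 40)
  tr <- synth_trajectory(arena, duration = 600, speed = 20, seed = 21)
  m <- ideal_rate_map(grid_params(25, 10, peak_rate = 12), arena)
  sp <- spikes_from_rate(m, tr, seed = 22)
  est <- average_rate_map(tr, sp, arena)
  ok <- est$visited & m$visited
  expect_gt(cor(est$values[ok], m$values[ok]), 0.8)
})
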