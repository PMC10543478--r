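test_that("average_rate_map follows the smoothed occupancy-normalized formula", {
  arena <- geometry("arena", 40)
  # no spikes: all-zero map, visited where the animal went
  tr <- synth_trajectory(arena, duration = 30, speed = 20, seed = 1)
  m0 <- average_rate_map(tr, spike_train(numeric(0)), arena)
  expect_true(all(m0$values == 0))
  expect_true(any(m0$visited) && !all(m0$visited))

  # a single spike under dense uniform 2D occupancy peaks at the spike bin
  sweep_y <- seq(-25, 25, by = 1)
  sweep_x <- seq(-25, 25, by = 0.5)
  pos <- cbind(rep(sweep_x, times = length(sweep_y)),
               rep(sweep_y, each = length(sweep_x)))
  tr1 <- structure(list(times = seq(0, 200,
                                    length.out = nrow(pos)),
                        positions = pos),
                   class = "gp_trajectory")
  t_spk <- tr1$times[which.min((pos[, 1] - 4.2)^2 + (pos[, 2] - 7.3)^2)]
  m1 <- average_rate_map(tr1, spike_train(t_spk), arena)
  pk <- which(m1$values == max(m1$values), arr.ind = TRUE)
  expect_lt(abs(arena$xs[pk[1, 1]] - 4.2), 1.5)
  expect_lt(abs(arena$ys[pk[1, 2]] - 7.3), 1.5)

  expect_error(average_rate_map(tr1, spike_train(999), arena), "time range")
  expect_error(average_rate_map(list(times = numeric(0), positions = NULL),
                                spike_train(numeric(0)), arena), "empty")
})

test_that("homogeneous firing is recovered and spike mass is conserved", {
  arena <- geometry("arena", 40)
  tr <- synth_trajectory(arena, duration = 600, speed = 20, seed = 31)
  sp <- spikes_from_rate(function(x, y) rep(5, length(x)), tr, seed = 32)
  m <- average_rate_map(tr, sp, arena)
  expect_lt(abs(mean(m$values[m$visited]) - 5), 0.5)

  # conservation: sum over bins of rate x occupancy time ~ spike count
  dt <- median(diff(tr$times))
  ix <- pmin(pmax(floor(tr$positions[, 1] - arena$origin[1]) + 1, 1), arena$n)
  iy <- pmin(pmax(floor(tr$positions[, 2] - arena$origin[2]) + 1, 1), arena$n)
  occ <- matrix(0, arena$n, arena$n)
  for (k in seq_along(ix)) occ[ix[k], iy[k]] <- occ[ix[k], iy[k]] + dt
  expect_lt(abs(sum(m$values * occ) / length(sp$spike_times) - 1), 0.05)
})

test_that("rate maps are invariant under rigid translation", {
  g1 <- geometry("arena", 30)
  g2 <- geometry("arena", 30, center = c(7, -13))
  tr <- synth_trajectory(g1, duration = 120, speed = 20, seed = 41)
  sp <- spikes_from_rate(function(x, y) 3 + pmax(0, x) / 10, tr, seed = 42)
  tr2 <- structure(list(times = tr$times,
                        positions = sweep(tr$positions, 2, c(-7, 13), "-")),
                   class = "gp_trajectory")
  m1 <- average_rate_map(tr, sp, g1)
  m2 <- average_rate_map(tr2, sp, g2)
  expect_equal(m1$values, m2$values, tolerance = 1e-10)
  expect_identical(m1$visited, m2$visited)
})

test_that("linearization accumulates signed angular distance", {
  # stationary animal: zero distance, all activity in one bin
  n <- 101
  trs <- structure(list(times = seq(0, 10, length.out = n),
                        positions = cbind(rep(67.5, n), rep(0, n))),
                   class = "gp_trajectory")
  l0 <- linearize(trs, spike_train(c(2, 5)), radius_convention = 75)
  expect_equal(l0$total_distance, 0)
  expect_equal(sum(l0$rates > 0), 1)

  # one full clockwise lap at radius 75 ends near 471 cm
  ang <- seq(0, -2 * pi, length.out = 2001)
  trc <- structure(list(times = seq(0, 40, length.out = 2001),
                        positions = cbind(75 * cos(ang), 75 * sin(ang))),
                   class = "gp_trajectory")
  lc <- linearize(trc, spike_train(numeric(0)), radius_convention = 75)
  expect_lt(abs(lc$total_distance - 2 * pi * 75), 1)
  expect_equal(lc$circumference, 2 * pi * 75)

  # half lap clockwise then back: ends near zero
  ang2 <- c(seq(0, -pi, length.out = 500), seq(-pi, 0, length.out = 501))
  trr <- structure(list(times = seq(0, 40, length.out = 1001),
                        positions = cbind(70 * cos(ang2), 70 * sin(ang2))),
                   class = "gp_trajectory")
  lr <- linearize(trr, spike_train(numeric(0)), radius_convention = 75)
  expect_lt(abs(lr$total_distance), 1)

  expect_error(linearize(trs, spike_train(numeric(0)), center = c(67.5, 0)),
               "center")
})

test_that("linearized distance is additive over concatenated segments", {
  track <- std_track()
  tr <- synth_trajectory(track, duration = 100, speed = 15, seed = 51)
  n <- length(tr$times)
  cut <- 1200
  l_all <- linearize(tr, spike_train(numeric(0)))
  seg1 <- structure(list(times = tr$times[1:cut],
                         positions = tr$positions[1:cut, ]),
                    class = "gp_trajectory")
  seg2 <- structure(list(times = tr$times[cut:n],
                         positions = tr$positions[cut:n, ]),
                    class = "gp_trajectory")
  d1 <- linearize(seg1, spike_train(numeric(0)))$total_distance
  d2 <- linearize(seg2, spike_train(numeric(0)))$total_distance
  expect_equal(l_all$total_distance, d1 + d2, tolerance = 1e-8)
})

test_that("per-bin linear rates equal spikes / (timestamps x dt)", {
  # two laps with a fixed firing position: rate follows the book-keeping rule
  ang <- seq(0, -4 * pi, length.out = 4001)
  dt <- 0.02
  tr <- structure(list(times = (0:4000) * dt,
                       positions = cbind(67.5 * cos(ang), 67.5 * sin(ang))),
                  class = "gp_trajectory")
  sp <- spike_train(tr$times[c(100, 300, 300, 1000)])
  l <- linearize(tr, sp, radius_convention = 67.5)
  # manual recount in the bin containing each spike
  lin <- cumsum(c(0, -diff(ang))) * 67.5
  for (t_idx in c(100, 1000)) {
    b <- findInterval(lin[t_idx + 1], l$bin_edges)
    nspk <- sum(findInterval(approx(tr$times, lin, sp$spike_times)$y,
                             l$bin_edges) == b)
    nts <- sum(findInterval(lin, l$bin_edges) == b)
    expect_equal(l$rates[b], nspk / nts / dt, tolerance = 1e-10)
  }
})
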