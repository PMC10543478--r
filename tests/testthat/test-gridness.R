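# A radially symmetric correlogram built from a Gaussian central bump.
bump_corr <- function(n = 41, s = 6) {
  lag <- -(n - 1):(n - 1)
  v <- exp(-outer(lag^2, lag^2, "+") / (2 * s^2))
  structure(list(values = v, valid = matrix(TRUE, nrow(v), ncol(v)),
                 lag_x = lag, lag_y = lag, bin_size = 1,
                 mode = "zero_fill_pearson", n_cells = 1L),
            class = "gp_correlogram2d")
}

test_that("the radial profile averages over concentric circles", {
  bc <- bump_corr()
  M <- radial_profile(bc)
  expect_equal(M$M[M$r == 0], bc$values[bc$lag_x == 0, bc$lag_y == 0])
  expect_true(all(diff(M$M[M$r <= 30]) < 1e-12))

  Mi <- radial_profile(std_pop_corr("arena"))
  # ring of six peaks leaves a local maximum near the 45-cm spacing
  near <- Mi$r >= 40 & Mi$r <= 50
  i <- which(near)[which.max(Mi$M[near])]
  expect_gt(Mi$M[i], Mi$M[Mi$r == 30])
  expect_gt(Mi$M[i], Mi$M[Mi$r == 58])
  expect_lt(abs(Mi$r[i] - 45), 3.5)
})

test_that("annulus bounds bracket the peak ring, with fallback when absent", {
  ann <- annulus_bounds(std_pop_corr("arena"))
  expect_false(ann$fallback_used)
  expect_gt(ann$r_min, 10); expect_lt(ann$r_min, 35)
  expect_gt(ann$r_max, 38); expect_lt(ann$r_max, 50)
  expect_equal(ann$outer_radius, ann$r_max + (ann$r_max - ann$r_min))

  # structureless monotone profile: fallback radii 25 and 40
  fb <- annulus_bounds(bump_corr(60, 10))
  expect_true(fb$fallback_used)
  expect_equal(fb$r_min, 25)
  expect_equal(fb$r_max, 40)
  expect_identical(annulus_bounds(std_pop_corr("arena")),
                   annulus_bounds(std_pop_corr("arena")))
})

test_that("rotational autocorrelation reflects the annulus symmetry", {
  bc <- bump_corr()
  ann <- structure(list(r_min = 10, r_max = 20, inner_radius = 10,
                        outer_radius = 30, fallback_used = FALSE),
                   class = "gp_annulus")
  expect_equal(rotational_autocorrelation(bc, ann, 0), 1, tolerance = 1e-9)
  # radially symmetric: correlation ~1 at every angle, so gridness ~0
  rc <- rotational_autocorrelation(bc, ann, c(30, 60, 90, 120, 150))
  expect_true(all(abs(rc - 1) < 0.01))
  expect_lt(abs(as.numeric(gridness_score(bc, annulus = ann))), 0.02)

  pop <- std_pop_corr("arena")
  ann2 <- annulus_bounds(pop)
  rc2 <- rotational_autocorrelation(pop, ann2, c(30, 60, 90, 120, 150))
  expect_true(all(rc2[c(2, 4)] > 0.6))
  expect_true(all(rc2[c(1, 3, 5)] < 0))
})

test_that("gridness separates hexagonal, square and symmetric patterns", {
  expect_gt(as.numeric(gridness_score(std_pop_corr("arena"))), 1)

  # square lattice: sum of two orthogonal gratings scores negative
  g <- geometry("arena", 75)
  k <- 2 * pi / 45
  sq <- (cos(k * outer(g$xs, rep(1, g$n))) +
           cos(k * outer(rep(1, g$n), g$ys)) + 2) / 4 * 10
  sq[!g$mask] <- 0
  msq <- rate_map(sq, g$mask, origin = g$origin)
  expect_lt(as.numeric(gridness_score(autocorrelation_2d(msq))), 0)

  # invariant under uniform scaling of the correlogram values
  pop <- std_pop_corr("arena")
  scaled <- pop; scaled$values <- pop$values * 3.7
  expect_lt(abs(as.numeric(gridness_score(scaled)) -
                  as.numeric(gridness_score(pop))), 0.05)
})

test_that("peak location and lattice inference recover the generative lattice", {
  lat <- infer_lattice(std_pop_corr("arena"))
  expect_lt(abs(lat$spacing - 45), 1)
  expect_equal(length(lat$orientations), 3L)
  expect_lt(max(abs(lat$orientations - c(14.9, 74.9, 134.9))), 2)
  gaps <- diff(c(lat$orientations, lat$orientations[1] + 180))
  expect_true(all(abs(gaps - 60) < 2.5))
  expect_equal(lat$spacing, mean(sqrt(rowSums(lat$peaks^2))))

  # rotating the generative lattice rotates the inferred orientations
  g <- std_arena()
  rot_mod <- make_module(20, orient_mean = 24.9, seed = 42)
  pr <- population_autocorrelation(
    lapply(rot_mod, function(p) autocorrelation_2d(ideal_rate_map(p, g))))
  lat_r <- infer_lattice(pr)
  expect_lt(max(abs(lat_r$orientations - (lat$orientations + 10))), 1.5)
  expect_lt(abs(lat_r$spacing - lat$spacing), 1)
})

test_that("track populations express the second ring at sqrt(3) spacing", {
  arena_lat <- infer_lattice(std_pop_corr("arena"))
  for (seed in c(1, 42)) {
    mod <- make_module(20, seed = seed)
    # masked windows avoid the slight peak bias of the zero-filled square
    # window on annular geometry, so ring radii are read off cleanly
    pt <- population_autocorrelation(lapply(mod, function(p)
      autocorrelation_2d(slice_to_track(ideal_rate_map(p, std_arena()),
                                        std_track()),
                         mode = "masked_pearson")))
    rings <- lattice_peaks_2d(pt)
    expect_gte(length(rings), 2)
    r2 <- rings[[2]]
    expect_lt(abs(r2$radius / 45 - sqrt(3)), 0.05)
    offs <- sapply(r2$orientations, function(o)
      min(abs(((o - arena_lat$orientations) %% 180 + 180) %% 180),
          abs(180 - ((o - arena_lat$orientations) %% 180 + 180) %% 180)))
    expect_true(all(abs(offs - 30) < 3))
  }
})

test_that("ring-resolved 2D peak detection separates neighbouring rings", {
  big <- geometry("arena", 150)
  mod <- make_module(20, seed = 4)
  pb <- population_autocorrelation(
    lapply(mod, function(p) autocorrelation_2d(ideal_rate_map(p, big))))
  rings <- lattice_peaks_2d(pb)
  expect_gte(length(rings), 3)
  expect_lt(abs(rings[[1]]$radius - 45), 1.5)
  expect_lt(abs(rings[[2]]$radius / rings[[1]]$radius - sqrt(3)), 0.05)
  expect_lt(abs(rings[[3]]$radius / rings[[1]]$radius - 2), 0.05)
  # ring 2 rotated 30 degrees; ring 3 aligned with ring 1
  off12 <- min(outer(rings[[1]]$orientations, rings[[2]]$orientations,
                     function(a, b) pmin(abs(a - b) %% 180,
                                         180 - abs(a - b) %% 180)))
  expect_lt(abs(off12 - 30), 3)
})
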