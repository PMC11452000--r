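test_that("first negative distance scans correctly and order-independently", {
  expect_equal(first_negative_distance(c(0.5, 0.2, -0.1, -0.3), c(0, 1, 2, 3)), 2)
  expect_true(is.na(first_negative_distance(c(0.5, 0, 0.2), c(0, 1, 2))))
  expect_equal(first_negative_distance(c(-0.3, 0.5, -0.1, 0.2), c(3, 0, 2, 1)), 2)
  # weights at or above the -1e-12 noise floor do not count as negative
  expect_true(is.na(first_negative_distance(c(0.1, -1e-13), c(0, 1))))
  expect_error(first_negative_distance(c(1, 2), c(0, 1, 2)), "same length")
})

test_that("effective bandwidth matches a brute-force oracle on random point sets", {
  cases <- effbw:::with_local_seed(101, replicate(20, list(
    n = sample(12:40, 1), df = sample(3:10, 1), seed = sample.int(1e6, 1)
  ), simplify = FALSE))
  for (cs in cases) {
    ps <- irregular_points(cs$n, seed = cs$seed)
    d <- pairwise_distances(ps)
    s <- smoothing_matrix(build_tprs_basis(ps, cs$df), cs$df)
    expected <- brute_force_bandwidth(s, d)
    got <- suppressWarnings(effective_bandwidth(s, d))
    expect_identical(got$per_point, expected$per_point)
    expect_equal(got$n_undefined, sum(is.na(expected$per_point)))
    if (got$n_undefined <= cs$n / 2) {
      expect_identical(got$k_hat, expected$k_hat)
    }
    # every defined per-point distance occurs in its own distance column
    for (i in which(!is.na(got$per_point))) {
      expect_true(got$per_point[i] %in% d[, i])
    }
  }
})

test_that("the median uses the mean of the central pair for even counts", {
  ps <- irregular_points(24, seed = 55)
  d <- pairwise_distances(ps)
  s <- smoothing_matrix(build_tprs_basis(ps, 8), 8)
  res <- suppressWarnings(effective_bandwidth(s, d))
  defined <- sort(res$per_point[!is.na(res$per_point)])
  m <- length(defined)
  expected <- if (m %% 2L == 0L) {
    mean(defined[c(m / 2, m / 2 + 1)])
  } else {
    defined[(m + 1) / 2]
  }
  expect_identical(res$k_hat, expected)
})

test_that("mostly-positive smoothers are declared undefined, not silently numeric", {
  d <- pairwise_distances(irregular_points(10, seed = 2))
  s <- diag(10) # no negative weights anywhere
  expect_error(effective_bandwidth(s, d), "no location has a negative")
  s[2, 1] <- -1 # exactly one defined location out of ten
  expect_warning(res <- effective_bandwidth(s, d), "declared undefined")
  expect_true(is.na(res$k_hat))
  expect_equal(res$n_undefined, 9L)
})

test_that("effective bandwidth is invariant under rigid motions end-to-end", {
  ps <- irregular_points(40, seed = 77)
  base <- suppressWarnings(bandwidth_sweep(ps, max_df = 8))
  moved <- rigid_motion(ps, theta = 1.234, shift = c(-250, 940))
  swept <- suppressWarnings(bandwidth_sweep(moved, max_df = 8))
  expect_equal(base$k_hat, swept$k_hat, tolerance = 1e-8)
})

test_that("loess bandwidth recovers an exact linear zero crossing", {
  ps <- irregular_points(15, seed = 42, scale = 200)
  d <- pairwise_distances(ps)
  stopifnot(max(d) > 100)
  w <- 0.2 - 0.002 * d # crosses zero at exactly d = 100
  step <- max(d) / 999
  for (span in c(0.4, 0.75, 1)) {
    res <- loess_effective_bandwidth(w, d, span = span)
    expect_lt(abs(res$k_hat - 100), step + 1e-9)
  }
})

test_that("loess bandwidth is undefined for everywhere-positive weights", {
  ps <- irregular_points(12, seed = 4)
  d <- pairwise_distances(ps)
  w <- matrix(0.05, 12, 12) + 0.001 * d
  res <- loess_effective_bandwidth(w, d, span = 0.8)
  expect_true(is.na(res$k_hat))
  expect_equal(res$method, "loess")
})

test_that("a span too small for the local quadratic fit is rejected with advice", {
  ps <- irregular_points(25, seed = 6)
  d <- pairwise_distances(ps)
  s <- smoothing_matrix(build_tprs_basis(ps, 5), 5)
  expect_error(loess_effective_bandwidth(s, d, span = 0.02), "larger span")
  expect_error(loess_effective_bandwidth(s, d, span = 0), "span")
  expect_error(loess_effective_bandwidth(s, d, span = 1.5), "span")
  expect_error(loess_effective_bandwidth(s, d, span = 0.5, n_eval = 1), "n_eval")
})

test_that("the average-radius (loess) variant is at least the minimum-radius value", {
  # asserted on an irregular fixture; on tiny symmetric grids the ordering
  # can invert at isolated df (the loess curve averages the ringing of the
  # weights, while the minimum-radius scan latches onto the first dip)
  ps <- irregular_points(100, seed = 88, scale = 90)
  basis <- build_tprs_basis(ps, 10)
  d <- pairwise_distances(ps)
  for (df in c(5L, 10L)) {
    s <- smoothing_matrix(basis, df)
    new_k <- suppressWarnings(effective_bandwidth(s, d))$k_hat
    loess_k <- loess_effective_bandwidth(s, d, span = 0.5)$k_hat
    expect_gte(loess_k, new_k)
  }
})

test_that("the df sweep reuses one basis, is deterministic, and flags undefined rows", {
  g <- make_rect_grid(190, 190, 10) # 20x20
  tab <- suppressWarnings(bandwidth_sweep(g, max_df = 25))
  expect_s3_class(tab, "sweep_table")
  expect_equal(tab$df, 3:25)
  expect_equal(nrow(tab), 23L)
  expect_true(all(tab$n_points == 400L))
  expect_true(all(is.na(tab$seed)))

  # k_hat decreases over the coarse df grid used in bandwidth reporting
  coarse <- tab$k_hat[match(c(3, 5, 10, 25), tab$df)]
  expect_false(is.unsorted(rev(coarse), strictly = TRUE))

  # subsampled sweeps reproduce exactly under a fixed seed
  ps <- irregular_points(300, seed = 14)
  t1 <- suppressWarnings(bandwidth_sweep(ps, 10, subsample_to = 200, seed = 1))
  t2 <- suppressWarnings(bandwidth_sweep(ps, 10, subsample_to = 200, seed = 1))
  expect_identical(t1, t2)
  expect_true(all(t1$n_points == 200L))
  expect_true(all(t1$seed == 1L))

  # a df where the smoother is the identity is flagged, not fatal
  tiny <- irregular_points(8, seed = 3)
  tt <- suppressWarnings(bandwidth_sweep(tiny, 7))
  expect_true(is.na(tt$k_hat[tt$df == 7]))
  expect_equal(tt$n_undefined[tt$df == 7], 8L)

  expect_error(bandwidth_sweep(tiny, 8), "may not exceed")
  expect_error(bandwidth_sweep(ps, 10, subsample_to = 100), "seed")
  expect_error(bandwidth_sweep(ps, 10, method = "loess"), "span")
})

test_that("sweep values on a seeded jittered grid match frozen references", {
  # regression pin: frozen from the first computation on this fixture.
  # note the profile is not monotone per df — it rises locally (e.g. df
  # 6-8) before settling; only the coarse df grid (3, 5, 10, 25)
  # decreases monotonically.
  tab <- bandwidth_sweep(jittered_grid_400(), max_df = 25)
  frozen <- c(
    103.8935539858, 84.4985995623, 65.3480270624, 60.4162970575,
    65.2175836642, 69.0892389758, 65.1552882177, 64.3007320426,
    61.5496894279, 58.2482989532, 56.2996622858, 54.4854739226,
    53.8592910471, 52.2869421720, 51.5750600432, 50.0327058539,
    49.0829735482, 48.3162990594, 48.2693534928, 46.0635215065,
    44.5132126396, 43.4929316980, 42.5077758897
  )
  expect_equal(tab$k_hat, frozen, tolerance = 1e-9)
})

test_that("target-bandwidth lookup takes the smallest qualifying df, inclusive", {
  tab <- data.frame(df = c(5L, 10L), k_hat = c(130.0, 92.2))
  expect_identical(df_for_target_bandwidth(tab, 92.2), 10L)
  expect_identical(df_for_target_bandwidth(tab, 100), 10L)
  expect_identical(df_for_target_bandwidth(tab, 130), 5L)
  expect_identical(df_for_target_bandwidth(tab, 90), NA_integer_)
  # undefined rows are ignored
  tab2 <- data.frame(df = 3:5, k_hat = c(NA, 80, 70))
  expect_identical(df_for_target_bandwidth(tab2, 85), 4L)
  expect_error(df_for_target_bandwidth(tab[0, ], 1), "non-empty")
})
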