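test_that("the radial function has its closed form and removable singularity", {
  expect_equal(tps_eta(0), 0)
  expect_equal(tps_eta(1), 0)
  expect_equal(tps_eta(exp(1)), exp(2))
  expect_equal(tps_eta(c(0, 2)), c(0, 4 * log(2)))
  expect_error(tps_eta(-0.1), "nonnegative")
})

test_that("smoother invariants hold on a 7x7 grid for df in {3, 5, 10}", {
  g <- make_rect_grid(60, 60, 10)
  basis <- suppressWarnings(build_tprs_basis(g, 10))
  for (df in c(3L, 5L, 10L)) {
    s <- smoothing_matrix(basis, df)
    expect_equal(dim(s), c(49L, 49L))
    expect_lt(max(abs(s - t(s))), 1e-8)
    expect_lt(max(abs(s %*% s - s)), 1e-8)
    expect_equal(sum(diag(s)), df + 1, tolerance = 1e-6)
    expect_lt(max(abs(rowSums(s) - 1)), 1e-8)
  }
})

test_that("the null-space projection is the planar regression hat matrix", {
  # the intercept + linear-coordinate columns span ordinary planar
  # regression; their projection must match the direct normal-equations
  # hat matrix even though the smoother is computed via QR
  ps <- irregular_points(35, seed = 21)
  basis <- build_tprs_basis(ps, 6)
  q3 <- qr.Q(qr(basis$design[, 1:3]))
  expect_lt(max(abs(tcrossprod(q3) - planar_hat(ps$coords))), 1e-8)
})

test_that("the full-rank smoother at df + 1 = n is the identity", {
  ps <- irregular_points(20, seed = 13)
  basis <- build_tprs_basis(ps, 19)
  s <- smoothing_matrix(basis, 19)
  expect_lt(max(abs(s - diag(20))), 1e-8)
  # an identity smoother has no negative weights: bandwidth must refuse
  expect_error(
    effective_bandwidth(s, pairwise_distances(ps)),
    "undefined at df = 19"
  )
})

test_that("the basis is nested: truncation equals direct construction", {
  ps <- irregular_points(40, seed = 17)
  wide <- build_tprs_basis(ps, 10)
  narrow <- build_tprs_basis(ps, 5)
  p_wide <- tcrossprod(qr.Q(qr(wide$design[, 1:6])))
  p_narrow <- tcrossprod(qr.Q(qr(narrow$design)))
  expect_lt(max(abs(p_wide - p_narrow)), 1e-10)
  # the stored nested orthonormal factor agrees with a direct per-df QR
  for (df in 3:10) {
    direct <- tcrossprod(qr.Q(qr(wide$design[, seq_len(df + 1)])))
    expect_lt(max(abs(smoothing_matrix(wide, df) - direct)), 1e-8)
  }
})

test_that("eigenvalues are retained by descending magnitude", {
  ps <- irregular_points(30, seed = 3)
  basis <- build_tprs_basis(ps, 8)
  expect_length(basis$eigenvalues, 6L)
  expect_false(is.unsorted(rev(abs(basis$eigenvalues))))
  # retained set dominates the discarded set in magnitude
  e <- tps_eta(pairwise_distances(ps))
  all_ev <- eigen(e, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(
    sort(abs(basis$eigenvalues), decreasing = TRUE),
    sort(abs(all_ev), decreasing = TRUE)[1:6]
  )
})

test_that("degenerate geometry and bad df are rejected", {
  collinear <- point_set(1:10, 2 * (1:10) + 5)
  expect_error(build_tprs_basis(collinear, 4), "rank deficient")
  ps <- irregular_points(10, seed = 1)
  expect_error(build_tprs_basis(ps, 10), "smaller than the number of points")
  expect_error(build_tprs_basis(ps, 2), "at least 3")
  basis <- build_tprs_basis(ps, 6)
  expect_error(smoothing_matrix(basis, 7), "\\[3, 6\\]")
  expect_error(smoothing_matrix(basis, 2), "\\[3, 6\\]")
})

test_that("a symmetric grid warns when the retention boundary splits a degenerate pair", {
  # on the 7x7 grid the 7th and 8th eigenvalues by magnitude are equal by
  # symmetry, so max_df = 9 places the retention boundary inside the pair
  g <- make_rect_grid(60, 60, 10)
  expect_warning(build_tprs_basis(g, 9), "near-degenerate")
})

test_that("smoothers are invariant under rigid motions", {
  ps <- irregular_points(30, seed = 7)
  basis <- build_tprs_basis(ps, 10)
  motions <- effbw:::with_local_seed(8, replicate(4, list(
    theta = runif(1, 0, 2 * pi), shift = runif(2, -500, 500)
  ), simplify = FALSE))
  for (m in motions) {
    moved <- rigid_motion(ps, m$theta, m$shift)
    basis2 <- build_tprs_basis(moved, 10)
    for (df in 3:10) {
      expect_lt(
        max(abs(smoothing_matrix(basis, df) - smoothing_matrix(basis2, df))),
        1e-8
      )
    }
  }
})

test_that("column sign flips and rescalings leave the smoother unchanged", {
  # representation freedom: the projection depends only on column spans,
  # which is also why constant factors in the radial function are immaterial
  ps <- irregular_points(25, seed = 19)
  basis <- build_tprs_basis(ps, 7)
  h <- basis$design
  h2 <- h %*% diag(c(1, -1, 2.5, 1, -3, 1, 0.1, 1))
  p1 <- tcrossprod(qr.Q(qr(h)))
  p2 <- tcrossprod(qr.Q(qr(h2)))
  expect_lt(max(abs(p1 - p2)), 1e-10)
  # scaling the radial function rescales only eigen columns: same smoother
  d <- pairwise_distances(ps)
  e_scaled <- 7.3 * tps_eta(d)
  ev <- eigen(e_scaled, symmetric = TRUE)
  ord <- order(-abs(ev$values))
  h3 <- cbind(1, ps$coords, ev$vectors[, ord[1:5]])
  expect_lt(max(abs(tcrossprod(qr.Q(qr(h3))) - p1)), 1e-8)
})
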