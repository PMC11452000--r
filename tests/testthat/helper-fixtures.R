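# Shared fixtures and independent oracles. The oracles deliberately use
# different algorithms from the package code paths they check.

# Irregular (uniform random) point set; seeded, restoring RNG state.
irregular_points <- function(n, seed, scale = 100) {
  xy <- effbw:::with_local_seed(seed, matrix(runif(2 * n, 0, scale), ncol = 2))
  point_set(xy[, 1], xy[, 2])
}

# 20x20 grid at 10 km spacing with +/- 2 km seeded jitter: large enough to
# show the bandwidth's df profile, irregular enough that no eigenpair at
# the retention boundary is degenerate.
jittered_grid_400 <- function() {
  xy <- expand.grid(x = 0:19 * 10, y = 0:19 * 10)
  jit <- effbw:::with_local_seed(2024, matrix(runif(800, -2, 2), ncol = 2))
  point_set(xy$x + jit[, 1], xy$y + jit[, 2])
}

# Even-odd (crossing-count) ray-casting point-in-polygon oracle, one point
# at a time. Independent of the package's winding-number implementation.
# Boundary handling matches the package's inclusive rule via an explicit
# point-to-segment distance test.
ray_cast_inside <- function(px, py, poly) {
  on_any_ring <- function(ring) {
    m <- nrow(ring)
    for (e in seq_len(m)) {
      a <- ring[e, ]
      b <- ring[if (e == m) 1L else e + 1L, ]
      ab2 <- sum((b - a)^2)
      t <- if (ab2 == 0) 0 else ((px - a[1]) * (b[1] - a[1]) + (py - a[2]) * (b[2] - a[2])) / ab2
      t <- min(max(t, 0), 1)
      proj <- a + t * (b - a)
      if (sqrt((px - proj[1])^2 + (py - proj[2])^2) < 1e-9) {
        return(TRUE)
      }
    }
    FALSE
  }
  crossings <- function(ring) {
    m <- nrow(ring)
    cnt <- 0L
    for (e in seq_len(m)) {
      a <- ring[e, ]
      b <- ring[if (e == m) 1L else e + 1L, ]
      if ((a[2] > py) != (b[2] > py)) {
        xint <- a[1] + (py - a[2]) / (b[2] - a[2]) * (b[1] - a[1])
        if (px < xint) cnt <- cnt + 1L
      }
    }
    cnt %% 2L == 1L
  }
  if (on_any_ring(poly$outer)) {
    return(TRUE)
  }
  if (!crossings(poly$outer)) {
    return(FALSE)
  }
  for (h in poly$holes) {
    if (on_any_ring(h)) {
      return(TRUE)
    }
    if (crossings(h)) {
      return(FALSE)
    }
  }
  TRUE
}

# Brute-force effective-bandwidth oracle: sort each smoother column by its
# distances and scan for the first strictly negative weight.
brute_force_bandwidth <- function(s, d) {
  n <- nrow(d)
  per_point <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ord <- order(d[, i])
    for (j in ord) {
      if (s[j, i] < -1e-12) {
        per_point[i] <- d[j, i]
        break
      }
    }
  }
  list(per_point = per_point, k_hat = stats::median(per_point, na.rm = TRUE))
}

# Direct normal-equations planar regression hat matrix.
planar_hat <- function(coords) {
  x <- cbind(1, coords)
  x %*% solve(t(x) %*% x, t(x))
}

# Apply a rigid motion (rotation by `theta` plus translation) to a point set.
rigid_motion <- function(points, theta, shift = c(0, 0)) {
  r <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  xy <- points$coords %*% r
  point_set(xy[, 1] + shift[1], xy[, 2] + shift[2], unit = points$unit)
}
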