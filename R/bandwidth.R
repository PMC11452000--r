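#' Smallest distance with a negative smoothing weight
#'
#' Scans one location's smoothing weights (one column of the smoother
#' matrix) paired with its distances to all locations, and returns the
#' smallest distance whose weight is negative — where the equivalent kernel
#' first dips below zero. The result does not depend on the input order.
#' Weights must fall strictly below `-1e-12` to count as negative, so exact
#' zeros perturbed by floating-point noise are not mistaken for sign
#' changes.
#'
#' @param weights Numeric vector of smoothing weights.
#' @param distances Numeric vector of nonnegative distances, same length.
#' @return The smallest qualifying distance, or `NA_real_` when no weight
#'   is negative (the bandwidth is undefined at this location).
#' @export
first_negative_distance <- function(weights, distances) {
  if (length(weights) != length(distances)) {
    stop(
      "`weights` (", length(weights), ") and `distances` (",
      length(distances), ") must have the same length",
      call. = FALSE
    )
  }
  neg <- weights < -1e-12
  if (!any(neg)) {
    return(NA_real_)
  }
  min(distances[neg])
}

#' Effective bandwidth of a smoother (minimum-radius method)
#'
#' For each location `i`, finds the smallest distance at which the
#' smoothing weight `S[, i]` turns negative; the effective bandwidth
#' `k_hat` is the median of these per-location distances. It is interpreted
#' as the approximate minimum radius of the area over which locations are
#' smoothed: within `k_hat` of a typical location, spatial adjustment is
#' averaging rather than contrasting.
#'
#' Locations whose weights never go negative contribute no distance: they
#' are excluded from the median and counted in `n_undefined`. If more than
#' half the locations are undefined the bandwidth itself is declared
#' undefined (`k_hat = NA` with a warning); if all of them are — as for the
#' identity smoother at `df + 1 = n` — that is an error, since a number
#' here would be meaningless.
#'
#' @param smoother An n x n [smoothing_matrix()] (any numeric matrix with
#'   the same interpretation is accepted).
#' @param distances The n x n distance matrix from [pairwise_distances()],
#'   built from the same point set.
#' @return An object of class `bandwidth_result`: list with `per_point`
#'   (the n first-negative distances, `NA` where undefined), `k_hat`,
#'   `df`, `n`, `n_undefined`, `method = "new"`, and `unit`.
#' @export
effective_bandwidth <- function(smoother, distances) {
  check_smoother_pair(smoother, distances)
  n <- nrow(distances)
  per_point <- vapply(
    seq_len(n),
    function(i) first_negative_distance(smoother[, i], distances[, i]),
    numeric(1)
  )
  n_undefined <- sum(is.na(per_point))
  df <- attr(smoother, "df")
  if (n_undefined == n) {
    stop(
      "effective bandwidth undefined",
      if (!is.null(df)) paste0(" at df = ", df),
      ": no location has a negative smoothing weight ",
      "(the smoother may be the identity)",
      call. = FALSE
    )
  }
  if (n_undefined > n / 2) {
    warning(
      "more than half the locations (", n_undefined, "/", n,
      ") have no negative smoothing weight; effective bandwidth declared undefined"
    )
    k_hat <- NA_real_
  } else {
    k_hat <- stats::median(per_point, na.rm = TRUE)
  }
  new_bandwidth_result(
    per_point = per_point, k_hat = k_hat, df = df, n = n,
    n_undefined = n_undefined, method = "new",
    unit = attr(distances, "unit") %||% attr(smoother, "unit")
  )
}

#' Effective bandwidth by the original loess method (average radius)
#'
#' The original formulation of the effective bandwidth: for each location,
#' a loess curve (local quadratic regression with tricube weights, each
#' local fit using the fraction `span` of the points nearest in distance)
#' is fitted to the smoothing weights `S[, i]` as a function of distance.
#' Weights are then predicted on `n_eval` evenly spaced distances from 0 to
#' the maximum pairwise distance, and the bandwidth is the smallest
#' evaluation distance at which the across-location median predicted weight
#' is negative. Because the loess curve averages over a neighbourhood of
#' distances, this measures an average smoothing radius and is typically
#' larger than the minimum-radius value from [effective_bandwidth()],
#' with the gap narrowing as df grows.
#'
#' @param smoother,distances As in [effective_bandwidth()].
#' @param span Fraction of points in each local fit, `0 < span <= 1`.
#' @param n_eval Number of evaluation distances (default 1000).
#' @return A `bandwidth_result` with `method = "loess"`. `k_hat` is
#'   `NA_real_` when the median predicted weight never crosses zero.
#' @export
loess_effective_bandwidth <- function(smoother, distances, span, n_eval = 1000L) {
  check_smoother_pair(smoother, distances)
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1) {
    stop("`span` must be a single value in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(n_eval) || length(n_eval) != 1L || n_eval < 2) {
    stop("`n_eval` must be at least 2", call. = FALSE)
  }
  n <- nrow(distances)
  eval_d <- seq(0, max(distances), length.out = as.integer(n_eval))
  preds <- matrix(NA_real_, nrow = length(eval_d), ncol = n)
  for (i in seq_len(n)) {
    dat <- data.frame(d = distances[, i], w = smoother[, i])
    fit <- tryCatch(
      suppressWarnings(stats::loess(
        w ~ d,
        data = dat, span = span, degree = 2, family = "gaussian",
        control = stats::loess.control(surface = "direct")
      )),
      error = function(e) {
        stop(
          "loess fit failed for location ", i, " at span = ", span, " (",
          conditionMessage(e), "); try a larger span",
          call. = FALSE
        )
      }
    )
    preds[, i] <- suppressWarnings(
      stats::predict(fit, newdata = data.frame(d = eval_d))
    )
  }
  med <- apply(preds, 1L, stats::median, na.rm = TRUE)
  crossing <- which(med < 0)
  k_hat <- if (length(crossing) == 0L) NA_real_ else eval_d[min(crossing)]
  new_bandwidth_result(
    per_point = NULL, k_hat = k_hat, df = attr(smoother, "df"), n = n,
    n_undefined = NA_integer_, method = "loess", span = span,
    unit = attr(distances, "unit") %||% attr(smoother, "unit")
  )
}

new_bandwidth_result <- function(per_point, k_hat, df, n, n_undefined,
                                 method, span = NA_real_, unit = NULL) {
  structure(
    list(
      per_point = per_point, k_hat = k_hat,
      df = if (is.null(df)) NA_integer_ else as.integer(df),
      n = n, n_undefined = n_undefined, method = method, span = span,
      unit = unit %||% ""
    ),
    class = "bandwidth_result"
  )
}

#' @export
print.bandwidth_result <- function(x, ...) {
  cat(
    "<bandwidth_result> method = ", x$method,
    if (x$method == "loess") paste0(" (span ", format(x$span), ")"),
    ", df = ", x$df, ", n = ", x$n, "\n",
    "  k_hat = ", format(x$k_hat), " ", x$unit,
    if (!is.na(x$n_undefined) && x$n_undefined > 0) {
      paste0("  (", x$n_undefined, " location(s) with no negative weight)")
    },
    "\n",
    sep = ""
  )
  invisible(x)
}

check_smoother_pair <- function(smoother, distances) {
  if (!is.matrix(smoother) || !is.matrix(distances)) {
    stop("`smoother` and `distances` must be matrices", call. = FALSE)
  }
  if (!all(dim(smoother) == dim(distances)) || nrow(smoother) != ncol(smoother)) {
    stop(
      "`smoother` and `distances` must be square matrices of equal size ",
      "built from the same point set",
      call. = FALSE
    )
  }
}

#' Sweep the effective bandwidth over degrees of freedom
#'
#' Computes the effective bandwidth for every df between 3 and `max_df` on
#' one point set. The point set is (optionally) subsampled once, a single
#' nested spline basis is built at `max_df`, and each df reuses the nested
#' projection — so the whole sweep costs one eigendecomposition. A df where
#' the bandwidth is undefined yields an `NA` row and the sweep continues.
#'
#' @param points A [point_set()].
#' @param max_df Largest df in the sweep; must be at most one less than the
#'   number of points after subsampling.
#' @param method `"new"` (minimum radius, the default) or `"loess"`
#'   (average radius).
#' @param span Loess span; required when `method = "loess"`.
#' @param n_eval Evaluation-grid size for the loess method.
#' @param subsample_to Optional cap on the number of points; when smaller
#'   than `n`, a seeded uniform subsample is used for basis, smoother and
#'   median alike.
#' @param seed Integer seed, required whenever subsampling actually
#'   triggers, and echoed in the output.
#' @return A data frame of class `sweep_table` with columns `df`, `k_hat`,
#'   `method`, `span`, `n_points`, `n_undefined`, `seed`, one row per df.
#' @examples
#' sweep <- bandwidth_sweep(make_rect_grid(60, 60, 10), max_df = 8)
#' sweep
#' @export
bandwidth_sweep <- function(points, max_df, method = c("new", "loess"),
                            span = NULL, n_eval = 1000L,
                            subsample_to = NULL, seed = NULL) {
  stopifnot(inherits(points, "point_set"))
  method <- match.arg(method)
  if (method == "loess" && is.null(span)) {
    stop("`span` is required when method = \"loess\"", call. = FALSE)
  }
  subsampled <- FALSE
  if (!is.null(subsample_to) && subsample_to < n_points(points)) {
    if (is.null(seed)) {
      stop("`seed` is required when subsampling triggers", call. = FALSE)
    }
    points <- subsample_points(points, subsample_to, seed)
    subsampled <- TRUE
  }
  n <- n_points(points)
  if (max_df > n - 1L) {
    stop(
      "`max_df` (", max_df, ") may not exceed the number of coordinates ",
      "minus one (", n - 1L, " after any subsampling)",
      call. = FALSE
    )
  }
  basis <- build_tprs_basis(points, max_df)
  distances <- pairwise_distances(points)
  dfs <- seq(3L, as.integer(max_df))
  rows <- lapply(dfs, function(df) {
    s <- smoothing_matrix(basis, df)
    res <- tryCatch(
      switch(method,
        new = suppressWarnings(effective_bandwidth(s, distances)),
        loess = loess_effective_bandwidth(s, distances, span = span, n_eval = n_eval)
      ),
      error = function(e) {
        new_bandwidth_result(
          per_point = NULL, k_hat = NA_real_, df = df, n = n,
          n_undefined = n, method = method,
          span = if (method == "loess") span else NA_real_,
          unit = points$unit
        )
      }
    )
    data.frame(
      df = df, k_hat = res$k_hat, method = method,
      span = if (method == "loess") span else NA_real_,
      n_points = n, n_undefined = res$n_undefined,
      seed = if (subsampled) as.integer(seed) else NA_integer_
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "unit") <- points$unit
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Smallest df achieving a target bandwidth
#'
#' Looks up the smallest df in a sweep table whose effective bandwidth is
#' at or below the target distance — i.e. the fewest splines that smooth at
#' least as finely as the target radius. The rule is boundary-inclusive: a
#' row with `k_hat` exactly equal to the target qualifies. Rows with
#' undefined bandwidth are ignored.
#'
#' @param table A [bandwidth_sweep()] result.
#' @param target Target bandwidth, in the table's distance units.
#' @return The qualifying df as an integer, or `NA_integer_` when every
#'   defined `k_hat` in the table exceeds the target.
#' @export
df_for_target_bandwidth <- function(table, target) {
  stopifnot(is.data.frame(table), all(c("df", "k_hat") %in% names(table)))
  if (nrow(table) == 0L) {
    stop("`table` must be non-empty", call. = FALSE)
  }
  ok <- !is.na(table$k_hat) & table$k_hat <= target
  if (!any(ok)) {
    return(NA_integer_)
  }
  as.integer(min(table$df[ok]))
}
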