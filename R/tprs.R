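#' Thin-plate spline radial basis function
#'
#' The 2-D second-order thin-plate radial function
#' \eqn{\eta(r) = r^2 \log r}, with the removable singularity at the origin
#' filled in as \eqn{\eta(0) = 0}. Any positive constant multiple yields the
#' same projection smoother (only column spans matter), so no normalising
#' constant is carried.
#'
#' @param r Nonnegative distance(s); vectors and matrices are handled
#'   elementwise.
#' @return `r^2 * log(r)`, with 0 at `r = 0`, same shape as `r`.
#' @export
tps_eta <- function(r) {
  if (any(r < 0)) {
    stop("distances must be nonnegative", call. = FALSE)
  }
  out <- r
  pos <- r > 0
  out[pos] <- r[pos]^2 * log(r[pos])
  out[!pos] <- 0
  out
}

#' Build a nested thin-plate regression spline basis
#'
#' Constructs the unpenalized TPRS design matrix
#' `H = [1, x, y, u_1, ..., u_{max_df - 2}]` for a point set: the radial
#' matrix `E[i, j] = tps_eta(||s_i - s_j||)` is eigendecomposed and the
#' `max_df - 2` eigenvectors with largest absolute eigenvalue are appended
#' to the polynomial null-space columns (intercept and linear coordinates).
#' Because `E` is indefinite, selection is by descending `|eigenvalue|`
#' (ties broken by original index). The basis is nested: the first `j + 1`
#' columns span the `j`-df basis for every `3 <= j <= max_df`, so one
#' construction serves a whole degrees-of-freedom sweep.
#'
#' A warning is emitted when the retained/discarded boundary falls inside a
#' near-degenerate eigenvalue pair (relative gap below `1e-10`): on highly
#' symmetric point layouts the retained span — and hence the smoother — is
#' implementation-dependent at exactly those df.
#'
#' @param points A [point_set()] whose points are not all collinear.
#' @param max_df Largest number of splines the basis will support;
#'   `3 <= max_df <= n - 1`.
#' @return An object of class `tprs_basis`: list with `design` (n x
#'   (max_df + 1) matrix `H`), `Q` (orthonormal basis of the columns of `H`,
#'   nested by construction), `eigenvalues` (the retained eigenvalues, by
#'   descending magnitude), `max_df`, `n`, and `unit`.
#' @export
build_tprs_basis <- function(points, max_df) {
  stopifnot(inherits(points, "point_set"))
  n <- n_points(points)
  if (!is.numeric(max_df) || length(max_df) != 1L || max_df != round(max_df)) {
    stop("`max_df` must be a single integer", call. = FALSE)
  }
  max_df <- as.integer(max_df)
  if (max_df < 3L) {
    stop("`max_df` must be at least 3", call. = FALSE)
  }
  if (max_df >= n) {
    stop(
      "`max_df` (", max_df, ") must be smaller than the number of points (",
      n, "): the number of splines may not exceed the number of coordinates",
      call. = FALSE
    )
  }
  d <- pairwise_distances(points)
  e <- tps_eta(d)
  eig <- eigen(e, symmetric = TRUE)
  ord <- order(-abs(eig$values), seq_along(eig$values))
  k <- max_df - 2L
  lam <- eig$values[ord]
  if (k < n) {
    gap_num <- abs(abs(lam[k]) - abs(lam[k + 1L]))
    if (abs(lam[k]) > 0 && gap_num / abs(lam[k]) < 1e-10) {
      warning(
        "retained/discarded eigenvalue boundary at max_df = ", max_df,
        " splits a near-degenerate eigenpair; the spline span at this df ",
        "is not uniquely determined on this (highly symmetric) point layout"
      )
    }
  }
  u <- eig$vectors[, ord[seq_len(k)], drop = FALSE]
  h <- cbind(1, points$coords[, 1], points$coords[, 2], u)
  colnames(h) <- basis_column_names(max_df)

  sv <- svd(h, nu = 0, nv = 0)$d
  if (min(sv) < 1e-10 * max(sv)) {
    qrp <- qr(h, tol = 1e-10)
    bad <- sort(qrp$pivot[-seq_len(qrp$rank)])
    stop(
      "spline design matrix is rank deficient (collinear or duplicated ",
      "geometry); dependent column(s): ",
      paste(colnames(h)[bad], collapse = ", "),
      call. = FALSE
    )
  }
  # Householder QR without column pivoting: the leading j columns of Q span
  # the leading j columns of H, which is what makes the nested df sweep
  # cheap. (LAPACK = TRUE would pivot and break the prefix property.)
  qrh <- qr(h)
  if (!identical(qrh$pivot, seq_len(ncol(h))) || qrh$rank < ncol(h)) {
    stop("unexpected pivoting/rank loss in QR of the spline design matrix",
      call. = FALSE
    )
  }
  q <- qr.Q(qrh)
  structure(
    list(
      design = h, Q = q, eigenvalues = lam[seq_len(k)],
      max_df = max_df, n = n, unit = points$unit
    ),
    class = "tprs_basis"
  )
}

basis_column_names <- function(max_df) {
  c("intercept", "x", "y", if (max_df > 2L) paste0("u", seq_len(max_df - 2L)))
}

#' @export
print.tprs_basis <- function(x, ...) {
  cat(
    "<tprs_basis> n = ", x$n, ", max_df = ", x$max_df,
    " (design ", x$n, " x ", x$max_df + 1L, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Projection smoothing matrix for a given degrees of freedom
#'
#' The smoother `S = H(H'H)^{-1}H'` is the orthogonal projection onto the
#' span of the first `df + 1` columns of the nested basis. It is computed
#' from an orthonormal basis (`S = QQ'` with `Q` from a Householder QR of
#' `H`), never via an explicit normal-equations inverse, so it is symmetric
#' and idempotent to machine precision even for large `df`. Column `S[, i]`
#' holds the smoothing weights location `i` assigns to every location — the
#' equivalent kernel whose sign changes define the effective bandwidth.
#'
#' @param basis A [build_tprs_basis()] result.
#' @param df Degrees of freedom (number of splines), `3 <= df <= max_df`.
#' @return An n x n matrix of class `smoother_matrix` with attribute `df`.
#'   It satisfies `trace(S) = df + 1` and has unit row sums (the intercept
#'   lies in its column space).
#' @export
smoothing_matrix <- function(basis, df) {
  stopifnot(inherits(basis, "tprs_basis"))
  if (!is.numeric(df) || length(df) != 1L || df != round(df)) {
    stop("`df` must be a single integer", call. = FALSE)
  }
  df <- as.integer(df)
  if (df < 3L || df > basis$max_df) {
    stop(
      "`df` must lie in [3, ", basis$max_df, "] for this basis (got ", df, ")",
      call. = FALSE
    )
  }
  s <- tcrossprod(basis$Q[, seq_len(df + 1L), drop = FALSE])
  structure(s, df = df, unit = basis$unit, class = c("smoother_matrix", "matrix"))
}

#' @export
print.smoother_matrix <- function(x, ...) {
  cat(
    "<smoother_matrix> ", nrow(x), " x ", ncol(x), ", df = ", attr(x, "df"),
    " (trace ", format(sum(diag(x))), ")\n",
    sep = ""
  )
  invisible(x)
}
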