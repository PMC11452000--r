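#' Create a planar point set
#'
#' A `point_set` is an ordered collection of 2-D coordinates in a consistent
#' planar projected coordinate system (e.g. kilometres on a Transverse
#' Mercator grid). All downstream quantities — distances, smoothing matrices,
#' effective bandwidths — inherit its length unit, so coordinates must already
#' be projected; longitude/latitude degrees are not valid input.
#'
#' Duplicate locations are permitted (they arise naturally from rounded
#' coordinates) and do not break the projection mathematics, but they are
#' reported with a message because they produce zero off-diagonal distances.
#'
#' @param x,y Numeric vectors of equal length with the planar coordinates.
#' @param unit Free-text length unit used in reports and plots (default
#'   `"km"`).
#' @return An object of class `point_set`: a list with elements `coords`
#'   (an n x 2 numeric matrix with columns `x`, `y`) and `unit`.
#' @examples
#' ps <- point_set(c(0, 3), c(0, 4))
#' n_points(ps)
#' @export
point_set <- function(x, y, unit = "km") {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (length(x) < 1L) {
    stop("a point set must contain at least one point", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    bad <- which(!is.finite(x) | !is.finite(y))
    stop(
      "non-finite coordinates at row(s): ",
      paste(utils::head(bad, 5L), collapse = ", "),
      if (length(bad) > 5L) ", ...",
      call. = FALSE
    )
  }
  coords <- cbind(x = x, y = y)
  ndup <- sum(duplicated(coords))
  if (ndup > 0L) {
    message(ndup, " duplicate point(s) in point set (zero off-diagonal distances)")
  }
  structure(list(coords = coords, unit = unit), class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat("<point_set> ", n_points(x), " points [", x$unit, "]\n", sep = "")
  cat(
    "  x range: [", format(min(x$coords[, 1])), ", ", format(max(x$coords[, 1])),
    "], y range: [", format(min(x$coords[, 2])), ", ", format(max(x$coords[, 2])),
    "]\n",
    sep = ""
  )
  invisible(x)
}

#' Number of points in a point set
#' @param points A [point_set()].
#' @return Integer point count.
#' @export
n_points <- function(points) {
  stopifnot(inherits(points, "point_set"))
  nrow(points$coords)
}

#' Generate a rectangular grid of points
#'
#' Lays out points at `(i * increment, j * increment)` for
#' `0 <= i <= floor(width / increment)` and
#' `0 <= j <= floor(height / increment)`, anchored at the origin, in
#' row-major order (x varies fastest). This mirrors how regular analysis
#' grids are laid over a study region before clipping to its boundary.
#'
#' @param width,height Extent of the grid in planar length units.
#' @param increment Spacing between neighbouring grid points, same units.
#' @param unit Length-unit label, passed to [point_set()].
#' @return A [point_set()] with
#'   `(floor(width/increment) + 1) * (floor(height/increment) + 1)` points.
#' @examples
#' make_rect_grid(100, 100, 50) # 3 x 3 = 9 points
#' @export
make_rect_grid <- function(width, height, increment, unit = "km") {
  for (nm in c("width", "height", "increment")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive number", call. = FALSE)
    }
  }
  xs <- seq(0L, floor(width / increment)) * increment
  ys <- seq(0L, floor(height / increment)) * increment
  point_set(rep(xs, times = length(ys)), rep(ys, each = length(xs)), unit = unit)
}

#' Read a point set from a delimited text file
#'
#' Reads coordinates from a CSV (or other delimited) file with a header row,
#' taking the x and y coordinates from the named columns. Rows with missing
#' or non-numeric coordinates are rejected with a row-indexed error rather
#' than silently dropped, since a truncated point set silently changes the
#' bandwidth.
#'
#' @param path Path to the file.
#' @param x_col,y_col Names of the columns holding the x and y coordinates.
#' @param unit Length-unit label for the resulting point set.
#' @param sep Field separator (default comma).
#' @return A [point_set()] in file row order.
#' @export
read_points_table <- function(path, x_col, y_col, unit = "km", sep = ",") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.table(
    path,
    header = TRUE, sep = sep, stringsAsFactors = FALSE,
    colClasses = "character", check.names = FALSE,
    comment.char = ""
  )
  if (nrow(df) == 0L) {
    stop("no data rows in ", path, call. = FALSE)
  }
  for (col in c(x_col, y_col)) {
    if (!col %in% names(df)) {
      stop(
        "column '", col, "' not found; available columns: ",
        paste(names(df), collapse = ", "),
        call. = FALSE
      )
    }
  }
  parse_num <- function(v, col) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) | trimws(v) == "")
    if (length(bad) > 0L) {
      stop(
        "non-numeric or missing value in column '", col, "' at data row(s): ",
        paste(utils::head(bad, 5L), collapse = ", "),
        if (length(bad) > 5L) ", ...",
        call. = FALSE
      )
    }
    out
  }
  point_set(parse_num(df[[x_col]], x_col), parse_num(df[[y_col]], y_col),
    unit = unit
  )
}

#' Subsample a point set without replacement
#'
#' Draws a uniform random subsample of `min(n_keep, n)` points, preserving
#' the original ordering of the retained points. When the set already has
#' `n_keep` points or fewer, all points are returned unchanged. Subsampling
#' is intended to be applied once, before basis construction, so that the
#' basis, smoother and bandwidth median all use the same subsample.
#'
#' The draw uses R's Mersenne-Twister generator seeded with `seed` in a
#' temporary RNG scope: the caller's `.Random.seed` is restored on exit, and
#' the same seed reproduces the same subsample across runs and platforms.
#'
#' @param points A [point_set()].
#' @param n_keep Number of points to keep (>= 1).
#' @param seed Integer seed; mandatory so every subsampled result is
#'   reproducible.
#' @return A [point_set()] with `min(n_keep, n)` points.
#' @export
subsample_points <- function(points, n_keep, seed) {
  stopifnot(inherits(points, "point_set"))
  if (!is.numeric(n_keep) || length(n_keep) != 1L || n_keep < 1) {
    stop("`n_keep` must be a single integer >= 1", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be supplied as a single integer", call. = FALSE)
  }
  n <- n_points(points)
  if (n_keep >= n) {
    return(points)
  }
  keep <- with_local_seed(seed, sort(sample.int(n, size = n_keep)))
  structure(
    list(coords = points$coords[keep, , drop = FALSE], unit = points$unit),
    class = "point_set"
  )
}

#' Pairwise Euclidean distance matrix
#'
#' @param points A [point_set()].
#' @return An n x n symmetric numeric matrix of Euclidean distances with a
#'   zero diagonal, in the point set's units (stored in the `"unit"`
#'   attribute).
#' @export
pairwise_distances <- function(points) {
  stopifnot(inherits(points, "point_set"))
  d <- as.matrix(stats::dist(points$coords, method = "euclidean"))
  dimnames(d) <- NULL
  attr(d, "unit") <- points$unit
  d
}

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}
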