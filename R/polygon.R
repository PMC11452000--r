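#' Create a polygon with optional holes
#'
#' A `bw_polygon` is one outer ring plus zero or more hole rings, used to
#' clip regular grids to a study region (a country boundary, a coastline, a
#' masked-out lake). Rings are ordered vertex lists in the same planar units
#' as the point sets they clip. Each ring must have at least three distinct
#' vertices and be simple (no self-intersections); violations are rejected
#' here, at construction, so downstream point-in-polygon tests can assume a
#' well-formed region.
#'
#' @param outer Two-column numeric matrix (or data frame) of outer-ring
#'   vertices. A closing vertex repeating the first is accepted and dropped.
#' @param holes Optional list of hole rings in the same format.
#' @return An object of class `bw_polygon`: list with `outer` (m x 2 matrix)
#'   and `holes` (list of matrices).
#' @export
bw_polygon <- function(outer, holes = list()) {
  outer <- check_ring(outer, "outer ring")
  holes <- lapply(seq_along(holes), function(i) {
    check_ring(holes[[i]], paste0("hole ring ", i))
  })
  structure(list(outer = outer, holes = holes), class = "bw_polygon")
}

#' @export
print.bw_polygon <- function(x, ...) {
  cat(
    "<bw_polygon> outer ring: ", nrow(x$outer), " vertices, ",
    length(x$holes), " hole(s), area ", format(polygon_area(x)), "\n",
    sep = ""
  )
  invisible(x)
}

# Validate one ring: coerce to matrix, drop a closing duplicate vertex,
# require >= 3 distinct vertices and simplicity.
check_ring <- function(ring, label) {
  ring <- as.matrix(ring)
  if (!is.numeric(ring) || ncol(ring) != 2L) {
    stop(label, " must be a two-column numeric matrix of vertices", call. = FALSE)
  }
  if (!all(is.finite(ring))) {
    stop(label, " contains non-finite vertices", call. = FALSE)
  }
  n <- nrow(ring)
  if (n >= 2L && all(ring[1L, ] == ring[n, ])) {
    ring <- ring[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (nrow(unique(ring)) < 3L) {
    stop(label, " needs at least 3 distinct vertices", call. = FALSE)
  }
  if (!ring_is_simple(ring)) {
    stop(label, " is self-intersecting; rings must be simple", call. = FALSE)
  }
  dimnames(ring) <- NULL
  ring
}

# Simplicity test: no two non-adjacent edges intersect, and adjacent edges
# meet only at their shared vertex. O(m^2), fine for boundary rings.
ring_is_simple <- function(ring) {
  m <- nrow(ring)
  a <- ring
  b <- ring[c(2:m, 1L), , drop = FALSE]
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      adjacent <- (j == i + 1L) || (i == 1L && j == m)
      if (segments_intersect(
        a[i, ], b[i, ], a[j, ], b[j, ],
        allow_shared_endpoint = adjacent
      )) {
        return(FALSE)
      }
    }
  }
  TRUE
}

cross2 <- function(o, p, q) {
  (p[1] - o[1]) * (q[2] - o[2]) - (p[2] - o[2]) * (q[1] - o[1])
}

# Proper or improper intersection of segments p1-p2 and q1-q2. When
# `allow_shared_endpoint`, touching at exactly one shared endpoint is not
# counted (consecutive ring edges always share one).
segments_intersect <- function(p1, p2, q1, q2, allow_shared_endpoint = FALSE) {
  d1 <- cross2(q1, q2, p1)
  d2 <- cross2(q1, q2, p2)
  d3 <- cross2(p1, p2, q1)
  d4 <- cross2(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  on_seg <- function(p, a, b) {
    cross2(a, b, p) == 0 &&
      min(a[1], b[1]) <= p[1] && p[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= p[2] && p[2] <= max(a[2], b[2])
  }
  touches <- list(
    if (on_seg(p1, q1, q2)) p1, if (on_seg(p2, q1, q2)) p2,
    if (on_seg(q1, p1, p2)) q1, if (on_seg(q2, p1, p2)) q2
  )
  touches <- touches[!vapply(touches, is.null, logical(1))]
  if (length(touches) == 0L) {
    return(FALSE)
  }
  if (allow_shared_endpoint) {
    shared <- identical(unname(p1), unname(q1)) || identical(unname(p1), unname(q2)) ||
      identical(unname(p2), unname(q1)) || identical(unname(p2), unname(q2))
    pts <- unique(do.call(rbind, lapply(touches, function(v) unname(as.numeric(v)))))
    return(!(shared && nrow(pts) == 1L))
  }
  TRUE
}

#' Polygon area (holes subtracted)
#'
#' Shoelace area of the outer ring minus the areas of the holes, in squared
#' input units.
#'
#' @param poly A [bw_polygon()].
#' @return Nonnegative numeric area.
#' @export
polygon_area <- function(poly) {
  stopifnot(inherits(poly, "bw_polygon"))
  shoelace <- function(r) {
    m <- nrow(r)
    nxt <- c(2:m, 1L)
    abs(sum(r[, 1] * r[nxt, 2] - r[nxt, 1] * r[, 2])) / 2
  }
  shoelace(poly$outer) - sum(vapply(poly$holes, shoelace, numeric(1)))
}

#' Read a polygon from GeoJSON
#'
#' Accepts a GeoJSON `Polygon` geometry, a `Feature` wrapping one, or a
#' `FeatureCollection` whose first Polygon feature is used. The first
#' coordinate ring is the outer boundary; any further rings are holes.
#' Coordinates must already be in a planar projected system — this reader
#' performs no reprojection.
#'
#' @param path Path to a GeoJSON file.
#' @return A [bw_polygon()].
#' @export
read_polygon_geojson <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geom <- switch(gj$type %||% "",
    Polygon = gj,
    Feature = gj$geometry,
    FeatureCollection = {
      polys <- Filter(
        function(f) identical(f$geometry$type, "Polygon"),
        gj$features
      )
      if (length(polys) == 0L) {
        stop("no Polygon feature in ", path, call. = FALSE)
      }
      polys[[1L]]$geometry
    },
    stop("unsupported GeoJSON type: ", gj$type %||% "<missing>", call. = FALSE)
  )
  if (!identical(geom$type, "Polygon")) {
    stop("geometry type must be Polygon, got: ", geom$type, call. = FALSE)
  }
  rings <- lapply(geom$coordinates, function(ring) {
    do.call(rbind, lapply(ring, function(v) as.numeric(v[1:2])))
  })
  bw_polygon(rings[[1L]], holes = rings[-1L])
}

#' Read a polygon from a plain vertex-list file
#'
#' Text format: one `x,y` pair per line (comma or whitespace separated);
#' blank lines separate rings. The first ring is the outer boundary, the
#' rest are holes. Lines starting with `#` are comments.
#'
#' @param path Path to the vertex-list file.
#' @return A [bw_polygon()].
#' @export
read_polygon_vertices <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!startsWith(lines, "#")]
  rings <- list()
  cur <- list()
  flush_ring <- function() {
    if (length(cur) > 0L) rings[[length(rings) + 1L]] <<- do.call(rbind, cur)
    cur <<- list()
  }
  for (ln in lines) {
    if (ln == "") {
      flush_ring()
    } else {
      v <- suppressWarnings(as.numeric(strsplit(ln, "[,[:space:]]+")[[1]]))
      v <- v[!is.na(v)]
      if (length(v) != 2L) {
        stop("cannot parse vertex line: '", ln, "'", call. = FALSE)
      }
      cur[[length(cur) + 1L]] <- v
    }
  }
  flush_ring()
  if (length(rings) == 0L) {
    stop("no vertices in ", path, call. = FALSE)
  }
  bw_polygon(rings[[1L]], holes = rings[-1L])
}

#' Built-in fixture polygons
#'
#' Deterministic test-bed shapes standing in for real study-region
#' boundaries: an L-shape (a square with one quadrant removed, area
#' `3/4 * scale^2`), a notched rectangle (non-convex, re-entrant notch), and
#' a convex blob (an ellipse sampled at 12 vertices). All fit inside
#' `[0, scale]^2`.
#'
#' @param kind One of `"L-shape"`, `"notched-rectangle"`, `"convex-blob"`.
#' @param scale Positive length setting the bounding size.
#' @return A [bw_polygon()].
#' @export
make_fixture_polygon <- function(kind = c("L-shape", "notched-rectangle", "convex-blob"),
                                 scale = 100) {
  kind <- match.arg(kind)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("`scale` must be a single positive number", call. = FALSE)
  }
  s <- scale
  verts <- switch(kind,
    "L-shape" = rbind(
      c(0, 0), c(s, 0), c(s, s / 2), c(s / 2, s / 2), c(s / 2, s), c(0, s)
    ),
    "notched-rectangle" = rbind(
      c(0, 0), c(s, 0), c(s, 0.6 * s), c(0.65 * s, 0.6 * s),
      c(0.65 * s, 0.3 * s), c(0.35 * s, 0.3 * s), c(0.35 * s, 0.6 * s),
      c(0, 0.6 * s)
    ),
    "convex-blob" = {
      th <- 2 * pi * (0:11) / 12
      cbind(0.5 * s + 0.48 * s * cos(th), 0.5 * s + 0.38 * s * sin(th))
    }
  )
  bw_polygon(verts)
}

# Classify points against one ring: +1 strictly inside, 0 on the boundary,
# -1 strictly outside. Winding-number rule (Sunday's algorithm) with an
# exact on-segment test, vectorised over points.
ring_position <- function(px, py, ring) {
  m <- nrow(ring)
  nxt <- c(2:m, 1L)
  ax <- ring[, 1]; ay <- ring[, 2]
  bx <- ring[nxt, 1]; by <- ring[nxt, 2]
  np <- length(px)
  wn <- integer(np)
  on_bd <- logical(np)
  for (e in seq_len(m)) {
    # cross product of edge vector with point offset; 0 means collinear
    cr <- (bx[e] - ax[e]) * (py - ay[e]) - (px - ax[e]) * (by[e] - ay[e])
    on_bd <- on_bd | (cr == 0 &
      px >= pmin(ax[e], bx[e]) & px <= pmax(ax[e], bx[e]) &
      py >= pmin(ay[e], by[e]) & py <= pmax(ay[e], by[e]))
    up <- ay[e] <= py & by[e] > py & cr > 0
    down <- ay[e] > py & by[e] <= py & cr < 0
    wn <- wn + up - down
  }
  out <- ifelse(on_bd, 0L, ifelse(wn != 0L, 1L, -1L))
  as.integer(out)
}

#' Clip a point set to a polygon
#'
#' Retains points that are strictly inside or on the boundary of the outer
#' ring and not strictly inside any hole, preserving the original point
#' order. Boundary points count as inside so that grid points falling
#' exactly on a boundary are kept deterministically rather than dropped by
#' floating-point jitter.
#'
#' @param points A [point_set()].
#' @param poly A [bw_polygon()] in the same planar units.
#' @return A [point_set()] with the retained points. An empty result raises
#'   a warning and returns a zero-point set (callers decide how to proceed).
#' @export
clip_to_polygon <- function(points, poly) {
  stopifnot(inherits(points, "point_set"), inherits(poly, "bw_polygon"))
  px <- points$coords[, 1]
  py <- points$coords[, 2]
  keep <- ring_position(px, py, poly$outer) >= 0L
  for (h in poly$holes) {
    keep <- keep & ring_position(px, py, h) <= 0L
  }
  if (!any(keep)) {
    warning("no points fall inside the polygon; returning an empty point set")
    return(structure(
      list(
        coords = matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))),
        unit = points$unit
      ),
      class = "point_set"
    ))
  }
  structure(
    list(coords = points$coords[keep, , drop = FALSE], unit = points$unit),
    class = "point_set"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
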