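#' Assemble a run configuration
#'
#' Bundles and validates everything one analysis run needs: exactly one
#' input source (a coordinate file, a rectangular grid specification, or a
#' named fixture polygon), the sweep settings, and output paths. The fixed
#' menus of the interactive tool (maximum splines of 10, 25, 100, 300 or
#' 500; subsamples of 1000, 2000 or 5000) are sensible presets here, but
#' any values are accepted.
#'
#' @param input Path to a delimited coordinate file, or `NULL`.
#' @param x_col,y_col Column names for `input`.
#' @param grid Numeric `c(width, height, increment)` for a rectangular
#'   grid, or `NULL`.
#' @param fixture Name of a fixture polygon ([make_fixture_polygon()]) to
#'   cover with a grid, or `NULL`.
#' @param fixture_scale,fixture_increment Size and grid spacing used with
#'   `fixture`.
#' @param polygon Optional path to a GeoJSON (`.json`/`.geojson`) or plain
#'   vertex-list polygon file; the points are clipped to it.
#' @param max_df Largest degrees of freedom in the sweep (>= 3).
#' @param method `"new"` or `"loess"`.
#' @param span Loess span; required iff `method = "loess"`.
#' @param n_eval Loess evaluation-grid size.
#' @param subsample_to Optional point cap before basis construction.
#' @param seed Integer seed; required whenever subsampling can trigger.
#' @param unit Length-unit label.
#' @param out_table,out_plot,out_points_plot,out_log Output paths (CSV,
#'   bandwidth-vs-df plot, coordinate plot, metadata log). `NULL` skips
#'   that artifact.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input = NULL, x_col = "x", y_col = "y",
                       grid = NULL,
                       fixture = NULL, fixture_scale = 100,
                       fixture_increment = 10,
                       polygon = NULL,
                       max_df, method = c("new", "loess"), span = NULL,
                       n_eval = 1000L,
                       subsample_to = NULL, seed = NULL, unit = "km",
                       out_table = NULL, out_plot = NULL,
                       out_points_plot = NULL, out_log = NULL) {
  method <- match.arg(method)
  sources <- c(input = !is.null(input), grid = !is.null(grid), fixture = !is.null(fixture))
  if (sum(sources) != 1L) {
    stop(
      "exactly one input source must be given (got ",
      if (sum(sources) == 0L) "none" else paste(names(sources)[sources], collapse = " + "),
      "): --input FILE, --grid W H INC, or --fixture NAME",
      call. = FALSE
    )
  }
  if (missing(max_df) || is.null(max_df)) {
    stop("`max_df` is required (smallest usable value is 3)", call. = FALSE)
  }
  if (!is.numeric(max_df) || length(max_df) != 1L || max_df < 3) {
    stop("`max_df` must be a single integer >= 3", call. = FALSE)
  }
  if (!is.null(grid) && (length(grid) != 3L || !is.numeric(grid))) {
    stop("`grid` must be numeric c(width, height, increment)", call. = FALSE)
  }
  if (method == "loess" && is.null(span)) {
    stop("`span` is required when method = \"loess\"", call. = FALSE)
  }
  if (method == "new" && !is.null(span)) {
    stop("`span` only applies to method = \"loess\"", call. = FALSE)
  }
  if (!is.null(subsample_to) && is.null(seed)) {
    stop("`seed` is required when `subsample_to` is set", call. = FALSE)
  }
  structure(
    list(
      input = input, x_col = x_col, y_col = y_col, grid = grid,
      fixture = fixture, fixture_scale = fixture_scale,
      fixture_increment = fixture_increment, polygon = polygon,
      max_df = as.integer(max_df), method = method, span = span,
      n_eval = n_eval, subsample_to = subsample_to, seed = seed,
      unit = unit, out_table = out_table, out_plot = out_plot,
      out_points_plot = out_points_plot, out_log = out_log
    ),
    class = "run_config"
  )
}

#' Lay a grid over a polygon and clip it
#'
#' Covers the polygon's bounding box with a regular grid at the given
#' spacing, anchored at the bounding box's lower-left corner, and keeps the
#' points inside the polygon. This is how analysis grids are built over
#' study-region boundaries; note that a different anchoring convention can
#' shift the grid by up to one row/column of points.
#'
#' @param poly A [bw_polygon()].
#' @param increment Grid spacing in the polygon's units.
#' @param unit Length-unit label for the resulting point set.
#' @return A clipped [point_set()].
#' @export
grid_over_polygon <- function(poly, increment, unit = "km") {
  stopifnot(inherits(poly, "bw_polygon"))
  all_xy <- do.call(rbind, c(list(poly$outer), poly$holes))
  x0 <- min(all_xy[, 1])
  y0 <- min(all_xy[, 2])
  base <- make_rect_grid(
    max(all_xy[, 1]) - x0, max(all_xy[, 2]) - y0, increment,
    unit = unit
  )
  shifted <- structure(
    list(coords = sweep(base$coords, 2L, c(-x0, -y0)), unit = unit),
    class = "point_set"
  )
  clip_to_polygon(shifted, poly)
}

load_config_points <- function(config) {
  points <- if (!is.null(config$input)) {
    read_points_table(config$input, config$x_col, config$y_col, unit = config$unit)
  } else if (!is.null(config$grid)) {
    make_rect_grid(config$grid[1], config$grid[2], config$grid[3], unit = config$unit)
  } else {
    grid_over_polygon(
      make_fixture_polygon(config$fixture, config$fixture_scale),
      config$fixture_increment,
      unit = config$unit
    )
  }
  if (!is.null(config$polygon)) {
    poly <- if (grepl("\\.(geojson|json)$", config$polygon, ignore.case = TRUE)) {
      read_polygon_geojson(config$polygon)
    } else {
      read_polygon_vertices(config$polygon)
    }
    points <- clip_to_polygon(points, poly)
  }
  points
}

#' Run a full effective-bandwidth analysis
#'
#' Loads the configured point set, sweeps the effective bandwidth over df,
#' and writes the requested artifacts: the sweep table as CSV, a
#' bandwidth-versus-df plot, a coordinate map, and a plain-text metadata
#' log recording the seed, point count, and package version — enough to
#' reproduce any (possibly subsampled) run. A df with undefined bandwidth
#' appears as an `NA` row; the run continues.
#'
#' @param config A [run_config()].
#' @return The [bandwidth_sweep()] table, invisibly.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  points <- load_config_points(config)
  table <- bandwidth_sweep(
    points,
    max_df = config$max_df, method = config$method, span = config$span,
    n_eval = config$n_eval, subsample_to = config$subsample_to,
    seed = config$seed
  )
  if (!is.null(config$out_table)) {
    write_sweep_csv(table, config$out_table)
  }
  if (!is.null(config$out_plot)) {
    ggplot2::ggsave(config$out_plot, plot_sweep(table),
      width = 6, height = 4, dpi = 150
    )
  }
  if (!is.null(config$out_points_plot)) {
    ggplot2::ggsave(config$out_points_plot, plot_points(points),
      width = 5, height = 5, dpi = 150
    )
  }
  if (!is.null(config$out_log)) {
    writeLines(
      c(
        paste0("effbw version: ", as.character(utils::packageVersion("effbw"))),
        paste0("n_points: ", table$n_points[1L]),
        paste0("max_df: ", config$max_df),
        paste0("method: ", config$method),
        paste0("span: ", if (is.null(config$span)) "NA" else config$span),
        paste0("subsample_to: ", if (is.null(config$subsample_to)) "NA" else config$subsample_to),
        paste0("seed: ", if (is.null(config$seed)) "NA" else config$seed),
        paste0("unit: ", config$unit)
      ),
      config$out_log
    )
  }
  invisible(table)
}

#' Plot effective bandwidth against degrees of freedom
#'
#' @param table A [bandwidth_sweep()] table, or several row-bound together
#'   (add a `dataset` column to get one line per dataset).
#' @return A ggplot object.
#' @export
plot_sweep <- function(table) {
  stopifnot(is.data.frame(table))
  unit <- attr(table, "unit") %||% ""
  p <- if ("dataset" %in% names(table)) {
    ggplot2::ggplot(table, ggplot2::aes(
      x = .data$df, y = .data$k_hat,
      colour = .data$dataset, group = .data$dataset
    ))
  } else {
    ggplot2::ggplot(table, ggplot2::aes(x = .data$df, y = .data$k_hat, group = 1))
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "degrees of freedom (number of splines)",
      y = paste0(
        "effective bandwidth",
        if (nzchar(unit)) paste0(" (", unit, ")")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot the coordinates of a point set
#'
#' @param points A [point_set()].
#' @return A ggplot object with equal-scaled axes.
#' @export
plot_points <- function(points) {
  stopifnot(inherits(points, "point_set"))
  df <- as.data.frame(points$coords)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = paste0("x (", points$unit, ")"),
      y = paste0("y (", points$unit, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Write / read a sweep table as CSV
#'
#' The CSV starts with a `# unit:` comment line followed by a header and
#' one row per df (`df, k_hat, method, span, n_points, n_undefined, seed`).
#' Numeric values are written with 17 significant digits so that
#' `read_sweep_csv()` reproduces the table bit-for-bit.
#'
#' @param table A [bandwidth_sweep()] table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  out$k_hat <- ifelse(is.na(out$k_hat), "NA", sprintf("%.17g", out$k_hat))
  out$span <- ifelse(is.na(out$span), "NA", sprintf("%.17g", out$span))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# unit: ", attr(table, "unit") %||% ""), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  first <- readLines(path, n = 1L)
  unit <- sub("^# unit: ?", "", first)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df$df <- as.integer(df$df)
  df$k_hat <- as.numeric(df$k_hat)
  df$span <- as.numeric(df$span)
  df$n_points <- as.integer(df$n_points)
  df$n_undefined <- as.integer(df$n_undefined)
  df$seed <- as.integer(df$seed)
  attr(df, "unit") <- unit
  class(df) <- c("sweep_table", "data.frame")
  df
}

#' Reproduce a country block of the demonstration tables
#'
#' Builds regular grids at the given increments over a country boundary,
#' clips them to the boundary, and sweeps the effective bandwidth,
#' reporting the point count and the bandwidth at the requested df — one
#' row per increment. The boundary must be supplied by the user (e.g. a
#' Natural Earth admin-0 polygon) as GeoJSON **already projected** to a
#' planar system in kilometres (Transverse Mercator or Lambert Conformal
#' Conic are the usual choices); no reprojection is built in, and
#' geographic (longitude/latitude) input is rejected.
#'
#' @param boundary_file Path to a projected GeoJSON Polygon boundary.
#' @param increments Grid spacings to evaluate, in the boundary's units.
#' @param dfs Degrees of freedom to report.
#' @param subsample_to Point cap applied before basis construction
#'   (default 5000).
#' @param seed Seed used when the cap triggers.
#' @param unit Length-unit label.
#' @return A data frame with columns `increment`, `n_points`,
#'   `n_points_used`, and one `k_hat_df<j>` column per requested df.
#' @export
replicate_country_table <- function(boundary_file, increments, dfs,
                                    subsample_to = 5000L, seed = 1L,
                                    unit = "km") {
  poly <- read_polygon_geojson(boundary_file)
  rng <- apply(poly$outer, 2L, range)
  if (all(abs(rng[, 1]) <= 360) && all(abs(rng[, 2]) <= 90)) {
    stop(
      "boundary coordinates look like longitude/latitude degrees; ",
      "project them to a planar system (Transverse Mercator or Lambert ",
      "Conformal Conic) before use — reprojection is not built in",
      call. = FALSE
    )
  }
  rows <- lapply(increments, function(inc) {
    pts <- grid_over_polygon(poly, inc, unit = unit)
    n_all <- n_points(pts)
    sweep_tab <- bandwidth_sweep(
      pts,
      max_df = max(dfs), method = "new",
      subsample_to = subsample_to, seed = seed
    )
    k <- vapply(
      dfs,
      function(j) sweep_tab$k_hat[match(j, sweep_tab$df)],
      numeric(1)
    )
    out <- data.frame(
      increment = inc, n_points = n_all,
      n_points_used = sweep_tab$n_points[1L]
    )
    out[paste0("k_hat_df", dfs)] <- as.list(k)
    out
  })
  do.call(rbind, rows)
}

#' @importFrom ggplot2 .data
NULL
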