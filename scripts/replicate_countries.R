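#!/usr/bin/env Rscript
# Optional country replication: effective bandwidths on regular grids over
# real country boundaries (England, India, Ireland, Northern Ireland, the
# contiguous United States).
#
# This script needs externally prepared boundary data that the package does
# not ship:
#   1. Download admin-0 country boundaries from Natural Earth
#      (https://www.naturalearthdata.com), e.g. ne_10m_admin_0_countries.
#   2. Project each country to a planar system in KILOMETRES — Transverse
#      Mercator for England, Ireland and Northern Ireland; Lambert
#      Conformal Conic for India and the contiguous United States — with
#      any standard GIS tool (ogr2ogr, QGIS, or Python pyproj/geopandas).
#      The package performs no reprojection itself.
#   3. Save each as GeoJSON (largest polygon, outer ring first) named
#      <country>.geojson in one directory.
#
# Usage:
#   Rscript scripts/replicate_countries.R <boundary-dir> [out.csv]

suppressMessages(library(effbw))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  message(
    "no boundary directory given — skipping country replication.\n",
    "Prepare projected GeoJSON boundaries first (see the header of this ",
    "script), then run:\n  Rscript scripts/replicate_countries.R <dir> [out.csv]"
  )
  quit(save = "no", status = 0L)
}
dir <- args[1L]
out_csv <- if (length(args) >= 2L) args[2L] else NULL

# grid increments (km) per country, as in the published demonstration
plan <- list(
  england = c(1, 10, 25),
  ireland = c(1, 10, 25),
  northern_ireland = c(1, 10),
  india = c(10, 25, 50),
  united_states = c(10, 25, 50)
)
report_dfs <- c(5, 10, 25, 100)

all_rows <- list()
for (country in names(plan)) {
  boundary <- file.path(dir, paste0(country, ".geojson"))
  if (!file.exists(boundary)) {
    message("skipping ", country, ": ", boundary, " not found")
    next
  }
  tab <- replicate_country_table(
    boundary,
    increments = plan[[country]],
    dfs = report_dfs, subsample_to = 5000L, seed = 1L
  )
  tab <- cbind(country = country, tab)
  print(tab, row.names = FALSE)
  all_rows[[country]] <- tab
}

if (length(all_rows) > 0L && !is.null(out_csv)) {
  utils::write.csv(do.call(rbind, all_rows), out_csv, row.names = FALSE)
  message("wrote ", out_csv)
}
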