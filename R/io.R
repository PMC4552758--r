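# Plain-text interchange: tree tables as CSV, tract polygons as GeoJSON
# (FeatureCollection of rectangles in a planar CRS), run manifests as JSON.

#' Write a tree inventory to CSV
#'
#' Columns: `tree_id, tract_id, x, y, height_m, crown_m, dbh_m, landuse,
#' region, jurisdiction, species_group`.
#'
#' @param trees Tree records.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trees_csv <- function(trees, path) {
  cols <- intersect(.tree_columns, names(trees))
  utils::write.csv(trees[cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a tree inventory from CSV
#'
#' @param path CSV written by [write_trees_csv()].
#' @return Data frame of tree records.
#' @export
read_trees_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(tract_id = "character"))
}

#' Write tracts as GeoJSON
#'
#' Emits a FeatureCollection of closed rectangular Polygons built from the
#' tract bounds, with the requested columns as feature properties.
#' Coordinates are planar (projected) units.
#'
#' @param tracts A `tract_set` (or any data frame with `tract_id` and
#'   `xmin`/`ymin`/`xmax`/`ymax`).
#' @param path Output file.
#' @param property_cols Columns to write as properties (default: everything
#'   except the bounds).
#' @return The path, invisibly.
#' @export
write_tracts_geojson <- function(tracts, path,
                                 property_cols = setdiff(names(tracts),
                                                         c("xmin", "ymin",
                                                           "xmax", "ymax"))) {
  features <- lapply(seq_len(nrow(tracts)), function(i) {
    ring <- matrix(c(tracts$xmin[i], tracts$ymin[i],
                     tracts$xmax[i], tracts$ymin[i],
                     tracts$xmax[i], tracts$ymax[i],
                     tracts$xmin[i], tracts$ymax[i],
                     tracts$xmin[i], tracts$ymin[i]),
                   ncol = 2, byrow = TRUE)
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = as.list(tracts[i, property_cols, drop = FALSE]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read tracts from GeoJSON
#'
#' Reconstructs the tract table (bounds from the polygon's bounding box plus
#' all feature properties) from a file written by [write_tracts_geojson()].
#'
#' @param path GeoJSON file.
#' @return Data frame of class `tract_set`.
#' @export
read_tracts_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  stopifnot(identical(fc$type, "FeatureCollection"))
  rows <- lapply(fc$features, function(f) {
    coords <- f$geometry$coordinates[[1]]
    xs <- vapply(coords, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(coords, function(p) as.numeric(p[[2]]), numeric(1))
    props <- lapply(f$properties, function(p) if (is.null(p)) NA else p)
    c(list(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys)),
      props)
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  front <- intersect(c("tract_id", "xmin", "ymin", "xmax", "ymax"),
                     names(out))
  out <- out[c(front, setdiff(names(out), front))]
  class(out) <- c("tract_set", class(out))
  out
}

#' Write a run manifest
#'
#' Records the seed, configuration and stage sizes of a pipeline run so the
#' run can be reproduced exactly.
#'
#' @param manifest Named list.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_run_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
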