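# Plain-text interchange: detection CSVs, occurrence CSVs, and grid GeoJSON.
# The GeoJSON FeatureCollection carries the grid's construction metadata in
# its top-level "properties" so a written grid reads back exactly.

#' Read point detection records from CSV
#'
#' Expected header: \code{lon,lat,year,detected[,source]}.
#' @param path CSV path.
#' @return Data frame of detection records.
#' @export
read_detections_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lon", "lat", "year", "detected")
  if (!all(need %in% names(df)))
    stop("detections CSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) > 0 && !all(df$detected %in% c(0, 1)))
    stop("detected must be 0 or 1")
  df
}

#' Write an occurrence table to CSV (hex_id,year,presence)
#' @param occ An \code{\link{occurrence_table}}.
#' @param path Output path.
#' @export
write_occurrence_csv <- function(occ, path) {
  utils::write.csv(as.data.frame(occ)[c("hex_id", "year", "presence")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an occurrence table from CSV
#' @param path CSV with columns hex_id, year, presence.
#' @param first_year Optional explicit first covered year.
#' @return An \code{\link{occurrence_table}}.
#' @export
read_occurrence_csv <- function(path, first_year = NULL) {
  occurrence_table(utils::read.csv(path), first_year = first_year)
}

#' Write a hexagonal grid to GeoJSON
#'
#' One Polygon feature per cell with \code{hex_id}, lattice \code{col} and
#' \code{row} properties; grid metadata in the collection's
#' \code{properties}.
#'
#' @param grid A \code{hex_grid}.
#' @param path Output path.
#' @export
write_grid_geojson <- function(grid, path) {
  stopifnot(inherits(grid, "hex_grid"))
  polys <- hex_polygons(grid)
  features <- lapply(seq_along(polys), function(i) {
    ring <- polys[[i]]
    list(type = "Feature",
         properties = list(hex_id = grid$cells$hex_id[i],
                           col = grid$cells$col[i], row = grid$cells$row[i],
                           centroid_lon = grid$cells$lon[i],
                           centroid_lat = grid$cells$lat[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(j) c(ring[j, 1], ring[j, 2])))))
  })
  fc <- list(type = "FeatureCollection",
             properties = list(side_m = grid$side_m,
                               cell_area_km2 = grid$cell_area_km2,
                               lon0 = grid$lon0, lat0 = grid$lat0,
                               bbox = grid$bbox),
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a hexagonal grid written by \code{\link{write_grid_geojson}}
#' @param path GeoJSON path.
#' @return A \code{hex_grid}.
#' @export
read_grid_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  pr <- fc$properties
  if (is.null(pr$side_m))
    stop("GeoJSON lacks hexinvade grid metadata; rebuild with build_hex_grid")
  cells <- do.call(rbind, lapply(fc$features, function(f) {
    p <- f$properties
    data.frame(hex_id = p$hex_id, col = p$col, row = p$row,
               lon = p$centroid_lon, lat = p$centroid_lat)
  }))
  s <- pr$side_m
  dx <- 1.5 * s; dy <- sqrt(3) * s
  cells$x <- cells$col * dx
  cells$y <- cells$row * dy + ifelse(cells$col %% 2 != 0, dy / 2, 0)
  cells <- cells[order(cells$hex_id),
                 c("hex_id", "col", "row", "x", "y", "lon", "lat")]
  rownames(cells) <- NULL
  structure(list(cells = cells, side_m = s,
                 cell_area_km2 = pr$cell_area_km2,
                 lon0 = pr$lon0, lat0 = pr$lat0,
                 bbox = unlist(pr$bbox)),
            class = "hex_grid")
}
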