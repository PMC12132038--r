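# Hexagonal tessellation of a geographic bounding box, point aggregation and
# geodetic distances. The grid is laid out in a local Lambert azimuthal
# equal-area projection centred on the bbox so that every cell has the target
# area; centroids and polygons are reported back in WGS84.

EARTH_RADIUS_M <- 6371008.8  # mean Earth radius (IUGG R1)

#' Great-circle distance between WGS84 points
#'
#' Haversine distance on a sphere of radius 6,371,008.8 m. Vectorised over
#' rows; inputs are recycled to a common length.
#'
#' @param lon1,lat1 Coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 Coordinates of the second point(s), decimal degrees.
#' @return Distance(s) in metres.
#' @examples
#' geodetic_distance(0, 0, 0, 1)  # one degree of latitude, ~111.2 km
#' @export
geodetic_distance <- function(lon1, lat1, lon2, lat2) {
  stopifnot(all(abs(lat1) <= 90), all(abs(lat2) <= 90),
            all(abs(lon1) <= 360), all(abs(lon2) <= 360))
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  h <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  # clamp rounding overshoot so the central angle stays in [0, pi]
  h <- pmin(pmax(h, 0), 1)
  2 * EARTH_RADIUS_M * asin(sqrt(h))
}

# Spherical Lambert azimuthal equal-area projection, forward and inverse,
# centred on (lon0, lat0). Used only to lay out the lattice; distances between
# centroids are always geodetic.
.laea_forward <- function(lon, lat, lon0, lat0) {
  lam <- (lon - lon0) * pi / 180
  phi <- lat * pi / 180
  phi0 <- lat0 * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam)
  kp <- sqrt(2 / denom)
  list(x = EARTH_RADIUS_M * kp * cos(phi) * sin(lam),
       y = EARTH_RADIUS_M * kp * (cos(phi0) * sin(phi) -
                                    sin(phi0) * cos(phi) * cos(lam)))
}

.laea_inverse <- function(x, y, lon0, lat0) {
  phi0 <- lat0 * pi / 180
  rho <- sqrt(x^2 + y^2)
  cc <- 2 * asin(pmin(rho / (2 * EARTH_RADIUS_M), 1))
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cos(cc) * sin(phi0) + y * sin(cc) * cos(phi0) / rho))
  lam <- ifelse(rho < 1e-12, 0,
                atan2(x * sin(cc),
                      rho * cos(phi0) * cos(cc) - y * sin(phi0) * sin(cc)))
  list(lon = lon0 + lam * 180 / pi, lat = phi * 180 / pi)
}

#' Build an equal-area hexagonal grid over a bounding box
#'
#' Tessellates the box with flat-top hexagons of the requested cell area laid
#' out in a local Lambert azimuthal equal-area projection, so every point of
#' the box is covered by exactly one cell. Cell ids are assigned row-major
#' (south to north, west to east within a row).
#'
#' @param bbox Numeric vector \code{c(lon_min, lat_min, lon_max, lat_max)} in
#'   decimal degrees WGS84.
#' @param cell_area_km2 Target cell area in square kilometres (default 1).
#' @return An object of class \code{hex_grid}: a list with a \code{cells}
#'   data frame (\code{hex_id}, lattice \code{col}/\code{row}, projected
#'   \code{x}/\code{y} in metres, centroid \code{lon}/\code{lat}), the hexagon
#'   side length \code{side_m}, the projection centre and the input bbox.
#' @export
build_hex_grid <- function(bbox, cell_area_km2 = 1) {
  stopifnot(length(bbox) == 4, is.numeric(bbox), cell_area_km2 > 0)
  lon_min <- bbox[1]; lat_min <- bbox[2]; lon_max <- bbox[3]; lat_max <- bbox[4]
  if (!(lon_max > lon_min) || !(lat_max > lat_min))
    stop("bbox is degenerate: need lon_max > lon_min and lat_max > lat_min")
  if (lon_min < -180 || lon_max > 180)
    stop("unsupported region: bbox crosses the antimeridian")
  lon0 <- (lon_min + lon_max) / 2
  lat0 <- (lat_min + lat_max) / 2

  s <- sqrt(2 * cell_area_km2 * 1e6 / (3 * sqrt(3)))  # side length, metres

  # projected extent of the bbox (corners + edge midpoints; ample for the
  # modest boxes this supports)
  lons <- c(lon_min, lon0, lon_max)
  lats <- c(lat_min, lat0, lat_max)
  pts <- expand.grid(lon = lons, lat = lats)
  xy <- .laea_forward(pts$lon, pts$lat, lon0, lat0)
  # one full cell of margin guarantees coverage of the box edges
  x_rng <- range(xy$x) + c(-2 * s, 2 * s)
  y_rng <- range(xy$y) + c(-2 * s, 2 * s)

  dx <- 1.5 * s           # column pitch (flat-top)
  dy <- sqrt(3) * s       # row pitch
  cols <- seq(floor(x_rng[1] / dx), ceiling(x_rng[2] / dx))
  rows <- seq(floor(y_rng[1] / dy) - 1, ceiling(y_rng[2] / dy) + 1)
  lattice <- expand.grid(col = cols, row = rows)
  lattice$x <- lattice$col * dx
  lattice$y <- lattice$row * dy + ifelse(lattice$col %% 2 != 0, dy / 2, 0)

  # coarse pre-filter on the projected extent (padded against curvature of
  # the projected bbox edges), then exact hexagon/bbox intersection in lon/lat
  xpad <- s; ypad <- dy / 2
  pad <- s / 2
  keep <- lattice[lattice$x + xpad >= min(xy$x) - pad &
                  lattice$x - xpad <= max(xy$x) + pad &
                  lattice$y + ypad >= min(xy$y) - pad &
                  lattice$y - ypad <= max(xy$y) + pad, , drop = FALSE]
  if (nrow(keep) == 0) stop("internal error: empty lattice")
  hits <- vapply(seq_len(nrow(keep)), function(i) {
    ring <- .hex_ring(keep$x[i], keep$y[i], s)
    ll <- .laea_inverse(ring[, 1], ring[, 2], lon0, lat0)
    .poly_rect_intersect(ll$lon[1:6], ll$lat[1:6],
                         lon_min, lat_min, lon_max, lat_max)
  }, logical(1))
  keep <- keep[hits, , drop = FALSE]
  if (nrow(keep) == 0) stop("internal error: no cell intersects the bbox")
  # row-major id order: by row, then column
  keep <- keep[order(keep$row, keep$col), , drop = FALSE]
  keep$hex_id <- seq_len(nrow(keep))
  ll <- .laea_inverse(keep$x, keep$y, lon0, lat0)
  cells <- data.frame(hex_id = keep$hex_id, col = keep$col, row = keep$row,
                      x = keep$x, y = keep$y, lon = ll$lon, lat = ll$lat)
  structure(list(cells = cells, side_m = s, cell_area_km2 = cell_area_km2,
                 lon0 = lon0, lat0 = lat0, bbox = bbox),
            class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat("Hexagonal grid:", nrow(x$cells), "cells of", x$cell_area_km2,
      "km2 (side", round(x$side_m), "m)\n")
  cat("bbox: [", paste(signif(x$bbox, 6), collapse = ", "), "]\n")
  invisible(x)
}

# Convex polygon vs axis-aligned rectangle intersection (separating axis
# theorem). Vertices in the same planar coordinate system as the rectangle;
# boundary contact counts as intersection.
.poly_rect_intersect <- function(px, py, xmin, ymin, xmax, ymax) {
  eps <- 1e-12
  # rectangle axes
  if (max(px) < xmin - eps || min(px) > xmax + eps ||
      max(py) < ymin - eps || min(py) > ymax + eps) return(FALSE)
  rx <- c(xmin, xmax, xmax, xmin)
  ry <- c(ymin, ymin, ymax, ymax)
  n <- length(px)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- -(py[j] - py[i]); ay <- px[j] - px[i]  # edge normal
    pp <- ax * px + ay * py
    rp <- ax * rx + ay * ry
    if (max(rp) < min(pp) - eps || min(rp) > max(pp) + eps) return(FALSE)
  }
  TRUE
}

# Vertices of the flat-top hexagon around a projected centre, closed ring.
.hex_ring <- function(x, y, s) {
  ang <- seq(0, 2 * pi, length.out = 7)
  cbind(x + s * cos(ang), y + s * sin(ang))
}

#' Hexagon polygons in WGS84
#'
#' @param grid A \code{hex_grid}.
#' @param hex_ids Cells to return (default all).
#' @return Named list of closed 7 x 2 matrices (lon, lat), one per cell.
#' @export
hex_polygons <- function(grid, hex_ids = grid$cells$hex_id) {
  stopifnot(inherits(grid, "hex_grid"))
  cells <- grid$cells[match(hex_ids, grid$cells$hex_id), , drop = FALSE]
  if (anyNA(cells$hex_id)) stop("unknown hex_id requested")
  out <- lapply(seq_len(nrow(cells)), function(i) {
    ring <- .hex_ring(cells$x[i], cells$y[i], grid$side_m)
    ll <- .laea_inverse(ring[, 1], ring[, 2], grid$lon0, grid$lat0)
    cbind(lon = ll$lon, lat = ll$lat)
  })
  names(out) <- cells$hex_id
  out
}

#' Neighbour lists of a hexagonal grid
#'
#' Interior cells have exactly six neighbours (lattice distance one).
#'
#' @param grid A \code{hex_grid}.
#' @return Named list mapping each hex_id to the integer ids of its neighbours.
#' @export
hex_neighbors <- function(grid) {
  stopifnot(inherits(grid, "hex_grid"))
  cells <- grid$cells
  key <- paste(cells$col, cells$row)
  idx <- stats::setNames(cells$hex_id, key)
  # flat-top, odd columns shifted up by half a row pitch
  offs_even <- cbind(c(0, 0, -1, 1, -1, 1), c(1, -1, 0, 0, -1, -1))
  offs_odd  <- cbind(c(0, 0, -1, 1, -1, 1), c(1, -1, 0, 0, 1, 1))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    offs <- if (cells$col[i] %% 2 != 0) offs_odd else offs_even
    k <- paste(cells$col[i] + offs[, 1], cells$row[i] + offs[, 2])
    nb <- idx[k]
    out[[i]] <- sort(unname(nb[!is.na(nb)]))
  }
  names(out) <- cells$hex_id
  out
}

# Point-in-flat-top-hexagon test in projected coordinates, boundary-inclusive.
.in_hex <- function(px, py, cx, cy, s, tol = 1e-9) {
  dxp <- abs(px - cx); dyp <- abs(py - cy)
  dyp <= sqrt(3) / 2 * s + tol & sqrt(3) * dxp + dyp <= sqrt(3) * s + tol
}

#' Assign points to hexagons
#'
#' Boundary points (shared edges or vertices) resolve to the lowest hex_id.
#'
#' @param grid A \code{hex_grid}.
#' @param lon,lat Point coordinates, decimal degrees WGS84.
#' @return Integer vector of hex_ids, \code{NA} for points outside the grid.
#' @export
hex_assign <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "hex_grid"), length(lon) == length(lat))
  if (length(lon) == 0) return(integer(0))
  xy <- .laea_forward(lon, lat, grid$lon0, grid$lat0)
  cells <- grid$cells
  s <- grid$side_m
  dx <- 1.5 * s; dy <- sqrt(3) * s
  key <- paste(cells$col, cells$row)
  idx <- stats::setNames(seq_len(nrow(cells)), key)
  out <- rep(NA_integer_, length(lon))
  for (i in seq_along(lon)) {
    c0 <- round(xy$x[i] / dx)
    rows <- lapply(c0 + (-1:1), function(cc) {
      y0 <- xy$y[i] - ifelse(cc %% 2 != 0, dy / 2, 0)
      r0 <- round(y0 / dy)
      data.frame(col = cc, row = r0 + (-1:1))
    })
    cand <- do.call(rbind, rows)
    j <- idx[paste(cand$col, cand$row)]
    j <- sort(j[!is.na(j)])  # ascending hex_id: ties resolve low
    for (jj in j) {
      if (.in_hex(xy$x[i], xy$y[i], cells$x[jj], cells$y[jj], s)) {
        out[i] <- cells$hex_id[jj]
        break
      }
    }
  }
  out
}

#' Aggregate point detection records into a hexagon-year occurrence table
#'
#' A hexagon-year is coded presence 1 if any record in it has
#' \code{detected = 1}, presence 0 if records exist and none detected.
#' Hexagon-years with no records do not appear (never-surveyed cells are not
#' absences). Points falling outside the grid are dropped with a message and
#' counted in the \code{n_rejected} attribute.
#'
#' @param points Data frame with columns \code{lon}, \code{lat}, \code{year},
#'   \code{detected} (0/1); a \code{source} column is optional.
#' @param grid A \code{hex_grid}.
#' @return An \code{occurrence_table}: data frame with columns \code{hex_id},
#'   \code{year}, \code{presence}.
#' @export
aggregate_detections <- function(points, grid) {
  stopifnot(is.data.frame(points),
            all(c("lon", "lat", "year", "detected") %in% names(points)))
  if (nrow(points) > 0 && !all(points$detected %in% c(0, 1)))
    stop("detected must be 0 or 1")
  if (nrow(points) == 0) {
    return(occurrence_table(data.frame(hex_id = integer(0), year = integer(0),
                                       presence = integer(0))))
  }
  hid <- hex_assign(grid, points$lon, points$lat)
  n_rej <- sum(is.na(hid))
  if (n_rej > 0)
    message(n_rej, " point(s) outside the grid were rejected")
  ok <- !is.na(hid)
  if (!any(ok)) {
    tab <- data.frame(hex_id = integer(0), year = integer(0),
                      presence = integer(0))
  } else {
    agg <- stats::aggregate(points$detected[ok],
                            by = list(hex_id = hid[ok], year = points$year[ok]),
                            FUN = max)
    tab <- data.frame(hex_id = agg$hex_id, year = agg$year,
                      presence = as.integer(agg$x))
    tab <- tab[order(tab$year, tab$hex_id), ]
    rownames(tab) <- NULL
  }
  out <- occurrence_table(tab)
  attr(out, "n_rejected") <- n_rej
  out
}

#' Construct an occurrence table
#'
#' Binary presence/absence per surveyed hexagon-year. At most one row per
#' (hexagon, year); rows exist only for surveyed hexagon-years.
#'
#' @param df Data frame with columns \code{hex_id}, \code{year},
#'   \code{presence} (0/1).
#' @param first_year Optional first year the table covers (defaults to the
#'   earliest year present); used to validate lag availability downstream.
#' @return The data frame with class \code{occurrence_table}.
#' @export
occurrence_table <- function(df, first_year = NULL) {
  stopifnot(is.data.frame(df),
            all(c("hex_id", "year", "presence") %in% names(df)))
  if (nrow(df) > 0) {
    if (!all(df$presence %in% c(0, 1))) stop("presence must be 0 or 1")
    if (anyDuplicated(df[c("hex_id", "year")]) > 0)
      stop("duplicate (hex_id, year) rows")
  }
  if (is.null(first_year))
    first_year <- if (nrow(df) > 0) min(df$year) else NA_integer_
  structure(df, class = c("occurrence_table", "data.frame"),
            first_year = first_year)
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat("Occurrence table:", nrow(x), "surveyed hexagon-years, ",
      sum(x$presence), "presences")
  if (nrow(x) > 0) cat(", years ", min(x$year), "-", max(x$year), sep = "")
  cat("\n")
  invisible(x)
}

#' Default landcover class vocabulary
#'
#' The two classes coded 1 by \code{\link{encode_landcover}} plus the other
#' class labels accepted (coded 0).
#' @return Character vector of known class labels.
#' @export
landcover_vocabulary <- function() {
  c("Urban and built-up",
    "mixed needle-leaved cold deciduous forest, medium density",
    "Water", "Snow and ice", "Rock and rubble", "Exposed land",
    "Shrub tall", "Shrub low", "Wetland treed", "Wetland shrub",
    "Wetland herb", "Herb", "Coniferous dense", "Coniferous open",
    "Coniferous sparse", "Broadleaf dense", "Broadleaf open",
    "Mixedwood dense", "Mixedwood open", "Mixedwood sparse",
    "Agriculture cropland", "Agriculture pasture", "Grassland",
    "Lichen-heath", "Burns and regenerating")
}

#' Dichotomise a majority landcover class
#'
#' Codes 1 for "Urban and built-up" and "mixed needle-leaved cold deciduous
#' forest, medium density", 0 for every other class in the vocabulary.
#'
#' @param majority_class Character vector of majority class labels.
#' @param vocabulary Accepted class labels.
#' @return Integer vector of 0/1 flags.
#' @export
encode_landcover <- function(majority_class,
                             vocabulary = landcover_vocabulary()) {
  unknown <- setdiff(unique(majority_class), vocabulary)
  if (length(unknown) > 0)
    stop("unknown landcover label(s): ", paste(unknown, collapse = ", "))
  positive <- c("Urban and built-up",
                "mixed needle-leaved cold deciduous forest, medium density")
  as.integer(majority_class %in% positive)
}
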