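# Lagged infestation-pressure ("force of invasion") predictor: for a target
# hexagon i in year t, the sum over hexagons k infested in the lag years
# (t-1, t-2 by default) within the cutoff distance of a negative-exponential
# kernel of the standardised centroid distance. A cell infested in both lag
# years contributes one term per lag year; the target's own lagged infestation
# contributes exp(0) = 1 per lag year.

#' Configuration of the infestation-pressure kernel
#'
#' @param a Positive shape parameter of the dispersal kernel. Low values
#'   concentrate colonisation risk near sources; high values flatten the
#'   kernel towards distant sources.
#' @param cutoff_m Neighbourhood cutoff in metres (default 300 km), also the
#'   denominator of the 0-1 distance standardisation.
#' @param lags Positive integer lags defining the source years (default 1, 2,
#'   reflecting a one- or two-year insect life cycle).
#' @param form Kernel form: \code{"power"} for exp(-(d/cutoff)^a) (default) or
#'   \code{"scale"} for exp(-(d/cutoff)/a).
#' @return A list of class \code{pressure_config}.
#' @export
pressure_config <- function(a = 1, cutoff_m = 300000, lags = c(1, 2),
                            form = c("power", "scale")) {
  form <- match.arg(form)
  stopifnot(is.numeric(a), length(a) == 1, a > 0, cutoff_m > 0,
            length(lags) >= 1, all(lags >= 1), all(lags == round(lags)))
  structure(list(a = a, cutoff_m = cutoff_m, lags = as.integer(sort(lags)),
                 form = form),
            class = "pressure_config")
}

#' Standardise a distance by the neighbourhood cutoff
#'
#' @param d Distance(s) in metres, within \code{[0, cutoff]}.
#' @param cutoff_m Cutoff in metres.
#' @return d / cutoff, in \code{[0, 1]}.
#' @export
standardize_distance <- function(d, cutoff_m = 300000) {
  stopifnot(cutoff_m > 0)
  if (any(d < 0)) stop("negative distance")
  if (any(d > cutoff_m * (1 + 1e-12)))
    stop("distance exceeds the neighbourhood cutoff; pre-filter sources")
  pmin(d / cutoff_m, 1)
}

# Kernel value for standardised distances in [0, 1].
.kernel <- function(d_std, a, form) {
  switch(form,
         power = exp(-d_std^a),
         scale = exp(-d_std / a))
}

# Source table for year t: one row per (infested hexagon, lag year) with
# centroid coordinates. A hexagon infested in both lag years appears twice.
.pressure_sources <- function(year, occ, grid, cfg) {
  src <- do.call(rbind, lapply(cfg$lags, function(l) {
    rows <- occ[occ$year == year - l & occ$presence == 1, , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    data.frame(hex_id = rows$hex_id, lag = l)
  }))
  if (is.null(src)) return(NULL)
  m <- match(src$hex_id, grid$cells$hex_id)
  if (anyNA(m)) stop("occurrence table references hexagons absent from grid")
  src$lon <- grid$cells$lon[m]
  src$lat <- grid$cells$lat[m]
  src
}

.check_history <- function(year, occ, cfg) {
  fy <- attr(occ, "first_year")
  if (is.null(fy) || is.na(fy)) fy <- if (nrow(occ) > 0) min(occ$year) else NA
  if (is.na(fy) || any(year - max(cfg$lags) < fy))
    stop("insufficient history: lag years precede the first year of the ",
         "occurrence table")
}

#' Infestation pressure on one hexagon-year
#'
#' @param target A hex_id present in \code{grid}.
#' @param year Calendar year of the target.
#' @param occ An \code{\link{occurrence_table}} covering the lag years.
#' @param grid The \code{\link{build_hex_grid}} grid.
#' @param cfg A \code{\link{pressure_config}}.
#' @return Non-negative scalar: the summed kernel contribution of all lagged
#'   infested hexagons within the cutoff. Infestations in the current year
#'   itself do not contribute.
#' @export
infestation_pressure <- function(target, year, occ, grid,
                                 cfg = pressure_config()) {
  stopifnot(inherits(grid, "hex_grid"), inherits(cfg, "pressure_config"))
  if (!target %in% grid$cells$hex_id) stop("target hexagon not in grid")
  .check_history(year, occ, cfg)
  src <- .pressure_sources(year, occ, grid, cfg)
  if (is.null(src)) return(0)
  tc <- grid$cells[grid$cells$hex_id == target, ]
  d <- geodetic_distance(tc$lon, tc$lat, src$lon, src$lat)
  d <- d[d <= cfg$cutoff_m]
  if (length(d) == 0) return(0)
  sum(.kernel(d / cfg$cutoff_m, cfg$a, cfg$form))
}

#' Infestation-pressure surface over a grid and year range
#'
#' Computes \code{\link{infestation_pressure}} for every (hexagon, year)
#' requested. Sources are pre-filtered by a latitude/longitude window around
#' each year's infested set, so cost scales with the number of cells within
#' the cutoff rather than all pairs.
#'
#' @param occ An \code{\link{occurrence_table}} covering
#'   \code{min(years) - max(lags)} onward.
#' @param grid A \code{hex_grid}.
#' @param cfg A \code{\link{pressure_config}}.
#' @param years Integer vector of target years.
#' @param hex_ids Target cells (default: every cell of the grid).
#' @return Data frame of class \code{pressure_table} with columns
#'   \code{hex_id}, \code{year}, \code{spatial}.
#' @export
pressure_surface <- function(occ, grid, cfg = pressure_config(), years,
                             hex_ids = grid$cells$hex_id) {
  stopifnot(inherits(grid, "hex_grid"), inherits(cfg, "pressure_config"))
  .check_history(years, occ, cfg)
  cells <- grid$cells[match(hex_ids, grid$cells$hex_id), , drop = FALSE]
  if (anyNA(cells$hex_id)) stop("unknown hex_id among targets")
  out <- vector("list", length(years))
  for (yi in seq_along(years)) {
    t <- years[yi]
    spatial <- numeric(nrow(cells))
    src <- .pressure_sources(t, occ, grid, cfg)
    if (!is.null(src)) {
      # coarse geographic window: cutoff in degrees, padded
      dlat <- cfg$cutoff_m / 111000 * 1.05
      dlon <- dlat / max(cos(max(abs(cells$lat)) * pi / 180), 0.05)
      near <- which(cells$lat >= min(src$lat) - dlat &
                    cells$lat <= max(src$lat) + dlat &
                    cells$lon >= min(src$lon) - dlon &
                    cells$lon <= max(src$lon) + dlon)
      if (length(near) > 0) {
        # chunk targets to bound the distance-matrix size
        chunk <- max(1L, floor(5e6 / nrow(src)))
        for (start in seq(1L, length(near), by = chunk)) {
          ii <- near[start:min(start + chunk - 1L, length(near))]
          d <- outer(seq_along(ii), seq_len(nrow(src)), function(i, k) {
            geodetic_distance(cells$lon[ii[i]], cells$lat[ii[i]],
                              src$lon[k], src$lat[k])
          })
          kv <- .kernel(pmin(d / cfg$cutoff_m, 1), cfg$a, cfg$form)
          kv[d > cfg$cutoff_m] <- 0
          spatial[ii] <- rowSums(kv)
        }
      }
    }
    out[[yi]] <- data.frame(hex_id = cells$hex_id, year = t, spatial = spatial)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pressure_table", "data.frame")
  res
}
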