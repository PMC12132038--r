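# Synthetic landscapes and stratified-dispersal invasions with known
# parameters. The generator emulates the statistical structure of a
# multi-year forest-pest detection survey: strong class imbalance, spatial
# clustering of presences around epicentres with occasional long-distance
# jumps, and spatially autocorrelated predictor surfaces whose coefficient
# signs mirror the fitted occurrence model (negative elevation and
# campgrounds effects; positive slope, population density, crown closure,
# urban landcover, degree-days and infestation-pressure effects).

#' Default simulated predictor supports
#'
#' One row per predictor: name, lower and upper support, and the kind of
#' marginal ("continuous", "count" or "derived").
#' @return Data frame describing the simulated predictor surfaces.
#' @export
predictor_specs <- function() {
  data.frame(
    name = c("elev", "slope", "aspect", "roads_log10", "rail_log10",
             "stations", "campgrounds", "parks", "popdensity_log10",
             "crown", "treed", "broadleaf", "landcover", "deg_days", "cqmt"),
    lo   = c(0,   0,  -1, 0,   0,   0, 0, 0,   0, 0,   0,   0,   0, 150, -25),
    hi   = c(500, 15,  1, 4.5, 3.5, 2, 3, 100, 4, 100, 100, 100, 1, 1200,  0),
    kind = c("continuous", "continuous", "continuous", "continuous",
             "continuous", "count", "count", "continuous", "continuous",
             "continuous", "continuous", "continuous", "derived",
             "continuous", "continuous"),
    stringsAsFactors = FALSE
  )
}

#' Default generating coefficients (log-odds per unit)
#'
#' Per-unit slopes for the colonisation model, with the sign structure of the
#' fitted multivariable occurrence model; predictors outside that model get
#' coefficient zero. \code{spatial} multiplies the infestation-pressure term.
#' @return Named numeric vector.
#' @export
default_true_betas <- function() {
  c(spatial = 0.35, elev = -0.008, slope = 0.154, campgrounds = -0.803,
    popdensity_log10 = 0.403, crown = 0.046, landcover = 1.147,
    deg_days = 0.004,
    aspect = 0, roads_log10 = 0, rail_log10 = 0, stations = 0,
    parks = 0, treed = 0, broadleaf = 0, cqmt = 0)
}

#' Configuration of a simulated invasion scenario
#'
#' The default scenario is a 40 x 40 hexagon landscape of 2,500 km2 cells,
#' spanning roughly six to seven kernel cutoffs like a continental study
#' area: centroid distances cover the full 0-300 km kernel range, only a
#' small fraction of the landscape lies within reach of any one infestation,
#' and spread is wave-limited rather than instantaneous. The horizon is 15
#' years with the first two as epicentre-only burn-in, and the survey
#' parameters are calibrated to the ~7% presence prevalence typical of
#' regional pest detection data.
#'
#' @param grid_rows,grid_cols Lattice dimensions.
#' @param cell_area_km2 Hexagon area, km2.
#' @param years Horizon (calendar years 1..years); must exceed \code{max(lags)}.
#' @param seed Integer seed; every stochastic draw derives from it.
#' @param autocorr_range_km Range of the moving-average smoother generating
#'   spatially autocorrelated predictor fields; 0 gives white noise.
#' @param true_betas Named per-unit generating coefficients
#'   (see \code{\link{default_true_betas}}).
#' @param beta0 Intercept of the colonisation model on the log-odds scale,
#'   applied to mean-centred predictors (baseline yearly colonisation
#'   probability at average conditions and zero pressure).
#' @param true_a,form,cutoff_m,lags Kernel parameters used to generate spread.
#' @param detection_prob Probability an infested, surveyed cell is detected.
#' @param jump_rate Expected number of human-assisted long-distance jumps per
#'   year, landing on uniformly random cells.
#' @param surveyed_fraction Fraction of uninfested cells surveyed (recorded as
#'   absences) each response year.
#' @param n_epicenters Number of initial infested cells.
#' @param origin Bbox origin \code{c(lon, lat)} of the landscape.
#' @return A list of class \code{landscape_config}.
#' @export
landscape_config <- function(grid_rows = 40, grid_cols = 40,
                             cell_area_km2 = 2500, years = 15, seed = 1,
                             autocorr_range_km = 60,
                             true_betas = default_true_betas(),
                             beta0 = -9.1, true_a = 1,
                             form = c("power", "scale"),
                             cutoff_m = 300000, lags = c(1, 2),
                             detection_prob = 0.9, jump_rate = 0.3,
                             surveyed_fraction = 0.15, n_epicenters = 12,
                             n_clusters = 3, survey_range_m = 1e9,
                             origin = c(-75, 45)) {
  form <- match.arg(form)
  stopifnot(grid_rows > 0, grid_cols > 0, cell_area_km2 > 0,
            detection_prob > 0, detection_prob <= 1,
            surveyed_fraction > 0, surveyed_fraction <= 1,
            jump_rate >= 0, n_epicenters >= 1)
  if (years < max(lags) + 1)
    stop("horizon must exceed the maximum kernel lag")
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 cell_area_km2 = cell_area_km2, years = years, seed = seed,
                 autocorr_range_km = autocorr_range_km,
                 true_betas = true_betas, beta0 = beta0, true_a = true_a,
                 form = form, cutoff_m = cutoff_m, lags = as.integer(lags),
                 detection_prob = detection_prob, jump_rate = jump_rate,
                 surveyed_fraction = surveyed_fraction,
                 n_epicenters = n_epicenters, n_clusters = n_clusters,
                 survey_range_m = survey_range_m, origin = origin),
            class = "landscape_config")
}

# Grid spanning rows x cols cells of the configured area from the origin.
.scenario_grid <- function(cfg) {
  s <- sqrt(2 * cfg$cell_area_km2 * 1e6 / (3 * sqrt(3)))
  width_m <- cfg$grid_cols * 1.5 * s
  height_m <- cfg$grid_rows * sqrt(3) * s
  lat0 <- cfg$origin[2]
  dlat <- height_m / 111000
  dlon <- width_m / (111000 * cos((lat0 + dlat / 2) * pi / 180))
  build_hex_grid(c(cfg$origin[1], lat0, cfg$origin[1] + dlon, lat0 + dlat),
                 cfg$cell_area_km2)
}

# Spatially autocorrelated standard-normal-ish field: white noise smoothed by
# a row-normalised moving average over cells within the range, then
# re-standardised. dist_m is the projected centroid distance matrix.
.smooth_field <- function(z, dist_m, range_m) {
  if (range_m <= 0) return(as.numeric(scale(z)))
  w <- dist_m <= range_m
  f <- as.numeric((w %*% z) / rowSums(w))
  as.numeric(scale(f))
}

#' Generate a synthetic predictor landscape
#'
#' Draws one spatially autocorrelated field per predictor (seeded, so the
#' result is deterministic), rescales each to its declared support, and
#' derives the dichotomous landcover flag by thresholding the population
#' density field at its 85th percentile so that "urban" cells cluster.
#'
#' @param cfg A \code{\link{landscape_config}}.
#' @return A list of class \code{simulated_study} with elements \code{grid},
#'   \code{predictors} (data frame keyed by \code{hex_id}) and \code{truth}
#'   (the config). Occurrences are added by \code{\link{simulate_invasion}}.
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  grid <- .scenario_grid(cfg)
  n <- nrow(grid$cells)
  xy <- grid$cells[c("x", "y")]
  dist_m <- as.matrix(stats::dist(xy))
  specs <- predictor_specs()
  set.seed(cfg$seed)
  pred <- data.frame(hex_id = grid$cells$hex_id)
  fields <- list()
  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[i]
    if (specs$kind[i] == "derived") next
    f <- .smooth_field(stats::rnorm(n), dist_m, cfg$autocorr_range_km * 1000)
    fields[[nm]] <- f
    if (specs$kind[i] == "count") {
      # quantile-coupled Poisson counts, clipped to the declared support
      lam <- if (nm == "stations") 0.15 else 0.10
      pred[[nm]] <- pmin(stats::qpois(stats::pnorm(f), lam), specs$hi[i])
    } else {
      # Gaussian marginal centred on the support midpoint with sd = range/6,
      # clipped to the support: landscapes concentrate around typical values
      # rather than spreading uniformly over the physical extremes
      mid <- (specs$lo[i] + specs$hi[i]) / 2
      sdv <- (specs$hi[i] - specs$lo[i]) / 6
      pred[[nm]] <- pmin(pmax(mid + sdv * f, specs$lo[i]), specs$hi[i])
    }
  }
  # urban cells cluster where population density is high
  pd <- fields[["popdensity_log10"]]
  pred$landcover <- as.integer(pd >= stats::quantile(pd, 0.85))
  structure(list(grid = grid, predictors = pred, occurrences = NULL,
                 truth = cfg),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Simulated study:", nrow(x$grid$cells), "hexagons of",
      x$truth$cell_area_km2, "km2,", x$truth$years, "years\n")
  if (!is.null(x$occurrences)) print(x$occurrences)
  invisible(x)
}

# Fixed per-cell linear predictor contribution (mean-centred predictors).
.eta_fixed <- function(study) {
  cfg <- study$truth
  pred <- study$predictors
  betas <- cfg$true_betas
  eta <- rep(cfg$beta0, nrow(pred))
  for (nm in names(betas)) {
    if (betas[[nm]] == 0 || !nm %in% names(pred)) next
    x <- pred[[nm]]
    eta <- eta + betas[[nm]] * (x - mean(x))
  }
  eta
}

#' Simulate a stratified-dispersal invasion over the landscape
#'
#' Epicentre cells are infested in years 1..max(lags) (burn-in); from the
#' first year with full lag history onward, each uninfested cell is colonised
#' with probability inverse-logit(beta0 + beta_spatial * pressure + fixed
#' effects), pressure being the lagged kernel term with the generating shape
#' \code{true_a}. Poisson(jump_rate) long-distance jumps land on uniformly
#' random cells each year. Infested cells stay infested. Observed presences
#' are infested cells thinned by the detection probability; a seeded fraction
#' of uninfested cells is surveyed and recorded as absences each response
#' year.
#'
#' @param study A \code{simulated_study} from \code{\link{generate_landscape}}.
#' @param cfg Scenario config (defaults to the one inside \code{study}).
#' @return An \code{\link{occurrence_table}} of observed surveys, with the
#'   latent infestation table in attribute \code{"latent"} and the first
#'   response year in attribute \code{"first_response_year"}.
#' @export
simulate_invasion <- function(study, cfg = study$truth) {
  stopifnot(inherits(study, "simulated_study"))
  if (cfg$years < max(cfg$lags) + 1)
    stop("horizon must exceed the maximum kernel lag")
  grid <- study$grid
  n <- nrow(grid$cells)
  pcfg <- pressure_config(a = cfg$true_a, cutoff_m = cfg$cutoff_m,
                          lags = cfg$lags, form = cfg$form)
  eta_fix <- .eta_fixed(study)
  b_sp <- if ("spatial" %in% names(cfg$true_betas))
    cfg$true_betas[["spatial"]] else 0

  set.seed(cfg$seed + 1L)
  # established infestation cores: n_clusters widely separated epicentre
  # clusters (like the multiple invasion foci of a real landscape-scale
  # infestation), each the cells nearest a sampled centre
  per <- max(1L, ceiling(cfg$n_epicenters / cfg$n_clusters))
  ctrs <- sample.int(n, 1)
  while (length(ctrs) < cfg$n_clusters) {
    cand <- sample.int(n, 25)
    dmin <- vapply(cand, function(cc) min(geodetic_distance(
      grid$cells$lon[cc], grid$cells$lat[cc],
      grid$cells$lon[ctrs], grid$cells$lat[ctrs])), numeric(1))
    ctrs <- c(ctrs, cand[which.max(dmin)])  # farthest-point placement
  }
  epi <- unique(unlist(lapply(ctrs, function(cc) {
    d_ctr <- geodetic_distance(grid$cells$lon[cc], grid$cells$lat[cc],
                               grid$cells$lon, grid$cells$lat)
    order(d_ctr)[seq_len(per)]
  })))
  burn_in <- max(cfg$lags)
  infested <- matrix(FALSE, n, cfg$years)
  infested[epi, seq_len(burn_in)] <- TRUE

  latent_rows <- lapply(seq_len(burn_in), function(t)
    data.frame(hex_id = grid$cells$hex_id[infested[, t]], year = t,
               presence = 1L))

  for (t in seq(burn_in + 1, cfg$years)) {
    infested[, t] <- infested[, t - 1]
    latent <- occurrence_table(do.call(rbind, latent_rows), first_year = 1L)
    sp <- pressure_surface(latent, grid, pcfg, years = t)$spatial
    p <- stats::plogis(eta_fix + b_sp * sp)
    new_col <- !infested[, t] & stats::runif(n) < p
    n_jump <- stats::rpois(1, cfg$jump_rate)
    if (n_jump > 0) new_col[sample.int(n, n_jump)] <- TRUE
    infested[new_col, t] <- TRUE
    latent_rows[[t]] <- data.frame(
      hex_id = grid$cells$hex_id[infested[, t]], year = t, presence = 1L)
  }

  # observation process over the response years
  first_resp <- burn_in + 1L
  obs_rows <- list()
  for (t in seq_len(cfg$years)) {
    inf <- which(infested[, t])
    if (t < first_resp) {
      # burn-in years enter the record as known presences (they seed the lags)
      if (length(inf) > 0)
        obs_rows[[t]] <- data.frame(hex_id = grid$cells$hex_id[inf], year = t,
                                    presence = 1L)
      next
    }
    det <- stats::runif(length(inf)) < cfg$detection_prob
    uninf <- which(!infested[, t])
    n_surv <- round(cfg$surveyed_fraction * length(uninf))
    # survey effort concentrates around prior detections (delimitation
    # surveys), with a floor so remote pre-detection surveys still occur
    prior_det <- unique(unlist(lapply(obs_rows[seq_len(t - 1)], function(r)
      if (is.null(r)) integer(0) else r$hex_id[r$presence == 1])))
    w <- rep(1, length(uninf))
    if (length(prior_det) > 0 && length(uninf) > 0) {
      pd <- match(prior_det, grid$cells$hex_id)
      dm <- matrix(vapply(pd, function(k)
        geodetic_distance(grid$cells$lon[uninf], grid$cells$lat[uninf],
                          grid$cells$lon[k], grid$cells$lat[k]),
        numeric(length(uninf))), nrow = length(uninf))
      dmin <- apply(dm, 1, min)
      w <- 0.1 + exp(-dmin / cfg$survey_range_m)
    }
    surv <- if (n_surv > 0)
      uninf[sample.int(length(uninf), n_surv, prob = w)] else integer(0)
    obs_rows[[t]] <- data.frame(
      hex_id = grid$cells$hex_id[c(inf, surv)],
      year = t,
      presence = c(as.integer(det), rep(0L, length(surv))))
  }
  latent_all <- occurrence_table(do.call(rbind, latent_rows), first_year = 1L)
  obs <- do.call(rbind, obs_rows)
  obs <- obs[order(obs$year, obs$hex_id), ]
  rownames(obs) <- NULL
  out <- occurrence_table(obs, first_year = 1L)
  attr(out, "latent") <- latent_all
  attr(out, "first_response_year") <- first_resp
  out
}

#' Generate a complete simulated study (landscape + invasion)
#'
#' @param cfg A \code{\link{landscape_config}}.
#' @return A \code{simulated_study} with \code{occurrences} filled in.
#' @export
simulate_study <- function(cfg = landscape_config()) {
  study <- generate_landscape(cfg)
  study$occurrences <- simulate_invasion(study, cfg)
  study
}

#' Accumulated degree-days above a base temperature
#'
#' @param daily_mean_temps Numeric series of daily mean temperatures, deg C.
#' @param base Base temperature, deg C (default 10).
#' @return Sum of positive exceedances, deg C-days.
#' @export
accumulate_degree_days <- function(daily_mean_temps, base = 10) {
  stopifnot(length(daily_mean_temps) >= 1)
  sum(pmax(0, daily_mean_temps - base))
}
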