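# Shared fixtures and independent oracles. Oracles here deliberately avoid
# the package's own computation paths.

# small grid reused across tests
small_grid <- function(width_deg = 0.1, cell_area_km2 = 1) {
  build_hex_grid(c(-75, 45, -75 + width_deg, 45 + width_deg), cell_area_km2)
}

# independent haversine (textbook formula, written from scratch)
oracle_haversine <- function(lon1, lat1, lon2, lat2, R = 6371008.8) {
  to_rad <- pi / 180
  a <- sin((lat2 - lat1) * to_rad / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) *
      sin((lon2 - lon1) * to_rad / 2)^2
  2 * R * atan2(sqrt(a), sqrt(1 - a))
}

# brute-force all-pairs pressure oracle: double loop over targets and every
# (infested hexagon, lag year) pair, no spatial index, no vectorisation
oracle_pressure <- function(occ, grid, cfg, years,
                            hex_ids = grid$cells$hex_id) {
  out <- list()
  for (t in years) {
    for (h in hex_ids) {
      tc <- grid$cells[grid$cells$hex_id == h, ]
      total <- 0
      for (l in cfg$lags) {
        inf <- occ[occ$year == t - l & occ$presence == 1, ]
        if (nrow(inf) == 0) next
        for (k in seq_len(nrow(inf))) {
          kc <- grid$cells[grid$cells$hex_id == inf$hex_id[k], ]
          d <- oracle_haversine(tc$lon, tc$lat, kc$lon, kc$lat)
          if (d > cfg$cutoff_m) next
          ds <- d / cfg$cutoff_m
          total <- total + if (cfg$form == "power") exp(-ds^cfg$a)
                           else exp(-ds / cfg$a)
        }
      }
      out[[length(out) + 1]] <- data.frame(hex_id = h, year = t,
                                           spatial = total)
    }
  }
  do.call(rbind, out)
}

# direct Bernoulli log-likelihood maximisation (independent of glm/IRLS)
oracle_logistic <- function(X, y) {
  X <- cbind(1, as.matrix(X))
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  fit$par
}

# a tiny design matrix with known structure
toy_design <- function(n = 200, seed = 1, betas = c(1, -0.5), b0 = -0.2) {
  set.seed(seed)
  p <- length(betas)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  eta <- b0 + drop(X %*% betas)
  df <- data.frame(presence = rbinom(n, 1, plogis(eta)), X)
  class(df) <- c("design_matrix", "data.frame")
  df
}
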