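# Logistic-regression model building and comparison: design assembly with
# balanced pseudo-absence sampling, kernel-shape selection by AIC,
# correlation/VIF collinearity screening, backward elimination, and
# AIC/Akaike-weight comparison tables.

#' Assemble a hexagon-year design matrix
#'
#' Joins the occurrence response with the infestation-pressure surface and the
#' per-hexagon predictor table. Optionally balances classes by pairing every
#' presence with an equal-size seeded draw of surveyed absences (uniform over
#' the absence hexagon-years).
#'
#' @param occ An \code{\link{occurrence_table}}.
#' @param pressure A \code{pressure_table} from \code{\link{pressure_surface}}
#'   covering the response rows (or NULL to omit the spatial column).
#' @param predictors Data frame keyed by \code{hex_id} with predictor columns.
#' @param years Response years to include (default: all years in \code{occ}).
#' @param balanced If TRUE, keep all presences and an equal number of sampled
#'   absences.
#' @param seed Seed for the absence draw (required when \code{balanced}).
#' @return Data frame with key columns \code{hex_id}, \code{year}, response
#'   \code{presence}, and predictor columns; class \code{design_matrix}.
#' @export
build_design <- function(occ, pressure = NULL, predictors = NULL,
                         years = NULL, balanced = FALSE, seed = NULL) {
  df <- as.data.frame(occ)
  if (!is.null(years)) df <- df[df$year %in% years, , drop = FALSE]
  if (!is.null(pressure)) {
    key <- paste(df$hex_id, df$year)
    pkey <- paste(pressure$hex_id, pressure$year)
    m <- match(key, pkey)
    if (anyNA(m)) stop("pressure surface does not cover all response rows")
    df$spatial <- pressure$spatial[m]
  }
  if (!is.null(predictors)) {
    m <- match(df$hex_id, predictors$hex_id)
    if (anyNA(m)) stop("predictor table does not cover all response hexagons")
    for (nm in setdiff(names(predictors), "hex_id")) df[[nm]] <- predictors[[nm]][m]
  }
  if (balanced) {
    if (is.null(seed)) stop("balanced sampling requires a seed")
    pres <- which(df$presence == 1)
    abs_ <- which(df$presence == 0)
    if (length(abs_) < length(pres))
      stop("not enough absences to balance the presences")
    set.seed(seed)
    keep <- sort(c(pres, abs_[sample.int(length(abs_), length(pres))]))
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("design_matrix", "data.frame")
  df
}

.design_predictors <- function(X) {
  setdiff(names(X), c("hex_id", "year", "presence"))
}

#' Fit a logistic regression on a design matrix
#'
#' Maximum-likelihood logistic regression (logit link, fitted by iteratively
#' reweighted least squares via \code{stats::glm}) of \code{presence} on the
#' design's predictor columns.
#'
#' @param X A \code{\link{build_design}} data frame (or any data frame with a
#'   0/1 \code{presence} column; \code{hex_id}/\code{year} are ignored).
#' @param predictors Predictor columns to use (default: all non-key columns);
#'   \code{character(0)} fits the intercept-only model.
#' @return Object of class \code{fitted_logistic}: coefficient table
#'   (estimate, SE, z, p, odds ratio and Wald 95% CI), \code{log_likelihood},
#'   \code{aic}, \code{k} (all estimated coefficients, intercept included),
#'   \code{converged}, and the underlying \code{glm} fit.
#' @export
fit_logistic <- function(X, predictors = NULL) {
  stopifnot(is.data.frame(X), "presence" %in% names(X))
  if (is.null(predictors)) predictors <- .design_predictors(X)
  y <- X$presence
  if (!all(y %in% c(0, 1))) stop("presence must be 0/1")
  if (sum(y == 1) < 1 || sum(y == 0) < 1)
    stop("need at least one presence and one absence")
  rhs <- if (length(predictors) == 0) "1"
         else paste(sprintf("`%s`", predictors), collapse = " + ")
  fml <- stats::as.formula(paste("presence ~", rhs))
  fit <- suppressWarnings(
    stats::glm(fml, data = X, family = stats::binomial("logit"),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("singular design; aliased column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  # complete separation: boundary fitted probabilities with exploding SEs
  separated <- any(fit$fitted.values > 1 - 1e-10 |
                     fit$fitted.values < 1e-10) &&
    any(sm[, "Std. Error"] > 100)
  if (separated)
    warning("possible complete separation; coefficients diverging")
  ors <- odds_ratio(cf, sm[, "Std. Error"])
  tab <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                    se = sm[, "Std. Error"], z = sm[, "z value"],
                    p = sm[, "Pr(>|z|)"], or = ors$or, or_low = ors$low,
                    or_high = ors$high, row.names = NULL)
  ll <- as.numeric(stats::logLik(fit))
  k <- length(cf)
  structure(list(coefficients = tab, log_likelihood = ll,
                 aic = 2 * k - 2 * ll, k = k,
                 converged = fit$converged && !separated,
                 n = length(y), model = fit,
                 predictors = predictors),
            class = "fitted_logistic")
}

#' @export
print.fitted_logistic <- function(x, digits = 3, ...) {
  cat("Logistic regression (", x$n, " obs, K = ", x$k, ")\n", sep = "")
  tab <- x$coefficients
  out <- data.frame(term = tab$term,
                    estimate = sprintf("%.*f ± %.*f", digits,
                                       tab$estimate, digits, tab$se),
                    OR = sprintf("%.*f (%.*f to %.*f)", digits, tab$or,
                                 digits, tab$or_low, digits, tab$or_high),
                    z = round(tab$z, 2),
                    p = signif(tab$p, 2))
  print(out, row.names = FALSE)
  cat(sprintf("logLik = %.1f, AIC = %.1f%s\n", x$log_likelihood, x$aic,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
coef.fitted_logistic <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
predict.fitted_logistic <- function(object, newdata = NULL, ...) {
  stats::predict(object$model, newdata = newdata, type = "response")
}

#' Odds ratio with Wald confidence interval
#'
#' @param beta Log-odds coefficient(s).
#' @param se Standard error(s), > 0.
#' @param level Confidence level (default 0.95, multiplier 1.96 at default).
#' @return Data frame with columns \code{or}, \code{low}, \code{high}.
#' @export
odds_ratio <- function(beta, se, level = 0.95) {
  if (any(se <= 0)) stop("standard errors must be positive")
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(or = exp(beta), low = exp(beta - zq * se),
             high = exp(beta + zq * se))
}

#' Select the dispersal-kernel shape by AIC
#'
#' Fits the single-predictor spatial logistic model for each candidate shape
#' value on the same balanced response rows and returns the shape with the
#' smallest AIC (ties within 1e-6 break to the smallest shape).
#'
#' By default the response is restricted to the at-risk set: rows of cells
#' with no presence recorded in an earlier year, so presences are first
#' detections (colonisation events). Repeated re-detections of persistently
#' infested cells carry no information about the dispersal kernel and, left
#' in, bias selection towards the steepest shape (their own lagged
#' infestation dominates every kernel at distance zero). The pressure term
#' itself is always computed from the full occurrence table, so known
#' infestations still act as sources.
#'
#' @param occ An \code{\link{occurrence_table}}.
#' @param grid The \code{hex_grid}.
#' @param a_values Candidate shapes (default 1, 3, 5, 10).
#' @param base_cfg \code{\link{pressure_config}} supplying cutoff, lags, form.
#' @param years Response years (default: years with full lag history).
#' @param balanced Balance absences against presences (default TRUE).
#' @param seed Seed for the balanced absence draw.
#' @param risk_set \code{"colonization"} (default) restricts response rows to
#'   the at-risk set; \code{"all"} uses every surveyed hexagon-year.
#' @param sources Occurrence table supplying the infested source cells for
#'   the pressure term (defaults to \code{occ}); a separate table supports
#'   designs where the response rows and the infestation registry differ.
#' @return List of class \code{kernel_selection}: \code{best_a}, per-shape
#'   \code{fits}, and an AIC \code{table}.
#' @export
select_kernel_shape <- function(occ, grid, a_values = c(1, 3, 5, 10),
                                base_cfg = pressure_config(), years = NULL,
                                balanced = TRUE, seed = 1,
                                risk_set = c("colonization", "all"),
                                sources = NULL) {
  stopifnot(length(a_values) >= 2)
  risk_set <- match.arg(risk_set)
  if (is.null(sources)) sources <- occ
  fy <- attr(occ, "first_year")
  if (is.null(years))
    years <- seq(fy + max(base_cfg$lags), max(occ$year))
  resp <- occ
  if (risk_set == "colonization") {
    df <- as.data.frame(occ)
    pres <- df[df$presence == 1, , drop = FALSE]
    first_pres <- tapply(pres$year, pres$hex_id, min)
    fp <- first_pres[as.character(df$hex_id)]
    keep <- is.na(fp) | df$year <= fp
    resp <- occurrence_table(df[keep, , drop = FALSE], first_year = fy)
  }
  # one response-row draw shared across shapes so AICs are comparable
  base <- build_design(resp, pressure = NULL, years = years,
                       balanced = balanced, seed = seed)
  fits <- list()
  for (a in sort(a_values)) {
    cfg_a <- pressure_config(a = a, cutoff_m = base_cfg$cutoff_m,
                             lags = base_cfg$lags, form = base_cfg$form)
    ps <- pressure_surface(sources, grid, cfg_a, years = years,
                           hex_ids = unique(base$hex_id))
    Xa <- base
    m <- match(paste(Xa$hex_id, Xa$year), paste(ps$hex_id, ps$year))
    Xa$spatial <- ps$spatial[m]
    # a constant pressure column (e.g. no sources in reach anywhere) carries
    # no information for any shape: fall back to the intercept-only fit so
    # the candidates tie and the smallest shape wins
    fits[[as.character(a)]] <-
      if (stats::var(Xa$spatial) == 0)
        fit_logistic(Xa, predictors = character(0))
      else fit_logistic(Xa, predictors = "spatial")
  }
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  best <- sort(a_values)[which(aic <= min(aic) + 1e-6)[1]]
  structure(list(best_a = best, fits = fits,
                 table = data.frame(a = sort(a_values), aic = unname(aic))),
            class = "kernel_selection")
}

#' @export
print.kernel_selection <- function(x, ...) {
  cat("Kernel-shape selection by AIC (best a =", x$best_a, ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Screen predictors for collinearity
#'
#' Drops constant columns, then resolves each pair with |Pearson r| at or
#' above \code{r_max} by dropping the member whose single-predictor logistic
#' model has the larger AIC, then iteratively drops the largest-VIF column
#' while any VIF is at or above \code{vif_max}
#' (VIF_j = 1 / (1 - R^2) of column j regressed on the others).
#'
#' @param X A design matrix with a \code{presence} column.
#' @param r_max Pairwise correlation threshold (default 0.75).
#' @param vif_max VIF threshold (default 5).
#' @param keep Columns never dropped.
#' @return List: \code{retained} column names and a \code{report} data frame
#'   of drop decisions (column, reason, statistic).
#' @export
screen_predictors <- function(X, r_max = 0.75, vif_max = 5,
                              keep = character()) {
  preds <- .design_predictors(X)
  stopifnot(length(preds) >= 2)
  report <- data.frame(column = character(0), reason = character(0),
                       statistic = numeric(0))
  const <- preds[vapply(preds, function(p) stats::var(X[[p]]) == 0,
                        logical(1))]
  for (p in const) {
    warning("dropping constant column: ", p)
    report <- rbind(report, data.frame(column = p, reason = "constant",
                                       statistic = 0))
  }
  preds <- setdiff(preds, const)
  single_aic <- function(p) fit_logistic(X, predictors = p)$aic

  repeat {
    if (length(preds) < 2) break
    cm <- stats::cor(X[preds])
    diag(cm) <- 0
    mx <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    if (abs(cm[mx[1], mx[2]]) < r_max) break
    pair <- preds[mx]
    drop_candidates <- setdiff(pair, keep)
    if (length(drop_candidates) == 0) break
    aics <- vapply(drop_candidates, single_aic, numeric(1))
    drop <- drop_candidates[which.max(aics)]
    report <- rbind(report, data.frame(column = drop, reason = "correlation",
                                       statistic = cm[mx[1], mx[2]]))
    preds <- setdiff(preds, drop)
  }

  repeat {
    if (length(preds) < 2) break
    vifs <- vapply(preds, function(p) {
      r2 <- summary(stats::lm(
        stats::reformulate(sprintf("`%s`", setdiff(preds, p)),
                           response = sprintf("`%s`", p)),
        data = X))$r.squared
      1 / max(1 - r2, 1e-12)
    }, numeric(1))
    candidates <- setdiff(preds, keep)
    if (length(candidates) == 0 || max(vifs[candidates]) < vif_max) break
    drop <- candidates[which.max(vifs[candidates])]
    report <- rbind(report, data.frame(column = drop, reason = "vif",
                                       statistic = vifs[drop]))
    preds <- setdiff(preds, drop)
  }
  list(retained = preds, report = report)
}

#' Backward elimination by AIC
#'
#' Starting from the full model on the design's predictors, repeatedly removes
#' the single term whose removal most decreases AIC, stopping when no removal
#' decreases it. Terms in \code{keep} (for example the spatial
#' infestation-pressure term) are never removed.
#'
#' @param X Design matrix with a \code{presence} column.
#' @param keep Character vector of protected terms.
#' @param predictors Starting predictor set (default: all).
#' @return The final \code{\link{fit_logistic}} fit, with the elimination
#'   path in attribute \code{"path"}.
#' @export
backward_eliminate <- function(X, keep = character(), predictors = NULL) {
  if (is.null(predictors)) predictors <- .design_predictors(X)
  stopifnot(all(keep %in% predictors))
  current <- predictors
  fit <- fit_logistic(X, predictors = current)
  path <- data.frame(step = 0L, dropped = NA_character_, aic = fit$aic)
  step <- 0L
  repeat {
    droppable <- setdiff(current, keep)
    if (length(droppable) == 0) break
    aics <- vapply(droppable, function(p)
      fit_logistic(X, predictors = setdiff(current, p))$aic, numeric(1))
    if (min(aics) >= fit$aic) break
    step <- step + 1L
    drop <- droppable[which.min(aics)]
    current <- setdiff(current, drop)
    fit <- fit_logistic(X, predictors = current)
    path <- rbind(path, data.frame(step = step, dropped = drop,
                                   aic = fit$aic))
  }
  attr(fit, "path") <- path
  fit
}

#' AIC comparison table from raw AIC values
#'
#' @param aic Named numeric vector of AIC values.
#' @param k Optional parameter counts.
#' @param loglik Optional log-likelihoods.
#' @return Data frame of class \code{comparison_table}, sorted by AIC, with
#'   \code{delta_aic} (minimum 0) and Akaike \code{weight}
#'   (exp(-delta/2) normalised to sum 1).
#' @export
aic_compare <- function(aic, k = NULL, loglik = NULL) {
  stopifnot(length(aic) >= 2, !is.null(names(aic)))
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(model = names(aic), k = if (is.null(k)) NA else k,
                    aic = unname(aic), delta_aic = unname(delta),
                    weight = unname(w),
                    loglik = if (is.null(loglik)) NA else loglik)
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Compare fitted logistic models by AIC
#'
#' @param fits Named list of \code{\link{fit_logistic}} objects fitted to the
#'   same response vector.
#' @return A \code{comparison_table} (see \code{\link{aic_compare}}).
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2, !is.null(names(fits)))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1)
    stop("models fitted to different response lengths cannot be compared")
  aic_compare(vapply(fits, function(f) f$aic, numeric(1)),
              k = vapply(fits, function(f) f$k, numeric(1)),
              loglik = vapply(fits, function(f) f$log_likelihood, numeric(1)))
}

#' @export
print.comparison_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$aic <- round(y$aic, 1); y$delta_aic <- round(y$delta_aic, 1)
  y$weight <- round(y$weight, 2)
  if (all(is.na(y$loglik))) y$loglik <- NULL else y$loglik <- round(y$loglik, 1)
  if (all(is.na(y$k))) y$k <- NULL
  print(y, row.names = FALSE)
  invisible(x)
}
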