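# End-to-end orchestration: simulate (or ingest) -> infestation pressure and
# kernel-shape selection -> design assembly -> logistic model selection ->
# multi-algorithm comparison -> ensemble, variable importance -> artifacts.
# Every stage writes plain CSV/GeoJSON/JSON so any stage can be re-entered,
# and a manifest records seeds, record counts, wall time and checksums.

#' Configure a full pipeline run
#'
#' Either a simulation \code{scenario} or the three input paths
#' (\code{occ_csv}, \code{grid_geojson}, \code{predictors_csv}) must be
#' given.
#'
#' @param scenario A \code{\link{landscape_config}} for simulated input, or
#'   NULL to ingest files.
#' @param occ_csv,grid_geojson,predictors_csv Input paths (ingest mode).
#' @param a_values Candidate kernel shapes (default 1, 3, 5, 10).
#' @param cutoff_m,lags,form Kernel parameters (see
#'   \code{\link{pressure_config}}).
#' @param r_max,vif_max Collinearity screening thresholds.
#' @param train_frac,n_absence_sets,n_cv,cv_calibration_fraction Split-plan
#'   parameters (see \code{\link{split_plan}}).
#' @param families Model families for the comparison stage.
#' @param member_tss_min Ensemble membership bar on validation TSS.
#' @param outdir Output directory (created if absent).
#' @param seed Master seed; no stage uses wall-clock seeding.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(scenario = landscape_config(),
                            occ_csv = NULL, grid_geojson = NULL,
                            predictors_csv = NULL,
                            a_values = c(1, 3, 5, 10),
                            cutoff_m = 300000, lags = c(1, 2),
                            form = "power",
                            r_max = 0.75, vif_max = 5,
                            train_frac = 0.8, n_absence_sets = 10, n_cv = 3,
                            cv_calibration_fraction = 0.70,
                            families = ZOO_FAMILIES,
                            member_tss_min = 0.6,
                            outdir = "hexinvade_run", seed = 1) {
  if (is.null(scenario)) {
    paths <- c(occ_csv, grid_geojson, predictors_csv)
    if (length(paths) != 3)
      stop("config error: no simulation scenario and missing input path(s)")
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0)
      stop("config error: input file(s) not found: ",
           paste(missing, collapse = ", "))
  } else stopifnot(inherits(scenario, "landscape_config"))
  stopifnot(length(seed) == 1, is.finite(seed))
  structure(list(scenario = scenario, occ_csv = occ_csv,
                 grid_geojson = grid_geojson, predictors_csv = predictors_csv,
                 a_values = a_values, cutoff_m = cutoff_m, lags = lags,
                 form = form, r_max = r_max, vif_max = vif_max,
                 train_frac = train_frac, n_absence_sets = n_absence_sets,
                 n_cv = n_cv,
                 cv_calibration_fraction = cv_calibration_fraction,
                 families = families, member_tss_min = member_tss_min,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{pipeline_config}}; a
#' \code{scenario} mapping is passed to \code{\link{landscape_config}}.
#'
#' @param path YAML file.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenario)) {
    sc <- y$scenario
    if (!is.null(sc$true_betas)) sc$true_betas <- unlist(sc$true_betas)
    if (!is.null(sc$lags)) sc$lags <- unlist(sc$lags)
    y$scenario <- do.call(landscape_config, sc)
  }
  for (nm in c("a_values", "lags", "families"))
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  do.call(pipeline_config, y)
}

.stage_record <- function(manifest, name, t0, n_records, note = "") {
  manifest$stages[[name]] <- list(
    status = "completed",
    seconds = round(as.numeric(Sys.time()) - t0, 2),
    n_records = n_records, note = note)
  manifest
}

#' Run the full invasion-risk pipeline
#'
#' Executes simulate/ingest, pressure + kernel selection, design assembly,
#' logistic model selection, the model-zoo comparison, and the ensemble/
#' variable-importance stage, writing every intermediate artifact under
#' \code{cfg$outdir}. Rerunning with the same config and seed reproduces
#' byte-identical CSV/JSON outputs.
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @return Invisibly, a list of class \code{pipeline_run} with the in-memory
#'   stage results (grid, occurrences, design, fits, zoo, ensemble,
#'   manifest).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("hexinvade")),
    seed = cfg$seed, stages = list())
  out <- list(config = cfg)

  # stage 1: simulate or ingest -------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (!is.null(cfg$scenario)) {
    study <- simulate_study(cfg$scenario)
    grid <- study$grid
    occ <- study$occurrences
    predictors <- study$predictors
    first_resp <- attr(occ, "first_response_year")
    truth <- cfg$scenario
    jsonlite::write_json(truth[setdiff(names(truth), "true_betas")],
                         file.path(cfg$outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  } else {
    grid <- read_grid_geojson(cfg$grid_geojson)
    occ <- read_occurrence_csv(cfg$occ_csv)
    predictors <- utils::read.csv(cfg$predictors_csv)
    first_resp <- min(occ$year) + max(cfg$lags)
  }
  write_grid_geojson(grid, file.path(cfg$outdir, "grid.geojson"))
  write_occurrence_csv(occ, file.path(cfg$outdir, "occ.csv"))
  utils::write.csv(predictors, file.path(cfg$outdir, "predictors.csv"),
                   row.names = FALSE)
  manifest <- .stage_record(manifest, "input", t0, nrow(occ))
  out$grid <- grid; out$occurrences <- occ; out$predictors <- predictors

  resp_years <- seq(first_resp, max(occ$year))

  # stage 2: kernel-shape selection and pressure surface -------------------
  t0 <- as.numeric(Sys.time())
  base_cfg <- pressure_config(a = cfg$a_values[1], cutoff_m = cfg$cutoff_m,
                              lags = cfg$lags, form = cfg$form)
  ks <- select_kernel_shape(occ, grid, a_values = cfg$a_values,
                            base_cfg = base_cfg, years = resp_years,
                            seed = cfg$seed)
  best_cfg <- pressure_config(a = ks$best_a, cutoff_m = cfg$cutoff_m,
                              lags = cfg$lags, form = cfg$form)
  pressure <- pressure_surface(occ, grid, best_cfg, years = resp_years)
  utils::write.csv(pressure, file.path(cfg$outdir, "spatial.csv"),
                   row.names = FALSE)
  manifest <- .stage_record(manifest, "pressure", t0, nrow(pressure),
                            note = paste("best a =", ks$best_a))
  out$kernel_selection <- ks; out$pressure <- pressure

  # stage 3: design assembly (balanced response rows) ----------------------
  t0 <- as.numeric(Sys.time())
  design <- build_design(occ, pressure = pressure, predictors = predictors,
                         years = resp_years, balanced = TRUE,
                         seed = cfg$seed)
  utils::write.csv(design, file.path(cfg$outdir, "design.csv"),
                   row.names = FALSE)
  manifest <- .stage_record(manifest, "design", t0, nrow(design))
  out$design <- design

  # stage 4: logistic model selection --------------------------------------
  t0 <- as.numeric(Sys.time())
  scr <- screen_predictors(design, r_max = cfg$r_max, vif_max = cfg$vif_max,
                           keep = "spatial")
  final <- backward_eliminate(design, keep = "spatial",
                              predictors = scr$retained)
  fits <- list(
    final = final,
    spatial_only = fit_logistic(design, predictors = "spatial"),
    intercept_only = fit_logistic(design, predictors = character(0)))
  cmp <- compare_models(fits)
  report <- list(screening = scr$report,
                 eliminated = attr(final, "path"),
                 coefficients = final$coefficients,
                 comparison = as.data.frame(cmp))
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  manifest <- .stage_record(manifest, "glmselect", t0,
                            nrow(final$coefficients),
                            note = sprintf("final AIC %.1f", final$aic))
  out$screening <- scr; out$final_model <- final; out$comparison <- cmp

  # stage 5: multi-model comparison ----------------------------------------
  t0 <- as.numeric(Sys.time())
  zoo_preds <- final$predictors
  pres_rows <- which(design$presence == 1)
  abs_rows <- which(design$presence == 0)
  plan <- split_plan(pres_rows, abs_rows, train_frac = cfg$train_frac,
                     n_absence_sets = cfg$n_absence_sets, n_cv = cfg$n_cv,
                     cv_calibration_fraction = cfg$cv_calibration_fraction,
                     seed = cfg$seed)
  zoo <- run_model_zoo(plan, design, families = cfg$families,
                       predictors = zoo_preds)
  runs_tab <- zoo_results(zoo)
  utils::write.csv(runs_tab, file.path(cfg$outdir, "runs.csv"),
                   row.names = FALSE)
  tss_cmp <- compare_tss(zoo, "evaluation")
  jsonlite::write_json(list(anova = tss_cmp$anova, means = tss_cmp$means,
                            pairwise = tss_cmp$pairwise),
                       file.path(cfg$outdir, "tss_comparison.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  manifest <- .stage_record(manifest, "zoo", t0, nrow(runs_tab),
                            note = paste(sum(runs_tab$status == "failed"),
                                         "failed"))
  out$plan <- plan; out$zoo <- zoo; out$tss_comparison <- tss_cmp

  # stage 6: ensemble and variable importance ------------------------------
  t0 <- as.numeric(Sys.time())
  spec <- tryCatch(ensemble_spec(zoo, cfg$member_tss_min),
                   error = function(e) NULL)
  ok_runs <- Filter(function(r) r$status == "ok", zoo$runs)
  best_by_family <- lapply(split(ok_runs, vapply(ok_runs, function(r)
    r$family, character(1))), function(rs)
      rs[[which.max(vapply(rs, function(r) r$tss_validation, numeric(1)))]])
  vi <- do.call(rbind, lapply(best_by_family, function(r) {
    v <- permutation_importance(r, design[c("presence", zoo_preds)],
                                n_rep = 6, seed = cfg$seed)
    data.frame(family = r$family, predictor = names(v), vi = unname(v))
  }))
  rownames(vi) <- NULL
  utils::write.csv(vi, file.path(cfg$outdir, "vi.csv"), row.names = FALSE)
  manifest <- .stage_record(manifest, "ensemble", t0,
                            if (is.null(spec)) 0 else length(spec$members))
  out$ensemble <- spec; out$vi <- vi

  files <- c("grid.geojson", "occ.csv", "predictors.csv", "spatial.csv",
             "design.csv", "report.json", "runs.csv", "vi.csv",
             "tss_comparison.json")
  files <- files[file.exists(file.path(cfg$outdir, files))]
  manifest$checksums <- as.list(tools::md5sum(file.path(cfg$outdir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out$manifest <- manifest
  class(out) <- "pipeline_run"
  invisible(out)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run (seed", x$config$seed, ") in", x$config$outdir, "\n")
  for (nm in names(x$manifest$stages)) {
    st <- x$manifest$stages[[nm]]
    cat(sprintf("  %-10s %s (%.1fs, %d records) %s\n", nm, st$status,
                st$seconds, st$n_records, st$note))
  }
  invisible(x)
}

#' Project ensemble risk onto a (possibly uninvaded) region
#'
#' Applies the committee and the per-family member models to a new region's
#' predictor table. For regions with no detections within the kernel cutoff,
#' \code{zero_spatial} sets the infestation-pressure term to zero, the
#' no-information baseline.
#'
#' @param zoo A \code{model_zoo} (members are re-filtered at
#'   \code{member_tss_min}) or an \code{\link{ensemble_spec}}.
#' @param predictors Data frame with one row per hexagon of the new region;
#'   must contain every model predictor (\code{spatial} may be absent when
#'   \code{zero_spatial}).
#' @param zero_spatial Set the spatial term to 0 (default TRUE).
#' @param member_tss_min Membership bar when \code{zoo} is a
#'   \code{model_zoo}.
#' @return Data frame of class \code{risk_map}: per hexagon the committee
#'   \code{consensus}, \code{vote_fraction}, number of members flagging
#'   presence, and per-family mean probability.
#' @export
project_region <- function(zoo, predictors, zero_spatial = TRUE,
                           member_tss_min = 0.6) {
  spec <- if (inherits(zoo, "ensemble_spec")) zoo
          else ensemble_spec(zoo, member_tss_min)
  X <- as.data.frame(predictors)
  if (zero_spatial) X$spatial <- 0
  missing <- setdiff(spec$predictors, names(X))
  if (length(missing) > 0)
    stop("missing predictor column(s): ", paste(missing, collapse = ", "))
  cp <- committee_predict(spec, X)
  fams <- vapply(spec$members, function(m) m$family, character(1))
  probs <- vapply(spec$members, function(m) m$model$predict_prob(X),
                  numeric(nrow(X)))
  probs <- matrix(probs, nrow = nrow(X))
  fam_mean <- sapply(unique(fams), function(f)
    rowMeans(probs[, fams == f, drop = FALSE]))
  fam_mean <- matrix(fam_mean, nrow = nrow(X),
                     dimnames = list(NULL, paste0("prob_", unique(fams))))
  flags <- vapply(seq_along(spec$members), function(i)
    as.integer(probs[, i] >= spec$members[[i]]$threshold),
    integer(nrow(X)))
  flags <- matrix(flags, nrow = nrow(X))
  out <- data.frame(hex_id = if ("hex_id" %in% names(X)) X$hex_id
                             else seq_len(nrow(X)),
                    consensus = cp$consensus,
                    vote_fraction = cp$vote_fraction,
                    n_members_flagging = rowSums(flags))
  out <- cbind(out, as.data.frame(fam_mean))
  class(out) <- c("risk_map", "data.frame")
  out
}

#' @export
print.risk_map <- function(x, ...) {
  cat("Risk map:", nrow(x), "hexagons;", sum(x$consensus),
      "consensus presences;", sum(x$n_members_flagging > 0),
      "flagged by >= 1 member\n")
  invisible(x)
}
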