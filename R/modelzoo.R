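# Multi-algorithm comparison stage: balanced pseudo-absence training sets,
# calibration/validation splits, six model families (GLM, MARS, ANN, CTA,
# GBM, RF), True Skill Statistic scoring at a TSS-maximising threshold,
# committee-averaging ensembles, permutation variable importance, marginal
# response curves and an ANOVA comparison of TSS across families.

ZOO_FAMILIES <- c("GLM", "MARS", "ANN", "CTA", "GBM", "RF")

# One master seed drives every draw: a seeded table of sub-seeds is generated
# up front and indexed by purpose, so adding draws never perturbs earlier ones.
.seed_table <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(2147483646L, n)
}

#' Plan the presence/absence splits for the model comparison
#'
#' Partitions presences and absences into training and evaluation portions at
#' the given ratio (80/20 by default; counts are floored, so 1,325 presences
#' give 1,060 for training).
#'
#' @param presence_ids,absence_ids Row identifiers (any vector) of the
#'   presence and absence observations.
#' @param train_frac Training fraction (default 0.8).
#' @param n_absence_sets Number of balanced absence draws (default 10).
#' @param n_cv Cross-validation repetitions per absence set (default 3).
#' @param cv_calibration_fraction Calibration share of each training set
#'   within a cross-validation run (default 0.70; the rest validates).
#' @param seed Master seed for all draws derived from this plan.
#' @return List of class \code{split_plan}.
#' @export
split_plan <- function(presence_ids, absence_ids, train_frac = 0.8,
                       n_absence_sets = 10, n_cv = 3,
                       cv_calibration_fraction = 0.70, seed = 1) {
  stopifnot(length(presence_ids) >= 2, length(absence_ids) >= 2,
            train_frac > 0, train_frac < 1,
            cv_calibration_fraction > 0, cv_calibration_fraction < 1,
            n_absence_sets >= 1, n_cv >= 1)
  seeds <- .seed_table(seed, 2)
  n_tr_p <- floor(train_frac * length(presence_ids))
  set.seed(seeds[1])
  idx_p <- sample.int(length(presence_ids), n_tr_p)
  n_tr_a <- floor(train_frac * length(absence_ids))
  set.seed(seeds[2])
  idx_a <- sample.int(length(absence_ids), n_tr_a)
  structure(list(train_presence_ids = presence_ids[idx_p],
                 eval_presence_ids = presence_ids[-idx_p],
                 train_absence_pool_ids = absence_ids[idx_a],
                 eval_absence_pool_ids = absence_ids[-idx_a],
                 n_absence_sets = n_absence_sets, n_cv = n_cv,
                 cv_calibration_fraction = cv_calibration_fraction,
                 seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Split plan:", length(x$train_presence_ids), "training /",
      length(x$eval_presence_ids), "evaluation presences;",
      length(x$train_absence_pool_ids), "/",
      length(x$eval_absence_pool_ids), "absence pools;",
      x$n_absence_sets, "absence sets x", x$n_cv, "CV runs\n")
  invisible(x)
}

#' Draw balanced presence-absence training sets
#'
#' Each set contains every training presence plus a fresh seeded
#' without-replacement draw of absences of equal size; absences may recur
#' across sets but never within one.
#'
#' @param presence_ids Training presence identifiers.
#' @param absence_pool_ids Pool of absence identifiers (at least as many as
#'   presences).
#' @param n_sets Number of sets.
#' @param seed Seed for the draws.
#' @return List of id vectors (presences first), one per set.
#' @export
make_balanced_sets <- function(presence_ids, absence_pool_ids, n_sets, seed) {
  n_p <- length(presence_ids)
  if (length(absence_pool_ids) < n_p)
    stop("absence pool smaller than the presence count")
  seeds <- .seed_table(seed, n_sets)
  lapply(seq_len(n_sets), function(b) {
    set.seed(seeds[b])
    c(presence_ids,
      absence_pool_ids[sample.int(length(absence_pool_ids), n_p)])
  })
}

#' True Skill Statistic at a threshold
#'
#' Sensitivity + specificity - 1, predicting presence where
#' \code{predicted_prob >= threshold}.
#'
#' @param predicted_prob Numeric predictions.
#' @param observed 0/1 observations (both classes must occur).
#' @param threshold Classification threshold in [0, 1].
#' @return TSS in [-1, 1].
#' @export
tss <- function(predicted_prob, observed, threshold) {
  stopifnot(length(predicted_prob) == length(observed))
  if (length(unique(observed)) < 2)
    stop("TSS undefined: observed vector contains a single class")
  pred <- predicted_prob >= threshold
  sens <- sum(pred & observed == 1) / sum(observed == 1)
  spec <- sum(!pred & observed == 0) / sum(observed == 0)
  sens + spec - 1
}

#' TSS-maximising threshold
#'
#' Scans midpoints of sorted unique predictions plus 0 and 1; ties break to
#' the smallest threshold.
#'
#' @inheritParams tss
#' @return List with \code{threshold} and \code{tss}.
#' @export
best_threshold <- function(predicted_prob, observed) {
  if (length(unique(observed)) < 2)
    stop("TSS undefined: observed vector contains a single class")
  u <- sort(unique(predicted_prob))
  cand <- sort(unique(c(0, 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  scores <- vapply(cand, function(th) tss(predicted_prob, observed, th),
                   numeric(1))
  i <- which(scores >= max(scores) - 1e-12)[1]  # smallest maximising threshold
  list(threshold = cand[i], tss = scores[i])
}

# ---- model family adapters -------------------------------------------------
# Thin wrappers over established learners with fixed, logged hyperparameters.
# Each returns list(family, fit, predict_prob(newdata)).

.zoo_hyperparameters <- function() {
  list(GLM = list(),
       MARS = list(max_terms = 21L, n_knots = 15L, penalty = 3),
       ANN = list(size = 8L, decay = 0.01, maxit = 200L),
       CTA = list(cp_grow = 0.001, minbucket = 5L),
       GBM = list(nrounds = 1000L, eta = 0.01, max_depth = 3L),
       RF = list(ntree = 500L))
}

.fit_family <- function(family, data, predictors, seed) {
  hp <- .zoo_hyperparameters()[[family]]
  x <- as.matrix(data[predictors])
  y <- data$presence
  set.seed(seed)
  switch(family,
    GLM = {
      fml <- stats::as.formula(paste("presence ~",
        paste(sprintf("`%s`", predictors), collapse = " + ")))
      # separation on small calibration folds is routine for a learner
      # adapter; predictions remain usable
      fit <- suppressWarnings(
        stats::glm(fml, data = data, family = stats::binomial()))
      list(family = family, fit = fit, predict_prob = function(nd)
        as.numeric(stats::predict(fit, newdata = nd, type = "response")))
    },
    MARS = {
      fit <- .fit_mars(x, y, max_terms = hp$max_terms, n_knots = hp$n_knots,
                       penalty = hp$penalty)
      list(family = family, fit = fit, predict_prob = function(nd)
        .predict_mars(fit, as.matrix(nd[, predictors, drop = FALSE])))
    },
    ANN = {
      fit <- nnet::nnet(x, y, size = hp$size, decay = hp$decay,
                        maxit = hp$maxit, entropy = TRUE, trace = FALSE)
      list(family = family, fit = fit, predict_prob = function(nd)
        as.numeric(stats::predict(fit,
          as.matrix(nd[, predictors, drop = FALSE]))))
    },
    CTA = {
      df <- data.frame(presence = factor(y, levels = c(0, 1)), data[predictors])
      fit <- rpart::rpart(presence ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            cp = hp$cp_grow, minbucket = hp$minbucket,
                            xval = 10))
      # cost-complexity pruning at the minimum cross-validated error
      cp_tab <- fit$cptable
      fit <- rpart::prune(fit, cp = cp_tab[which.min(cp_tab[, "xerror"]), "CP"])
      list(family = family, fit = fit, predict_prob = function(nd)
        as.numeric(stats::predict(fit, newdata = nd, type = "prob")[, "1"]))
    },
    GBM = {
      dm <- xgboost::xgb.DMatrix(x, label = y)
      fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              eta = hp$eta,
                                              max_depth = hp$max_depth,
                                              nthread = 1, seed = seed),
                                data = dm, nrounds = hp$nrounds, verbose = 0)
      list(family = family, fit = fit, predict_prob = function(nd)
        as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(
          as.matrix(nd[, predictors, drop = FALSE])))))
    },
    RF = {
      fit <- randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                        ntree = hp$ntree)
      list(family = family, fit = fit, predict_prob = function(nd)
        as.numeric(stats::predict(fit,
          as.matrix(nd[, predictors, drop = FALSE]), type = "prob")[, "1"]))
    },
    stop("unknown model family: ", family)
  )
}

#' Run the full model-comparison factorial
#'
#' For every (family, absence set, cross-validation run) combination: fits on
#' the calibration slice of a balanced set, picks the TSS-maximising threshold
#' on the calibration predictions, scores TSS on the validation slice and on
#' the held-out evaluation table. Failures are caught and recorded as
#' \code{status = "failed"} without aborting the batch.
#'
#' @param plan A \code{\link{split_plan}}; its ids must index rows of
#'   \code{design}.
#' @param design A design matrix with \code{presence} and predictor columns.
#' @param families Model families to run (default all six).
#' @param predictors Predictor columns (default: all non-key columns).
#' @return Object of class \code{model_zoo}: list of runs, the evaluation
#'   table row ids, the plan, and the predictor set.
#' @export
run_model_zoo <- function(plan, design, families = ZOO_FAMILIES,
                          predictors = NULL) {
  stopifnot(inherits(plan, "split_plan"))
  families <- match.arg(families, ZOO_FAMILIES, several.ok = TRUE)
  if (is.null(predictors)) predictors <- .design_predictors(design)
  all_ids <- c(plan$train_presence_ids, plan$eval_presence_ids,
               plan$train_absence_pool_ids, plan$eval_absence_pool_ids)
  if (!all(all_ids %in% seq_len(nrow(design))))
    stop("plan ids must index rows of the design")

  n_draws <- 3 + plan$n_absence_sets +
    plan$n_absence_sets * plan$n_cv * (1 + length(families))
  seeds <- .seed_table(plan$seed, n_draws)
  si <- 3  # first two consumed conceptually by split_plan, third by eval draw

  sets <- make_balanced_sets(plan$train_presence_ids,
                             plan$train_absence_pool_ids,
                             plan$n_absence_sets, seed = plan$seed + 1L)

  # evaluation table: all evaluation presences + one seeded equal-size
  # absence draw
  n_ep <- length(plan$eval_presence_ids)
  if (length(plan$eval_absence_pool_ids) < n_ep)
    stop("evaluation absence pool smaller than evaluation presence count")
  set.seed(seeds[3])
  eval_ids <- c(plan$eval_presence_ids,
                plan$eval_absence_pool_ids[
                  sample.int(length(plan$eval_absence_pool_ids), n_ep)])
  eval_tab <- design[eval_ids, , drop = FALSE]

  runs <- list()
  for (b in seq_len(plan$n_absence_sets)) {
    set_tab <- design[sets[[b]], , drop = FALSE]
    for (cv in seq_len(plan$n_cv)) {
      si <- si + 1
      set.seed(seeds[si])
      n_cal <- floor(plan$cv_calibration_fraction * nrow(set_tab))
      cal_idx <- sample.int(nrow(set_tab), n_cal)
      calib <- set_tab[cal_idx, , drop = FALSE]
      valid <- set_tab[-cal_idx, , drop = FALSE]
      for (fam in families) {
        si <- si + 1
        run <- tryCatch({
          mod <- .fit_family(fam, calib, predictors, seed = seeds[si])
          p_cal <- mod$predict_prob(calib)
          if (anyNA(p_cal)) stop("NA predictions")
          bt <- best_threshold(p_cal, calib$presence)
          tv <- tss(mod$predict_prob(valid), valid$presence, bt$threshold)
          te <- tss(mod$predict_prob(eval_tab), eval_tab$presence,
                    bt$threshold)
          list(family = fam, absence_set = b, cv = cv, model = mod,
               threshold = bt$threshold, tss_calibration = bt$tss,
               tss_validation = tv, tss_evaluation = te,
               seed = seeds[si], status = "ok", error = NA_character_)
        }, error = function(e) {
          list(family = fam, absence_set = b, cv = cv, model = NULL,
               threshold = NA_real_, tss_calibration = NA_real_,
               tss_validation = NA_real_, tss_evaluation = NA_real_,
               seed = seeds[si], status = "failed",
               error = conditionMessage(e))
        })
        class(run) <- "model_run"
        runs[[length(runs) + 1]] <- run
      }
    }
  }
  if (all(vapply(runs, function(r) r$status, character(1)) == "failed"))
    stop("every model run failed; first error: ", runs[[1]]$error)
  structure(list(runs = runs, eval_ids = eval_ids, plan = plan,
                 predictors = predictors,
                 hyperparameters = .zoo_hyperparameters()[families]),
            class = "model_zoo")
}

#' Tabulate model-zoo runs
#'
#' @param zoo A \code{model_zoo}.
#' @return Data frame with one row per run (family, absence set, cv run,
#'   threshold, TSS scores, status).
#' @export
zoo_results <- function(zoo) {
  stopifnot(inherits(zoo, "model_zoo"))
  do.call(rbind, lapply(zoo$runs, function(r)
    data.frame(family = r$family, absence_set = r$absence_set, cv = r$cv,
               threshold = r$threshold, tss_calibration = r$tss_calibration,
               tss_validation = r$tss_validation,
               tss_evaluation = r$tss_evaluation, status = r$status)))
}

#' @export
print.model_zoo <- function(x, ...) {
  tab <- zoo_results(x)
  cat("Model zoo:", nrow(tab), "runs (", sum(tab$status == "failed"),
      "failed )\n")
  ok <- tab[tab$status == "ok", ]
  if (nrow(ok) > 0) {
    agg <- stats::aggregate(cbind(tss_validation, tss_evaluation) ~ family,
                            data = ok, FUN = mean)
    print(agg, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.model_zoo <- function(object, ...) {
  tab <- zoo_results(object)
  ok <- tab[tab$status == "ok", ]
  agg <- stats::aggregate(cbind(tss_validation, tss_evaluation) ~ family,
                          data = ok,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  agg
}

#' Select committee members for the ensemble
#'
#' Members are the successful runs whose validation TSS exceeds
#' \code{member_tss_min} (0.6 by default, the conventional "good model" bar).
#'
#' @param zoo A \code{model_zoo}.
#' @param member_tss_min Minimum validation TSS (exclusive).
#' @return Object of class \code{ensemble_spec}.
#' @export
ensemble_spec <- function(zoo, member_tss_min = 0.6) {
  stopifnot(inherits(zoo, "model_zoo"))
  members <- Filter(function(r) r$status == "ok" &&
                      r$tss_validation > member_tss_min, zoo$runs)
  if (length(members) == 0)
    stop("no runs pass the TSS filter; lower member_tss_min")
  structure(list(members = members, member_tss_min = member_tss_min,
                 predictors = zoo$predictors),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  fams <- table(vapply(x$members, function(m) m$family, character(1)))
  cat("Committee of", length(x$members), "members (validation TSS >",
      x$member_tss_min, ")\n")
  print(fams)
  invisible(x)
}

#' Committee-averaging consensus prediction
#'
#' Each member votes its thresholded binary prediction; the consensus is
#' presence when the vote fraction strictly exceeds one half. Exact ties
#' (even committees) resolve to absence, the conservative choice for a risk
#' map; the vote fraction is always returned for re-thresholding.
#'
#' @param spec An \code{\link{ensemble_spec}}.
#' @param X Predictor table covering the member predictors.
#' @return Data frame with \code{consensus} (0/1) and \code{vote_fraction}.
#' @export
committee_predict <- function(spec, X) {
  stopifnot(inherits(spec, "ensemble_spec"))
  missing <- setdiff(spec$predictors, names(X))
  if (length(missing) > 0)
    stop("missing predictor column(s): ", paste(missing, collapse = ", "))
  votes <- vapply(spec$members, function(m)
    as.integer(m$model$predict_prob(X) >= m$threshold),
    integer(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  frac <- rowMeans(votes)
  data.frame(consensus = as.integer(frac > 0.5), vote_fraction = frac)
}

#' Permutation variable importance
#'
#' Shuffles one predictor at a time (others fixed), re-predicts, and scores
#' 1 - Pearson correlation between original and shuffled-input predictions,
#' averaged over \code{n_rep} seeded shuffles and clamped to [0, 1]. Constant
#' original predictions give importance 0 for every predictor.
#'
#' @param run A successful \code{model_run}.
#' @param train_table The table to permute (typically the run's training
#'   data).
#' @param n_rep Shuffles per predictor (default 6).
#' @param seed Seed for the shuffles.
#' @return Named numeric vector of importances in [0, 1].
#' @export
permutation_importance <- function(run, train_table, n_rep = 6, seed = 1) {
  stopifnot(inherits(run, "model_run"), run$status == "ok", n_rep >= 1)
  preds <- names(train_table)
  preds <- setdiff(preds, c("hex_id", "year", "presence"))
  p0 <- run$model$predict_prob(train_table)
  if (stats::sd(p0) < 1e-12)
    return(stats::setNames(rep(0, length(preds)), preds))
  seeds <- .seed_table(seed, n_rep)
  vi <- vapply(preds, function(nm) {
    vals <- vapply(seq_len(n_rep), function(r) {
      set.seed(seeds[r])
      shuf <- train_table
      shuf[[nm]] <- shuf[[nm]][sample.int(nrow(shuf))]
      ps <- run$model$predict_prob(shuf)
      rr <- suppressWarnings(stats::cor(p0, ps))
      if (is.na(rr)) rr <- 0
      1 - rr
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  pmin(pmax(vi, 0), 1)
}

#' Marginal response curve of one predictor
#'
#' Predictions over an even grid of the predictor's observed range, all other
#' continuous predictors fixed at their training medians and \code{landcover}
#' at 0; averaged over runs with a standard error when several are supplied.
#'
#' @param runs A \code{model_run} or list of successful runs.
#' @param train_table Training data defining ranges and medians.
#' @param predictor Predictor name.
#' @param grid_points Number of grid points (default 30).
#' @return Data frame with \code{value}, \code{mean_prob}, \code{se}.
#' @export
marginal_response <- function(runs, train_table, predictor,
                              grid_points = 30) {
  if (inherits(runs, "model_run")) runs <- list(runs)
  preds <- setdiff(names(train_table), c("hex_id", "year", "presence"))
  if (!predictor %in% preds) stop("unknown predictor: ", predictor)
  ref <- lapply(preds, function(nm)
    if (nm == "landcover") 0 else stats::median(train_table[[nm]]))
  names(ref) <- preds
  grid_vals <- seq(min(train_table[[predictor]]),
                   max(train_table[[predictor]]), length.out = grid_points)
  nd <- as.data.frame(ref)[rep(1, grid_points), , drop = FALSE]
  nd[[predictor]] <- grid_vals
  rownames(nd) <- NULL
  probs <- vapply(runs, function(r) r$model$predict_prob(nd),
                  numeric(grid_points))
  probs <- matrix(probs, nrow = grid_points)
  data.frame(value = grid_vals, mean_prob = rowMeans(probs),
             se = apply(probs, 1, stats::sd) / sqrt(ncol(probs)))
}

#' Compare TSS across model families
#'
#' One-way ANOVA of TSS by family over the successful runs, plus all pairwise
#' mean differences with Welch t statistics and Holm-adjusted p-values.
#' Families with fewer than two successful runs are excluded with a warning.
#'
#' @param zoo A \code{model_zoo} (or a run table from
#'   \code{\link{zoo_results}}).
#' @param which Score to compare: \code{"validation"} or \code{"evaluation"}.
#' @return List of class \code{tss_comparison}: \code{anova} (F, df1, df2,
#'   p), \code{means} per family and \code{pairwise} data frame.
#' @export
compare_tss <- function(zoo, which = c("validation", "evaluation")) {
  which <- match.arg(which)
  tab <- if (inherits(zoo, "model_zoo")) zoo_results(zoo) else zoo
  tab <- tab[tab$status == "ok", , drop = FALSE]
  tab$score <- tab[[paste0("tss_", which)]]
  counts <- table(tab$family)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning("excluding family(ies) with < 2 runs: ",
            paste(small, collapse = ", "))
    tab <- tab[!tab$family %in% small, , drop = FALSE]
  }
  if (length(unique(tab$family)) < 2)
    stop("need at least two families with two or more runs")
  tab$family <- factor(tab$family)
  av <- stats::anova(stats::lm(score ~ family, data = tab))
  f_stat <- av$`F value`[1]
  # numerically zero between-family variation: report no effect
  if (!is.finite(f_stat) || av$`Sum Sq`[1] < 1e-12) f_stat <- 0
  fams <- levels(tab$family)
  pairs <- utils::combn(fams, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- tab$score[tab$family == pairs[1, j]]
    b <- tab$score[tab$family == pairs[2, j]]
    tt <- tryCatch(stats::t.test(a, b),  # Welch
                   error = function(e) NULL)  # degenerate: zero variance
    d <- mean(a) - mean(b)
    data.frame(family1 = pairs[1, j], family2 = pairs[2, j], diff = d,
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
               p = if (is.null(tt)) as.numeric(abs(d) < 1e-15)
                   else tt$p.value)
  }))
  pw$p_holm <- stats::p.adjust(pw$p, method = "holm")
  means <- stats::aggregate(score ~ family, data = tab, FUN = mean)
  structure(list(anova = list(F = f_stat, df1 = av$Df[1],
                              df2 = av$Df[2], p = av$`Pr(>F)`[1]),
                 means = means, pairwise = pw, which = which),
            class = "tss_comparison")
}

#' @export
print.tss_comparison <- function(x, ...) {
  cat(sprintf("TSS by family (%s): F = %.2f, df = %d, %d, p = %.3g\n",
              x$which, x$anova$F, x$anova$df1, x$anova$df2, x$anova$p))
  print(x$means, row.names = FALSE)
  cat("Pairwise (Welch t, Holm-adjusted):\n")
  pw <- x$pairwise
  pw$diff <- round(pw$diff, 3); pw$t <- round(pw$t, 2)
  pw$df <- round(pw$df, 1)
  pw$p <- signif(pw$p, 3); pw$p_holm <- signif(pw$p_holm, 3)
  print(pw, row.names = FALSE)
  invisible(x)
}

# ---- hand-rolled MARS (forward hinge-basis selection, backward pruning) ----
# Least-squares MARS on the 0/1 response: forward pass greedily adds mirrored
# hinge pairs max(x - k, 0) / max(k - x, 0) at observed-quantile knots;
# backward pass prunes terms by generalised cross-validation with the
# conventional penalty of `penalty` effective parameters per knot.
# Predictions are clamped to [0, 1].

.mars_basis <- function(x, terms) {
  n <- nrow(x)
  B <- matrix(1, n, 1)
  for (tm in terms) {
    v <- x[, tm$var]
    B <- cbind(B, if (tm$dir > 0) pmax(v - tm$knot, 0) else pmax(tm$knot - v, 0))
  }
  B
}

.mars_gcv <- function(rss, n, n_terms, penalty) {
  # effective parameters: coefficients + penalty per hinge term
  c_m <- (1 + n_terms) + penalty * n_terms / 2
  rss / n / (1 - min(c_m / n, 0.99))^2
}

.fit_mars <- function(x, y, max_terms = 21L, n_knots = 15L, penalty = 3) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  n <- nrow(x)
  vars <- seq_len(ncol(x))
  knots <- lapply(vars, function(j) {
    q <- unique(stats::quantile(x[, j], probs = seq(0.05, 0.95,
                                                    length.out = n_knots)))
    q[q > min(x[, j]) & q < max(x[, j])]
  })
  terms <- list()
  B <- .mars_basis(x, terms)
  fit <- stats::lm.fit(B, y)
  rss <- sum(fit$residuals^2)
  repeat {
    if (length(terms) >= max_terms) break
    best <- NULL
    for (j in vars) {
      for (k in knots[[j]]) {
        h1 <- pmax(x[, j] - k, 0)
        h2 <- pmax(k - x[, j], 0)
        Bc <- cbind(B, h1, h2)
        f <- stats::lm.fit(Bc, y)
        r <- sum(f$residuals^2, na.rm = TRUE)
        if (is.null(best) || r < best$rss) best <- list(var = j, knot = k,
                                                        rss = r)
      }
    }
    if (is.null(best) || best$rss > rss * (1 - 1e-4)) break
    terms <- c(terms, list(list(var = best$var, knot = best$knot, dir = 1),
                           list(var = best$var, knot = best$knot, dir = -1)))
    B <- .mars_basis(x, terms)
    fit <- stats::lm.fit(B, y)
    rss <- sum(fit$residuals^2)
  }
  # backward pruning by GCV over single-term deletions
  best_terms <- terms
  best_gcv <- .mars_gcv(rss, n, length(terms), penalty)
  cur <- terms
  while (length(cur) > 0) {
    gcvs <- vapply(seq_along(cur), function(i) {
      f <- stats::lm.fit(.mars_basis(x, cur[-i]), y)
      .mars_gcv(sum(f$residuals^2), n, length(cur) - 1, penalty)
    }, numeric(1))
    i <- which.min(gcvs)
    cur <- cur[-i]
    if (gcvs[i] < best_gcv) {
      best_gcv <- gcvs[i]
      best_terms <- cur
    }
  }
  B <- .mars_basis(x, best_terms)
  fit <- stats::lm.fit(B, y)
  list(terms = best_terms, coef = fit$coefficients, gcv = best_gcv,
       varnames = colnames(x))
}

.predict_mars <- function(fit, x) {
  B <- .mars_basis(x, fit$terms)
  cf <- fit$coef
  cf[is.na(cf)] <- 0
  pmin(pmax(as.numeric(B %*% cf), 0), 1)
}
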