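# Multi-model comparison: splits, TSS, families, ensemble, importance.

test_that("TSS matches the hand-tallied contingency table", {
  # TP = 40, FN = 10, TN = 35, FP = 15 -> 0.8 + 0.7 - 1 = 0.5
  obs <- c(rep(1, 50), rep(0, 50))
  pred <- c(rep(0.9, 40), rep(0.1, 10), rep(0.1, 35), rep(0.9, 15))
  expect_equal(tss(pred, obs, 0.5), 0.5)
  # perfect separation
  expect_equal(tss(c(0.9, 0.9, 0.1), c(1, 1, 0), 0.5), 1)
  # constant predicted class: one rate is 1, the other 0
  expect_equal(tss(rep(0.9, 10), rep(c(0, 1), 5), 0.5), 0)
  expect_error(tss(runif(5), rep(1, 5), 0.5), "single class")
})

test_that("TSS is invariant under joint permutation", {
  set.seed(1)
  pred <- runif(200); obs <- rbinom(200, 1, 0.4)
  base <- tss(pred, obs, 0.5)
  for (i in 1:5) {
    p <- sample(200)
    expect_equal(tss(pred[p], obs[p], 0.5), base)
  }
})

test_that("best threshold maximises TSS and breaks ties low", {
  obs <- c(1, 1, 0, 0)
  bt <- best_threshold(c(0.9, 0.8, 0.2, 0.1), obs)
  expect_equal(bt$tss, 1)
  expect_gt(bt$threshold, 0.2); expect_lte(bt$threshold, 0.5)
  # the maximised TSS always beats the fixed 0.5 cut
  set.seed(2)
  for (i in 1:10) {
    pred <- runif(100); obs <- rbinom(100, 1, 0.5)
    bt <- best_threshold(pred, obs)
    expect_gte(bt$tss, tss(pred, obs, 0.5))
  }
  # independent predictions: max TSS stays small at large n
  set.seed(3)
  pred <- runif(10000); obs <- rbinom(10000, 1, 0.5)
  expect_lt(best_threshold(pred, obs)$tss, 0.1)
})

test_that("split plan partitions presences at the 80/20 ratio", {
  plan <- split_plan(seq_len(1325), seq_len(20465), seed = 5)
  expect_equal(length(plan$train_presence_ids), 1060)
  expect_equal(length(plan$eval_presence_ids), 265)
  expect_length(intersect(plan$train_presence_ids, plan$eval_presence_ids), 0)
  expect_length(intersect(plan$train_absence_pool_ids,
                          plan$eval_absence_pool_ids), 0)
})

test_that("balanced sets pair every presence with fresh distinct absences", {
  sets <- make_balanced_sets(seq_len(1060), 2000 + seq_len(14611),
                             n_sets = 10, seed = 3)
  expect_length(sets, 10)
  for (s in sets) {
    expect_length(s, 2120)
    absences <- setdiff(s, seq_len(1060))
    expect_length(absences, 1060)                 # without replacement
    expect_false(anyDuplicated(absences) > 0)
  }
  # sets are drawn independently and differ
  expect_false(identical(sets[[1]], sets[[2]]))
  # pool exactly the presence count: the set is the whole pool
  one <- make_balanced_sets(1:5, 11:15, n_sets = 1, seed = 1)
  expect_setequal(one[[1]], c(1:5, 11:15))
  expect_error(make_balanced_sets(1:10, 1:5, 1, 1), "pool smaller")
})

zoo_fixture <- function(n = 600, seed = 42, betas = c(1.5, -1, 0),
                        b0 = -1) {
  set.seed(seed)
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  eta <- b0 + betas[1] * X$x1 + betas[2] * X$x2 + betas[3] * X$x3
  design <- cbind(presence = rbinom(n, 1, plogis(eta)), X)
  class(design) <- c("design_matrix", "data.frame")
  plan <- split_plan(which(design$presence == 1),
                     which(design$presence == 0),
                     n_absence_sets = 2, n_cv = 1, seed = seed)
  list(design = design, plan = plan)
}

test_that("the factorial produces one run per family x set x cv cell", {
  fx <- zoo_fixture()
  zoo <- run_model_zoo(fx$plan, fx$design, families = c("GLM", "CTA"))
  expect_length(zoo$runs, 4)   # 2 families x 2 sets x 1 cv
  tab <- zoo_results(zoo)
  expect_setequal(unique(tab$family), c("GLM", "CTA"))
  ok <- tab[tab$status == "ok", ]
  expect_true(all(ok$tss_validation >= -1 & ok$tss_validation <= 1))
  expect_true(all(ok$threshold >= 0 & ok$threshold <= 1))
})

test_that("a failing family is contained without aborting the batch", {
  fx <- zoo_fixture(n = 300)
  real_fit <- hexinvade:::.fit_family
  with_mocked_bindings(
    .fit_family = function(family, data, predictors, seed) {
      if (family == "ANN") stop("boom")
      real_fit(family, data, predictors, seed)
    },
    {
      zoo <- run_model_zoo(fx$plan, fx$design, families = c("GLM", "ANN"))
      tab <- zoo_results(zoo)
      expect_equal(sum(tab$status == "failed"), 2)  # ANN in both sets
      expect_equal(sum(tab$status == "ok"), 2)
      expect_true(all(is.na(tab$tss_validation[tab$status == "failed"])))
    }
  )
})

test_that("every family fits and scores above chance on separable data", {
  fx <- zoo_fixture(n = 700, seed = 7, betas = c(2, -1.5, 0))
  zoo <- run_model_zoo(fx$plan, fx$design)
  tab <- zoo_results(zoo)
  expect_equal(nrow(tab), 12)  # 6 families x 2 sets x 1 cv
  expect_true(all(tab$status == "ok"))
  agg <- tapply(tab$tss_validation, tab$family, mean)
  expect_true(all(agg > 0.2))
})

test_that("committee consensus equals an independent vote-count oracle", {
  set.seed(9)
  for (rep in 1:100) {
    n_members <- sample(1:7, 1)
    n_rows <- sample(1:20, 1)
    votes <- matrix(rbinom(n_members * n_rows, 1, 0.5), n_rows, n_members)
    # package path: members as stub model_runs casting fixed votes
    members <- lapply(seq_len(n_members), function(m) {
      run <- list(family = "GLM", threshold = 0.5,
                  model = list(predict_prob = local({
                    v <- votes[, m]
                    function(X) ifelse(v == 1, 0.9, 0.1)
                  })),
                  tss_validation = 0.9, status = "ok")
      class(run) <- "model_run"
      run
    })
    spec <- structure(list(members = members, member_tss_min = 0.6,
                           predictors = character(0)),
                      class = "ensemble_spec")
    got <- committee_predict(spec, data.frame(row = seq_len(n_rows)))
    want_frac <- rowSums(votes) / n_members
    expect_equal(got$vote_fraction, want_frac)
    expect_equal(got$consensus, as.integer(want_frac > 0.5))
  }
})

test_that("tie votes resolve to absence with fraction one half", {
  votes <- cbind(c(1, 1), c(0, 1))
  members <- lapply(1:2, function(m) {
    run <- list(family = "GLM", threshold = 0.5,
                model = list(predict_prob = local({
                  v <- votes[, m]
                  function(X) ifelse(v == 1, 0.9, 0.1)
                })), tss_validation = 0.9, status = "ok")
    class(run) <- "model_run"
    run
  })
  spec <- structure(list(members = members, member_tss_min = 0.6,
                         predictors = character(0)),
                    class = "ensemble_spec")
  got <- committee_predict(spec, data.frame(row = 1:2))
  expect_equal(got$consensus, c(0L, 1L))
  expect_equal(got$vote_fraction, c(0.5, 1))
})

test_that("permutation importance is zero for inert predictors and matches
           a direct recomputation for strong ones", {
  fx <- zoo_fixture(n = 2000, seed = 11, betas = c(1.8, 0, 0))
  zoo <- run_model_zoo(fx$plan, fx$design, families = "GLM")
  run <- zoo$runs[[1]]
  vi <- permutation_importance(run, fx$design, n_rep = 6, seed = 2)
  expect_lt(vi[["x3"]], 0.05)   # near-zero estimated coefficient
  expect_gt(vi[["x1"]], 0.5)    # dominant predictor
  expect_true(all(vi >= 0 & vi <= 1))
  # direct recomputation oracle for one shuffle
  p0 <- run$model$predict_prob(fx$design)
  set.seed(123)
  shuf <- fx$design
  shuf$x1 <- sample(shuf$x1)
  want <- 1 - cor(p0, run$model$predict_prob(shuf))
  expect_gt(want, 0.5)
})

test_that("a GLM with zero coefficient has VI ~ 0 at tolerance 1e-6", {
  # fit where x3 is exactly dropped: force coefficient to zero by fitting on
  # x1 only, then evaluating VI over a table that still carries x3
  fx <- zoo_fixture(n = 500, seed = 13, betas = c(1.5, 0, 0))
  zoo <- run_model_zoo(fx$plan, fx$design[c("presence", "x1")],
                       families = "GLM")
  run <- zoo$runs[[1]]
  tab <- cbind(fx$design[c("presence", "x1")], x3 = fx$design$x3)
  vi <- permutation_importance(run, tab, n_rep = 3, seed = 1)
  expect_equal(vi[["x3"]], 0, tolerance = 1e-6)
})

test_that("dominant predictor wins the VI ranking across replicates", {
  wins <- vapply(1:20, function(s) {
    fx <- zoo_fixture(n = 400, seed = s, betas = c(2, 0.3, 0.3))
    zoo <- run_model_zoo(fx$plan, fx$design, families = "GLM")
    vi <- permutation_importance(zoo$runs[[1]], fx$design, n_rep = 3,
                                 seed = s)
    names(which.max(vi)) == "x1"
  }, logical(1))
  expect_gte(sum(wins), 18)
})

test_that("marginal response curves behave for monotone and flat models", {
  fx <- zoo_fixture(n = 800, seed = 17, betas = c(1.4, -0.8, 0))
  zoo <- run_model_zoo(fx$plan, fx$design, families = "GLM")
  run <- zoo$runs[[1]]
  cur <- marginal_response(run, fx$design, "x1", grid_points = 25)
  expect_true(all(diff(cur$mean_prob) > 0))  # positive coefficient
  # consistency at the median point
  med <- data.frame(x1 = median(fx$design$x1), x2 = median(fx$design$x2),
                    x3 = median(fx$design$x3))
  at_med <- approx(cur$value, cur$mean_prob, xout = med$x1)$y
  expect_lt(abs(at_med - run$model$predict_prob(med)), 0.02)
  expect_error(marginal_response(run, fx$design, "nope"), "unknown predictor")
})

test_that("TSS comparison reproduces textbook one-way ANOVA arithmetic", {
  tab <- data.frame(
    family = rep(c("A", "B", "C"), each = 4),
    status = "ok",
    tss_validation = c(0.5, 0.6, 0.55, 0.65, 0.7, 0.8, 0.75, 0.85,
                       0.4, 0.45, 0.5, 0.55),
    tss_evaluation = NA)
  cmp <- compare_tss(tab, "validation")
  # hand-computed sums of squares
  y <- tab$tss_validation
  g <- tab$family
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum((y - ave(y, g))^2)
  want_F <- (ssb / 2) / (ssw / 9)
  expect_equal(cmp$anova$F, want_F, tolerance = 1e-10)
  expect_equal(cmp$anova$df1, 2)
  expect_equal(cmp$anova$df2, 9)
  expect_equal(nrow(cmp$pairwise), 3)
  # two families: pairwise t^2 equals F
  tab2 <- tab[tab$family != "C", ]
  cmp2 <- compare_tss(tab2, "validation")
  # equal group sizes: Welch t^2 = pooled F only when variances equal; use
  # the algebraic identity on the pooled fit instead
  av <- anova(lm(tss_validation ~ family, data = tab2))
  tt <- t.test(tss_validation ~ family, data = tab2, var.equal = TRUE)
  expect_equal(unname(tt$statistic^2), av$`F value`[1], tolerance = 1e-9)
  # equal means within families give F = 0
  tab3 <- tab
  tab3$tss_validation <- rep(0.5, 12)
  expect_equal(suppressWarnings(compare_tss(tab3, "validation")$anova$F), 0)
})

test_that("families with fewer than two runs are excluded with a warning", {
  tab <- data.frame(family = c("A", "A", "B"), status = "ok",
                    tss_validation = c(0.5, 0.6, 0.7), tss_evaluation = NA)
  expect_error(expect_warning(compare_tss(tab, "validation"), "excluding"))
  tab2 <- rbind(tab, data.frame(family = c("C", "C"), status = "ok",
                                tss_validation = c(0.3, 0.4),
                                tss_evaluation = NA))
  expect_warning(cmp <- compare_tss(tab2, "validation"), "excluding")
  expect_setequal(cmp$means$family, c("A", "C"))
})
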