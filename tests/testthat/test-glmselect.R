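# Logistic model fitting, screening, elimination and AIC comparison.

test_that("intercept-only fit on balanced data gives a zero intercept", {
  X <- data.frame(presence = rep(c(0, 1), each = 50))
  f <- fit_logistic(X, predictors = character(0))
  expect_equal(unname(coef(f)), 0, tolerance = 1e-8)
  expect_equal(f$k, 1)
})

test_that("a 2x2 table recovers the closed-form log odds ratio", {
  # cells (x=0: 30 absent, 10 present), (x=1: 10 absent, 30 present)
  X <- data.frame(presence = c(rep(0, 30), rep(1, 10), rep(0, 10), rep(1, 30)),
                  x = c(rep(0, 40), rep(1, 40)))
  f <- fit_logistic(X)
  expect_equal(unname(coef(f)["x"]), log(9), tolerance = 1e-6)
  expect_equal(unname(coef(f)["x"]), 2.1972, tolerance = 1e-4)
})

test_that("fitted probabilities average to the observed prevalence", {
  for (seed in 1:3) {
    X <- toy_design(n = 300, seed = seed, betas = c(0.8, -1.2))
    f <- fit_logistic(X)
    expect_equal(mean(predict(f, X)), mean(X$presence), tolerance = 1e-6)
  }
})

test_that("coefficients match direct likelihood maximisation", {
  # IRLS-fitted coefficients vs an independent BFGS maximisation of the
  # Bernoulli log-likelihood on random small designs
  for (seed in 1:10) {
    set.seed(seed + 100)
    X <- toy_design(n = 200, seed = seed, betas = rnorm(3, 0, 0.8))
    f <- fit_logistic(X)
    want <- oracle_logistic(X[c("x1", "x2", "x3")], X$presence)
    expect_equal(unname(coef(f)), want, tolerance = 1e-5)
  }
})

test_that("AIC identity holds exactly and likelihood is monotone in terms", {
  for (seed in 1:5) {
    X <- toy_design(n = 150, seed = seed, betas = c(0.5, 0, -0.3))
    f0 <- fit_logistic(X, predictors = c("x1", "x2"))
    f1 <- fit_logistic(X, predictors = c("x1", "x2", "x3"))
    expect_identical(f0$aic - (2 * f0$k - 2 * f0$log_likelihood), 0)
    expect_identical(f1$aic - (2 * f1$k - 2 * f1$log_likelihood), 0)
    expect_gte(f1$log_likelihood, f0$log_likelihood - 1e-10)
  }
})

test_that("degenerate designs are caught", {
  X <- toy_design(n = 100, seed = 1)
  expect_error(fit_logistic(data.frame(presence = rep(1, 10), x = rnorm(10))),
               "at least one")
  X$dup <- X$x1
  expect_error(fit_logistic(X), "dup")
  # complete separation warns and flags non-convergence
  Xs <- data.frame(presence = rep(c(0, 1), each = 20),
                   x = c(rnorm(20, -5), rnorm(20, 5)))
  expect_warning(fs <- fit_logistic(Xs), "separation")
  expect_false(fs$converged)
})

test_that("odds ratios reproduce printed worked examples", {
  # published coefficient/odds-ratio pairs from a fitted occurrence model
  expect_equal(odds_ratio(1.147, 0.158)$or, 3.149, tolerance = 5e-4)
  expect_equal(odds_ratio(-0.803, 0.304)$or, 0.448, tolerance = 1e-3)
  expect_equal(odds_ratio(0.403, 0.060)$or, 1.496, tolerance = 5e-4)
  expect_equal(odds_ratio(0.154, 0.058)$or, 1.166, tolerance = 5e-4)
  expect_equal(odds_ratio(0, 1)$or, 1)
  # Wald interval, e.g. exp(1.147 +/- 1.96 * 0.158) ~ (2.315, 4.296)
  ci <- odds_ratio(1.147, 0.158)
  expect_equal(ci$low, 2.315, tolerance = 5e-3)
  expect_equal(ci$high, 4.296, tolerance = 5e-3)
  expect_error(odds_ratio(1, 0), "positive")
})

test_that("orthogonal predictors all survive screening with unit VIFs", {
  set.seed(2)
  n <- 120
  X <- data.frame(presence = rbinom(n, 1, 0.5),
                  a = rep(c(-1, 1), n / 2),
                  b = rep(c(-1, -1, 1, 1), n / 4),
                  c = rnorm(n))
  X$a <- X$a - mean(X$a); X$b <- X$b - mean(X$b)
  scr <- screen_predictors(X)
  expect_setequal(scr$retained, c("a", "b", "c"))
  expect_equal(nrow(scr$report), 0)
})

test_that("duplicated and near-collinear columns are dropped like an R2 oracle", {
  set.seed(3)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  x3 <- x1 + x2 + rnorm(n, sd = 0.05)
  X <- data.frame(presence = rbinom(n, 1, plogis(x1)), x1 = x1, x2 = x2,
                  x3 = x3)
  # oracle VIF of x3 from a hand-rolled R^2
  r2 <- summary(lm(x3 ~ x1 + x2))$r.squared
  expect_gt(1 / (1 - r2), 5)
  scr <- screen_predictors(X)
  expect_false("x3" %in% scr$retained)
  expect_true(all(c("x1", "x2") %in% scr$retained))

  Xd <- data.frame(presence = X$presence, x1 = x1, x1b = x1, x2 = x2)
  scr2 <- screen_predictors(Xd)
  expect_equal(sum(c("x1", "x1b") %in% scr2$retained), 1)

  Xc <- data.frame(presence = X$presence, x1 = x1, const = 1)
  expect_warning(scr3 <- screen_predictors(Xc), "constant")
  expect_equal(scr3$retained, "x1")
})

test_that("backward elimination drops noise, honours keep, never raises AIC", {
  set.seed(4)
  n <- 600
  X <- data.frame(presence = NA, signal = rnorm(n), n1 = rnorm(n),
                  n2 = rnorm(n), n3 = rnorm(n), spatial = rnorm(n))
  X$presence <- rbinom(n, 1, plogis(1.2 * X$signal))
  fit <- backward_eliminate(X, keep = "spatial")
  expect_true("spatial" %in% fit$predictors)    # keep contract
  expect_true("signal" %in% fit$predictors)
  full <- fit_logistic(X)
  expect_lte(fit$aic, full$aic)                 # stopping rule
  # pure-noise terms are mostly eliminated across replicates
  kept_noise <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 400
    Xn <- data.frame(presence = rbinom(n, 1, 0.3), a = rnorm(n),
                     b = rnorm(n), c = rnorm(n), d = rnorm(n))
    length(backward_eliminate(Xn)$predictors)
  }, numeric(1))
  expect_gte(sum(kept_noise <= 1), 8)
})

test_that("AIC comparison reproduces printed model-selection arithmetic", {
  # published AIC column of a candidate-model table
  aic <- c(all_combined = 2481.7, host = 2943.2, topography = 2998.2,
           transport = 3044.3, weather = 3109.8, spatial_only = 3437.6,
           intercept_only = 3675.7)
  tab <- aic_compare(aic)
  expect_equal(tab$delta_aic[tab$model == "host"], 461.5)
  expect_equal(tab$delta_aic[tab$model == "spatial_only"], 955.9)
  expect_equal(tab$delta_aic[tab$model == "intercept_only"], 1194.0)
  expect_equal(min(tab$delta_aic), 0)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  expect_false(is.unsorted(tab$aic))
})

test_that("identical AICs split the Akaike weight evenly", {
  tab <- aic_compare(c(m1 = 100, m2 = 100))
  expect_equal(tab$delta_aic, c(0, 0))
  expect_equal(tab$weight, c(0.5, 0.5))
})

test_that("models on different responses cannot be compared", {
  X1 <- toy_design(n = 100, seed = 1)
  X2 <- toy_design(n = 120, seed = 2)
  f1 <- fit_logistic(X1); f2 <- fit_logistic(X2)
  expect_error(compare_models(list(a = f1, b = f2)), "different response")
})

test_that("an all-zero spatial column selects the smallest shape by the tie rule", {
  g <- small_grid(0.1)
  # presences exist only in the far past: every candidate pressure column is 0
  occ <- occurrence_table(
    data.frame(hex_id = c(1, 2, 3, 4, 5, 6),
               year = c(1990, rep(2006, 5)),
               presence = c(1L, 1L, 1L, 0L, 0L, 0L)),
    first_year = 1990)
  ks <- select_kernel_shape(occ, g, years = 2006, seed = 1)
  expect_equal(ks$best_a, 1)
  expect_equal(length(unique(round(ks$table$aic, 9))), 1)
})

test_that("wald CI coverage of the generating coefficients is nominal", {
  # conditional simulation: fixed design, response redrawn from the true
  # logistic model; 95% CI coverage per coefficient should be ~0.95
  set.seed(77)
  n <- 800
  design <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  truth <- c(b0 = -1, x1 = 0.7, x2 = -0.4)
  hits <- matrix(0L, 100, 3)
  for (r in 1:100) {
    eta <- truth[1] + truth[2] * design$x1 + truth[3] * design$x2
    X <- cbind(presence = rbinom(n, 1, plogis(eta)), design)
    f <- fit_logistic(X)
    tab <- f$coefficients
    lo <- tab$estimate - 1.96 * tab$se
    hi <- tab$estimate + 1.96 * tab$se
    hits[r, ] <- as.integer(lo <= truth & truth <= hi)
  }
  cov <- colMeans(hits)
  expect_true(all(cov >= 0.90 & cov <= 0.99))
})
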