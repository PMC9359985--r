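test_that("GLM recovers the closed-form two-cell logistic MLE", {
  # 2/10 presences at x = 0, 8/10 at x = 1: intercept ln(1/4), slope ln(16)
  X <- data.frame(x = c(rep(0, 10), rep(1, 10)))
  y <- c(rep(1, 2), rep(0, 8), rep(1, 8), rep(0, 2))
  d <- manual_design(X, y)
  fit <- fit_glm(d, terms = "linear")
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(1 / 4),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["x"]), log(16), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("GLM matches stats::glm on weighted designs and balanced prevalence", {
  d <- make_logistic_design(n = 500, beta = c(-0.5, 2, -1), seed = 3,
                            balanced_weights = TRUE)
  fit <- fit_glm(d, terms = "linear")
  ref <- suppressWarnings(
    stats::glm(d$y ~ x1 + x2, data = d$X, weights = d$w,
               family = stats::binomial()))
  expect_equal(unname(fit$coefficients),
               unname(stats::coef(ref)[names(fit$coefficients)]),
               tolerance = 1e-6)
  # intercept-only model on a balanced design predicts 0.5 everywhere
  d0 <- d; d0$X <- data.frame(z = rep(1, length(d$y))); d0$variables <- "z"
  fit0 <- fit_glm(d0, terms = "linear")
  expect_equal(predict(fit0, d0$X), rep(0.5, length(d$y)), tolerance = 1e-8)
  # zero-variance covariate is excluded, coefficient absent
  dz <- d; dz$X$flat <- 1; dz$variables <- c("x1", "x2", "flat")
  fitz <- fit_glm(dz, terms = "linear")
  expect_false("flat" %in% names(fitz$coefficients))
})

test_that("GLM recovers known coefficients within 3 SE on n = 2000", {
  beta <- c(-0.4, 1.5, -2)
  d <- make_logistic_design(n = 2000, beta = beta, seed = 8)
  fit <- fit_glm(d, terms = "linear")
  ref <- stats::glm(d$y ~ x1 + x2, data = d$X, family = stats::binomial())
  se <- summary(ref)$coefficients[, "Std. Error"]
  est <- fit$coefficients[c("(Intercept)", "x1", "x2")]
  expect_true(all(abs(est - beta) < 3 * se))
})

test_that("GLM flags perfect separation without crashing", {
  X <- data.frame(x = c(1:10, 21:30))
  d <- manual_design(X, y = rep(c(0, 1), each = 10))
  expect_warning(fit <- fit_glm(d, terms = "linear"), "separation")
  expect_true(fit$separation)
  expect_true(all(predict(fit, X) >= 0 & predict(fit, X) <= 1))
})

test_that("SRE envelopes are presence quantiles under the declared rule", {
  set.seed(14)
  xp <- sort(runif(200, 1, 100))
  X <- data.frame(v = c(xp, runif(100, -50, 200)))
  d <- manual_design(X, y = c(rep(1, 200), rep(0, 100)))
  fit <- fit_sre(d, alpha = 0.025)
  expect_equal(unname(fit$envelope[, "v"]),
               unname(quantile(xp, c(0.025, 0.975), type = 7)))
  # alpha = 0: full presence span; inside -> 1, outside -> 0
  fit0 <- fit_sre(d, alpha = 0)
  expect_equal(predict(fit0, data.frame(v = 50)), 1)
  expect_equal(predict(fit0, data.frame(v = max(xp) + 1)), 0)
  expect_true(all(predict(fit, X) %in% c(0, 1)))
  expect_error(fit_sre(d, alpha = 0.5), "alpha")
})

test_that("SRE presence coverage respects the quantile union bound", {
  set.seed(15)
  n <- 400
  X <- data.frame(a = runif(n), b = rnorm(n), c = rexp(n))
  d <- manual_design(X, y = rep(c(1, 0), each = n / 2))
  alpha <- 0.05
  fit <- fit_sre(d, alpha = alpha)
  pres_pred <- predict(fit, X[d$y == 1, ])
  expect_gte(mean(pres_pred), 1 - 2 * alpha * ncol(X))
})

test_that("CTA root split equals the exhaustive minimum-Gini split", {
  exhaustive_root <- function(X, y, w) {
    best <- list(gini = Inf)
    for (v in seq_along(X)) {
      xs <- sort(unique(X[[v]]))
      if (length(xs) < 2) next
      for (cut in (xs[-1] + xs[-length(xs)]) / 2) {
        L <- X[[v]] < cut
        gini_part <- function(sel) {
          W <- sum(w[sel]); if (W == 0) return(0)
          p <- sum(w[sel] * y[sel]) / W
          2 * p * (1 - p) * W
        }
        g <- gini_part(L) + gini_part(!L)
        if (g < best$gini - 1e-12) best <- list(gini = g, var = v, cut = cut)
      }
    }
    best
  }
  set.seed(19)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    X <- data.frame(a = round(runif(n), 2), b = round(rnorm(n), 2))
    y <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- 1L - y[1]
    w <- round(runif(n, 0.5, 2), 2)
    d <- manual_design(X, y, w)
    fit <- fit_cta(d, max_depth = 1, min_node_weight = 0)
    oracle <- exhaustive_root(X, y, w)
    gini_at <- function(v, cut) {
      L <- X[[v]] < cut
      part <- function(sel) {
        W <- sum(w[sel]); if (W == 0) return(0)
        p <- sum(w[sel] * y[sel]) / W
        2 * p * (1 - p) * W
      }
      part(L) + part(!L)
    }
    root_gini <- {
      W <- sum(w); p <- sum(w * y) / W; 2 * p * (1 - p) * W
    }
    if (is.na(fit$tree$var[1])) {
      # refused to split: no split strictly improves on the root impurity
      expect_gte(oracle$gini, root_gini - 1e-9)
    } else {
      # the chosen split achieves the exhaustive minimum impurity (equally
      # good splits may differ in variable/value only when impurities tie)
      expect_equal(gini_at(fit$tree$var[1], fit$tree$split[1]), oracle$gini,
                   tolerance = 1e-9)
    }
  }
})

test_that("CTA handles separable data, depth 0, and stays in [0, 1]", {
  X <- data.frame(x = c(1:5, 11:15))
  d <- manual_design(X, y = rep(c(0L, 1L), each = 5))
  fit <- fit_cta(d, max_depth = 3)
  expect_equal(sort(unique(predict(fit, X))), c(0, 1))
  expect_equal(predict(fit, data.frame(x = 0)), 0)
  expect_equal(predict(fit, data.frame(x = 20)), 1)
  # depth 0: single leaf at the weighted prevalence
  d2 <- make_logistic_design(n = 100, seed = 2, balanced_weights = TRUE)
  stump <- fit_cta(d2, max_depth = 0)
  expect_equal(unique(predict(stump, d2$X)), 0.5)
  # training AUC at least chance
  full <- fit_cta(d2, max_depth = 5)
  p <- predict(full, d2$X)
  expect_gte(auc(p[d2$y == 1], p[d2$y == 0]), 0.5)
})

test_that("GBM: zero trees, separable data, and per-stage deviance decrease", {
  d <- make_logistic_design(n = 200, seed = 6, balanced_weights = TRUE)
  null_fit <- fit_gbm(d, n_trees = 0)
  expect_equal(unique(predict(null_fit, d$X)), 0.5)  # logit of prevalence
  # monotone separable 1-D data: training AUC hits 1
  Xs <- data.frame(x = 1:40)
  ds <- manual_design(Xs, y = rep(c(0L, 1L), each = 20))
  sep_fit <- fit_gbm(ds, n_trees = 100)
  ps <- predict(sep_fit, Xs)
  expect_equal(auc(ps[ds$y == 1], ps[ds$y == 0]), 1)
  # weighted training deviance is non-increasing across stages
  fit <- fit_gbm(d, n_trees = 150)
  expect_true(all(diff(fit$train_deviance) <= 1e-9))
  p <- predict(fit, d$X)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(auc(p[d$y == 1], p[d$y == 0]), 0.5)
})

test_that("all algorithms are deterministic and bounded on a common design", {
  d <- make_logistic_design(n = 150, seed = 10, balanced_weights = TRUE)
  for (algo in default_algorithms(gbm_n_trees = 30)) {
    f1 <- algo(d); f2 <- algo(d)
    p1 <- predict(f1, d$X); p2 <- predict(f2, d$X)
    expect_identical(p1, p2)
    expect_true(all(p1 >= 0 & p1 <= 1))
  }
})

test_that("adapters obey the uniform contract and feed the ensemble", {
  # a trivial 'mean of covariates through plogis' adapter
  fit_toy <- sdm_adapter("TOY",
                         function(design) colMeans(design$X),
                         function(model, X) plogis(rowMeans(X) - mean(model)))
  d <- make_logistic_design(n = 120, seed = 1, balanced_weights = TRUE)
  m <- fit_toy(d)
  expect_s3_class(m, "sdm_adapter_model")
  p <- predict(m, d$X)
  expect_true(all(p >= 0 & p <= 1))
  # an adapter violating the [0, 1] contract is caught
  fit_bad <- sdm_adapter("BAD", function(design) NULL,
                         function(model, X) rowMeans(X) * 100)
  expect_error(predict(fit_bad(d), d$X), "outside")
})

test_that("map predictions agree with pointwise predictions and propagate nodata", {
  set.seed(23)
  g1 <- sdm_grid(matrix(runif(200), 10, 20))
  g2 <- sdm_grid(matrix(runif(200), 10, 20))
  g2$values[1, 1] <- NA
  st <- sdm_stack(list(x1 = g1, x2 = g2))
  pres <- data.frame(x = runif(40, 0, 20), y = runif(40, 0, 9))
  bg <- data.frame(x = runif(80, 0, 20), y = runif(80, 0, 9))
  d <- build_design(pres, bg, st)
  fit <- fit_glm(d)
  mp <- predict_map(fit, st)
  expect_true(is.na(mp$values[1, 1]))
  pts <- stack_extract(st, pres$x, pres$y)
  ok <- complete.cases(pts)
  expect_equal(grid_extract(mp, pres$x, pres$y)[ok],
               unname(predict(fit, pts[ok, ])))
  # SRE maps are binary; intercept-only GLM maps are constant
  sre_map <- predict_map(fit_sre(d), st)
  expect_true(all(sre_map$values[!is.na(sre_map$values)] %in% c(0, 1)))
  expect_error(predict_map(fit, sdm_stack(list(x1 = g1))), "lacks")
})
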