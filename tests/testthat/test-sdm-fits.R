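# Simulate a labeled table from a known logistic model of woodland cover.
simulate_logistic <- function(n, beta0, beta_wood, seed) {
  withr::local_seed(seed)
  x <- runif(n)
  p <- plogis(beta0 + beta_wood * x)
  y <- rbinom(n, 1, p)
  make_table(woodland = x,
             label = ifelse(y == 1, "presence", "pseudo_absence"))
}

test_that("balanced intercept-only data give a zero intercept and p = 0.5", {
  tab <- make_table(woodland = c(runif(50, 0.4, 0.6), runif(50, 0.4, 0.6)),
                    label = rep(c("presence", "pseudo_absence"), each = 50))
  # constant-signal check via an explicitly balanced, symmetric design
  tab$woodland <- rep(0.5, 100) + rep(c(-0.1, 0.1), 50)
  fit <- fit_sdm_glm(tab)
  expect_equal(unname(fit$coefficients["(intercept)"]), 0, tolerance = 1e-6)
  expect_equal(mean(predict(fit, tab)), 0.5, tolerance = 1e-6)
})

test_that("ridge IRLS matches stats::glm away from separation", {
  tab <- simulate_logistic(400, -0.5, 2, seed = 7)
  fit <- fit_sdm_glm(tab)
  ref <- stats::glm(I(label == "presence") ~ woodland, data = tab,
                    family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("perfect separation yields finite coefficients on the right side", {
  tab <- make_table(woodland = c(0.8, 0.9, 0.95, 0.1, 0.2, 0.05),
                    label = rep(c("presence", "pseudo_absence"), each = 3))
  fit <- suppressWarnings(fit_sdm_glm(tab))
  expect_true(all(is.finite(fit$coefficients)))
  p <- predict(fit, tab)
  expect_true(all(p[1:3] > 0.5) && all(p[4:6] < 0.5))
})

test_that("single-class labels and zero-variance covariates are rejected", {
  tab <- make_table(woodland = runif(10), label = rep("presence", 10))
  expect_error(fit_sdm_glm(tab), "single class")
  expect_error(fit_sdm_gbm(tab), "single class")
  tab2 <- make_table(woodland = rep(0.3, 10),
                     label = rep(c("presence", "pseudo_absence"), 5))
  expect_error(fit_sdm_glm(tab2), "zero-variance")
})

test_that("GLM recovers known coefficients within 3 SE on simulated data", {
  hits <- vapply(1:25, function(s) {
    tab <- simulate_logistic(2000, -1, 2, seed = 1000 + s)
    fit <- fit_sdm_glm(tab)
    all(abs(fit$coefficients - c(-1, 2)) <= 3 * fit$se)
  }, TRUE)
  expect_gte(mean(hits), 0.95 - 1e-9)
})

test_that("a single stump separates threshold data perfectly", {
  tab <- make_table(woodland = c(seq(0.6, 0.9, length.out = 10),
                                 seq(0.1, 0.4, length.out = 10)),
                    label = rep(c("presence", "pseudo_absence"), each = 10))
  fit <- fit_sdm_gbm(tab, n_stages = 1L, learning_rate = 1, max_depth = 1L)
  p <- predict(fit, tab)
  expect_equal(mean((p > 0.5) == (tab$label == "presence")), 1.0)
})

test_that("GBM training deviance is non-increasing across stages", {
  tab <- simulate_logistic(300, -0.5, 3, seed = 11)
  fit <- fit_sdm_gbm(tab, n_stages = 60L)
  expect_false(is.null(fit$train_deviance))
  expect_true(all(diff(fit$train_deviance) <= 1e-10))
})

test_that("GBM beats GLM on step-function suitability in most splits", {
  wins <- vapply(1:50, function(s) {
    withr::local_seed(2000 + s)
    x <- runif(240)
    p <- ifelse(x > 0.3 & x < 0.6, 0.9, 0.1)  # nonlinear in cover
    y <- rbinom(240, 1, p)
    tab <- make_table(woodland = x,
                      label = ifelse(y == 1, "presence", "pseudo_absence"))
    if (length(unique(tab$label)) < 2) return(NA)
    tr <- sample(240, 180)
    tr_tab <- tab[tr, ]
    attr(tr_tab, "covariate_classes") <- "woodland"
    if (length(unique(tr_tab$label)) < 2) return(NA)
    g1 <- fit_sdm_glm(tr_tab)
    g2 <- fit_sdm_gbm(tr_tab, n_stages = 100L)
    te <- setdiff(1:240, tr)
    evaluate_auc(predict(g2, tab[te, ]), tab$label[te]) >
      evaluate_auc(predict(g1, tab[te, ]), tab$label[te])
  }, TRUE)
  expect_gte(mean(wins, na.rm = TRUE), 0.8)
})

test_that("maxent shrinks to no effect when presences mirror the background", {
  withr::local_seed(5)
  x <- runif(300)
  tab <- make_table(woodland = x,
                    label = rep(c("presence", "pseudo_absence"), length.out = 300))
  fit <- fit_sdm_maxent(tab, l1_penalty = 0.05)
  expect_lt(max(abs(fit$weights)), 0.05)
})

test_that("maxent picks up the sign of a woodland-only presence signal", {
  tab <- make_table(woodland = c(rep(1, 40), runif(200)),
                    label = c(rep("presence", 40), rep("pseudo_absence", 200)))
  fit <- fit_sdm_maxent(tab, features = "linear", l1_penalty = 0.01)
  expect_gt(fit$weights[["woodland"]], 0)
})

test_that("unpenalized maxent matches the empirical presence moment and optim", {
  # toy 4-cell landscape, one linear feature, penalty 0
  bg <- c(0.0, 0.25, 0.5, 1.0)
  pres <- c(0.5, 1.0, 1.0)
  tab <- make_table(woodland = c(pres, bg),
                    label = c(rep("presence", 3), rep("pseudo_absence", 4)))
  fit <- fit_sdm_maxent(tab, features = "linear", l1_penalty = 0)
  # moment matching: E_gibbs[f] over the background equals the presence mean
  w <- fit$weights[[1]]
  fs <- (bg - fit$center) / fit$scale
  q <- exp(fs * w)
  q <- q / sum(q)
  expect_equal(sum(q * fs), mean((pres - fit$center) / fit$scale),
               tolerance = 1e-6)
  # independent route: direct numeric optimization of the Gibbs likelihood
  nll <- function(wv) {
    -mean((pres - fit$center) / fit$scale) * wv +
      log(mean(exp(fs * wv)))
  }
  opt <- optim(0, nll, method = "BFGS")
  expect_equal(w, opt$par, tolerance = 1e-4)
})

test_that("all fits are reproducible and bounded in [0, 1]", {
  tab <- simulate_logistic(200, -1, 2, seed = 31)
  for (fitter in list(function(t) fit_sdm_glm(t),
                      function(t) fit_sdm_gbm(t, n_stages = 30L, seed = 4),
                      function(t) fit_sdm_maxent(t, seed = 4))) {
    p1 <- predict(fitter(tab), tab)
    p2 <- predict(fitter(tab), tab)
    expect_identical(p1, p2)
    expect_true(all(p1 >= 0 & p1 <= 1))
  }
})
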