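test_that("AUC handles perfect ranking, all ties, and the worked example", {
  lab <- c("presence", "presence", "pseudo_absence", "pseudo_absence")
  expect_equal(evaluate_auc(c(0.9, 0.8, 0.2, 0.1), lab), 1.0)
  expect_equal(evaluate_auc(rep(0.5, 4), lab), 0.5)
  expect_equal(evaluate_auc(c(0.9, 0.4, 0.8, 0.2), lab), 0.75)
  expect_error(evaluate_auc(1:3, rep("presence", 3)), "both classes")
})

test_that("AUC equals the Mann-Whitney pairwise oracle on random instances", {
  withr::local_seed(99)
  for (i in 1:60) {
    n1 <- sample(2:8, 1)
    n0 <- sample(2:8, 1)
    scores <- round(runif(n1 + n0), 2)  # rounding forces ties
    labels <- c(rep("presence", n1), rep("pseudo_absence", n0))
    expect_equal(evaluate_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
    # cross-check against the U statistic of wilcox.test
    u <- suppressWarnings(stats::wilcox.test(
      scores[1:n1], scores[-(1:n1)])$statistic)
    expect_equal(evaluate_auc(scores, labels), unname(u) / (n1 * n0),
                 tolerance = 1e-12)
  }
})

test_that("TSS handles separation, ties, and the worked example", {
  lab <- c("presence", "presence", "pseudo_absence", "pseudo_absence")
  expect_equal(evaluate_tss(c(0.9, 0.8, 0.2, 0.1), lab), 1.0)
  expect_equal(evaluate_tss(rep(0.5, 4), lab), 0.0)
  expect_equal(evaluate_tss(c(0.9, 0.4, 0.8, 0.2), lab), 0.5)
})

test_that("TSS is invariant to strictly monotone transforms of the scores", {
  withr::local_seed(17)
  for (i in 1:25) {
    scores <- runif(12)
    labels <- sample(c("presence", "pseudo_absence"), 12, replace = TRUE)
    if (length(unique(labels)) < 2) next
    t0 <- evaluate_tss(scores, labels)
    expect_equal(evaluate_tss(qlogis(scores), labels), t0)
    expect_equal(evaluate_tss(scores^3, labels), t0)
    expect_equal(evaluate_tss(exp(scores), labels), t0)
  }
})

test_that("replicated splits are stratified, shared across models, and seeded", {
  tab <- make_table(woodland = c(runif(40, 0.5, 1), runif(60, 0, 0.5)),
                    label = c(rep("presence", 40), rep("pseudo_absence", 60)))
  fitters <- list(glm = function(t) fit_sdm_glm(t),
                  gbm = function(t) fit_sdm_gbm(t, n_stages = 20L))
  ev <- cross_validate(tab, fitters, seed = 5)
  expect_equal(nrow(ev), 6)  # 3 replicates per model kind
  expect_equal(as.vector(table(ev$model)), c(3L, 3L))
  expect_true(all(ev$auc >= 0 & ev$auc <= 1))
  expect_true(all(ev$tss >= -1 & ev$tss <= 1))

  ev2 <- cross_validate(tab, fitters, seed = 5)
  expect_identical(attr(ev, "splits"), attr(ev2, "splits"))
  expect_equal(ev$auc, ev2$auc)

  # splits preserve the presence:pseudo-absence ratio
  sp <- attr(ev, "splits")[[1]]
  expect_equal(sum(tab$label[sp$train] == "presence"), 30)
  expect_equal(length(sp$train), 75)

  expect_error(cross_validate(tab, fitters, train_fraction = 1.0),
               "strictly between")
  expect_error(cross_validate(tab, fitters, train_fraction = 0), "strictly")
})

test_that("ensemble weights follow mean test AUC and predictions stay bounded", {
  tab <- make_table(woodland = c(runif(30, 0.5, 1), runif(30, 0, 0.5)),
                    label = rep(c("presence", "pseudo_absence"), each = 30))
  fitters <- list(glm = function(t) fit_sdm_glm(t),
                  maxent = function(t) fit_sdm_maxent(t, l1_penalty = 0.01))
  ev <- cross_validate(tab, fitters, seed = 2)
  members <- lapply(fitters, function(f) f(tab))
  ens <- sdm_ensemble(members, ev)
  expect_equal(sum(ens$weights), 1, tolerance = 1e-12)
  mean_auc <- tapply(ev$auc, ev$model, mean)[names(ens$weights)]
  expect_equal(unname(ens$weights), as.vector(mean_auc / sum(mean_auc)),
               tolerance = 1e-12)
  p <- predict(ens, tab)
  members_p <- sapply(members, predict, newdata = tab)
  expect_true(all(p >= apply(members_p, 1, min) - 1e-12))
  expect_true(all(p <= apply(members_p, 1, max) + 1e-12))
})

test_that("closed-form ensemble averaging cases hold", {
  # stub members with fixed predictions exercise the weighting arithmetic
  stub <- function(value) {
    f <- list(kind = "stub", classes = "woodland", value = value)
    class(f) <- c("sdm_stub", "sdm_fit")
    f
  }
  assign("predict.sdm_stub",
         function(object, newdata, ...) rep(object$value, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.sdm_stub", envir = globalenv()))
  registerS3method("predict", "sdm_stub", get("predict.sdm_stub"),
                   envir = globalenv())
  newdata <- data.frame(woodland = 0.5)

  ev_eq <- data.frame(model = c("a", "b"), replicate = 1, auc = c(0.7, 0.7),
                      tss = 0)
  ens <- sdm_ensemble(list(a = stub(0.2), b = stub(0.8)), ev_eq)
  expect_equal(predict(ens, newdata), 0.5)

  ens1 <- sdm_ensemble(list(a = stub(0.37)), ev_eq[1, ])
  expect_equal(predict(ens1, newdata), 0.37)

  ev_w <- data.frame(model = c("a", "b"), replicate = 1, auc = c(0.8, 0.6),
                     tss = 0)
  ens2 <- sdm_ensemble(list(a = stub(1.0), b = stub(0.0)), ev_w)
  expect_equal(predict(ens2, newdata), 0.8 / 1.4, tolerance = 1e-12)

  expect_error(sdm_ensemble(list(a = stub(1)),
                            data.frame(model = "a", replicate = 1, auc = 0,
                                       tss = 0)),
               "all ensemble weights are zero")
})

test_that("randomization importance is zero for ignored variables and exact", {
  tab <- make_table(woodland = runif(60), urban = runif(60),
                    label = rep(c("presence", "pseudo_absence"), 30))
  fit <- fit_sdm_glm(tab)
  fit$coefficients["urban"] <- 0  # force the model to ignore urban
  imp <- variable_importance(fit, tab, n_permutations = 3, seed = 1)
  expect_equal(imp$importance[imp$variable == "urban"], 0)
  expect_true(all(imp$importance >= 0 & imp$importance <= 1))

  # single informative variable: importance is maximal for it
  tab1 <- make_table(woodland = c(runif(30, 0.6, 1), runif(30, 0, 0.4)),
                     urban = runif(60),
                     label = rep(c("presence", "pseudo_absence"), each = 30))
  fit1 <- fit_sdm_glm(tab1)
  imp1 <- variable_importance(fit1, tab1, n_permutations = 5, seed = 2)
  expect_equal(imp1$variable[which.max(imp1$importance)], "woodland")

  # one permutation with a fixed seed equals the hand-computed 1 - |r|
  imp2 <- variable_importance(fit1, tab1, n_permutations = 1, seed = 7)
  p0 <- predict(fit1, tab1)
  hand <- withr::with_seed(7, {
    out <- numeric(0)
    for (v in c("woodland", "urban")) {
      tabp <- tab1
      tabp[[v]] <- tabp[[v]][sample.int(60)]
      out <- c(out, 1 - abs(cor(p0, predict(fit1, tabp))))
    }
    out
  })
  expect_equal(imp2$importance, hand, tolerance = 1e-12)
})
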