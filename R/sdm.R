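#' Species distribution model fits
#'
#' Three model families share the `sdm_fit` interface: a binomial-logit GLM
#' fitted by ridge-stabilised iteratively reweighted least squares, a
#' gradient-boosted tree model, and a maximum-entropy (Gibbs) model over the
#' background. All fits predict occurrence probability in `[0, 1]` from a
#' covariate table via [predict()].
#'
#' @name sdm_fits
NULL

# Extract response (1 = presence) and design matrix from a covariate table.
sdm_design <- function(table, classes = covariate_classes(table),
                       require_both = TRUE) {
  y <- as.integer(table$label == "presence")
  if (require_both && length(unique(y)) < 2L) {
    fail("training data contain a single class; need presences and pseudo-absences")
  }
  x <- as.matrix(as.data.frame(table)[, classes, drop = FALSE])
  storage.mode(x) <- "double"
  list(y = y, x = x, classes = classes)
}

#' @describeIn sdm_fits Binomial-logit GLM via ridge-stabilised IRLS. The
#'   small ridge penalty (on slopes only) keeps coefficients finite under
#'   complete separation; convergence is declared when the largest
#'   coefficient change falls below `tol` (default 1e-8) within `max_iter`
#'   (default 100) iterations, otherwise a warning reports the iteration
#'   count.
#' @param table a `covariate_table` with a `label` column.
#' @param quadratic also include squared covariate terms (default linear
#'   only).
#' @param ridge ridge stabiliser on slope coefficients.
#' @param max_iter,tol IRLS stopping rule.
#' @export
fit_sdm_glm <- function(table, quadratic = FALSE, ridge = 1e-6,
                        max_iter = 100L, tol = 1e-8) {
  d <- sdm_design(table)
  v <- apply(d$x, 2L, stats::var)
  if (any(v == 0)) {
    fail("zero-variance covariate(s): %s (drop before fitting)",
         paste(d$classes[v == 0], collapse = ", "))
  }
  x <- d$x
  if (quadratic) {
    xq <- x^2
    colnames(xq) <- paste0(colnames(x), "^2")
    x <- cbind(x, xq)
  }
  X <- cbind(`(intercept)` = 1, x)
  p_pen <- c(0, rep(ridge, ncol(x)))
  b <- rep(0, ncol(X))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X * w, X) + diag(p_pen, ncol(X))
    g <- drop(crossprod(X, d$y - p)) - p_pen * b
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning(sprintf("IRLS did not converge in %d iterations", iter))
  eta <- drop(X %*% b)
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  se <- sqrt(diag(solve(crossprod(X * w, X) + diag(p_pen, ncol(X)))))
  fit <- list(kind = "glm", coefficients = stats::setNames(b, colnames(X)),
              se = stats::setNames(se, colnames(X)), classes = d$classes,
              quadratic = quadratic, ridge = ridge, converged = converged,
              iterations = iter, n = nrow(X))
  class(fit) <- c("sdm_glm", "sdm_fit")
  fit
}

#' @export
predict.sdm_glm <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$classes, drop = FALSE])
  if (object$quadratic) x <- cbind(x, x^2)
  drop(stats::plogis(cbind(1, x) %*% object$coefficients))
}

#' @describeIn sdm_fits Gradient-boosted classification trees (stagewise
#'   boosting on logistic deviance with depth-limited trees, via xgboost;
#'   single-threaded for bit-reproducibility). Defaults: 500 stages,
#'   learning rate 0.05, depth 3, bag fraction 1.
#' @param n_stages,learning_rate,max_depth,bag_fraction boosting
#'   hyperparameters.
#' @param seed integer seed (relevant when `bag_fraction < 1`).
#' @export
fit_sdm_gbm <- function(table, n_stages = 500L, learning_rate = 0.05,
                        max_depth = 3L, bag_fraction = 1, seed = 1L) {
  d <- sdm_design(table)
  dtrain <- xgboost::xgb.DMatrix(d$x, label = d$y, nthread = 1)
  params <- list(objective = "binary:logistic", eta = learning_rate,
                 max_depth = max_depth, subsample = bag_fraction,
                 nthread = 1, seed = as.integer(seed),
                 eval_metric = "logloss")
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = n_stages,
                                evals = list(train = dtrain), verbose = 0)
  log <- tryCatch(attributes(booster)$evaluation_log,
                  error = function(e) NULL)
  fit <- list(kind = "gbm", booster = booster, classes = d$classes,
              n_stages = n_stages, learning_rate = learning_rate,
              max_depth = max_depth, bag_fraction = bag_fraction,
              train_deviance = if (!is.null(log)) log$train_logloss else NULL,
              n = nrow(d$x))
  class(fit) <- c("sdm_gbm", "sdm_fit")
  fit
}

#' @export
predict.sdm_gbm <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$classes, drop = FALSE])
  storage.mode(x) <- "double"
  as.numeric(predict(object$booster, xgboost::xgb.DMatrix(x, nthread = 1)))
}

# log(mean(exp(v))) without overflow
log_mean_exp <- function(v) {
  m <- max(v)
  m + log(mean(exp(v - m)))
}

# Gibbs objective over background: -mean_p(Fw) + log mean_b exp(Fw)
maxent_objective <- function(w, fp_bar, Fb) {
  -sum(fp_bar * w) + log_mean_exp(drop(Fb %*% w))
}

maxent_gradient <- function(w, fp_bar, Fb) {
  eta <- drop(Fb %*% w)
  q <- exp(eta - max(eta))
  q <- q / sum(q)
  drop(crossprod(Fb, q)) - fp_bar
}

# FISTA with backtracking for the L1-penalised Gibbs likelihood.
maxent_solve <- function(fp_bar, Fb, lambda, w0 = NULL, max_iter = 5000L,
                         tol = 1e-10) {
  p <- length(fp_bar)
  w <- if (is.null(w0)) rep(0, p) else w0
  z <- w
  t_k <- 1
  L <- 1
  f_z <- maxent_objective(z, fp_bar, Fb)
  for (it in seq_len(max_iter)) {
    g <- maxent_gradient(z, fp_bar, Fb)
    repeat {
      w_new <- sign(z - g / L) * pmax(abs(z - g / L) - lambda / L, 0)
      dw <- w_new - z
      f_new <- maxent_objective(w_new, fp_bar, Fb)
      if (is.finite(f_new) &&
          f_new <= f_z + sum(g * dw) + 0.5 * L * sum(dw^2) + 1e-15) break
      L <- L * 2
    }
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- w_new + ((t_k - 1) / t_new) * (w_new - w)
    if (max(abs(w_new - w)) < tol && it > 1L) {
      w <- w_new
      break
    }
    w <- w_new
    t_k <- t_new
    f_z <- maxent_objective(z, fp_bar, Fb)
    if (!is.finite(f_z)) {  # momentum overshoot: restart at the last iterate
      z <- w
      t_k <- 1
      f_z <- maxent_objective(z, fp_bar, Fb)
    }
    L <- max(L / 1.5, 1e-6)
  }
  w
}

maxent_features <- function(x, features) {
  out <- NULL
  if ("linear" %in% features) out <- x
  if ("quadratic" %in% features) {
    xq <- x^2
    colnames(xq) <- paste0(colnames(x), "^2")
    out <- cbind(out, xq)
  }
  out
}

#' @describeIn sdm_fits Maximum-entropy model: a Gibbs distribution over the
#'   background (pseudo-absence) cells with linear and quadratic features,
#'   fitted by L1-penalised likelihood maximisation (proximal gradient).
#'   When `l1_penalty` is `NULL` the penalty is chosen by held-out Gibbs
#'   log-likelihood on a 20% presence holdout and the model refitted on all
#'   presences. Predictions use the logistic output form
#'   `plogis(eta - alpha)`, `alpha` the log mean background exponent, so a
#'   background-average cell scores 0.5.
#' @param features feature set, subset of `c("linear", "quadratic")`.
#' @param l1_penalty L1 penalty; `NULL` selects it by presence holdout.
#' @export
fit_sdm_maxent <- function(table, features = c("linear", "quadratic"),
                           l1_penalty = NULL, seed = 1L) {
  d <- sdm_design(table)
  Fall <- maxent_features(d$x, features)
  mu <- colMeans(Fall[d$y == 0L, , drop = FALSE])
  sdv <- apply(Fall[d$y == 0L, , drop = FALSE], 2L, stats::sd)
  keep <- which(sdv > 0)
  if (!length(keep)) fail("all features are zero-variance on the background")
  Fs <- sweep(sweep(Fall[, keep, drop = FALSE], 2L, mu[keep]), 2L, sdv[keep],
              `/`)
  Fp <- Fs[d$y == 1L, , drop = FALSE]
  Fb <- Fs[d$y == 0L, , drop = FALSE]

  if (is.null(l1_penalty)) {
    n_p <- nrow(Fp)
    hold <- with_seed(seed, sample.int(n_p, max(1L, round(0.2 * n_p))))
    fp_tr <- colMeans(Fp[-hold, , drop = FALSE])
    lam_max <- max(abs(maxent_gradient(rep(0, ncol(Fs)), fp_tr, Fb)))
    grid <- lam_max * 10^seq(-0.5, -3.5, length.out = 8L)
    w <- NULL
    best <- -Inf
    l1_penalty <- grid[1L]
    for (lam in grid) {
      w <- maxent_solve(fp_tr, Fb, lam, w0 = w, max_iter = 1000L, tol = 1e-8)
      eta_h <- drop(Fp[hold, , drop = FALSE] %*% w)
      ll <- mean(eta_h) - log_mean_exp(drop(Fb %*% w))
      if (ll > best + 1e-12) {
        best <- ll
        l1_penalty <- lam
      }
    }
  }
  fp_bar <- colMeans(Fp)
  w <- maxent_solve(fp_bar, Fb, l1_penalty)
  alpha <- log_mean_exp(drop(Fb %*% w))
  fit <- list(kind = "maxent", weights = stats::setNames(w, colnames(Fs)),
              feature_names = colnames(Fall)[keep], features = features,
              center = mu[keep], scale = sdv[keep], alpha = alpha,
              l1_penalty = l1_penalty, classes = d$classes, n = nrow(d$x))
  class(fit) <- c("sdm_maxent", "sdm_fit")
  fit
}

#' @export
predict.sdm_maxent <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$classes, drop = FALSE])
  Fall <- maxent_features(x, object$features)
  Fs <- sweep(sweep(Fall[, object$feature_names, drop = FALSE], 2L,
                    object$center), 2L, object$scale, `/`)
  drop(stats::plogis(Fs %*% object$weights - object$alpha))
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit: %s> %d training rows, covariates: %s\n", x$kind,
              x$n, paste(x$classes, collapse = ", ")))
  if (x$kind == "glm") {
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

# ---- evaluation --------------------------------------------------------

#' ROC AUC (Mann-Whitney form)
#'
#' Probability that a randomly chosen presence is scored above a randomly
#' chosen pseudo-absence, ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels labels, `"presence"`/`"pseudo_absence"` or logical/0-1 with
#'   TRUE/1 = presence.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores, labels) {
  y <- as_presence(labels)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) fail("AUC needs both classes")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic
#'
#' Maximum over candidate thresholds (midpoints between sorted unique
#' scores, plus the two infinities) of sensitivity + specificity - 1, with
#' "presence" predicted when score > threshold.
#'
#' @inheritParams evaluate_auc
#' @return TSS in `[-1, 1]`.
#' @export
evaluate_tss <- function(scores, labels) {
  y <- as_presence(labels)
  if (!any(y) || all(y)) fail("TSS needs both classes")
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
  best <- -1
  for (t in thr) {
    sens <- mean(scores[y] > t)
    spec <- mean(scores[!y] <= t)
    best <- max(best, sens + spec - 1)
  }
  best
}

as_presence <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "presence"
  } else {
    as.logical(labels)
  }
}

#' Replicated split-sample evaluation
#'
#' Repeats stratified 75/25 (by default) train/test splits and records AUC
#' and TSS of every model kind on every replicate. Splits are generated
#' once from the seed, so all model kinds see identical splits.
#'
#' @param table a `covariate_table`.
#' @param fitters named list of fitting functions, each `function(table)`
#'   returning an `sdm_fit`.
#' @param train_fraction fraction of rows used for training, in (0, 1).
#' @param n_reps number of replicated splits (default 3).
#' @param seed integer seed.
#' @return a `sdm_eval` data.frame with columns model, replicate, auc, tss;
#'   the test row indices per replicate are kept in attribute `"splits"`.
#' @export
cross_validate <- function(table, fitters, train_fraction = 0.75,
                           n_reps = 3L, seed = 1L) {
  if (!is.list(fitters) || is.null(names(fitters)) || any(names(fitters) == "")) {
    fail("fitters must be a named list of fitting functions")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    fail("train_fraction must lie strictly between 0 and 1")
  }
  y <- as_presence(table$label)
  idx1 <- which(y)
  idx0 <- which(!y)
  splits <- with_seed(seed, lapply(seq_len(n_reps), function(r) {
    for (try in 1:100) {
      tr <- c(sample(idx1, round(train_fraction * length(idx1))),
              sample(idx0, round(train_fraction * length(idx0))))
      te <- setdiff(seq_len(nrow(table)), tr)
      if (length(unique(y[tr])) == 2L && length(unique(y[te])) == 2L) {
        return(list(train = sort(tr), test = sort(te)))
      }
    }
    fail("could not build a split with both classes in train and test")
  }))
  out <- list()
  for (m in names(fitters)) {
    for (r in seq_len(n_reps)) {
      tr_tab <- table[splits[[r]]$train, , drop = FALSE]
      attributes(tr_tab)$covariate_classes <- covariate_classes(table)
      fit <- fitters[[m]](tr_tab)
      te <- splits[[r]]$test
      sc <- predict(fit, table[te, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        model = m, replicate = r,
        auc = evaluate_auc(sc, table$label[te]),
        tss = evaluate_tss(sc, table$label[te]))
    }
  }
  ev <- do.call(rbind, out)
  attr(ev, "splits") <- splits
  class(ev) <- c("sdm_eval", "data.frame")
  ev
}

# ---- ensemble ----------------------------------------------------------

#' Accuracy-weighted model ensemble
#'
#' Combines fitted distribution models by weighted averaging, each member
#' weighted by its mean test accuracy (AUC by default) across evaluation
#' replicates; weights are normalised to sum to one.
#'
#' @param members named list of `sdm_fit` objects; names must match the
#'   `model` column of `eval_records`.
#' @param eval_records an `sdm_eval` data.frame from [cross_validate()].
#' @param metric weighting metric column, `"auc"` (default) or `"tss"`.
#' @return an `sdm_ensemble` object.
#' @export
sdm_ensemble <- function(members, eval_records, metric = "auc") {
  stopifnot(is.list(members), !is.null(names(members)))
  w <- vapply(names(members), function(m) {
    rows <- eval_records$model == m
    if (!any(rows)) fail("no evaluation records for member '%s'", m)
    mean(eval_records[[metric]][rows])
  }, 0)
  if (any(w < 0)) w <- pmax(w, 0)
  if (sum(w) <= 0) fail("all ensemble weights are zero")
  w <- w / sum(w)
  ens <- list(members = members, weights = w, metric = metric,
              eval_records = eval_records)
  class(ens) <- "sdm_ensemble"
  ens
}

#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object$members, function(m) predict(m, newdata),
                  numeric(nrow(as.data.frame(newdata))))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  drop(preds %*% object$weights)
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat("<sdm_ensemble> weighted by mean test", x$metric, "\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' @export
summary.sdm_ensemble <- function(object, ...) {
  ag <- stats::aggregate(cbind(auc, tss) ~ model, data = object$eval_records,
                         FUN = mean)
  ag$weight <- object$weights[ag$model]
  ag
}

# ---- variable importance ----------------------------------------------

#' Randomization variable importance
#'
#' For each covariate, predictions on the original table are correlated
#' with predictions after permuting that single column; importance is
#' `1 - |Pearson r|`, averaged over `n_permutations` permutations. A
#' variable the model ignores scores exactly 0.
#'
#' @param model an `sdm_fit` or `sdm_ensemble`.
#' @param table a `covariate_table`.
#' @param n_permutations permutations per variable (default 10).
#' @param seed integer seed.
#' @return data.frame with columns variable, importance, n_permutations,
#'   seed.
#' @export
variable_importance <- function(model, table, n_permutations = 10L,
                                seed = 1L) {
  if (nrow(table) < 3L) fail("variable importance needs >= 3 rows")
  vars <- if (inherits(model, "sdm_ensemble")) {
    model$members[[1L]]$classes
  } else {
    model$classes
  }
  p0 <- predict(model, table)
  if (stats::sd(p0) == 0) {
    warning("model predictions have zero variance; importances reported as 0")
    return(data.frame(variable = vars, importance = 0,
                      n_permutations = n_permutations, seed = seed))
  }
  imp <- with_seed(seed, vapply(vars, function(v) {
    vals <- vapply(seq_len(n_permutations), function(k) {
      tab <- table
      tab[[v]] <- tab[[v]][sample.int(nrow(tab))]
      p1 <- predict(model, tab)
      if (stats::sd(p1) == 0) return(NA_real_)
      1 - abs(stats::cor(p0, p1))
    }, 0)
    if (anyNA(vals)) {
      warning(sprintf("zero-variance permuted predictions for '%s'", v))
      vals[is.na(vals)] <- 0
    }
    mean(vals)
  }, 0))
  data.frame(variable = vars, importance = unname(pmin(pmax(imp, 0), 1)),
             n_permutations = n_permutations, seed = seed)
}
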