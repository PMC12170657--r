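## Correlation, single-descriptor linear regression, and RBF-kernel
## support vector regression with the study's tuning protocol.
##
## LR is fit on all observations with no train/test split: the published
## LR coefficients of determination equal the squared printed Pearson
## correlations (e.g. 0.8180^2 = 0.6692), which is only true for
## full-data fits.  RMSE uses denominator n, not n - 2.
##
## SVR follows the published protocol: 80/20 train/test split, grid
## search over C in {10, 50, 100, 500}, epsilon in {0.1, ..., 0.5} and
## gamma mode in {scale, auto} (40 combinations), model selection by mean
## validation R^2 under 5-fold cross-validation on the training split,
## refit with the winning combination, evaluation on the held-out 20%.
## The epsilon-insensitive dual problem itself is solved by libsvm
## (through e1071); this module fixes the objective, kernel and grid.

.INDEX_LABELS <- c(W = "Wiener Index", WW = "Hyper-Wiener Index",
                   H = "Harary Index", D = "Detour Index",
                   DH = "Detour Harary Index")

#' Pearson correlation matrix between indices and properties
#'
#' Sample Pearson coefficient for every (index, property) cell, matching
#' records by the `drug` column.
#'
#' @param indices data.frame with columns `drug, W, WW, H, D, DH`
#'   ([computeIndexTable()] or [loadReferenceIndices()] output).
#' @param props data.frame with columns `abbreviation` (or `drug`) and
#'   `BP, E, FP, MR, P, MV` ([loadDrugs()] output).
#' @return a 5-by-6 numeric matrix (indices by properties).
#' @export
pearsonMatrix <- function(indices, props) {
  key <- if ("abbreviation" %in% names(props)) "abbreviation" else "drug"
  m <- merge(indices, props, by.x = "drug", by.y = key, sort = TRUE)
  if (nrow(m) < 3)
    .stopf("tcaQSPR_config_error",
           "need at least 3 paired observations, got %d", nrow(m))
  x <- as.matrix(m[, .INDEX_COLS])
  y <- as.matrix(m[, .PROPERTY_COLS])
  for (cn in colnames(x)) if (stats::sd(x[, cn]) == 0)
    .stopf("tcaQSPR_degenerate_error",
           "index column '%s' is constant; correlation undefined", cn)
  for (cn in colnames(y)) if (stats::sd(y[, cn]) == 0)
    .stopf("tcaQSPR_degenerate_error",
           "property column '%s' is constant; correlation undefined", cn)
  stats::cor(x, y)
}

#' Single-descriptor ordinary least squares with the study's metrics
#'
#' Fits `y = v + w x` on all observations (no split).  `r2` is the
#' coefficient of determination `1 - SS_res / SS_tot`; for a
#' single-predictor full-data OLS fit this equals the squared Pearson
#' correlation (an identity the tests assert to 1e-12).  `rmse` is
#' `sqrt(mean((y - yhat)^2))`, denominator `n`.
#'
#' @param x numeric predictor (an index column).
#' @param y numeric response (a property column).
#' @return an object of class `LRFit`: a list with `intercept`, `slope`,
#'   `r2`, `rmse`, `n`, `fitted`.
#' @export
fitLR <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    .stopf("tcaQSPR_config_error",
           "need equal-length x and y with at least 3 observations")
  if (stats::sd(x) == 0)
    .stopf("tcaQSPR_degenerate_error", "predictor is constant; fit degenerate")
  fit <- stats::lm(y ~ x)
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(
    list(intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]),
         r2 = r2, rmse = sqrt(mean(res^2)), n = length(x),
         fitted = unname(stats::predict(fit))),
    class = "LRFit")
}

#' @export
print.LRFit <- function(x, ...) {
  cat(sprintf("LRFit: y = %.6g + %.6g x  (n = %d)\n  R2 = %.4f, RMSE = %.4f\n",
              x$intercept, x$slope, x$n, x$r2, x$rmse))
  invisible(x)
}

#' Linear-regression report over all index/property pairs
#'
#' @inheritParams pearsonMatrix
#' @return a data.frame with one row per (property, index) pair:
#'   `property, index, intercept, slope, r2, rmse`.
#' @export
lrReport <- function(indices, props) {
  key <- if ("abbreviation" %in% names(props)) "abbreviation" else "drug"
  m <- merge(indices, props, by.x = "drug", by.y = key, sort = TRUE)
  rows <- list()
  for (p in .PROPERTY_COLS) for (ix in .INDEX_COLS) {
    f <- fitLR(m[[ix]], m[[p]])
    rows[[length(rows) + 1L]] <- data.frame(
      property = p, index = ix, intercept = f$intercept, slope = f$slope,
      r2 = f$r2, rmse = f$rmse, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' RBF kernel value
#'
#' `K(x, y) = exp(-alpha * ||x - y||^2)`, the similarity function used by
#' the SVR stage.
#'
#' @param x,y equal-length numeric vectors.
#' @param alpha positive kernel width parameter.
#' @return a number in (0, 1].
#' @export
rbfKernel <- function(x, y, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    .stopf("tcaQSPR_config_error", "alpha must be a positive scalar")
  if (length(x) != length(y))
    .stopf("tcaQSPR_config_error", "x and y must have equal length")
  exp(-alpha * sum((x - y)^2))
}

#' Standardize a column with an invertible stored transform
#'
#' @param x non-constant numeric vector.
#' @return an object of class `ScalingTransform` with elements `center`,
#'   `scale` and `scaled`.
#' @seealso [applyScaling()], [invertScaling()]
#' @export
featureScaling <- function(x) {
  if (stats::sd(x) == 0)
    .stopf("tcaQSPR_degenerate_error", "cannot standardize a constant column")
  ctr <- mean(x); scl <- stats::sd(x)
  structure(list(center = ctr, scale = scl, scaled = (x - ctr) / scl),
            class = "ScalingTransform")
}

#' @rdname featureScaling
#' @param tf a `ScalingTransform`.
#' @param z numeric vector on the transformed (for [invertScaling()]) or
#'   original (for [applyScaling()]) scale.
#' @export
applyScaling <- function(tf, z) (z - tf$center) / tf$scale

#' @rdname featureScaling
#' @export
invertScaling <- function(tf, z) z * tf$scale + tf$center

#' SVR tuning specification
#'
#' The study's hyperparameter grid and protocol: cost C in
#' {10, 50, 100, 500}, epsilon in {0.1, 0.2, 0.3, 0.4, 0.5}, gamma mode
#' in {"scale", "auto"} (40 combinations), 80/20 split, 5-fold CV.
#' Gamma follows the conventional definitions on the training design
#' matrix actually fed to the solver: `scale` = 1 / (n_features * var(x))
#' with population variance, `auto` = 1 / n_features.  Features (and, by
#' default, targets) are standardized with training-split statistics;
#' both switches are recorded in the result.
#'
#' @param cost candidate values of the regularization parameter C.
#' @param epsilon candidate half-widths of the insensitive tube.
#' @param gammaMode subset of `c("scale", "auto")`.
#' @param splitFraction fraction of observations used for training.
#' @param cvFolds number of cross-validation folds.
#' @param seed integer seed controlling split and fold shuffling.
#' @param scaleX,scaleY standardize features / targets before the solver.
#' @return an object of class `SVRSpec`.
#' @export
svrSpec <- function(cost = c(10, 50, 100, 500),
                    epsilon = seq(0.1, 0.5, by = 0.1),
                    gammaMode = c("scale", "auto"),
                    splitFraction = 0.8, cvFolds = 5, seed = 42,
                    scaleX = TRUE, scaleY = TRUE) {
  if (length(cost) == 0 || any(cost <= 0))
    .stopf("tcaQSPR_config_error", "cost values must be positive")
  if (length(epsilon) == 0 || any(epsilon < 0))
    .stopf("tcaQSPR_config_error", "epsilon values must be non-negative")
  gammaMode <- match.arg(gammaMode, several.ok = TRUE)
  if (splitFraction <= 0 || splitFraction >= 1)
    .stopf("tcaQSPR_config_error", "splitFraction must be in (0, 1)")
  if (cvFolds < 2)
    .stopf("tcaQSPR_config_error", "cvFolds must be at least 2")
  structure(list(cost = sort(cost), epsilon = sort(epsilon),
                 gammaMode = gammaMode, splitFraction = splitFraction,
                 cvFolds = as.integer(cvFolds), seed = as.integer(seed),
                 scaleX = isTRUE(scaleX), scaleY = isTRUE(scaleY)),
            class = "SVRSpec")
}

#' @export
print.SVRSpec <- function(x, ...) {
  cat(sprintf(paste0("SVRSpec: %d-point grid (C: %s; eps: %s; gamma: %s), ",
                     "%.0f%%/%.0f%% split, %d-fold CV, seed %d\n"),
              length(x$cost) * length(x$epsilon) * length(x$gammaMode),
              paste(x$cost, collapse = "/"),
              paste(x$epsilon, collapse = "/"),
              paste(x$gammaMode, collapse = "/"),
              100 * x$splitFraction, 100 * (1 - x$splitFraction),
              x$cvFolds, x$seed))
  invisible(x)
}

## coefficient of determination (study definition)
.r2 <- function(actual, predicted) {
  sstot <- sum((actual - mean(actual))^2)
  if (sstot == 0) return(NA_real_)
  1 - sum((actual - predicted)^2) / sstot
}

## one libsvm fit; gamma computed from the design matrix fed to the solver
.fitSVR <- function(xtr, ytr, cost, epsilon, gammaMode) {
  vp <- mean((xtr - mean(xtr))^2)             # population variance
  gamma <- if (gammaMode == "scale") {
    if (vp == 0) 1 else 1 / vp                # 1 feature
  } else 1                                    # "auto": 1 / n_features
  e1071::svm(x = matrix(xtr, ncol = 1), y = ytr, type = "eps-regression",
             kernel = "radial", cost = cost, epsilon = epsilon,
             gamma = gamma, scale = FALSE)
}

#' Tune and evaluate RBF-kernel support vector regression
#'
#' Implements the study's protocol on one (index, property) pair: split,
#' grid search by 5-fold cross-validated mean validation R^2 on the
#' training portion (ties broken toward smaller C, then smaller epsilon,
#' then the first gamma mode), refit on the full training split, report
#' R^2 and RMSE on the held-out test observations (original scale).
#' Fully reproducible given `spec$seed`.
#'
#' @param x numeric predictor (an index column), length at least 10.
#' @param y numeric response (a property column).
#' @param spec an [svrSpec()] object.
#' @param property,index optional identifiers carried into the result.
#' @return an object of class `SVRResult`: chosen `cost`, `epsilon`,
#'   `gammaMode`, `cvR2`, `testR2`, `testRMSE`, `seed`, scaling switches,
#'   the train/test membership, and the fitted model.
#' @export
tuneSVR <- function(x, y, spec = svrSpec(), property = NA_character_,
                    index = NA_character_) {
  stopifnot(inherits(spec, "SVRSpec"))
  n <- length(x)
  if (length(y) != n)
    .stopf("tcaQSPR_config_error", "x and y must have equal length")
  if (n < 10)
    .stopf("tcaQSPR_config_error",
           "need at least 10 observations for the tuning protocol, got %d", n)
  nTrain <- floor(spec$splitFraction * n)
  if (nTrain < spec$cvFolds)
    .stopf("tcaQSPR_config_error",
           "training split (%d) smaller than the number of folds (%d)",
           nTrain, spec$cvFolds)

  splits <- .withSeed(spec$seed, {
    perm <- sample.int(n)
    foldId <- sample(rep(seq_len(spec$cvFolds), length.out = nTrain))
    list(train = sort(perm[seq_len(nTrain)]),
         test = sort(perm[-seq_len(nTrain)]), foldId = foldId)
  })
  train <- splits$train; test <- splits$test
  foldId <- splits$foldId        # foldId[i] labels train[i]

  xs <- x; ys <- y
  tfx <- NULL; tfy <- NULL
  if (spec$scaleX) {
    tfx <- featureScaling(x[train]); xs <- applyScaling(tfx, x)
  }
  if (spec$scaleY) {
    tfy <- featureScaling(y[train]); ys <- applyScaling(tfy, y)
  }

  ## grid rows ordered so that the first maximum realises the tie-break
  grid <- expand.grid(gammaMode = spec$gammaMode, epsilon = spec$epsilon,
                      cost = spec$cost, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("cost", "epsilon", "gammaMode")]
  cvR2 <- vapply(seq_len(nrow(grid)), function(gi) {
    r2s <- vapply(seq_len(spec$cvFolds), function(f) {
      tr <- train[foldId != f]; va <- train[foldId == f]
      if (length(va) == 0L || length(tr) < 2L) return(NA_real_)
      fit <- .fitSVR(xs[tr], ys[tr], grid$cost[gi], grid$epsilon[gi],
                     grid$gammaMode[gi])
      pred <- stats::predict(fit, matrix(xs[va], ncol = 1))
      .r2(ys[va], pred)
    }, numeric(1))
    if (all(is.na(r2s))) NA_real_ else mean(r2s, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(cvR2)))
    .stopf("tcaQSPR_config_error",
           "cross-validation produced no usable validation folds")
  best <- which.max(cvR2)

  fit <- .fitSVR(xs[train], ys[train], grid$cost[best], grid$epsilon[best],
                 grid$gammaMode[best])
  predTest <- stats::predict(fit, matrix(xs[test], ncol = 1))
  if (spec$scaleY) predTest <- invertScaling(tfy, predTest)

  structure(
    list(property = property, index = index,
         cost = grid$cost[best], epsilon = grid$epsilon[best],
         gammaMode = grid$gammaMode[best], cvR2 = cvR2[best],
         testR2 = .r2(y[test], predTest),
         testRMSE = sqrt(mean((y[test] - predTest)^2)),
         seed = spec$seed, scaledX = spec$scaleX, scaledY = spec$scaleY,
         trainIndex = train, testIndex = test, n = n,
         model = fit, tfx = tfx, tfy = tfy),
    class = "SVRResult")
}

#' @export
print.SVRResult <- function(x, ...) {
  cat(sprintf(paste0("SVRResult%s: C = %g, epsilon = %g, gamma = %s ",
                     "(cv R2 = %.4f)\n  test R2 = %.4f, test RMSE = %.4f ",
                     "(n = %d, seed = %d)\n"),
              if (is.na(x$property)) "" else
                sprintf(" [%s ~ %s]", x$property, x$index),
              x$cost, x$epsilon, x$gammaMode, x$cvR2, x$testR2, x$testRMSE,
              x$n, x$seed))
  invisible(x)
}

#' Predict from a tuned SVR result on the original scales
#'
#' @param result an `SVRResult` from [tuneSVR()].
#' @param x numeric predictor values on the original scale.
#' @return predicted response values on the original scale.
#' @export
predictSVR <- function(result, x) {
  stopifnot(inherits(result, "SVRResult"))
  xs <- if (!is.null(result$tfx)) applyScaling(result$tfx, x) else x
  p <- stats::predict(result$model, matrix(xs, ncol = 1))
  if (!is.null(result$tfy)) p <- invertScaling(result$tfy, p)
  unname(p)
}

#' SVR report over all index/property pairs
#'
#' Runs [tuneSVR()] for every (property, index) combination.
#'
#' @inheritParams pearsonMatrix
#' @param spec an [svrSpec()] object.
#' @return a data.frame with columns `property, index, cost, epsilon,
#'   gammaMode, cvR2, testR2, testRMSE, seed`, with the full `SVRResult`
#'   objects attached as the `"results"` attribute.
#' @export
svrReport <- function(indices, props, spec = svrSpec()) {
  key <- if ("abbreviation" %in% names(props)) "abbreviation" else "drug"
  m <- merge(indices, props, by.x = "drug", by.y = key, sort = TRUE)
  rows <- list(); results <- list()
  for (p in .PROPERTY_COLS) for (ix in .INDEX_COLS) {
    r <- tuneSVR(m[[ix]], m[[p]], spec, property = p, index = ix)
    results[[paste(p, ix, sep = ".")]] <- r
    rows[[length(rows) + 1L]] <- data.frame(
      property = p, index = ix, cost = r$cost, epsilon = r$epsilon,
      gammaMode = r$gammaMode, cvR2 = r$cvR2, testR2 = r$testR2,
      testRMSE = r$testRMSE, seed = r$seed, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}

#' Best index per property
#'
#' Argmax of the fit statistic per property; ties are broken toward the
#' lexicographically first index identifier.
#'
#' @param results a data.frame with columns `property`, `index` and a fit
#'   statistic (`testR2` if present, else `r2`).
#' @return a data.frame with one row per property: `property, index` plus
#'   the winning statistic.
#' @export
selectBestIndex <- function(results) {
  metric <- if ("testR2" %in% names(results)) "testR2" else "r2"
  if (!all(c("property", "index", metric) %in% names(results)))
    .stopf("tcaQSPR_config_error",
           "results must contain property, index and %s columns", metric)
  out <- do.call(rbind, lapply(split(results, results$property), function(d) {
    d <- d[order(-d[[metric]], d$index), ]
    d[1, c("property", "index", metric)]
  }))
  ## preserve canonical property order
  out <- out[match(intersect(.PROPERTY_COLS, out$property), out$property), ]
  rownames(out) <- NULL
  out
}
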