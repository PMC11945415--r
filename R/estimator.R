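# Features -> circumference regression. Four tree-based algorithms are
# supported behind one interface: a fully grown CART tree (rpart), a random
# forest (randomForest), extremely randomized trees (ranger with the
# extratrees split rule) and AdaBoost.R2 boosting of shallow CART trees
# (implemented here: weighted base fits, linear loss, weighted-median
# prediction — there is no regression AdaBoost among the installed packages).
# All fits are deterministic for a fixed seed.

#' @importFrom randomForest randomForest
#' @importFrom ranger ranger
#' @importFrom rpart rpart
NULL

HC_ALGORITHMS <- c("random_forest", "decision_tree", "extra_trees", "adaboost")

.adaboost_r2_fit <- function(x, y, n_estimators = 50, maxdepth = 3) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  dat <- cbind(x, .y = y)
  fits <- list(); betas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "anova",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, minsplit = 2, minbucket = 1,
                          cp = 0, xval = 0))
    pred <- predict(fit, x)
    err <- abs(pred - y)
    emax <- max(err)
    if (emax <= 0) {             # perfect fit: keep it with full weight
      fits[[length(fits) + 1L]] <- fit
      betas <- c(betas, 1e-10)
      break
    }
    loss <- err / emax           # linear loss
    lbar <- sum(w * loss)
    if (lbar >= 0.5) {
      if (length(fits) == 0L) {  # keep one estimator even if weak
        fits[[1L]] <- fit
        betas <- 1 - 1e-10
      }
      break
    }
    beta <- lbar / (1 - lbar)
    fits[[length(fits) + 1L]] <- fit
    betas <- c(betas, beta)
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
  }
  list(fits = fits, betas = betas)
}

.adaboost_r2_predict <- function(model, x) {
  P <- vapply(model$fits, function(f) as.numeric(predict(f, x)),
              numeric(nrow(x)))
  P <- matrix(P, nrow = nrow(x))
  lw <- log(1 / model$betas)
  # weighted median across estimators, per sample
  apply(P, 1, function(p) {
    o <- order(p)
    cw <- cumsum(lw[o])
    p[o][which(cw >= 0.5 * sum(lw))[1]]
  })
}

#' Train a circumference regression model
#'
#' Fits one of four tree-ensemble algorithms mapping the section features to
#' head circumference in cm. The random forest (the pipeline default) uses
#' 100 fully grown trees (unrestricted depth, leaves down to single
#' observations) with all features considered at every split.
#' Training is deterministic for a fixed `seed`, and the model records the
#' feature ordering so prediction can validate its input.
#'
#' @param x Data frame of numeric features (one row per scene).
#' @param y Numeric vector of true circumferences (cm), all positive.
#' @param algorithm One of `"random_forest"`, `"decision_tree"`,
#'   `"extra_trees"`, `"adaboost"`.
#' @param seed RNG seed for the fit (default 1).
#' @param ntree Ensemble size for forest-type algorithms (default 100).
#' @return Object of class `hc_model`.
#' @export
hc_train <- function(x, y, algorithm = "random_forest", seed = 1, ntree = 100) {
  algorithm <- match.arg(algorithm, HC_ALGORITHMS)
  x <- as.data.frame(x)
  if (!all(vapply(x, is.numeric, logical(1))))
    hc_stop("all features must be numeric")
  y <- as.numeric(y)
  if (nrow(x) != length(y)) hc_stop("x and y lengths differ")
  if (nrow(x) < 10L) hc_stop("need at least 10 training rows")
  if (any(!is.finite(y)) || any(y <= 0))
    hc_stop("all target circumferences must be finite and positive")

  fit <- with_seed(seed, switch(algorithm,
    decision_tree = rpart::rpart(
      .y ~ ., data = cbind(x, .y = y), method = "anova",
      control = rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0,
                                     xval = 0)),
    random_forest = randomForest::randomForest(
      x = x, y = y, ntree = ntree, mtry = ncol(x), nodesize = 1),
    extra_trees = ranger::ranger(
      y = y, x = x, num.trees = ntree, splitrule = "extratrees",
      num.random.splits = 1, replace = FALSE, sample.fraction = 1,
      mtry = ncol(x), min.node.size = 1, seed = as.integer(seed),
      num.threads = 1),
    adaboost = .adaboost_r2_fit(x, y)))

  structure(list(algorithm = algorithm, fit = fit,
                 feature_names = names(x), n = nrow(x),
                 seed = seed, target_range = range(y), units = "cm"),
            class = "hc_model")
}

#' Predict head circumference
#'
#' @param object An [hc_train()] model.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of circumference estimates (cm).
#' @export
predict.hc_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing))
    hc_stop(paste("missing feature columns:", paste(missing, collapse = ", ")))
  x <- newdata[, object$feature_names, drop = FALSE]
  out <- switch(object$algorithm,
    decision_tree = as.numeric(predict(object$fit, x)),
    random_forest = as.numeric(predict(object$fit, x)),
    extra_trees = ranger::predictions(predict(object$fit, x, num.threads = 1)),
    adaboost = .adaboost_r2_predict(object$fit, x))
  as.numeric(out)
}

#' @export
print.hc_model <- function(x, ...) {
  cat(sprintf("Head-circumference model: %s, %d training scenes, targets %.1f-%.1f cm\n",
              x$algorithm, x$n, x$target_range[1], x$target_range[2]))
  cat("features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.hc_model <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Save / load a trained model
#'
#' Thin RDS wrappers; a reloaded model predicts identically.
#'
#' @param model An `hc_model`.
#' @param path File path.
#' @return `path` invisibly ([hc_save_model()]) or the model
#'   ([hc_load_model()]).
#' @export
hc_save_model <- function(model, path) {
  stopifnot(inherits(model, "hc_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname hc_save_model
#' @export
hc_load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "hc_model")) hc_stop("file does not contain an hc_model")
  m
}

#' Evaluate circumference predictions
#'
#' Mean absolute error in cm (the headline metric: robust to the occasional
#' large miss, interpretable in the clinical unit), RMSE for diagnostics,
#' and the error distribution over the bins <=1 cm, 1-2 cm and >2 cm.
#'
#' @param predictions_cm,truths_cm Equal-length numeric vectors (cm).
#' @return Object of class `hc_eval`: `mae_cm`, `rmse_cm`, `abs_errors_cm`,
#'   `bins` (named fractions summing to 1), `n`.
#' @export
hc_evaluate <- function(predictions_cm, truths_cm) {
  if (length(predictions_cm) != length(truths_cm))
    hc_stop("predictions and truths differ in length")
  if (length(predictions_cm) == 0L) hc_stop("empty input")
  err <- abs(predictions_cm - truths_cm)
  bins <- c("<=1cm" = mean(err <= 1),
            "1-2cm" = mean(err > 1 & err <= 2),
            ">2cm" = mean(err > 2))
  structure(list(mae_cm = mean(err),
                 rmse_cm = sqrt(mean(err^2)),
                 abs_errors_cm = err,
                 bins = bins,
                 n = length(err)),
            class = "hc_eval")
}

#' @export
print.hc_eval <- function(x, ...) {
  cat(sprintf("Evaluation on %d cases: MAE %.3f cm (RMSE %.3f cm)\n",
              x$n, x$mae_cm, x$rmse_cm))
  cat(sprintf("  error <= 1 cm: %5.1f%%\n", 100 * x$bins["<=1cm"]))
  cat(sprintf("  1 - 2 cm     : %5.1f%%\n", 100 * x$bins["1-2cm"]))
  cat(sprintf("  error > 2 cm : %5.1f%%\n", 100 * x$bins[">2cm"]))
  invisible(x)
}

#' Compare regression algorithms on one split
#'
#' Trains every requested algorithm on the identical seeded train/test split
#' and reports test MAE (and RMSE) per algorithm. Duplicate algorithm tags
#' are dropped with a warning. The default split mirrors the pipeline's
#' evaluation protocol: a 135/49-proportioned random split.
#'
#' @param x Feature data frame.
#' @param y True circumferences (cm).
#' @param algorithms Character vector of algorithm tags (default all four).
#' @param seed Seed controlling both the split and each fit (default 1).
#' @param train_n Training-set size (default `round(n * 135/184)`).
#' @return Object of class `hc_comparison`: data frame with columns
#'   `algorithm`, `mae_cm`, `rmse_cm`, plus split sizes as attributes.
#' @export
hc_compare <- function(x, y, algorithms = HC_ALGORITHMS, seed = 1,
                       train_n = NULL) {
  x <- as.data.frame(x)
  n <- nrow(x)
  if (anyDuplicated(algorithms)) {
    warning("duplicate algorithm tags removed")
    algorithms <- unique(algorithms)
  }
  algorithms <- vapply(algorithms, function(a) match.arg(a, HC_ALGORITHMS),
                       character(1))
  if (is.null(train_n)) train_n <- round(n * 135 / 184)
  if (train_n < 10 || train_n >= n)
    hc_stop("train_n must leave at least one test row and >= 10 training rows")
  idx <- with_seed(seed, sample.int(n, train_n))
  res <- lapply(algorithms, function(alg) {
    m <- hc_train(x[idx, , drop = FALSE], y[idx], algorithm = alg, seed = seed)
    ev <- hc_evaluate(predict(m, x[-idx, , drop = FALSE]), y[-idx])
    data.frame(algorithm = alg, mae_cm = ev$mae_cm, rmse_cm = ev$rmse_cm)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("hc_comparison", "data.frame"),
            train_n = train_n, test_n = n - train_n, seed = seed)
}

#' @export
print.hc_comparison <- function(x, ...) {
  cat(sprintf("Algorithm comparison (train %d / test %d, seed %d)\n",
              attr(x, "train_n"), attr(x, "test_n"), attr(x, "seed")))
  df <- as.data.frame(x)
  df$mae_cm <- sprintf("%.2f", df$mae_cm)
  df$rmse_cm <- sprintf("%.2f", df$rmse_cm)
  print(df, row.names = FALSE)
  invisible(x)
}
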