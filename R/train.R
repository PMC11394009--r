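# Threshold-model training: preprocessing -> Boruta-style selection ->
# repeated stratified cross-validation with per-fold downsampling and a
# hyperparameter grid search (AUC-optimised), refit on the full training set.

.CLS_FAMILIES <- c(RF = "ranger", XGB = "xgbTree", SVC = "svmRadial",
                   GPC = "gaussprRadial", KNN = "knn", LR = "glm")
.REG_FAMILIES <- c(PLS = "pls_mixomics", RF = "ranger", XGB = "xgbTree",
                   LM = "lm", SVR = "svmRadial", GPR = "gaussprRadial")

#' Training configuration
#'
#' @param folds CV folds (default 5)
#' @param repeats CV repeats (default 20 for classification, 10 for regression)
#' @param tune_length caret grid size (default 20; gradient boosting uses 5)
#' @param seed integer seed
#' @param downsample balance classes inside each training fold
#' @param boruta run feature selection before training
#' @param ad_k,ad_z applicability-domain parameters
#' @param num_trees random-forest size
#' @export
pox_config <- function(folds = 5, repeats = 20, tune_length = 20, seed = 1,
                       downsample = TRUE, boruta = TRUE, ad_k = 5, ad_z = 0.5,
                       num_trees = 300, boruta_runs = 40) {
  list(folds = folds, repeats = repeats, tune_length = tune_length, seed = seed,
       downsample = downsample, boruta = boruta, ad_k = ad_k, ad_z = ad_z,
       num_trees = num_trees, boruta_runs = boruta_runs)
}

#' @keywords internal
caret_cls_control <- function(config) {
  caret::trainControl(
    method = "repeatedcv", number = config$folds, repeats = config$repeats,
    classProbs = TRUE, summaryFunction = caret::twoClassSummary,
    sampling = if (config$downsample) "down" else NULL,
    savePredictions = "final")
}

#' @keywords internal
cv_classification_metrics <- function(fit) {
  pred <- fit$pred
  if (is.null(pred) || !nrow(pred)) return(NULL)
  per <- lapply(split(pred, pred$Resample), function(pp) {
    m <- classification_metrics(
      TP = sum(pp$pred == "pos" & pp$obs == "pos"),
      TN = sum(pp$pred == "neg" & pp$obs == "neg"),
      FP = sum(pp$pred == "pos" & pp$obs == "neg"),
      FN = sum(pp$pred == "neg" & pp$obs == "pos"))
    auc <- tryCatch(
      as.numeric(pROC::auc(pROC::roc(pp$obs, pp$pos, levels = c("neg", "pos"),
                                     direction = "<", quiet = TRUE))),
      error = function(e) NA_real_)
    c(unlist(m[c("Sens", "Spec", "PPV", "NPV", "Acc", "F1", "nMCC")]), AUC = auc)
  })
  mat <- do.call(rbind, per)
  as.list(colMeans(mat, na.rm = TRUE))
}

#' Train one threshold classifier
#'
#' The canonical fitting entry point: takes the feature matrix and binary
#' labels of the training set, fits the preprocessing state, optionally
#' selects features with the Boruta-style procedure, then grid-searches the
#' chosen model family under repeated stratified CV with fold-wise
#' downsampling, AUC as the optimisation metric, and refits on the full set.
#'
#' @param X numeric feature matrix (training rows)
#' @param y factor with levels `neg`/`pos` (or coercible)
#' @param family one of `"RF"`, `"XGB"`, `"SVC"`, `"GPC"`, `"KNN"`, `"LR"`
#' @param threshold_id label such as `"LC40"` or `"LE20"`
#' @param config a [pox_config()] list
#' @param subset_meta optional feature-assembly metadata stored for prediction
#' @return object of class `pox_model`
#' @export
pox_train <- function(X, y, family = "RF", threshold_id = "LC10",
                      config = pox_config(), subset_meta = NULL) {
  family <- match.arg(family, names(.CLS_FAMILIES))
  y <- factor(y, levels = c("neg", "pos"))
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (nlevels(droplevels(y)) < 2) {
    stop("pipeline error: both classes required", call. = FALSE)
  }
  folds <- config$folds
  if (min(table(y)) < folds) {
    warning("minority class smaller than fold count; reducing folds", call. = FALSE)
    config$folds <- max(2L, min(table(y)))
  }
  prep <- preprocess_fit(X)
  Xp <- preprocess_apply(prep, X)
  features <- colnames(Xp)
  if (config$boruta) {
    features <- boruta_select(Xp, y, seed = config$seed,
                              max_runs = config$boruta_runs,
                              num_trees = config$num_trees)
    if (!length(features)) features <- colnames(Xp)
  }
  Xs <- Xp[, features, drop = FALSE]
  tl <- if (family == "XGB") min(config$tune_length, 5L) else config$tune_length
  fit <- with_seed(config$seed, {
    caret::train(x = as.data.frame(Xs), y = y,
                 method = .CLS_FAMILIES[[family]],
                 metric = "ROC", tuneLength = tl,
                 trControl = caret_cls_control(config))
  })
  ad <- fit_ad(Xs, k = min(config$ad_k, nrow(Xs) - 1L), z = config$ad_z)
  structure(list(threshold_id = threshold_id, family = family,
                 preprocess = prep, features = features, fit = fit,
                 cv_metrics = cv_classification_metrics(fit),
                 ad = ad, config = config, subset_meta = subset_meta,
                 levels = c("neg", "pos")),
            class = "pox_model")
}

#' @export
print.pox_model <- function(x, ...) {
  cat(sprintf("<pox_model> %s %s: %d features, CV nMCC %.3f AUC %.3f Acc %.3f\n",
              x$threshold_id, x$family, length(x$features),
              x$cv_metrics$nMCC %||% NA, x$cv_metrics$AUC %||% NA,
              x$cv_metrics$Acc %||% NA))
  invisible(x)
}

#' @export
summary.pox_model <- function(object, ...) {
  cat("Threshold model", object$threshold_id, "(", object$family, ")\n")
  print(object$preprocess)
  cat("Selected features:", length(object$features), "\n")
  cat("Best tune:\n"); print(object$fit$bestTune)
  cat("CV metrics (mean over folds x repeats):\n")
  print(vapply(object$cv_metrics, round, numeric(1), digits = 3))
  print(object$ad)
  invisible(object)
}

#' Predict with a threshold model
#'
#' @param object a `pox_model`
#' @param newdata raw (untransformed) feature matrix or single named vector
#' @param type `"class"`, `"prob"` or `"report"` (class + probability + AD)
#' @param apply_ad treat out-of-domain rows as negative (`"report"` only
#'   flags; `"class"` downgrades to `neg`)
#' @param ... unused
#' @export
predict.pox_model <- function(object, newdata, type = c("report", "class", "prob"),
                              apply_ad = TRUE, ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  Xp <- preprocess_apply(object$preprocess, newdata)
  Xs <- Xp[, object$features, drop = FALSE]
  prob <- stats::predict(object$fit, as.data.frame(Xs), type = "prob")[, "pos"]
  cls <- factor(ifelse(prob >= 0.5, "pos", "neg"), levels = c("neg", "pos"))
  dom <- in_domain(Xs, object$ad)
  if (apply_ad) cls[!dom$in_domain] <- "neg"
  switch(type,
         prob = prob,
         class = cls,
         report = data.frame(threshold = object$threshold_id,
                             score = prob, pass = cls == "pos",
                             in_ad = dom$in_domain, distance = dom$distance,
                             stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Regression
# ---------------------------------------------------------------------------

#' @keywords internal
pls_caret_spec <- function() {
  # PLS regression through the mixOmics backend, exposed as a caret method
  list(
    label = "PLS (mixOmics)", library = "mixOmics", type = "Regression",
    parameters = data.frame(parameter = "ncomp", class = "numeric",
                            label = "#Components"),
    grid = function(x, y, len = NULL, search = "grid") {
      data.frame(ncomp = seq_len(min(len %||% 3, ncol(x), nrow(x) - 1)))
    },
    fit = function(x, y, wts, param, lev, last, weights, classProbs, ...) {
      mixOmics::pls(as.matrix(x), y, ncomp = param$ncomp, mode = "regression")
    },
    predict = function(modelFit, newdata, submodels = NULL) {
      drop(stats::predict(modelFit, as.matrix(newdata))$predict[, 1,
                                                                modelFit$ncomp])
    },
    prob = NULL, sort = function(x) x)
}

#' Train a regression model for LC or LE values
#'
#' Same pipeline as [pox_train()] with regression families and RMSE as the
#' optimisation metric; CV repeats and tune lengths default to 10 (3 for
#' gradient boosting).
#'
#' @param X feature matrix
#' @param y numeric response
#' @param family one of `"PLS"`, `"RF"`, `"XGB"`, `"LM"`, `"SVR"`, `"GPR"`
#' @param config a [pox_config()]; `repeats`/`tune_length` default to 10 here
#' @return object of class `pox_regressor` with CV RMSE/MAE/R2
#' @export
train_regressor <- function(X, y, family = "RF",
                            config = pox_config(repeats = 10, tune_length = 10)) {
  family <- match.arg(family, names(.REG_FAMILIES))
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  prep <- preprocess_fit(X)
  Xp <- preprocess_apply(prep, X)
  features <- colnames(Xp)
  if (config$boruta) {
    features <- boruta_select(Xp, y, seed = config$seed,
                              max_runs = config$boruta_runs,
                              num_trees = config$num_trees)
    if (!length(features)) features <- colnames(Xp)
  }
  Xs <- Xp[, features, drop = FALSE]
  tl <- if (family == "XGB") min(config$tune_length, 3L) else config$tune_length
  method <- .REG_FAMILIES[[family]]
  if (method == "pls_mixomics") method <- pls_caret_spec()
  ctrl <- caret::trainControl(method = "repeatedcv", number = config$folds,
                              repeats = config$repeats, savePredictions = "final")
  fit <- with_seed(config$seed, {
    caret::train(x = as.data.frame(Xs), y = y, method = method,
                 metric = "RMSE", tuneLength = tl, trControl = ctrl)
  })
  pred <- fit$pred
  cv <- list(RMSE = sqrt(mean((pred$pred - pred$obs)^2)),
             MAE = mean(abs(pred$pred - pred$obs)),
             R2 = if (stats::var(pred$obs) > 0) {
               1 - sum((pred$pred - pred$obs)^2) /
                 sum((pred$obs - mean(pred$obs))^2)
             } else NA_real_)
  structure(list(family = family, preprocess = prep, features = features,
                 fit = fit, cv_metrics = cv, config = config),
            class = "pox_regressor")
}

#' @export
print.pox_regressor <- function(x, ...) {
  cat(sprintf("<pox_regressor> %s: %d features, CV RMSE %.3f MAE %.3f R2 %.3f\n",
              x$family, length(x$features), x$cv_metrics$RMSE,
              x$cv_metrics$MAE, x$cv_metrics$R2))
  invisible(x)
}

#' @export
predict.pox_regressor <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  Xp <- preprocess_apply(object$preprocess, newdata)
  stats::predict(object$fit, as.data.frame(Xp[, object$features, drop = FALSE]))
}

# ---------------------------------------------------------------------------
# Y-randomization
# ---------------------------------------------------------------------------

#' Chance-correlation assessment by label permutation
#'
#' Repeats the training pipeline on permuted labels and collects the CV
#' metric distribution under the null.
#'
#' @param X,y,family,config as in [pox_train()]
#' @param n_rounds number of permutation rounds
#' @param seed seed controlling the permutations
#' @return list with `rounds` (data.frame of per-round CV metrics) and
#'   `quantiles` (2.5/50/97.5 percent of each metric)
#' @export
y_randomize <- function(X, y, family = "RF", config = pox_config(),
                        n_rounds = 10, seed = 1) {
  rounds <- lapply(seq_len(n_rounds), function(r) {
    yp <- with_seed(seed * 100L + r, sample(y))
    cfg <- config
    cfg$seed <- seed * 100L + r
    m <- pox_train(X, yp, family = family, threshold_id = "yrand", config = cfg)
    as.data.frame(m$cv_metrics)
  })
  rounds <- do.call(rbind, rounds)
  qs <- apply(rounds, 2, stats::quantile,
              probs = c(0.025, 0.5, 0.975), na.rm = TRUE)
  list(rounds = rounds, quantiles = qs)
}
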