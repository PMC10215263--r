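#' Hyperparameter search spaces for the six architectures
#'
#' The searched boxes for the Bayesian-optimized architectures: SVM
#' (kernel, epsilon, box constraint, kernel scale), tree ensembles
#' (method, minimum leaf size, number of learners, predictors to sample),
#' GPR (kernel, noise sigma, basis) and NN (layer size, lambda).  Linear
#' and stepwise regression have no tuned hyperparameters.
#'
#' @param architecture one of `"LR"`, `"SR"`, `"SVM"`, `"Ensemble"`,
#'   `"GPR"`, `"NN"`.
#' @param n_features number of predictors (bounds the
#'   predictors-to-sample range).
#' @param n_train number of training rows (bounds the leaf size).
#' @return list of parameter descriptors (empty for LR/SR).
#' @export
default_search_space <- function(architecture, n_features, n_train = 229) {
  switch(architecture,
         LR = , SR = list(),
         SVM = list(
           bo_param_cat("kernel", c("Gaussian", "Quadratic", "Cubic", "Linear")),
           bo_param_num("epsilon", 3.15e-4, 31.50, log = TRUE),
           bo_param_num("cost", 1e-3, 1e3, log = TRUE),
           bo_param_num("kernel_scale", 1e-3, 1e3, log = TRUE)),
         Ensemble = list(
           bo_param_cat("method", c("Bag", "LSBoost")),
           bo_param_num("min_leaf", 1, min(114, max(2, floor(n_train / 2))),
                        log = TRUE, integer = TRUE),
           bo_param_num("learners", 10, 500, log = TRUE, integer = TRUE),
           bo_param_num("n_predictors", 1, n_features, integer = TRUE)),
         GPR = list(
           bo_param_cat("kernel", gpr_kernels),
           bo_param_num("sigma", 1e-4, 3.05, log = TRUE),
           bo_param_cat("basis", c("constant", "zero", "linear"))),
         NN = list(
           bo_param_num("size", 1, 300, log = TRUE, integer = TRUE),
           bo_param_num("lambda", 4.36e-8, 4.36e2, log = TRUE)),
         stop_sljump("sljump_contract_error", "unknown architecture '%s'", architecture))
}

fit_architecture <- function(architecture, hp, X, y) {
  X <- as.matrix(X)
  df <- data.frame(X, check.names = FALSE)
  df$.y <- y
  fit <- switch(
    architecture,
    LR = lm(.y ~ ., data = df),
    SR = step(lm(.y ~ ., data = df), direction = "both", trace = 0, k = 2),
    SVM = {
      kern <- switch(hp$kernel, Gaussian = "radial", Quadratic = "polynomial",
                     Cubic = "polynomial", Linear = "linear")
      deg <- switch(hp$kernel, Quadratic = 2, Cubic = 3, 3)
      e1071::svm(X, y, type = "eps-regression", kernel = kern,
                 degree = deg, coef0 = if (kern == "polynomial") 1 else 0,
                 gamma = 1 / (2 * hp$kernel_scale^2),
                 cost = hp$cost, epsilon = hp$epsilon, scale = FALSE)
    },
    Ensemble = {
      if (hp$method == "Bag") {
        randomForest::randomForest(X, y, ntree = hp$learners,
                                   nodesize = hp$min_leaf,
                                   mtry = min(hp$n_predictors, ncol(X)))
      } else {
        xgboost::xgboost(data = X, label = y, nrounds = hp$learners,
                         params = list(objective = "reg:squarederror",
                                       eta = 0.1, max_depth = 3,
                                       min_child_weight = hp$min_leaf,
                                       colsample_bytree =
                                         min(hp$n_predictors, ncol(X)) / ncol(X),
                                       nthread = 1),
                         verbose = 0)
      }
    },
    GPR = gpr_fit(X, y, kernel = hp$kernel, sigma = hp$sigma, basis = hp$basis),
    NN = nnet::nnet(X, y, size = hp$size, decay = hp$lambda, linout = TRUE,
                    maxit = 300, trace = FALSE, MaxNWts = 100000),
    stop_sljump("sljump_contract_error", "unknown architecture '%s'", architecture))
  fit
}

predict_architecture <- function(architecture, fit, X) {
  X <- as.matrix(X)
  switch(architecture,
         LR = , SR = as.numeric(predict(fit, data.frame(X, check.names = FALSE))),
         SVM = as.numeric(predict(fit, X)),
         Ensemble = as.numeric(predict(fit, X)),
         GPR = predict(fit, X),
         NN = as.numeric(predict(fit, X)))
}

#' K-fold cross-validated RMSE of an architecture at fixed hyperparameters
#'
#' @param architecture architecture id.
#' @param hp named hyperparameter list.
#' @param X,y training data.
#' @param folds number of folds (default 10).
#' @param seed seed for the fold assignment.
#' @return pooled out-of-fold RMSE.
#' @export
cv_rmse <- function(architecture, hp, X, y, folds = 10, seed = 1) {
  n <- length(y)
  assign <- withr::with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  sq <- numeric(n)
  for (f in seq_len(folds)) {
    hold <- assign == f
    fit <- fit_architecture(architecture, hp, X[!hold, , drop = FALSE], y[!hold])
    sq[hold] <- (y[hold] - predict_architecture(architecture, fit,
                                                X[hold, , drop = FALSE]))^2
  }
  sqrt(mean(sq))
}

#' Train one regression architecture with Bayesian-optimized tuning
#'
#' For the four tunable architectures the hyperparameters minimizing the
#' 10-fold cross-validated RMSE are found by Bayesian optimization over
#' [default_search_space()] within `budget` evaluations (default 30), and
#' the final model is refit on all training data.  `LR` has no tuning and
#' `SR` uses AIC-based forward-backward stepwise selection.
#'
#' @param architecture one of `"LR"`, `"SR"`, `"SVM"`, `"Ensemble"`,
#'   `"GPR"`, `"NN"`.
#' @param train_X normalized training features (matrix or data frame).
#' @param train_y response (m).
#' @param budget optimization budget (objective evaluations).
#' @param cv_folds number of cross-validation folds.
#' @param seed integer seed controlling folds and the optimizer.
#' @param space optional replacement search space.
#' @return object of class `slj_model` carrying the fitted model, chosen
#'   hyperparameters, feature names, CV RMSE and training metrics.
#' @export
train_model <- function(architecture, train_X, train_y, budget = 30,
                        cv_folds = 10, seed = 1, space = NULL) {
  X <- as.matrix(train_X)
  if (length(train_y) < 2 * cv_folds)
    stop_sljump("sljump_data_error",
                "need at least %d training rows for %d-fold CV", 2 * cv_folds, cv_folds)
  space <- space %||% default_search_space(architecture, ncol(X), nrow(X))
  if (length(space)) {
    opt <- bo_optimize(
      function(hp) cv_rmse(architecture, hp, X, train_y, cv_folds, seed),
      space, budget = budget, seed = seed)
    hp <- opt$best_params
    cv <- opt$best_value
    history <- opt$history
  } else {
    hp <- list()
    cv <- cv_rmse(architecture, hp, X, train_y, cv_folds, seed)
    history <- NULL
  }
  fit <- fit_architecture(architecture, hp, X, train_y)
  train_metrics <- regression_metrics(
    train_y, predict_architecture(architecture, fit, X))
  structure(list(architecture = architecture, hyperparameters = hp,
                 fit = fit, features = colnames(X),
                 cv_rmse = cv, train_metrics = train_metrics,
                 optimization_history = history, seed = seed),
            class = "slj_model")
}

#' @export
print.slj_model <- function(x, ...) {
  hp <- if (length(x$hyperparameters))
    paste(names(x$hyperparameters),
          vapply(x$hyperparameters, function(v) format(v, digits = 4), ""),
          sep = "=", collapse = ", ") else "none"
  cat(sprintf("<slj_model> %s (%d features); CV RMSE %.4f m; hyperparameters: %s\n",
              x$architecture, length(x$features), x$cv_rmse, hp))
  invisible(x)
}

#' @export
predict.slj_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (is.null(colnames(X)) || !all(object$features %in% colnames(X)))
    stop_sljump("sljump_contract_error",
                "newdata must contain the model's feature columns")
  predict_architecture(object$architecture, object$fit,
                       X[, object$features, drop = FALSE])
}

#' Run the full modelling pipeline on a feature dataset
#'
#' Split, z-score normalization fitted on the training set, Lasso feature
#' reduction, Bayesian-optimized training of one architecture, and test
#' evaluation.
#'
#' @param ds data frame with the 61 features and `l_meter`.
#' @param architecture architecture id (default `"GPR"`).
#' @param train_frac split fraction.
#' @param alpha Lasso penalty.
#' @param budget,cv_folds tuning controls.
#' @param seed integer seed for split, folds and optimizer.
#' @return list with the trained `model`, `selection`, `normalization`,
#'   `split`, test `predictions` and train/test `metrics`.
#' @export
run_model_pipeline <- function(ds, architecture = "GPR", train_frac = 0.8,
                               alpha = 0.1, budget = 30, cv_folds = 10,
                               seed = 1) {
  feats <- intersect(feature_names(), names(ds))
  sp <- split_dataset(ds, train_frac, seed = seed)
  norm <- fit_normalization(sp$train[, feats])
  Xtr <- apply_normalization(sp$train[, feats], norm)
  sel <- lasso_select(Xtr, sp$train$l_meter, alpha = alpha)
  model <- train_model(architecture, Xtr[, sel$selected, drop = FALSE],
                       sp$train$l_meter, budget = budget,
                       cv_folds = cv_folds, seed = seed)
  Xte <- apply_normalization(sp$test[, feats], norm)[, sel$selected, drop = FALSE]
  pred <- predict(model, Xte)
  list(model = model, selection = sel, normalization = norm, split = sp,
       predictions = pred,
       metrics = list(train = model$train_metrics,
                      test = regression_metrics(sp$test$l_meter, pred)))
}

#' Persist / restore a trained model
#'
#' The archive is a self-describing R list (architecture id,
#' hyperparameters, selected features, normalization parameters, fitted
#' state) serialized with `saveRDS`.
#'
#' @param model an `slj_model` (or the list returned by
#'   [run_model_pipeline()]).
#' @param path archive path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
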