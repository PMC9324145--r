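#' The ten-classifier registry
#'
#' The benchmark's ten supervised model families: RBF support vector
#' machine, decision tree, AdaBoost, feed-forward neural network, random
#' forest (200 trees), k-nearest neighbors, logistic regression, linear
#' discriminant analysis, gradient-boosted trees, and Gaussian naive Bayes.
#' Each entry is a `fit(x, y)` closure returning an object whose
#' `predict_prob(fit, x)` gives a samples-by-classes probability matrix.
#' AdaBoost is a SAMME implementation over depth-limited `rpart` trees; the
#' neural network is a single-hidden-layer `nnet` (size 32, decay 0.01).
#'
#' @param models optional character subset of
#'   `c("SVM","DT","Ada","NN","RF","KNN","LR","DA","GBDT","NB")`.
#' @return named list of model descriptors.
#' @export
model_registry <- function(models = NULL) {
  reg <- list(
    SVM = list(
      fit = function(x, y) e1071::svm(x, y, kernel = "radial",
                                      probability = TRUE),
      prob = function(fit, x) {
        pr <- attr(predict(fit, x, probability = TRUE), "probabilities")
        pr[, levels(fit$fitted), drop = FALSE]
      }),
    DT = list(
      fit = function(x, y) {
        df <- data.frame(x, .y = y, check.names = FALSE)
        rpart::rpart(.y ~ ., data = df, method = "class")
      },
      prob = function(fit, x)
        predict(fit, data.frame(x, check.names = FALSE), type = "prob")),
    Ada = list(
      fit = function(x, y) adaboost_fit(x, y, n_rounds = 50L, maxdepth = 2L),
      prob = function(fit, x) adaboost_prob(fit, x)),
    NN = list(
      fit = function(x, y) nnet::nnet(x, nnet::class.ind(y), size = 32,
                                      decay = 0.01, maxit = 300,
                                      softmax = TRUE, trace = FALSE,
                                      MaxNWts = 100000),
      prob = function(fit, x) {
        pr <- predict(fit, x)
        if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)
        pr
      }),
    RF = list(
      fit = function(x, y) randomForest::randomForest(x, y, ntree = 200),
      prob = function(fit, x) predict(fit, x, type = "prob")),
    KNN = list(
      fit = function(x, y) caret::knn3(x, y, k = 5),
      prob = function(fit, x) predict(fit, x, type = "prob")),
    LR = list(
      fit = function(x, y) {
        df <- data.frame(x, .y = y, check.names = FALSE)
        nnet::multinom(.y ~ ., data = df, decay = 1e-4, maxit = 500,
                       trace = FALSE, MaxNWts = 100000)
      },
      prob = function(fit, x) {
        pr <- predict(fit, data.frame(x, check.names = FALSE),
                      type = "probs")
        if (is.null(dim(pr))) {
          pr <- cbind(1 - pr, pr)
          colnames(pr) <- fit$lev
        }
        pr
      }),
    DA = list(
      fit = function(x, y) {
        keep <- apply(x, 2L, var) > 0
        if (!any(keep)) keep[1] <- TRUE
        fit <- MASS::lda(x[, keep, drop = FALSE], grouping = y)
        attr(fit, "keep") <- keep
        fit
      },
      prob = function(fit, x)
        predict(fit, x[, attr(fit, "keep"), drop = FALSE])$posterior),
    GBDT = list(
      fit = function(x, y) xgboost::xgboost(as.matrix(x), y, nrounds = 100,
                                            max_depth = 3,
                                            learning_rate = 0.1,
                                            nthreads = 1, verbosity = 0),
      prob = function(fit, x) {
        pr <- predict(fit, as.matrix(x), type = "response")
        if (is.null(dim(pr))) {
          lev <- attr(fit, "classes")
          pr <- cbind(1 - pr, pr)
          colnames(pr) <- lev
        }
        pr
      }),
    NB = list(
      fit = function(x, y) e1071::naiveBayes(x, y),
      prob = function(fit, x) predict(fit, x, type = "raw"))
  )
  if (!is.null(models)) {
    models <- match.arg(models, names(reg), several.ok = TRUE)
    reg <- reg[models]
  }
  reg
}

# SAMME AdaBoost over rpart trees (no AdaBoost package is available, and
# the algorithm is small): reweighted trees with log((1-err)/err) +
# log(K-1) stage weights; class probabilities from normalized stage votes.
adaboost_fit <- function(x, y, n_rounds = 50L, maxdepth = 2L) {
  y <- as.factor(y)
  k <- nlevels(y)
  n <- length(y)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  df <- data.frame(x, .y = y, check.names = FALSE)
  for (r in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = maxdepth,
                                                       cp = 0, xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / k) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(k - 1)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err < 1e-8) break
  }
  structure(list(trees = trees, alphas = alphas, levels = levels(y)),
            class = "perfrad_adaboost")
}

adaboost_prob <- function(model, x) {
  df <- data.frame(x, check.names = FALSE)
  k <- length(model$levels)
  votes <- matrix(0, nrow(df), k, dimnames = list(NULL, model$levels))
  if (length(model$trees) == 0) return(votes + 1 / k)
  for (r in seq_along(model$trees)) {
    pred <- predict(model$trees[[r]], df, type = "class")
    votes[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(df)), as.integer(pred))] + model$alphas[r]
  }
  votes / rowSums(votes)
}

# Align a probability matrix to the label levels and neutralize non-finite
# or all-zero rows (degenerate density estimates) to the uniform
# distribution.
sanitize_prob <- function(pr, lev) {
  if (is.null(dim(pr))) pr <- matrix(pr, ncol = length(lev))
  if (is.null(colnames(pr))) colnames(pr) <- lev
  pr <- pr[, lev, drop = FALSE]
  pr[!is.finite(pr)] <- 0
  rs <- rowSums(pr)
  bad <- rs <= 0
  if (any(bad)) { pr[bad, ] <- 1; rs[bad] <- length(lev) }
  pr / rs
}

# --- evaluation indexes ----------------------------------------------------

#' Five classification indexes from truth, predictions and probabilities
#'
#' Accuracy; macro-averaged precision, recall and F1 (classes absent from
#' the truth are skipped; empty predicted classes contribute precision 0);
#' AUC as the two-class probability AUC or its one-vs-rest macro average
#' for more classes (degenerate single-class truth gives NA, excluded
#' upstream by stratification).
#'
#' @param truth factor of true labels.
#' @param pred factor of predicted labels (same levels).
#' @param prob samples-by-classes probability matrix, columns named or
#'   ordered by `levels(truth)`.
#' @return named numeric: `Pre`, `Acc`, `Auc`, `F1`, `Recall`.
#' @export
classification_indexes <- function(truth, pred, prob) {
  lev <- levels(truth)
  pred <- factor(as.character(pred), levels = lev)
  acc <- mean(pred == truth)
  present <- lev[lev %in% as.character(truth)]
  prec <- rec <- f1 <- numeric(0)
  for (cl in present) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec <- c(prec, p); rec <- c(rec, r)
    f1 <- c(f1, if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  if (is.null(colnames(prob))) colnames(prob) <- lev
  aucs <- vapply(present, function(cl) {
    resp <- as.integer(truth == cl)
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, prob[, cl], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  c(Pre = mean(prec), Acc = acc, Auc = mean(aucs, na.rm = TRUE),
    F1 = mean(f1), Recall = mean(rec))
}

#' Cross-validated index matrix for one feature set
#'
#' Stratified tenfold cross-validation of the ten models on the selected
#' columns, averaging the five indexes over folds into the 10 x 5 metrics
#' matrix that feeds the composite score.
#'
#' @param featureset a `feature_set`, or a character vector of column
#'   names, or `NULL` for all columns.
#' @param m samples x features numeric matrix.
#' @param labels class labels.
#' @param models a [model_registry()] (defaults to all ten).
#' @param folds number of folds (default 10).
#' @param seed integer seed (fold assignment and stochastic learners).
#' @param cv_repeats number of repeated cross-validation rounds averaged
#'   together (default 1).
#' @return `metrics_matrix`: models x indexes numeric matrix with
#'   attributes `folds` and `seed`.
#' @export
crossval_metrics <- function(featureset, m, labels,
                             models = model_registry(), folds = 10L,
                             seed = 1L, cv_repeats = 1L) {
  cols <- if (inherits(featureset, "feature_set")) featureset$features
          else if (is.null(featureset)) colnames(m) else featureset
  miss <- setdiff(cols, colnames(m))
  if (length(miss) > 0) stop("unknown feature columns: ",
                             paste(head(miss, 3), collapse = ", "))
  x <- m[, cols, drop = FALSE]
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2) stop("need >= 2 classes")
  if (any(table(y) < folds))
    folds <- max(2L, min(folds, min(table(y))))
  idx_names <- c("Pre", "Acc", "Auc", "F1", "Recall")
  acc <- matrix(0, length(models), length(idx_names),
                dimnames = list(names(models), idx_names))
  set.seed(seed)
  for (rep in seq_len(cv_repeats)) {
    fold <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      if (length(unique(y[te])) < 1 || length(unique(y[tr])) < 2)
        stop("fold ", f, " lost a class despite stratification")
      for (mm in names(models)) {
        fit <- models[[mm]]$fit(x[tr, , drop = FALSE], y[tr])
        if (mm == "GBDT") attr(fit, "classes") <- levels(y)
        pr <- sanitize_prob(models[[mm]]$prob(fit, x[te, , drop = FALSE]),
                            levels(y))
        pred <- factor(levels(y)[max.col(pr, ties.method = "first")],
                       levels = levels(y))
        acc[mm, ] <- acc[mm, ] +
          classification_indexes(y[te], pred, pr)
      }
    }
  }
  out <- acc / (folds * cv_repeats)
  attr(out, "folds") <- folds
  attr(out, "seed") <- seed
  class(out) <- c("metrics_matrix", class(out))
  out
}

#' Composite score of a metrics matrix
#'
#' The grand mean of the five indexes over the ten models,
#' `CS = (1 / (K * M)) * sum over all cells`, with `K = 5` indexes and
#' `M = 10` models in the full benchmark (any complete grid is accepted).
#'
#' @param matrix a models x indexes numeric matrix.
#' @return scalar in `[0, 1]`.
#' @export
composite_score <- function(matrix) {
  if (anyNA(matrix)) stop("metrics matrix has missing cells")
  mean(matrix)
}

#' Benchmark every feature set and pick the best selection method
#'
#' Runs [crossval_metrics()] for each method's feature set and computes its
#' composite score; the best method attains the maximum CS, ties broken
#' alphabetically (and logged).
#'
#' @param featuresets named list of `feature_set` objects.
#' @param m samples x features matrix.
#' @param labels class labels.
#' @inheritParams crossval_metrics
#' @return list with `matrices` (named list), `cs` (named numeric),
#'   `best_method`.
#' @export
benchmark_selectors <- function(featuresets, m, labels,
                                models = model_registry(), folds = 10L,
                                seed = 1L, cv_repeats = 1L) {
  stopifnot(length(featuresets) >= 1)
  matrices <- list()
  cs <- setNames(numeric(0), character(0))
  for (nm in names(featuresets)) {
    fs <- featuresets[[nm]]
    if (length(fs$features) == 0) {
      warning("feature set ", nm, " is empty; scored 0")
      cs[nm] <- 0
      next
    }
    mat <- crossval_metrics(fs, m, labels, models, folds, seed, cv_repeats)
    matrices[[nm]] <- mat
    cs[nm] <- composite_score(mat)
  }
  list(matrices = matrices, cs = cs,
       best_method = select_best_method(cs))
}

#' @rdname benchmark_selectors
#' @param cs named numeric vector of composite scores.
#' @export
select_best_method <- function(cs) {
  stopifnot(length(cs) >= 1)
  best <- max(cs)
  winners <- sort(names(cs)[cs == best])
  if (length(winners) > 1)
    message("composite-score tie between ",
            paste(winners, collapse = ", "), "; keeping ", winners[1])
  winners[1]
}
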