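#' Regroup 7-level 90-day mRS labels
#'
#' The three prediction granularities: the native 7-category score (0..6),
#' the 4-category regrouping (0 = no symptoms; 1-2 mild; 3-4 moderate;
#' 5-6 severe) and the 2-category good/poor split (0-2 vs 3-6).
#'
#' @param mrs7 integer vector with values in 0..6.
#' @param scheme 2, 4 or 7.
#' @return factor of regrouped labels.
#' @export
regroup_mrs <- function(mrs7, scheme = c(7, 4, 2)) {
  scheme <- match.arg(as.character(scheme[1]), c("7", "4", "2"))
  if (any(mrs7 < 0 | mrs7 > 6 | mrs7 != floor(mrs7)))
    stop("mRS labels must be integers in 0..6")
  out <- switch(scheme,
    "7" = factor(mrs7, levels = 0:6),
    "4" = factor(c("0", "1-2", "1-2", "3-4", "3-4", "5-6", "5-6")[mrs7 + 1L],
                 levels = c("0", "1-2", "3-4", "5-6")),
    "2" = factor(ifelse(mrs7 <= 2, "good", "poor"),
                 levels = c("good", "poor"))
  )
  out
}

#' Select mRS radiomics features (mRSRF) with the winning method
#'
#' Applies the benchmark's best selection method against the outcome labels
#' of one situation. For Lasso (the expected winner) this is the printed
#' squared-loss L1 regression on the numeric label; features with nonzero
#' coefficients at the cross-validated penalty are kept. Any other winner
#' falls back to [select_features()] with the outcome labels as classes.
#'
#' @param m samples x features matrix of outstanding (selected) features.
#' @param labels outcome labels for the situation (factor or numeric).
#' @param best_method selection method name (default `"Lasso"`).
#' @param params a [selector_params()].
#' @param seed integer seed (cross-validation folds).
#' @param lambda optional fixed L1 penalty overriding the cross-validated
#'   choice.
#' @return a `feature_set` (possibly empty, with a warning).
#' @export
select_mrsrf <- function(m, labels, best_method = "Lasso",
                         params = selector_params(), seed = 1L,
                         lambda = NULL) {
  stopifnot(nrow(m) == length(labels))
  if (best_method != "Lasso")
    return(select_features(m, labels, best_method, params, seed))
  y <- if (is.factor(labels)) as.numeric(labels) - 1 else as.numeric(labels)
  set.seed(seed)
  if (!is.null(lambda) || ncol(m) < 2) {
    beta <- glmnet_coefs(m, y, "gaussian", lambda %||% params$lasso_lambda)
  } else {
    cvfit <- glmnet::cv.glmnet(m, y, alpha = 1, nfolds = 5)
    beta <- as.numeric(coef(cvfit, s = "lambda.min"))[-1L]
  }
  keep <- which(beta != 0)
  keep <- keep[order(-abs(beta[keep]), keep)]
  if (length(keep) == 0)
    warning("mRSRF selection kept no features")
  structure(list(method = "Lasso", features = colnames(m)[keep],
                 scores = setNames(beta[keep], colnames(m)[keep]),
                 params = params),
            class = "feature_set")
}

#' Assemble the seven feature groups
#'
#' Three single groups (CTI, mRSRF, SurvF) and their four fusions
#' (CTI+mRSRF, CTI+SurvF, mRSRF+SurvF, ALL), each a column-concatenated,
#' range-normalized matrix. Binary clinical indicators are kept 0/1;
#' continuous columns are range-normalized. Groups touching an empty mRSRF
#' are flagged degenerate and dropped from evaluation with a warning.
#'
#' @param cti clinical table (data frame).
#' @param mrsrf matrix of selected mRS radiomics feature values (columns may
#'   be empty).
#' @param survf numeric vector, the survival feature.
#' @return named list of numeric matrices (degenerate groups omitted, names
#'   recorded in `attr(, "degenerate")`).
#' @export
assemble_feature_groups <- function(cti, mrsrf, survf) {
  n <- nrow(cti)
  if (!is.null(mrsrf) && ncol(mrsrf) > 0 && nrow(mrsrf) != n)
    stop("misaligned sample counts between CTI and mRSRF")
  if (length(survf) != n) stop("misaligned sample counts for SurvF")
  cti_m <- as.matrix(vapply(cti, function(col) {
    if (all(col %in% c(0, 1))) as.numeric(col) else normalize_feature(col)
  }, numeric(n)))
  if (n == 1L) cti_m <- matrix(cti_m, nrow = 1L,
                               dimnames = list(NULL, names(cti)))
  colnames(cti_m) <- paste0("cti_", names(cti))
  sv <- matrix(normalize_feature(survf), ncol = 1L,
               dimnames = list(NULL, "survf"))
  has_mrsrf <- !is.null(mrsrf) && ncol(mrsrf) > 0
  mr <- if (has_mrsrf) {
    mm <- apply(mrsrf, 2L, normalize_feature)
    colnames(mm) <- paste0("mrsrf_", colnames(mrsrf))
    mm
  } else NULL
  groups <- list(CTI = cti_m)
  degenerate <- character(0)
  if (has_mrsrf) groups$mRSRF <- mr else degenerate <- c(degenerate, "mRSRF")
  groups$SurvF <- sv
  if (has_mrsrf) groups$`CTI+mRSRF` <- cbind(cti_m, mr) else
    degenerate <- c(degenerate, "CTI+mRSRF")
  groups$`CTI+SurvF` <- cbind(cti_m, sv)
  if (has_mrsrf) {
    groups$`mRSRF+SurvF` <- cbind(mr, sv)
    groups$ALL <- cbind(cti_m, mr, sv)
  } else degenerate <- c(degenerate, "mRSRF+SurvF", "ALL")
  if (length(degenerate) > 0)
    warning("degenerate groups without mRSRF: ",
            paste(degenerate, collapse = ", "))
  attr(groups, "degenerate") <- degenerate
  groups
}

#' Evaluate feature groups on a held-out split
#'
#' One stratified 70/30 train/test split per call; every group x model pair
#' is fitted on the training rows and scored on the test rows with the five
#' indexes, then group means over models (mAuc, mAcc, mPre, mF1, mRecall)
#' are attached.
#'
#' @param groups named list of feature matrices ([assemble_feature_groups()]).
#' @param labels outcome labels (factor).
#' @param models a [model_registry()].
#' @param ratio training fraction (default 0.7).
#' @param seed integer seed (split and stochastic learners).
#' @param split optional logical vector (TRUE = train) overriding the
#'   internal split, e.g. to reuse the split the survival net was trained
#'   on.
#' @return list with `metrics` (data frame: group, model, five indexes),
#'   `group_means` (data frame), `split`.
#' @export
evaluate_outcomes <- function(groups, labels, models = model_registry(),
                              ratio = 0.7, seed = 1L, split = NULL) {
  y <- droplevels(as.factor(labels))
  if (any(table(y) < 2))
    stop("every outcome class needs >= 2 samples to stratify the split")
  set.seed(seed)
  if (is.null(split)) split <- stratified_split(y, ratio)
  if (length(unique(y[split])) < nlevels(y) ||
      length(unique(y[!split])) < nlevels(y))
    stop("a class is absent from one side of the split")
  rows <- list()
  for (g in names(groups)) {
    x <- groups[[g]]
    for (mm in names(models)) {
      fit <- models[[mm]]$fit(x[split, , drop = FALSE], y[split])
      if (mm == "GBDT") attr(fit, "classes") <- levels(y)
      pr <- sanitize_prob(models[[mm]]$prob(fit, x[!split, , drop = FALSE]),
                          levels(y))
      pred <- factor(levels(y)[max.col(pr, ties.method = "first")],
                     levels = levels(y))
      idx <- classification_indexes(y[!split], pred, pr)
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, model = mm, t(idx))
    }
  }
  metrics <- do.call(rbind, rows)
  gm <- do.call(rbind, lapply(base::split(metrics, metrics$group), function(d)
    data.frame(group = d$group[1], mAuc = mean(d$Auc), mAcc = mean(d$Acc),
               mPre = mean(d$Pre), mF1 = mean(d$F1),
               mRecall = mean(d$Recall))))
  rownames(gm) <- NULL
  gm <- gm[match(names(groups), gm$group), ]
  list(metrics = metrics, group_means = gm, split = split)
}
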