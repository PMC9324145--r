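#' Levene variance-homogeneity gate
#'
#' Mean-centered Levene test: a one-way ANOVA of the absolute deviations
#' from each group's mean. The flag `equal_var = (p >= alpha)` decides
#' between the pooled-variance and Welch branches of the two-sample t-test.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @param alpha gate threshold (default 0.05).
#' @return list with `statistic`, `p`, `equal_var`.
#' @export
variance_gate <- function(x, y, alpha = 0.05) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  zx <- abs(x - mean(x))
  zy <- abs(y - mean(y))
  n1 <- length(zx); n2 <- length(zy); N <- n1 + n2
  zbar <- mean(c(zx, zy))
  ssb <- n1 * (mean(zx) - zbar)^2 + n2 * (mean(zy) - zbar)^2
  ssw <- sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2)
  if (ssw == 0) {
    stat <- if (ssb == 0) 0 else Inf
  } else stat <- (ssb / 1) / (ssw / (N - 2))
  p <- pf(stat, 1, N - 2, lower.tail = FALSE)
  list(statistic = stat, p = p, equal_var = p >= alpha)
}

#' Two-sample t-test with a precomputed variance-homogeneity decision
#'
#' Pooled-variance t when `equal_var`, Welch t with Satterthwaite degrees of
#' freedom otherwise; two-sided p-value.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @param equal_var logical from [variance_gate()].
#' @return list with `statistic`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, equal_var = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  md <- mean(x) - mean(y)
  if (equal_var) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se2 == 0) {
    if (md == 0) stop("zero variance in both groups with equal means")
    stat <- sign(md) * Inf
  } else stat <- md / sqrt(se2)
  p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

# Vectorized column-wise Levene gate + gated t-test over a samples x
# features matrix split by binary labels; returns a data frame.
columnwise_gated_t <- function(m, labels, alpha = 0.05) {
  g1 <- labels == 1
  g0 <- labels == 0
  x <- m[g1, , drop = FALSE]
  y <- m[g0, , drop = FALSE]
  n1 <- nrow(x); n2 <- nrow(y); N <- n1 + n2
  mx <- colMeans(x); my <- colMeans(y)
  # Levene on absolute deviations from group means
  zx <- abs(sweep(x, 2L, mx)); zy <- abs(sweep(y, 2L, my))
  mzx <- colMeans(zx); mzy <- colMeans(zy)
  zbar <- (n1 * mzx + n2 * mzy) / N
  ssb <- n1 * (mzx - zbar)^2 + n2 * (mzy - zbar)^2
  ssw <- colSums(sweep(zx, 2L, mzx)^2) + colSums(sweep(zy, 2L, mzy)^2)
  lev_stat <- ifelse(ssw > 0, ssb / (ssw / (N - 2)),
                     ifelse(ssb > 0, Inf, 0))
  levene_p <- pf(lev_stat, 1, N - 2, lower.tail = FALSE)
  equal_var <- levene_p >= alpha
  # both branches, vectorized
  v1 <- colSums(sweep(x, 2L, mx)^2) / (n1 - 1)
  v2 <- colSums(sweep(y, 2L, my)^2) / (n2 - 1)
  md <- mx - my
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (N - 2)
  se2_pool <- sp2 * (1 / n1 + 1 / n2)
  se2_w <- v1 / n1 + v2 / n2
  df_w <- se2_w^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  se2 <- ifelse(equal_var, se2_pool, se2_w)
  df <- ifelse(equal_var, N - 2, df_w)
  stat <- ifelse(se2 > 0, md / sqrt(se2), ifelse(md == 0, 0, Inf * sign(md)))
  t_p <- ifelse(se2 > 0 | md != 0,
                2 * pt(abs(stat), df, lower.tail = FALSE), 1)
  data.frame(feature = colnames(m), levene_p = levene_p,
             equal_var = equal_var, t_p = t_p, stringsAsFactors = FALSE)
}

#' Filter features significantly different between lesion and normal tissue
#'
#' Each column is range-normalized (see [normalize_feature()]), gated by the
#' mean-centered Levene test at `alpha`, then tested with the pooled or
#' Welch two-sample t-test between the tissue classes; columns with
#' `t_p < alpha` are kept. No multiple-testing correction is applied (the
#' procedure deliberately uses raw p < alpha).
#'
#' @param table a `feature_table` (see [build_table()]) or numeric matrix.
#' @param labels tissue labels, 0 = normal, 1 = lesion; defaults to the
#'   table's row metadata.
#' @param alpha significance level (default 0.05).
#' @param normalization `"range"` (default) or `"zscore"`.
#' @return list with `results` (per-feature data frame: `feature`,
#'   `levene_p`, `equal_var`, `t_p`, `significant`), `reduced` (the table
#'   restricted to significant columns, normalized values), and `alpha`.
#' @export
filter_significant <- function(table, labels = NULL, alpha = 0.05,
                               normalization = c("range", "zscore")) {
  normalization <- match.arg(normalization)
  if (inherits(table, "feature_table")) {
    m <- table$values
    if (is.null(labels)) labels <- table$row_meta$tissue
  } else m <- as.matrix(table)
  if (is.null(labels)) stop("labels required for a bare matrix")
  if (length(unique(labels)) < 2)
    stop("both tissue classes must be present")
  stopifnot(nrow(m) == length(labels))
  mn <- apply(m, 2L, normalize_feature, method = normalization)
  res <- columnwise_gated_t(mn, labels, alpha)
  res$significant <- res$t_p < alpha
  keep <- which(res$significant)
  reduced <- mn[, keep, drop = FALSE]
  out <- list(results = res, reduced = reduced, alpha = alpha,
              labels = labels)
  if (inherits(table, "feature_table"))
    out$col_meta <- table$col_meta[keep, , drop = FALSE]
  out
}
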