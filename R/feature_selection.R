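#' Selector parameters
#'
#' Shared tuning knobs of the 13 feature-selection methods. The selection
#' thresholds are fixed by the benchmarked procedure: Lasso keeps features
#' with |coefficient| > 0.02, all other methods keep features whose
#' (min-max normalized) score exceeds 0.9, and every method returns at most
#' 20 features.
#'
#' @param mi_bins equal-width discretization bins for mutual information.
#' @param mifs_beta redundancy weight of MIFS.
#' @param knn_k neighbor count for the Laplacian-score / MCFS affinity
#'   graph and for ReliefF hits/misses.
#' @param relieff_iters number of ReliefF anchor samples (`NULL` = all).
#' @param mcfs_clusters number of spectral-embedding components in MCFS.
#' @param mcfs_lambda L1 penalty of the per-component MCFS regressions.
#' @param alpha_wealth `(initial wealth, payout)` of alpha investing; the
#'   per-feature test level is `0.5 * wealth`.
#' @param lasso_lambda L1 penalty of the Lasso selector.
#' @param max_features selection cap (20).
#' @param score_threshold normalized-score cutoff (0.9).
#' @param lasso_coef_threshold Lasso coefficient cutoff (0.02).
#' @return object of class `selector_params`.
#' @export
selector_params <- function(mi_bins = 10L, mifs_beta = 0.5, knn_k = 5L,
                            relieff_iters = NULL, mcfs_clusters = 2L,
                            mcfs_lambda = 0.01,
                            alpha_wealth = c(0.5, 0.5),
                            lasso_lambda = 0.05, max_features = 20L,
                            score_threshold = 0.9,
                            lasso_coef_threshold = 0.02) {
  stopifnot(mi_bins >= 1, knn_k >= 1, mcfs_clusters >= 1,
            max_features >= 1, length(alpha_wealth) == 2L)
  structure(as.list(environment()), class = "selector_params")
}

#' All thirteen selector names
#' @return character vector in canonical order.
#' @export
selector_methods <- function() {
  c("CMIM", "JMI", "MIFS", "MIM", "MRMR", "Fisher", "LS", "ReliefF",
    "FS", "TS", "MCFS", "Alpha", "Lasso")
}

# --- mutual information primitives ----------------------------------------

# Equal-width discretization into `bins` integer levels 1..bins.
discretize_ew <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1L, length(x)))
  lev <- floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
  lev[lev > bins] <- bins
  as.integer(lev)
}

entropy_nats <- function(y) {
  p <- tabulate(as.integer(factor(y)))
  p <- p[p > 0] / length(y)
  -sum(p * log(p))
}

#' Plug-in mutual information between a feature and class labels
#'
#' `x` is discretized into `bins` equal-width levels (already-integer input
#' with few levels is used as is when `bins` is `NULL`); MI is computed from
#' the joint empirical distribution, in nats.
#'
#' @param x numeric or integer vector.
#' @param y class labels.
#' @param bins discretization bin count (default 10).
#' @return mutual information in nats (>= 0).
#' @export
mutual_information <- function(x, y, bins = 10L) {
  if (length(x) == 0 || length(x) != length(y)) stop("empty or unaligned input")
  xi <- if (is.null(bins)) as.integer(factor(x)) else discretize_ew(x, bins)
  mi_disc(xi, as.integer(factor(y)))
}

mi_disc <- function(xi, yi) {
  nx <- max(xi); ny <- max(yi)
  joint <- tabulate((yi - 1L) * nx + xi, nbins = nx * ny) / length(xi)
  px <- tabulate(xi, nbins = nx) / length(xi)
  py <- tabulate(yi, nbins = ny) / length(yi)
  pij <- matrix(joint, nx, ny)
  pp <- outer(px, py)
  ok <- pij > 0
  sum(pij[ok] * log(pij[ok] / pp[ok]))
}

# I(x; y | z) for integer-coded vectors.
cond_mi_disc <- function(xi, yi, zi) {
  out <- 0
  for (z in unique(zi)) {
    sel <- zi == z
    pz <- mean(sel)
    xs <- as.integer(factor(xi[sel])); ys <- as.integer(factor(yi[sel]))
    out <- out + pz * mi_disc(xs, ys)
  }
  out
}

# --- information-theoretic greedy selectors -------------------------------

#' Greedy information-theoretic feature scoring
#'
#' Implements the five mutual-information selectors. `MIM` scores every
#' feature by its marginal MI with the class. The other four run greedy
#' forward selection, scoring each candidate `f_i` against the selected set
#' `S` by the printed criteria: `MIFS = I(fi;C) - beta * sum_s I(fi;fs)`,
#' `MRMR = I(fi;C) - mean_s I(fi;fs)`,
#' `JMI = I(fi;C) - mean_s [I(fi;C) - I(fi;C|fs)]`,
#' `CMIM = min_s I(fi;C|fs)`; with an empty `S` all four reduce to MIM.
#' The recorded score of a selected feature is its criterion value at the
#' step it was chosen; ties break toward the earlier column.
#'
#' @param method one of `"MIM"`, `"MIFS"`, `"MRMR"`, `"JMI"`, `"CMIM"`.
#' @param m samples x features numeric matrix with column names.
#' @param labels class labels (>= 2 classes).
#' @param params a [selector_params()].
#' @return list with `scores` (named; `NA` for features never reached by
#'   the greedy pass) and `order` (selected feature names in order).
#' @export
score_features_ti <- function(method, m, labels, params = selector_params()) {
  method <- match.arg(method, c("MIM", "MIFS", "MRMR", "JMI", "CMIM"))
  if (length(unique(labels)) < 2) stop("need >= 2 classes")
  p <- ncol(m)
  yi <- as.integer(factor(labels))
  disc <- matrix(0L, nrow(m), p)
  for (j in seq_len(p)) disc[, j] <- discretize_ew(m[, j], params$mi_bins)
  rel <- vapply(seq_len(p), function(j) mi_disc(disc[, j], yi), numeric(1))
  nm <- colnames(m)
  if (method == "MIM") {
    scores <- setNames(rel, nm)
    return(list(scores = scores, order = nm[order(-rel, seq_len(p))]))
  }
  k_max <- min(params$max_features, p)
  selected <- integer(0)
  scores <- setNames(rep(NA_real_, p), nm)
  red_sum <- numeric(p)   # running sum of I(fi; fs), s in S
  cmi_sum <- numeric(p)   # running sum of I(fi; C | fs)
  cmi_min <- rep(Inf, p)  # running min of I(fi; C | fs)
  for (step in seq_len(k_max)) {
    cand <- setdiff(seq_len(p), selected)
    crit <- switch(method,
      MIFS = rel[cand] - params$mifs_beta * red_sum[cand],
      MRMR = if (length(selected) == 0) rel[cand] else
        rel[cand] - red_sum[cand] / length(selected),
      JMI = if (length(selected) == 0) rel[cand] else
        rel[cand] - (length(selected) * rel[cand] - cmi_sum[cand]) /
          length(selected),
      CMIM = if (length(selected) == 0) rel[cand] else
        pmin(rel[cand], cmi_min[cand])
    )
    best <- cand[which.max(crit)]
    scores[best] <- max(crit)
    selected <- c(selected, best)
    if (length(selected) == k_max) break
    rest <- setdiff(seq_len(p), selected)
    if (method %in% c("MIFS", "MRMR")) {
      red_sum[rest] <- red_sum[rest] + vapply(rest, function(j)
        mi_disc(disc[, j], disc[, best]), numeric(1))
    } else {
      new_cmi <- vapply(rest, function(j)
        cond_mi_disc(disc[, j], yi, disc[, best]), numeric(1))
      cmi_sum[rest] <- cmi_sum[rest] + new_cmi
      cmi_min[rest] <- pmin(cmi_min[rest], new_cmi)
    }
  }
  list(scores = scores, order = nm[selected])
}

# --- similarity-based selectors -------------------------------------------

knn_heat_affinity <- function(m, k) {
  d2 <- as.matrix(dist(m))^2
  n <- nrow(d2)
  bw <- mean(d2[upper.tri(d2)])
  if (!is.finite(bw) || bw == 0) bw <- 1
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[2:min(k + 1L, n)]
    W[i, nb] <- exp(-d2[i, nb] / bw)
  }
  pmax(W, t(W))  # symmetrize: kNN in either direction
}

#' Similarity-based feature scoring (Fisher, Laplacian score, ReliefF)
#'
#' `Fisher`: ratio of between-class to within-class variance,
#' `sum_c n_c (mu_c - mu)^2 / sum_c n_c sigma_c^2` (population variances).
#' `LS`: Laplacian score on a `knn_k`-NN heat-kernel affinity graph
#' (bandwidth = mean pairwise squared distance); reported as `1 - LS` so
#' higher is better, like every other method. `ReliefF`: average normalized
#' near-hit/near-miss difference over anchor samples (`knn_k` neighbors,
#' Manhattan distance, all samples as anchors by default).
#'
#' @inheritParams score_features_ti
#' @param method one of `"Fisher"`, `"LS"`, `"ReliefF"`.
#' @return list with `scores` (named) and `order`.
#' @export
score_features_sif <- function(method, m, labels, params = selector_params()) {
  method <- match.arg(method, c("Fisher", "LS", "ReliefF"))
  nm <- colnames(m)
  p <- ncol(m)
  if (method == "Fisher") {
    if (length(unique(labels)) < 2) stop("need >= 2 classes")
    f <- as.factor(labels)
    if (any(table(f) < 2)) stop("every class needs >= 2 samples")
    mu <- colMeans(m)
    between <- numeric(p); within <- numeric(p)
    for (cl in levels(f)) {
      sub <- m[f == cl, , drop = FALSE]
      nc <- nrow(sub)
      muc <- colMeans(sub)
      between <- between + nc * (muc - mu)^2
      within <- within + nc * colMeans(sweep(sub, 2L, muc)^2)
    }
    scores <- ifelse(within > 0, between / within,
                     ifelse(between > 0, Inf, 0))
  } else if (method == "LS") {
    W <- knn_heat_affinity(m, params$knn_k)
    Dv <- rowSums(W)
    scores <- vapply(seq_len(p), function(j) {
      f <- m[, j]
      ft <- f - sum(f * Dv) / sum(Dv)
      den <- sum(Dv * ft^2)
      if (den == 0) return(0)  # constant feature: worst score after 1 - LS
      num <- sum(ft * (Dv * ft - W %*% ft))  # f' L f
      1 - num / den
    }, numeric(1))
  } else {
    scores <- relieff_weights(m, labels, params)
  }
  scores <- setNames(scores, nm)
  list(scores = scores, order = nm[order(-scores, seq_len(p))])
}

relieff_weights <- function(m, labels, params) {
  f <- as.factor(labels)
  if (nlevels(f) < 2) stop("need >= 2 classes")
  n <- nrow(m); p <- ncol(m)
  rngs <- apply(m, 2L, function(x) diff(range(x)))
  rngs[rngs == 0] <- 1
  mn <- sweep(m, 2L, rngs, `/`)
  d <- as.matrix(dist(mn, method = "manhattan"))
  anchors <- if (is.null(params$relieff_iters)) seq_len(n) else
    sample.int(n, min(params$relieff_iters, n), replace = FALSE)
  k <- params$knn_k
  priors <- table(f) / n
  W <- numeric(p)
  for (i in anchors) {
    same <- which(f == f[i]); same <- setdiff(same, i)
    if (length(same) == 0) next
    hits <- same[order(d[i, same])][seq_len(min(k, length(same)))]
    hit_term <- colMeans(abs(sweep(mn[hits, , drop = FALSE], 2L, mn[i, ])))
    miss_term <- numeric(p)
    other <- setdiff(levels(f), as.character(f[i]))
    po <- 1 - priors[[as.character(f[i])]]
    for (cl in other) {
      cls <- which(f == cl)
      miss <- cls[order(d[i, cls])][seq_len(min(k, length(cls)))]
      wcl <- priors[[cl]] / po
      miss_term <- miss_term +
        wcl * colMeans(abs(sweep(mn[miss, , drop = FALSE], 2L, mn[i, ])))
    }
    W <- W + (miss_term - hit_term)
  }
  W / length(anchors)
}

# --- statistical selectors -------------------------------------------------

#' Statistical feature scoring (F-score and T-score)
#'
#' Two-class statistics on each feature:
#' `FS = [(mu+ - mu)^2 + (mu- - mu)^2] / (s+^2 + s-^2)` with sample
#' variances, and the t-statistic
#' `TS = (mu+ - mu-) / sqrt(s+^2/n+ + s-^2/n-)` (scale-invariant; zero when
#' the class means agree). Ranking uses `|TS|`-compatible min-max
#' normalization downstream.
#'
#' @inheritParams score_features_ti
#' @param method `"FS"` or `"TS"`.
#' @return list with `scores` (named) and `order`.
#' @export
score_features_stf <- function(method, m, labels) {
  method <- match.arg(method, c("FS", "TS"))
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("FS/TS require exactly 2 classes")
  pos <- m[f == levels(f)[2L], , drop = FALSE]
  neg <- m[f == levels(f)[1L], , drop = FALSE]
  np <- nrow(pos); nn <- nrow(neg)
  mup <- colMeans(pos); mun <- colMeans(neg); mu <- colMeans(m)
  vp <- apply(pos, 2L, var); vn <- apply(neg, 2L, var)
  if (method == "FS") {
    den <- vp + vn
    scores <- ifelse(den > 0, ((mup - mu)^2 + (mun - mu)^2) / den,
                     ifelse((mup - mu)^2 + (mun - mu)^2 > 0, Inf, 0))
  } else {
    den <- sqrt(vp / np + vn / nn)
    scores <- ifelse(den > 0, (mup - mun) / den,
                     ifelse(mup == mun, 0, Inf * sign(mup - mun)))
  }
  scores <- setNames(scores, colnames(m))
  list(scores = scores, order = names(sort(-abs(scores))))
}

# --- sparse / streaming selectors -----------------------------------------

# glmnet needs >= 2 columns; pad single-feature input with a zero dummy and
# return only the real coefficients.
glmnet_coefs <- function(x, y, family, lambda) {
  p <- ncol(x)
  if (p == 1L) x <- cbind(x, `.dummy.` = 0)
  fit <- glmnet::glmnet(x, y, family = family, alpha = 1, lambda = lambda,
                        standardize = TRUE)
  as.numeric(fit$beta)[seq_len(p)]
}

#' Sparse and streaming feature scoring (MCFS, alpha investing, Lasso)
#'
#' `MCFS`: spectral embedding of a `knn_k`-NN heat-kernel graph into
#' `mcfs_clusters` components (smallest non-trivial generalized Laplacian
#' eigenvectors), one L1 regression of each component on the features,
#' score = `max_k |coefficient|`. `Alpha`: a streaming pass over features in
#' column order; feature `j` is admitted when the Rao score test p-value of
#' adding it to a running logistic model beats the wealth-derived level
#' `alpha_j = 0.5 * wealth`; wealth gains the configured payout on
#' admission and pays `alpha_j / (1 - alpha_j)` otherwise. `Lasso`:
#' L1-penalized logistic fit at `lasso_lambda`, score = |coefficient|.
#'
#' @inheritParams score_features_ti
#' @param method `"MCFS"`, `"Alpha"` or `"Lasso"`.
#' @return list with `scores` (named), `order`, and for `Alpha` the
#'   admitted-feature names as `admitted`.
#' @export
score_features_ssl <- function(method, m, labels, params = selector_params()) {
  method <- match.arg(method, c("MCFS", "Alpha", "Lasso"))
  nm <- colnames(m)
  p <- ncol(m)
  if (method == "MCFS") {
    W <- knn_heat_affinity(m, params$knn_k)
    Dv <- rowSums(W)
    Dv[Dv == 0] <- 1e-12
    # generalized eigenproblem L y = lambda D y via the symmetric form
    S <- diag(1 / sqrt(Dv)) %*% W %*% diag(1 / sqrt(Dv))
    eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
    k <- min(params$mcfs_clusters, nrow(m) - 1L)
    comp <- diag(1 / sqrt(Dv)) %*% eg$vectors[, 1L + seq_len(k), drop = FALSE]
    # unit-variance components so L1 coefficients are comparable across
    # the per-component regressions
    comp <- apply(comp, 2L, function(v)
      if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0)
    coefs <- matrix(0, p, k)
    for (j in seq_len(k))
      coefs[, j] <- glmnet_coefs(m, comp[, j], "gaussian",
                                 params$mcfs_lambda)
    scores <- apply(abs(coefs), 1L, max)
  } else if (method == "Alpha") {
    return(alpha_investing(m, labels, params))
  } else {
    y <- as.integer(as.factor(labels)) - 1L
    scores <- abs(glmnet_coefs(m, y, "binomial", params$lasso_lambda))
  }
  scores <- setNames(scores, nm)
  list(scores = scores, order = nm[order(-scores, seq_len(p))])
}

# Streaming alpha-investing over features in column order; logistic model,
# Rao score test for each candidate given the currently admitted set.
alpha_investing <- function(m, labels, params) {
  y <- as.integer(as.factor(labels)) - 1L
  n <- nrow(m); p <- ncol(m)
  wealth <- params$alpha_wealth[1L]
  payout <- params$alpha_wealth[2L]
  admitted <- integer(0)
  pvals <- rep(NA_real_, p)
  X <- matrix(1, n, 1L)  # intercept-only start
  fit <- stats::glm.fit(X, y, family = stats::binomial())
  for (j in seq_len(p)) {
    alpha_j <- 0.5 * wealth
    if (alpha_j <= 0) { pvals[j] <- 1; next }
    mu <- fit$fitted.values
    w <- pmax(mu * (1 - mu), 1e-10)
    xj <- m[, j]
    XtWX <- crossprod(X, X * w)
    beta <- tryCatch(solve(XtWX, crossprod(X, xj * w)),
                     error = function(e) NULL)
    xt <- if (is.null(beta)) xj - mean(xj) else xj - as.numeric(X %*% beta)
    U <- sum(xt * (y - mu))
    V <- sum(w * xt^2)
    pv <- if (V <= 0) 1 else pf(U^2 / V, 1, Inf, lower.tail = FALSE)
    pvals[j] <- pv
    if (pv < alpha_j) {
      admitted <- c(admitted, j)
      X <- cbind(X, xj)
      fit <- stats::glm.fit(X, y, family = stats::binomial())
      wealth <- wealth + payout
    } else {
      wealth <- wealth - alpha_j / (1 - alpha_j)
      if (wealth < 0) wealth <- 0
    }
  }
  alpha_ref <- 0.5 * params$alpha_wealth[1L]
  scores <- ifelse(seq_len(ncol(m)) %in% admitted, 1,
                   pmin(0.89, pmax(0, 1 - pvals / max(alpha_ref, 1e-12))))
  scores <- setNames(scores, colnames(m))
  list(scores = scores, order = colnames(m)[admitted],
       admitted = colnames(m)[admitted])
}

# --- selection rule and dispatcher ----------------------------------------

#' Apply the benchmark's selection-threshold rule to raw scores
#'
#' Lasso keeps features with raw |coefficient| > 0.02; every other method
#' min-max normalizes its scores to `[0, 1]` (magnitudes for the signed
#' T-score; only greedily reached features participate for the greedy
#' selectors; alpha investing's scores are already on `[0, 1]` and are used
#' as is) and keeps scores > 0.9. Both branches truncate to the top 20 by
#' score, ties broken by column order. An empty selection triggers a
#' warning.
#'
#' @param method selector name (see [selector_methods()]).
#' @param scored list with `scores`/`order` from a `score_features_*`
#'   function.
#' @param params a [selector_params()].
#' @return object of class `feature_set`: list with `method`, `features`,
#'   `scores` (raw scores of the kept features), `params`.
#' @export
apply_selection_rule <- function(method, scored, params = selector_params()) {
  scores <- scored$scores
  nm <- names(scores)
  if (method == "Lasso") {
    keep <- which(abs(scores) > params$lasso_coef_threshold)
    keep <- keep[order(-abs(scores[keep]), keep)]
  } else {
    s <- scores
    if (method == "TS") s <- abs(s)
    avail <- which(!is.na(s) & is.finite(s))
    inf_pos <- which(is.infinite(s) & s > 0)
    if (method == "Alpha") {
      norm <- s
    } else {
      norm <- rep(NA_real_, length(s))
      if (length(avail) > 0) {
        rng <- range(s[avail])
        norm[avail] <- if (rng[1] == rng[2]) 1 else
          (s[avail] - rng[1]) / (rng[2] - rng[1])
      }
      norm[inf_pos] <- 1
    }
    keep <- which(!is.na(norm) & norm > params$score_threshold)
    keep <- keep[order(-norm[keep], keep)]
  }
  if (length(keep) > params$max_features)
    keep <- keep[seq_len(params$max_features)]
  if (length(keep) == 0)
    warning("selection rule kept no features for method ", method)
  structure(list(method = method, features = nm[keep],
                 scores = scores[keep], params = params),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s: %d features\n", x$method,
              length(x$features)))
  invisible(x)
}

#' Run one (or all) of the thirteen selectors on a feature matrix
#'
#' @param m samples x features numeric matrix with column names (typically
#'   the significance-filtered, normalized table).
#' @param labels class labels (tissue 0/1 for the lesion benchmark).
#' @param method a selector name, or `"all"`.
#' @param params a [selector_params()].
#' @param seed integer seed fixing ReliefF anchor sampling and any solver
#'   randomness.
#' @return a `feature_set`, or a named list of them for `"all"`.
#' @export
select_features <- function(m, labels, method = "all",
                            params = selector_params(), seed = 1L) {
  if (identical(method, "all")) {
    out <- lapply(selector_methods(), function(mm)
      select_features(m, labels, mm, params, seed))
    names(out) <- selector_methods()
    return(out)
  }
  method <- match.arg(method, selector_methods())
  set.seed(seed)
  scored <- switch(method,
    MIM = , MIFS = , MRMR = , JMI = , CMIM =
      score_features_ti(method, m, labels, params),
    Fisher = , LS = , ReliefF =
      score_features_sif(method, m, labels, params),
    FS = , TS = score_features_stf(method, m, labels),
    MCFS = , Alpha = , Lasso =
      score_features_ssl(method, m, labels, params)
  )
  apply_selection_rule(method, scored, params)
}
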