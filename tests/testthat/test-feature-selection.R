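test_that("mutual information matches contingency-table oracles", {
  y <- rep(c(0, 1), each = 40)
  # identity: MI equals the label entropy
  expect_equal(mutual_information(y, y, bins = 2), log(2))
  y2 <- c(rep(0, 60), rep(1, 20))
  h <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(mutual_information(y2, y2, bins = 2), h)
  # independence: constant feature carries nothing
  expect_equal(mutual_information(rep(1, 80), y, bins = 5), 0)
  # 2x2 joint counts (30,10;10,30)
  x <- c(rep(0, 30), rep(1, 10), rep(0, 10), rep(1, 30))
  expect_equal(mutual_information(x, y, bins = 2), mi_oracle(x, y))
})

test_that("greedy selectors equal exhaustive per-step evaluation", {
  toy <- discrete_toy(n = 40L, p = 5L)
  params <- selector_params(mi_bins = 4L, max_features = 4L)
  yi <- as.integer(factor(toy$y))
  disc <- apply(toy$m, 2L, perfrad:::discretize_ew, bins = 4L)
  rel <- vapply(1:5, function(j) mi_oracle(disc[, j], yi), numeric(1))

  for (method in c("MIFS", "MRMR", "JMI", "CMIM")) {
    got <- score_features_ti(method, toy$m, toy$y, params)
    # brute-force greedy with oracle criteria
    sel <- integer(0)
    for (step in 1:4) {
      cand <- setdiff(1:5, sel)
      crit <- vapply(cand, function(i) {
        if (length(sel) == 0) return(rel[i])
        switch(method,
          MIFS = rel[i] - params$mifs_beta *
            sum(vapply(sel, function(s) mi_oracle(disc[, i], disc[, s]),
                       numeric(1))),
          MRMR = rel[i] -
            mean(vapply(sel, function(s) mi_oracle(disc[, i], disc[, s]),
                        numeric(1))),
          JMI = rel[i] -
            mean(vapply(sel, function(s)
              rel[i] - cmi_oracle(disc[, i], yi, disc[, s]), numeric(1))),
          CMIM = min(vapply(sel, function(s)
            cmi_oracle(disc[, i], yi, disc[, s]), numeric(1)))
        )
      }, numeric(1))
      sel <- c(sel, cand[which.max(crit)])
    }
    expect_equal(got$order, colnames(toy$m)[sel],
                 label = paste(method, "greedy order"))
  }
})

test_that("with one candidate every greedy method reduces to MIM", {
  toy <- discrete_toy(p = 5L)
  m1 <- toy$m[, 1, drop = FALSE]
  params <- selector_params(mi_bins = 4L)
  mim <- score_features_ti("MIM", m1, toy$y, params)$scores
  for (method in c("MIFS", "MRMR", "JMI", "CMIM"))
    expect_equal(score_features_ti(method, m1, toy$y, params)$scores[1],
                 mim[1], label = method)
})

test_that("redundant duplicates are penalized below their marginal score", {
  toy <- discrete_toy(p = 5L)
  m <- cbind(toy$m, f1_copy = toy$m[, 1])
  params <- selector_params(mi_bins = 4L, max_features = 6L)
  mim <- score_features_ti("MIM", m, toy$y, params)$scores
  for (method in c("MIFS", "MRMR")) {
    got <- score_features_ti(method, m, toy$y, params)
    dup <- intersect(c("f1", "f1_copy"), got$order[-1])[1]
    expect_lt(got$scores[dup], mim[dup])
  }
})

test_that("Fisher score matches the between/within variance ratio", {
  # population means 0 and 2, population within-variance 1, equal sizes
  m <- matrix(c(-1, 1, 1, 3), ncol = 1)
  colnames(m) <- "f1"
  got <- score_features_sif("Fisher", m, c(0, 0, 1, 1))
  expect_equal(unname(got$scores["f1"]), 1)
  # near-indicator feature dwarfs pure noise
  set.seed(3)
  y <- rep(c(0, 1), each = 30)
  m2 <- cbind(ind = y + rnorm(60, sd = 0.05), noise = rnorm(60))
  s <- score_features_sif("Fisher", m2, y)$scores
  expect_gt(s[["ind"]], 100 * max(s[["noise"]], 1e-9))
})

test_that("Laplacian score favors locally smooth features", {
  set.seed(9)
  cl <- rep(c(0, 5), each = 20)
  m <- cbind(smooth = cl + rnorm(40, sd = 0.2), noise = rnorm(40))
  s <- score_features_sif("LS", m, rep(c(0, 1), each = 20))$scores
  expect_gt(s[["smooth"]], s[["noise"]])  # reported as 1 - LS
})

test_that("ReliefF is maximal for a perfectly separating feature", {
  y <- rep(c(0, 1), each = 20)
  set.seed(10)
  m <- cbind(sep = y, noise = rnorm(40))
  s <- score_features_sif("ReliefF", m, y)$scores
  expect_equal(unname(s[["sep"]]), 1)
  expect_gt(s[["sep"]], s[["noise"]] + 0.5)
})

test_that("F-score and T-score match a hand-computed toy", {
  pos <- c(4, 5, 6); neg <- c(1, 2, 3)
  m <- matrix(c(neg, pos), ncol = 1); colnames(m) <- "f1"
  y <- c(0, 0, 0, 1, 1, 1)
  fs <- score_features_stf("FS", m, y)$scores[["f1"]]
  mu <- mean(c(pos, neg))
  expect_equal(fs, ((mean(pos) - mu)^2 + (mean(neg) - mu)^2) /
                 (var(pos) + var(neg)))
  ts <- score_features_stf("TS", m, y)$scores[["f1"]]
  expect_equal(ts, (mean(pos) - mean(neg)) /
                 sqrt(var(pos) / 3 + var(neg) / 3))
  # equal class means: zero T-score; positive scaling leaves TS unchanged
  m0 <- matrix(c(1, 2, 3, 3, 2, 1), ncol = 1); colnames(m0) <- "f1"
  expect_equal(score_features_stf("TS", m0, y)$scores[["f1"]], 0)
  expect_equal(score_features_stf("TS", m * 7, y)$scores[["f1"]], ts)
})

test_that("full shrinkage empties the Lasso selection", {
  pm <- planted_matrix(n_per_class = 30L, p = 10L)
  fs <- select_features(pm$m, pm$labels, "Lasso",
                        selector_params(lasso_lambda = 1e6))
  expect_length(fs$features, 0L)
})

test_that("Lasso ranks a single informative feature first across replicates", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    m <- matrix(rnorm(200 * 10), 200, 10)
    colnames(m) <- paste0("f", 1:10)
    y <- rbinom(200, 1, plogis(2 * m[, 4]))
    sc <- score_features_ssl("Lasso", m, y,
                             selector_params(lasso_lambda = 0.02))
    names(which.max(sc$scores)) == "f4"
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("alpha investing respects its wealth budget", {
  pm <- planted_matrix(n_per_class = 40L, p = 10L)
  none <- score_features_ssl("Alpha", pm$m, pm$labels,
                             selector_params(alpha_wealth = c(0, 0.5)))
  expect_length(none$admitted, 0L)
  some <- score_features_ssl("Alpha", pm$m, pm$labels, selector_params())
  expect_true(all(c("f1", "f2", "f3") %in% some$admitted))
})

test_that("MCFS surfaces the feature that separates the clusters", {
  set.seed(17)
  cl <- rep(c(0, 4), each = 25)
  m <- cbind(sep = cl + rnorm(50, sd = 0.3),
             n1 = rnorm(50), n2 = rnorm(50))
  sc <- score_features_ssl("MCFS", m, rep(c(0, 1), each = 25),
                           selector_params())
  expect_equal(names(which.max(sc$scores)), "sep")
})

test_that("the selection rule applies the printed thresholds exactly", {
  params <- selector_params()
  # Lasso: 0.02 coefficient cutoff
  scored <- list(scores = c(a = 0.019, b = 0.021, c = 0.5))
  fs <- apply_selection_rule("Lasso", scored, params)
  expect_false("a" %in% fs$features)
  expect_true(all(c("b", "c") %in% fs$features))
  # generic: min-max normalized score > 0.9, capped at the top 20
  raw <- c(seq(0.905, 0.995, length.out = 25), seq(0.1, 0.5, length.out = 10))
  names(raw) <- paste0("g", seq_along(raw))
  fs2 <- apply_selection_rule("MIM", list(scores = raw / max(raw)), params)
  expect_length(fs2$features, 20L)
  expect_equal(fs2$features,
               names(sort(raw, decreasing = TRUE))[1:20])
  # nothing above the cutoff (unit-scale scores, used as is): empty set
  low <- setNames(c(0.1, 0.5, 0.9), c("a", "b", "c"))
  expect_warning(
    fs3 <- apply_selection_rule("Alpha", list(scores = low), params),
    "no features")
  expect_length(fs3$features, 0L)
})

test_that("selection is deterministic under a fixed seed", {
  pm <- planted_matrix(n_per_class = 25L, p = 12L)
  a <- select_features(pm$m, pm$labels, "all", seed = 5L)
  b <- select_features(pm$m, pm$labels, "all", seed = 5L)
  expect_identical(lapply(a, `[[`, "features"), lapply(b, `[[`, "features"))
  expect_length(a, 13L)
  expect_true(all(vapply(a, function(f) length(f$features) <= 20, logical(1))))
  all_cols <- colnames(pm$m)
  expect_true(all(unlist(lapply(a, `[[`, "features")) %in% all_cols))
})
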