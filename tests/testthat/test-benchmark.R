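test_that("a leaked label feature saturates every model's indexes", {
  set.seed(2)
  n <- 60
  labels <- rep(c(0, 1), each = n / 2)
  m <- cbind(leak = labels + rnorm(n, sd = 0.01), noise = rnorm(n))
  colnames(m) <- c("leak", "noise")
  mat <- crossval_metrics(c("leak"), m, labels, model_registry(),
                          folds = 5, seed = 3)
  expect_equal(dim(mat), c(10L, 5L))
  expect_true(all(mat >= 0.9))
})

test_that("pure-noise features score at chance", {
  set.seed(4)
  n <- 200
  labels <- rep(c(0, 1), each = n / 2)
  m <- matrix(rnorm(n * 5), n, 5)
  colnames(m) <- paste0("f", 1:5)
  mat <- crossval_metrics(NULL, m, labels, fast_models(),
                          folds = 10, seed = 5)
  expect_lt(abs(mean(mat[, "Auc"]) - 0.5), 0.12)
  expect_lt(abs(mean(mat[, "Acc"]) - 0.5), 3 * sqrt(0.25 / n) + 0.05)
})

test_that("cross-validation is deterministic under a fixed seed", {
  pm <- planted_matrix(n_per_class = 25L, p = 6L)
  a <- crossval_metrics(NULL, pm$m, pm$labels, fast_models(),
                        folds = 5, seed = 7)
  b <- crossval_metrics(NULL, pm$m, pm$labels, fast_models(),
                        folds = 5, seed = 7)
  expect_identical(unclass(a), unclass(b))
})

test_that("composite score is the grand mean of the index grid", {
  m <- matrix(0.6, 10, 5)
  expect_equal(composite_score(m), 0.6)
  g <- matrix(c(0.6, 1.0, 0.8, 0.6), 2, 2)  # rows = models, cols = indexes
  expect_equal(composite_score(g), 0.75)
  expect_equal(composite_score(g[2:1, ]), composite_score(g))
  expect_equal(composite_score(g[, 2:1]), composite_score(g))
  gna <- g; gna[1, 1] <- NA
  expect_error(composite_score(gna), "missing")
})

test_that("the best method is the CS argmax with alphabetical ties", {
  expect_equal(select_best_method(c(Lasso = 0.9)), "Lasso")
  expect_equal(select_best_method(c(MIM = 0.8, Lasso = 0.95, TS = 0.9)),
               "Lasso")
  expect_message(
    tie <- select_best_method(c(TS = 0.9, Fisher = 0.9, MIM = 0.5)),
    "tie")
  expect_equal(tie, "Fisher")
})

test_that("an informative feature set outscores a noise set", {
  set.seed(11)
  n <- 80
  labels <- rep(c(0, 1), each = n / 2)
  m <- cbind(sig1 = labels + rnorm(n, sd = 0.5),
             sig2 = labels + rnorm(n, sd = 0.7),
             n1 = rnorm(n), n2 = rnorm(n))
  good <- crossval_metrics(c("sig1", "sig2"), m, labels, fast_models(),
                           folds = 5, seed = 13)
  noise <- crossval_metrics(c("n1", "n2"), m, labels, fast_models(),
                            folds = 5, seed = 13)
  expect_gt(composite_score(good), composite_score(noise))
})

test_that("benchmarking several feature sets reports a coherent winner", {
  set.seed(15)
  n <- 60
  labels <- rep(c(0, 1), each = n / 2)
  m <- cbind(sig = labels + rnorm(n, sd = 0.4), n1 = rnorm(n))
  colnames(m) <- c("sig", "n1")
  mk <- function(method, cols) structure(
    list(method = method, features = cols,
         scores = setNames(rep(1, length(cols)), cols),
         params = selector_params()), class = "feature_set")
  out <- benchmark_selectors(
    list(Good = mk("MIM", "sig"), Bad = mk("TS", "n1")),
    m, labels, fast_models(), folds = 5, seed = 2)
  expect_equal(out$best_method, "Good")
  expect_true(all(out$cs >= 0 & out$cs <= 1))
  expect_warning(
    empty <- benchmark_selectors(list(E = mk("MIM", character(0))),
                                 m, labels, fast_models(), folds = 5),
    "empty")
  expect_equal(unname(empty$cs["E"]), 0)
})
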