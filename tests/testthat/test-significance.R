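test_that("range normalization matches its closed form", {
  expect_equal(normalize_feature(c(0, 1, 2)), c(-0.5, 0, 0.5))
  expect_equal(normalize_feature(rep(3, 5)), rep(0, 5))
  set.seed(1)
  x <- rnorm(50)
  expect_equal(mean(normalize_feature(x)), 0)
  expect_equal(normalize_feature(x), (x - mean(x)) / diff(range(x)))
  expect_equal(normalize_feature(x, "zscore"), (x - mean(x)) / sd(x))
})

test_that("variance gate agrees with the mean-centered Levene oracle", {
  set.seed(4)
  x <- rnorm(50); y <- rnorm(50, sd = 10)
  g <- variance_gate(x, y)
  oracle <- car::leveneTest(c(x, y), factor(rep(1:2, each = 50)),
                            center = mean)
  expect_equal(g$p, oracle$`Pr(>F)`[1], tolerance = 1e-10)
  expect_false(g$equal_var)

  # identical groups: maximal homogeneity
  z <- rnorm(20)
  gid <- variance_gate(z, z)
  expect_equal(gid$p, 1)
  expect_true(gid$equal_var)

  # order within groups is irrelevant
  g2 <- variance_gate(sample(x), sample(y))
  expect_equal(g2$p, g$p)
})

test_that("gated t-test matches stats::t.test in both branches", {
  set.seed(5)
  x <- rnorm(30); y <- rnorm(25, mean = 1, sd = 3)
  w <- two_sample_t(x, y, equal_var = FALSE)
  ref_w <- t.test(x, y, var.equal = FALSE)
  expect_equal(w$p, ref_w$p.value, tolerance = 1e-12)
  expect_equal(unname(w$df), unname(ref_w$parameter), tolerance = 1e-10)
  p <- two_sample_t(x, y, equal_var = TRUE)
  ref_p <- t.test(x, y, var.equal = TRUE)
  expect_equal(p$p, ref_p$p.value, tolerance = 1e-12)
  # symmetry under swapping groups
  expect_equal(two_sample_t(y, x, FALSE)$p, w$p)
  # identical groups: no evidence
  expect_equal(two_sample_t(x, x, TRUE)$p, 1)
  # strong separation
  set.seed(6)
  a <- rnorm(40); b <- rnorm(40, mean = 3)
  expect_lt(two_sample_t(a, b, TRUE)$p, 1e-6)
})

test_that("vectorized column tests agree with per-column stats oracles", {
  set.seed(8)
  m <- matrix(rnorm(60 * 12), 60, 12)
  m[, 3] <- m[, 3] * c(rep(1, 30), rep(4, 30))  # heteroscedastic column
  colnames(m) <- paste0("f", 1:12)
  labels <- rep(c(0, 1), each = 30)
  res <- perfrad:::columnwise_gated_t(m, labels)
  for (j in c(1, 3, 7)) {
    lev <- car::leveneTest(m[, j], factor(labels), center = mean)
    expect_equal(res$levene_p[j], lev$`Pr(>F)`[1], tolerance = 1e-10)
    ref <- t.test(m[labels == 1, j], m[labels == 0, j],
                  var.equal = res$equal_var[j])
    expect_equal(res$t_p[j], ref$p.value, tolerance = 1e-10)
  }
  expect_false(res$equal_var[3])
})

test_that("null features are retained at about the nominal rate", {
  fracs <- vapply(1:20, function(s) {
    set.seed(s)
    m <- matrix(rnorm(100 * 500), 100, 500)
    colnames(m) <- paste0("f", 1:500)
    sig <- filter_significant(m, rep(c(0, 1), each = 50))
    mean(sig$results$significant)
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / (500 * 20))
  expect_lt(abs(mean(fracs) - 0.05), 3 * se)
})

test_that("planted mean shifts survive the filter; alpha = 0 empties it", {
  pm <- planted_matrix(n_per_class = 80L, p = 50L, shift = 2,
                       n_informative = 5L, seed = 12L)
  sig <- filter_significant(pm$m, pm$labels)
  expect_true(all(paste0("f", 1:5) %in%
                    sig$results$feature[sig$results$significant]))
  sig0 <- filter_significant(pm$m, pm$labels, alpha = 0)
  expect_equal(ncol(sig0$reduced), 0L)
  expect_error(filter_significant(pm$m, rep(1, nrow(pm$m))), "class")
})

test_that("pooled and Welch branches agree under forced homoscedasticity", {
  set.seed(14)
  diffs <- replicate(50, {
    x <- rnorm(40); y <- rnorm(40)
    abs(two_sample_t(x, y, TRUE)$p - two_sample_t(x, y, FALSE)$p)
  })
  expect_lt(median(diffs), 0.01)
})
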