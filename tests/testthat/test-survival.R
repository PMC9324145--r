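test_that("Cox partial-likelihood loss matches hand-evaluated toys", {
  # a lone event is its own risk set
  expect_equal(cox_partial_likelihood_loss(0.3, 10, 1), 0)
  # two samples with equal risks, event on the shorter time: log 2
  expect_equal(cox_partial_likelihood_loss(c(1, 1), c(2, 5), c(1, 0)),
               log(2))
  # shift invariance
  r <- c(0.2, -1, 0.5, 2); tm <- c(4, 3, 2, 1); ev <- c(1, 0, 1, 1)
  expect_equal(cox_partial_likelihood_loss(r + 17, tm, ev),
               cox_partial_likelihood_loss(r, tm, ev))
  expect_error(cox_partial_likelihood_loss(r, tm, c(0, 0, 0, 0)),
               "no events")
})

test_that("Cox loss gradient matches numerical differentiation", {
  set.seed(2)
  r <- rnorm(6); tm <- runif(6); ev <- c(1, 0, 1, 1, 0, 1)
  g <- perfrad:::cox_loss_gradient(r, tm, ev)
  num <- vapply(1:6, function(i) {
    e <- rep(0, 6); e[i] <- 1e-6
    (cox_partial_likelihood_loss(r + e, tm, ev) -
       cox_partial_likelihood_loss(r - e, tm, ev)) / 2e-6
  }, numeric(1))
  expect_equal(g, num, tolerance = 1e-5)
})

test_that("concordance index matches brute-force pair enumeration", {
  # perfectly anti-ordered risks and times, all events
  expect_equal(concordance_index(c(3, 2, 1, 0), 1:4, rep(1, 4)), 1)
  # exactly one discordant pair of six comparable
  expect_equal(concordance_index(c(4, 3, 1, 2), 1:4, rep(1, 4)), 5 / 6)
  # risk ties count one half
  expect_equal(concordance_index(c(1, 1), c(1, 2), c(1, 1)), 0.5)
  expect_error(concordance_index(c(1, 2), c(5, 1), c(0, 0)), "comparable")
})

test_that("concordance agrees with the survival package on random data", {
  set.seed(6)
  n <- 60
  tm <- runif(n); r <- rnorm(n); ev <- rbinom(n, 1, 0.7)
  if (sum(ev) == 0) ev[1] <- 1
  got <- concordance_index(r, tm, ev)
  ref <- survival::concordance(survival::Surv(tm, ev) ~ r, reverse = TRUE)
  expect_equal(got, unname(ref$concordance), tolerance = 1e-10)
  # random risks sit near one half
  expect_lt(abs(got - 0.5), 0.15)
})

test_that("c-index is invariant under strictly monotone risk transforms", {
  set.seed(7)
  r <- rnorm(30); tm <- runif(30); ev <- rbinom(30, 1, 0.8); ev[1] <- 1
  expect_equal(concordance_index(exp(r), tm, ev),
               concordance_index(r, tm, ev))
})

test_that("the Cox net recovers a planted linear hazard", {
  set.seed(3)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3)
  colnames(x) <- c("a", "b", "c")
  tm <- rexp(n, rate = exp(1.5 * x[, 1]))
  net <- train_survival_net(x, tm, rep(1, n),
                            survival_config(epochs = 300, seed = 11))
  sv <- compute_survf(net, x)
  expect_gt(abs(cor(sv$risk, x[, 1], method = "spearman")), 0.8)
  expect_gt(sv$cindex, 0.75)
})

test_that("a net trained on permuted events carries no signal out of sample", {
  set.seed(5)
  n <- 120
  x <- matrix(rnorm(n * 3), n, 3)
  tm <- rexp(n, rate = exp(1.2 * x[, 1]))
  perm <- sample.int(n)
  net <- train_survival_net(x, tm[perm], rep(1, n),
                            survival_config(epochs = 150, seed = 7))
  x_new <- matrix(rnorm(n * 3), n, 3)
  tm_new <- rexp(n, rate = exp(1.2 * x_new[, 1]))
  r_new <- compute_survf(net, x_new)$risk
  ci <- concordance_index(r_new, tm_new, rep(1, n))
  expect_lt(abs(ci - 0.5), 0.1)
})

test_that("training and scoring are deterministic given the seed", {
  set.seed(9)
  x <- matrix(rnorm(40 * 2), 40, 2)
  tm <- runif(40); ev <- rbinom(40, 1, 0.6); ev[1] <- 1
  cfg <- survival_config(epochs = 50, seed = 21)
  a <- compute_survf(train_survival_net(x, tm, ev, cfg), x)
  b <- compute_survf(train_survival_net(x, tm, ev, cfg), x)
  expect_identical(a$survf, b$survf)
})

test_that("SurvF follows the range-normalization conventions", {
  set.seed(10)
  x <- matrix(rnorm(30 * 2), 30, 2)
  tm <- runif(30); ev <- rep(1, 30)
  net <- train_survival_net(x, tm, ev, survival_config(epochs = 20, seed = 2))
  # zeroed network: constant risks map to all-zero SurvF
  zeroed <- net
  zeroed$layers <- lapply(zeroed$layers, function(l)
    list(W = l$W * 0, b = l$b * 0))
  expect_equal(compute_survf(zeroed, x)$survf, rep(0, 30))
  # ranking preserved by the affine normalization
  sv <- compute_survf(net, x)
  expect_equal(rank(sv$survf), rank(sv$risk))
  expect_error(compute_survf(net, x[, 1, drop = FALSE]), "schema")
})
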