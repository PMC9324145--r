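test_that("mRS regrouping reproduces the published cohort distribution", {
  mrs7 <- rep(0:6, times = c(25, 11, 9, 4, 8, 9, 14))
  two <- regroup_mrs(mrs7, 2)
  expect_equal(as.integer(table(two)), c(45, 35))
  four <- regroup_mrs(mrs7, 4)
  expect_equal(as.integer(table(four)), c(25, 20, 12, 23))
  seven <- regroup_mrs(mrs7, 7)
  expect_equal(as.integer(table(seven)), c(25, 11, 9, 4, 8, 9, 14))
  # regrouping conserves the sample count under every scheme
  for (s in c(2, 4, 7))
    expect_equal(sum(table(regroup_mrs(mrs7, s))), length(mrs7))
})

test_that("degenerate and invalid labels are handled", {
  expect_equal(nlevels(droplevels(regroup_mrs(rep(0L, 10), 2))), 1L)
  expect_equal(nlevels(droplevels(regroup_mrs(rep(0L, 10), 4))), 1L)
  expect_error(regroup_mrs(c(1, 7), 2), "0..6")
  expect_error(regroup_mrs(c(-1, 2), 4), "0..6")
})

test_that("mRSRF selection finds a planted predictor and respects closure", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    m <- matrix(rnorm(120 * 8), 120, 8)
    colnames(m) <- paste0("r", 1:8)
    y <- 3 * m[, 5] + rnorm(120, sd = 0.5)
    fs <- select_mrsrf(m, y, seed = s)
    "r5" %in% fs$features
  }, logical(1))
  expect_gte(sum(hits), 19)
  set.seed(1)
  m <- matrix(rnorm(60 * 6), 60, 6); colnames(m) <- paste0("r", 1:6)
  y <- m[, 2] + rnorm(60)
  fs <- select_mrsrf(m, y)
  expect_true(all(fs$features %in% colnames(m)))
  # infinite penalty: empty selection
  expect_warning(none <- select_mrsrf(m, y, lambda = 1e9), "no features")
  expect_length(none$features, 0L)
})

test_that("the seven feature groups concatenate as documented", {
  set.seed(3)
  n <- 30
  cti <- generate_cti_table(n, seed = 4)
  mrsrf <- matrix(rnorm(n * 3), n, 3,
                  dimnames = list(NULL, paste0("r", 1:3)))
  survf <- rnorm(n)
  groups <- assemble_feature_groups(cti, mrsrf, survf)
  expect_named(groups, c("CTI", "mRSRF", "SurvF", "CTI+mRSRF", "CTI+SurvF",
                         "mRSRF+SurvF", "ALL"))
  expect_equal(ncol(groups$ALL),
               ncol(groups$CTI) + ncol(groups$mRSRF) + 1L)
  expect_true(all(colnames(groups$CTI) %in% colnames(groups$`CTI+SurvF`)))
  # continuous columns are centered; binary columns stay 0/1
  expect_equal(mean(groups$CTI[, "cti_age"]), 0)
  expect_true(all(groups$CTI[, "cti_hypertension"] %in% c(0, 1)))
  # an empty mRSRF degrades gracefully
  expect_warning(
    g2 <- assemble_feature_groups(cti, matrix(nrow = n, ncol = 0), survf),
    "degenerate")
  expect_named(g2, c("CTI", "SurvF", "CTI+SurvF"))
  expect_error(assemble_feature_groups(cti, mrsrf[1:10, ], survf),
               "misaligned")
})

test_that("evaluation produces a complete grid and detects leaks", {
  set.seed(5)
  n <- 60
  mrs7 <- rep(0:6, length.out = n)
  labels <- regroup_mrs(mrs7, 2)
  groups <- list(
    Leak = cbind(leak = as.numeric(labels) + rnorm(n, sd = 0.01)),
    Noise = cbind(x = rnorm(n))
  )
  ev <- evaluate_outcomes(groups, labels, fast_models(), seed = 6)
  expect_equal(nrow(ev$metrics), 2L * length(fast_models()))
  expect_true(all(c("Pre", "Acc", "Auc", "F1", "Recall") %in%
                    names(ev$metrics)))
  leak_rows <- ev$metrics[ev$metrics$group == "Leak", ]
  expect_true(all(leak_rows$Auc > 0.95))
  expect_equal(ev$group_means$group, c("Leak", "Noise"))
  # split respects stratification and the 7:3 ratio
  expect_equal(sum(ev$split), round(0.7 * sum(table(labels))), tolerance = 2)
  expect_error(
    evaluate_outcomes(groups, factor(c("a", rep("b", n - 1))),
                      fast_models()),
    ">= 2 samples")
})
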