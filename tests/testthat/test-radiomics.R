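test_that("series decomposition is the exact inverse of stacking", {
  out <- tiny_series(noise_sd = 2, n_timepoints = 7L)
  vols <- decompose_series(out$series)
  expect_length(vols, 7L)
  for (t in c(1L, 4L)) {
    v <- out$series$data[t, , , ]
    dim(v) <- dim(out$series$data)[-1]
    expect_equal(vols[[t]], v)
  }
  restacked <- aperm(simplify2array(vols), c(4, 1, 2, 3))
  expect_equal(restacked, out$series$data)
  single <- perfusion_series(array(1:8, dim = c(1, 2, 2, 2)))
  expect_length(decompose_series(single), 1L)
})

test_that("temporal naming follows the base_timepoint convention", {
  expect_equal(name_feature("log-sigma-1-0-mm-3D_firstorder_Skewness", 17),
               "log-sigma-1-0-mm-3D_firstorder_Skewness_17")
  expect_equal(name_feature("original_shape_Sphericity", 0),
               "original_shape_Sphericity_0")
  p <- parse_feature_name("wavelet-LLH_glcm_Contrast_49")
  expect_equal(p$base, "wavelet-LLH_glcm_Contrast")
  expect_equal(p$timepoint, 49L)
  # parse . name is the identity
  nm <- name_feature("original_ngtdm_Busyness", 3)
  p2 <- parse_feature_name(nm)
  expect_equal(name_feature(p2$base, p2$timepoint), nm)
})

test_that("full configuration yields exactly 1316 deterministic features", {
  out <- tiny_series(noise_sd = 2, n_timepoints = 5L)
  v <- decompose_series(out$series)[[3]]
  f <- extract_timepoint_features(v, out$roi$lt_mask, feature_config(),
                                  out$series$spacing)
  expect_length(f, 1316L)
  expect_true(all(is.finite(f)))
  counts <- table(perfrad:::feature_group(names(f)))
  expect_equal(counts[["Shape"]], 14L)
  expect_equal(counts[["First-order"]], 18L)
  expect_equal(counts[["GLCM"]], 24L)
  expect_equal(counts[["GLRLM"]], 16L)
  expect_equal(counts[["GLSZM"]], 16L)
  expect_equal(counts[["NGTDM"]], 5L)
  expect_equal(counts[["GLDM"]], 14L)
  expect_equal(counts[["Log-Sigma"]], 465L)
  expect_equal(counts[["Wavelet"]], 744L)
  f2 <- extract_timepoint_features(v, out$roi$lt_mask, feature_config(),
                                   out$series$spacing)
  expect_identical(f, f2)
})

test_that("shape features ignore intensities; first-order degenerates to zero", {
  out <- tiny_series(noise_sd = 2, n_timepoints = 5L)
  v <- decompose_series(out$series)[[2]]
  cfg <- feature_config(enabled_classes = "Shape")
  f1 <- extract_timepoint_features(v, out$roi$lt_mask, cfg,
                                   out$series$spacing)
  f2 <- extract_timepoint_features(v * 3 + 100, out$roi$lt_mask, cfg,
                                   out$series$spacing)
  expect_length(f1, 14L)
  expect_identical(f1, f2)

  cfg_fo <- feature_config(enabled_classes = "First-order")
  const <- array(42, dim(v))
  fc <- extract_timepoint_features(const, out$roi$lt_mask, cfg_fo,
                                   out$series$spacing)
  expect_equal(fc[["original_firstorder_Variance"]], 0)
  expect_equal(fc[["original_firstorder_Entropy"]], 0)
  expect_equal(fc[["original_firstorder_Uniformity"]], 1)
})

test_that("first-order statistics match direct computation on the ROI", {
  out <- tiny_series(noise_sd = 5, n_timepoints = 5L)
  v <- decompose_series(out$series)[[4]]
  vals <- v[out$roi$lt_mask == 1]
  cfg <- feature_config(enabled_classes = "First-order")
  f <- extract_timepoint_features(v, out$roi$lt_mask, cfg,
                                  out$series$spacing)
  expect_equal(f[["original_firstorder_Mean"]], mean(vals))
  expect_equal(f[["original_firstorder_Median"]], median(vals))
  expect_equal(f[["original_firstorder_Range"]], diff(range(vals)))
  expect_equal(f[["original_firstorder_Energy"]], sum(vals^2))
  expect_equal(f[["original_firstorder_RootMeanSquared"]],
               sqrt(mean(vals^2)))
  expect_equal(f[["original_firstorder_Variance"]],
               mean((vals - mean(vals))^2))
})

test_that("extraction rejects contract violations", {
  out <- tiny_series(n_timepoints = 5L)
  v <- decompose_series(out$series)[[1]]
  empty <- array(0, dim(v))
  expect_error(extract_timepoint_features(v, empty), "empty")
  wrong <- array(0, dim(v) + 1L); wrong[1] <- 1
  expect_error(extract_timepoint_features(v, wrong), "shape")
})

test_that("a shape-only table has 2 rows and 700 columns for 50 timepoints", {
  out <- tiny_series(noise_sd = 0, n_timepoints = 50L,
                     shape = c(4L, 12L, 12L))
  cfg <- feature_config(enabled_classes = "Shape")
  tab <- build_table(list(out$series), list(out$roi), cfg)
  expect_equal(dim(tab$values), c(2L, 700L))
  expect_equal(unname(table_group_counts(tab)[["Shape"]]), 700L)
  expect_equal(tab$row_meta$tissue, c(1L, 0L))
  expect_equal(sort(unique(tab$col_meta$timepoint)), 0:49)
})

test_that("an empty series list still yields the full column schema", {
  tab <- build_table(list(), list(), feature_config(), n_timepoints = 50L)
  expect_equal(nrow(tab$values), 0L)
  expect_equal(ncol(tab$values), 65800L)
  counts <- table_group_counts(tab)
  expect_equal(unname(counts[["Wavelet"]]), 37200L)
  expect_equal(unname(counts[["Log-Sigma"]]), 23250L)
})

test_that("noise-free lesion rows have higher mean intensity at the bolus peak", {
  cfg <- synth_config(n_patients = 2L, n_timepoints = 30L,
                      volume_shape = c(5L, 14L, 14L), noise_sd = 0,
                      amplitude_jitter = 0, seed = 31L)
  coh <- generate_cohort(cfg)
  tab <- build_table(coh$series, coh$rois,
                     feature_config(enabled_classes = "First-order"))
  peak_t <- cfg$bolus_onset_nt + cfg$bolus_shape_params[["beta"]]
  col <- name_feature("original_firstorder_Mean", peak_t)
  lt <- tab$values[tab$row_meta$tissue == 1L, col]
  nt <- tab$values[tab$row_meta$tissue == 0L, col]
  expect_true(all(lt > nt))
})
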