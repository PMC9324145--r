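test_that("identical seeds give bit-identical cohorts", {
  cfg <- synth_config(n_patients = 3L, n_timepoints = 10L,
                      volume_shape = c(4L, 10L, 10L), seed = 11L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$series[[2]]$data, b$series[[2]]$data)
  expect_identical(a$cti, b$cti)
  expect_identical(a$mrs7, b$mrs7)
})

test_that("bolus curves obey the lesion/normal-tissue contrast model", {
  # symmetry: equal amplitudes, no delay, no noise -> identical mean curves
  cfg <- synth_config(n_patients = 1L, n_timepoints = 40L,
                      volume_shape = c(6L, 16L, 16L), noise_sd = 0,
                      bolus_amplitude_lt = 150, bolus_amplitude_nt = 150,
                      bolus_delay_lt = 0, seed = 2L)
  set.seed(2)
  out <- generate_perfusion_series(cfg)
  lt_idx <- which(out$roi$lt_mask == 1)
  nt_idx <- which(out$roi$nt_mask == 1)
  d <- out$series$data
  dim(d) <- c(40, prod(dim(d)[-1]))
  expect_equal(rowMeans(d[, lt_idx]), rowMeans(d[, nt_idx]))

  # NT minimum equals baseline - amplitude (gamma-variate peak is 1)
  cfg2 <- synth_config(n_patients = 1L, n_timepoints = 50L,
                       volume_shape = c(6L, 16L, 16L), noise_sd = 0, seed = 3L)
  set.seed(3)
  out2 <- generate_perfusion_series(cfg2)
  d2 <- out2$series$data
  dim(d2) <- c(50, prod(dim(d2)[-1]))
  nt_curve <- rowMeans(d2[, which(out2$roi$nt_mask == 1)])
  expect_equal(min(nt_curve),
               cfg2$baseline_intensity - cfg2$bolus_amplitude_nt,
               tolerance = 1e-8)
  # lesion dips less and later
  lt_curve <- rowMeans(d2[, which(out2$roi$lt_mask == 1)])
  expect_gt(min(lt_curve), min(nt_curve))
  expect_gte(which.min(lt_curve), which.min(nt_curve))
})

test_that("amplitude ordering is enforced", {
  cfg <- synth_config(n_patients = 1L, volume_shape = c(4L, 10L, 10L))
  expect_error(generate_perfusion_series(cfg, amplitude_lt = 1e4),
               "must not exceed")
  expect_error(synth_config(bolus_amplitude_lt = 200,
                            bolus_amplitude_nt = 100))
})

test_that("clinical table reproduces the configured cohort marginals", {
  cti <- generate_cti_table(10000L, seed = 5L)
  expect_lt(abs(mean(cti$age) - 71.362), 3 * 10.91 / sqrt(10000))
  # binary rates within 3 binomial SE
  for (fld in c(sex_female = 0.2679, hypertension = 0.7375,
                diabetes = 0.325)) NULL
  rates <- c(sex_female = 0.2679, hypertension = 0.7375, diabetes = 0.325,
             atrial_fibrillation = 0.35, thrombectomy = 0.275)
  for (nm in names(rates)) {
    se <- sqrt(rates[[nm]] * (1 - rates[[nm]]) / 10000)
    expect_lt(abs(mean(cti[[nm]]) - rates[[nm]]), 3 * se)
  }
  expect_true(all(cti$nihss_income >= 0))
  expect_true(all(cti$lesion_volume >= 0))
})

test_that("clinical table boundary cases hold", {
  one <- generate_cti_table(1L, seed = 9L)
  expect_equal(nrow(one), 1L)
  expect_equal(ncol(one), 13L)
  expect_true(all(one$sex_female %in% c(0, 1)))
  allhyp <- generate_cti_table(50L, seed = 9L,
                               rates = c(hypertension = 1.0))
  expect_true(all(allhyp$hypertension == 1))
})

test_that("outcome generator plants signal and controls marginals", {
  cfg <- synth_config(n_patients = 500L, seed = 21L,
                      effect_config = c(age = 3))
  set.seed(21)
  cti <- generate_cti_table(500L)
  oc <- generate_outcomes(cti, NULL, cfg)
  expect_true(all(oc$mrs7 %in% 0:6))
  expect_gt(cor(cti$age, oc$mrs7, method = "spearman"), 0)

  # default quantile bucketing imitates the configured label counts at n=80
  cfg80 <- synth_config(n_patients = 80L, seed = 22L,
                        effect_config = c(age = 0.8, nihss_income = 1.0))
  set.seed(22)
  cti80 <- generate_cti_table(80L)
  oc80 <- generate_outcomes(cti80, NULL, cfg80)
  expect_equal(as.integer(table(factor(oc80$mrs7, levels = 0:6))),
               c(25, 11, 9, 4, 8, 9, 14))

  # zero coefficients: marginal still follows the configured priors
  cfg0 <- synth_config(n_patients = 400L, seed = 23L,
                       effect_config = c(age = 0))
  set.seed(23)
  cti0 <- generate_cti_table(400L)
  oc0 <- generate_outcomes(cti0, NULL, cfg0)
  pri <- cfg0$mrs_priors / sum(cfg0$mrs_priors)
  expect_lt(max(abs(as.integer(table(factor(oc0$mrs7, levels = 0:6))) / 400 -
                  pri)), 0.02)
})

test_that("outcome generator rejects unknown effect covariates", {
  cfg <- synth_config(effect_config = c(not_a_column = 1))
  cti <- generate_cti_table(10L, seed = 1L)
  expect_error(generate_outcomes(cti, NULL, cfg), "not_a_column")
})

test_that("planted truth records the imaging deficit that drives outcomes", {
  cfg <- synth_config(n_patients = 30L, n_timepoints = 8L,
                      volume_shape = c(4L, 10L, 10L), seed = 13L)
  coh <- generate_cohort(cfg)
  expect_length(coh$truth$perfusion_deficit, 30L)
  expect_true(all(coh$truth$amplitude_lt <= cfg$bolus_amplitude_nt))
  expect_named(coh$truth$coefficients)
})
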