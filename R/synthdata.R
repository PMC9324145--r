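#' Synthetic cohort configuration
#'
#' Parameters of the synthetic DSC-PWI cohort generator. The generator
#' emulates the three properties the downstream analysis relies on:
#' (a) time-intensity bolus curves in which lesion tissue (LT) shows a
#' smaller, delayed intensity dip than its mirrored normal tissue (NT);
#' (b) a clinical covariate table whose marginal distributions match the
#' published stroke-cohort statistics (age 71.362 +/- 10.91 years, 26.79%
#' female, lesion volume 95.583 +/- 72.304 mL, admission NIHSS
#' 9.919 +/- 6.747, outcome NIHSS 6.275 +/- 6.875, and the binary symptom /
#' comorbidity rates); and (c) a 7-level 90-day mRS label with a plantable
#' dependence on clinical and imaging covariates.
#'
#' The bolus is a gamma-variate
#' `g(t) = ((t - t0)/beta)^alpha * exp(alpha - alpha * (t - t0)/beta)`
#' for `t > t0` (zero before onset), which peaks at `t0 + beta` with value 1,
#' so `bolus_amplitude_*` is exactly the depth of the mean intensity dip.
#'
#' @param n_patients number of series to simulate.
#' @param n_timepoints timepoints per series (default 50, the scanner's
#'   number of measurements).
#' @param volume_shape integer length-3 `(slices, rows, cols)`; all >= 4.
#' @param baseline_intensity pre-bolus tissue intensity, a.u.
#' @param bolus_amplitude_nt depth of the normal-tissue intensity dip, a.u.
#' @param bolus_amplitude_lt depth of the lesion dip, a.u.; must not exceed
#'   `bolus_amplitude_nt` (hypoperfused tissue dips less).
#' @param bolus_onset_nt bolus arrival timepoint in normal tissue.
#' @param bolus_delay_lt additional arrival delay in lesion tissue
#'   (timepoints, >= 0).
#' @param bolus_shape_params `(alpha, beta)` of the gamma-variate.
#' @param noise_sd additive Gaussian noise sd, a.u. (>= 0).
#' @param amplitude_jitter per-patient sd of the lesion-amplitude deficit;
#'   makes the imaging signal patient-specific so it can drive the outcome.
#' @param effect_config named numeric vector: coefficient of each clinical or
#'   imaging covariate on the latent outcome score (see
#'   [generate_outcomes()]).
#' @param outcome_noise scale of the logistic noise on the latent outcome
#'   score (default 0.5, chosen so clinical covariates alone separate the
#'   good/poor split at the strong-but-imperfect level reported for real
#'   stroke cohorts, AUC around 0.85).
#' @param mrs_priors length-7 non-negative weights, the target marginal
#'   distribution of the 7-level mRS label (default: the published 80-set
#'   cohort counts 25, 11, 9, 4, 8, 9, 14).
#' @param repeated_measures if `TRUE`, `n_patients` series are drawn but a
#'   random subset of patients contributes two series (independent draws;
#'   within-patient correlation is not emulated).
#' @param seed integer seed controlling every random draw.
#' @return object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_patients = 80L,
                         n_timepoints = 50L,
                         volume_shape = c(8L, 32L, 32L),
                         baseline_intensity = 300,
                         bolus_amplitude_nt = 150,
                         bolus_amplitude_lt = 60,
                         bolus_onset_nt = 10,
                         bolus_delay_lt = 4,
                         bolus_shape_params = c(alpha = 3, beta = 6),
                         noise_sd = 5,
                         amplitude_jitter = 15,
                         effect_config = c(age = 0.8, nihss_income = 1.0,
                                           lesion_volume = 0.6,
                                           perfusion_deficit = 1.0),
                         outcome_noise = 0.5,
                         mrs_priors = c(25, 11, 9, 4, 8, 9, 14),
                         repeated_measures = FALSE,
                         seed = 1L) {
  stopifnot(n_timepoints >= 3L, length(volume_shape) == 3L,
            all(volume_shape >= 4L), noise_sd >= 0,
            bolus_amplitude_lt <= bolus_amplitude_nt,
            bolus_delay_lt >= 0, outcome_noise >= 0,
            length(bolus_shape_params) == 2L,
            all(bolus_shape_params > 0), length(mrs_priors) == 7L,
            all(mrs_priors >= 0), sum(mrs_priors) > 0)
  structure(as.list(environment()), class = "synth_config")
}

#' Gamma-variate bolus kernel
#'
#' `g(t) = ((t - t0)/beta)^alpha * exp(alpha - alpha*(t - t0)/beta)` for
#' `t > t0`, else 0; normalized so the peak (at `t = t0 + beta`) equals 1.
#'
#' @param t numeric vector of timepoints.
#' @param t0 onset time.
#' @param alpha,beta shape parameters (> 0).
#' @return numeric vector in `[0, 1]`.
#' @export
gamma_variate <- function(t, t0, alpha, beta) {
  u <- (t - t0) / beta
  g <- ifelse(u > 0, u^alpha * exp(alpha - alpha * u), 0)
  g
}

#' Generate one synthetic perfusion series with its ROI pair
#'
#' Builds an ellipsoidal lesion in the left half of the volume, mirrors it
#' across the midline for the NT mask, and fills every voxel with
#' `baseline - A * g(t - t0) + noise`, where lesion voxels use the smaller,
#' delayed bolus `(A_LT, t0_NT + delay)` and all other voxels the normal
#' bolus `(A_NT, t0_NT)`. Intensities are clipped at 0.
#'
#' @param config a [synth_config()].
#' @param amplitude_lt optional lesion amplitude override (per-patient
#'   heterogeneity); defaults to `config$bolus_amplitude_lt`.
#' @param lesion_spec optional list `(center, radii)` in voxel units to place
#'   the lesion deterministically; by default drawn from the current RNG
#'   state.
#' @return list with elements `series` ([perfusion_series()]) and `roi`
#'   ([roi_pair()]).
#' @export
generate_perfusion_series <- function(config, amplitude_lt = NULL,
                                      lesion_spec = NULL) {
  stopifnot(inherits(config, "synth_config"))
  shp <- config$volume_shape
  if (is.null(amplitude_lt)) amplitude_lt <- config$bolus_amplitude_lt
  if (amplitude_lt > config$bolus_amplitude_nt)
    stop("lesion amplitude must not exceed normal-tissue amplitude")
  if (is.null(lesion_spec)) lesion_spec <- draw_lesion_spec(shp)
  lt <- ellipsoid_mask(shp, lesion_spec$center, lesion_spec$radii)
  if (sum(lt) == 0) stop("degenerate lesion specification: empty mask")
  roi <- roi_pair(lt)

  t <- seq_len(config$n_timepoints) - 1
  ab <- config$bolus_shape_params
  g_nt <- gamma_variate(t, config$bolus_onset_nt, ab[1], ab[2])
  g_lt <- gamma_variate(t, config$bolus_onset_nt + config$bolus_delay_lt,
                        ab[1], ab[2])
  curve_nt <- config$baseline_intensity - config$bolus_amplitude_nt * g_nt
  curve_lt <- config$baseline_intensity - amplitude_lt * g_lt

  nt <- config$n_timepoints
  nvox <- prod(shp)
  dat <- matrix(rep(curve_nt, times = nvox), nrow = nt)
  lt_idx <- which(lt == 1)
  dat[, lt_idx] <- rep(curve_lt, times = length(lt_idx))
  dim(dat) <- c(nt, shp)
  if (config$noise_sd > 0)
    dat <- dat + rnorm(length(dat), sd = config$noise_sd)
  dat[dat < 0] <- 0
  list(series = perfusion_series(dat, spacing = c(5, 1, 1)), roi = roi)
}

# Random ellipsoid confined to the left half (columns below the midline)
# so mirroring cannot overlap.
draw_lesion_spec <- function(shp) {
  radii <- c(
    runif(1, 1.2, max(1.3, shp[1] / 4)),
    runif(1, 2.0, max(2.1, shp[2] / 5)),
    runif(1, 2.0, max(2.1, shp[3] / 8))
  )
  half <- shp[3] / 2
  cmax <- floor(half - radii[3] - 0.5)
  cmin <- ceiling(1 + radii[3])
  if (cmax < cmin) { cmin <- max(2, floor(half / 2)); cmax <- cmin }
  center <- c(
    runif(1, 1 + radii[1], shp[1] - radii[1]),
    runif(1, 1 + radii[2], shp[2] - radii[2]),
    runif(1, cmin, cmax)
  )
  list(center = center, radii = radii)
}

# Binary ellipsoid mask on a (slices, rows, cols) grid, 1-based centers.
ellipsoid_mask <- function(shp, center, radii) {
  s <- slice.index(array(0, shp), 1L)
  r <- slice.index(array(0, shp), 2L)
  c_ <- slice.index(array(0, shp), 3L)
  d <- ((s - center[1]) / radii[1])^2 + ((r - center[2]) / radii[2])^2 +
    ((c_ - center[3]) / radii[3])^2
  m <- array(as.numeric(d <= 1), shp)
  m
}

#' Generate a synthetic clinical table
#'
#' Draws `n` rows of the clinical covariates recorded for the stroke cohort:
#' age (normal), sex and seven binary symptom / comorbidity / treatment
#' indicators (Bernoulli), admission ("income") and outcome NIHSS and lesion
#' volume (normal truncated at 0). Defaults reproduce the published cohort
#' marginals.
#'
#' @param n number of rows.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param age_mean,age_sd age distribution parameters (years).
#' @param rates named Bernoulli rates for the binary fields; a partial
#'   vector overrides the matching defaults and leaves the rest in place.
#' @param nihss_income_mean,nihss_income_sd,nihss_outcome_mean,nihss_outcome_sd
#'   NIHSS distribution parameters.
#' @param volume_mean,volume_sd lesion-volume distribution (mL).
#' @return data frame with one row per patient series.
#' @export
generate_cti_table <- function(n, seed = NULL,
                               age_mean = 71.362, age_sd = 10.91,
                               rates = NULL,
                               nihss_income_mean = 9.919, nihss_income_sd = 6.747,
                               nihss_outcome_mean = 6.275, nihss_outcome_sd = 6.875,
                               volume_mean = 95.583, volume_sd = 72.304) {
  stopifnot(n >= 1)
  defaults <- c(sex_female = 0.2679, weak_right = 0.475, weak_left = 0.45,
                lisp = 0.7375, confusion = 0.125, hypertension = 0.7375,
                diabetes = 0.325, atrial_fibrillation = 0.35,
                thrombectomy = 0.275)
  bad <- setdiff(names(rates), names(defaults))
  if (length(bad) > 0)
    stop("unknown binary fields: ", paste(bad, collapse = ", "))
  if (!is.null(rates)) defaults[names(rates)] <- rates
  rates <- defaults
  if (!is.null(seed)) set.seed(seed)
  cti <- data.frame(
    age = rnorm(n, age_mean, age_sd),
    nihss_income = truncated_normal(n, nihss_income_mean, nihss_income_sd),
    nihss_outcome = truncated_normal(n, nihss_outcome_mean, nihss_outcome_sd),
    lesion_volume = truncated_normal(n, volume_mean, volume_sd)
  )
  for (nm in names(rates)) cti[[nm]] <- rbinom(n, 1L, rates[[nm]])
  cti[, c("age", "sex_female", "nihss_income", "nihss_outcome",
          "weak_right", "weak_left", "lisp", "confusion", "hypertension",
          "diabetes", "atrial_fibrillation", "thrombectomy",
          "lesion_volume")]
}

# Normal truncated below at 0 by rejection; deterministic under the RNG.
truncated_normal <- function(n, mean, sd, lower = 0) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  guard <- 0L
  while (length(bad) > 0 && guard < 1000L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
    guard <- guard + 1L
  }
  x[x < lower] <- lower
  x
}

#' Generate ordinal 90-day mRS outcomes with a planted dependence
#'
#' A latent score is formed as the linear combination of range-normalized
#' covariates named by `effect_config` plus standard logistic noise, then
#' bucketed into the 7 mRS levels. Default bin edges are the empirical
#' quantiles of the latent score at the cumulative `mrs_priors`, so the
#' marginal label counts imitate the configured cohort distribution while
#' the planted coefficients control which covariates carry signal.
#'
#' @param cti clinical table ([generate_cti_table()]).
#' @param features optional data frame of imaging covariates, same row count.
#' @param config a [synth_config()] (uses `effect_config` and `mrs_priors`).
#' @param bin_edges optional explicit increasing length-6 vector of latent
#'   cutpoints, overriding the quantile rule.
#' @return list with `mrs7` (integer 0..6), `latent` (the scores), and
#'   `truth` (the coefficients used).
#' @export
generate_outcomes <- function(cti, features = NULL, config,
                              bin_edges = NULL) {
  stopifnot(inherits(config, "synth_config"))
  pool <- cti
  if (!is.null(features)) {
    stopifnot(nrow(features) == nrow(cti))
    pool <- cbind(pool, features)
  }
  eff <- config$effect_config
  missing_cols <- setdiff(names(eff), names(pool))
  if (length(missing_cols) > 0)
    stop("effect_config names missing from covariates: ",
         paste(missing_cols, collapse = ", "))
  latent <- rlogis(nrow(pool)) * config$outcome_noise
  for (nm in names(eff))
    latent <- latent + eff[[nm]] * normalize_feature(pool[[nm]]) * 4
  if (is.null(bin_edges)) {
    pri <- config$mrs_priors / sum(config$mrs_priors)
    cum <- cumsum(pri)[1:6]
    bin_edges <- quantile(latent, probs = cum, type = 1, names = FALSE)
  }
  stopifnot(length(bin_edges) == 6L, !is.unsorted(bin_edges))
  mrs7 <- findInterval(latent, bin_edges, left.open = TRUE)
  list(mrs7 = as.integer(mrs7), latent = latent, truth = eff)
}

#' Generate a full synthetic cohort
#'
#' Draws `n_patients` perfusion series with per-patient lesion geometry and
#' lesion-amplitude deficits, the clinical table, and mRS labels whose
#' latent score includes the per-patient perfusion deficit
#' (`A_NT - A_LT`), so both clinical and imaging information carry outcome
#' signal. All randomness derives from `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list of class `synthetic_cohort`: `series` (list), `rois` (list),
#'   `cti` (data frame), `mrs7` (integer vector), `truth` (planted
#'   coefficients, per-patient amplitudes, lesion specs and seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_patients
  deficit_target <- config$bolus_amplitude_nt - config$bolus_amplitude_lt
  deficits <- truncated_normal(n, deficit_target, config$amplitude_jitter,
                               lower = 0)
  deficits <- pmin(deficits, config$bolus_amplitude_nt)
  amps_lt <- config$bolus_amplitude_nt - deficits

  series <- vector("list", n)
  rois <- vector("list", n)
  for (i in seq_len(n)) {
    out <- generate_perfusion_series(config, amplitude_lt = amps_lt[i])
    series[[i]] <- out$series
    rois[[i]] <- out$roi
  }
  cti <- generate_cti_table(n)
  imaging <- data.frame(perfusion_deficit = deficits)
  oc <- generate_outcomes(cti, imaging, config)
  structure(
    list(series = series, rois = rois, cti = cti, mrs7 = oc$mrs7,
         truth = list(coefficients = oc$truth, amplitude_lt = amps_lt,
                      perfusion_deficit = deficits, latent = oc$latent,
                      seed = config$seed)),
    class = "synthetic_cohort"
  )
}
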