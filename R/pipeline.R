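#' Pipeline configuration
#'
#' Nested configuration for the full analysis: synthetic-cohort generation
#' (or file inputs), smoothing, temporal radiomics, the significance
#' filter, the thirteen selectors, the ten-model benchmark, survival
#' fusion, and the three-situation evaluation. Unknown keys are rejected.
#'
#' @param seed global integer seed; every stage derives its own stream.
#' @param outdir run directory for artifacts (created if needed).
#' @param synthetic generate the cohort (`TRUE`) or read `inputs` paths.
#' @param synth list of [synth_config()] overrides.
#' @param radiomics list of [feature_config()] overrides.
#' @param selector list of [selector_params()] overrides.
#' @param benchmark list: `folds`, `cv_repeats`, `models` (name subset).
#' @param survival list of [survival_config()] overrides.
#' @param evaluate list: `ratio`, `models` (name subset).
#' @param situations outcome granularities to evaluate (subset of 2, 4, 7).
#' @param smooth apply [smooth_series()] before feature extraction.
#' @param alpha significance level of the lesion/normal-tissue filter.
#' @param inputs list of file paths when `synthetic = FALSE`: `series`
#'   (character vector), `lt_masks` (character vector), `cti` (CSV),
#'   `labels` (CSV with an `mrs7` column).
#' @param write_feature_table write the full feature table CSV (off by
#'   default; it can be very wide).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("perfrad_run_"),
                            synthetic = TRUE, synth = list(),
                            radiomics = list(), selector = list(),
                            benchmark = list(), survival = list(),
                            evaluate = list(), situations = c(2, 4, 7),
                            smooth = TRUE, alpha = 0.05, inputs = list(),
                            write_feature_table = FALSE) {
  known_bench <- c("folds", "cv_repeats", "models")
  if (length(setdiff(names(benchmark), known_bench)) > 0)
    stop("unknown benchmark keys: ",
         paste(setdiff(names(benchmark), known_bench), collapse = ", "))
  known_eval <- c("ratio", "models")
  if (length(setdiff(names(evaluate), known_eval)) > 0)
    stop("unknown evaluate keys: ",
         paste(setdiff(names(evaluate), known_eval), collapse = ", "))
  check_keys <- function(lst, fn, what) {
    bad <- setdiff(names(lst), names(formals(fn)))
    if (length(bad) > 0)
      stop("unknown ", what, " keys: ", paste(bad, collapse = ", "))
  }
  check_keys(synth, synth_config, "synth")
  check_keys(radiomics, feature_config, "radiomics")
  check_keys(selector, selector_params, "selector")
  check_keys(survival, survival_config, "survival")
  stopifnot(all(situations %in% c(2, 4, 7)))
  structure(as.list(environment())[names(formals(pipeline_config))],
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror the
#'   [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(bad) > 0)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- cohort, smoothing, temporal radiomics,
#' significance filter, the thirteen selectors, the composite-score
#' benchmark, per-situation mRSRF selection, survival fusion (trained on
#' the training split only), and the seven-group evaluation -- writing each
#' stage's artifact into `config$outdir` together with a manifest recording
#' seeds and artifact hashes. Reruns with the same configuration are
#' bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with every stage's in-memory result and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 8L)
  artifacts <- character(0)
  say <- function(...) message("[perfrad] ", sprintf(...))

  ## stage 1: cohort
  if (isTRUE(config$synthetic)) {
    scfg <- do.call(synth_config, c(config$synth,
                                    list(seed = as.integer(seeds[1] %% 2^31))))
    cohort <- generate_cohort(scfg)
  } else {
    cohort <- load_cohort_inputs(config$inputs)
  }
  n <- length(cohort$series)
  say("cohort: %d series, volume %s", n,
      paste(dim(cohort$series[[1]]$data)[-1], collapse = "x"))

  ## stage 2: smoothing
  if (isTRUE(config$smooth))
    cohort$series <- lapply(cohort$series, smooth_series)

  ## stage 3: temporal radiomics
  fcfg <- do.call(feature_config, config$radiomics)
  tab <- build_table(cohort$series, cohort$rois, fcfg)
  say("features: %d samples x %d columns", nrow(tab$values), ncol(tab$values))

  ## stage 4: significance filter
  sig <- filter_significant(tab, alpha = config$alpha)
  say("significant: %d / %d columns", ncol(sig$reduced), ncol(tab$values))
  sig_path <- file.path(config$outdir, "significance.csv")
  sig_out <- sig$results
  sig_out$levene_p <- signif(sig_out$levene_p, 5)
  sig_out$t_p <- signif(sig_out$t_p, 5)
  utils::write.csv(sig_out, sig_path, row.names = FALSE)
  artifacts <- c(artifacts, sig_path)
  if (isTRUE(config$write_feature_table)) {
    ft_path <- file.path(config$outdir, "feature_table.csv")
    utils::write.csv(data.frame(tab$row_meta, tab$values,
                                check.names = FALSE),
                     ft_path, row.names = FALSE)
    artifacts <- c(artifacts, ft_path)
  }
  if (ncol(sig$reduced) == 0) stop("stage significance: no features survive")

  ## stage 5: thirteen selectors on the LT/NT task
  sparams <- do.call(selector_params, config$selector)
  fsets <- select_features(sig$reduced, sig$labels, "all", sparams,
                           seed = as.integer(seeds[2] %% 2^31))
  for (nm in names(fsets)) {
    p <- file.path(config$outdir, sprintf("featureset_%s.json", nm))
    write_json_artifact(list(method = nm, features = fsets[[nm]]$features,
                             scores = as.list(fsets[[nm]]$scores)), p)
    artifacts <- c(artifacts, p)
  }

  ## stage 6: composite-score benchmark
  bcfg <- config$benchmark
  models <- model_registry(bcfg$models)
  bench <- benchmark_selectors(fsets, sig$reduced, sig$labels, models,
                               folds = bcfg$folds %||% 10L,
                               seed = as.integer(seeds[3] %% 2^31),
                               cv_repeats = bcfg$cv_repeats %||% 1L)
  say("best method: %s (CS = %.3f)", bench$best_method,
      max(bench$cs))
  bench_path <- file.path(config$outdir, "benchmark_report.json")
  write_json_artifact(list(
    cs = as.list(bench$cs), best_method = bench$best_method,
    matrices = lapply(bench$matrices, function(mm)
      as.data.frame(unclass(mm)))), bench_path)
  artifacts <- c(artifacts, bench_path)

  ## outstanding features: union over the thirteen feature sets
  outstanding <- unique(unlist(lapply(fsets, `[[`, "features")))
  say("outstanding features: %d", length(outstanding))
  lt_rows <- tab$row_meta$tissue == 1L
  lesion_m <- sig$reduced[lt_rows, outstanding, drop = FALSE]

  ## stages 7-9 per situation: mRSRF, SurvF, evaluation
  ecfg <- config$evaluate
  eval_models <- model_registry(ecfg$models)
  vcfg_base <- config$survival
  situation_results <- list()
  for (s in config$situations) {
    skey <- sprintf("mRS_%d", s)
    labels <- regroup_mrs(cohort$mrs7, s)
    mrsrf_set <- select_mrsrf(lesion_m, labels, bench$best_method, sparams,
                              seed = as.integer(seeds[4] %% 2^31))
    mrsrf_m <- lesion_m[, mrsrf_set$features, drop = FALSE]

    set.seed(as.integer(seeds[5] %% 2^31) + s)
    train_idx <- stratified_split(labels, ecfg$ratio %||% 0.7)
    if (length(unique(labels[train_idx])) < nlevels(labels) ||
        length(unique(labels[!train_idx])) < nlevels(labels))
      stop("stage evaluate (", skey, "): class missing from the split")

    vcfg <- do.call(survival_config,
                    c(vcfg_base, list(seed = as.integer(seeds[6] %% 2^31))))
    events <- vcfg$event_rule(cohort$mrs7)
    surv_x <- cbind(normalize_columns(cohort$cti), mrsrf_m)
    net <- train_survival_net(as.matrix(surv_x)[train_idx, , drop = FALSE],
                              cohort$cti$age[train_idx],
                              events[train_idx], vcfg)
    sv <- compute_survf(net, as.matrix(surv_x))
    sv_path <- file.path(config$outdir, sprintf("survf_%s.csv", skey))
    utils::write.csv(data.frame(sample = seq_len(n), survf = sv$survf,
                                risk = sv$risk), sv_path, row.names = FALSE)
    artifacts <- c(artifacts, sv_path)
    say("%s: mRSRF %d features, SurvF training C-index %.3f", skey,
        length(mrsrf_set$features), sv$cindex)

    groups <- withCallingHandlers(
      assemble_feature_groups(cohort$cti, mrsrf_m, sv$survf),
      warning = function(w) invokeRestart("muffleWarning"))
    ev <- evaluate_outcomes(groups, labels, eval_models,
                            ratio = ecfg$ratio %||% 0.7,
                            seed = as.integer(seeds[7] %% 2^31) + s,
                            split = train_idx)
    situation_results[[skey]] <- list(
      labels = labels, mrsrf = mrsrf_set, survf = sv$survf,
      survf_cindex = sv$cindex, evaluation = ev)
  }
  eval_path <- file.path(config$outdir, "evaluation_report.json")
  write_json_artifact(lapply(situation_results, function(r) list(
    mrsrf = r$mrsrf$features, survf_cindex = r$survf_cindex,
    metrics = r$evaluation$metrics, group_means = r$evaluation$group_means)),
    eval_path)
  artifacts <- c(artifacts, eval_path)

  ## manifest
  manifest <- list(
    seed = config$seed,
    stages = c("cohort", "smooth", "features", "significance", "selection",
               "benchmark", "mrsrf", "survf", "evaluation"),
    n_series = n,
    n_features = ncol(tab$values),
    n_significant = ncol(sig$reduced),
    best_method = bench$best_method,
    situations = as.character(names(situation_results)),
    artifacts = as.list(setNames(
      as.character(tools::md5sum(artifacts)), basename(artifacts)))
  )
  man_path <- file.path(config$outdir, "manifest.json")
  write_json_artifact(manifest, man_path)
  invisible(list(cohort = cohort, table = tab, significance = sig,
                 featuresets = fsets, benchmark = bench,
                 situations = situation_results, manifest = manifest,
                 outdir = config$outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Read a cohort from NIfTI series / masks and CSV clinical + label tables.
load_cohort_inputs <- function(inputs) {
  needed <- c("series", "lt_masks", "cti", "labels")
  miss <- setdiff(needed, names(inputs))
  if (length(miss) > 0)
    stop("missing input paths: ", paste(miss, collapse = ", "))
  for (p in c(inputs$series, inputs$lt_masks, inputs$cti, inputs$labels))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  stopifnot(length(inputs$series) == length(inputs$lt_masks))
  series <- lapply(inputs$series, read_series)
  rois <- lapply(inputs$lt_masks, function(p) roi_pair(read_mask(p)))
  cti <- utils::read.csv(inputs$cti)
  lab <- utils::read.csv(inputs$labels)
  if (!"mrs7" %in% names(lab)) stop("labels CSV needs an 'mrs7' column")
  list(series = series, rois = rois, cti = cti,
       mrs7 = as.integer(lab$mrs7), truth = NULL)
}
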