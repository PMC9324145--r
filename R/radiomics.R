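#' Radiomics feature configuration
#'
#' Pins the nine feature classes and their per-class feature lists so the
#' table schema is stable: 14 shape + 18 first-order + 24 GLCM + 16 GLRLM +
#' 16 GLSZM + 5 NGTDM + 14 GLDM = 107 features on the original image, plus
#' the 93 non-shape features recomputed on each of 5 Laplacian-of-Gaussian
#' images (465) and 8 wavelet decomposition bands (744), for 1316 features
#' per timepoint.
#'
#' @param enabled_classes subset of
#'   `c("Shape", "First-order", "GLCM", "GLRLM", "GLSZM", "NGTDM", "GLDM",
#'   "Log-Sigma", "Wavelet")`.
#' @param log_sigmas Gaussian widths in mm for the LoG filter bank
#'   (default 1-5 mm in 1 mm steps; 5 values).
#' @param wavelet_bands the 8 single-level 3D Haar band labels
#'   (`LLL` ... `HHH`, low/high-pass per axis).
#' @param bin_width intensity discretization bin width in a.u. (default 25)
#'   applied before every texture-matrix computation.
#' @return object of class `feature_config`.
#' @export
feature_config <- function(enabled_classes = c("Shape", "First-order", "GLCM",
                                               "GLRLM", "GLSZM", "NGTDM",
                                               "GLDM", "Log-Sigma", "Wavelet"),
                           log_sigmas = c(1, 2, 3, 4, 5),
                           wavelet_bands = c("LLL", "LLH", "LHL", "LHH",
                                             "HLL", "HLH", "HHL", "HHH"),
                           bin_width = 25) {
  all_classes <- c("Shape", "First-order", "GLCM", "GLRLM", "GLSZM", "NGTDM",
                   "GLDM", "Log-Sigma", "Wavelet")
  enabled_classes <- match.arg(enabled_classes, all_classes, several.ok = TRUE)
  stopifnot(length(log_sigmas) == 5L, all(log_sigmas > 0),
            length(wavelet_bands) == 8L, bin_width > 0)
  structure(
    list(enabled_classes = enabled_classes,
         class_feature_lists = radiomics_feature_lists(),
         log_sigmas = log_sigmas,
         wavelet_bands = wavelet_bands,
         bin_width = bin_width),
    class = "feature_config"
  )
}

# Pinned per-class feature name lists (14, 18, 24, 16, 16, 5, 14).
radiomics_feature_lists <- function() {
  list(
    shape = c("VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
              "Sphericity", "Compactness1", "Compactness2",
              "SphericalDisproportion", "Maximum3DDiameter",
              "Maximum2DDiameterSlice", "MajorAxisLength", "MinorAxisLength",
              "LeastAxisLength", "Elongation", "Flatness"),
    firstorder = c("Energy", "TotalEnergy", "Entropy", "Minimum",
                   "Percentile10", "Percentile90", "Maximum", "Mean",
                   "Median", "InterquartileRange", "Range",
                   "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
                   "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
                   "Uniformity"),
    glcm = c("Autocorrelation", "JointAverage", "ClusterProminence",
             "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
             "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn",
             "Id", "Idn", "InverseVariance", "MaximumProbability",
             "SumAverage", "SumEntropy", "SumSquares", "MCC"),
    glrlm = c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
              "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
              "RunLengthNonUniformityNormalized", "RunPercentage",
              "GrayLevelVariance", "RunVariance", "RunEntropy",
              "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
              "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
              "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"),
    glszm = c("SmallAreaEmphasis", "LargeAreaEmphasis",
              "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
              "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
              "ZoneEntropy", "LowGrayLevelZoneEmphasis",
              "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
              "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
              "LargeAreaHighGrayLevelEmphasis"),
    ngtdm = c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength"),
    gldm = c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
             "GrayLevelNonUniformity", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "GrayLevelVariance",
             "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
             "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
             "SmallDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis",
             "LargeDependenceHighGrayLevelEmphasis")
  )
}

#' Decompose a 4D perfusion series into per-timepoint 3D volumes
#'
#' @param series a [perfusion_series()].
#' @return list of `n_timepoints` 3D arrays; element `n + 1` is the volume
#'   at time index `n` (0-based time naming is used in feature names).
#' @export
decompose_series <- function(series) {
  stopifnot(inherits(series, "perfusion_series"))
  lapply(seq_len(series$n_timepoints), function(t) {
    v <- series$data[t, , , , drop = FALSE]
    dim(v) <- dim(series$data)[-1L]
    v
  })
}

#' Append / parse the timepoint suffix of a temporal feature name
#'
#' Temporal features are named `<base>_<t>` where `t` is the 0-based index
#' of the 3D volume the feature was computed from, e.g.
#' `log-sigma-1-0-mm-3D_firstorder_Skewness_17`.
#'
#' @param base base feature name (image label + class + feature).
#' @param t timepoint index (0-based).
#' @return `name_feature()` returns the composed name;
#'   `parse_feature_name()` a list with `base` and `timepoint`.
#' @export
name_feature <- function(base, t) {
  stopifnot(all(t >= 0), all(t == floor(t)))
  paste0(base, "_", format(t, scientific = FALSE, trim = TRUE))
}

#' @rdname name_feature
#' @param name full temporal feature name.
#' @export
parse_feature_name <- function(name) {
  m <- regmatches(name, regexpr("_[0-9]+$", name))
  if (length(m) == 0 || any(!nzchar(m)))
    stop("feature name has no timepoint suffix: ", name)
  t <- as.integer(sub("^_", "", m))
  list(base = sub("_[0-9]+$", "", name), timepoint = t)
}

# --- filter bank -----------------------------------------------------------

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  radius <- max(1L, ceiling(3 * sigma_vox))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Laplacian of Gaussian: separable Gaussian smoothing (sigma in mm,
# converted per-axis to voxels) followed by the discrete 3D Laplacian with
# spacing-aware second differences.
log_filter <- function(vol, sigma_mm, spacing) {
  sm <- vol
  for (ax in 1:3) {
    sv <- sigma_mm / spacing[ax]
    sm <- conv_along_axis(sm, gaussian_kernel_1d(sv), axis = ax)
  }
  lap <- array(0, dim(vol))
  for (ax in 1:3) {
    second <- conv_along_axis(sm, c(1, -2, 1), axis = ax) / spacing[ax]^2
    lap <- lap + second
  }
  lap
}

# Single-level undecimated 3D Haar decomposition: low-pass (1, 1)/sqrt(2),
# high-pass (1, -1)/sqrt(2) applied per axis; returns the 8 bands LLL..HHH
# at the original resolution (band letter order: slice, row, column axis).
wavelet_bands_3d <- function(vol) {
  lo <- c(1, 1) / sqrt(2)
  hi <- c(1, -1) / sqrt(2)
  bands <- list(vol)
  labels <- ""
  for (ax in 1:3) {
    nxt <- list()
    nxt_labels <- character(0)
    for (i in seq_along(bands)) {
      nxt[[length(nxt) + 1L]] <- conv_along_axis(bands[[i]], lo, axis = ax)
      nxt_labels <- c(nxt_labels, paste0(labels[i], "L"))
      nxt[[length(nxt) + 1L]] <- conv_along_axis(bands[[i]], hi, axis = ax)
      nxt_labels <- c(nxt_labels, paste0(labels[i], "H"))
    }
    bands <- nxt
    labels <- nxt_labels
  }
  names(bands) <- labels
  bands
}

log_sigma_label <- function(sigma) {
  sprintf("log-sigma-%s-mm-3D",
          gsub("\\.", "-", format(sigma, nsmall = 1, trim = TRUE)))
}

# All derived images needed for one timepoint under `config`.
filter_bank <- function(vol, config, spacing) {
  bank <- list(original = vol)
  if ("Log-Sigma" %in% config$enabled_classes)
    for (s in config$log_sigmas)
      bank[[log_sigma_label(s)]] <- log_filter(vol, s, spacing)
  if ("Wavelet" %in% config$enabled_classes) {
    wb <- wavelet_bands_3d(vol)
    for (b in config$wavelet_bands)
      bank[[paste0("wavelet-", b)]] <- wb[[b]]
  }
  bank
}

# --- feature formulas ------------------------------------------------------

# Equal-width discretization with fixed bin width; returns integer levels
# 1..ng inside the mask and 0 outside, as a 3D integer array.
discretize_image <- function(vol, mask, bin_width) {
  idx <- which(mask == 1)
  vals <- vol[idx]
  lev <- floor((vals - min(vals)) / bin_width) + 1L
  out <- array(0L, dim(vol))
  out[idx] <- as.integer(lev)
  out
}

first_order_features <- function(vals, voxel_volume, bin_width) {
  n <- length(vals)
  mu <- mean(vals)
  m2 <- mean((vals - mu)^2)
  m3 <- mean((vals - mu)^3)
  m4 <- mean((vals - mu)^4)
  lev <- floor((vals - min(vals)) / bin_width)
  p <- tabulate(lev + 1L) / n
  p <- p[p > 0]
  qs <- quantile(vals, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  robust <- vals[vals >= qs[1] & vals <= qs[4]]
  c(Energy = sum(vals^2),
    TotalEnergy = voxel_volume * sum(vals^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(vals),
    Percentile10 = qs[1],
    Percentile90 = qs[4],
    Maximum = max(vals),
    Mean = mu,
    Median = median(vals),
    InterquartileRange = qs[3] - qs[2],
    Range = max(vals) - min(vals),
    MeanAbsoluteDeviation = mean(abs(vals - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    RootMeanSquared = sqrt(mean(vals^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

shape_features <- function(mask, spacing) {
  idx <- which(mask == 1)
  n <- length(idx)
  vox <- prod(spacing)
  V <- n * vox
  d <- dim(mask)
  ar <- arrayInd(idx, d)
  # surface area: count faces exposed to background (or volume boundary)
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  A <- 0
  for (ax in 1:3) for (dir in c(-1L, 1L)) {
    nb <- ar
    nb[, ax] <- nb[, ax] + dir
    inside <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
    exposed <- !inside
    if (any(inside)) {
      lin <- nb[inside, 1L] + d[1] * (nb[inside, 2L] - 1L) +
        d[1] * d[2] * (nb[inside, 3L] - 1L)
      exposed[inside] <- mask[lin] == 0
    }
    A <- A + sum(exposed) * face_area[ax]
  }
  coords <- sweep(ar, 2L, spacing, `*`)
  max3d <- if (n > 1) max(dist(coords)) else 0
  max2d <- 0
  for (s in unique(ar[, 1L])) {
    cc <- coords[ar[, 1L] == s, 2:3, drop = FALSE]
    if (nrow(cc) > 1) max2d <- max(max2d, max(dist(cc)))
  }
  if (n > 1) {
    ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev[ev < 0] <- 0
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  sph <- if (A > 0) (36 * pi * V^2)^(1 / 3) / A else 0
  c(VoxelVolume = V,
    SurfaceArea = A,
    SurfaceVolumeRatio = if (V > 0) A / V else 0,
    Sphericity = sph,
    Compactness1 = if (A > 0) V / (sqrt(pi) * A^1.5) else 0,
    Compactness2 = if (A > 0) 36 * pi * V^2 / A^3 else 0,
    SphericalDisproportion = if (sph > 0) 1 / sph else 0,
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = max2d,
    MajorAxisLength = axes[1],
    MinorAxisLength = axes[2],
    LeastAxisLength = axes[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

glcm_features <- function(counts) {
  ng <- nrow(counts)
  tot <- sum(counts)
  if (tot == 0) return(setNames(numeric(24), radiomics_feature_lists()$glcm))
  P <- counts / tot
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # diagonal / cross-diagonal marginals
  k_sum <- 2:(2 * ng)
  pxy_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), numeric(1))
  k_dif <- 0:(ng - 1)
  pxy_dif <- vapply(k_dif, function(k) sum(P[abs(i - j) == k]), numeric(1))
  DA <- sum(k_dif * pxy_dif)
  HX <- -sum(xlog2(px)); HY <- -sum(xlog2(py))
  HXY <- -sum(xlog2(P))
  pxpy <- outer(px, py)
  HXY1 <- -sum(P * ifelse(pxpy > 0, log2(pxpy), 0))
  HXY2 <- -sum(xlog2(pxpy))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  offd <- i != j
  # MCC: second largest eigenvalue of Q
  mcc <- 1
  if (ng > 1) {
    Pn <- P / ifelse(px > 0, px, 1)      # rows scaled by px
    Pk <- t(t(P) / ifelse(py > 0, py, 1)) # cols scaled by py
    Q <- Pn %*% t(Pk)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- if (length(ev) > 1 && ev[2] > 0) sqrt(ev[2]) else 0
  }
  c(Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = if (sx > 0 && sy > 0)
      (sum(i * j * P) - mux * muy) / (sx * sy) else 1,
    DifferenceAverage = DA,
    DifferenceEntropy = -sum(xlog2(pxy_dif)),
    DifferenceVariance = sum((k_dif - DA)^2 * pxy_dif),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    InverseVariance = sum(P[offd] / (i[offd] - j[offd])^2),
    MaximumProbability = max(P),
    SumAverage = sum(k_sum * pxy_sum),
    SumEntropy = -sum(xlog2(pxy_sum)),
    SumSquares = sum((i - mux)^2 * P),
    MCC = mcc)
}

# Shared arithmetic for run-length-style matrices (GLRLM with runs,
# GLSZM with zones): rows = gray levels, cols = run length / zone size.
rl_style_features <- function(R, n_voxels, names_out) {
  Nr <- sum(R)
  if (Nr == 0) return(setNames(numeric(length(names_out)), names_out))
  ng <- nrow(R); nl <- ncol(R)
  iv <- matrix(seq_len(ng), ng, nl)
  jv <- matrix(seq_len(nl), ng, nl, byrow = TRUE)
  p <- R / Nr
  mu_i <- sum(iv * p); mu_j <- sum(jv * p)
  vals <- c(
    sum(R / jv^2) / Nr,
    sum(R * jv^2) / Nr,
    sum(rowSums(R)^2) / Nr,
    sum(rowSums(R)^2) / Nr^2,
    sum(colSums(R)^2) / Nr,
    sum(colSums(R)^2) / Nr^2,
    Nr / n_voxels,
    sum((iv - mu_i)^2 * p),
    sum((jv - mu_j)^2 * p),
    -sum(xlog2(p)),
    sum(R / iv^2) / Nr,
    sum(R * iv^2) / Nr,
    sum(R / (iv^2 * jv^2)) / Nr,
    sum(R * iv^2 / jv^2) / Nr,
    sum(R * jv^2 / iv^2) / Nr,
    sum(R * iv^2 * jv^2) / Nr
  )
  setNames(vals, names_out)
}

glrlm_features <- function(R, n_voxels) {
  # run percentage denominator: potential runs = voxels x 13 directions
  out <- rl_style_features(R, n_voxels * 13, radiomics_feature_lists()$glrlm)
  out
}

glszm_features <- function(zones, ng, n_voxels) {
  nm <- radiomics_feature_lists()$glszm
  if (nrow(zones) == 0) return(setNames(numeric(16), nm))
  maxsz <- max(zones[, 2L])
  R <- matrix(0, ng, maxsz)
  for (z in seq_len(nrow(zones)))
    R[zones[z, 1L], zones[z, 2L]] <- R[zones[z, 1L], zones[z, 2L]] + 1
  rl_style_features(R, n_voxels, nm)
}

ngtdm_features <- function(stats_mat, n_voxels) {
  nm <- radiomics_feature_lists()$ngtdm
  n_i <- stats_mat[, 1L]; s_i <- stats_mat[, 2L]
  N <- sum(n_i)
  if (N == 0) return(setNames(numeric(5), nm))
  p_i <- n_i / N
  lev <- seq_along(p_i)
  act <- p_i > 0
  ngp <- sum(act)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1)
    (sum(outer(p_i[act], p_i[act]) *
           outer(lev[act], lev[act], `-`)^2) / (ngp * (ngp - 1))) *
      (sum(s_i) / N) else 0
  busy_den <- sum(abs(outer(lev[act] * p_i[act], lev[act] * p_i[act], `-`)))
  busyness <- if (busy_den > 0) coarse_den / busy_den else 0
  # complexity / strength over active level pairs
  pa <- p_i[act]; sa <- s_i[act]; la <- lev[act]
  psum <- outer(pa, pa, `+`)
  complexity <- sum(abs(outer(la, la, `-`)) *
                      (outer(pa * sa, pa * sa, `+`)) / psum) / N
  strength_num <- sum(psum * outer(la, la, `-`)^2)
  strength <- if (sum(s_i) > 0) strength_num / sum(s_i) else 0
  setNames(c(coarseness, contrast, busyness, complexity, strength), nm)
}

gldm_features <- function(D) {
  nm <- radiomics_feature_lists()$gldm
  Nz <- sum(D)
  if (Nz == 0) return(setNames(numeric(14), nm))
  D <- D[, colSums(D) > 0 | seq_len(ncol(D)) == 1, drop = FALSE]
  ng <- nrow(D); nd <- ncol(D)
  iv <- matrix(seq_len(ng), ng, nd)
  jv <- matrix(seq_len(nd), ng, nd, byrow = TRUE)
  p <- D / Nz
  mu_i <- sum(iv * p); mu_j <- sum(jv * p)
  setNames(c(
    sum(D / jv^2) / Nz,
    sum(D * jv^2) / Nz,
    sum(rowSums(D)^2) / Nz,
    sum(colSums(D)^2) / Nz,
    sum(colSums(D)^2) / Nz^2,
    sum((iv - mu_i)^2 * p),
    sum((jv - mu_j)^2 * p),
    -sum(xlog2(p)),
    sum(D / iv^2) / Nz,
    sum(D * iv^2) / Nz,
    sum(D / (iv^2 * jv^2)) / Nz,
    sum(D * iv^2 / jv^2) / Nz,
    sum(D * jv^2 / iv^2) / Nz,
    sum(D * iv^2 * jv^2) / Nz
  ), nm)
}

# Non-shape features (first-order + 5 texture families) for one image/mask.
intensity_features <- function(vol, mask, config, spacing, classes) {
  idx <- which(mask == 1)
  vals <- vol[idx]
  out <- c()
  if ("First-order" %in% classes) {
    fo <- first_order_features(vals, prod(spacing), config$bin_width)
    names(fo) <- paste0("firstorder_", radiomics_feature_lists()$firstorder)
    out <- c(out, fo)
  }
  tex_classes <- intersect(classes, c("GLCM", "GLRLM", "GLSZM", "NGTDM", "GLDM"))
  if (length(tex_classes) > 0) {
    disc <- discretize_image(vol, mask, config$bin_width)
    ng <- max(disc)
    dims <- as.integer(dim(vol))
    if ("GLCM" %in% tex_classes) {
      f <- glcm_features(.glcm_counts(as.integer(disc), dims, ng))
      names(f) <- paste0("glcm_", radiomics_feature_lists()$glcm)
      out <- c(out, f)
    }
    if ("GLRLM" %in% tex_classes) {
      f <- glrlm_features(.glrlm_counts(as.integer(disc), dims, ng),
                          length(idx))
      names(f) <- paste0("glrlm_", radiomics_feature_lists()$glrlm)
      out <- c(out, f)
    }
    if ("GLSZM" %in% tex_classes) {
      f <- glszm_features(.glszm_zones(as.integer(disc), dims), ng,
                          length(idx))
      names(f) <- paste0("glszm_", radiomics_feature_lists()$glszm)
      out <- c(out, f)
    }
    if ("NGTDM" %in% tex_classes) {
      f <- ngtdm_features(.ngtdm_stats(as.integer(disc), dims, ng),
                          length(idx))
      names(f) <- paste0("ngtdm_", radiomics_feature_lists()$ngtdm)
      out <- c(out, f)
    }
    if ("GLDM" %in% tex_classes) {
      f <- gldm_features(.gldm_counts(as.integer(disc), dims, ng, 0L))
      names(f) <- paste0("gldm_", radiomics_feature_lists()$gldm)
      out <- c(out, f)
    }
  }
  out
}

# Extract all configured features for one mask given a precomputed filter
# bank; returns a named vector of base feature names (no timepoint suffix).
extract_from_bank <- function(bank, mask, config, spacing) {
  classes <- config$enabled_classes
  out <- c()
  if ("Shape" %in% classes) {
    f <- shape_features(mask, spacing)
    names(f) <- paste0("original_shape_", radiomics_feature_lists()$shape)
    out <- c(out, f)
  }
  base_classes <- intersect(classes, c("First-order", "GLCM", "GLRLM",
                                       "GLSZM", "NGTDM", "GLDM"))
  if (length(base_classes) > 0) {
    f <- intensity_features(bank$original, mask, config, spacing, base_classes)
    names(f) <- paste0("original_", names(f))
    out <- c(out, f)
  }
  deriv <- setdiff(names(bank), "original")
  all_int <- c("First-order", "GLCM", "GLRLM", "GLSZM", "NGTDM", "GLDM")
  for (im in deriv) {
    f <- intensity_features(bank[[im]], mask, config, spacing, all_int)
    names(f) <- paste0(im, "_", names(f))
    out <- c(out, f)
  }
  out
}

#' Extract radiomics features from one 3D volume and mask
#'
#' With the full nine-class configuration this yields exactly 1316 features:
#' the 107 original-image features plus the 93 non-shape features on each of
#' 5 LoG and 8 wavelet images. Extraction is deterministic in
#' `(volume, mask, config)`.
#'
#' @param volume 3D numeric array.
#' @param mask 3D 0/1 array of the same shape, non-empty.
#' @param config a [feature_config()].
#' @param spacing voxel spacing `(slice, row, col)` in mm.
#' @return named numeric vector of base feature names.
#' @export
extract_timepoint_features <- function(volume, mask, config = feature_config(),
                                       spacing = c(1, 1, 1)) {
  check_mask(mask)
  if (!identical(dim(volume), dim(mask)))
    stop("volume and mask shapes differ")
  if (sum(mask) == 0) stop("mask is empty")
  bank <- filter_bank(volume, config, spacing)
  extract_from_bank(bank, mask, config, spacing)
}

# Ordered base feature names implied by a configuration (no timepoint
# suffix); defines the column schema even for an empty table.
base_feature_names <- function(config) {
  fl <- radiomics_feature_lists()
  classes <- config$enabled_classes
  out <- character(0)
  if ("Shape" %in% classes)
    out <- c(out, paste0("original_shape_", fl$shape))
  int_map <- c("First-order" = "firstorder", GLCM = "glcm", GLRLM = "glrlm",
               GLSZM = "glszm", NGTDM = "ngtdm", GLDM = "gldm")
  base_int <- intersect(names(int_map), classes)
  for (cl in base_int)
    out <- c(out, paste0("original_", int_map[[cl]], "_", fl[[int_map[[cl]]]]))
  imgs <- character(0)
  if ("Log-Sigma" %in% classes)
    imgs <- c(imgs, vapply(config$log_sigmas, log_sigma_label, character(1)))
  if ("Wavelet" %in% classes)
    imgs <- c(imgs, paste0("wavelet-", config$wavelet_bands))
  for (im in imgs)
    for (cl in names(int_map))
      out <- c(out, paste0(im, "_", int_map[[cl]], "_", fl[[int_map[[cl]]]]))
  out
}

# Group label (one of the nine printed classes) for a base feature name.
feature_group <- function(base) {
  img <- sub("_.*$", "", base)
  cls <- sub("^[^_]+_([^_]+)_.*$", "\\1", base)
  ifelse(grepl("^log-sigma", base), "Log-Sigma",
  ifelse(grepl("^wavelet", base), "Wavelet",
    c(shape = "Shape", firstorder = "First-order", glcm = "GLCM",
      glrlm = "GLRLM", glszm = "GLSZM", ngtdm = "NGTDM",
      gldm = "GLDM")[cls]))
}

#' Build the temporal radiomics feature table
#'
#' Runs the full per-timepoint extraction for every series and both ROIs
#' (lesion and mirrored normal tissue), producing a samples-by-features
#' matrix: 2 rows per series (LT coded `1`, NT coded `0`) and
#' `features-per-timepoint x n_timepoints` named columns, each carrying
#' group and timepoint metadata. Filtered images are computed once per
#' timepoint and shared between the two masks.
#'
#' @param series_list list of [perfusion_series()].
#' @param roi_list list of [roi_pair()], same length.
#' @param config a [feature_config()].
#' @param n_timepoints timepoint count used for the column schema when
#'   `series_list` is empty (otherwise taken from the series).
#' @return object of class `feature_table`: list with `values` (numeric
#'   matrix), `col_meta` (data frame: `column`, `base`, `group`,
#'   `timepoint`), `row_meta` (data frame: `series`, `tissue`).
#' @export
build_table <- function(series_list, roi_list, config = feature_config(),
                        n_timepoints = 50L) {
  stopifnot(length(series_list) == length(roi_list))
  n_series <- length(series_list)
  rows <- list()
  row_meta <- data.frame(series = integer(0), tissue = integer(0))
  for (i in seq_len(n_series)) {
    ser <- series_list[[i]]
    roi <- roi_list[[i]]
    stopifnot(inherits(ser, "perfusion_series"), inherits(roi, "roi_pair"))
    if (!identical(dim(ser$data)[-1L], dim(roi$lt_mask)))
      stop("series ", i, ": mask shape does not match series spatial shape")
    vols <- decompose_series(ser)
    per_t <- lapply(seq_along(vols), function(t) {
      bank <- filter_bank(vols[[t]], config, ser$spacing)
      lt <- extract_from_bank(bank, roi$lt_mask, config, ser$spacing)
      nt <- extract_from_bank(bank, roi$nt_mask, config, ser$spacing)
      names(lt) <- name_feature(names(lt), t - 1L)
      names(nt) <- name_feature(names(nt), t - 1L)
      list(lt = lt, nt = nt)
    })
    rows[[length(rows) + 1L]] <- unlist(lapply(per_t, `[[`, "lt"))
    row_meta <- rbind(row_meta, data.frame(series = i, tissue = 1L))
    rows[[length(rows) + 1L]] <- unlist(lapply(per_t, `[[`, "nt"))
    row_meta <- rbind(row_meta, data.frame(series = i, tissue = 0L))
  }
  if (n_series == 0) {
    base <- base_feature_names(config)
    cols <- as.vector(vapply(seq_len(n_timepoints) - 1L,
                             function(t) name_feature(base, t),
                             character(length(base))))
    values <- matrix(numeric(0), nrow = 0, ncol = length(cols),
                     dimnames = list(NULL, cols))
  } else {
    values <- do.call(rbind, rows)
    cols <- names(rows[[1]])
    colnames(values) <- cols
  }
  parsed <- if (length(cols)) parse_feature_name(cols) else
    list(base = character(0), timepoint = integer(0))
  col_meta <- data.frame(column = cols, base = parsed$base,
                         group = feature_group(parsed$base),
                         timepoint = parsed$timepoint,
                         stringsAsFactors = FALSE)
  structure(list(values = values, col_meta = col_meta, row_meta = row_meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (nrow(x$col_meta)) print(table(x$col_meta$group))
  invisible(x)
}

#' Empty-schema feature table column counts per group
#'
#' Convenience summary used to check the structural counts of the pinned
#' configuration (e.g. 1316 features per timepoint, 65,800 for 50).
#'
#' @param table a `feature_table`.
#' @return named integer vector of column counts by group.
#' @export
table_group_counts <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  tab <- table(factor(table$col_meta$group,
                      levels = c("Shape", "First-order", "GLCM", "GLRLM",
                                 "GLSZM", "NGTDM", "GLDM", "Log-Sigma",
                                 "Wavelet")))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
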