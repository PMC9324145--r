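# Shared in-code fixtures; everything is generated, nothing is read from disk.

# Small noise-free synthetic series + ROI with fixed lesion geometry.
tiny_series <- function(noise_sd = 0, n_timepoints = 30L,
                        shape = c(6L, 16L, 16L), amplitude_lt = 60,
                        seed = 1L) {
  cfg <- synth_config(n_patients = 1L, n_timepoints = n_timepoints,
                      volume_shape = shape, noise_sd = noise_sd, seed = seed)
  set.seed(seed)
  c_rad <- min(2.2, shape[3] / 6)
  generate_perfusion_series(
    cfg, amplitude_lt = amplitude_lt,
    lesion_spec = list(center = c(shape[1] / 2 + 0.5, shape[2] / 2,
                                  ceiling(shape[3] / 4)),
                       radii = c(min(1.6, shape[1] / 3),
                                 min(2.5, shape[2] / 4), c_rad)))
}

# Two-class Gaussian matrix with a planted mean shift on the first columns.
planted_matrix <- function(n_per_class = 40L, p = 20L, shift = 2,
                           n_informative = 3L, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  colnames(m) <- paste0("f", seq_len(p))
  labels <- rep(c(0L, 1L), each = n_per_class)
  m[labels == 1L, seq_len(n_informative)] <-
    m[labels == 1L, seq_len(n_informative)] + shift
  list(m = m, labels = labels)
}

# Discrete toy dataset for the greedy-selector oracle checks.
discrete_toy <- function(n = 40L, p = 5L, seed = 7L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  m <- matrix(0, n, p)
  m[, 1] <- y + rnorm(n, sd = 0.3)          # strong signal
  m[, 2] <- m[, 1] + rnorm(n, sd = 0.1)     # redundant copy
  m[, 3] <- rnorm(n)                        # noise
  m[, 4] <- y * rbinom(n, 1, 0.7) + rnorm(n, sd = 0.4)  # partial signal
  if (p >= 5) m[, 5] <- rnorm(n)
  colnames(m) <- paste0("f", seq_len(p))
  list(m = m, y = y)
}

# Test-side mutual information from a plain contingency table (independent
# of the package's implementation).
mi_oracle <- function(xi, yi) {
  tab <- table(xi, yi)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  unname(s)
}

# Test-side conditional mutual information I(x; y | z).
cmi_oracle <- function(xi, yi, zi) {
  s <- 0
  for (z in unique(zi)) {
    sel <- zi == z
    s <- s + mean(sel) * mi_oracle(xi[sel], yi[sel])
  }
  s
}

# Fast model subset for evaluation-heavy tests.
fast_models <- function() model_registry(c("LR", "DA", "NB", "KNN"))
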