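#' @useDynLib perfrad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rbinom runif rlogis quantile var sd median aov
#'   pt pf predict coef complete.cases setNames cor p.adjust qnorm
#' @importFrom utils head
NULL

#' Range-denominator feature normalization
#'
#' Centers a feature on its mean and divides by its range,
#' `(x - mean(x)) / (max(x) - min(x))`. This is the normalization applied
#' before the lesion/normal-tissue significance tests and to the survival
#' feature. A zero-range (constant) feature maps to all zeros by convention.
#'
#' @param x numeric vector (at least one finite value).
#' @param method `"range"` (default) for the range denominator, `"zscore"`
#'   for classical standardization `(x - mean) / sd` (offered as a
#'   sensitivity-analysis alternative).
#' @return numeric vector of the same length.
#' @export
normalize_feature <- function(x, method = c("range", "zscore")) {
  method <- match.arg(method)
  if (!is.numeric(x)) stop("`x` must be numeric")
  rng <- diff(range(x))
  if (!is.finite(rng) || rng == 0) return(rep(0, length(x)))
  if (method == "range") (x - mean(x)) / rng else (x - mean(x)) / sd(x)
}

#' Column-wise range normalization of a matrix or data frame
#'
#' @param m numeric matrix or data frame.
#' @inheritParams normalize_feature
#' @return object of the same shape with each column normalized.
#' @export
normalize_columns <- function(m, method = c("range", "zscore")) {
  method <- match.arg(method)
  if (is.data.frame(m)) {
    m[] <- lapply(m, normalize_feature, method = method)
    return(m)
  }
  apply(m, 2L, normalize_feature, method = method)
}

# Derive a stream of child seeds from one integer seed, each < 2^31.
derive_seeds <- function(seed, n, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.double(seed) * 48271 + salt * 16807 + seq_len(n) * 69621) %% 2147483629
}

# 1D convolution of a 3D/4D array along one axis with replicate padding.
# Kernel offsets are centered: a kernel of odd length k covers offsets
# -(k-1)/2 .. +(k-1)/2; even-length kernels are centered on the lower index.
conv_along_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  stopifnot(axis >= 1L, axis <= length(d))
  perm <- c(axis, setdiff(seq_along(d), axis))
  x <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(x, nrow = n)
  k <- length(kernel)
  offs <- seq_len(k) - 1L - (k - 1L) %/% 2L
  out <- matrix(0, nrow = n, ncol = ncol(m))
  base <- seq_len(n)
  for (j in seq_len(k)) {
    idx <- pmin(pmax(base + offs[j], 1L), n)
    out <- out + kernel[j] * m[idx, , drop = FALSE]
  }
  res <- array(out, dim = d[perm])
  aperm(res, order(perm))
}

#' Stratified fold assignment and train/test splitting
#'
#' `stratified_folds()` assigns each sample a fold id in `1..k` such that
#' every class is spread as evenly as possible across folds;
#' `stratified_split()` draws a train/test partition keeping roughly
#' `train_frac` of every class in training (at least one sample of each
#' class on both sides when the class allows it). Both are deterministic
#' given the RNG state.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @return `stratified_folds()`: integer vector of fold ids;
#'   `stratified_split()`: logical vector, `TRUE` marks a training row.
#' @export
stratified_folds <- function(labels, k) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' @rdname stratified_folds
#' @param train_frac training fraction.
#' @export
stratified_split <- function(labels, train_frac) {
  labels <- as.factor(labels)
  train <- logical(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, round(length(idx) * train_frac))
    if (n_tr >= length(idx)) n_tr <- length(idx) - 1L
    if (n_tr < 1L) n_tr <- 1L
    pick <- idx[sample.int(length(idx))][seq_len(n_tr)]
    train[pick] <- TRUE
  }
  train
}
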