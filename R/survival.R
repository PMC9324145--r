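#' Survival-fusion configuration
#'
#' Settings of the Cox partial-likelihood feed-forward scorer that fuses
#' clinical covariates and mRS radiomics features into one survival feature
#' (SurvF) per sample. Age plays the role of event time and the event
#' indicator derives from the 90-day mRS (default: poor outcome,
#' `mRS >= 3`).
#'
#' @param epochs training epochs (default 4000).
#' @param batch_size minibatch size (default 20).
#' @param hidden_layout hidden layer sizes (default `c(32, 16)`).
#' @param learning_rate Adam step size (default 1e-3).
#' @param event_rule function mapping an mRS 0..6 vector to 0/1 event
#'   indicators (default `mRS >= 3`, the good/poor split).
#' @param seed integer seed for initialization and batching.
#' @return object of class `survival_config`.
#' @export
survival_config <- function(epochs = 4000L, batch_size = 20L,
                            hidden_layout = c(32L, 16L),
                            learning_rate = 1e-3,
                            event_rule = function(mrs) as.integer(mrs >= 3),
                            seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, all(hidden_layout >= 1),
            learning_rate > 0, is.function(event_rule))
  structure(as.list(environment()), class = "survival_config")
}

#' Negative log Cox partial likelihood
#'
#' `-sum over events i of [r_i - log sum_{j: t_j >= t_i} exp(r_j)] / D`
#' with `D` the event count and Breslow handling of tied times (tied event
#' times share the same risk set). Adding a constant to all risks leaves
#' the loss unchanged.
#'
#' @param risks numeric risk scores.
#' @param times event/censoring times (here: age).
#' @param events 0/1 event indicators; at least one event.
#' @return scalar loss (>= 0 is not guaranteed; it is a mean negative
#'   log-likelihood).
#' @export
cox_partial_likelihood_loss <- function(risks, times, events) {
  stopifnot(length(risks) == length(times), length(times) == length(events))
  d <- sum(events == 1)
  if (d == 0) stop("no events: Cox loss undefined")
  # log cumulative sum of exp(risk) over the risk set {j: t_j >= t_i}
  loss <- 0
  mx <- max(risks)
  for (i in which(events == 1)) {
    rs <- risks[times >= times[i]]
    loss <- loss - (risks[i] - (mx + log(sum(exp(rs - mx)))))
  }
  loss / d
}

# Gradient of the mean negative partial log-likelihood wrt risks.
cox_loss_gradient <- function(risks, times, events) {
  d <- sum(events == 1)
  n <- length(risks)
  g <- numeric(n)
  mx <- max(risks)
  er <- exp(risks - mx)
  for (i in which(events == 1)) {
    rs <- times >= times[i]
    tot <- sum(er[rs])
    g[rs] <- g[rs] + er[rs] / tot
    g[i] <- g[i] - 1
  }
  g / d
}

#' Concordance index
#'
#' The fraction of comparable pairs ordered correctly by the risk score. A
#' pair is comparable when the sample with the shorter time experienced the
#' event; it counts as concordant when that sample also has the higher
#' risk, and risk ties count one half.
#'
#' @inheritParams cox_partial_likelihood_loss
#' @return value in `[0, 1]`.
#' @export
concordance_index <- function(risks, times, events) {
  n <- length(risks)
  conc <- 0; comp <- 0
  for (i in which(events == 1)) {
    later <- which(times > times[i])
    if (length(later) == 0) next
    comp <- comp + length(later)
    conc <- conc + sum(risks[i] > risks[later]) +
      0.5 * sum(risks[i] == risks[later])
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

# --- feed-forward Cox network ---------------------------------------------

init_net <- function(n_in, hidden) {
  sizes <- c(n_in, hidden, 1L)
  layers <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[l + 1L]),
      b = rep(0, sizes[l + 1L])
    )
  }
  layers
}

net_forward <- function(layers, x) {
  acts <- list(x)
  nl <- length(layers)
  for (l in seq_len(nl)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, `+`)
    acts[[l + 1L]] <- if (l < nl) pmax(z, 0) else z  # ReLU hidden, linear out
  }
  acts
}

net_backward <- function(layers, acts, dout) {
  nl <- length(layers)
  grads <- vector("list", nl)
  delta <- dout
  for (l in rev(seq_len(nl))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1L) {
      delta <- delta %*% t(layers[[l]]$W)
      delta <- delta * (acts[[l]] > 0)
    }
  }
  grads
}

#' Train the Cox partial-likelihood feed-forward scorer
#'
#' Minibatch Adam on the negative log partial likelihood, with the loss and
#' risk sets formed within each minibatch (the common practice for
#' neural Cox models). Inputs should be normalized; age is the event time
#' and the mRS-derived indicator the event. Deterministic given
#' `config$seed`.
#'
#' @param x samples x features numeric matrix (normalized covariates:
#'   clinical + mRS radiomics features).
#' @param times event times (age, years).
#' @param events 0/1 event indicators.
#' @param config a [survival_config()].
#' @return object of class `cox_net`: layers, training history (loss and
#'   C-index per reporting interval), config.
#' @export
train_survival_net <- function(x, times, events, config = survival_config()) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(times), length(times) == length(events))
  if (sum(events) == 0) stop("no events in the training data")
  set.seed(config$seed)
  layers <- init_net(ncol(x), config$hidden_layout)
  mstate <- vstate <- lapply(layers, function(l)
    list(W = l$W * 0, b = l$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  n <- nrow(x)
  bs <- min(config$batch_size, n)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        cindex = numeric(0))
  step <- 0
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      if (sum(events[idx]) == 0) next
      acts <- net_forward(layers, x[idx, , drop = FALSE])
      r <- as.numeric(acts[[length(acts)]])
      if (any(!is.finite(r))) stop("training diverged: non-finite risks")
      g <- cox_loss_gradient(r, times[idx], events[idx])
      grads <- net_backward(layers, acts, matrix(g, ncol = 1L))
      step <- step + 1
      for (l in seq_along(layers)) {
        for (nm in c("W", "b")) {
          mstate[[l]][[nm]] <- b1 * mstate[[l]][[nm]] +
            (1 - b1) * grads[[l]][[nm]]
          vstate[[l]][[nm]] <- b2 * vstate[[l]][[nm]] +
            (1 - b2) * grads[[l]][[nm]]^2
          mhat <- mstate[[l]][[nm]] / (1 - b1^step)
          vhat <- vstate[[l]][[nm]] / (1 - b2^step)
          layers[[l]][[nm]] <- layers[[l]][[nm]] -
            lr * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    if (epoch %% max(1L, config$epochs %/% 20L) == 0 ||
        epoch == config$epochs) {
      r_all <- as.numeric(net_forward(layers, x)[[length(layers) + 1L]])
      history <- rbind(history, data.frame(
        epoch = epoch,
        loss = cox_partial_likelihood_loss(r_all, times, events),
        cindex = concordance_index(r_all, times, events)))
    }
  }
  structure(list(layers = layers, history = history, config = config,
                 n_features = ncol(x), feature_names = colnames(x)),
            class = "cox_net")
}

#' @export
print.cox_net <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<cox_net> %d inputs, hidden %s; final loss %.4f, C-index %.3f\n",
              x$n_features, paste(x$config$hidden_layout, collapse = "-"),
              last$loss, last$cindex))
  invisible(x)
}

#' Compute the survival feature (SurvF) for a cohort
#'
#' Raw network risk scores, range-normalized across the cohort (a constant
#' output maps to all zeros).
#'
#' @param model a trained [train_survival_net()] `cox_net`.
#' @param x samples x features matrix with the training feature schema.
#' @return list with `survf` (normalized scores), `risk` (raw scores),
#'   `cindex` (training C-index at the last epoch).
#' @export
compute_survf <- function(model, x) {
  stopifnot(inherits(model, "cox_net"))
  x <- as.matrix(x)
  if (ncol(x) != model$n_features)
    stop("feature schema mismatch: expected ", model$n_features,
         " columns, got ", ncol(x))
  r <- as.numeric(net_forward(model$layers, x)[[length(model$layers) + 1L]])
  list(survf = normalize_feature(r), risk = r,
       cindex = model$history$cindex[nrow(model$history)])
}
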