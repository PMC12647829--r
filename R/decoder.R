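# Single-layer perceptron read-out of spike-count matrices: softmax
# activation, categorical cross-entropy loss, mini-batch stochastic gradient
# descent, early stopping on validation accuracy. Counts are fed raw (no
# standardization).

#' Decoder hyperparameters
#'
#' @param lr Learning rate.
#' @param batch Mini-batch size.
#' @param epochs Maximal number of epochs (early-stopping mode) or the exact
#'   number of epochs (fixed mode).
#' @param patience Early-stopping patience in epochs without a validation
#'   accuracy improvement.
#' @param mode `"early"` or `"fixed"`.
#' @param split Train/validation/test fractions (must sum to 1).
#' @param seed Integer seed for weight init and batch shuffling.
#' @return Object of class `grc_decoder_config`.
#' @export
decoder_config <- function(lr = 0.001, batch = 32L, epochs = 2000L,
                           patience = 5L, mode = c("early", "fixed"),
                           split = c(0.70, 0.10, 0.20), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(lr > 0, batch >= 1, epochs >= 1, patience >= 1,
            length(split) == 3, abs(sum(split) - 1) < 1e-9)
  structure(list(lr = lr, batch = as.integer(batch),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 mode = mode, split = split, seed = as.integer(seed)),
            class = "grc_decoder_config")
}

#' Split samples into train / validation / test index sets
#'
#' Seeded shuffle, sizes rounded from the configured fractions (test takes
#' the remainder); the three sets are disjoint and exhaustive.
#'
#' @param n Number of samples (>= 10).
#' @param config A [decoder_config()].
#' @param seed Integer seed (defaults to the config seed).
#' @return List with integer vectors `train`, `val`, `test`.
#' @export
split_samples <- function(n, config = decoder_config(), seed = config$seed) {
  stopifnot(n >= 10)
  set.seed(derive_seed(seed, "split"))
  idx <- sample.int(n)
  n_train <- round(config$split[1] * n)
  n_val <- round(config$split[2] * n)
  list(train = idx[seq_len(n_train)],
       val = idx[n_train + seq_len(n_val)],
       test = idx[(n_train + n_val + 1):n])
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

slp_accuracy <- function(model, X, y) {
  S <- X %*% model$W + matrix(model$b, nrow(X), length(model$b), byrow = TRUE)
  pred <- max.col(S, ties.method = "first") - 1L
  mean(pred == y)
}

#' Train the single-layer perceptron decoder
#'
#' @param X Count matrix (samples x neurons), raw spike counts.
#' @param y Integer class labels in `0 .. K-1`.
#' @param config A [decoder_config()].
#' @param split Optional index sets from [split_samples()]; computed from the
#'   config otherwise.
#' @return Object of class `grc_slp`: weights `W`, bias `b`, per-split
#'   `accuracy`, `epochs_run`, training `loss` history.
#' @export
train_slp <- function(X, y, config = decoder_config(),
                      split = split_samples(nrow(X), config)) {
  stopifnot(nrow(X) == length(y))
  classes <- sort(unique(y))
  K <- length(classes)
  if (length(unique(y[split$train])) < 2)
    stop("training set is degenerate: fewer than 2 classes present")
  if (!all(y %in% 0:(K - 1))) stop("labels must be 0..K-1")
  d <- ncol(X)
  set.seed(derive_seed(config$seed, "decoder"))
  W <- matrix(runif(d * K, -0.01, 0.01), d, K)
  b <- numeric(K)
  Xtr <- X[split$train, , drop = FALSE]
  ytr <- y[split$train]
  Ytr <- diag(K)[ytr + 1L, , drop = FALSE]
  n_tr <- nrow(Xtr)
  best <- list(W = W, b = b, val = -Inf, since = 0L)
  loss_hist <- numeric(0)
  epochs_run <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n_tr)
    ep_loss <- 0
    for (start in seq(1, n_tr, by = config$batch)) {
      ii <- ord[start:min(start + config$batch - 1L, n_tr)]
      Xi <- Xtr[ii, , drop = FALSE]
      P <- softmax_rows(Xi %*% W + matrix(b, length(ii), K, byrow = TRUE))
      Yi <- Ytr[ii, , drop = FALSE]
      ep_loss <- ep_loss - sum(log(pmax(P[Yi == 1], 1e-12)))
      G <- (P - Yi) / length(ii)
      W <- W - config$lr * crossprod(Xi, G)
      b <- b - config$lr * colSums(G)
    }
    loss_hist <- c(loss_hist, ep_loss / n_tr)
    epochs_run <- ep
    if (config$mode == "early") {
      val_acc <- slp_accuracy(list(W = W, b = b),
                              X[split$val, , drop = FALSE], y[split$val])
      if (val_acc > best$val) {
        best <- list(W = W, b = b, val = val_acc, since = 0L)
      } else {
        best$since <- best$since + 1L
        if (best$since >= config$patience) break
      }
    }
  }
  if (config$mode == "early") { W <- best$W; b <- best$b }
  model <- structure(list(W = W, b = b, classes = classes,
                          epochs_run = epochs_run, loss = loss_hist,
                          config = config, split = split),
                     class = "grc_slp")
  model$accuracy <- c(
    train = slp_accuracy(model, Xtr, ytr),
    val = slp_accuracy(model, X[split$val, , drop = FALSE], y[split$val]),
    test = slp_accuracy(model, X[split$test, , drop = FALSE], y[split$test]))
  model
}

#' @export
print.grc_slp <- function(x, ...) {
  cat(sprintf(
    "SLP decoder: %d features -> %d classes, %d epochs (%s mode)\n",
    nrow(x$W), ncol(x$W), x$epochs_run, x$config$mode))
  cat(sprintf("  accuracy: train %.3f, val %.3f, test %.3f\n",
              x$accuracy[["train"]], x$accuracy[["val"]],
              x$accuracy[["test"]]))
  invisible(x)
}

#' Evaluate a trained decoder on counts from another condition
#'
#' Applies a decoder trained under one condition (e.g. intact inhibition) to
#' matched samples recorded under another (e.g. blocked inhibition); pattern
#' identities and labels must correspond across conditions.
#'
#' @param model A trained `grc_slp`.
#' @param X Count matrix from the other condition.
#' @param y Labels.
#' @param idx Optional index subset (e.g. `model$split$test`).
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_cross_condition <- function(model, X, y, idx = NULL) {
  if (!is.null(idx)) { X <- X[idx, , drop = FALSE]; y <- y[idx] }
  slp_accuracy(model, X, y)
}

#' Accuracy over repeated decoder seeds with CIs and paired tests
#'
#' Trains the decoder on each dataset of a named list for several seeds and
#' summarizes mean test accuracy with a 95 percent t-based confidence
#' interval per arm, plus paired t-tests between all pairs of arms (paired
#' over seeds).
#'
#' @param datasets Named list; each element is `list(X = counts, y = labels)`.
#' @param config A [decoder_config()].
#' @param seeds Integer vector of decoder seeds.
#' @return List with `summary` (data frame arm/mean/sd/ci_lo/ci_hi),
#'   `accuracy` (seeds x arms matrix) and `tests` (pairwise paired t-tests).
#' @export
accuracy_over_seeds <- function(datasets, config = decoder_config(),
                                seeds = 1:6) {
  stopifnot(length(datasets) >= 1, !is.null(names(datasets)))
  acc <- matrix(NA_real_, length(seeds), length(datasets),
                dimnames = list(NULL, names(datasets)))
  for (a in seq_along(datasets)) {
    d <- datasets[[a]]
    for (s in seq_along(seeds)) {
      cfg <- config
      cfg$seed <- as.integer(seeds[s])
      acc[s, a] <- train_slp(d$X, d$y, cfg)$accuracy[["test"]]
    }
  }
  summ <- do.call(rbind, lapply(colnames(acc), function(nm)
    cbind(data.frame(arm = nm), summary_stats(acc[, nm]))))
  tests <- NULL
  if (ncol(acc) >= 2) {
    pairs <- utils::combn(colnames(acc), 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      pt <- paired_test(acc[, pairs[1, k]], acc[, pairs[2, k]])
      data.frame(arm1 = pairs[1, k], arm2 = pairs[2, k],
                 mean_diff = pt$mean_diff, p = pt$p)
    }))
  }
  list(summary = summ, accuracy = acc, tests = tests)
}
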