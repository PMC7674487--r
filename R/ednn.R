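#' Training configuration for the two-layer classifier
#'
#' The network is `k` selected voxels -> `n_hidden` ReLU units -> one
#' logistic output, trained by Adam on binary cross-entropy plus
#' `lambda_reg` times the KL-L1 penalty on both weight matrices. The
#' sparsity target `epsilon` and all optimizer knobs are exposed because
#' none of them is canonical; defaults are logged with every run.
#'
#' @param n_hidden hidden-layer width.
#' @param epsilon sparsity target for each row's L1 norm, in (0, 1).
#' @param lambda_reg penalty weight (>= 0).
#' @param learning_rate Adam step size.
#' @param max_epochs training epochs cap.
#' @param batch_size mini-batch size (capped at n during training).
#' @param patience epochs without loss improvement before early stop.
#' @param seed RNG seed for initialization and shuffling.
#' @return a named list.
#' @export
ednnConfig <- function(n_hidden = 64L, epsilon = 0.05, lambda_reg = 1e-3,
                       learning_rate = 0.01, max_epochs = 500L,
                       batch_size = 32L, patience = 50L, seed = 1L) {
  stopifnot(epsilon > 0, epsilon < 1, lambda_reg >= 0, n_hidden >= 1L,
            max_epochs >= 0L, batch_size >= 1L, learning_rate > 0)
  list(n_hidden = as.integer(n_hidden), epsilon = epsilon,
       lambda_reg = lambda_reg, learning_rate = learning_rate,
       max_epochs = as.integer(max_epochs),
       batch_size = as.integer(batch_size),
       patience = as.integer(patience), seed = as.integer(seed))
}

#' Bernoulli KL sparsity penalty on weight-row L1 norms
#'
#' For each row \eqn{i} of `W`, let
#' \eqn{p_i = \mathrm{clip}(\|W_{i\cdot}\|_1, \delta, 1-\delta)} with
#' \eqn{\delta = 10^{-6}}. The penalty is the summed Bernoulli KL
#' divergence to the target \eqn{\epsilon}:
#' \deqn{\sum_i p_i \log\frac{p_i}{\epsilon}
#'       + (1-p_i) \log\frac{1-p_i}{1-\epsilon}.}
#' It is non-negative and zero exactly when every clipped row norm equals
#' \eqn{\epsilon}. The formula is only defined for norms in (0, 1); the
#' clip keeps it finite for arbitrary weights, and the gradient is zero
#' in the clipped regime.
#'
#' @param W numeric weight matrix (rows = units).
#' @param epsilon sparsity target in (0, 1).
#' @return non-negative scalar, in nats.
#' @export
#' @examples
#' klL1Penalty(matrix(c(0.025, -0.025), 1), 0.05)  # row norm == target: 0
klL1Penalty <- function(W, epsilon) {
  if (epsilon <= 0 || epsilon >= 1)
    stop("epsilon must be in (0, 1)", call. = FALSE)
  delta <- 1e-6
  p <- pmin(pmax(rowSums(abs(W)), delta), 1 - delta)
  sum(p * log(p / epsilon) + (1 - p) * log((1 - p) / (1 - epsilon)))
}

# Gradient of klL1Penalty wrt W. d/dp of the row term is
# log(p/eps) - log((1-p)/(1-eps)); dp/dW_ij = sign(W_ij). With
# extend = FALSE the gradient is exactly that of the clipped penalty
# (zero where the clip is active). Training uses extend = TRUE: the
# boundary slope is continued outside (delta, 1-delta), i.e. the
# gradient of the linearly extended penalty, so rows that leave the
# formula's domain still feel a restoring force instead of sitting in a
# flat region forever.
klL1PenaltyGrad <- function(W, epsilon, extend = FALSE) {
  delta <- 1e-6
  raw <- rowSums(abs(W))
  p <- pmin(pmax(raw, delta), 1 - delta)
  dp <- log(p / epsilon) - log((1 - p) / (1 - epsilon))
  if (!extend) dp[raw < delta | raw > 1 - delta] <- 0
  sign(W) * dp
}

ednnForward <- function(W1, b1, W2, b2, X) {
  Z1 <- sweep(X %*% t(W1), 2, b1, "+")
  H <- pmax(Z1, 0)
  p <- sigmoid(as.numeric(H %*% t(W2)) + b2)
  list(Z1 = Z1, H = H, p = p)
}

bce <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

#' Total training loss: cross-entropy plus weighted KL-L1 penalty
#'
#' `BCE(y, p) + lambda_reg * (penalty(W1) + penalty(W2))`, evaluated on a
#' batch. With `lambda_reg = 0` this reduces to plain cross-entropy.
#'
#' @param model a [TrainedEDNN].
#' @param X batch matrix (subjects x k), already on the model's input
#'   scale.
#' @param y binary labels.
#' @param config an [ednnConfig()] list supplying `epsilon` and
#'   `lambda_reg`.
#' @return scalar loss.
#' @export
ednnLoss <- function(model, X, y, config) {
  if (ncol(X) != ncol(model@W1))
    stop("feature-count mismatch between batch and model", call. = FALSE)
  fwd <- ednnForward(model@W1, model@b1, model@W2, model@b2, X)
  bce(fwd$p, y) + config$lambda_reg *
    (klL1Penalty(model@W1, config$epsilon) +
       klL1Penalty(model@W2, config$epsilon))
}

#' Train the KL-L1-regularized two-layer classifier
#'
#' Restricts the cohort to the selected voxels, standardizes features by
#' the training mean/SD (the scaler is frozen into the model, so a
#' shifted new cohort is scored on the original scale — the situation
#' transfer retraining exists to repair), and fits by mini-batch Adam.
#' When warm-starting (`init`), weights are inherited but the scaler is
#' re-estimated from the new training data; re-centering onto the new
#' cohort is what lets retraining adapt to covariate shift.
#' The model at the best training loss is returned; training stops early
#' after `patience` epochs without improvement. Bit-reproducible given
#' `config$seed`.
#'
#' @param cohort a [VbmCohort] (training subjects).
#' @param features a [SelectedFeatures] (from the same training split).
#' @param config an [ednnConfig()] list.
#' @param init optional [TrainedEDNN] to warm-start from (transfer
#'   retraining); its weights seed the optimizer, its feature set must
#'   match, and the scaler is re-estimated from `cohort`.
#' @return a [TrainedEDNN].
#' @export
trainEDNN <- function(cohort, features, config = ednnConfig(),
                      init = NULL) {
  y <- diagnosis(cohort)
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  Xall <- densityMatrix(cohort)
  X <- Xall[, features@columns, drop = FALSE]
  n <- nrow(X); k <- ncol(X); h <- config$n_hidden

  if (!is.null(init))
    stopifnot(identical(init@features@columns, features@columns))
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")

  withSeed(config$seed, {
    if (is.null(init)) {
      # random directions with each row's L1 norm at 0.5, the middle of
      # the penalty's (0, 1) domain, so the KL-L1 gradient is live from
      # the first step (outside the domain the clipped penalty is flat)
      rowUnit <- function(nr, nc) {
        M <- matrix(stats::rnorm(nr * nc), nr, nc)
        M * (0.5 / rowSums(abs(M)))
      }
      W1 <- rowUnit(h, k)
      b1 <- numeric(h)
      W2 <- rowUnit(1L, h)
      b2 <- 0
    } else {
      W1 <- init@W1; b1 <- init@b1; W2 <- init@W2; b2 <- init@b2
    }
    adam <- list(t = 0)
    for (nm in c("W1", "b1", "W2", "b2"))
      adam[[nm]] <- list(m = get(nm) * 0, v = get(nm) * 0)
    beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8; lr <- config$learning_rate

    history <- data.frame(epoch = integer(), loss = numeric(),
                          penalty = numeric(), accuracy = numeric())
    best <- list(loss = Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    stall <- 0L
    bs <- min(config$batch_size, n)

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        Xb <- Xs[idx, , drop = FALSE]; yb <- y[idx]; nb <- length(idx)
        fwd <- ednnForward(W1, b1, W2, b2, Xb)
        dz2 <- (fwd$p - yb) / nb
        gW2 <- matrix(dz2, 1) %*% fwd$H
        gb2 <- sum(dz2)
        dH <- outer(dz2, as.numeric(W2))
        dZ1 <- dH * (fwd$Z1 > 0)
        gW1 <- t(dZ1) %*% Xb
        gb1 <- colSums(dZ1)
        if (config$lambda_reg > 0) {
          gW1 <- gW1 + config$lambda_reg *
            klL1PenaltyGrad(W1, config$epsilon, extend = TRUE)
          gW2 <- gW2 + config$lambda_reg *
            klL1PenaltyGrad(W2, config$epsilon, extend = TRUE)
        }
        adam$t <- adam$t + 1
        step <- function(nm, g) {
          st <- adam[[nm]]
          st$m <- beta1 * st$m + (1 - beta1) * g
          st$v <- beta2 * st$v + (1 - beta2) * g^2
          adam[[nm]] <<- st
          mhat <- st$m / (1 - beta1^adam$t)
          vhat <- st$v / (1 - beta2^adam$t)
          lr * mhat / (sqrt(vhat) + aeps)
        }
        W1 <- W1 - step("W1", gW1); b1 <- b1 - step("b1", gb1)
        W2 <- W2 - step("W2", gW2); b2 <- b2 - step("b2", gb2)
      }
      fwd <- ednnForward(W1, b1, W2, b2, Xs)
      pen <- klL1Penalty(W1, config$epsilon) +
        klL1Penalty(W2, config$epsilon)
      loss <- bce(fwd$p, y) + config$lambda_reg * pen
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d", epoch), call. = FALSE)
      acc <- mean(as.integer(fwd$p >= 0.5) == y)
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = loss,
                                  penalty = pen, accuracy = acc))
      if (loss < best$loss - 1e-6) {
        best <- list(loss = loss, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })

  new("TrainedEDNN", W1 = best$W1, b1 = best$b1, W2 = best$W2,
      b2 = best$b2, features = features,
      scaler = list(center = center, scale = scale), config = config,
      history = history)
}

#' Predict patient probability for each subject
#'
#' Forward pass of the two layers on the model's feature scale. `X` may
#' be a full cohort matrix (columns are then taken from the model's
#' selected features) or already restricted to `k` columns.
#'
#' @param model a [TrainedEDNN].
#' @param X subjects x voxels matrix or a [VbmCohort].
#' @return numeric probabilities in \[0, 1\].
#' @export
predictProba <- function(model, X) {
  if (is(X, "VbmCohort")) X <- densityMatrix(X)
  k <- ncol(model@W1)
  if (ncol(X) != k) {
    if (max(model@features@columns) <= ncol(X))
      X <- X[, model@features@columns, drop = FALSE]
    else
      stop("feature-count mismatch with model", call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, model@scaler$center, "-"), 2,
              model@scaler$scale, "/")
  ednnForward(model@W1, model@b1, model@W2, model@b2, Xs)$p
}

#' Combine gray- and white-matter probabilities into one diagnosis
#'
#' The two tissue models are independent end-to-end; the combined verdict
#' defaults to the arithmetic mean of their probabilities, with
#' probability `>= threshold` called patient (ties break toward the
#' patient class).
#'
#' @param p_gm,p_wm probabilities in \[0, 1\].
#' @param rule combination function of two probability vectors.
#' @param threshold decision threshold.
#' @return list with `probability` and integer `label`.
#' @export
#' @examples
#' combineTissues(0.2, 0.9)  # 0.55 -> patient
combineTissues <- function(p_gm, p_wm,
                           rule = function(a, b) (a + b) / 2,
                           threshold = 0.5) {
  if (any(p_gm < 0 | p_gm > 1 | p_wm < 0 | p_wm > 1))
    stop("probabilities must be in [0, 1]", call. = FALSE)
  p <- rule(p_gm, p_wm)
  list(probability = p, label = as.integer(p >= threshold))
}

#' Persist or restore a trained model as a JSON archive
#'
#' Single-file JSON holding the weights, scaler, selected features and
#' configuration; text-only and exactly invertible at double precision.
#'
#' @param model a [TrainedEDNN].
#' @param path archive path.
#' @export
saveEDNN <- function(model, path) {
  obj <- list(W1 = model@W1, b1 = model@b1, W2 = model@W2, b2 = model@b2,
              scaler = model@scaler, config = model@config,
              features = list(columns = model@features@columns,
                              score = model@features@score,
                              coords = model@features@coords,
                              n_bins = model@features@n_bins),
              history = model@history)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveEDNN
#' @export
loadEDNN <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- new("SelectedFeatures",
               columns = as.integer(o$features$columns),
               score = as.numeric(o$features$score),
               coords = matrix(as.integer(o$features$coords),
                               ncol = 3,
                               dimnames = list(NULL, c("i", "j", "k"))),
               n_bins = as.integer(o$features$n_bins))
  cfg <- o$config
  cfg[c("n_hidden", "max_epochs", "batch_size", "patience", "seed")] <-
    lapply(cfg[c("n_hidden", "max_epochs", "batch_size", "patience",
                 "seed")], as.integer)
  new("TrainedEDNN",
      W1 = matrix(as.numeric(o$W1), nrow = nrow(o$W1)),
      b1 = as.numeric(o$b1),
      W2 = matrix(as.numeric(o$W2), nrow = 1),
      b2 = as.numeric(o$b2), features = feats,
      scaler = list(center = as.numeric(o$scaler$center),
                    scale = as.numeric(o$scaler$scale)),
      config = cfg, history = as.data.frame(o$history))
}
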