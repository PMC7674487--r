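# Independent oracles, kept deliberately naive so they share no code path
# with the package implementations they check.

# Mutual information by explicit double sum over the empirical joint
# table, in nats.
bruteMI <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (xv in unique(x)) for (yv in unique(y)) {
    pxy <- sum(x == xv & y == yv) / n
    if (pxy > 0) {
      px <- sum(x == xv) / n
      py <- sum(y == yv) / n
      mi <- mi + pxy * log(pxy / (px * py))
    }
  }
  mi
}

# AUC as the pairwise concordance probability over all (patient,
# control) pairs, ties counted 1/2.
bruteAUC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Bernoulli KL divergence KL(p || eps), one scalar.
bernKL <- function(p, eps) {
  p * log(p / eps) + (1 - p) * log((1 - p) / (1 - eps))
}

# Forward pass written out long-hand for loss/prediction cross-checks.
bruteForward <- function(W1, b1, W2, b2, x) {
  h <- numeric(nrow(W1))
  for (i in seq_len(nrow(W1)))
    h[i] <- max(sum(W1[i, ] * x) + b1[i], 0)
  1 / (1 + exp(-(sum(W2[1, ] * h) + b2)))
}

# A hand-assembled TrainedEDNN with explicit weights (identity scaler).
toyModel <- function(W1, b1, W2, b2) {
  k <- ncol(W1)
  feats <- new("SelectedFeatures", columns = seq_len(k),
               score = rep(0, k),
               coords = matrix(1L, k, 3,
                               dimnames = list(NULL, c("i", "j", "k"))),
               n_bins = 4L)
  new("TrainedEDNN", W1 = W1, b1 = b1, W2 = W2, b2 = b2,
      features = feats,
      scaler = list(center = rep(0, k), scale = rep(1, k)),
      config = ednnConfig(),
      history = data.frame(epoch = 1L, loss = 0, penalty = 0,
                           accuracy = 1))
}
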