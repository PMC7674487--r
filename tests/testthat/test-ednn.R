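test_that("KL-L1 penalty matches closed-form Bernoulli KL values", {
  # every row norm at the target: KL minimum of 0
  W <- rbind(c(0.03, -0.02), c(-0.01, 0.04))  # row L1 norms 0.05
  expect_equal(klL1Penalty(W, 0.05), 0, tolerance = 1e-12)

  # single rows, frozen from direct evaluation of p ln(p/e)+(1-p)ln((1-p)/(1-e))
  expect_equal(klL1Penalty(matrix(c(0.3, -0.2), 1), 0.05),
               0.8303656, tolerance = 1e-6)
  expect_equal(klL1Penalty(matrix(c(0.03, -0.02), 1), 0.5),
               0.4946319, tolerance = 1e-6)
  # and against the scalar oracle
  expect_equal(klL1Penalty(matrix(c(0.3, -0.2), 1), 0.05),
               bernKL(0.5, 0.05), tolerance = 1e-12)

  expect_error(klL1Penalty(matrix(1, 1, 1), 0), "epsilon")
  expect_error(klL1Penalty(matrix(1, 1, 1), 1), "epsilon")
})

test_that("penalty is non-negative and zero iff clipped row norms equal the target", {
  set.seed(501)
  for (rep in 1:20) {
    W <- matrix(rnorm(12, sd = 0.3), 3, 4)
    eps <- runif(1, 0.02, 0.9)
    expect_gte(klL1Penalty(W, eps), 0)
    # scale each row so its L1 norm is exactly eps -> penalty 0
    W0 <- W * (eps / rowSums(abs(W)))
    expect_equal(klL1Penalty(W0, eps), 0, tolerance = 1e-10)
    # move one row off the target -> strictly positive
    W1 <- W0; W1[2, ] <- W1[2, ] * 1.5
    expect_gt(klL1Penalty(W1, eps), 1e-6)
  }
})

test_that("analytic penalty gradient matches finite differences in-domain", {
  set.seed(502)
  for (rep in 1:10) {
    W <- matrix(runif(12, 0.01, 0.2) * sample(c(-1, 1), 12, TRUE), 3, 4)
    eps <- runif(1, 0.05, 0.5)
    g <- vbmednn:::klL1PenaltyGrad(W, eps)
    h <- 1e-7
    for (idx in sample(12, 4)) {
      Wp <- W; Wp[idx] <- Wp[idx] + h
      Wm <- W; Wm[idx] <- Wm[idx] - h
      fd <- (klL1Penalty(Wp, eps) - klL1Penalty(Wm, eps)) / (2 * h)
      expect_equal(g[idx], fd, tolerance = 1e-5)
    }
  }
})

test_that("total loss reduces to cross-entropy and matches a hand-summed toy", {
  # 2 subjects, 3 features, 2 hidden units, fixed tiny weights
  W1 <- rbind(c(0.10, -0.05, 0.02), c(-0.04, 0.08, 0.01))
  b1 <- c(0.01, -0.02)
  W2 <- matrix(c(0.07, -0.03), 1)
  b2 <- 0.05
  model <- toyModel(W1, b1, W2, b2)
  X <- rbind(c(0.2, 0.5, -0.1), c(-0.3, 0.4, 0.6))
  y <- c(1, 0)

  # independent arithmetic: long-hand forward, BCE and Bernoulli terms
  p <- c(bruteForward(W1, b1, W2, b2, X[1, ]),
         bruteForward(W1, b1, W2, b2, X[2, ]))
  bce_hand <- -(log(p[1]) + log(1 - p[2])) / 2
  pen_hand <- bernKL(sum(abs(W1[1, ])), 0.05) +
    bernKL(sum(abs(W1[2, ])), 0.05) + bernKL(sum(abs(W2)), 0.05)

  cfg0 <- ednnConfig(lambda_reg = 0)
  expect_equal(ednnLoss(model, X, y, cfg0), bce_hand, tolerance = 1e-12)
  cfg <- ednnConfig(lambda_reg = 0.3, epsilon = 0.05)
  expect_equal(ednnLoss(model, X, y, cfg), bce_hand + 0.3 * pen_hand,
               tolerance = 1e-10)

  expect_error(ednnLoss(model, X[, 1:2], y, cfg), "mismatch")
})

test_that("forward pass matches closed forms and is row-stable", {
  zero <- toyModel(matrix(0, 2, 2), c(0, 0), matrix(0, 1, 2), 0)
  expect_equal(predictProba(zero, rbind(c(5, -3), c(0.1, 100))),
               c(0.5, 0.5))

  # 1 hidden unit: W1=(1,0), ReLU then logistic with W2=1 -> sigmoid(2)
  m <- toyModel(matrix(c(1, 0), 1), 0, matrix(1, 1, 1), 0)
  expect_equal(predictProba(m, matrix(c(2, 5), 1)), 1 / (1 + exp(-2)),
               tolerance = 1e-12)

  X <- rbind(c(0.3, 0.7), c(0.3, 0.7))
  p <- predictProba(zero, X)
  expect_identical(p[1], p[2])
})

test_that("training is deterministic given the seed and rejects one-class data", {
  fx <- phantomFixture()
  cfg <- ednnConfig(seed = 99L, max_epochs = 15L, n_hidden = 8L)
  m1 <- trainEDNN(fx$train, fx$feats, cfg)
  m2 <- trainEDNN(fx$train, fx$feats, cfg)
  expect_identical(m1@W1, m2@W1)
  expect_identical(m1@b2, m2@b2)
  expect_identical(m1@history, m2@history)

  onecls <- fx$train[, diagnosis(fx$train) == 0]
  expect_error(trainEDNN(onecls, fx$feats, cfg), "both classes")
})

test_that("large penalty weights drive row L1 norms toward the target", {
  fx <- phantomFixture()
  dist <- vapply(c(0, 1e-3, 1e-1, 10), function(lam) {
    m <- trainEDNN(fx$train, fx$feats,
                   ednnConfig(seed = 5L, lambda_reg = lam,
                              max_epochs = 120L))
    mean(abs(rowSums(abs(m@W1)) - 0.05))
  }, numeric(1))
  expect_true(all(diff(dist) < 0))
})

test_that("tissue combination averages probabilities with ties to patient", {
  expect_equal(combineTissues(0.9, 0.9),
               list(probability = 0.9, label = 1L))
  expect_equal(combineTissues(0.5, 0.5),
               list(probability = 0.5, label = 1L))
  expect_equal(combineTissues(0.2, 0.9),
               list(probability = 0.55, label = 1L))
  expect_equal(combineTissues(0.2, 0.3)$label, 0L)
  expect_error(combineTissues(1.2, 0.5), "0, 1")
})

test_that("model archives round-trip through JSON exactly", {
  fx <- phantomFixture()
  f <- withr::local_tempfile(fileext = ".json")
  saveEDNN(fx$model, f)
  back <- loadEDNN(f)
  expect_equal(back@W1, fx$model@W1, tolerance = 1e-15)
  expect_identical(selectedColumns(back@features),
                   selectedColumns(fx$model@features))
  X <- densityMatrix(fx$test)
  expect_equal(predictProba(back, X), predictProba(fx$model, X),
               tolerance = 1e-12, ignore_attr = TRUE)
})
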