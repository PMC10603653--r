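test_that("episodes sample exactly n per class, seeded", {
  tw <- tinyWorld(K = 5, dim = 16, nTrain = 16, nTest = 2, noise = 0.1)
  ep <- makeEpisode(tw$world$train$embeddings, tw$world$train$labels,
                    tw$bank, n = 16, seed = 4)
  expect_identical(nrow(weightMatrix(ep@W)), 80L)   # N = n*K
  expect_identical(unname(tabulate(ep@labels + 1L, 5)), rep(16L, 5))

  ep2 <- makeEpisode(tw$world$train$embeddings, tw$world$train$labels,
                     tw$bank, n = 16, seed = 4)
  expect_identical(ep, ep2)
  ep3 <- makeEpisode(tw$world$train$embeddings, tw$world$train$labels,
                     tw$bank, n = 3, seed = 5)
  expect_false(identical(
    ep3, makeEpisode(tw$world$train$embeddings, tw$world$train$labels,
                     tw$bank, n = 3, seed = 6)))

  # a class with too few samples is named in the error
  drop <- tw$world$train$labels != 2L
  sub <- embeddingMatrix(
    embeddingValues(tw$world$train$embeddings)[drop, , drop = FALSE],
    rowIds(tw$world$train$embeddings)[drop])
  expect_error(makeEpisode(sub, tw$world$train$labels[drop], tw$bank,
                           n = 1, seed = 0),
               "synthetic-species-03")
})

test_that("cross-entropy has its closed forms and matches a loop oracle", {
  onehot <- diag(3)[c(1, 2, 3), ]
  expect_equal(crossEntropyLoss(onehot, c(0, 1, 2)), 0, tolerance = 1e-12)
  expect_equal(crossEntropyLoss(matrix(rep(0.1, 10), 1), 4), log(10),
               tolerance = 1e-12)
  withr::local_seed(8)
  for (i in 1:20) {
    n <- sample(1:6, 1); K <- sample(2:5, 1)
    P <- matrix(rexp(n * K), n)
    P <- P / rowSums(P)
    labels <- sample(K, n, replace = TRUE) - 1L
    expect_equal(crossEntropyLoss(P, labels), naiveCrossEntropy(P, labels),
                 tolerance = 1e-12)
    # logits route agrees with softmax-then-probability route
    L <- matrix(rnorm(n * K), n)
    expect_equal(crossEntropyLoss(L, labels, logits = TRUE),
                 naiveCrossEntropy(t(apply(L, 1, naiveSoftmax)), labels),
                 tolerance = 1e-12)
  }
  expect_error(crossEntropyLoss(matrix(c(.5, .5), 1), 2), "out of range")
  expect_error(crossEntropyLoss(matrix(c(.9, .3), 1), 0), "sum to 1")
})

test_that("a separable episode is learned to training accuracy 1", {
  tw <- tinyWorld(K = 4, dim = 16, nTrain = 8, nTest = 4, noise = 0)
  # nearest-prototype oracle confirms separability first
  expect_equal(nearestPrototypeAccuracy(tw$bank, tw$world$train$embeddings,
                                        tw$world$train$labels), 1)
  ep <- makeEpisode(tw$world$train$embeddings, tw$world$train$labels,
                    tw$bank, n = 8, seed = 1)
  fit <- trainAdapter(
    ep,
    adapterConfig(nrow(embeddingValues(tw$bank)), 4, hiddenDim = 32,
                  attnDim = 8, nFeatures = nFeatures(tw$bank), seed = 1),
    trainConfig(seed = 1, maxEpochs = 150))
  expect_identical(nrow(fit$history), 150L)
  expect_equal(fit$history$accuracy[150], 1)
  expect_lte(fit$history$loss[150], fit$history$loss[1])

  Wt <- computeFusionWeights(tw$bank, tw$world$test$embeddings)
  expect_equal(evaluateAccuracy(fit$adapter, Wt, tw$world$test$labels), 1)
})

test_that("training is bit-deterministic per seed", {
  tw <- tinyWorld(K = 3, dim = 16, nTrain = 4, nTest = 2, noise = 0.1)
  ep <- makeEpisode(tw$world$train$embeddings, tw$world$train$labels,
                    tw$bank, n = 4, seed = 2)
  cfg <- adapterConfig(nrow(embeddingValues(tw$bank)), 3, hiddenDim = 16,
                       attnDim = 4, nFeatures = nFeatures(tw$bank), seed = 3)
  f1 <- trainAdapter(ep, cfg, trainConfig(seed = 9, maxEpochs = 30))
  f2 <- trainAdapter(ep, cfg, trainConfig(seed = 9, maxEpochs = 30))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$adapter@params, f2$adapter@params)
  f3 <- trainAdapter(ep, cfg, trainConfig(seed = 10, maxEpochs = 30))
  expect_false(identical(f1$history$loss, f3$history$loss))
})

test_that("an untrained adapter sits near chance on balanced data", {
  tw <- tinyWorld(K = 10, dim = 32, nTrain = 2, nTest = 50, noise = 0.05,
                  unknown = 0)
  ad0 <- initAdapter(adapterConfig(nrow(embeddingValues(tw$bank)), 10,
                                   hiddenDim = 64, attnDim = 16,
                                   nFeatures = nFeatures(tw$bank), seed = 5))
  Wt <- computeFusionWeights(tw$bank, tw$world$test$embeddings)
  acc <- evaluateAccuracy(ad0, Wt, tw$world$test$labels)   # 500 samples
  expect_lt(abs(acc - 0.1), 0.1)
})

test_that("accuracy equals a loop-and-count oracle", {
  withr::local_seed(4)
  ad <- initAdapter(adapterConfig(6, 3, hiddenDim = 4, attnDim = 2,
                                  nFeatures = 0, seed = 1))
  for (i in 1:10) {
    X <- matrix(rnorm(5 * 6), 5, 6)
    labels <- sample(0:2, 5, replace = TRUE)
    logits <- adapterForward(ad, X)
    hits <- 0
    for (r in 1:5) {
      best <- 1
      for (k in 2:3) if (logits[r, k] > logits[r, best]) best <- k
      if (best - 1 == labels[r]) hits <- hits + 1
    }
    expect_equal(evaluateAccuracy(ad, X, labels), hits / 5)
  }
  expect_error(evaluateAccuracy(ad, matrix(0, 0, 6), integer()), "empty")
})

test_that("the repeated-subsample protocol reports a mean over repeats", {
  tw <- tinyWorld(K = 3, dim = 16, nTrain = 4, nTest = 30, noise = 0)
  ep <- makeEpisode(tw$world$train$embeddings, tw$world$train$labels,
                    tw$bank, n = 4, seed = 1)
  fit <- trainAdapter(
    ep, adapterConfig(nrow(embeddingValues(tw$bank)), 3, hiddenDim = 16,
                      attnDim = 4, nFeatures = nFeatures(tw$bank), seed = 1),
    trainConfig(seed = 1, maxEpochs = 80))
  Wt <- computeFusionWeights(tw$bank, tw$world$test$embeddings)
  pa <- protocolAccuracy(fit$adapter, Wt, tw$world$test$labels,
                         perClass = 24, repeats = 5, seed = 2)
  expect_length(pa$accuracies, 5)
  expect_equal(pa$mean, mean(pa$accuracies))
  expect_identical(pa, protocolAccuracy(fit$adapter, Wt,
                                        tw$world$test$labels,
                                        perClass = 24, repeats = 5,
                                        seed = 2))
})
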