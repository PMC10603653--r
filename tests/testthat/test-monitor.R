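test_that("zero-shot scores are per-class mean cosines over name+description", {
  tw <- tinyWorld(K = 4, dim = 16, nTrain = 2, nTest = 3, noise = 0.3)
  v <- embeddingValues(tw$world$test$embeddings)
  for (i in c(1, 5, 9)) {
    got <- zeroShotScores(tw$bank, v[i, ])
    expect_equal(got, naiveZeroShot(tw$bank, v[i, ]), tolerance = 1e-9)
  }
  # matrix input gives stacked rows
  gotM <- zeroShotScores(tw$bank, v[1:3, ])
  expect_identical(dim(gotM), c(3L, 4L))
  expect_equal(gotM[2, ], zeroShotScores(tw$bank, v[2, ]), tolerance = 1e-12)

  expect_error(zeroShotScores(tw$bank, rep(0.25, 15)), "dim mismatch")
})

test_that("noiseless samples zero-shot to their own species; K=1 degenerates", {
  tw <- tinyWorld(K = 5, dim = 16, nTrain = 2, nTest = 4, noise = 0)
  zs <- zeroShotScores(tw$bank, tw$world$test$embeddings)
  expect_identical(max.col(zs, ties.method = "first") - 1L,
                   tw$world$test$labels)

  be <- mockEncoder(dim = 8, seed = 0)
  soloBank <- buildBank(be, assembleKnowledgeTexts(
    list(knowledgeRecord("ibis", "a wading bird"))))
  s <- zeroShotScores(soloBank, embeddingValues(
    encodeImages(be, "img:ibis:0.5:x"))[1, ])
  expect_length(s, 1)
  expect_identical(which.max(s) - 1L, 0L)
})

test_that("the trigger follows the confidence-band rule", {
  # uniform vector: statistic == mu, always inside the band
  d <- incrementalTrigger(rep(0.1, 10), gamma = 0.12)
  expect_identical(d@indicator, 1L)
  expect_equal(d@statistic, 0.1)
  expect_equal(d@mu, 0.1)

  # one-hot: far above mu + gamma
  expect_identical(incrementalTrigger(c(1, rep(0, 9)), 0.12)@indicator, 0L)

  # the default tolerance is (1 + 0.2)/K
  expect_equal(incrementalTrigger(rep(0.1, 10))@gamma, 0.12)
  expect_equal(incrementalTrigger(rep(0.25, 4))@gamma, 0.3)

  # monotone in gamma: once triggered, any larger tolerance triggers too
  withr::local_seed(6)
  for (i in 1:30) {
    K <- sample(3:12, 1)
    p <- rexp(K); p <- p / sum(p)
    gammas <- sort(runif(4, 0.01, 1))
    ind <- vapply(gammas, function(g)
      incrementalTrigger(p, g)@indicator, integer(1))
    expect_true(all(diff(ind) >= 0))
  }

  expect_error(incrementalTrigger(c(0.5, 0.4)), "sum to 1")
  expect_error(incrementalTrigger(c(0.5, 0.5), gamma = 0), "> 0")
})

test_that("prediction blends adapter and zero-shot scores and queues flags", {
  tw <- tinyWorld(K = 4, dim = 16, nTrain = 8, nTest = 4, noise = 0)
  st <- fitMonitor(tw$bank, tw$backend, tw$world$train$embeddings,
                   tw$world$train$labels, shots = 8,
                   adapterOptions = tinyAdapterOpts(1),
                   trainOptions = list(seed = 1, maxEpochs = 100), seed = 1)
  v <- embeddingValues(tw$world$test$embeddings)
  bankBefore <- embeddingValues(st@bank)
  pr <- predictSample(st, v[1, ])
  expect_identical(pr$label, tw$world$test$labels[1])
  expect_identical(pr$decision@indicator, 0L)
  expect_equal(sum(pr$probabilities), 1, tolerance = 1e-9)
  # prediction never mutates the bank
  expect_identical(embeddingValues(st@bank), bankBefore)

  # a zeroed adapter forces uniform probabilities -> indicator 1 + queue
  st0 <- st
  st0@adapter@params <- lapply(st0@adapter@params, function(p) p * 0)
  st0@calibration <- 0
  pr0 <- predictSample(st0, v[1, ], id = "flagged-one")
  expect_identical(pr0$decision@indicator, 1L)
  expect_length(pr0$state@pendingUnknowns, 1)
  expect_identical(pr0$state@pendingUnknowns[[1]]$id, "flagged-one")

  # pure zero-shot state predicts from the bank alone
  stz <- fitMonitor(tw$bank, tw$backend)
  prz <- predictSample(stz, v[1, ])
  expect_identical(prz$label, tw$world$test$labels[1])
})

test_that("registration extends the bank without touching old rows", {
  tw <- tinyWorld(K = 4, dim = 16, nTrain = 8, nTest = 4, noise = 0.05)
  st <- fitMonitor(tw$bank, tw$backend, tw$world$train$embeddings,
                   tw$world$train$labels, shots = 8,
                   adapterOptions = tinyAdapterOpts(1),
                   trainOptions = list(seed = 1, maxEpochs = 60), seed = 1)
  M0 <- nFeatures(tw$bank); K0 <- nSpecies(tw$bank)
  oldT <- embeddingValues(tw$bank)

  # j=1, no new features: the bank grows by exactly 2 rows
  rec <- knowledgeRecord("latecomer", "a newly described species")
  shots <- encodeImages(tw$backend, sprintf("img:latecomer:0.05:s%d", 1:8))
  st2 <- registerSpecies(st, list(rec), shots, rep(4L, 8))
  expect_identical(nrow(embeddingValues(st2@bank)),
                   nrow(oldT) + 2L)
  expect_identical(nSpecies(st2), K0 + 1L)
  expect_identical(nFeatures(st2@bank), M0)

  # old rows, block by block, are bit-identical (cache contract)
  newT <- embeddingValues(st2@bank)
  expect_identical(newT[seq_len(M0), ], oldT[seq_len(M0), ])
  expect_identical(newT[M0 + seq_len(K0), ], oldT[M0 + seq_len(K0), ])
  expect_identical(newT[M0 + K0 + 1L + seq_len(K0), ],
                   oldT[M0 + K0 + seq_len(K0), ])

  # default gamma follows the new K
  expect_equal(KnowShot:::stateGamma(st2), 1.2 / (K0 + 1))

  # new class is recognisable after retraining
  probe <- embeddingValues(encodeImages(tw$backend,
                                        "img:latecomer:0.05:probe"))[1, ]
  expect_identical(predictSample(st2, probe)$species, "latecomer")

  expect_error(registerSpecies(st, list(knowledgeRecord(
    "synthetic-species-01", "dup"))), "already registered")
  badShots <- embeddingMatrix(matrix(1 / sqrt(4), 2, 4), c("a", "b"))
  expect_error(registerSpecies(st, list(rec), badShots, c(4L, 4L)),
               "dim mismatch")
})

test_that("new species without shots become zero-shot classes", {
  tw <- tinyWorld(K = 4, dim = 16, nTrain = 8, nTest = 4, noise = 0)
  st <- fitMonitor(tw$bank, tw$backend, tw$world$train$embeddings,
                   tw$world$train$labels, shots = 8,
                   adapterOptions = tinyAdapterOpts(1),
                   trainOptions = list(seed = 1, maxEpochs = 60), seed = 1)
  st2 <- registerSpecies(st, list(
    knowledgeRecord("ghost", "a species known only from texts")))
  expect_identical(nSpecies(st2), 5L)
  expect_false(4L %in% st2@trainedClasses)
  probe <- embeddingValues(encodeImages(tw$backend, "img:ghost:0:z"))[1, ]
  expect_identical(predictSample(st2, probe)$species, "ghost")
})

test_that("total accuracy implements the open-set convention", {
  expect_equal(totalAccuracy(c(0, 1, 2), rep(FALSE, 3),
                             c(0, 1, 2), rep(FALSE, 3)), 1)
  # an unseen sample predicted as a *different* unseen species is correct
  expect_equal(totalAccuracy(5, TRUE, 7, TRUE), 1)
  # 4 seen (3 correct) + 2 unseen (1 predicted unseen, 1 predicted seen)
  expect_equal(totalAccuracy(
    predicted = c(0, 1, 2, 2, 8, 1),
    predictedUnseen = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    truth = c(0, 1, 2, 3, 9, 9),
    truthUnseen = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)), 4 / 6)
  # with no unseen samples TA is plain accuracy
  withr::local_seed(2)
  pred <- sample(0:3, 40, replace = TRUE)
  truth <- sample(0:3, 40, replace = TRUE)
  expect_equal(totalAccuracy(pred, rep(FALSE, 40), truth, rep(FALSE, 40)),
               mean(pred == truth))
  expect_error(totalAccuracy(1, FALSE, c(1, 2), c(FALSE, FALSE)),
               "equal length")
})
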