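smallCfg <- function(dropout = 0, ...) {
  adapterConfig(inputDim = 9, outputDim = 3, hiddenDim = 5, attnDim = 4,
                nFeatures = 3, dropout = dropout, seed = 7, ...)
}

test_that("initialisation is seeded, shaped by config, and shallow", {
  cfg <- smallCfg()
  a1 <- initAdapter(cfg)
  a2 <- initAdapter(cfg)
  expect_identical(a1@params, a2@params)

  # exactly two hidden dense layers by default
  expect_true(all(c("W1", "W2", "Wout") %in% names(a1@params)))
  expect_false("W3" %in% names(a1@params))

  # the reported best structure is the default shape
  big <- adapterConfig(40, 10, nFeatures = 20)
  expect_identical(big$hiddenDim, 256L)
  expect_identical(big$nHiddenLayers, 2L)
  expect_identical(big$nBranches, 3L)
  ab <- initAdapter(big)
  expect_identical(dim(ab@params$W1), c(256L, 40L))
  expect_identical(dim(ab@params$W2), c(256L, 256L))
  expect_length(grep("^E", names(ab@params)), 3L)

  # closed-form parameter count matches, and grows linearly
  for (cfgx in list(cfg, big, smallCfg(useAttention = FALSE),
                    smallCfg(useResidual = FALSE))) {
    expect_identical(adapterParameterCount(cfgx),
                     as.integer(sum(lengths(initAdapter(cfgx)@params))))
  }
  n1 <- adapterParameterCount(adapterConfig(20, 4, hiddenDim = 8, attnDim = 4,
                                            nFeatures = 12, useResidual = FALSE))
  n2 <- adapterParameterCount(adapterConfig(40, 4, hiddenDim = 8, attnDim = 4,
                                            nFeatures = 32, useResidual = FALSE))
  n3 <- adapterParameterCount(adapterConfig(60, 4, hiddenDim = 8, attnDim = 4,
                                            nFeatures = 52, useResidual = FALSE))
  expect_identical(n3 - n2, n2 - n1)   # linear in inputDim

  expect_error(adapterConfig(3, 5), "inputDim >= outputDim")
  expect_error(adapterConfig(9, 3, dropout = 1), "dropout")
})

test_that("forward pass is deterministic in eval mode and symmetric at zero", {
  cfg <- smallCfg()
  ad <- initAdapter(cfg)
  x <- seq(-1, 1, length.out = 9)
  expect_identical(adapterForward(ad, x), adapterForward(ad, x))
  expect_length(as.numeric(adapterForward(ad, x)), 3L)

  # all-zero parameters: equal logits, uniform probabilities
  ad0 <- ad
  ad0@params <- lapply(ad0@params, function(p) p * 0)
  logits <- as.numeric(adapterForward(ad0, x))
  expect_equal(logits, rep(logits[1], 3), tolerance = 1e-12)
  expect_equal(classProbabilities(logits), rep(1 / 3, 3), tolerance = 1e-12)

  expect_error(adapterForward(ad, rep(0, 8)), "row length")
})

test_that("dropout is active only in train mode", {
  cfg <- smallCfg(dropout = 0.5)
  ad <- initAdapter(cfg)
  X <- matrix(rnorm(5 * 9), 5, 9)
  e1 <- adapterForward(ad, X, trainMode = FALSE)
  e2 <- adapterForward(ad, X, trainMode = FALSE)
  expect_identical(e1, e2)
  withr::local_seed(1)
  t1 <- adapterForward(ad, X, trainMode = TRUE)
  t2 <- adapterForward(ad, X, trainMode = TRUE)
  expect_false(identical(t1, t2))
})

test_that("softmax is stable, monotone and matches the naive oracle", {
  expect_equal(classProbabilities(c(0, 0, 0)), rep(1 / 3, 3))
  p <- classProbabilities(c(2, 2.5))
  expect_gt(p[2], p[1])
  # invariant to large shifts (max subtraction)
  expect_equal(classProbabilities(c(1000, 1001)),
               classProbabilities(c(0, 1)), tolerance = 1e-12)
  withr::local_seed(3)
  for (i in 1:25) {
    x <- rnorm(sample(2:8, 1), sd = 3)
    got <- classProbabilities(x)
    expect_equal(got, naiveSoftmax(x), tolerance = 1e-12)
    expect_lt(abs(sum(got) - 1), 1e-9)
    expect_true(all(got > 0))
  }
  expect_error(classProbabilities(c(1, NaN)), "finite")
})

test_that("analytic gradients match finite differences in all variants", {
  withr::local_seed(42)
  X <- matrix(rnorm(4 * 9), 4, 9)
  labels <- c(0L, 1L, 2L, 1L)
  for (att in c(TRUE, FALSE)) for (res in c(TRUE, FALSE)) {
    ad <- initAdapter(smallCfg(useAttention = att, useResidual = res))
    gr <- KnowShot:::adapterGradients(ad, X, labels, trainMode = FALSE)
    num <- numericalGradients(ad, X, labels)
    for (nm in names(ad@params))
      expect_lt(max(abs(gr$grads[[nm]] - num[[nm]])), 1e-6)
  }
})

test_that("ablation flags produce the four structural variants", {
  base <- names(initAdapter(smallCfg())@params)
  noAtt <- names(initAdapter(smallCfg(useAttention = FALSE))@params)
  noRes <- names(initAdapter(smallCfg(useResidual = FALSE))@params)
  plain <- names(initAdapter(smallCfg(useAttention = FALSE,
                                      useResidual = FALSE))@params)
  attNames <- grep("^[EQag][0-9]+$", base, value = TRUE)
  expect_gt(length(attNames), 0)
  expect_identical(setdiff(base, noAtt), attNames)
  expect_identical(setdiff(base, noRes), c("R", "gateRaw"))
  expect_identical(setdiff(base, plain), c(attNames, "R", "gateRaw"))
})
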