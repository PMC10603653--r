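# Shared fixtures (built in code) and independent oracles used across
# the suite. Oracles are deliberately written as naive loops / direct
# formulas so they stay independent of the vectorised implementation.

tinyRecords <- function(K = 3L, featsPerSpecies = 2L) {
  lapply(seq_len(K), function(i) {
    feats <- sprintf("feat-%d-%d", i, seq_len(featsPerSpecies))
    knowledgeRecord(sprintf("species-%s", letters[i]),
                    sprintf("a small test animal number %d", i), feats)
  })
}

tinyWorld <- function(K = 4L, dim = 16L, nTrain = 8L, nTest = 6L,
                      noise = 0.05, unknown = 2L, seed = 1L,
                      backendSeed = 0L) {
  be <- mockEncoder(dim = dim, seed = backendSeed)
  sc <- syntheticConfig(K = K, M = 2L * K, dim = dim, nTrain = nTrain,
                        nTest = nTest, noiseSigma = noise,
                        unknownClasses = unknown, seed = seed)
  w <- generateWorld(sc, be)
  bank <- buildBank(be, assembleKnowledgeTexts(w$records))
  list(backend = be, config = sc, world = w, bank = bank)
}

tinyAdapterOpts <- function(seed = 0L)
  list(hiddenDim = 32L, attnDim = 8L, seed = seed)

# --- independent reimplementation of the mock hash pipeline ---------
# 32-bit FNV-1a over UTF-8 bytes (seed bytes first), then a
# splitmix-style finalising mix per counter, mapped through qnorm.
refMul32 <- function(a, b) {
  lo <- a %% 65536
  hi <- (a - lo) / 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 2^32
}
refXor32 <- function(a, b) {
  r <- 0; bit <- 1
  for (k in 1:32) {
    r <- r + bit * ((a %% 2 + b %% 2) %% 2)
    a <- a %/% 2; b <- b %/% 2; bit <- bit * 2
  }
  r
}
refHashVector <- function(s, dim, seed = 0L, salt = 0) {
  h <- 2166136261
  for (b in c(seed %% 256, (seed %/% 256) %% 256, (seed %/% 65536) %% 256,
              (seed %/% 16777216) %% 256, utf8ToInt(enc2utf8(s)) %% 256))
    h <- refMul32(refXor32(h, b), 16777619)
  vapply(seq_len(dim), function(j) {
    x <- (h + refMul32(j + salt, 2654435761)) %% 2^32
    x <- refMul32(refXor32(x, x %/% 65536), 2246822519)
    x <- refMul32(refXor32(x, x %/% 8192), 3266489917)
    x <- refXor32(x, x %/% 65536)
    qnorm((x + 0.5) / 2^32)
  }, numeric(1))
}

# --- naive oracles ---------------------------------------------------
naiveFusion <- function(I, Tm, temperature = 1) {
  W <- matrix(0, nrow(I), nrow(Tm))
  for (i in seq_len(nrow(I)))
    for (j in seq_len(nrow(Tm))) {
      acc <- 0
      for (d in seq_len(ncol(I))) acc <- acc + I[i, d] * Tm[j, d]
      W[i, j] <- temperature * acc
    }
  W
}

naiveSoftmax <- function(x) exp(x) / sum(exp(x))

naiveCrossEntropy <- function(P, labels) {
  tot <- 0
  for (i in seq_len(nrow(P))) tot <- tot - log(P[i, labels[i] + 1])
  tot / nrow(P)
}

naiveZeroShot <- function(bank, v) {
  Tm <- embeddingValues(bank)
  idx <- classIndex(bank)
  vapply(seq_len(nSpecies(bank)) - 1L, function(k) {
    rows <- which(!is.na(idx) & idx == k)
    mean(vapply(rows, function(r) {
      num <- sum(v * Tm[r, ])
      num / (sqrt(sum(v^2)) * sqrt(sum(Tm[r, ]^2)))
    }, numeric(1)))
  }, numeric(1))
}

nearestPrototypeAccuracy <- function(bank, emb, labels) {
  ts <- bank@textset
  protos <- embeddingValues(bank)[ts@M + seq_len(ts@K), , drop = FALSE]
  pred <- max.col(tcrossprod(embeddingValues(emb), protos),
                  ties.method = "first") - 1L
  mean(pred == labels)
}

numericalGradients <- function(adapter, X, labels, eps = 1e-6) {
  lapply(stats::setNames(nm = names(adapter@params)), function(nm) {
    p <- adapter@params[[nm]]
    num <- p * 0
    for (i in seq_along(p)) {
      for (s in c(1, -1)) {
        a2 <- adapter
        a2@params[[nm]][i] <- p[i] + s * eps
        l <- KnowShot:::adapterGradients(a2, X, labels,
                                         trainMode = FALSE)$loss
        num[i] <- num[i] + s * l / (2 * eps)
      }
    }
    num
  })
}
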