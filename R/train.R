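#' Few-shot training episode
#'
#' An n-shot, K-way episode: the fusion weights of exactly n seeded
#' training shots per class (N = n*K rows) plus their 0-based labels.
#'
#' @slot W the episode's [FusionWeights-class] (N rows).
#' @slot labels integer 0-based class labels, length N.
#' @slot n shots per class.
#' @slot K class count.
#' @slot seed sampling seed.
#' @export
setClass("Episode",
  representation(W = "FusionWeights", labels = "integer", n = "integer",
                 K = "integer", seed = "integer"))

setValidity("Episode", function(object) {
  msg <- character()
  if (nrow(object@W@W) != object@n * object@K)
    msg <- c(msg, "episode must have exactly N = n*K rows")
  if (length(object@labels) != nrow(object@W@W))
    msg <- c(msg, "one label per row required")
  if (length(object@labels) &&
      (any(object@labels < 0L) || any(object@labels >= object@K)))
    msg <- c(msg, "labels must lie in 0..K-1")
  tab <- tabulate(object@labels + 1L, nbins = object@K)
  if (any(tab != object@n))
    msg <- c(msg, "each class must contribute exactly n rows")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Episode", function(object) {
  cat("Episode:", object@n, "shot(s) x", object@K, "classes =",
      object@n * object@K, "rows, seed", object@seed, "\n")
})

#' Build a few-shot episode by seeded sampling
#'
#' Samples n shots per class uniformly without replacement from the
#' labelled embedding pool and computes their fusion weights against
#' the bank. Sampling is fully determined by \code{seed}.
#'
#' @param embeddings [EmbeddingMatrix-class] of candidate images.
#' @param labels 0-based class labels parallel to rows.
#' @param bank the [EncodedKnowledgeBank-class].
#' @param n shots per class (1, 2, 4, 8 and 16 are the conventional
#'   settings).
#' @param seed sampling seed.
#' @param temperature passed to [computeFusionWeights()].
#' @return an [Episode-class].
#' @export
makeEpisode <- function(embeddings, labels, bank, n, seed = 0L,
                        temperature = 1) {
  stopifnot(is(embeddings, "EmbeddingMatrix"))
  labels <- as.integer(labels)
  K <- nSpecies(bank)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  counts <- tabulate(labels + 1L, nbins = K)
  short <- which(counts < n) - 1L
  if (length(short))
    stop("class(es) with fewer than n = ", n, " samples: ",
         paste(speciesNames(bank)[short + 1L], collapse = ", "),
         call. = FALSE)
  picked <- withLocalSeed(seed, {
    unlist(lapply(seq_len(K) - 1L, function(k) {
      pool <- which(labels == k)
      pool[sample.int(length(pool), n)]
    }))
  })
  sub <- embeddingMatrix(embeddings@values[picked, , drop = FALSE],
                         embeddings@ids[picked],
                         normalized = embeddings@normalized)
  new("Episode", W = computeFusionWeights(bank, sub, temperature),
      labels = labels[picked], n = as.integer(n), K = K,
      seed = as.integer(seed))
}

#' Mean categorical cross-entropy
#'
#' Mean over the batch of -log p[label]. Non-negative, and zero exactly
#' when every row puts probability 1 on its label. Accepts probability
#' rows (each summing to 1) or raw logits via \code{logits = TRUE}.
#'
#' @param probabilities n x K matrix of class probabilities (or logits).
#' @param labels 0-based labels, length n.
#' @param logits if TRUE, rows are logits and are passed through
#'   softmax first.
#' @return scalar loss.
#' @examples
#' crossEntropyLoss(matrix(rep(0.1, 10), 1), 3)  # log(10)
#' @export
crossEntropyLoss <- function(probabilities, labels, logits = FALSE) {
  if (!is.matrix(probabilities)) probabilities <- matrix(probabilities, 1)
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= ncol(probabilities)))
    stop("label out of range 0..K-1", call. = FALSE)
  if (logits) probabilities <- softmaxRows(probabilities)
  else if (any(abs(rowSums(probabilities) - 1) > 1e-6))
    stop("probability rows must sum to 1", call. = FALSE)
  p <- probabilities[cbind(seq_len(nrow(probabilities)), labels + 1L)]
  -mean(log(pmax(p, 1e-300)))
}

#' Training configuration
#'
#' Optimisation settings for the adapter; the defaults are the standard
#' recipe for this head: Adam with learning rate 0.0005 and 200 epochs
#' of full-batch training (episodes have at most 16*K rows, so there is
#' no mini-batching and no early stopping).
#'
#' @param learningRate positive step size (default 0.0005).
#' @param maxEpochs positive epoch count (default 200).
#' @param beta1,beta2,epsilon Adam moment/stability constants.
#' @param seed RNG seed for dropout draws.
#' @return config list (class \code{"trainConfig"}).
#' @export
trainConfig <- function(learningRate = 5e-4, maxEpochs = 200L,
                        beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                        seed = 0L) {
  if (learningRate <= 0 || maxEpochs < 1L)
    stop("learningRate must be > 0 and maxEpochs >= 1", call. = FALSE)
  structure(list(learningRate = learningRate,
                 maxEpochs = as.integer(maxEpochs),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

#' Train the adapter on an episode
#'
#' Full-batch Adam on mean cross-entropy over the episode's fusion
#' rows. Only the adapter parameters are mutated; the bank and
#' encoders are frozen throughout. Fixed seeds give bit-identical
#' parameter trajectories and histories.
#'
#' @param episode an [Episode-class].
#' @param adapterConfig an [adapterConfig()]; its inputDim/outputDim
#'   must match the episode.
#' @param trainConfig a [trainConfig()].
#' @return list with \code{adapter} (trained [SAMLPAdapter-class]) and
#'   \code{history} (data.frame epoch / loss / accuracy; training-mode
#'   loss, training-set accuracy).
#' @export
trainAdapter <- function(episode, adapterConfig, trainConfig = NULL) {
  if (is.null(trainConfig)) trainConfig <- KnowShot::trainConfig()
  stopifnot(is(episode, "Episode"), inherits(adapterConfig, "adapterConfig"),
            inherits(trainConfig, "trainConfig"))
  X <- episode@W@W
  if (ncol(X) != adapterConfig$inputDim)
    stop(sprintf("episode row length %d != adapter inputDim %d",
                 ncol(X), adapterConfig$inputDim), call. = FALSE)
  if (episode@K != adapterConfig$outputDim)
    stop(sprintf("episode K %d != adapter outputDim %d",
                 episode@K, adapterConfig$outputDim), call. = FALSE)
  adapter <- initAdapter(adapterConfig)
  p <- adapter@params
  m <- lapply(p, function(x) x * 0)
  v <- m
  lr <- trainConfig$learningRate
  b1 <- trainConfig$beta1; b2 <- trainConfig$beta2; eps <- trainConfig$epsilon
  hist <- data.frame(epoch = seq_len(trainConfig$maxEpochs),
                     loss = NA_real_, accuracy = NA_real_)
  withLocalSeed(trainConfig$seed, {
    for (t in seq_len(trainConfig$maxEpochs)) {
      adapter@params <- p
      gr <- adapterGradients(adapter, X, episode@labels, trainMode = TRUE)
      for (nmp in names(gr$grads)) {
        g <- gr$grads[[nmp]]
        m[[nmp]] <- b1 * m[[nmp]] + (1 - b1) * g
        v[[nmp]] <- b2 * v[[nmp]] + (1 - b2) * g^2
        mhat <- m[[nmp]] / (1 - b1^t)
        vhat <- v[[nmp]] / (1 - b2^t)
        p[[nmp]] <- p[[nmp]] - lr * mhat / (sqrt(vhat) + eps)
      }
      pred <- max.col(gr$probs, ties.method = "first") - 1L
      hist$loss[t] <- gr$loss
      hist$accuracy[t] <- mean(pred == episode@labels)
    }
  })
  adapter@params <- p
  list(adapter = adapter, history = hist)
}

#' Classification accuracy of a trained adapter
#'
#' Fraction of fusion rows whose argmax logit (lowest class index wins
#' ties) equals the 0-based label.
#'
#' @param adapter a [SAMLPAdapter-class].
#' @param W a [FusionWeights-class] or numeric matrix of fusion rows.
#' @param labels 0-based labels.
#' @return accuracy in [0, 1].
#' @export
evaluateAccuracy <- function(adapter, W, labels) {
  if (is(W, "FusionWeights")) W <- W@W
  if (!is.matrix(W)) W <- matrix(W, nrow = 1)
  if (!nrow(W)) stop("empty test set", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != nrow(W))
    stop("one label per row required", call. = FALSE)
  logits <- adapterForward(adapter, W, trainMode = FALSE)
  pred <- max.col(logits, ties.method = "first") - 1L
  mean(pred == labels)
}

#' Repeated-subsample evaluation protocol
#'
#' Mirrors the standard reporting protocol for this method family: the
#' same number of test samples (default 24) is drawn at random from
#' each species, accuracy is measured, and the procedure is repeated
#' (default 5 times); the mean accuracy is reported.
#'
#' @param adapter trained [SAMLPAdapter-class].
#' @param W [FusionWeights-class] or matrix of all test fusion rows.
#' @param labels 0-based labels.
#' @param perClass test samples drawn per species per repeat.
#' @param repeats number of repeats.
#' @param seed sampling seed.
#' @return list with \code{mean} accuracy and per-repeat \code{accuracies}.
#' @export
protocolAccuracy <- function(adapter, W, labels, perClass = 24L,
                             repeats = 5L, seed = 0L) {
  if (is(W, "FusionWeights")) W <- W@W
  labels <- as.integer(labels)
  K <- max(labels) + 1L
  acc <- withLocalSeed(seed, {
    vapply(seq_len(repeats), function(r) {
      idx <- unlist(lapply(seq_len(K) - 1L, function(k) {
        pool <- which(labels == k)
        pool[sample.int(length(pool), min(perClass, length(pool)))]
      }))
      evaluateAccuracy(adapter, W[idx, , drop = FALSE], labels[idx])
    }, numeric(1))
  })
  list(mean = mean(acc), accuracies = acc)
}
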