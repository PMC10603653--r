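# Field-deployment loop: zero-/few-shot prediction, the softmax-
# confidence incremental trigger, species registration with retraining,
# and the open-set total-accuracy metric.

#' Zero-shot class scores from the knowledge bank
#'
#' For each species, the mean cosine similarity between the image
#' embedding and that species' name and description rows of the bank.
#' Feature rows are excluded: features are class-shared and carry no
#' class index. The argmax (lowest index wins ties) is the zero-shot
#' label.
#'
#' @param bank an [EncodedKnowledgeBank-class].
#' @param imageEmbedding numeric vector of length dim, an
#'   [EmbeddingMatrix-class], or an n x dim matrix.
#' @return numeric vector of K scores (or n x K matrix for matrix input).
#' @export
zeroShotScores <- function(bank, imageEmbedding) {
  if (is(imageEmbedding, "EmbeddingMatrix"))
    imageEmbedding <- imageEmbedding@values
  single <- !is.matrix(imageEmbedding)
  if (single) imageEmbedding <- matrix(imageEmbedding, nrow = 1)
  if (ncol(imageEmbedding) != embeddingDim(bank))
    stop(sprintf("embedding dim mismatch: image %d, bank %d",
                 ncol(imageEmbedding), embeddingDim(bank)), call. = FALSE)
  K <- nSpecies(bank)
  Tm <- embeddingValues(bank)
  idx <- classIndex(bank)
  sims <- tcrossprod(imageEmbedding, Tm)
  scores <- vapply(seq_len(K) - 1L, function(k)
    rowMeans(sims[, which(idx == k), drop = FALSE]), numeric(nrow(sims)))
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = nrow(sims))
  if (single) drop(scores) else scores
}

#' Incremental-learning trigger
#'
#' Flags a prediction whose top-1 softmax confidence lies within the
#' tolerance band around the uniform-prediction level mu = 1/K:
#' indicator = 1 iff statistic is in [max(0, mu - gamma), mu + gamma].
#' The default tolerance is (1 + 0.2)/K; a fixed scalar (e.g. 0.2) is
#' also accepted.
#'
#' @param probabilities probability vector of length K (sum 1 within
#'   1e-6).
#' @param gamma tolerance > 0; NULL selects the (1+0.2)/K default.
#' @return an [IncrementalDecision-class].
#' @examples
#' incrementalTrigger(rep(0.1, 10))           # indicator 1 (E = mu)
#' incrementalTrigger(c(1, rep(0, 9)))        # indicator 0
#' @export
incrementalTrigger <- function(probabilities, gamma = NULL) {
  K <- length(probabilities)
  if (any(!is.finite(probabilities)) || abs(sum(probabilities) - 1) > 1e-6)
    stop("probabilities must be finite and sum to 1 within 1e-6",
         call. = FALSE)
  if (is.null(gamma)) gamma <- (1 + 0.2) / K
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  statistic <- max(probabilities)
  mu <- 1 / K
  inside <- statistic >= max(0, mu - gamma) && statistic <= mu + gamma
  new("IncrementalDecision", indicator = if (inside) 1L else 0L,
      statistic = statistic, mu = mu, gamma = gamma)
}

setMethod("show", "IncrementalDecision", function(object) {
  cat("IncrementalDecision: I =", object@indicator,
      sprintf("(top-1 %.4f vs mu %.4f +/- %.4f)\n",
              object@statistic, object@mu, object@gamma))
})

stateGamma <- function(state) {
  if (is.na(state@gamma)) (1 + 0.2) / nSpecies(state@bank) else state@gamma
}

buildSubsetEpisode <- function(bank, embeddings, labels, trainedClasses,
                               shots, seed, temperature) {
  remap <- match(labels, trainedClasses) - 1L
  picked <- withLocalSeed(seed, {
    unlist(lapply(seq_along(trainedClasses), function(j) {
      pool <- which(remap == j - 1L)
      if (length(pool) < shots)
        stop("class ", speciesNames(bank)[trainedClasses[j] + 1L],
             " has fewer than ", shots, " samples", call. = FALSE)
      pool[sample.int(length(pool), shots)]
    }))
  })
  sub <- embeddingMatrix(embeddings@values[picked, , drop = FALSE],
                         embeddings@ids[picked],
                         normalized = embeddings@normalized)
  new("Episode", W = computeFusionWeights(bank, sub, temperature),
      labels = remap[picked], n = as.integer(shots),
      K = length(trainedClasses), seed = as.integer(seed))
}

#' Assemble (and optionally train) a monitor state
#'
#' Builds the deployable state around a frozen bank. With labelled
#' training embeddings, an adapter is trained from scratch on an n-shot
#' episode over the classes present in \code{labels}; classes absent
#' from \code{labels} are handled zero-shot at prediction time. With no
#' training data the state is pure zero-shot.
#'
#' The blending calibration (one scalar mapping zero-shot cosine scores
#' into the adapter logit range, the ratio of their standard deviations
#' on the training episode) is fitted here.
#'
#' @param bank an [EncodedKnowledgeBank-class].
#' @param backend the frozen [EncoderBackend-class] that built the bank.
#' @param embeddings optional [EmbeddingMatrix-class] training pool.
#' @param labels 0-based bank class labels parallel to rows.
#' @param shots shots per class drawn from the pool.
#' @param gamma trigger tolerance; NA (default) means (1+0.2)/K,
#'   recomputed whenever K changes.
#' @param zsScale logit scale for cosine scores in a pure zero-shot
#'   state (default 20).
#' @param adapterOptions named list of [adapterConfig()] overrides.
#' @param trainOptions named list of [trainConfig()] overrides; may also
#'   carry \code{temperature} for the fusion step.
#' @param seed episode-sampling seed (training uses the seeds in the
#'   option lists).
#' @return a [MonitorState-class].
#' @export
fitMonitor <- function(bank, backend, embeddings = NULL, labels = NULL,
                       shots = NULL, gamma = NA_real_, zsScale = 20,
                       adapterOptions = list(), trainOptions = list(),
                       seed = 0L) {
  stopifnot(is(bank, "EncodedKnowledgeBank"), is(backend, "EncoderBackend"))
  temperature <- if (!is.null(trainOptions$temperature))
    trainOptions$temperature else 1
  state <- new("MonitorState", bank = bank, backend = backend,
               adapter = NULL, trainedClasses = integer(),
               gamma = as.numeric(gamma), zsScale = zsScale,
               calibration = NULL, trainEmbeddings = NULL,
               trainLabels = integer(),
               adapterOptions = adapterOptions,
               trainOptions = trainOptions, pendingUnknowns = list())
  if (is.null(embeddings)) return(state)
  labels <- as.integer(labels)
  trained <- sort(unique(labels))
  if (length(trained) < 2L)
    stop("need at least two trained classes to fit an adapter", call. = FALSE)
  if (is.null(shots)) stop("shots must be given with training data",
                           call. = FALSE)
  episode <- buildSubsetEpisode(bank, embeddings, labels, trained,
                                shots, seed, temperature)
  ts <- bank@textset
  aopts <- adapterOptions
  aopts$inputDim <- 2L * ts@K + ts@M
  aopts$outputDim <- length(trained)
  aopts$nFeatures <- ts@M
  aopts$nClasses <- ts@K
  acfg <- do.call(adapterConfig, aopts)
  topts <- trainOptions; topts$temperature <- NULL
  tcfg <- do.call(trainConfig, topts)
  fit <- trainAdapter(episode, acfg, tcfg)
  state@adapter <- fit$adapter
  state@trainedClasses <- trained
  state@trainEmbeddings <- embeddings
  state@trainLabels <- labels
  state@trainOptions <- trainOptions
  state@trainOptions$shots <- shots
  state@trainOptions$episodeSeed <- seed
  state@calibration <- fitCalibration(state, episode)
  validObject(state)
  state
}

# scalar mapping cosine scores into the adapter logit range, fitted on
# the training episode (sd ratio; falls back to zsScale for degenerate
# score spreads)
fitCalibration <- function(state, episode) {
  emb <- state@trainEmbeddings
  logits <- adapterForward(state@adapter, episode@W)
  zs <- zeroShotScores(state@bank, emb)
  sZs <- stats::sd(as.numeric(zs))
  if (!is.finite(sZs) || sZs < 1e-12) return(state@zsScale)
  stats::sd(as.numeric(logits)) / sZs
}

setMethod("nSpecies", "MonitorState", function(x) nSpecies(x@bank))
setMethod("speciesNames", "MonitorState", function(x) speciesNames(x@bank))

setMethod("show", "MonitorState", function(object) {
  K <- nSpecies(object)
  cat("MonitorState:", K, "species (", length(object@trainedClasses),
      "trained,", K - length(object@trainedClasses), "zero-shot ), gamma =",
      signif(stateGamma(object), 4), ",",
      length(object@pendingUnknowns), "pending unknown(s)\n")
})

blendedLogits <- function(state, imageEmbedding) {
  K <- nSpecies(state@bank)
  zs <- zeroShotScores(state@bank, imageEmbedding)
  if (is.null(state@adapter)) {
    if (K == 0L) stop("state has no classes and no adapter", call. = FALSE)
    return(state@zsScale * zs)
  }
  temperature <- if (!is.null(state@trainOptions$temperature))
    state@trainOptions$temperature else 1
  w <- temperature * as.numeric(
    embeddingValues(state@bank) %*% imageEmbedding)
  adLogits <- as.numeric(adapterForward(state@adapter, matrix(w, 1)))
  cal <- if (!is.null(state@calibration)) state@calibration else state@zsScale
  logits <- cal * zs
  logits[state@trainedClasses + 1L] <- adLogits
  logits
}

#' Predict one sample and apply the incremental trigger
#'
#' Scores the image embedding against every species — trained classes
#' through the adapter, zero-shot classes through calibrated cosine
#' scores — takes a softmax over the blended logits, and applies the
#' confidence trigger. Samples with indicator 1 are appended to the
#' state's pending-unknowns queue. The bank, backend and adapter are
#' never mutated.
#'
#' @param state a [MonitorState-class].
#' @param imageEmbedding numeric vector of length dim (unit-norm).
#' @param id optional sample identifier recorded with flagged samples.
#' @return list with \code{label} (0-based), \code{species},
#'   \code{probabilities}, \code{decision}
#'   ([IncrementalDecision-class]) and \code{state} (updated queue).
#' @export
predictSample <- function(state, imageEmbedding, id = NULL) {
  stopifnot(is(state, "MonitorState"))
  logits <- blendedLogits(state, imageEmbedding)
  probs <- classProbabilities(logits)
  decision <- incrementalTrigger(probs, gamma = stateGamma(state))
  label <- which.max(probs) - 1L
  if (decision@indicator == 1L)
    state@pendingUnknowns <- c(state@pendingUnknowns,
      list(list(id = id, embedding = imageEmbedding,
                probabilities = probs)))
  list(label = label, species = speciesNames(state)[label + 1L],
       probabilities = probs, decision = decision, state = state)
}

#' Register new species into a monitor state
#'
#' Extends the knowledge bank by encoding only the new texts (existing
#' bank rows are reused bit-identically), grows K by the number of new
#' records, recomputes the default trigger tolerance, and — when
#' few-shot embeddings are supplied — retrains the adapter from
#' scratch on the combined episode of old and new shots. New species
#' without embeddings become zero-shot classes.
#'
#' @param state a [MonitorState-class].
#' @param newRecords list of [KnowledgeRecord-class] with names not yet
#'   in the bank.
#' @param fewShotEmbeddings optional [EmbeddingMatrix-class] of shots
#'   for (some of) the new species.
#' @param fewShotLabels 0-based labels into the new classes (old K for
#'   the first new record, and so on), parallel to the rows.
#' @return a new [MonitorState-class]; the input state is unchanged.
#' @export
registerSpecies <- function(state, newRecords, fewShotEmbeddings = NULL,
                            fewShotLabels = NULL) {
  stopifnot(is(state, "MonitorState"))
  checkRecordList(newRecords)
  oldTs <- state@bank@textset
  newNames <- vapply(newRecords, function(r) r@speciesName, character(1))
  clash <- intersect(newNames, oldTs@speciesNames)
  if (length(clash))
    stop("species already registered: ", paste(clash, collapse = ", "),
         call. = FALSE)
  K0 <- oldTs@K; M0 <- oldTs@M
  oldFeat <- oldTs@texts[seq_len(M0)]
  allNewFeat <- unique(unlist(lapply(newRecords, function(r) r@features),
                              use.names = FALSE))
  addFeat <- setdiff(if (is.null(allNewFeat)) character() else allNewFeat,
                     oldFeat)
  j <- length(newRecords)
  newTs <- new("KnowledgeTextSet",
    texts = c(oldFeat, addFeat,
              oldTs@texts[M0 + seq_len(K0)],
              sprintf(oldTs@nameTemplate, newNames),
              oldTs@texts[M0 + K0 + seq_len(K0)],
              vapply(newRecords, function(r) r@description, character(1))),
    roles = c(rep("feature", M0 + length(addFeat)),
              rep("name", K0 + j), rep("description", K0 + j)),
    classIdx = c(rep(NA_integer_, M0 + length(addFeat)),
                 seq_len(K0 + j) - 1L, seq_len(K0 + j) - 1L),
    K = K0 + j, M = M0 + length(addFeat),
    speciesNames = c(oldTs@speciesNames, newNames),
    nameTemplate = oldTs@nameTemplate)
  oldT <- embeddingValues(state@bank)
  newTexts <- c(addFeat, sprintf(oldTs@nameTemplate, newNames),
                vapply(newRecords, function(r) r@description, character(1)))
  newRows <- embeddingValues(encodeText(state@backend, newTexts))
  if (ncol(newRows) != ncol(oldT))
    stop("backend dim changed between build and registration", call. = FALSE)
  pick <- function(texts) newRows[match(texts, newTexts), , drop = FALSE]
  Tnew <- rbind(oldT[seq_len(M0), , drop = FALSE],
                pick(addFeat),
                oldT[M0 + seq_len(K0), , drop = FALSE],
                pick(sprintf(oldTs@nameTemplate, newNames)),
                oldT[M0 + K0 + seq_len(K0), , drop = FALSE],
                pick(vapply(newRecords, function(r) r@description,
                            character(1))))
  newBank <- new("EncodedKnowledgeBank",
    embeddings = embeddingMatrix(Tnew, ids = newTs@texts,
                                 normalized = state@bank@embeddings@normalized),
    textset = newTs, backendName = state@bank@backendName)
  # pool old and new shots, then retrain from scratch
  emb <- state@trainEmbeddings
  labels <- state@trainLabels
  if (!is.null(fewShotEmbeddings)) {
    stopifnot(is(fewShotEmbeddings, "EmbeddingMatrix"))
    if (embeddingDim(fewShotEmbeddings) != embeddingDim(newBank))
      stop(sprintf("embedding dim mismatch: shots %d, bank %d",
                   embeddingDim(fewShotEmbeddings), embeddingDim(newBank)),
           call. = FALSE)
    fewShotLabels <- as.integer(fewShotLabels)
    if (any(fewShotLabels < K0) || any(fewShotLabels >= K0 + j))
      stop("fewShotLabels must index the new classes ", K0, "..", K0 + j - 1L,
           call. = FALSE)
    if (is.null(emb)) {
      emb <- fewShotEmbeddings
      labels <- fewShotLabels
    } else {
      emb <- embeddingMatrix(rbind(emb@values, fewShotEmbeddings@values),
                             c(emb@ids, fewShotEmbeddings@ids),
                             normalized = emb@normalized &&
                               fewShotEmbeddings@normalized)
      labels <- c(labels, fewShotLabels)
    }
  }
  if (is.null(emb))
    return(fitMonitor(newBank, state@backend, gamma = state@gamma,
                      zsScale = state@zsScale,
                      adapterOptions = state@adapterOptions,
                      trainOptions = state@trainOptions))
  topts <- state@trainOptions
  shots <- topts$shots
  seed <- if (!is.null(topts$episodeSeed)) topts$episodeSeed else 0L
  topts$shots <- NULL; topts$episodeSeed <- NULL
  fitMonitor(newBank, state@backend, embeddings = emb, labels = labels,
             shots = shots, gamma = state@gamma, zsScale = state@zsScale,
             adapterOptions = state@adapterOptions, trainOptions = topts,
             seed = seed)
}

#' Open-set total accuracy (TA)
#'
#' A sample counts as correct if it is a seen-species sample predicted
#' with its true label, or an unseen-species sample predicted as any
#' unseen species. With no unseen samples TA equals plain accuracy.
#'
#' @param predicted 0-based predicted labels.
#' @param predictedUnseen logical: is each predicted label an unseen
#'   class?
#' @param truth 0-based true labels.
#' @param truthUnseen logical: is each sample truly of an unseen class?
#' @return TA in [0, 1].
#' @export
totalAccuracy <- function(predicted, predictedUnseen, truth, truthUnseen) {
  n <- length(predicted)
  if (length(predictedUnseen) != n || length(truth) != n ||
      length(truthUnseen) != n)
    stop("all four vectors must have equal length", call. = FALSE)
  if (!n) stop("empty prediction set", call. = FALSE)
  correct <- ifelse(truthUnseen, predictedUnseen, predicted == truth)
  mean(correct)
}
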