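# Synthetic embedding worlds: class-structured unit-norm embeddings in
# which image embeddings cluster around the embedding of their species'
# name prompt, with controllable Gaussian noise. Stands in for real
# camera-trap imagery so every stage (zero-shot, few-shot, incremental)
# is exercisable offline.

#' Synthetic-world configuration
#'
#' @param K species count (>= 2; default 10, a realistic species count
#'   for a single protected-area camera-trap deployment).
#' @param M total distinct feature strings shared out round-robin
#'   across species (default 2 per species).
#' @param dim embedding dimensionality (default 64).
#' @param nTrain training images per class (default 16, the largest
#'   conventional shot count).
#' @param nTest test images per class (default 24, the evaluation
#'   protocol's per-species draw).
#' @param noiseSigma Gaussian perturbation scale on the unit sphere
#'   (default 0.05; 0 collapses every image onto its class prototype).
#' @param unknownClasses count of out-of-bank species (default 2).
#' @param seed world seed.
#' @return validated config list (class \code{"syntheticConfig"}).
#' @export
syntheticConfig <- function(K = 10L, M = 2L * K, dim = 64L, nTrain = 16L,
                            nTest = 24L, noiseSigma = 0.05,
                            unknownClasses = 2L, seed = 0L) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  if (nTest < 1L) stop("nTest must be >= 1", call. = FALSE)
  if (noiseSigma < 0) stop("noiseSigma must be >= 0", call. = FALSE)
  structure(list(K = K, M = as.integer(M), dim = as.integer(dim),
                 nTrain = as.integer(nTrain), nTest = as.integer(nTest),
                 noiseSigma = noiseSigma,
                 unknownClasses = as.integer(unknownClasses),
                 seed = as.integer(seed)),
            class = "syntheticConfig")
}

synthSpeciesName <- function(i) sprintf("synthetic-species-%02d", i)
synthUnknownName <- function(i) sprintf("synthetic-unknown-%02d", i)

synthRecords <- function(config) {
  feats <- sprintf("synthetic-feature-%02d", seq_len(config$M))
  lapply(seq_len(config$K), function(i) {
    mine <- feats[which((seq_len(config$M) - 1L) %% config$K == i - 1L)]
    knowledgeRecord(
      synthSpeciesName(i),
      paste("a synthetic study species labelled", synthSpeciesName(i),
            if (length(mine)) paste("with", paste(mine, collapse = " and "))
            else ""),
      mine)
  })
}

synthTokens <- function(names, perClass, sigma, tag, seed) {
  unlist(lapply(seq_along(names), function(i)
    sprintf("img:%s:%g:%d-%s-%d", names[i], sigma, seed, tag,
            seq_len(perClass))))
}

#' Generate a synthetic test world
#'
#' Produces specialist-knowledge records for K template species, plus
#' balanced train/test image embeddings and embeddings for species
#' absent from the records. Every image embedding is the (renormalised)
#' species name-prompt vector plus \code{noiseSigma} times a seeded
#' Gaussian; with \code{noiseSigma = 0} images coincide exactly with
#' their class prototype, so nearest-prototype accuracy is 1. The world
#' is a pure function of the config and backend seeds.
#'
#' @param config a [syntheticConfig()].
#' @param backend a [MockEncoder-class] with matching dim.
#' @return list with \code{records}, \code{train}, \code{test} and
#'   \code{unknown}; the latter three hold \code{tokens},
#'   \code{labels} (0-based; unknown carries species names instead) and
#'   \code{embeddings} (an [EmbeddingMatrix-class]).
#' @export
generateWorld <- function(config, backend) {
  stopifnot(inherits(config, "syntheticConfig"), is(backend, "MockEncoder"))
  if (embeddingDim(backend) != config$dim)
    stop("backend dim does not match config dim", call. = FALSE)
  nm <- vapply(seq_len(config$K), synthSpeciesName, character(1))
  records <- synthRecords(config)
  makeSplit <- function(names, perClass, tag) {
    tokens <- synthTokens(names, perClass, config$noiseSigma, tag,
                          config$seed)
    list(tokens = tokens,
         labels = rep(seq_along(names) - 1L, each = perClass),
         embeddings = encodeImages(backend, tokens))
  }
  unknownNames <- vapply(seq_len(config$unknownClasses), synthUnknownName,
                         character(1))
  world <- list(records = records,
                train = makeSplit(nm, config$nTrain, "train"),
                test = makeSplit(nm, config$nTest, "test"),
                config = config)
  if (config$unknownClasses > 0L) {
    world$unknown <- makeSplit(unknownNames, config$nTest, "unknown")
    world$unknown$speciesNames <- unknownNames
  }
  world
}

#' Sweep worlds over open-set incremental rates
#'
#' For each rate, withholds that fraction of species from training so
#' they appear only in the test data (zero-shot classes). Withheld
#' sets are consecutive chunks of one seeded class permutation, so a
#' sweep whose rates sum to at most 1 partitions the chosen classes:
#' each withheld species appears in exactly one entry.
#'
#' @param config a [syntheticConfig()].
#' @param rates fractions in (0, 1); each must satisfy rate*K >= 1.
#' @param backend a [MockEncoder-class].
#' @return list of entries, each with \code{rate}, \code{withheld}
#'   (0-based class indices), \code{train} (withheld rows removed) and
#'   the shared \code{world}.
#' @export
sweepIncrementalRates <- function(config, rates, backend) {
  stopifnot(inherits(config, "syntheticConfig"))
  if (any(rates <= 0) || any(rates >= 1))
    stop("rates must lie in (0, 1)", call. = FALSE)
  nW <- floor(rates * config$K + 1e-9)
  if (any(nW < 1))
    stop("rate(s) too small to withhold one class: ",
         paste(rates[nW < 1], collapse = ", "), call. = FALSE)
  world <- generateWorld(config, backend)
  perm <- withLocalSeed(config$seed + 101L, sample.int(config$K)) - 1L
  start <- 0L
  lapply(seq_along(rates), function(r) {
    idx <- ((start + seq_len(nW[r]) - 1L) %% config$K) + 1L
    start <<- start + nW[r]
    withheld <- sort(perm[idx])
    keep <- !(world$train$labels %in% withheld)
    entry <- list(rate = rates[r], withheld = withheld,
                  train = list(
                    tokens = world$train$tokens[keep],
                    labels = world$train$labels[keep],
                    embeddings = embeddingMatrix(
                      world$train$embeddings@values[keep, , drop = FALSE],
                      world$train$embeddings@ids[keep],
                      normalized = TRUE)),
                  world = world)
    entry
  })
}
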