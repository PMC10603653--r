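#' Build the encoded knowledge bank
#'
#' Encodes the ordered knowledge text set once with the frozen text
#' encoder, giving the (2K+M) x dim matrix T. The bank is immutable:
#' rebuilding from identical inputs returns a bit-identical T, and
#' downstream operations never touch it.
#'
#' @param backend an [EncoderBackend-class].
#' @param textset a [KnowledgeTextSet-class].
#' @return an [EncodedKnowledgeBank-class].
#' @export
buildBank <- function(backend, textset) {
  stopifnot(is(backend, "EncoderBackend"), is(textset, "KnowledgeTextSet"))
  new("EncodedKnowledgeBank",
      embeddings = encodeText(backend, textset),
      textset = textset, backendName = backend@name)
}

setMethod("textRoles", "EncodedKnowledgeBank", function(x) x@textset@roles)
setMethod("classIndex", "EncodedKnowledgeBank", function(x) x@textset@classIdx)
setMethod("nSpecies", "EncodedKnowledgeBank", function(x) x@textset@K)
setMethod("nFeatures", "EncodedKnowledgeBank", function(x) x@textset@M)
setMethod("speciesNames", "EncodedKnowledgeBank", function(x) x@textset@speciesNames)
setMethod("embeddingValues", "EncodedKnowledgeBank", function(x) x@embeddings@values)
setMethod("rowIds", "EncodedKnowledgeBank", function(x) x@embeddings@ids)
setMethod("embeddingDim", "EncodedKnowledgeBank", function(x) ncol(x@embeddings@values))

setMethod("show", "EncodedKnowledgeBank", function(object) {
  ts <- object@textset
  cat("EncodedKnowledgeBank: T is", 2L * ts@K + ts@M, "x",
      embeddingDim(object), "(K =", ts@K, ", M =", ts@M,
      "), backend:", object@backendName, "\n")
})

#' Compute fusion knowledge weights
#'
#' W = temperature * I T', the scaled similarity between every image
#' embedding and every knowledge-bank row. With unit-norm inputs and
#' temperature 1 these are cosine similarities; W rows are what the
#' classifier head consumes. Neither bank nor images are mutated.
#'
#' @param bank an [EncodedKnowledgeBank-class].
#' @param images an [EmbeddingMatrix-class], N x dim, same dim as bank.
#' @param temperature positive multiplicative scale (default 1; a
#'   CLIP-style real backend conventionally uses 100).
#' @return a [FusionWeights-class], W of shape N x (2K+M).
#' @export
computeFusionWeights <- function(bank, images, temperature = 1) {
  stopifnot(is(bank, "EncodedKnowledgeBank"), is(images, "EmbeddingMatrix"))
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  dB <- embeddingDim(bank); dI <- embeddingDim(images)
  if (dB != dI)
    stop(sprintf("embedding dim mismatch: bank dim %d, images dim %d", dB, dI),
         call. = FALSE)
  W <- temperature * tcrossprod(images@values, bank@embeddings@values)
  new("FusionWeights", W = W, temperature = temperature,
      provenance = c(bank = bank@backendName,
                     images = paste0(length(images@ids), " rows")))
}

setMethod("weightMatrix", "FusionWeights", function(x) x@W)

setMethod("show", "FusionWeights", function(object) {
  cat("FusionWeights: W is", nrow(object@W), "x", ncol(object@W),
      ", temperature =", object@temperature, "\n")
})
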