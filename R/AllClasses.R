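setClassUnion("OptionalNumeric", c("numeric", "NULL"))

#' Specialist-knowledge record for one species
#'
#' Holds the three fields of a specialist-knowledge entry: the species
#' name, a short free-text description (at most 100 words) and a list of
#' short attribute strings such as \code{"fur:striped"}.
#'
#' @slot speciesName single non-empty character label, unique within a bank.
#' @slot description free text, word count <= 100.
#' @slot features character vector of non-empty attribute strings
#'   (possibly empty).
#' @seealso [knowledgeRecord()], [loadKnowledgeRecords()]
#' @export
setClass("KnowledgeRecord",
  representation(speciesName = "character",
                 description = "character",
                 features    = "character"))

setValidity("KnowledgeRecord", function(object) {
  msg <- character()
  if (length(object@speciesName) != 1L || !nzchar(object@speciesName))
    msg <- c(msg, "speciesName must be a single non-empty string")
  if (length(object@description) != 1L)
    msg <- c(msg, "description must be a single string")
  else if (countWords(object@description) > 100L)
    msg <- c(msg, sprintf("description of '%s' exceeds 100 words (%d)",
                          object@speciesName, countWords(object@description)))
  if (length(object@features) && any(!nzchar(object@features)))
    msg <- c(msg, sprintf("record '%s' has empty feature strings",
                          object@speciesName))
  if (length(msg)) msg else TRUE
})

#' Ordered specialist-knowledge text set
#'
#' The ordered concatenation of all M distinct feature strings, the K
#' species-name prompts and the K species descriptions, in that order,
#' so that \code{length(texts) == 2K + M}. This ordered set is what the
#' frozen text encoder consumes to build the knowledge bank.
#'
#' @slot texts character vector of length 2K+M.
#' @slot roles parallel character vector over
#'   \code{c("feature","name","description")}; roles partition into
#'   exactly M, K and K entries in that block order.
#' @slot classIdx integer vector, 0-based species index for name and
#'   description entries, \code{NA} for features (class-shared).
#' @slot K integer species count.
#' @slot M integer distinct-feature count.
#' @slot speciesNames character vector of the K raw species names in
#'   class-index order.
#' @slot nameTemplate the sprintf template applied to species names
#'   (names only; descriptions and features are kept raw).
#' @seealso [assembleKnowledgeTexts()]
#' @export
setClass("KnowledgeTextSet",
  representation(texts = "character", roles = "character",
                 classIdx = "integer", K = "integer", M = "integer",
                 speciesNames = "character", nameTemplate = "character"))

setValidity("KnowledgeTextSet", function(object) {
  K <- object@K; M <- object@M
  msg <- character()
  if (length(object@texts) != 2L * K + M)
    msg <- c(msg, sprintf("length(texts) is %d, expected 2K+M = %d",
                          length(object@texts), 2L * K + M))
  expectedRoles <- c(rep("feature", M), rep("name", K), rep("description", K))
  if (!identical(object@roles, expectedRoles))
    msg <- c(msg, "roles must be M features, then K names, then K descriptions")
  expectedIdx <- c(rep(NA_integer_, M), seq_len(K) - 1L, seq_len(K) - 1L)
  if (!identical(object@classIdx, expectedIdx))
    msg <- c(msg, "classIdx inconsistent with block ordering")
  if (length(object@speciesNames) != K)
    msg <- c(msg, "speciesNames must have length K")
  if (anyDuplicated(object@speciesNames))
    msg <- c(msg, "species names must be unique")
  if (length(msg)) msg else TRUE
})

#' Frozen dual-encoder backend (virtual)
#'
#' Contract for a frozen text/image dual encoder: both encoders emit
#' unit-norm vectors of exactly \code{dim} dimensions, encoding the same
#' input twice yields bit-identical output, and no downstream operation
#' mutates the backend.
#'
#' @slot name backend identifier.
#' @slot dim embedding dimensionality.
#' @slot deterministic logical flag; TRUE for the mock backend.
#' @seealso [mockEncoder()]
#' @export
setClass("EncoderBackend",
  representation("VIRTUAL", name = "character", dim = "integer",
                 deterministic = "logical"))

#' Deterministic mock dual encoder
#'
#' A hash-based test double for a frozen vision-language encoder. Each
#' input string is hashed (FNV-1a, mixed with the backend seed) to a
#' reproducible unit vector; a synthetic image token
#' \code{img:<species>:<sigma>[:<id>]} maps to the species-name prompt
#' vector perturbed by seeded Gaussian noise of scale \code{sigma} and
#' renormalised. Identical inputs give bit-identical vectors across
#' processes; the R global RNG is never touched.
#'
#' @slot seed integer mixed into every hash.
#' @slot nameTemplate sprintf template used to realise image tokens as
#'   name prompts; must match the template used at knowledge assembly.
#' @export
setClass("MockEncoder", contains = "EncoderBackend",
  representation(seed = "integer", nameTemplate = "character"))

setValidity("MockEncoder", function(object) {
  if (object@dim < 2L) "dim must be >= 2" else TRUE
})

#' Matrix of encoder embeddings
#'
#' Rows are items (texts or images) in input order; when
#' \code{normalized} is TRUE every row has unit Euclidean norm within
#' 1e-6 (enforced by validity).
#'
#' @slot values numeric matrix, items x dim.
#' @slot ids character provenance labels, one per row.
#' @slot normalized logical flag.
#' @export
setClass("EmbeddingMatrix",
  representation(values = "matrix", ids = "character", normalized = "logical"))

setValidity("EmbeddingMatrix", function(object) {
  msg <- character()
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be numeric")
  if (length(object@ids) != nrow(object@values))
    msg <- c(msg, "one id per row required")
  if (isTRUE(object@normalized) && nrow(object@values)) {
    norms <- sqrt(rowSums(object@values^2))
    if (any(abs(norms - 1) > 1e-6))
      msg <- c(msg, "normalized=TRUE but some row norms deviate from 1 by >1e-6")
  }
  if (length(msg)) msg else TRUE
})

#' Encoded knowledge bank
#'
#' The frozen text-encoder embeddings T of an ordered knowledge text
#' set, with the role/class metadata carried along. The bank is
#' precomputed once and treated as immutable: incremental registration
#' encodes only new texts and reuses old rows bit-identically.
#'
#' @slot embeddings an [EmbeddingMatrix-class] of shape (2K+M) x dim.
#' @slot textset the [KnowledgeTextSet-class] the bank encodes.
#' @slot backendName provenance: which encoder produced T.
#' @seealso [buildBank()], [computeFusionWeights()]
#' @export
setClass("EncodedKnowledgeBank",
  representation(embeddings = "EmbeddingMatrix", textset = "KnowledgeTextSet",
                 backendName = "character"))

setValidity("EncodedKnowledgeBank", function(object) {
  ts <- object@textset
  if (nrow(object@embeddings@values) != 2L * ts@K + ts@M)
    "bank row count must equal 2K+M" else TRUE
})

#' Fusion knowledge weights
#'
#' The N x (2K+M) matrix W of scaled image-to-knowledge similarities,
#' W[i,j] = temperature * <image_i, T_j>. With unit-norm inputs and
#' temperature 1 the entries are cosine similarities in [-1, 1]. W rows
#' are the classifier head's input.
#'
#' @slot W numeric matrix N x (2K+M).
#' @slot temperature positive multiplicative scaling.
#' @slot provenance character: bank backend and image batch ids.
#' @export
setClass("FusionWeights",
  representation(W = "matrix", temperature = "numeric", provenance = "character"))

setValidity("FusionWeights", function(object) {
  if (length(object@temperature) != 1L || object@temperature <= 0)
    "temperature must be a positive scalar" else TRUE
})

#' Self-attention MLP adapter
#'
#' The lightweight trainable classifier head: a shallow MLP over a
#' fusion-weight row with role-aligned additive self-attention branches,
#' a gated residual projection and dropout. Only these parameters are
#' ever trained; encoders and bank stay frozen.
#'
#' @slot config validated list from [adapterConfig()].
#' @slot params named list of parameter matrices/vectors from
#'   [initAdapter()] or training.
#' @export
setClass("SAMLPAdapter",
  representation(config = "list", params = "list"))

#' Incremental-learning trigger decision
#'
#' Output of the softmax-confidence trigger: indicator 1 means the
#' confidence statistic fell inside [max(0, mu-gamma), mu+gamma] around
#' the uniform-prediction level mu = 1/K, flagging a probable unseen or
#' unknown species.
#'
#' @slot indicator integer 0/1.
#' @slot statistic top-1 softmax probability of the prediction.
#' @slot mu reference confidence level 1/K.
#' @slot gamma tolerance (> 0).
#' @export
setClass("IncrementalDecision",
  representation(indicator = "integer", statistic = "numeric",
                 mu = "numeric", gamma = "numeric"))

setValidity("IncrementalDecision", function(object) {
  msg <- character()
  if (!object@indicator %in% c(0L, 1L)) msg <- c(msg, "indicator must be 0 or 1")
  if (object@gamma <= 0) msg <- c(msg, "gamma must be > 0")
  lo <- max(0, object@mu - object@gamma); hi <- object@mu + object@gamma
  inside <- object@statistic >= lo && object@statistic <= hi
  if (inside != (object@indicator == 1L))
    msg <- c(msg, "indicator inconsistent with [mu-gamma, mu+gamma] rule")
  if (length(msg)) msg else TRUE
})

#' Field-deployment monitor state
#'
#' Everything the deployed loop needs: the frozen knowledge bank, the
#' (possibly absent) trained adapter, which classes are trained versus
#' zero-shot, the trigger tolerance policy and the queue of flagged
#' samples awaiting expert review.
#'
#' @slot bank the [EncodedKnowledgeBank-class].
#' @slot backend the frozen [EncoderBackend-class] that built the bank;
#'   kept so registration can encode only the new texts.
#' @slot adapter a [SAMLPAdapter-class], or NULL for a pure zero-shot state.
#' @slot trainedClasses 0-based indices of classes with trained shots;
#'   the complement of 0..K-1 is handled zero-shot.
#' @slot gamma trigger tolerance; NA means the default (1+0.2)/K,
#'   recomputed whenever K changes.
#' @slot zsScale logit scale applied to zero-shot cosine scores when no
#'   adapter calibration is available.
#' @slot calibration fitted scalar mapping cosine scores into the
#'   adapter logit range (NULL before training).
#' @slot trainEmbeddings training-shot embeddings retained for
#'   from-scratch retraining on registration (NULL if zero-shot).
#' @slot trainLabels 0-based labels parallel to trainEmbeddings rows.
#' @slot adapterOptions,trainOptions option lists reused at retraining.
#' @slot pendingUnknowns list of flagged prediction records.
#' @seealso [monitorState()], [predictSample()], [registerSpecies()]
#' @export
setClass("MonitorState",
  representation(bank = "EncodedKnowledgeBank", backend = "ANY",
                 adapter = "ANY",
                 trainedClasses = "integer", gamma = "numeric",
                 zsScale = "numeric", calibration = "OptionalNumeric",
                 trainEmbeddings = "ANY", trainLabels = "integer",
                 adapterOptions = "list", trainOptions = "list",
                 pendingUnknowns = "list"))

setValidity("MonitorState", function(object) {
  K <- object@bank@textset@K
  msg <- character()
  if (length(object@trainedClasses) &&
      (any(object@trainedClasses < 0L) || any(object@trainedClasses >= K)))
    msg <- c(msg, "trainedClasses must lie in 0..K-1")
  if (!is.na(object@gamma) && object@gamma <= 0)
    msg <- c(msg, "gamma must be > 0 (or NA for the (1+0.2)/K default)")
  if (length(msg)) msg else TRUE
})
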