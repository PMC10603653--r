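#' @include AllClasses.R
NULL

#' Encode text strings with a frozen backend
#'
#' @param backend an [EncoderBackend-class] object.
#' @param texts character vector (or a [KnowledgeTextSet-class]).
#' @return an [EmbeddingMatrix-class] with one unit-norm row per input,
#'   in input order.
#' @export
setGeneric("encodeText", function(backend, texts) standardGeneric("encodeText"))

#' Encode image references with a frozen backend
#'
#' @param backend an [EncoderBackend-class] object.
#' @param images character vector of image references. For the mock
#'   backend these are synthetic tokens of the form
#'   \code{img:<species>:<sigma>[:<id>]}.
#' @return an [EmbeddingMatrix-class], one unit-norm row per input.
#' @export
setGeneric("encodeImages", function(backend, images) standardGeneric("encodeImages"))

#' Embedding dimensionality of a backend or matrix
#' @param x object with an embedding dimension.
#' @return integer scalar.
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' Numeric embedding values
#' @param x an [EmbeddingMatrix-class] or object containing one.
#' @return numeric matrix, rows are items.
#' @export
setGeneric("embeddingValues", function(x) standardGeneric("embeddingValues"))

#' Row provenance identifiers
#' @param x an [EmbeddingMatrix-class] or bank.
#' @return character vector of row ids.
#' @export
setGeneric("rowIds", function(x) standardGeneric("rowIds"))

#' Role of each knowledge-text entry
#' @param x a [KnowledgeTextSet-class] or [EncodedKnowledgeBank-class].
#' @return character vector over \code{"feature"}, \code{"name"},
#'   \code{"description"}.
#' @export
setGeneric("textRoles", function(x) standardGeneric("textRoles"))

#' Species index of each knowledge-text entry
#' @param x a [KnowledgeTextSet-class] or [EncodedKnowledgeBank-class].
#' @return integer vector, 0-based class index; \code{NA} for feature
#'   entries (features are class-shared).
#' @export
setGeneric("classIndex", function(x) standardGeneric("classIndex"))

#' Number of species in a knowledge object
#' @param x a knowledge text set, bank or monitor state.
#' @return integer scalar K.
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' Number of distinct feature strings
#' @param x a knowledge text set or bank.
#' @return integer scalar M.
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' Species names held by an object
#' @param x knowledge record(s), text set, bank or monitor state.
#' @return character vector of species names in class order.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' Fusion-weight matrix
#' @param x a [FusionWeights-class] object.
#' @return numeric matrix N x (2K+M).
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))
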