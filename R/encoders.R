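l2normalize <- function(m) {
  n <- sqrt(rowSums(m^2))
  if (any(n == 0)) stop("cannot normalize a zero vector", call. = FALSE)
  m / n
}

embeddingMatrix <- function(values, ids, normalized = TRUE) {
  new("EmbeddingMatrix", values = values, ids = as.character(ids),
      normalized = normalized)
}

setMethod("embeddingValues", "EmbeddingMatrix", function(x) x@values)
setMethod("rowIds", "EmbeddingMatrix", function(x) x@ids)
setMethod("embeddingDim", "EmbeddingMatrix", function(x) ncol(x@values))
setMethod("embeddingDim", "EncoderBackend", function(x) x@dim)

setMethod("show", "EmbeddingMatrix", function(object) {
  cat("EmbeddingMatrix:", nrow(object@values), "x", ncol(object@values),
      if (isTRUE(object@normalized)) "(unit-norm rows)" else "(raw)", "\n")
})

setMethod("show", "MockEncoder", function(object) {
  cat("MockEncoder: dim =", object@dim, ", seed =", object@seed, "\n")
})

#' Create the deterministic mock dual encoder
#'
#' The mock backend stands in for a frozen pretrained vision-language
#' encoder in tests and synthetic worlds. Text vectors are hash-derived
#' unit vectors (distinct strings give distinct directions with
#' overwhelming probability); image tokens of the form
#' \code{img:<species>:<sigma>[:<id>]} are realised as the species' name
#' prompt vector plus seeded Gaussian noise of scale \code{sigma},
#' renormalised. With \code{sigma = 0} the image vector equals the name
#' prompt vector exactly.
#'
#' @param dim embedding dimensionality, >= 2 (default 64).
#' @param seed integer mixed into every hash.
#' @param nameTemplate sprintf template matching the one used at
#'   knowledge assembly.
#' @return a [MockEncoder-class].
#' @examples
#' be <- mockEncoder(dim = 8, seed = 1)
#' encodeText(be, c("a", "b"))
#' @export
mockEncoder <- function(dim = 64L, seed = 0L, nameTemplate = "a photo of a %s") {
  if (dim < 2) stop("dim must be >= 2", call. = FALSE)
  new("MockEncoder", name = "mock", dim = as.integer(dim),
      deterministic = TRUE, seed = as.integer(seed),
      nameTemplate = nameTemplate)
}

mockTextVector <- function(backend, s) {
  v <- hashNormals(s, backend@dim, seed = backend@seed, salt = 0)
  v / sqrt(sum(v^2))
}

parseImageToken <- function(token) {
  parts <- strsplit(token, ":", fixed = TRUE)[[1]]
  if (length(parts) < 3L || parts[1] != "img")
    stop("unreadable mock image reference (expected img:<species>:<sigma>[:<id>]): ",
         token, call. = FALSE)
  sigma <- suppressWarnings(as.numeric(parts[3]))
  if (is.na(sigma) || sigma < 0)
    stop("unreadable mock image reference (bad sigma): ", token, call. = FALSE)
  list(species = parts[2], sigma = sigma,
       id = if (length(parts) >= 4L) paste(parts[-(1:3)], collapse = ":") else "")
}

mockImageVector <- function(backend, token) {
  p <- parseImageToken(token)
  base <- mockTextVector(backend, sprintf(backend@nameTemplate, p$species))
  if (p$sigma > 0) {
    noise <- hashNormals(token, backend@dim, seed = backend@seed, salt = 7919)
    base <- base + p$sigma * noise
    base <- base / sqrt(sum(base^2))
  }
  base
}

#' @describeIn mockEncoder encode a character vector of texts; rows are
#'   unit-norm, in input order, bit-identical for identical inputs.
#' @param backend,texts see generic.
#' @export
setMethod("encodeText", signature("MockEncoder", "character"),
  function(backend, texts) {
    if (!length(texts)) stop("empty text set", call. = FALSE)
    v <- t(vapply(texts, function(s) mockTextVector(backend, s),
                  numeric(backend@dim)))
    dimnames(v) <- NULL
    embeddingMatrix(v, ids = texts)
  })

setMethod("encodeText", signature("MockEncoder", "KnowledgeTextSet"),
  function(backend, texts) encodeText(backend, texts@texts))

#' @describeIn mockEncoder encode synthetic image tokens.
#' @param images see generic.
#' @export
setMethod("encodeImages", signature("MockEncoder", "character"),
  function(backend, images) {
    if (!length(images)) stop("empty image batch", call. = FALSE)
    v <- t(vapply(images, function(s) mockImageVector(backend, s),
                  numeric(backend@dim)))
    dimnames(v) <- NULL
    embeddingMatrix(v, ids = images)
  })
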