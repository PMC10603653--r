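#' @importFrom methods new validObject is slot
#' @importFrom stats qnorm sd median setNames
#' @importFrom utils write.table read.table packageVersion
NULL

countWords <- function(x) {
  x <- trimws(x)
  if (!nzchar(x)) return(0L)
  length(strsplit(x, "\\s+")[[1]])
}

#' Create a specialist-knowledge record
#'
#' @param speciesName species label, non-empty.
#' @param description short free text, at most 100 words.
#' @param features character vector of attribute strings (may be empty).
#' @return a validated [KnowledgeRecord-class].
#' @examples
#' knowledgeRecord("tiger", "big striped cat", c("fur:striped"))
#' @export
knowledgeRecord <- function(speciesName, description, features = character()) {
  new("KnowledgeRecord",
      speciesName = as.character(speciesName),
      description = as.character(description),
      features = as.character(features))
}

setMethod("speciesNames", "KnowledgeRecord", function(x) x@speciesName)

setMethod("show", "KnowledgeRecord", function(object) {
  cat("KnowledgeRecord:", object@speciesName, "\n",
      " description (", countWords(object@description), " words), ",
      length(object@features), " feature(s)\n", sep = "")
})

checkRecordList <- function(records) {
  if (!length(records))
    stop("at least one knowledge record is required", call. = FALSE)
  if (!all(vapply(records, is, logical(1), class2 = "KnowledgeRecord")))
    stop("all elements must be KnowledgeRecord objects", call. = FALSE)
  nm <- vapply(records, function(r) r@speciesName, character(1))
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("duplicate species name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  invisible(nm)
}

#' Load specialist-knowledge records from a JSON file
#'
#' The file is a JSON array of objects with keys \code{species_name},
#' \code{description} and \code{features} (array of strings). Records
#' are validated on load: a missing field, a description over 100 words
#' or a duplicated species name is an error naming the offending record.
#'
#' @param path path to the records JSON file.
#' @return list of [KnowledgeRecord-class] objects in file order.
#' @seealso [writeKnowledgeRecords()], [assembleKnowledgeTexts()]
#' @export
loadKnowledgeRecords <- function(path) {
  if (!file.exists(path))
    stop("records file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw) || !length(raw))
    stop("records file must be a non-empty JSON array: ", path, call. = FALSE)
  records <- lapply(seq_along(raw), function(i) {
    r <- raw[[i]]
    need <- c("species_name", "description", "features")
    missing <- setdiff(need, names(r))
    if (length(missing))
      stop(sprintf("record %d ('%s') is missing field(s): %s", i,
                   if (!is.null(r$species_name)) r$species_name else "?",
                   paste(missing, collapse = ", ")), call. = FALSE)
    knowledgeRecord(r$species_name, r$description,
                    unlist(r$features, use.names = FALSE))
  })
  checkRecordList(records)
  records
}

#' Write specialist-knowledge records to a JSON file
#'
#' Inverse of [loadKnowledgeRecords()]: write/reload/reassemble is an
#' exact round trip.
#'
#' @param records list of [KnowledgeRecord-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeKnowledgeRecords <- function(records, path) {
  checkRecordList(records)
  payload <- lapply(records, function(r)
    list(species_name = r@speciesName, description = r@description,
         features = as.list(r@features)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Assemble the ordered specialist-knowledge text set
#'
#' Concatenates, in fixed order, the M distinct feature strings (global
#' deduplicated union across records, first-seen order), the K species
#' name prompts and the K raw descriptions, yielding 2K+M texts. Name
#' entries are realised through a prompt template (default
#' \code{"a photo of a \%s"}), the CLIP-style convention; features and
#' descriptions are kept raw.
#'
#' @param records list of [KnowledgeRecord-class]; class index follows
#'   record order.
#' @param nameTemplate sprintf template applied to species names.
#' @return a [KnowledgeTextSet-class].
#' @examples
#' recs <- list(knowledgeRecord("tiger", "big striped cat", "fur:striped"),
#'              knowledgeRecord("panda", "black and white bear",
#'                              c("fur:patched", "diet:bamboo")))
#' ts <- assembleKnowledgeTexts(recs)
#' length(ts@texts)  # 2*2 + 3 = 7
#' @export
assembleKnowledgeTexts <- function(records, nameTemplate = "a photo of a %s") {
  checkRecordList(records)
  feats <- unique(unlist(lapply(records, function(r) r@features),
                         use.names = FALSE))
  if (is.null(feats)) feats <- character()
  nm <- vapply(records, function(r) r@speciesName, character(1))
  K <- length(records); M <- length(feats)
  new("KnowledgeTextSet",
      texts = c(feats, sprintf(nameTemplate, nm),
                vapply(records, function(r) r@description, character(1))),
      roles = c(rep("feature", M), rep("name", K), rep("description", K)),
      classIdx = c(rep(NA_integer_, M), seq_len(K) - 1L, seq_len(K) - 1L),
      K = K, M = M, speciesNames = nm, nameTemplate = nameTemplate)
}

setMethod("textRoles", "KnowledgeTextSet", function(x) x@roles)
setMethod("classIndex", "KnowledgeTextSet", function(x) x@classIdx)
setMethod("nSpecies", "KnowledgeTextSet", function(x) x@K)
setMethod("nFeatures", "KnowledgeTextSet", function(x) x@M)
setMethod("speciesNames", "KnowledgeTextSet", function(x) x@speciesNames)

setMethod("show", "KnowledgeTextSet", function(object) {
  cat("KnowledgeTextSet: K =", object@K, "species, M =", object@M,
      "features,", length(object@texts), "texts (2K+M)\n")
})
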