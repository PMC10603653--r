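# Plain-text persistence: every artifact is a TSV matrix plus a JSON
# sidecar (or JSON alone), inspectable with standard tools. Numeric
# values are written with 17 significant digits so save/load round
# trips are bit-identical.

writeNumericTSV <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  apply(m, 1, function(row)
    writeLines(paste(sprintf("%.17g", row), collapse = "\t"), con))
  invisible(path)
}

readNumericTSV <- function(path) {
  rows <- readLines(path)
  do.call(rbind, lapply(strsplit(rows, "\t", fixed = TRUE), as.numeric))
}

#' Write an embedding matrix as TSV + JSON sidecar
#'
#' \code{<prefix>.tsv} holds one row per item; \code{<prefix>.json}
#' records backend name, dim, normalization flag and row ids.
#'
#' @param emb an [EmbeddingMatrix-class].
#' @param prefix output path prefix.
#' @param backendName provenance string for the sidecar.
#' @return the prefix, invisibly.
#' @export
writeEmbeddings <- function(emb, prefix, backendName = "unknown") {
  stopifnot(is(emb, "EmbeddingMatrix"))
  writeNumericTSV(emb@values, paste0(prefix, ".tsv"))
  jsonlite::write_json(
    list(backend = backendName, dim = ncol(emb@values),
         normalized = emb@normalized, row_ids = emb@ids),
    paste0(prefix, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(prefix)
}

#' Read an embedding matrix written by [writeEmbeddings()]
#' @param prefix path prefix.
#' @return an [EmbeddingMatrix-class].
#' @export
readEmbeddings <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, ".json"))
  v <- readNumericTSV(paste0(prefix, ".tsv"))
  embeddingMatrix(v, ids = meta$row_ids, normalized = isTRUE(meta$normalized))
}

#' Save an encoded knowledge bank to a directory
#'
#' Writes \code{T.tsv} (the embedding rows) and \code{bank.json} (the
#' ordered texts, roles, counts and provenance).
#'
#' @param bank an [EncodedKnowledgeBank-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
saveBank <- function(bank, dir) {
  stopifnot(is(bank, "EncodedKnowledgeBank"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeNumericTSV(embeddingValues(bank), file.path(dir, "T.tsv"))
  ts <- bank@textset
  jsonlite::write_json(
    list(texts = ts@texts, roles = ts@roles,
         class_index = ifelse(is.na(ts@classIdx), -1L, ts@classIdx),
         K = ts@K, M = ts@M, species_names = ts@speciesNames,
         name_template = ts@nameTemplate, backend = bank@backendName,
         normalized = bank@embeddings@normalized),
    file.path(dir, "bank.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a bank saved by [saveBank()]
#' @param dir directory.
#' @return an [EncodedKnowledgeBank-class].
#' @export
loadBank <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "bank.json"))
  idx <- as.integer(meta$class_index)
  idx[idx < 0L] <- NA_integer_
  ts <- new("KnowledgeTextSet", texts = meta$texts, roles = meta$roles,
            classIdx = idx, K = as.integer(meta$K), M = as.integer(meta$M),
            speciesNames = meta$species_names,
            nameTemplate = meta$name_template)
  new("EncodedKnowledgeBank",
      embeddings = embeddingMatrix(readNumericTSV(file.path(dir, "T.tsv")),
                                   ids = ts@texts,
                                   normalized = isTRUE(meta$normalized)),
      textset = ts, backendName = meta$backend)
}

#' Save an adapter checkpoint
#'
#' A directory holding \code{config.json} plus one TSV per parameter
#' tensor; [inspectAdapter()] prints the shapes.
#'
#' @param adapter a [SAMLPAdapter-class].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
saveAdapter <- function(adapter, dir) {
  stopifnot(is(adapter, "SAMLPAdapter"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(adapter@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (nm in names(adapter@params)) {
    x <- adapter@params[[nm]]
    writeNumericTSV(if (is.matrix(x)) x else matrix(x, nrow = 1),
                    file.path(dir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(
    lapply(adapter@params, function(x)
      if (is.matrix(x)) dim(x) else length(x)),
    file.path(dir, "shapes.json"), pretty = TRUE)
  invisible(dir)
}

#' Load an adapter checkpoint written by [saveAdapter()]
#' @param dir directory.
#' @return a [SAMLPAdapter-class].
#' @export
loadAdapter <- function(dir) {
  cfgList <- jsonlite::fromJSON(file.path(dir, "config.json"))
  for (nm in c("nFeatures", "nClasses"))
    cfgList[[nm]] <- if (is.null(cfgList[[nm]])) NA_integer_
      else as.integer(cfgList[[nm]])
  shapes <- jsonlite::fromJSON(file.path(dir, "shapes.json"))
  params <- lapply(names(shapes), function(nm) {
    m <- readNumericTSV(file.path(dir, paste0(nm, ".tsv")))
    if (length(shapes[[nm]]) == 2L) m else as.numeric(m[1, ])
  })
  names(params) <- names(shapes)
  if (!is.null(params$gateRaw)) params$gateRaw <- params$gateRaw[1]
  new("SAMLPAdapter", config = cfgList, params = params)
}

#' Print checkpoint parameter shapes
#' @param dir adapter checkpoint directory.
#' @return invisibly, a named list of shapes.
#' @export
inspectAdapter <- function(dir) {
  shapes <- jsonlite::fromJSON(file.path(dir, "shapes.json"))
  for (nm in names(shapes))
    cat(sprintf("%-8s %s\n", nm, paste(shapes[[nm]], collapse = " x ")))
  invisible(shapes)
}

#' Save a monitor state directory
#'
#' Persists the bank, mock-backend settings, adapter (if any), the
#' retained training pool and the trigger policy, all as plain text.
#'
#' @param state a [MonitorState-class]; the backend must be the mock
#'   encoder (a real pretrained backend is reloaded by name at
#'   deployment, not serialised).
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
saveMonitorState <- function(state, dir) {
  stopifnot(is(state, "MonitorState"), is(state@backend, "MockEncoder"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveBank(state@bank, file.path(dir, "bank"))
  if (!is.null(state@adapter))
    saveAdapter(state@adapter, file.path(dir, "ckpt"))
  if (!is.null(state@trainEmbeddings))
    writeEmbeddings(state@trainEmbeddings, file.path(dir, "train"),
                    backendName = state@bank@backendName)
  jsonlite::write_json(
    list(backend = list(dim = state@backend@dim, seed = state@backend@seed,
                        name_template = state@backend@nameTemplate),
         trained_classes = state@trainedClasses,
         train_labels = state@trainLabels,
         gamma = if (is.na(state@gamma)) "default" else state@gamma,
         zs_scale = state@zsScale,
         calibration = state@calibration,
         adapter_options = state@adapterOptions,
         train_options = state@trainOptions),
    file.path(dir, "state.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}

#' Load a monitor state saved by [saveMonitorState()]
#' @param dir directory.
#' @return a [MonitorState-class].
#' @export
loadMonitorState <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "state.json"),
                             simplifyVector = TRUE)
  backend <- mockEncoder(dim = meta$backend$dim, seed = meta$backend$seed,
                         nameTemplate = meta$backend$name_template)
  state <- new("MonitorState",
    bank = loadBank(file.path(dir, "bank")), backend = backend,
    adapter = if (dir.exists(file.path(dir, "ckpt")))
      loadAdapter(file.path(dir, "ckpt")) else NULL,
    trainedClasses = as.integer(meta$trained_classes),
    gamma = if (identical(meta$gamma, "default")) NA_real_
      else as.numeric(meta$gamma),
    zsScale = as.numeric(meta$zs_scale),
    calibration = if (is.null(meta$calibration)) NULL
      else as.numeric(meta$calibration),
    trainEmbeddings = if (file.exists(file.path(dir, "train.tsv")))
      readEmbeddings(file.path(dir, "train")) else NULL,
    trainLabels = as.integer(meta$train_labels),
    adapterOptions = as.list(meta$adapter_options),
    trainOptions = as.list(meta$train_options),
    pendingUnknowns = list())
  validObject(state)
  state
}
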