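# Workflow plumbing: a run configuration with package-wide defaults, a
# staged pipeline over a state directory (learn -> infer -> increment),
# and a run manifest per stage for reproducibility.

runDefaults <- function() {
  list(stateDir = ".",
       seed = 0L,
       dim = 64L,
       backendSeed = 0L,
       nameTemplate = "a photo of a %s",
       temperature = 1,
       shots = 16L,
       gamma = NA,
       zsScale = 20,
       synth = list(K = 10L, M = 20L, nTrain = 16L, nTest = 24L,
                    noiseSigma = 0.05, unknownClasses = 2L),
       adapter = list(hiddenDim = 256L, nHiddenLayers = 2L, nBranches = 3L,
                      dropout = 0.1, useAttention = TRUE, useResidual = TRUE),
       train = list(learningRate = 5e-4, maxEpochs = 200L),
       verbose = TRUE)
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Build a run configuration
#'
#' Unspecified fields take the package defaults (the reported training
#' settings and adapter shape). The configuration round-trips through
#' YAML losslessly.
#'
#' @param ... scalar or nested-list overrides of the defaults.
#' @param file optional YAML file of overrides, applied before
#'   \code{...}.
#' @return config list (class \code{"runConfig"}).
#' @export
runConfig <- function(..., file = NULL) {
  cfg <- runDefaults()
  if (!is.null(file)) cfg <- mergeConfig(cfg, yaml::read_yaml(file))
  cfg <- mergeConfig(cfg, list(...))
  structure(cfg, class = "runConfig")
}

#' Write a run configuration as YAML
#' @param config a [runConfig()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

pipeLog <- function(config, ...) {
  if (isTRUE(config$verbose))
    message(format(Sys.time(), "%H:%M:%S"), " [KnowShot] ", ...)
}

configHash <- function(config) {
  h <- hashString(as.character(jsonlite::toJSON(unclass(config),
                                                auto_unbox = TRUE,
                                                digits = NA)))
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

writeRunManifest <- function(config, stage, dir) {
  runsDir <- file.path(dir, "runs")
  dir.create(runsDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stage = stage, config = unclass(config),
                   config_hash = configHash(config), seed = config$seed,
                   package_version = as.character(packageVersion("KnowShot")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest,
                       file.path(runsDir, paste0(stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

requireArtifact <- function(path, neededBy, producedBy) {
  if (!file.exists(path))
    stop(sprintf("stage '%s' needs %s; run stage '%s' first",
                 neededBy, path, producedBy), call. = FALSE)
  invisible(path)
}

writeManifestCSV <- function(split, path) {
  utils::write.csv(data.frame(path = split$tokens, label = split$labels),
                   path, row.names = FALSE, quote = FALSE)
}

#' Run one pipeline stage
#'
#' Stages over a plain-text state directory:
#' \describe{
#'   \item{synth}{generate a synthetic world: \code{records.json},
#'     train/test/unknown embedding caches and manifests.}
#'   \item{bank}{assemble and encode the knowledge bank from
#'     \code{records.json} into \code{bank/}.}
#'   \item{encode}{encode an image manifest (\code{path,label} CSV)
#'     into an embedding cache.}
#'   \item{train}{fit the monitor state (adapter training) from the
#'     bank and the train cache into \code{state/}.}
#'   \item{eval}{evaluate the state on the test cache; writes
#'     \code{reports/accuracy.json}.}
#'   \item{monitor}{predict every row of a cache, with the incremental
#'     trigger; writes \code{reports/monitor.csv}.}
#'   \item{register}{register new species from
#'     \code{new_records.json} (plus optional shots cache) and retrain.}
#' }
#' Artifacts are written atomically (temp file + rename where it
#' matters); each stage records a run manifest under \code{runs/} with
#' the config hash and seed, so identical config + seed reruns are
#' bit-identical.
#'
#' @param config a [runConfig()].
#' @param stage one of the stage names above.
#' @return invisibly, a stage-specific result list.
#' @export
runPipeline <- function(config,
                        stage = c("synth", "bank", "encode", "train",
                                  "eval", "monitor", "register")) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "runConfig"))
  dir <- config$stateDir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  backend <- mockEncoder(dim = config$dim, seed = config$backendSeed,
                         nameTemplate = config$nameTemplate)
  result <- switch(stage,
    synth = {
      sc <- syntheticConfig(K = config$synth$K, M = config$synth$M,
                            dim = config$dim, nTrain = config$synth$nTrain,
                            nTest = config$synth$nTest,
                            noiseSigma = config$synth$noiseSigma,
                            unknownClasses = config$synth$unknownClasses,
                            seed = config$seed)
      world <- generateWorld(sc, backend)
      writeKnowledgeRecords(world$records, file.path(dir, "records.json"))
      cache <- file.path(dir, "cache")
      dir.create(cache, showWarnings = FALSE)
      for (split in c("train", "test", "unknown")) {
        if (is.null(world[[split]])) next
        writeEmbeddings(world[[split]]$embeddings,
                        file.path(cache, split), backendName = backend@name)
        writeManifestCSV(world[[split]],
                         file.path(cache, paste0(split, ".csv")))
      }
      pipeLog(config, "synth: K=", sc$K, ", noise=", sc$noiseSigma)
      list(world = world)
    },
    bank = {
      requireArtifact(file.path(dir, "records.json"), "bank", "synth")
      records <- loadKnowledgeRecords(file.path(dir, "records.json"))
      bank <- buildBank(backend,
                        assembleKnowledgeTexts(records,
                                               config$nameTemplate))
      saveBank(bank, file.path(dir, "bank"))
      pipeLog(config, "bank: T is ", nrow(embeddingValues(bank)), " x ",
              embeddingDim(bank))
      list(bank = bank)
    },
    encode = {
      requireArtifact(file.path(dir, "manifest.csv"), "encode", "synth")
      man <- utils::read.csv(file.path(dir, "manifest.csv"))
      emb <- encodeImages(backend, man$path)
      dir.create(file.path(dir, "cache"), showWarnings = FALSE)
      writeEmbeddings(emb, file.path(dir, "cache", "encoded"),
                      backendName = backend@name)
      list(embeddings = emb)
    },
    train = {
      requireArtifact(file.path(dir, "bank", "bank.json"), "train", "bank")
      requireArtifact(file.path(dir, "cache", "train.tsv"), "train", "synth")
      bank <- loadBank(file.path(dir, "bank"))
      emb <- readEmbeddings(file.path(dir, "cache", "train"))
      man <- utils::read.csv(file.path(dir, "cache", "train.csv"))
      topts <- config$train
      topts$temperature <- config$temperature
      topts$seed <- config$seed
      aopts <- config$adapter
      aopts$seed <- config$seed
      state <- fitMonitor(bank, backend, embeddings = emb,
                          labels = man$label, shots = config$shots,
                          gamma = if (is.null(config$gamma) ||
                                      is.na(config$gamma)) NA_real_
                                  else config$gamma,
                          zsScale = config$zsScale,
                          adapterOptions = aopts, trainOptions = topts,
                          seed = config$seed)
      saveMonitorState(state, file.path(dir, "state"))
      pipeLog(config, "train: ", config$shots, "-shot adapter over ",
              length(state@trainedClasses), " classes")
      list(state = state)
    },
    eval = {
      requireArtifact(file.path(dir, "state", "state.json"), "eval", "train")
      requireArtifact(file.path(dir, "cache", "test.tsv"), "eval", "synth")
      state <- loadMonitorState(file.path(dir, "state"))
      emb <- readEmbeddings(file.path(dir, "cache", "test"))
      man <- utils::read.csv(file.path(dir, "cache", "test.csv"))
      W <- computeFusionWeights(state@bank, emb, config$temperature)
      acc <- protocolAccuracy(state@adapter, W,
                              match(man$label, state@trainedClasses) - 1L,
                              seed = config$seed)
      reports <- file.path(dir, "reports")
      dir.create(reports, showWarnings = FALSE)
      tmp <- tempfile(tmpdir = reports)
      jsonlite::write_json(list(mean_accuracy = acc$mean,
                                per_repeat = acc$accuracies),
                           tmp, auto_unbox = TRUE, digits = NA)
      file.rename(tmp, file.path(reports, "accuracy.json"))
      pipeLog(config, "eval: mean accuracy ", round(acc$mean, 4))
      list(accuracy = acc)
    },
    monitor = {
      requireArtifact(file.path(dir, "state", "state.json"),
                      "monitor", "train")
      requireArtifact(file.path(dir, "cache", "test.tsv"), "monitor", "synth")
      state <- loadMonitorState(file.path(dir, "state"))
      emb <- readEmbeddings(file.path(dir, "cache", "test"))
      rows <- lapply(seq_along(emb@ids), function(i) {
        pr <- predictSample(state, emb@values[i, ], id = emb@ids[i])
        data.frame(item = emb@ids[i], predicted_label = pr$label,
                   predicted_species = pr$species,
                   top1_prob = pr$decision@statistic,
                   indicator = pr$decision@indicator)
      })
      report <- do.call(rbind, rows)
      reports <- file.path(dir, "reports")
      dir.create(reports, showWarnings = FALSE)
      utils::write.csv(report, file.path(reports, "monitor.csv"),
                       row.names = FALSE, quote = FALSE)
      pipeLog(config, "monitor: flagged ", sum(report$indicator),
              " of ", nrow(report))
      list(report = report)
    },
    register = {
      requireArtifact(file.path(dir, "state", "state.json"),
                      "register", "train")
      requireArtifact(file.path(dir, "new_records.json"),
                      "register", "(author new_records.json)")
      state <- loadMonitorState(file.path(dir, "state"))
      newRecords <- loadKnowledgeRecords(file.path(dir, "new_records.json"))
      shotsPrefix <- file.path(dir, "cache", "new_shots")
      if (file.exists(paste0(shotsPrefix, ".tsv"))) {
        emb <- readEmbeddings(shotsPrefix)
        man <- utils::read.csv(paste0(shotsPrefix, ".csv"))
        state <- registerSpecies(state, newRecords, emb, man$label)
      } else {
        state <- registerSpecies(state, newRecords)
      }
      saveMonitorState(state, file.path(dir, "state"))
      pipeLog(config, "register: K is now ", nSpecies(state))
      list(state = state)
    })
  writeRunManifest(config, stage, dir)
  invisible(result)
}
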