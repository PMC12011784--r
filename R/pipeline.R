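# End-to-end pipeline orchestration: simulate -> split -> (augment) ->
# extract -> train -> evaluate, with every artifact persisted and a
# JSON-lines event log. Stage seeds are derived from the master seed
# (master + stage index), so a re-run with the same config reproduces the
# deterministic stages bit-for-bit.

.defaultRunConfig <- function() {
  list(outDir = NULL, seed = 1L, preset = "easy", nPerClass = 100L,
       imageSize = 64L, system = "system2", augmentTrain = FALSE,
       split = list(ratios = c(0.70, 0.15, 0.15), stratify = TRUE),
       backbone = list(preset = "tiny", trainEpochs = 1L, lr = 1e-3,
                       batchSize = 8L),
       ann = list(hiddenUnits = 128L, maxEpochs = 60L, learningRate = 1e-3,
                  batchSize = 32L, patience = NULL, mode = "joint",
                  standardize = TRUE))
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      .mergeConfig(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

.logEvent <- function(logPath, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = logPath, append = TRUE)
}

.writeMatrixCSV <- function(m, labels, file) {
  df <- data.frame(label = labels, check.names = FALSE)
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  # fixed 15-significant-digit formatting keeps re-runs byte-identical
  for (j in seq(2, ncol(df))) df[[j]] <- sprintf("%.15g", df[[j]])
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate, split, optional train-set augmentation, backbone
#' training, feature extraction, classifier training and evaluation, in
#' order, persisting every intermediate artifact (images + manifest, split
#' indices, feature tables, weight archives, training history, metrics
#' report) in the run directory along with a JSON-lines event log.
#'
#' Two systems are supported: `"system2"` (default) classifies fused deep +
#' handcrafted features with the feed-forward network; `"system1"` classifies
#' with the backbone's averaged branch logits alone.
#'
#' @param config a nested list (or path to a YAML file) overriding the
#'   defaults; `outDir` is required. See the package vignette for the schema.
#' @return invisibly, a list with `metrics`, `history` (system2 only),
#'   `config`, and `dir`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(.defaultRunConfig(), config)
  if (is.null(cfg$outDir)) stop("config error: outDir is required")
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(cfg$outDir, "run.log.jsonl")
  if (file.exists(logPath)) unlink(logPath)
  masterSeed <- as.integer(cfg$seed)
  stage <- function(name, seedOffset, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(masterSeed + seedOffset), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    .logEvent(logPath, name, seed = masterSeed + seedOffset,
              seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  .logEvent(logPath, "start", rVersion = as.character(getRversion()),
            package = as.character(utils::packageVersion("histofuse")),
            masterSeed = masterSeed)

  dataset <- stage("simulate", 1L, function(sd) {
    pr <- histoPreset(cfg$preset)
    ds <- generateDataset(pr$class1, pr$class2, cfg$nPerClass,
                          c(cfg$imageSize, cfg$imageSize), seed = sd,
                          tag = paste0(cfg$preset, "-", cfg$imageSize, "px"))
    writeDataset(ds, file.path(cfg$outDir, "images"))
    ds
  })

  splits <- stage("split", 2L, function(sd) {
    partitionDataset(dataset, splitSpec(cfg$split$ratios,
                                        cfg$split$stratify, seed = sd))
  })
  jsonlite::write_json(lapply(splits, function(d)
    list(n = length(d), labels = imageLabels(d))),
    file.path(cfg$outDir, "split.json"), auto_unbox = FALSE)

  if (isTRUE(cfg$augmentTrain)) {
    splits$train <- stage("augment", 3L, function(sd) {
      aug <- lapply(seq_len(length(splits$train)), function(i)
        augmentImage(images(splits$train)[[i]],
                     augmentSpec(seed = sd + i)))
      HistoDataset(c(images(splits$train), aug),
                   c(imageLabels(splits$train), imageLabels(splits$train)),
                   c(imageTags(splits$train),
                     paste0(imageTags(splits$train), "-aug")))
    })
  }

  model <- stage("backbone", 4L, function(sd) {
    bc <- backboneConfig(cfg$backbone$preset, imageSize = cfg$imageSize)
    m <- crossViT(bc, seed = sd)
    if (cfg$backbone$trainEpochs > 0) {
      tr <- trainBackbone(m, splits$train, epochs = cfg$backbone$trainEpochs,
                          lr = cfg$backbone$lr,
                          batchSize = cfg$backbone$batchSize, seed = sd)
      m <- tr$model
    }
    saveWeights(m, file.path(cfg$outDir, "backbone.json"))
    m
  })

  if (identical(cfg$system, "system1")) {
    metrics <- stage("evaluate", 6L, function(sd) {
      preds <- lapply(images(splits$test), predictBackbone, model = model)
      yPred <- vapply(preds, `[[`, integer(1), "label")
      scores <- vapply(preds, function(p) p$prob[2], numeric(1))
      metricsReport(imageLabels(splits$test), yPred, scores)
    })
    jsonlite::write_json(metrics, file.path(cfg$outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    .logEvent(logPath, "done", accuracy = metrics$accuracy)
    return(invisible(list(metrics = metrics, history = NULL, config = cfg,
                          dir = cfg$outDir)))
  }

  feats <- stage("extract", 5L, function(sd) {
    out <- lapply(splits, function(d) fusedMatrix(d, model))
    for (nm in names(out))
      .writeMatrixCSV(out[[nm]], imageLabels(splits[[nm]]),
                      file.path(cfg$outDir, paste0("features_", nm, ".csv")))
    out
  })

  fit <- stage("train", 6L, function(sd) {
    tc <- trainConfig(hiddenUnits = cfg$ann$hiddenUnits,
                      maxEpochs = cfg$ann$maxEpochs,
                      learningRate = cfg$ann$learningRate,
                      batchSize = cfg$ann$batchSize,
                      patience = if (is.null(cfg$ann$patience)) NULL else
                        min(cfg$ann$patience, cfg$ann$maxEpochs),
                      seed = sd,
                      standardize = cfg$ann$standardize, mode = cfg$ann$mode)
    trainANN(feats$train, imageLabels(splits$train), feats$val,
             imageLabels(splits$val), tc,
             splitAt = attr(feats$train, "splitAt"))
  })
  saveFusionANN(fit$model, file.path(cfg$outDir, "classifier.json"))
  jsonlite::write_json(list(trainLoss = trainLoss(fit$history),
                            valLoss = valLoss(fit$history),
                            bestEpoch = bestEpoch(fit$history),
                            bestValLoss = bestValLoss(fit$history)),
                       file.path(cfg$outDir, "history.json"),
                       auto_unbox = TRUE, digits = NA)

  metrics <- stage("evaluate", 7L, function(sd) {
    pred <- predict(fit$model, feats$test)
    metricsReport(imageLabels(splits$test), pred$labels, pred$scores)
  })
  jsonlite::write_json(metrics, file.path(cfg$outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(
    "histofuse evaluation report",
    sprintf("  items: %d", sum(metrics$counts)),
    sprintf("  TP %d  FP %d  TN %d  FN %d", metrics$counts["TP"],
            metrics$counts["FP"], metrics$counts["TN"],
            metrics$counts["FN"]),
    sprintf("  accuracy    %.4f", metrics$accuracy),
    sprintf("  sensitivity %.4f", metrics$sensitivity),
    sprintf("  specificity %.4f", metrics$specificity),
    sprintf("  precision   %.4f", metrics$precision),
    sprintf("  auc         %.4f", metrics$auc),
    sprintf("  kappa       %.4f", metrics$kappa),
    sprintf("  f1          %.4f", metrics$f1)),
    file.path(cfg$outDir, "report.txt"))
  .logEvent(logPath, "done", accuracy = metrics$accuracy)
  invisible(list(metrics = metrics, history = fit$history, config = cfg,
                 dir = cfg$outDir))
}

#' Re-evaluate a persisted run
#'
#' Reloads the persisted test feature table and classifier archive from a
#' run directory and recomputes the metrics report; a run directory is
#' self-contained, so this reproduces the persisted `metrics.json` exactly.
#'
#' @param dir a run directory written by [runPipeline()].
#' @return the recomputed metrics report list.
#' @export
reevaluateRun <- function(dir) {
  featPath <- file.path(dir, "features_test.csv")
  modelPath <- file.path(dir, "classifier.json")
  if (!file.exists(featPath) || !file.exists(modelPath))
    stop("run directory is missing persisted features or classifier: ", dir)
  df <- utils::read.csv(featPath, check.names = FALSE)
  model <- loadFusionANN(modelPath)
  feats <- as.matrix(df[, -1, drop = FALSE])
  pred <- predict(model, feats)
  metricsReport(as.integer(df$label), pred$labels, pred$scores)
}
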