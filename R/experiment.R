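#' Run the full link-prediction experiment
#'
#' End-to-end pipeline over the standard input files: read the expression
#' matrix, prior network and optional TF list; preprocess the expression
#' (low-expression filter, variance-significance gene selection, log
#' normalization); restrict the network to the kept genes; draw the labeled
#' 3:1:1 edge split with hard training negatives and density-matched test
#' negatives; build the message-passing adjacency from the training
#' positives; train the encoder; score all genes; evaluate on the held-out
#' test pairs; and write the ranked candidate edges plus a metrics report.
#'
#' @param exprPath path to the expression CSV ([readExpression()] dialect).
#' @param networkPath path to the prior edge-list CSV ([readNetwork()]).
#' @param tfPath optional path to a TF list ([readTFList()]); when NULL, the
#'   edge sources act as the TF set.
#' @param config a [trainConfig()].
#' @param outDir output directory; `rankedEdges.csv` and `metrics.json` are
#'   written there (plus the run artifacts when `writeArtifacts = TRUE`).
#' @param writeArtifacts also persist the checkpoint, the preprocessed
#'   matrix, the filtered network, the split files and a per-epoch history
#'   log (the layout the `evaluate`/`predict` CLI subcommands consume).
#' @return Invisibly, a list: `model`, `history`, `metrics`, `ranked`,
#'   `split`, `scores` (the score matrix), `expression` (preprocessed),
#'   `network` (filtered).
#' @export
runExperiment <- function(exprPath, networkPath, tfPath = NULL,
                          config = trainConfig(), outDir = tempfile("run"),
                          writeArtifacts = TRUE) {
  expr <- readExpression(exprPath)
  tfs <- if (!is.null(tfPath)) readTFList(tfPath) else NULL
  xp <- preprocessExpression(expr, tfs = if (is.null(tfs)) character() else tfs,
                             minCellFraction = config$minCellFraction,
                             alpha = config$alpha, topK = config$topK,
                             base = config$logBase)
  net <- readNetwork(networkPath, geneUniverse = geneIds(xp), tfSet = tfs)
  split <- makeEdgeSplit(net, seed = config$seed, negRatio = config$negRatio)
  Anorm <- buildNormalizedAdjacency(net, nodes = geneIds(xp),
                                    edgeSubset = split@trainPos)
  xin <- if (config$features == "coexpression") coexpressionProfile(xp)
         else xp
  fit <- trainGCN(xin, net, split, config, Anorm = Anorm)
  R <- gcnDecode(gcnEncode(xin, Anorm, fit$model))
  metrics <- evaluatePairs(R, split@testPos, split@testNeg)
  ranked <- rankCandidates(R, net, exclude = split@trainPos)

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeRankedEdges(ranked, file.path(outDir, "rankedEdges.csv"))
  report <- c(metrics,
              list(splitSizes = as.list(splitSizes(split)),
                   bestEpoch = fit$history$bestEpoch,
                   seed = config$seed, config = unclass(config)))
  jsonlite::write_json(report, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (writeArtifacts) {
    writeGCNModel(fit$model, geneIds(xp), file.path(outDir, "checkpoint.json"),
                  features = config$features)
    writeExpression(xp, file.path(outDir, "preprocessed.csv"))
    writeNetwork(net, file.path(outDir, "network.csv"))
    writeLines(tfSet(net), file.path(outDir, "TFs.txt"))
    writeEdgeSplit(split, file.path(outDir, "splits"))
    hist <- data.frame(epoch = seq_along(fit$history$trainLoss),
                       train_loss = fit$history$trainLoss,
                       val_auroc = fit$history$valAuroc)
    utils::write.csv(hist, file.path(outDir, "history.csv"),
                     row.names = FALSE)
  }
  invisible(list(model = fit$model, history = fit$history, metrics = metrics,
                 ranked = ranked, split = split, scores = R,
                 expression = xp, network = net))
}

# Rebuild the score matrix from a persisted run directory (CLI support).
.loadRunScores <- function(runDir) {
  ck <- readGCNModel(file.path(runDir, "checkpoint.json"))
  xp <- readExpression(file.path(runDir, "preprocessed.csv"))
  net <- readNetwork(file.path(runDir, "network.csv"),
                     geneUniverse = geneIds(xp),
                     tfSet = readTFList(file.path(runDir, "TFs.txt")))
  train <- readLabeledPairs(file.path(runDir, "splits", "train.csv"))
  trainPos <- train[train$label == 1, c("from", "to")]
  if (!identical(geneIds(xp), ck$geneOrder))
    .stopf("checkpoint gene order does not match preprocessed matrix")
  Anorm <- buildNormalizedAdjacency(net, nodes = geneIds(xp),
                                    edgeSubset = trainPos)
  xin <- if (ck$features == "coexpression") coexpressionProfile(xp) else xp
  list(scores = gcnDecode(gcnEncode(xin, Anorm, ck$model)), net = net,
       trainPos = trainPos)
}

#' Write a run manifest
#'
#' Records the configuration echo, seed, input-file MD5 digests, package
#' version and stage timings of a pipeline run. Written atomically (to a
#' temporary file, then renamed).
#'
#' @param path output JSON path.
#' @param config a [trainConfig()] (or any list to echo).
#' @param inputs named character vector of input file paths to digest.
#' @param timings named numeric vector of stage durations (seconds).
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(path, config, inputs = character(),
                             timings = numeric()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  names(digests) <- names(inputs)
  obj <- list(package = "grnlink",
              version = as.character(utils::packageVersion("grnlink")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = config$seed, config = unclass(config),
              inputDigests = digests, stageSeconds = as.list(timings))
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
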