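#' Save a trained encoder checkpoint
#'
#' Writes a single versioned JSON archive holding the layer shapes and
#' parameters, the mixing coefficient and the gene-identifier order the
#' model was trained against. Plain text, full double precision.
#'
#' @param model a [GCNModel-class].
#' @param geneOrder character vector: the gene order of the expression
#'   matrix / adjacency the model expects.
#' @param path output path (conventionally `checkpoint.json`).
#' @param features featurization the model was trained with
#'   (see [trainConfig()]), recorded so scoring can rebuild its input.
#' @return `path`, invisibly.
#' @export
writeGCNModel <- function(model, geneOrder, path,
                          features = "coexpression") {
  stopifnot(is(model, "GCNModel"))
  obj <- list(
    format = "grnlink-gcn-checkpoint",
    formatVersion = 1L,
    package = as.character(utils::packageVersion("grnlink")),
    features = features,
    lambdaMix = model@lambdaMix,
    geneOrder = as.character(geneOrder),
    layers = lapply(seq_along(model@weights), function(l) list(
      dim = dim(model@weights[[l]]),
      weights = as.vector(model@weights[[l]]),
      bias = model@biases[[l]])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an encoder checkpoint
#'
#' @param path a checkpoint written by [writeGCNModel()].
#' @return List with `model` ([GCNModel-class]) and `geneOrder`.
#' @export
readGCNModel <- function(path) {
  if (!file.exists(path)) .stopf("checkpoint not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "grnlink-gcn-checkpoint"))
    .stopf("not a grnlink checkpoint: %s", path)
  weights <- lapply(obj$layers$dim, function(d) NULL)
  L <- length(obj$layers$bias)
  weights <- vector("list", L); biases <- vector("list", L)
  for (l in seq_len(L)) {
    d <- obj$layers$dim[[l]]
    weights[[l]] <- matrix(obj$layers$weights[[l]], d[1L], d[2L])
    biases[[l]] <- obj$layers$bias[[l]]
  }
  list(model = new("GCNModel", weights = weights, biases = biases,
                   lambdaMix = obj$lambdaMix),
       geneOrder = obj$geneOrder,
       features = if (is.null(obj$features)) "coexpression" else obj$features)
}

#' Write/read labeled pair files
#'
#' Three-column CSV dialect `Gene1,Gene2,Label` used for persisted edge
#' splits.
#'
#' @param pairs data.frame with `from`, `to`, `label`.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
writeLabeledPairs <- function(pairs, path) {
  utils::write.csv(data.frame(Gene1 = pairs$from, Gene2 = pairs$to,
                              Label = pairs$label),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLabeledPairs
#' @export
readLabeledPairs <- function(path) {
  if (!file.exists(path)) .stopf("split file not found: %s", path)
  d <- utils::read.csv(path, colClasses = c("character", "character",
                                            "numeric"))
  data.frame(from = d[[1L]], to = d[[2L]], label = d[[3L]],
             stringsAsFactors = FALSE)
}

#' Persist an edge split as labeled CSV files
#'
#' Writes `train.csv`, `val.csv`, `test.csv` (dialect of
#' [writeLabeledPairs()]) into a directory.
#'
#' @param split an [EdgeSplit-class].
#' @param dir output directory (created if needed).
#' @return Named vector of the three paths, invisibly.
#' @export
writeEdgeSplit <- function(split, dir) {
  stopifnot(is(split, "EdgeSplit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(train = file.path(dir, "train.csv"),
             val = file.path(dir, "val.csv"),
             test = file.path(dir, "test.csv"))
  writeLabeledPairs(rbind(cbind(split@trainPos, label = 1),
                          cbind(split@trainNeg, label = 0)), paths[["train"]])
  writeLabeledPairs(rbind(cbind(split@valPos, label = 1),
                          cbind(split@valNeg, label = 0)), paths[["val"]])
  writeLabeledPairs(rbind(cbind(split@testPos, label = 1),
                          cbind(split@testNeg, label = 0)), paths[["test"]])
  invisible(paths)
}
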