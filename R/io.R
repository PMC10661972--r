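#' Read a gene-by-cell expression matrix
#'
#' Reads the BEELINE-style expression dialect: a delimited text file with the
#' first column holding gene identifiers and the header row holding cell
#' identifiers. The delimiter is auto-detected from comma and tab.
#'
#' @param path path to a CSV/TSV file.
#' @return An [ExpressionMatrix-class]; row and column order are preserved
#'   from the file.
#' @details Duplicate gene identifiers, non-numeric cells and negative values
#'   are hard errors; the error message names the offending identifier or
#'   file location.
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path) {
  if (!file.exists(path)) .stopf("expression file not found: %s", path)
  sep <- .detectSep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2L) .stopf("expression file needs gene IDs plus >= 1 cell: %s", path)
  gid <- raw[[1L]]
  dup <- gid[duplicated(gid)]
  if (length(dup)) .stopf("duplicate gene ID in %s: %s", path, dup[1L])
  vals <- suppressWarnings(
    vapply(raw[-1L], function(col) as.numeric(col), numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(gid, colnames(raw)[-1L]))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    .stopf("non-numeric value at gene '%s', cell '%s' in %s",
           gid[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]], path)
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg))
    .stopf("negative value (%g) at gene '%s', cell '%s' in %s",
           vals[neg[1L, , drop = FALSE]], gid[neg[1L, 1L]],
           colnames(vals)[neg[1L, 2L]], path)
  ExpressionMatrix(vals)
}

#' Write an ExpressionMatrix to CSV
#'
#' Inverse of [readExpression()]: genes as rows, first column `Gene`, header
#' row of cell identifiers. Full-precision round trip.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
  stopifnot(is(x, "ExpressionMatrix"))
  df <- data.frame(Gene = geneIds(x), exprValues(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a directed edge list into a PriorNetwork
#'
#' Reads a two-column delimited file of (source, target) pairs, source first
#' — the BEELINE reference-network dialect. A header row is auto-detected by
#' recognizing common column names (Gene1/Gene2, TF/target, from/to, ...).
#' Edges are deduplicated; self-edges are dropped with a logged count; when a
#' gene universe is supplied, edges with endpoints outside it are dropped
#' with a logged count.
#'
#' @param path path to a CSV/TSV file.
#' @param geneUniverse optional character vector restricting the node set.
#' @param tfSet optional character vector of allowed regulators; defaults to
#'   the observed edge sources.
#' @param caseInsensitive match identifiers against `geneUniverse`/`tfSet`
#'   ignoring case (matched edges are rewritten to the universe spelling).
#'   Default `FALSE`: matching is exact, case-sensitive string equality.
#' @return A [PriorNetwork-class].
#' @export
readNetwork <- function(path, geneUniverse = NULL, tfSet = NULL,
                        caseInsensitive = FALSE) {
  if (!file.exists(path)) .stopf("network file not found: %s", path)
  sep <- .detectSep(path)
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2L) .stopf("network file needs two columns: %s", path)
  raw <- raw[, 1:2]
  headerNames <- c("gene1", "gene2", "tf", "target", "source", "from", "to",
                   "regulator", "gene")
  if (nrow(raw) && all(tolower(trimws(unlist(raw[1L, ]))) %in% headerNames))
    raw <- raw[-1L, , drop = FALSE]
  if (!nrow(raw)) .stopf("network file has no edges: %s", path)
  from <- trimws(raw[[1L]]); to <- trimws(raw[[2L]])
  if (!is.null(geneUniverse)) {
    if (caseInsensitive) {
      idx <- match(tolower(from), tolower(geneUniverse))
      idy <- match(tolower(to), tolower(geneUniverse))
      keep <- !is.na(idx) & !is.na(idy)
      from <- geneUniverse[idx[keep] ]; to <- geneUniverse[idy[keep] ]
    } else {
      keep <- from %in% geneUniverse & to %in% geneUniverse
      from <- from[keep]; to <- to[keep]
    }
    if (any(!keep))
      message(sum(!keep), " edge(s) dropped: endpoint outside gene universe")
  }
  if (!is.null(tfSet)) {
    if (!is.null(geneUniverse)) tfSet <- intersect(tfSet, geneUniverse)
    keepTf <- from %in% tfSet
    if (any(!keepTf))
      message(sum(!keepTf), " edge(s) dropped: source not in TF list")
    from <- from[keepTf]; to <- to[keepTf]
  }
  if (!length(from)) .stopf("no edges remain after filtering: %s", path)
  net <- PriorNetwork(data.frame(from = from, to = to,
                                 stringsAsFactors = FALSE),
                      genes = geneUniverse, tfSet = tfSet)
  if (!nrow(edges(net))) .stopf("no edges remain after filtering: %s", path)
  net
}

#' Write a PriorNetwork edge list
#'
#' Writes the `Gene1,Gene2` (source, target) dialect read by [readNetwork()].
#'
#' @param net a [PriorNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path) {
  stopifnot(is(net, "PriorNetwork"))
  e <- edges(net)
  utils::write.csv(data.frame(Gene1 = e$from, Gene2 = e$to),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transcription-factor list
#'
#' Plain text, one identifier per line; blank lines ignored, duplicates
#' collapsed.
#'
#' @param path file path.
#' @return Character vector of TF identifiers.
#' @export
readTFList <- function(path) {
  if (!file.exists(path)) .stopf("TF list not found: %s", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x)]
  # tolerate a single header line named like a column
  if (length(x) && tolower(x[1L]) %in% c("tf", "tfs", "gene", "regulator"))
    x <- x[-1L]
  unique(x)
}

#' Write ranked candidate edges
#'
#' Writes a `Gene1,Gene2,EdgeWeight` CSV sorted by score descending; ties are
#' broken by (source, target) lexicographic order so output is deterministic.
#'
#' @param ranked data.frame with columns `from`, `to`, `score` (finite,
#'   nonnegative scores).
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [rankCandidates()]
#' @export
writeRankedEdges <- function(ranked, path) {
  ranked <- as.data.frame(ranked, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "score") %in% colnames(ranked)))
  if (nrow(ranked)) {
    if (any(!is.finite(ranked$score)) || any(ranked$score < 0))
      .stopf("scores must be finite and >= 0")
    ord <- order(-ranked$score, ranked$from, ranked$to, method = "radix")
    ranked <- ranked[ord, , drop = FALSE]
  }
  out <- data.frame(Gene1 = ranked$from, Gene2 = ranked$to,
                    EdgeWeight = ranked$score)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Delimiter auto-detection between comma and tab, from the header line.
.detectSep <- function(path) {
  l1 <- readLines(path, n = 1L, warn = FALSE)
  if (!length(l1)) .stopf("empty file: %s", path)
  nTab <- lengths(regmatches(l1, gregexpr("\t", l1, fixed = TRUE)))
  nCom <- lengths(regmatches(l1, gregexpr(",", l1, fixed = TRUE)))
  if (nTab > nCom) "\t" else ","
}
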