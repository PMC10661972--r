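#' Remove genes expressed in too few cells
#'
#' Drops genes whose nonzero-cell fraction is strictly below
#' `minCellFraction` (default 10% of cells). A gene expressed in exactly the
#' threshold fraction of cells is kept. Gene order is preserved.
#'
#' @param x an [ExpressionMatrix-class]; "expressed" means value > 0.
#' @param minCellFraction numeric in \[0, 1\].
#' @return The filtered [ExpressionMatrix-class].
#' @export
filterLowExpression <- function(x, minCellFraction = 0.10) {
  stopifnot(is(x, "ExpressionMatrix"),
            minCellFraction >= 0, minCellFraction <= 1)
  v <- exprValues(x)
  frac <- rowMeans(v > 0)
  keep <- frac >= minCellFraction
  if (!any(keep))
    .stopf("all %d genes expressed in < %.0f%% of cells; nothing left",
           nrow(v), 100 * minCellFraction)
  x[which(keep), ]
}

#' Per-gene variance and dispersion significance
#'
#' Computes each gene's sample variance (denominator M - 1) and a p-value
#' from the chi-square dispersion test of that variance against the dataset
#' median variance: the statistic s = (M - 1) * var_g / median(var) is
#' referred to the upper tail of the chi-square distribution with M - 1
#' degrees of freedom. Genes much more variable than the typical gene get
#' small p-values; a constant gene gets p = 1.
#'
#' @param x an [ExpressionMatrix-class] with at least two cells.
#' @return A [GeneSelection-class] with variances and p-values filled.
#' @seealso [selectGenes()]
#' @export
varianceSignificance <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  v <- exprValues(x)
  M <- ncol(v)
  if (M < 2L) .stopf("need at least 2 cells to estimate variance")
  vars <- apply(v, 1L, stats::var)
  medVar <- stats::median(vars)
  if (medVar == 0)
    .stopf("median gene variance is 0 (all genes constant); cannot screen")
  s <- (M - 1L) * vars / medVar
  p <- stats::pchisq(s, df = M - 1L, lower.tail = FALSE)
  new("GeneSelection", geneIds = rownames(v), variance = unname(vars),
      pValue = unname(p), params = list())
}

#' Select significant highly-variable genes and TFs
#'
#' Applies Bonferroni correction to the dispersion p-values (adjusted
#' p = min(1, p * N_tested), with N_tested the number of genes screened,
#' i.e. those that survived the low-expression filter) and keeps genes with
#' adjusted p strictly below `alpha`. From the significant genes, the result
#' is the union of (i) all significant TFs and (ii) the `topK` most variable
#' significant genes. The returned matrix is ordered by decreasing variance.
#'
#' @param sel a [GeneSelection-class] from [varianceSignificance()].
#' @param x the [ExpressionMatrix-class] the selection refers to.
#' @param tfs character vector of TF identifiers.
#' @param alpha significance level on the Bonferroni-adjusted p-value
#'   (default 0.01).
#' @param topK number of top-variance genes to retain (default 500).
#' @return The subsetted [ExpressionMatrix-class], genes in
#'   variance-descending order.
#' @export
selectGenes <- function(sel, x, tfs = character(), alpha = 0.01, topK = 500L) {
  stopifnot(is(sel, "GeneSelection"), is(x, "ExpressionMatrix"), topK >= 1L)
  if (!all(sel@geneIds %in% geneIds(x)))
    .stopf("selection refers to genes absent from the expression matrix")
  nTested <- length(sel@geneIds)
  padj <- pmin(1, sel@pValue * nTested)
  sig <- padj < alpha
  if (!any(sig))
    .stopf("no gene passes Bonferroni-adjusted p < %g; consider a larger alpha",
           alpha)
  sigIds <- sel@geneIds[sig]
  sigVar <- sel@variance[sig]
  ord <- order(-sigVar, sigIds, method = "radix")
  sigIds <- sigIds[ord]; sigVar <- sigVar[ord]
  keep <- unique(c(sigIds[sigIds %in% tfs], utils::head(sigIds, topK)))
  # final order: variance descending
  keep <- keep[order(-sigVar[match(keep, sigIds)], keep, method = "radix")]
  x[keep, ]
}

#' Log-normalize expression values
#'
#' Replaces each value x by log(x + 1) in the given base (default 2), the
#' standard variance-stabilizing transform for expression data. Zero maps to
#' zero; the transform is strictly monotone; shape and identifiers are
#' unchanged.
#'
#' @param x an [ExpressionMatrix-class] (values >= 0).
#' @param base logarithm base, default 2.
#' @return The transformed [ExpressionMatrix-class].
#' @export
logNormalize <- function(x, base = 2) {
  stopifnot(is(x, "ExpressionMatrix"), base > 1)
  ExpressionMatrix(log1p(exprValues(x)) / log(base))
}

#' Add Gaussian noise to an expression matrix
#'
#' Perturbation utility for robustness experiments: adds i.i.d.
#' Normal(0, sigma^2) noise to every entry, then clamps at zero to preserve
#' nonnegativity. Reproducible under a fixed seed.
#'
#' @param x an [ExpressionMatrix-class].
#' @param sigma noise standard deviation, >= 0.
#' @param seed integer seed.
#' @return The perturbed [ExpressionMatrix-class].
#' @export
perturbExpression <- function(x, sigma, seed = 1L) {
  stopifnot(is(x, "ExpressionMatrix"), sigma >= 0)
  if (sigma == 0) return(x)
  v <- exprValues(x)
  noise <- .withSeed(.deriveSeed(seed, "perturb"),
                     matrix(stats::rnorm(length(v), 0, sigma), nrow(v)))
  ExpressionMatrix(.relu(v + noise))
}

#' Full expression preprocessing pipeline
#'
#' Fixed-order pipeline: [filterLowExpression()] then
#' [varianceSignificance()] + [selectGenes()] then [logNormalize()]. The
#' output gene set is always a subset of the input.
#'
#' @inheritParams filterLowExpression
#' @inheritParams selectGenes
#' @inheritParams logNormalize
#' @return The preprocessed [ExpressionMatrix-class].
#' @export
preprocessExpression <- function(x, tfs = character(), minCellFraction = 0.10,
                                 alpha = 0.01, topK = 500L, base = 2) {
  x <- filterLowExpression(x, minCellFraction)
  sel <- varianceSignificance(x)
  x <- selectGenes(sel, x, tfs = tfs, alpha = alpha, topK = topK)
  logNormalize(x, base = base)
}
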