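#' Fit an ASIS model on the full shared gene universe
#'
#' ASIS (Absolute Scorer for Individual Samples) refits the embedding on
#' the complete gene universe shared by the training cohorts after an
#' expression filter, instead of the variable-gene panel. Gene-set scores
#' are later computed per sample by regressing out the batch components
#' (PC1/PC2) and summing residual normalized expression, which puts every
#' cohort on one absolute scale.
#'
#' @param cohortMatrices list of raw gene-by-sample matrices (training
#'   cohorts).
#' @param stableGenes stable reference genes; the filter must not remove
#'   any of them.
#' @param minMean expression filter: a gene is kept if its mean expression
#'   exceeds `minMean` in every cohort (default 0; set `-Inf` to keep all
#'   shared genes). Alternatively pass a function(matrix) -> logical
#'   vector via `filter`.
#' @param filter optional custom filter, function from a cohort matrix to
#'   a per-gene logical keep vector (rows aligned to the matrix).
#' @param nComponents retained components (>= 2; default 4).
#' @param batchComponents indices regressed out at scoring time
#'   (default 1:2).
#' @param trainSamples optional character vector of sample ids to pool for
#'   the PCA; default all samples of all cohorts.
#' @param anchorGene,anchorComponent,seed passed to [fitEmbedding()].
#' @return list with `model` (an [AsisModel-class]), `scores` (training
#'   scores), and `universe` (the filtered shared gene list).
#' @export
asisFit <- function(cohortMatrices, stableGenes, minMean = 0,
                    filter = NULL, nComponents = 4L,
                    batchComponents = 1:2, trainSamples = NULL,
                    anchorGene = NULL, anchorComponent = 3L,
                    seed = NA_integer_) {
  stopifnot(is.list(cohortMatrices), length(cohortMatrices) >= 1L)
  if (as.integer(nComponents) < 2L)
    stop("ASIS needs at least 2 components")
  shared <- Reduce(intersect, lapply(cohortMatrices, rownames))
  keep <- rep(TRUE, length(shared))
  for (X in cohortMatrices) {
    Xs <- X[shared, , drop = FALSE]
    keep <- keep & if (is.null(filter)) rowMeans(Xs) > minMean
                   else filter(Xs)
  }
  universe <- shared[keep]
  lostStable <- setdiff(stableGenes, universe)
  if (length(lostStable))
    stop("expression filter removed stable gene: ", lostStable[1L])
  if (!length(universe)) stop("empty gene universe after filtering")
  sel <- list(featureGenes = universe, stableGenes = as.character(stableGenes))
  norm <- do.call(cbind, lapply(cohortMatrices, function(X)
    rankNormalize(X[universe, , drop = FALSE], sel)))
  if (!is.null(trainSamples)) {
    norm <- norm[, intersect(colnames(norm), trainSamples), drop = FALSE]
  }
  fit <- fitEmbedding(norm, nComponents = nComponents,
                      stableGenes = stableGenes, anchorGene = anchorGene,
                      anchorComponent = anchorComponent, seed = seed)
  m <- fit$model
  model <- new("AsisModel", featureGenes = m@featureGenes,
               stableGenes = m@stableGenes, loadings = m@loadings,
               signAnchors = m@signAnchors,
               trainingInfo = c(m@trainingInfo,
                                list(minMean = minMean,
                                     universeSize = length(universe))),
               batchComponents = as.integer(batchComponents))
  validObject(model)
  list(model = model, scores = fit$scores, universe = universe)
}

#' Remove the batch components from a normalized sample
#'
#' Least-squares regression (no intercept: the batch span already contains
#' the mean direction, since PC1 of the uncentered PCA is the centering
#' direction) of the sample vector on the batch-component loading vectors.
#' The residual is exactly orthogonal to every batch loading, so adding
#' any vector in the batch span to a sample leaves its residual -- and
#' hence every ASIS score -- unchanged.
#'
#' @param model an [AsisModel-class].
#' @param sample named numeric vector on the model universe (missing genes
#'   are zero-filled), or a gene-by-sample matrix.
#' @param method `"lstsq"` (default) solves the normal equations;
#'   `"reconstruction"` subtracts loadings times projected scores. For
#'   orthonormal loadings the two coincide to machine precision.
#' @return residual vector (or matrix) over the universe. A zero input
#'   sample yields a zero residual with attribute `zeroSample = TRUE`.
#' @export
asisRegress <- function(model, sample,
                        method = c("lstsq", "reconstruction")) {
  method <- match.arg(method)
  B <- model@loadings[, model@batchComponents, drop = FALSE]
  vec <- is.null(dim(sample))
  X <- if (vec) {
    x <- stats::setNames(numeric(length(model@featureGenes)),
                         model@featureGenes)
    common <- intersect(names(sample), model@featureGenes)
    x[common] <- sample[common]
    base::matrix(x, ncol = 1L, dimnames = list(model@featureGenes, NULL))
  } else sample[model@featureGenes, , drop = FALSE]
  ## regress column by column so a sample's residual is bit-identical
  ## whether it is processed alone or inside a batch
  cpB <- crossprod(B)
  R <- X
  for (s in seq_len(ncol(X))) {
    coef <- if (method == "lstsq") solve(cpB, crossprod(B, X[, s]))
            else crossprod(B, X[, s])
    R[, s] <- X[, s] - B %*% coef
  }
  if (vec) {
    r <- R[, 1L]
    names(r) <- model@featureGenes
    if (all(X == 0)) attr(r, "zeroSample") <- TRUE
    r
  } else R
}

#' Score one gene set on a batch-regressed sample
#'
#' The score is the plain sum of residual normalized expression over the
#' set genes present in the universe -- an absolute, single-sample
#' quantity. Coverage (fraction of set genes available) below
#' `minCoverage` flags the score as low-coverage; coverage equal to the
#' threshold passes.
#'
#' @param residual residual vector from [asisRegress()].
#' @param geneSet character vector of gene identifiers (non-empty).
#' @param minCoverage coverage QC threshold (default 0.75).
#' @return list: `score`, `coverage`, `flagged`.
#' @export
asisScore <- function(residual, geneSet, minCoverage = 0.75) {
  geneSet <- unique(geneSet)
  if (!length(geneSet)) stop("empty gene set")
  avail <- intersect(geneSet, names(residual))
  if (!length(avail))
    stop("gene set shares no genes with the model universe")
  coverage <- length(avail) / length(geneSet)
  list(score = sum(residual[avail]),
       coverage = coverage,
       flagged = coverage < minCoverage)
}

#' Score a cohort against a gene-set collection
#'
#' Normalizes each sample on the model universe (ranks among available
#' genes, zero-fill for absent ones), regresses out the batch components,
#' and sums residuals per gene set. Every sample is scored independently:
#' scoring a held-out sample alone gives bit-identical results to scoring
#' it inside a batch.
#'
#' @param model an [AsisModel-class].
#' @param matrix raw gene-by-sample expression matrix.
#' @param collection named list of gene sets (see [readGmt()]).
#' @param minCoverage passed to [asisScore()].
#' @return data.frame: `sample_id`, `set_name`, `score`, `coverage`,
#'   `flagged`.
#' @export
scoreCohort <- function(model, matrix, collection, minCoverage = 0.75) {
  stopifnot(is.list(collection), length(collection) >= 1L,
            !is.null(names(collection)))
  norm <- normalizeSamples(model, matrix)
  res <- asisRegress(model, norm)
  out <- vector("list", ncol(res) * length(collection))
  i <- 0L
  for (s in seq_len(ncol(res))) {
    r <- stats::setNames(res[, s], rownames(res))
    for (nm in names(collection)) {
      sc <- asisScore(r, collection[[nm]], minCoverage)
      i <- i + 1L
      out[[i]] <- data.frame(sample_id = colnames(res)[s], set_name = nm,
                             score = sc$score, coverage = sc$coverage,
                             flagged = sc$flagged,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
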