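#' Per-gene coefficient of variation
#'
#' CV = sample standard deviation (n-1 denominator) divided by the mean
#' expression level, computed per gene over the samples of one cohort.
#' Genes with mean exactly 0 have no defined CV and get `NA`; they are
#' excluded from variable-gene ranking downstream.
#'
#' @param matrix numeric gene-by-sample matrix (>= 2 samples).
#' @return named numeric vector of CVs (NA where the mean is 0).
#' @export
computeCV <- function(matrix) {
  stopifnot(is.matrix(matrix))
  if (ncol(matrix) < 2L)
    stop("computeCV needs at least 2 samples")
  m <- rowMeans(matrix)
  s <- apply(matrix, 1L, stats::sd)
  cv <- ifelse(m == 0, NA_real_, s / m)
  names(cv) <- rownames(matrix)
  cv
}

#' Select the feature-gene panel across training cohorts
#'
#' Candidate genes are those shared by all cohorts, excluding the stable
#' genes; they are ranked by the unweighted mean of their per-cohort CVs
#' (genes whose CV is undefined in any cohort are dropped) and the top
#' `nVariable` are taken. The stable genes are appended last, so the panel
#' size is exactly `nVariable + length(stableGenes)` (1000 + 44 = 1044 at
#' the defaults used on real cohorts).
#'
#' @param cohortMatrices list of gene-by-sample matrices (one per cohort).
#' @param stableGenes character vector of stable reference genes; each must
#'   be present in every cohort.
#' @param nVariable number of variable genes to keep (default 1000).
#' @return list with elements `variableGenes`, `stableGenes`,
#'   `featureGenes` (variable then stable) and `cvTable` (data.frame:
#'   gene, per-cohort CVs, meanCV, rank).
#' @export
selectFeatureGenes <- function(cohortMatrices, stableGenes,
                               nVariable = 1000L) {
  stopifnot(is.list(cohortMatrices), length(cohortMatrices) >= 1L)
  shared <- Reduce(intersect, lapply(cohortMatrices, rownames))
  missingStable <- setdiff(stableGenes, shared)
  if (length(missingStable))
    stop("stable gene absent from a cohort: ", missingStable[1L])
  cvs <- lapply(cohortMatrices, function(x) computeCV(x[shared, , drop = FALSE]))
  cvMat <- do.call(cbind, cvs)
  meanCV <- rowMeans(cvMat)                     # NA if undefined anywhere
  candidates <- setdiff(shared, stableGenes)
  candCV <- meanCV[candidates]
  candCV <- candCV[!is.na(candCV)]
  if (length(candCV) < nVariable)
    stop(sprintf("only %d candidate genes shared across cohorts, need %d",
                 length(candCV), nVariable))
  ord <- order(-candCV, names(candCV))          # deterministic tie-break
  variableGenes <- names(candCV)[ord][seq_len(nVariable)]
  cvTable <- data.frame(gene = shared, cvMat, meanCV = meanCV,
                        row.names = NULL, check.names = FALSE)
  colnames(cvTable)[1L + seq_along(cohortMatrices)] <-
    paste0("cv_cohort", seq_along(cohortMatrices))
  cvTable$rank <- rank(-cvTable$meanCV, ties.method = "min",
                       na.last = "keep")
  list(variableGenes = variableGenes,
       stableGenes = as.character(stableGenes),
       featureGenes = c(variableGenes, as.character(stableGenes)),
       cvTable = cvTable)
}

## per-sample ranking over the feature panel, divided by the mean stable
## rank -- shared by the strict and the projection-path normalizers
.rankNormalizeCols <- function(X, stableIdx) {
  R <- apply(X, 2L, rank, ties.method = "average")
  if (!is.matrix(R)) R <- matrix(R, ncol = ncol(X), dimnames = dimnames(X))
  div <- colMeans(R[stableIdx, , drop = FALSE])
  sweep(R, 2L, div, "/")
}

#' qPCR-like stable-gene rank normalization
#'
#' For each sample, the feature genes are ranked from lowest to highest
#' expression (ties get average ranks) and every rank is divided by that
#' sample's mean rank of the stable genes. The per-sample mean of the
#' stable-gene values is therefore exactly 1, and the result is invariant
#' to any strictly increasing per-sample transform of the raw values --
#' which is what makes platforms comparable.
#'
#' @param matrix gene-by-sample matrix containing every feature gene.
#'   Missing feature genes are an error here; samples with missing genes
#'   are handled at projection time by [normalizeSamples()].
#' @param selection result of [selectFeatureGenes()] (or any list with
#'   `featureGenes` and `stableGenes`).
#' @return normalized matrix over `selection$featureGenes` (rows in panel
#'   order), strictly positive values.
#' @export
rankNormalize <- function(matrix, selection) {
  feat <- selection$featureGenes
  absent <- setdiff(feat, rownames(matrix))
  if (length(absent))
    stop("feature gene absent from matrix: ", absent[1L],
         " (samples with missing genes must go through normalizeSamples(),",
         " which zero-fills at projection)")
  X <- matrix[feat, , drop = FALSE]
  .rankNormalizeCols(X, match(selection$stableGenes, feat))
}

#' Normalize samples against a fitted model, tolerating missing genes
#'
#' The projection-path normalizer: ranks are computed among the feature
#' genes actually present in the input, divided by the mean stable-gene
#' rank, and genes absent from the input are filled with 0 (they then
#' contribute nothing to the projection). At least one stable gene must be
#' present.
#'
#' @param model an [EmberModel-class].
#' @param matrix gene-by-sample matrix (any superset or subset of the
#'   feature panel).
#' @return matrix over the full feature panel (absent genes as 0), with
#'   attributes `missingGenes` and `missingFraction`.
#' @export
normalizeSamples <- function(model, matrix) {
  feat <- model@featureGenes
  present <- intersect(feat, rownames(matrix))
  if (!length(present))
    stop("sample shares no genes with the model")
  stab <- intersect(model@stableGenes, present)
  if (!length(stab))
    stop("no stable genes available; normalization divisor undefined")
  Xp <- matrix[present, , drop = FALSE]
  Np <- .rankNormalizeCols(Xp, match(stab, present))
  out <- base::matrix(0, length(feat), ncol(matrix),
                      dimnames = list(feat, colnames(matrix)))
  out[present, ] <- Np
  miss <- setdiff(feat, present)
  attr(out, "missingGenes") <- miss
  attr(out, "missingFraction") <- length(miss) / length(feat)
  out
}

#' Sensitivity of the normalization to the number of stable genes
#'
#' Randomly subsamples the stable panel, renormalizes with only the
#' sampled reference genes, and reports how well each variable gene's
#' normalized profile across samples correlates (Spearman) with the
#' full-panel normalization. Since ranks are unchanged, only the
#' per-sample divisor varies; correlations below 1 measure divisor noise.
#'
#' @param matrix raw gene-by-sample matrix containing the feature panel.
#' @param selection result of [selectFeatureGenes()].
#' @param subsetSizes integer vector of stable-subset sizes (each >= 2 and
#'   < number of stable genes, or equal to it for the identity check).
#' @param nDraws random subsets per size.
#' @param seed RNG seed.
#' @param probs quantiles of the per-gene correlation distribution to
#'   report alongside the minimum.
#' @return data.frame: size, draw, minCor, one column per quantile.
#' @export
stableGeneCountSweep <- function(matrix, selection, subsetSizes,
                                 nDraws = 10L, seed = 1L,
                                 probs = c(0.10, 0.50)) {
  if (any(subsetSizes < 2L))
    stop("stable subset sizes must be >= 2")
  nStab <- length(selection$stableGenes)
  if (any(subsetSizes > nStab))
    stop("subset size exceeds number of stable genes")
  full <- rankNormalize(matrix, selection)
  varG <- selection$variableGenes
  set.seed(seed)
  rows <- list()
  for (s in subsetSizes) {
    for (d in seq_len(nDraws)) {
      sub <- if (s == nStab) selection$stableGenes
             else sample(selection$stableGenes, s)
      subSel <- list(featureGenes = selection$featureGenes,
                     stableGenes = sub)
      renorm <- rankNormalize(matrix, subSel)
      cors <- vapply(varG, function(g)
        stats::cor(full[g, ], renorm[g, ], method = "spearman"),
        numeric(1))
      q <- stats::quantile(cors, probs, na.rm = TRUE)
      rows[[length(rows) + 1L]] <-
        c(size = s, draw = d, minCor = min(cors, na.rm = TRUE), q)
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  colnames(out) <- c("size", "draw", "minCor",
                     paste0("q", probs * 100))
  out
}
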