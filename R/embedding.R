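#' Fit the uncentered, unscaled PCA embedding
#'
#' Singular value decomposition of the samples-by-genes normalized
#' training matrix with no centering and no scaling. The loadings are the
#' right singular vectors; training scores are the data projected on them.
#' Because the data are not centered, PC1 aligns with the per-gene mean
#' profile and PC2 with the dominant scale/batch direction, leaving tumor
#' biology to PC3 and beyond. Component signs are fixed deterministically
#' by anchor rules (see Details).
#'
#' @details Sign anchoring: PC1 is oriented so the mean training profile
#' projects positively; the component given by `anchorComponent` is
#' oriented so `anchorGene` (an ER-program hub in real use) loads
#' positively; every other component is oriented so its largest-|loading|
#' gene loads positively. The resolved (gene, sign) pairs are stored in
#' the model so any refit can be aligned identically.
#'
#' @param normalized gene-by-sample rank-normalized matrix (training
#'   samples), e.g. from [rankNormalize()].
#' @param nComponents components to retain (default 4).
#' @param stableGenes character vector of the stable genes used by the
#'   normalization (stored in the model).
#' @param anchorGene optional gene whose loading sign pins
#'   `anchorComponent`; default none (largest-|loading| rule).
#' @param anchorComponent component the anchor gene pins (default 3).
#' @param seed integer recorded in the model's training info.
#' @return list with `model` (an [EmberModel-class]) and `scores`
#'   (training samples x components matrix).
#' @export
fitEmbedding <- function(normalized, nComponents = 4L, stableGenes,
                         anchorGene = NULL, anchorComponent = 3L,
                         seed = NA_integer_) {
  stopifnot(is.matrix(normalized))
  K <- as.integer(nComponents)
  if (ncol(normalized) < K)
    stop("need at least as many samples as components")
  sv <- svd(t(normalized), nu = 0L, nv = K)
  if (sv$d[K] <= 1e-12 * max(sv$d[1L], .Machine$double.eps))
    stop("training matrix rank is below the requested number of components")
  L <- sv$v
  dimnames(L) <- list(rownames(normalized), paste0("PC", seq_len(K)))

  ## resolve signs
  geneMeans <- rowMeans(normalized)
  anchors <- data.frame(component = paste0("PC", seq_len(K)),
                        gene = NA_character_, sign = NA_real_,
                        stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    if (k == 1L) {
      flip <- sum(L[, 1L] * geneMeans) < 0
    } else if (!is.null(anchorGene) && k == anchorComponent &&
               anchorGene %in% rownames(L) && L[anchorGene, k] != 0) {
      flip <- L[anchorGene, k] < 0
    } else {
      flip <- FALSE  # largest-|loading| positive
      j <- which.max(abs(L[, k]))
      flip <- L[j, k] < 0
    }
    if (flip) L[, k] <- -L[, k]
    j <- if (!is.null(anchorGene) && k == anchorComponent &&
             anchorGene %in% rownames(L) && L[anchorGene, k] != 0)
      match(anchorGene, rownames(L)) else which.max(abs(L[, k]))
    anchors$gene[k] <- rownames(L)[j]
    anchors$sign[k] <- sign(L[j, k])
  }

  model <- new("EmberModel",
               featureGenes = rownames(normalized),
               stableGenes = as.character(stableGenes),
               loadings = L,
               signAnchors = anchors,
               trainingInfo = list(nTrain = ncol(normalized), seed = seed,
                                   anchorGene = anchorGene,
                                   anchorComponent = anchorComponent,
                                   singularValues = sv$d[seq_len(K)]))
  validObject(model)
  scores <- crossprod(normalized, L)
  rownames(scores) <- colnames(normalized)
  list(model = model, scores = scores)
}

#' Project samples into a fitted embedding
#'
#' Coordinates are the loading matrix transposed times the normalized
#' sample vector; each sample is embedded independently of all others.
#' Genes absent from the sample (zero-filled by [normalizeSamples()])
#' contribute nothing.
#'
#' @param model an [EmberModel-class].
#' @param normalized gene-by-sample normalized matrix over the model's
#'   feature panel (from [rankNormalize()] or [normalizeSamples()]), or a
#'   single named vector.
#' @return samples x components score matrix. If more than half the panel
#'   was missing the attribute `missingWarning` is set.
#' @export
projectSamples <- function(model, normalized) {
  if (is.null(dim(normalized))) {
    v <- normalized
    if (is.null(names(v))) stop("a single sample must be a named vector")
    common <- intersect(names(v), model@featureGenes)
    if (!length(common)) stop("sample shares no genes with the model")
    x <- stats::setNames(numeric(length(model@featureGenes)),
                         model@featureGenes)
    x[common] <- v[common]
    normalized <- base::matrix(x, ncol = 1L,
                               dimnames = list(model@featureGenes, "sample"))
    attr(normalized, "missingFraction") <-
      1 - length(common) / length(model@featureGenes)
  }
  if (!identical(rownames(normalized), model@featureGenes)) {
    if (!all(model@featureGenes %in% rownames(normalized)))
      stop("normalized matrix must cover the model's feature panel ",
           "(use normalizeSamples() for samples with missing genes)")
    normalized <- normalized[model@featureGenes, , drop = FALSE]
  }
  scores <- crossprod(normalized, model@loadings)
  mf <- attr(normalized, "missingFraction")
  if (!is.null(mf) && mf > 0.5)
    attr(scores, "missingWarning") <-
      sprintf("%.0f%% of feature genes missing", 100 * mf)
  scores
}

#' Re-anchor the signs of an embedding's components
#'
#' Principal components are defined only up to sign; refits on resampled
#' training sets can come back reflected. `alignSigns` multiplies each
#' loading column by +/-1 so a designated anchor gene's loading has the
#' desired sign, and transforms any supplied scores consistently. Applying
#' it twice is a fixed point.
#'
#' @param model an [EmberModel-class].
#' @param anchorRules data.frame with columns `component` (e.g. "PC3"),
#'   `gene`, `sign` (+1/-1); defaults to the model's own stored anchors.
#' @param scores optional score matrix to transform alongside.
#' @return the re-anchored model, or `list(model, scores)` when scores are
#'   supplied. Anchor genes with exactly zero loading fall back to the
#'   largest-|loading| gene; fallbacks are recorded in
#'   `trainingInfo(model)$anchorFallbacks`.
#' @export
alignSigns <- function(model, anchorRules = signAnchors(model),
                       scores = NULL) {
  L <- model@loadings
  fallbacks <- character()
  for (i in seq_len(nrow(anchorRules))) {
    comp <- anchorRules$component[i]
    if (!comp %in% colnames(L)) stop("unknown component: ", comp)
    g <- anchorRules$gene[i]
    want <- anchorRules$sign[i]
    if (!g %in% rownames(L)) stop("anchor gene not in feature panel: ", g)
    cur <- L[g, comp]
    if (cur == 0) {
      j <- which.max(abs(L[, comp]))
      fallbacks <- c(fallbacks,
                     sprintf("%s: anchor %s has zero loading, using %s",
                             comp, g, rownames(L)[j]))
      g <- rownames(L)[j]
      cur <- L[g, comp]
    }
    if (sign(cur) != want) {
      L[, comp] <- -L[, comp]
      if (!is.null(scores)) scores[, comp] <- -scores[, comp]
    }
  }
  model@loadings <- L
  if (length(fallbacks))
    model@trainingInfo$anchorFallbacks <- fallbacks
  validObject(model)
  if (is.null(scores)) model else list(model = model, scores = scores)
}

#' Compare the uncentered embedding with a centered-and-scaled PCA
#'
#' Fits an ordinary centered, unit-variance-scaled PCA on the same
#' normalized data and reports (over samples) the absolute Pearson
#' correlation of uncentered PC3 with scaled PC2 and uncentered PC4 with
#' scaled PC3 -- the diagnostic that the first two uncentered components
#' merely absorb centering and scaling, so no biology is lost by skipping
#' them. Also reports the correlation of |PC2 loadings| with the post-
#' centering per-gene standard deviation.
#'
#' @param normalized gene-by-sample normalized matrix.
#' @param model the fitted [EmberModel-class] (>= 4 components).
#' @return list: `pc3VsScaledPc2`, `pc4VsScaledPc3` (absolute
#'   correlations), `pc2LoadingVsSd`, and `droppedGenes` (zero-variance
#'   genes removed before scaling, with a warning if any).
#' @export
scaledPcaEquivalence <- function(normalized, model) {
  if (ncol(model@loadings) < 4L)
    stop("need at least 4 components in the uncentered model")
  emberScores <- projectSamples(model, normalized)
  sds <- apply(normalized, 1L, stats::sd)
  keep <- sds > 0
  dropped <- rownames(normalized)[!keep]
  if (length(dropped))
    warning(length(dropped), " zero-variance gene(s) dropped before scaling")
  sp <- stats::prcomp(t(normalized[keep, , drop = FALSE]),
                      center = TRUE, scale. = TRUE, rank. = 4L)
  list(
    pc3VsScaledPc2 = abs(stats::cor(emberScores[, 3L], sp$x[, 2L])),
    pc4VsScaledPc3 = abs(stats::cor(emberScores[, 4L], sp$x[, 3L])),
    pc2LoadingVsSd = if (stats::sd(sds[keep]) == 0) NA_real_
                     else stats::cor(abs(model@loadings[keep, 2L]), sds[keep]),
    droppedGenes = dropped
  )
}
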