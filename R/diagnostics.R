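## k nearest neighbors (by Euclidean distance) among the rows of S,
## excluding self; returns an n x k index matrix
.knnIndex <- function(S, k) {
  n <- nrow(S)
  if (k >= n) stop("k must be smaller than the number of samples")
  D <- as.matrix(stats::dist(S))
  diag(D) <- Inf
  t(apply(D, 1L, function(d) order(d)[seq_len(k)]))
}

#' Localized Inverse Simpson Index of label mixing
#'
#' For every sample, Gaussian-kernel weights over its 3 x perplexity
#' nearest neighbors are tuned by bisection so the weight entropy matches
#' the target perplexity; the LISI is the inverse Simpson index of the
#' kernel-weighted label proportions. A value of 1 means the local
#' neighborhood is a single label (fully separated), a value equal to the
#' number of label categories means fully mixed.
#'
#' @param coords sample-by-dimension coordinate matrix (e.g. two score
#'   columns of an embedding).
#' @param labels character/factor vector of labels, one per sample.
#' @param perplexity effective neighborhood size (default 30); must be
#'   below n/3.
#' @return list: `perSample` (named numeric), `labelName`, `perplexity`,
#'   `median`, `mean`. Values are guaranteed in [1, #labels].
#' @export
lisi <- function(coords, labels, perplexity = 30) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 samples")
  if (length(labels) != n) stop("labels must cover all samples")
  if (perplexity >= n / 3)
    stop("perplexity must be below n/3")
  labels <- as.character(labels)
  cats <- unique(labels)
  k <- min(as.integer(3 * perplexity), n - 1L)
  nn <- .knnIndex(coords, k)
  D <- as.matrix(stats::dist(coords))
  target <- log(perplexity)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- D[i, nn[i, ]]^2
    ## bisection on precision beta so that entropy(p) = log(perplexity)
    lo <- 0; hi <- Inf; beta <- 1
    for (iter in 1:60) {
      w <- exp(-beta * d2)
      sw <- sum(w)
      if (sw == 0) { H <- 0 } else {
        p <- w / sw
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(H - target) < 1e-7) break
      if (H > target) {                # too flat -> increase beta
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (lo + beta) / 2
      }
    }
    w <- exp(-beta * d2)
    p <- if (sum(w) == 0) rep(1 / k, k) else w / sum(w)
    pl <- vapply(cats, function(cl) sum(p[labels[nn[i, ]] == cl]),
                 numeric(1))
    vals[i] <- 1 / sum(pl^2)
  }
  vals <- pmin(pmax(vals, 1), length(cats))
  names(vals) <- rownames(coords)
  list(perSample = vals, labelName = deparse(substitute(labels)),
       perplexity = perplexity,
       median = stats::median(vals), mean = mean(vals))
}

#' LISI as a function of the number of variable genes
#'
#' Re-runs selection, normalization and the uncentered PCA for each panel
#' size and reports cohort- and ER-label LISI in the batch plane (PC1/PC2)
#' and the biology plane (PC3/PC4). Good integration shows cohort-LISI
#' near 1 in PC1/PC2 (cohorts apart) and near 2 in PC3/PC4 (cohorts
#' mixed), with a plateau around the default 1000 genes.
#'
#' @param cohortMatrices list of raw cohort matrices.
#' @param stableGenes stable reference genes.
#' @param geneCounts integer vector of variable-gene panel sizes.
#' @param labels data.frame with columns `sample_id`, `cohort` and
#'   optionally `er_status`.
#' @param nTrain training samples pooled for each fit (default all).
#' @param perplexity LISI perplexity.
#' @param seed RNG seed for the training subsample.
#' @return data.frame: geneCount, label, plane, medianLisi, meanLisi.
#' @export
geneCountSweep <- function(cohortMatrices, stableGenes, geneCounts,
                           labels, nTrain = NULL, perplexity = 30,
                           seed = 1L) {
  rows <- list()
  for (gc in geneCounts) {
    sel <- selectFeatureGenes(cohortMatrices, stableGenes,
                              nVariable = gc)
    norm <- do.call(cbind, lapply(cohortMatrices, rankNormalize,
                                  selection = sel))
    set.seed(seed)
    tr <- if (is.null(nTrain) || nTrain >= ncol(norm)) seq_len(ncol(norm))
          else sample(ncol(norm), nTrain)
    fit <- fitEmbedding(norm[, tr, drop = FALSE], nComponents = 4L,
                        stableGenes = stableGenes, seed = seed)
    scores <- projectSamples(fit$model, norm)
    lab <- labels[match(colnames(norm), labels$sample_id), ]
    for (labName in intersect(c("cohort", "er_status"), colnames(lab))) {
      lv <- lab[[labName]]
      if (all(is.na(lv))) next
      for (plane in list(c("PC1", "PC2"), c("PC3", "PC4"))) {
        li <- lisi(scores[, plane], lv, perplexity)
        rows[[length(rows) + 1L]] <- data.frame(
          geneCount = gc, label = labName,
          plane = paste(plane, collapse = "/"),
          medianLisi = li$median, meanLisi = li$mean,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

## Jaccard similarity of two index/id sets
.jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' k-NN Jaccard stability of the embedding under retraining
#'
#' Refits the PCA on random training subsets and measures, for each probe
#' sample, the Jaccard index between its k-nearest-neighbor set in the
#' refit embedding and in the original embedding (distances in the
#' biology plane, which is invariant to the shift/reflection ambiguity of
#' refits).
#'
#' @param normalized gene-by-sample normalized matrix of all samples (the
#'   panel does not change across refits; only the training subset does).
#' @param model the original fitted [EmberModel-class].
#' @param nTrain training-set size per refit.
#' @param nSeeds number of refits (default 25).
#' @param kNeighbors neighborhood size (default 50).
#' @param nProbes number of probe samples (default all).
#' @param seed base RNG seed; refit r uses seed + r.
#' @param components plane in which neighbors are found.
#' @param refitScores optional list of precomputed score matrices to use
#'   instead of refitting (e.g. the original scores themselves to check
#'   the identity case).
#' @return list: `perProbe` (named mean Jaccard per probe), `matrix`
#'   (probe x refit), `mean`, `sd`, `kNeighbors`, `nSeeds`.
#' @export
jaccardStability <- function(normalized, model, nTrain = 1000L,
                             nSeeds = 25L, kNeighbors = 50L,
                             nProbes = NULL, seed = 1L,
                             components = c("PC3", "PC4"),
                             refitScores = NULL) {
  n <- ncol(normalized)
  if (kNeighbors >= n) stop("kNeighbors must be below the sample count")
  orig <- projectSamples(model, normalized)[, components, drop = FALSE]
  set.seed(as.integer(seed))
  probes <- if (is.null(nProbes) || nProbes >= n) seq_len(n)
            else sort(sample(n, nProbes))
  nnOrig <- .knnIndex(orig, kNeighbors)
  if (is.null(refitScores)) {
    refitScores <- lapply(seq_len(nSeeds), function(r) {
      set.seed(as.integer(seed) + r)
      tr <- sample(n, min(nTrain, n))
      fit <- fitEmbedding(normalized[, tr, drop = FALSE],
                          nComponents = max(4L, ncol(model@loadings)),
                          stableGenes = model@stableGenes,
                          seed = seed + r)
      al <- alignSigns(fit$model, signAnchors(model))
      projectSamples(al, normalized)[, components, drop = FALSE]
    })
  }
  J <- base::matrix(NA_real_, length(probes), length(refitScores))
  for (r in seq_along(refitScores)) {
    nnNew <- .knnIndex(refitScores[[r]], kNeighbors)
    J[, r] <- vapply(seq_along(probes), function(i) {
      p <- probes[i]
      .jaccard(nnOrig[p, ], nnNew[p, ])
    }, numeric(1))
  }
  perProbe <- rowMeans(J)
  names(perProbe) <- colnames(normalized)[probes]
  rownames(J) <- colnames(normalized)[probes]
  list(perProbe = perProbe, matrix = J,
       mean = mean(J), sd = stats::sd(as.vector(J)),
       kNeighbors = kNeighbors, nSeeds = length(refitScores))
}

## pointy-top axial hex coordinates for points (x, y) at hex size s
.hexAxial <- function(x, y, s) {
  q <- (sqrt(3) / 3 * x - y / 3) / s
  r <- (2 / 3 * y) / s
  ## cube rounding
  cx <- q; cz <- r; cy <- -cx - cz
  rx <- round(cx); ry <- round(cy); rz <- round(cz)
  dx <- abs(rx - cx); dy <- abs(ry - cy); dz <- abs(rz - cz)
  fixX <- dx > dy & dx > dz
  fixZ <- !fixX & dz > dy
  rx[fixX] <- -ry[fixX] - rz[fixX]
  rz[fixZ] <- -rx[fixZ] - ry[fixZ]
  cbind(q = rx, r = rz)
}

#' Hexagonal binning of embedding scores with per-cell averages
#'
#' Assigns every sample to exactly one pointy-top hexagonal cell in the
#' (PC3, PC4) plane and averages a per-sample value (e.g. a pathway
#' score) within each cell, preserving the count-weighted grand mean. A
#' weighted linear fit of cell means on cell centers gives the dominant
#' score gradient across the embedding.
#'
#' @param scores sample-by-2 coordinate matrix.
#' @param sampleValues numeric vector of values, one per sample (or named
#'   by sample id).
#' @param hexSize hexagon circumradius; default shrinks from a tenth of
#'   the coordinate range until the densest cell holds at most 5 percent of
#'   samples.
#' @return list: `hexSize`, `cells` (data.frame q, r, cx, cy, count,
#'   mean), `gradient` (unit 2-vector, NA when fewer than 3 cells).
#' @export
hexbinScores <- function(scores, sampleValues, hexSize = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) == 0L)
    return(list(hexSize = hexSize,
                cells = data.frame(q = integer(), r = integer(),
                                   cx = numeric(), cy = numeric(),
                                   count = integer(), mean = numeric()),
                gradient = c(NA_real_, NA_real_)))
  if (!is.null(names(sampleValues)) && !is.null(rownames(scores)))
    sampleValues <- sampleValues[rownames(scores)]
  stopifnot(length(sampleValues) == nrow(scores))
  x <- scores[, 1L]; y <- scores[, 2L]
  if (is.null(hexSize)) {
    span <- max(diff(range(x)), diff(range(y)), .Machine$double.eps)
    hexSize <- span / 10
    for (iter in 1:12) {
      ax <- .hexAxial(x, y, hexSize)
      counts <- table(paste(ax[, 1L], ax[, 2L]))
      if (max(counts) <= max(1, 0.05 * nrow(scores))) break
      hexSize <- hexSize / 2
    }
  }
  ax <- .hexAxial(x, y, hexSize)
  key <- paste(ax[, 1L], ax[, 2L])
  agg <- lapply(split(seq_len(nrow(scores)), key), function(idx) {
    c(q = unname(ax[idx[1L], 1L]), r = unname(ax[idx[1L], 2L]),
      count = length(idx), mean = mean(sampleValues[idx]))
  })
  cells <- as.data.frame(do.call(rbind, agg))
  cells$cx <- hexSize * (sqrt(3) * cells$q + sqrt(3) / 2 * cells$r)
  cells$cy <- hexSize * (3 / 2 * cells$r)
  cells <- cells[, c("q", "r", "cx", "cy", "count", "mean")]
  rownames(cells) <- NULL
  gradient <- c(NA_real_, NA_real_)
  if (nrow(cells) >= 3L) {
    fit <- stats::lm(mean ~ cx + cy, data = cells, weights = cells$count)
    g <- stats::coef(fit)[c("cx", "cy")]
    if (!anyNA(g) && sqrt(sum(g^2)) > 0) gradient <- g / sqrt(sum(g^2))
  }
  list(hexSize = hexSize, cells = cells, gradient = unname(gradient))
}

#' Sensitivity of projections to missing top-loading genes
#'
#' For each fraction f, removes the f top genes ranked by
#' max(|PC3 loading|, |PC4 loading|), re-normalizes among the remaining
#' genes, zero-fills and re-projects, and reports the mean Euclidean
#' displacement in the biology plane plus the mean k-NN Jaccard overlap
#' with the intact projection.
#'
#' @param model an [EmberModel-class].
#' @param matrix raw gene-by-sample matrix of the samples to probe.
#' @param fractions numeric fractions in [0, 1).
#' @param kNeighbors neighborhood size for the Jaccard overlap.
#' @param components biology plane (default PC3/PC4).
#' @return data.frame: fraction, meanDisplacement, meanJaccard.
#' @export
missingGeneSensitivity <- function(model, matrix, fractions,
                                   kNeighbors = 50L,
                                   components = c("PC3", "PC4")) {
  if (any(fractions < 0 | fractions >= 1))
    stop("fractions must lie in [0, 1)")
  L <- model@loadings[, components, drop = FALSE]
  pri <- apply(abs(L), 1L, max)
  ord <- order(-pri)            # most influential genes first
  full <- projectSamples(model, normalizeSamples(model, matrix))
  fullB <- full[, components, drop = FALSE]
  nnFull <- if (nrow(fullB) > kNeighbors) .knnIndex(fullB, kNeighbors)
            else NULL
  rows <- lapply(fractions, function(f) {
    nRemove <- floor(f * length(model@featureGenes))
    drop <- model@featureGenes[ord[seq_len(nRemove)]]
    keepRows <- setdiff(rownames(matrix), drop)
    deg <- projectSamples(model,
                          normalizeSamples(model,
                                           matrix[keepRows, , drop = FALSE]))
    degB <- deg[, components, drop = FALSE]
    disp <- sqrt(rowSums((degB - fullB)^2))
    mj <- if (!is.null(nnFull)) {
      nnDeg <- .knnIndex(degB, kNeighbors)
      mean(vapply(seq_len(nrow(degB)), function(i)
        .jaccard(nnFull[i, ], nnDeg[i, ]), numeric(1)))
    } else NA_real_
    data.frame(fraction = f, meanDisplacement = mean(disp),
               meanJaccard = mj)
  })
  do.call(rbind, rows)
}
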