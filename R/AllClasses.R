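#' @import methods
NULL

#' EmberModel: a fitted cross-platform embedding
#'
#' Holds everything needed to place a new sample into the embedding space:
#' the ordered feature-gene panel (variable genes followed by the stable
#' genes used as the rank-normalization reference), the gene-by-component
#' loading matrix of the uncentered, unscaled PCA, and the per-component
#' sign anchors that make the otherwise arbitrary component signs
#' reproducible across refits.
#'
#' @slot featureGenes character vector; ordered feature panel (variable
#'   genes then stable genes).
#' @slot stableGenes character vector; subset of \code{featureGenes} whose
#'   average per-sample rank is the normalization divisor.
#' @slot loadings numeric matrix, genes x components; columns are unit-norm
#'   and mutually orthogonal; rownames equal \code{featureGenes}.
#' @slot signAnchors data.frame with columns \code{component}, \code{gene},
#'   \code{sign}; each row pins the sign of one loading column.
#' @slot trainingInfo list of training metadata (sample counts per cohort,
#'   seed, anchor fallbacks, normalization scale tag).
#'
#' @seealso [fitEmbedding()], [projectSamples()], [alignSigns()]
#' @export
setClass("EmberModel",
  representation(
    featureGenes = "character",
    stableGenes  = "character",
    loadings     = "matrix",
    signAnchors  = "data.frame",
    trainingInfo = "list"
  )
)

.validEmberModel <- function(object) {
  msg <- character()
  fg <- object@featureGenes
  if (anyDuplicated(fg))
    msg <- c(msg, "duplicated feature genes")
  if (!all(object@stableGenes %in% fg))
    msg <- c(msg, "stable genes must be a subset of feature genes")
  L <- object@loadings
  if (nrow(L) != length(fg))
    msg <- c(msg, "loading rows must match feature genes")
  if (!is.null(rownames(L)) && !identical(rownames(L), fg))
    msg <- c(msg, "loading rownames must equal featureGenes")
  if (ncol(L) < 1L)
    msg <- c(msg, "at least one component required")
  if (ncol(L) >= 1L) {
    G <- crossprod(L)
    if (max(abs(G - diag(ncol(L)))) > 1e-8)
      msg <- c(msg, "loading columns must be orthonormal (tol 1e-8)")
  }
  if (!all(c("component", "gene", "sign") %in% names(object@signAnchors)))
    msg <- c(msg, "signAnchors needs columns component, gene, sign")
  if (length(msg)) msg else TRUE
}
setValidity("EmberModel", .validEmberModel)

#' AsisModel: a full-universe embedding for absolute gene-set scoring
#'
#' Extends [EmberModel-class]: the feature panel is the full shared gene
#' universe (after expression filtering) and \code{batchComponents} lists
#' the components regressed out of every sample before gene-set scores are
#' summed.
#'
#' @slot batchComponents integer vector of component indices treated as
#'   platform/batch directions (default 1:2).
#' @export
setClass("AsisModel",
  contains = "EmberModel",
  representation(batchComponents = "integer"),
  prototype(batchComponents = 1:2)
)

setValidity("AsisModel", function(object) {
  bc <- object@batchComponents
  if (length(bc) < 1L || any(bc < 1L) || any(bc > ncol(object@loadings)))
    return("batchComponents must index retained components")
  TRUE
})

#' PosteriorDraws: MCMC draws of a scalar parameter
#'
#' Container for the posterior samples returned by
#' [neighborhoodPosterior()] and [bayesGroupDifference()].
#'
#' @slot parameter character scalar naming the sampled quantity.
#' @slot draws numeric vector of post-warmup draws, all chains concatenated.
#' @slot chains integer vector of chain labels, one per draw.
#' @slot seed integer seed the sampler was run with.
#' @slot diagnostics list; includes split-chain \code{rhat} and flags
#'   (e.g. \code{prior_only} when no data were supplied).
#' @export
setClass("PosteriorDraws",
  representation(
    parameter   = "character",
    draws       = "numeric",
    chains      = "integer",
    seed        = "integer",
    diagnostics = "list"
  )
)

setValidity("PosteriorDraws", function(object) {
  msg <- character()
  if (length(object@draws) != length(object@chains))
    msg <- c(msg, "one chain label per draw required")
  nc <- length(unique(object@chains))
  if (nc < 2L)
    msg <- c(msg, "at least 2 chains required")
  if (length(unique(table(object@chains))) > 1L)
    msg <- c(msg, "chains must have equal numbers of draws")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @describeIn EmberModel ordered feature-gene panel
#' @param object an \code{EmberModel}
#' @export
setGeneric("featureGenes", function(object) standardGeneric("featureGenes"))
#' @export
setMethod("featureGenes", "EmberModel", function(object) object@featureGenes)

#' @describeIn EmberModel stable-gene (normalization reference) panel
#' @export
setGeneric("stableGenes", function(object) standardGeneric("stableGenes"))
#' @export
setMethod("stableGenes", "EmberModel", function(object) object@stableGenes)

#' Loading matrix of an embedding model
#'
#' @param object an [EmberModel-class]
#' @return numeric matrix, genes x components; rownames are the feature
#'   genes, colnames \code{PC1..PCK}.
#' @export
emberLoadings <- function(object) object@loadings

#' @describeIn EmberModel per-component sign anchors
#' @export
setGeneric("signAnchors", function(object) standardGeneric("signAnchors"))
#' @export
setMethod("signAnchors", "EmberModel", function(object) object@signAnchors)

#' @describeIn EmberModel training metadata list
#' @export
setGeneric("trainingInfo", function(object) standardGeneric("trainingInfo"))
#' @export
setMethod("trainingInfo", "EmberModel", function(object) object@trainingInfo)

#' @describeIn EmberModel number of retained components
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @export
setMethod("nComponents", "EmberModel", function(object) ncol(object@loadings))

#' @describeIn AsisModel the shared gene universe the model embeds
#' @param object an \code{AsisModel}
#' @export
setGeneric("universeGenes", function(object) standardGeneric("universeGenes"))
#' @export
setMethod("universeGenes", "AsisModel", function(object) object@featureGenes)

#' @describeIn AsisModel indices of the components regressed out as batch
#' @export
setGeneric("batchComponents", function(object) standardGeneric("batchComponents"))
#' @export
setMethod("batchComponents", "AsisModel", function(object) object@batchComponents)

setMethod("show", "EmberModel", function(object) {
  cat(sprintf("%s with %d feature genes (%d stable), %d components\n",
              class(object), length(object@featureGenes),
              length(object@stableGenes), ncol(object@loadings)))
  ti <- object@trainingInfo
  if (!is.null(ti$nTrain))
    cat(sprintf("  trained on %d samples\n", ti$nTrain))
  if (is(object, "AsisModel"))
    cat(sprintf("  batch components: %s\n",
                paste0("PC", object@batchComponents, collapse = ", ")))
  invisible(object)
})

setMethod("show", "PosteriorDraws", function(object) {
  cat(sprintf("PosteriorDraws of '%s': %d draws x %d chains (Rhat %.3f)\n",
              object@parameter, length(object@draws),
              length(unique(object@chains)),
              if (is.null(object@diagnostics$rhat)) NA_real_
              else object@diagnostics$rhat))
  q <- stats::quantile(object@draws, c(.025, .5, .975))
  cat(sprintf("  mean %.4f  q2.5 %.4f  median %.4f  q97.5 %.4f\n",
              mean(object@draws), q[1], q[2], q[3]))
  invisible(object)
})
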