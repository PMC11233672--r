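# desk-scale simulation used across test files: same structure as the
# default study, smaller sizes so each fit takes well under a second
smallConfig <- function(seed = 42L, ...) {
  simulationConfig(
    nSamplesPerCohort = 80L,
    nGenes = 300L,
    nStableGenes = 10L,
    programSizes = c(ER = 40L, Proliferation = 40L, EMT = 20L,
                     HER2amp = 20L),
    seed = seed,
    ...
  )
}

smallStudy <- function(seed = 42L, ...) simulateCohorts(smallConfig(seed, ...))

# full small pipeline: selection -> normalization -> embedding -> scores
smallPipeline <- function(study = smallStudy(), nVariable = 150L,
                          nTrain = 120L, seed = 7L) {
  sel <- selectFeatureGenes(study$cohorts, study$stableGenes, nVariable)
  norm <- do.call(cbind, lapply(study$cohorts, rankNormalize,
                                selection = sel))
  set.seed(seed)
  tr <- sample(ncol(norm), nTrain)
  hub <- study$programGenes$ER[1L]
  fit <- fitEmbedding(norm[, tr, drop = FALSE], 4L, study$stableGenes,
                      anchorGene = hub, seed = seed)
  md <- study$metadata[match(colnames(norm), study$metadata$sample_id), ]
  list(study = study, sel = sel, norm = norm, train = tr, fit = fit,
       scores = projectSamples(fit$model, norm), metadata = md,
       hub = hub)
}

# rank-based AUC of a score against a binary truth label
rankAuc <- function(score, positive) {
  r <- rank(score)
  nPos <- sum(positive)
  nNeg <- sum(!positive)
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

expect_same_matrix <- function(a, b, tol = 1e-12) {
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(a - b)), tol)
}
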