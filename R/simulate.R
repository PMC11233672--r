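#' Configuration for the two-cohort synthetic study
#'
#' Defaults emulate the structure the embedding assumes: two cohorts on
#' different measurement platforms sharing one gene universe, five latent
#' intrinsic-subtype groups forming a continuum, an ER-signaling and a
#' proliferation gene program (plus EMT and a HER2-like program), a
#' designated low-variance stable-gene panel, and a strong per-cohort
#' batch effect built from gene-wise affine offsets/scales topped by a
#' strictly monotone per-sample distortion (the rank-neutral part, mimicking
#' the dynamic-range compression of microarrays relative to RNA-seq).
#'
#' @param nSamplesPerCohort samples per cohort (default 600).
#' @param nGenes total genes (default 2000).
#' @param nStableGenes stable reference genes (default 44).
#' @param subtypeProportions named proportions over the 5 subtype groups
#'   (must sum to 1).
#' @param programSizes named sizes of the gene programs.
#' @param subtypeActivity matrix (subtypes x programs) of latent activity
#'   means.
#' @param withinSubtypeSd continuous within-subtype activity spread.
#' @param noiseSd per-gene Gaussian noise sd on the log scale.
#' @param stableNoiseSd noise sd of the stable genes (much smaller).
#' @param baselineMean,baselineSd gene baseline distribution (log scale).
#' @param stableBaselineMean,stableBaselineSd baseline distribution of the
#'   stable genes; housekeeping panels sit near the top of the expression
#'   range, which pins their per-sample ranks and keeps the normalization
#'   divisor steady.
#' @param programLoadingMean,programLoadingSd program gene loading
#'   distribution (loadings are positive: programs are induced gene sets).
#' @param batch list of per-cohort batch descriptors, each with
#'   `baselineCorrelation` (correlation of the platform's effective gene
#'   baseline with the reference baseline; 1 = no probe effect; the
#'   reshuffle preserves the baseline variance, mimicking probe affinity
#'   differences between platforms), `geneScaleSd` (log-normal sd of
#'   gene-wise scale factors) and optional `distortion`
#'   (list(offset, scale, softness) applied per value as
#'   offset + scale * softness * log1p(exp(x / softness)), strictly
#'   increasing and hence rank-neutral).
#' @param seed RNG seed; the whole study is reproducible bitwise.
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(
    nSamplesPerCohort = 600L,
    nGenes = 2000L,
    nStableGenes = 44L,
    subtypeProportions = c(LumA = 0.35, LumB = 0.20, HER2 = 0.15,
                           Basal = 0.20, NormalLike = 0.10),
    programSizes = c(ER = 150L, Proliferation = 150L, EMT = 100L,
                     HER2amp = 100L),
    subtypeActivity = rbind(
      LumA       = c(ER =  1.5, Proliferation = -0.8, EMT = -0.5, HER2amp = -0.5),
      LumB       = c( 1.2,  0.8, -0.3,  0.0),
      HER2       = c(-0.5,  0.6,  0.0,  1.5),
      Basal      = c(-1.5,  1.0,  0.8, -0.5),
      NormalLike = c( 0.3, -1.2,  0.5, -0.5)),
    withinSubtypeSd = 0.35,
    noiseSd = 0.35,
    stableNoiseSd = 0.05,
    baselineMean = 6, baselineSd = 2,
    stableBaselineMean = 10, stableBaselineSd = 0.75,
    programLoadingMean = 1.0, programLoadingSd = 0.15,
    batch = list(
      cohort1 = list(baselineCorrelation = 1, geneScaleSd = 0,
                     distortion = NULL),
      cohort2 = list(baselineCorrelation = 0.75, geneScaleSd = 0.05,
                     distortion = list(offset = 2, scale = 0.8,
                                       softness = 3))),
    seed = 1L) {
  cfg <- list(nSamplesPerCohort = as.integer(nSamplesPerCohort),
              nGenes = as.integer(nGenes),
              nStableGenes = as.integer(nStableGenes),
              subtypeProportions = subtypeProportions,
              programSizes = programSizes,
              subtypeActivity = subtypeActivity,
              withinSubtypeSd = withinSubtypeSd, noiseSd = noiseSd,
              stableNoiseSd = stableNoiseSd,
              baselineMean = baselineMean, baselineSd = baselineSd,
              stableBaselineMean = stableBaselineMean,
              stableBaselineSd = stableBaselineSd,
              programLoadingMean = programLoadingMean,
              programLoadingSd = programLoadingSd,
              batch = batch, seed = as.integer(seed))
  if (abs(sum(cfg$subtypeProportions) - 1) > 1e-8)
    stop("subtype proportions must sum to 1")
  if (any(cfg$subtypeProportions < 0))
    stop("subtype proportions must be non-negative")
  if (cfg$noiseSd <= 0 || cfg$stableNoiseSd <= 0)
    stop("noise sds must be positive")
  if (sum(cfg$programSizes) + cfg$nStableGenes > cfg$nGenes)
    stop("programs plus stable genes exceed the gene count")
  if (!identical(rownames(cfg$subtypeActivity),
                 names(cfg$subtypeProportions)))
    stop("subtypeActivity rows must match subtypeProportions names")
  if (is.null(names(cfg$programSizes)) ||
      length(cfg$programSizes) != ncol(cfg$subtypeActivity))
    stop("programSizes must be named, one per subtypeActivity column")
  class(cfg) <- "SimulationConfig"
  cfg
}

.softplusDistort <- function(x, d)
  d$offset + d$scale * d$softness * log1p(exp(x / d$softness))

#' Simulate a multi-cohort expression study with ground truth
#'
#' Base log-expression is gene baseline + program loadings x per-sample
#' latent activities + Gaussian noise; latent activities are drawn per
#' sample around subtype means, giving a continuum rather than discrete
#' clusters. Stable genes carry no program signal and minimal noise.
#' Each cohort then applies its gene-wise affine batch effect (the part
#' that shifts gene rankings between platforms) followed by a strictly
#' monotone per-sample distortion (rank-neutral). The matrices before the
#' monotone distortion are kept in `predistorted` so rank-invariance can
#' be asserted exactly.
#'
#' ER status is positive when the latent ER activity exceeds 0; a
#' responder label is drawn with probability increasing in ER activity
#' and decreasing in proliferation, mimicking endocrine-therapy response.
#'
#' @param config a [simulationConfig()] result.
#' @return a `SimulatedStudy` list: `cohorts` (named list of matrices),
#'   `predistorted`, `metadata` (sample_id, cohort, subtype, er_status,
#'   response), `activities` (samples x programs), `programGenes`,
#'   `stableGenes`, `config`.
#' @export
simulateCohorts <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  nG <- config$nGenes; nS <- config$nStableGenes
  genes <- sprintf("G%05d", seq_len(nG))
  stable <- sprintf("STB%03d", seq_len(nS))
  genes[seq_len(nS)] <- stable
  baseline <- stats::rnorm(nG, config$baselineMean, config$baselineSd)
  ## stable genes: high-expressed, like real housekeeping panels; program
  ## genes rarely cross their ranks, so the normalization divisor is steady
  baseline[seq_len(nS)] <- stats::rnorm(nS, config$stableBaselineMean,
                                        config$stableBaselineSd)

  progNames <- names(config$programSizes)
  pool <- setdiff(seq_len(nG), seq_len(nS))
  programGenes <- list()
  W <- base::matrix(0, nG, length(progNames),
                    dimnames = list(genes, progNames))
  for (p in progNames) {
    gi <- sample(pool, config$programSizes[[p]])
    pool <- setdiff(pool, gi)
    programGenes[[p]] <- genes[gi]
    W[gi, p] <- abs(stats::rnorm(length(gi), config$programLoadingMean,
                                 config$programLoadingSd))
  }

  nCohorts <- length(config$batch)
  subtypes <- names(config$subtypeProportions)
  cohorts <- predistorted <- list()
  meta <- list(); acts <- list()
  for (ci in seq_len(nCohorts)) {
    b <- config$batch[[ci]]
    n <- config$nSamplesPerCohort
    st <- sample(subtypes, n, replace = TRUE,
                 prob = config$subtypeProportions)
    A <- config$subtypeActivity[st, , drop = FALSE] +
      base::matrix(stats::rnorm(n * length(progNames), 0,
                                config$withinSubtypeSd),
                   n, length(progNames))
    X <- base::matrix(baseline, nG, n) + W %*% t(A)
    noise <- rbind(
      base::matrix(stats::rnorm(nS * n, 0, config$stableNoiseSd), nS, n),
      base::matrix(stats::rnorm((nG - nS) * n, 0, config$noiseSd),
                   nG - nS, n))
    X <- X + noise
    ## gene-wise affine platform effect (fixed per cohort): the effective
    ## baseline on this platform is a correlated Gaussian with the same
    ## spread as the reference baseline (probe-affinity reshuffle without
    ## dynamic-range stretching), plus gene-wise scale factors
    r <- b$baselineCorrelation %||% 1
    if (r < 1 || b$geneScaleSd > 0) {
      alpha <- (r - 1) * (baseline - mean(baseline)) +
        sqrt(1 - r^2) * stats::sd(baseline) * stats::rnorm(nG)
      beta <- exp(stats::rnorm(nG, 0, b$geneScaleSd))
      X <- alpha + beta * X
    }
    ids <- sprintf("C%d_S%04d", ci, seq_len(n))
    dimnames(X) <- list(genes, ids)
    predistorted[[ci]] <- X
    Xd <- if (is.null(b$distortion)) X
          else .softplusDistort(X, b$distortion)
    dimnames(Xd) <- dimnames(X)
    cohorts[[ci]] <- Xd
    er <- ifelse(A[, "ER"] > 0, "positive", "negative")
    pResp <- stats::plogis(1.2 * A[, "ER"] - 0.3 * A[, "Proliferation"])
    resp <- ifelse(stats::runif(n) < pResp, "responder", "non-responder")
    meta[[ci]] <- data.frame(sample_id = ids,
                             cohort = paste0("cohort", ci),
                             subtype = st, er_status = er,
                             response = resp, stringsAsFactors = FALSE)
    rownames(A) <- ids
    acts[[ci]] <- A
  }
  names(cohorts) <- names(predistorted) <- paste0("cohort", seq_len(nCohorts))
  study <- list(cohorts = cohorts, predistorted = predistorted,
                metadata = do.call(rbind, meta),
                activities = do.call(rbind, acts),
                programGenes = programGenes,
                stableGenes = stable, config = config)
  class(study) <- "SimulatedStudy"
  study
}

#' Remove genes from designated samples of a simulated study
#'
#' Supports the missing-gene sensitivity protocol: genes are removed
#' per sample either at random or by top PC3/PC4 loading (which requires
#' a fitted model), and the removal sets are recorded.
#'
#' @param study a `SimulatedStudy`.
#' @param missingFraction fraction of the gene universe to remove, in
#'   [0, 1).
#' @param rule `"random"` or `"top-loading"`.
#' @param model an [EmberModel-class]; required for `"top-loading"`.
#' @param samples sample ids to degrade (default: all).
#' @param seed RNG seed for the random rule.
#' @return the study with an added `removedGenes` element (named list
#'   sample -> character vector). Removing every stable gene is an error.
#' @export
degradeStudy <- function(study, missingFraction, rule = c("random",
                                                          "top-loading"),
                         model = NULL, samples = NULL, seed = 1L) {
  rule <- match.arg(rule)
  if (missingFraction < 0 || missingFraction >= 1)
    stop("missingFraction must lie in [0, 1)")
  allGenes <- rownames(study$cohorts[[1L]])
  nRemove <- floor(missingFraction * length(allGenes))
  if (is.null(samples)) samples <- study$metadata$sample_id
  removed <- list()
  if (rule == "top-loading") {
    if (is.null(model)) stop("top-loading rule requires a fitted model")
    L <- model@loadings[, intersect(c("PC3", "PC4"),
                                    colnames(model@loadings)),
                        drop = FALSE]
    pri <- apply(abs(L), 1L, max)
    drop <- names(sort(pri, decreasing = TRUE))[seq_len(
      min(nRemove, length(pri)))]
    for (s in samples) removed[[s]] <- drop
  } else {
    set.seed(as.integer(seed))
    for (s in samples) removed[[s]] <- sample(allGenes, nRemove)
  }
  for (s in samples) {
    if (all(study$stableGenes %in% removed[[s]]))
      stop("degradation would remove every stable gene for sample ", s)
  }
  study$removedGenes <- removed
  study
}

#' @export
print.SimulatedStudy <- function(x, ...) {
  cat(sprintf("SimulatedStudy: %d cohorts x %d samples, %d genes (%d stable)\n",
              length(x$cohorts), ncol(x$cohorts[[1L]]),
              nrow(x$cohorts[[1L]]), length(x$stableGenes)))
  invisible(x)
}
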