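## ---- internal Gibbs sampler for the Normal mean ----
## model: y ~ Normal(mu, sigma); mu ~ Normal(priorMean, priorSd);
## sigma ~ Exponential(1). mu is a conjugate update given sigma; sigma is
## updated by a random-walk Metropolis step on log(sigma).
.gibbsNormalMean <- function(y, nChains = 4L, nDraws = 1000L,
                             warmup = 500L, seed = 1L,
                             priorMean = 0, priorSd = 1, sigmaRate = 1) {
  n <- length(y)
  sy <- sum(y); ssy <- sum(y^2)
  drawsAll <- vector("list", nChains)
  set.seed(as.integer(seed))
  for (ch in seq_len(nChains)) {
    if (n == 0L) {
      ## no data: the posterior IS the prior
      drawsAll[[ch]] <- stats::rnorm(nDraws, priorMean, priorSd)
      next
    }
    mu <- mean(y)
    sigma <- max(stats::sd(y), 1e-3)
    if (is.na(sigma)) sigma <- 1
    keep <- numeric(nDraws)
    total <- warmup + nDraws
    for (it in seq_len(total)) {
      ## conjugate mu update
      prec <- n / sigma^2 + 1 / priorSd^2
      m <- (sy / sigma^2 + priorMean / priorSd^2) / prec
      mu <- stats::rnorm(1L, m, sqrt(1 / prec))
      ## MH update of sigma on the log scale (Jacobian included)
      ss <- ssy - 2 * mu * sy + n * mu^2
      lp <- function(s) -n * log(s) - ss / (2 * s^2) - sigmaRate * s + log(s)
      prop <- sigma * exp(stats::rnorm(1L, 0, 0.35))
      if (log(stats::runif(1L)) < lp(prop) - lp(sigma)) sigma <- prop
      if (it > warmup) keep[it - warmup] <- mu
    }
    drawsAll[[ch]] <- keep
  }
  list(draws = unlist(drawsAll),
       chains = rep(seq_len(nChains), each = nDraws))
}

## split-chain potential scale reduction factor
.splitRhat <- function(draws, chains) {
  split <- unlist(lapply(split(draws, chains), function(d) {
    h <- length(d) %/% 2L
    list(d[seq_len(h)], d[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(split); n <- length(split[[1L]])
  means <- vapply(split, mean, numeric(1))
  vars <- vapply(split, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Samples within a fixed radius in the biology components
#'
#' Members are all samples whose Euclidean distance to the center in the
#' (PC3, PC4) plane is at most `radius`; the center itself is excluded.
#'
#' @param scores sample-by-component score matrix with rownames.
#' @param center sample id of the neighborhood center.
#' @param radius inclusion radius (default 1, in embedding score units).
#' @param components columns to measure distance in (default PC3, PC4).
#' @return list: `center`, `radius`, `members` (ids), `distances` (named,
#'   members only), `empty` flag.
#' @export
findNeighborhood <- function(scores, center, radius = 1,
                             components = c("PC3", "PC4")) {
  if (!center %in% rownames(scores)) stop("unknown center sample: ", center)
  if (!all(components %in% colnames(scores)))
    stop("score matrix lacks components: ",
         paste(setdiff(components, colnames(scores)), collapse = ", "))
  S <- scores[, components, drop = FALSE]
  d <- sqrt(rowSums((S - base::matrix(S[center, ], nrow(S), ncol(S),
                                      byrow = TRUE))^2))
  members <- setdiff(rownames(scores)[d <= radius], center)
  list(center = center, radius = radius, members = members,
       distances = d[members], empty = length(members) == 0L)
}

#' Posterior of a neighborhood's mean pathway score
#'
#' Intercept-only Bayesian regression (score ~ 1) of the member scores
#' with prior Normal(0, 1) on the mean and Exponential(1) on the residual
#' scale, sampled with 4 chains by default. With no members the prior is
#' returned as a degenerate posterior and flagged.
#'
#' @param memberScores numeric vector of scores of the neighborhood
#'   members (may be empty).
#' @param nChains number of chains (>= 2).
#' @param nDraws post-warmup draws per chain.
#' @param warmup warmup iterations per chain.
#' @param seed RNG seed; draws are bitwise reproducible for a fixed seed
#'   and chain count.
#' @return a [PosteriorDraws-class] for the neighborhood mean.
#' @export
neighborhoodPosterior <- function(memberScores, nChains = 4L,
                                  nDraws = 1000L, warmup = 500L,
                                  seed = 1L) {
  memberScores <- memberScores[!is.na(memberScores)]
  g <- .gibbsNormalMean(memberScores, nChains = nChains, nDraws = nDraws,
                        warmup = warmup, seed = seed)
  new("PosteriorDraws", parameter = "neighborhood mean",
      draws = g$draws, chains = as.integer(g$chains),
      seed = as.integer(seed),
      diagnostics = list(rhat = .splitRhat(g$draws, g$chains),
                         n = length(memberScores),
                         prior_only = length(memberScores) == 0L))
}

#' Classify a sample score against a neighborhood posterior
#'
#' `"above"` if the score exceeds the upper tail quantile of the draws,
#' `"below"` if it falls under the lower tail quantile, `"middle"`
#' otherwise. Inequalities are strict, so a score exactly at a quantile is
#' `"middle"`.
#'
#' @param sampleScore numeric scalar.
#' @param posterior a [PosteriorDraws-class].
#' @param tail tail mass on each side (default 0.025, i.e. the central
#'   95 percent interval counts as middle).
#' @return one of `"above"`, `"middle"`, `"below"`.
#' @export
classifyRelative <- function(sampleScore, posterior, tail = 0.025) {
  d <- posterior@draws
  lo <- stats::quantile(d, tail, names = FALSE)
  hi <- stats::quantile(d, 1 - tail, names = FALSE)
  if (sampleScore > hi) "above"
  else if (sampleScore < lo) "below"
  else "middle"
}

#' Responder/non-responder pairs close in the embedding
#'
#' All cross-label pairs whose Euclidean distance in the (PC3, PC4) plane
#' satisfies the threshold; a sample may appear in several pairs.
#'
#' @param scores sample-by-component score matrix with rownames.
#' @param labels named character vector (`"responder"`/`"non-responder"`),
#'   names are sample ids.
#' @param maxDist pairing threshold (default 0.5).
#' @param strict if TRUE (default) use `distance < maxDist`, else `<=`.
#' @param components columns used for the distance.
#' @return data.frame: `responder_id`, `nonresponder_id`, `distance`;
#'   zero rows when no pair qualifies.
#' @export
findPairs <- function(scores, labels, maxDist = 0.5, strict = TRUE,
                      components = c("PC3", "PC4")) {
  labels <- labels[names(labels) %in% rownames(scores)]
  resp <- names(labels)[labels == "responder"]
  nonr <- names(labels)[labels == "non-responder"]
  if (!length(resp) || !length(nonr))
    stop("both responder and non-responder labels are required")
  S <- scores[, components, drop = FALSE]
  out <- list()
  for (r in resp) {
    d <- sqrt(rowSums((S[nonr, , drop = FALSE] -
                       base::matrix(S[r, ], length(nonr), ncol(S),
                                    byrow = TRUE))^2))
    hit <- if (strict) d < maxDist else d <= maxDist
    if (any(hit))
      out[[r]] <- data.frame(responder_id = r,
                             nonresponder_id = nonr[hit],
                             distance = unname(d[hit]),
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(responder_id = character(),
                      nonresponder_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pathway-contrast rule for a responder/non-responder pair
#'
#' `"low-in-nonresponder"`: yes iff the non-responder is below its
#' neighborhood distribution while the responder is middle or above.
#' `"high-in-nonresponder"`: yes iff the non-responder is above while the
#' responder is middle or below.
#'
#' @param responderCall,nonresponderCall calls from [classifyRelative()]
#'   for the same pathway.
#' @param direction `"low-in-nonresponder"` or `"high-in-nonresponder"`.
#' @return logical.
#' @export
pairRule <- function(responderCall, nonresponderCall,
                     direction = c("low-in-nonresponder",
                                   "high-in-nonresponder")) {
  direction <- match.arg(direction)
  calls <- c("above", "middle", "below")
  stopifnot(responderCall %in% calls, nonresponderCall %in% calls)
  if (direction == "low-in-nonresponder")
    nonresponderCall == "below" && responderCall %in% c("middle", "above")
  else
    nonresponderCall == "above" && responderCall %in% c("middle", "below")
}

#' Bayesian two-group difference of scores
#'
#' Regression of score on a group indicator with priors Normal(0, 1) on
#' both group means and Exponential(1) on the shared residual scale,
#' Gibbs-sampled. Reports the posterior draws of the difference
#' (mean of B minus mean of A), the probability of a difference (largest
#' one-sided sign fraction), and percentile-wise differences of the two
#' posterior predictive distributions. Internally the two groups are
#' processed in a canonical order, so swapping the arguments negates the
#' difference draws exactly.
#'
#' @param scoresA,scoresB numeric score vectors for the two groups
#'   (non-empty).
#' @param nChains,nDraws,warmup,seed sampler controls as in
#'   [neighborhoodPosterior()].
#' @param percentiles percentiles (in (0,1)) at which predictive
#'   distributions are differenced.
#' @return list: `posterior` (a [PosteriorDraws-class] of the difference),
#'   `meanDifference`, `probDifference`, `predictiveDifferences`
#'   (data.frame percentile/difference), `flaggedWide` (TRUE when either
#'   group has a single observation).
#' @export
bayesGroupDifference <- function(scoresA, scoresB, nChains = 4L,
                                 nDraws = 1000L, warmup = 500L, seed = 1L,
                                 percentiles = seq(0.01, 0.99, by = 0.01)) {
  if (!length(scoresA) || !length(scoresB))
    stop("both groups must be non-empty")
  ## canonical internal order makes label swaps exactly antisymmetric
  keyOf <- function(x) paste(length(x), format(sum(x), digits = 17),
                             format(x[1L], digits = 17))
  swapped <- keyOf(scoresA) > keyOf(scoresB)
  g1 <- if (swapped) scoresB else scoresA
  g2 <- if (swapped) scoresA else scoresB
  n1 <- length(g1); n2 <- length(g2)
  s1 <- sum(g1); s2 <- sum(g2)
  ss <- sum(g1^2) + sum(g2^2)
  total <- warmup + nDraws
  dAll <- sigAll <- m1All <- vector("list", nChains)
  set.seed(as.integer(seed))
  for (ch in seq_len(nChains)) {
    mu1 <- mean(g1); mu2 <- mean(g2)
    sigma <- max(stats::sd(c(g1 - mu1, g2 - mu2)), 1e-3)
    if (is.na(sigma)) sigma <- 1
    kd <- ks <- km <- numeric(nDraws)
    for (it in seq_len(total)) {
      for (g in 1:2) {
        n <- if (g == 1L) n1 else n2
        sy <- if (g == 1L) s1 else s2
        prec <- n / sigma^2 + 1
        m <- (sy / sigma^2) / prec
        if (g == 1L) mu1 <- stats::rnorm(1L, m, sqrt(1 / prec))
        else mu2 <- stats::rnorm(1L, m, sqrt(1 / prec))
      }
      ssq <- ss - 2 * mu1 * s1 + n1 * mu1^2 - 2 * mu2 * s2 + n2 * mu2^2
      n <- n1 + n2
      lp <- function(s) -n * log(s) - ssq / (2 * s^2) - s + log(s)
      prop <- sigma * exp(stats::rnorm(1L, 0, 0.35))
      if (log(stats::runif(1L)) < lp(prop) - lp(sigma)) sigma <- prop
      if (it > warmup) {
        kd[it - warmup] <- mu2 - mu1
        ks[it - warmup] <- sigma
        km[it - warmup] <- mu1
      }
    }
    dAll[[ch]] <- kd; sigAll[[ch]] <- ks; m1All[[ch]] <- km
  }
  d <- unlist(dAll)
  if (swapped) d <- -d
  chains <- rep(seq_len(nChains), each = nDraws)
  post <- new("PosteriorDraws", parameter = "group difference",
              draws = d, chains = as.integer(chains),
              seed = as.integer(seed),
              diagnostics = list(rhat = .splitRhat(d, chains),
                                 nA = length(scoresA), nB = length(scoresB)))
  ## percentile-wise difference of posterior predictive distributions
  sig <- unlist(sigAll); m1 <- unlist(m1All)
  m2 <- m1 + unlist(dAll)
  z <- stats::qnorm(percentiles)
  predDiff <- vapply(seq_along(percentiles), function(i) {
    qB <- mean(m2 + sig * z[i]); qA <- mean(m1 + sig * z[i])
    if (swapped) qA - qB else qB - qA
  }, numeric(1))
  list(posterior = post,
       meanDifference = mean(d),
       probDifference = max(mean(d > 0), mean(d < 0)),
       predictiveDifferences = data.frame(percentile = percentiles,
                                          difference = predDiff),
       flaggedWide = length(scoresA) == 1L || length(scoresB) == 1L)
}
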