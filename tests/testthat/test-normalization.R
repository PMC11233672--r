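test_that("coefficient of variation matches hand arithmetic", {
  m <- rbind(const = c(5, 5, 5, 5),
             two = c(1, 3, 1, 3),
             zero = c(0, 0, 0, 0))
  colnames(m) <- paste0("S", 1:4)
  cv <- computeCV(m)
  expect_equal(cv[["const"]], 0)
  expect_true(is.na(cv[["zero"]]))

  m2 <- rbind(g = c(1, 3)); colnames(m2) <- c("S1", "S2")
  # sd with n-1 denominator = sqrt(2), mean 2
  expect_equal(computeCV(m2)[["g"]], sqrt(2) / 2, tolerance = 1e-12)

  expect_error(computeCV(m[, 1, drop = FALSE]), "2 samples")
})

test_that("CV is scale-invariant but not shift-invariant", {
  set.seed(3)
  m <- matrix(abs(rnorm(50, 5, 2)), 10, 5,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  expect_equal(computeCV(10 * m), computeCV(m), tolerance = 1e-12)
  shifted <- computeCV(m + 4)
  expect_false(isTRUE(all.equal(shifted, computeCV(m))))
})

test_that("feature selection ranks genes by mean CV with stable genes last", {
  set.seed(11)
  genes <- paste0("g", 1:10)
  mk <- function() {
    m <- matrix(abs(rnorm(10 * 6, 5, 1)) + rep(seq(0.1, 5, length.out = 10), 6),
                10, 6, dimnames = list(genes, paste0("s", 1:6)))
    m[c("g9", "g10"), ] <- 5 + matrix(rnorm(12, 0, 0.01), 2, 6)  # stable
    m
  }
  c1 <- mk(); c2 <- mk()
  sel <- selectFeatureGenes(list(c1, c2), c("g9", "g10"), nVariable = 3L)
  expect_length(sel$featureGenes, 5L)
  expect_identical(tail(sel$featureGenes, 2L), c("g9", "g10"))
  # brute-force oracle: unweighted mean of per-cohort CVs on candidates
  cv <- (apply(c1, 1, sd) / rowMeans(c1) + apply(c2, 1, sd) / rowMeans(c2)) / 2
  cand <- setdiff(genes, c("g9", "g10"))
  expect_setequal(sel$variableGenes, cand[order(-cv[cand])][1:3])

  # identical cohorts duplicated give the single-cohort selection
  selDup <- selectFeatureGenes(list(c1, c1, c1), c("g9", "g10"), 3L)
  sel1 <- selectFeatureGenes(list(c1), c("g9", "g10"), 3L)
  expect_identical(selDup$featureGenes, sel1$featureGenes)

  # permutation invariance in gene and sample order
  perm <- sample(10); permS <- sample(6)
  selP <- selectFeatureGenes(list(c1[perm, permS], c2[perm, ]),
                             c("g9", "g10"), 3L)
  expect_identical(selP$featureGenes, sel$featureGenes)

  expect_error(selectFeatureGenes(list(c1[1:8, ], c2), c("g9", "g10"), 3L),
               "g9|g10")
  expect_error(selectFeatureGenes(list(c1, c2), c("g9", "g10"), 1000L),
               "candidate genes")
})

test_that("rank normalization matches the hand-computed example", {
  m <- matrix(c(10, 2, 7, 1, 5), 5, 1,
              dimnames = list(paste0("g", 1:5), "s1"))
  sel <- list(featureGenes = paste0("g", 1:5),
              stableGenes = c("g4", "g3"))
  # ranks [5,2,4,1,3]; stable mean rank (1+4)/2 = 2.5
  out <- rankNormalize(m, sel)
  expect_equal(out[, 1], c(g1 = 2.0, g2 = 0.8, g3 = 1.6, g4 = 0.4,
                           g5 = 1.2))
})

test_that("rank normalization is exactly invariant to per-sample monotone transforms", {
  set.seed(5)
  m <- matrix(rnorm(40 * 8, 6, 2), 40, 8,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:8)))
  sel <- list(featureGenes = paste0("g", 1:40),
              stableGenes = paste0("g", 37:40))
  base <- rankNormalize(m, sel)
  expect_identical(rankNormalize(exp(m / 3), sel), base)
  # a different strictly increasing transform per sample
  m2 <- m
  for (j in 1:8) m2[, j] <- j + (j + 1) * m[, j]^3
  expect_identical(rankNormalize(m2, sel), base)
  # ties get average ranks, preserving the stable-gene mean
  m3 <- m; m3[1:4, 1] <- 42
  expect_equal(colMeans(rankNormalize(m3, sel)[sel$stableGenes, ]),
               setNames(rep(1, 8), paste0("s", 1:8)))
})

test_that("stable-gene mean is exactly 1 per sample and values are positive", {
  st <- smallStudy()
  sel <- selectFeatureGenes(st$cohorts, st$stableGenes, 100L)
  for (X in st$cohorts) {
    n <- rankNormalize(X, sel)
    expect_true(all(n > 0))
    expect_equal(unname(colMeans(n[sel$stableGenes, ])),
                 rep(1, ncol(n)), tolerance = 1e-14)
    # per-sample maximum bounded by panel size over mean stable rank
    stabIdx <- match(sel$stableGenes, sel$featureGenes)
    bound <- apply(X[sel$featureGenes, ], 2, function(v)
      length(sel$featureGenes) / mean(rank(v)[stabIdx]))
    expect_true(all(apply(n, 2, max) <= bound + 1e-9))
  }
  expect_error(rankNormalize(st$cohorts[[1]][-1, ], sel),
               "normalizeSamples")
})

test_that("stable-subset renormalization sweep matches brute force", {
  set.seed(9)
  m <- matrix(rnorm(30 * 6, 5, 2), 30, 6,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:6)))
  sel <- list(featureGenes = paste0("g", 1:30),
              stableGenes = paste0("g", 27:30),
              variableGenes = paste0("g", 1:26))

  # full subset: identity renormalization, all correlations 1
  swFull <- stableGeneCountSweep(m, sel, subsetSizes = 4L, nDraws = 2L,
                                 seed = 1L)
  expect_equal(swFull$minCor, rep(1, 2))

  # 2-of-4 subsets: replicate the function's RNG stream and recompute
  # every quantile directly from ranks and divisors
  sw <- stableGeneCountSweep(m, sel, subsetSizes = 2L, nDraws = 3L,
                             seed = 123L, probs = 0.10)
  R <- apply(m, 2, rank)
  full <- sweep(R, 2, colMeans(R[27:30, ]), "/")
  set.seed(123L)
  for (d in 1:3) {
    sub <- sample(sel$stableGenes, 2L)
    renorm <- sweep(R, 2, colMeans(R[sub, , drop = FALSE]), "/")
    cors <- sapply(1:26, function(g) cor(full[g, ], renorm[g, ],
                                         method = "spearman"))
    expect_equal(sw$minCor[d], min(cors), tolerance = 1e-12)
    expect_equal(sw$q10[d], unname(quantile(cors, 0.10)),
                 tolerance = 1e-12)
  }

  expect_error(stableGeneCountSweep(m, sel, subsetSizes = 1L), ">= 2")
})
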