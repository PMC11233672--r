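test_that("a rank-1 matrix is captured exactly by one component", {
  v <- c(3, 1, 4, 1, 5) / sqrt(sum(c(3, 1, 4, 1, 5)^2))
  coefs <- c(2, 5, 7, 1)
  X <- outer(v, coefs)
  dimnames(X) <- list(paste0("g", 1:5), paste0("s", 1:4))
  fit <- fitEmbedding(X, nComponents = 1L, stableGenes = "g1")
  # scores proportional to sample norms, reconstruction exact
  expect_equal(unname(fit$scores[, 1]), coefs, tolerance = 1e-10)
  recon <- emberLoadings(fit$model) %*% t(fit$scores)
  expect_lt(max(abs(recon - X)), 1e-10)
})

test_that("training scores equal projection of the training samples", {
  pl <- smallPipeline()
  reproj <- projectSamples(pl$fit$model, pl$norm[, pl$train, drop = FALSE])
  expect_lt(max(abs(reproj - pl$fit$scores)), 1e-10)
})

test_that("loadings are orthonormal and captured variance is non-increasing", {
  pl <- smallPipeline()
  L <- emberLoadings(pl$fit$model)
  expect_lt(max(abs(crossprod(L) - diag(4))), 1e-8)
  d <- trainingInfo(pl$fit$model)$singularValues
  expect_true(all(diff(d) <= 0))
})

test_that("projection is linear and handles missing genes by zero-fill", {
  pl <- smallPipeline()
  m <- pl$fit$model
  x <- pl$norm[, 1]; y <- pl$norm[, 2]
  lhs <- projectSamples(m, 2 * x - 0.5 * y)
  rhs <- 2 * projectSamples(m, x) - 0.5 * projectSamples(m, y)
  expect_lt(max(abs(lhs - rhs)), 1e-10)

  # one-gene sample: coordinates are that gene's loading row scaled
  g <- featureGenes(m)[3]
  one <- setNames(1.7, g)
  expect_equal(unname(projectSamples(m, one)[1, ]),
               unname(1.7 * emberLoadings(m)[g, ]), tolerance = 1e-12)
  expect_match(attr(projectSamples(m, one), "missingWarning"), "missing")

  # zero-filling 0% of genes equals full projection exactly
  full <- projectSamples(m, pl$norm[, 1:3])
  again <- projectSamples(m, normalizeSamples(m, pl$study$cohorts[[1]][, 1:3]))
  expect_identical(dim(full), dim(again))

  expect_error(projectSamples(m, setNames(1, "NOT_A_GENE")), "no genes")
})

test_that("re-ranking among available genes reproduces projection after zero-fill", {
  pl <- smallPipeline()
  m <- pl$fit$model
  raw <- pl$study$cohorts[[1]][, 1:5]
  nFull <- normalizeSamples(m, raw)
  expect_equal(attr(nFull, "missingFraction"), 0)
  # with no missing genes the tolerant normalizer equals the strict one
  expect_equal(unclass(nFull)[, ], rankNormalize(raw, pl$sel)[, ],
               tolerance = 1e-14, ignore_attr = TRUE)
  # dropping non-stable panel genes re-ranks and zero-fills
  drop <- setdiff(featureGenes(m), stableGenes(m))[1:20]
  nDeg <- normalizeSamples(m, raw[setdiff(rownames(raw), drop), ])
  expect_true(all(nDeg[drop, ] == 0))
  expect_equal(attr(nDeg, "missingFraction"), 20 / length(featureGenes(m)))
})

test_that("sign alignment is idempotent and resolves reflections", {
  pl <- smallPipeline()
  m <- pl$fit$model
  once <- alignSigns(m)
  twice <- alignSigns(once)
  expect_identical(emberLoadings(once), emberLoadings(twice))
  expect_identical(emberLoadings(once), emberLoadings(m))  # already anchored

  # refit on a different training subset, align to the original anchors:
  # the biology axis must point the same way (positive PC3 correlation)
  set.seed(99)
  tr2 <- sample(ncol(pl$norm), 120L)
  fit2 <- fitEmbedding(pl$norm[, tr2], 4L, pl$study$stableGenes, seed = 99)
  al2 <- alignSigns(fit2$model, signAnchors(m))
  s2 <- projectSamples(al2, pl$norm)
  expect_gt(cor(s2[, 3], pl$scores[, 3]), 0.5)

  # negating the data only flips component orientations: after aligning
  # to the same anchors, loadings agree up to machine precision
  fitNeg <- fitEmbedding(-pl$norm[, pl$train], 4L, pl$study$stableGenes)
  alNeg <- alignSigns(fitNeg$model, signAnchors(m))
  expect_lt(max(abs(abs(emberLoadings(alNeg)) - abs(emberLoadings(m)))),
            1e-8)
  for (k in 1:4) {
    g <- signAnchors(m)$gene[k]
    expect_identical(sign(emberLoadings(alNeg)[g, k]),
                     signAnchors(m)$sign[k])
  }

  expect_error(alignSigns(m, data.frame(component = "PC9", gene = "x",
                                        sign = 1)), "unknown component")
})

test_that("exact low-rank batch + biology makes the scaled-PCA equivalence exact", {
  # orthonormal gene basis with equal |entries| (normalized Hadamard), so
  # per-gene variances are equal and unit-variance scaling is uniform
  H2 <- matrix(c(1, 1, 1, -1), 2)
  H8 <- kronecker(kronecker(H2, H2), H2) / sqrt(8)
  H16 <- kronecker(kronecker(H2, H2), kronecker(H2, H2))
  U <- H8                       # genes x basis
  # sample coefficients: constant mean direction + three exactly
  # orthogonal centered directions with decreasing norms
  C <- cbind(rep(10, 16), 3 * H16[, 2] / 4, 2 * H16[, 3] / 4,
             1 * H16[, 4] / 4)
  X <- U[, 1:4] %*% t(C)        # genes x samples
  dimnames(X) <- list(paste0("g", 1:8), paste0("s", 1:16))
  fit <- fitEmbedding(X, 4L, stableGenes = "g1")
  eq <- scaledPcaEquivalence(X, fit$model)
  expect_equal(eq$pc3VsScaledPc2, 1, tolerance = 1e-8)
  expect_equal(eq$pc4VsScaledPc3, 1, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(1, 5, 3, dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  expect_error(fitEmbedding(X, 3L, stableGenes = "g1"), "rank")
  expect_error(fitEmbedding(X[, 1, drop = FALSE], 2L, stableGenes = "g1"),
               "samples")
})
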