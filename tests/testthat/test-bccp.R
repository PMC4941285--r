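test_that("fitBCCP orients weights and class means by construction", {
  x <- matrix(c(0, 0.001, 1, 1.001), 1,
              dimnames = list("g1", paste0("s", 1:4)))
  fit <- fitBCCP(x, c("epithelial", "epithelial",
                      "mesenchymal", "mesenchymal"))
  expect_gt(bccpWeights(fit)[["g1"]], 0)
  expect_gt(classMeans(fit)[["mesenchymal"]],
            classMeans(fit)[["epithelial"]])
  expect_equal(sum(classPriors(fit)), 1)
})

test_that("degenerate training data is rejected", {
  x <- matrix(1, 3, 6, dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  lab <- rep(c("epithelial", "mesenchymal"), each = 3)
  expect_error(suppressWarnings(fitBCCP(x, lab)), "degenerate")
  expect_error(fitBCCP(x[, 1:3, drop = FALSE], lab[c(1, 1, 4)]),
               "at least 2 samples")
})

test_that("genes at the variance floor are dropped with a warning", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40), 4), rep(2, 10))
  rownames(x) <- paste0("g", 1:5); colnames(x) <- paste0("s", 1:10)
  lab <- rep(c("epithelial", "mesenchymal"), each = 5)
  expect_warning(fit <- fitBCCP(x, lab), "variance floor")
  expect_setequal(bccpGenes(fit), paste0("g", 1:4))
})

test_that("posterior matches the closed-form Gaussian Bayes rule", {
  m <- unitModel(mE = -1, mM = 1, s = 1)
  pr <- predictEMT(m, unitMatrix(c(0, 1)))
  expect_equal(pr$posterior[1], 0.5)
  # phi(0) / (phi(0) + phi(2))
  expect_equal(pr$posterior[2], dnorm(0) / (dnorm(0) + dnorm(2)),
               tolerance = 1e-12)
  # far-separated classes saturate the posterior
  m10 <- unitModel(mE = -5, mM = 5, s = 1)
  expect_equal(predictEMT(m10, unitMatrix(5))$posterior, 1,
               tolerance = 1e-10)
})

test_that("posterior is a probability, monotone in the compound covariate", {
  set.seed(5)
  for (i in 1:10) {
    mE <- rnorm(1); mM <- mE + runif(1, 0.5, 3); s <- runif(1, 0.5, 2)
    m <- unitModel(mE, mM, s)
    cc <- sort(rnorm(20, mean = (mE + mM) / 2, sd = 3 * s))
    post <- predictEMT(m, unitMatrix(cc))$posterior
    expect_true(all(post >= 0 & post <= 1))
    expect_true(all(diff(post) >= -1e-12))  # nondecreasing when mM > mE
  }
})

test_that("swapping class labels maps posteriors p to 1 - p", {
  tr <- generateExpression(expressionSpec(nPerClass = 10, nSignature = 20,
                                          nBackground = 0, delta = 0.8),
                           seed = 9)
  x <- tr$matrix[tr$signature, ]
  fit <- fitBCCP(x, tr$labels)
  swapped <- ifelse(tr$labels == "mesenchymal", "epithelial", "mesenchymal")
  fitSw <- fitBCCP(x, swapped)
  expect_equal(bccpWeights(fitSw), -bccpWeights(fit))
  p <- predictEMT(fit, x)$posterior
  pSw <- predictEMT(fitSw, x)$posterior
  expect_equal(pSw, 1 - p, tolerance = 1e-9)
})

test_that("LOOCV is 0 on separable data and ~0.5 under permuted labels", {
  tr <- generateExpression(expressionSpec(nPerClass = 20, nSignature = 75,
                                          nBackground = 0), seed = 21)
  x <- tr$matrix[tr$signature, ]
  expect_equal(as.numeric(loocvMisclassification(x, tr$labels)), 0)
  set.seed(22)
  perm <- sample(tr$labels)
  rate <- as.numeric(loocvMisclassification(x, perm))
  expect_gt(rate, 0.3)  # within binomial error of 0.5 at n = 40
  expect_lt(rate, 0.7)
})

test_that("LOOCV on overlapping classes is reproducible and intermediate", {
  tr <- generateExpression(expressionSpec(nPerClass = 20, nSignature = 75,
                                          nBackground = 0, delta = 0.5),
                           seed = 33)
  x <- tr$matrix[tr$signature, ]
  r1 <- as.numeric(loocvMisclassification(x, tr$labels))
  r2 <- as.numeric(loocvMisclassification(x, tr$labels))
  expect_identical(r1, r2)
  expect_gt(r1, 0)
  expect_lt(r1, 0.5)
})

test_that("threshold calibration honors the reference prevalence range", {
  post <- c(0.9, 0.8, rep(0.1, 8))
  expect_equal(as.numeric(calibrateThreshold(post, c(0.19, 0.374))), 0.5)
  # all posteriors below 0.5: a smaller threshold is selected and the
  # called fraction moves toward the range
  low <- c(0.45, 0.4, 0.35, rep(0.05, 7))
  tau <- calibrateThreshold(low, c(0.19, 0.374))
  expect_lt(as.numeric(tau), 0.5)
  expect_gte(attr(tau, "fraction"), 0.19)
  # vacuous range keeps the default
  expect_equal(as.numeric(calibrateThreshold(post, c(1e-6, 1 - 1e-6))), 0.5)
  expect_error(calibrateThreshold(numeric(0)), "no predictions")
})

test_that("gene harmonization restricts, warns and floors coverage", {
  tr <- generateExpression(expressionSpec(nPerClass = 10), seed = 2)
  x <- tr$matrix[tr$signature, ]
  fit <- fitBCCP(x, tr$labels)
  h <- harmonizeGenes(fit, x)
  expect_identical(bccpGenes(h$model), bccpGenes(fit))   # full coverage
  x60 <- x[1:60, , drop = FALSE]
  expect_warning(h60 <- harmonizeGenes(fit, x60), "15 model gene")
  expect_length(bccpGenes(h60$model), 60)
  expect_error(harmonizeGenes(fit, x[1:10, , drop = FALSE]), "covers only")
})

test_that("standardization yields unit-scale genes and is idempotent", {
  set.seed(4)
  x <- matrix(rnorm(200, 5, 3), 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  z <- standardizeMatrix(x)
  expect_equal(unname(rowMeans(z)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 10), tolerance = 1e-12)
  expect_equal(standardizeMatrix(z), z, tolerance = 1e-10)
  xc <- rbind(x, const = 7)
  expect_warning(zc <- standardizeMatrix(xc), "constant")
  expect_equal(unname(zc["const", ]), rep(0, 20))
})

test_that("missing values are imputed and heavily-missing genes dropped", {
  tr <- generateExpression(expressionSpec(nPerClass = 10, nSignature = 10,
                                          nBackground = 0), seed = 6)
  x <- tr$matrix[tr$signature, ]
  x[1, 1:12] <- NA      # > 20% missing -> dropped
  x[2, 1] <- NA         # mean-imputed
  expect_warning(
    expect_message(fit <- fitBCCP(x, tr$labels), "imputed"),
    "missing")
  expect_false("SIG001" %in% bccpGenes(fit))
  expect_true("SIG002" %in% bccpGenes(fit))
})

test_that("fitBCCP accepts a SummarizedExperiment with labels in colData", {
  tr <- generateExpression(expressionSpec(nPerClass = 10, nSignature = 20,
                                          nBackground = 0), seed = 8)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = tr$matrix),
    colData = S4Vectors::DataFrame(class = tr$labels))
  fitSE <- fitBCCP(se)
  fitM <- fitBCCP(tr$matrix, tr$labels)
  expect_equal(bccpWeights(fitSE), bccpWeights(fitM))
})
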