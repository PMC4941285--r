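test_that("cohort spec validates its inputs", {
  expect_error(cohortSpec(0), "positive integer")
  expect_error(cohortSpec(10, prevalence = list(pdl1 = 1.2, emt = 0.3)),
               "\\(0, 1\\)")
  expect_error(cohortSpec(10, oddsRatios = list(emt = -2)), "positive")
  expect_error(generateCohort(cohortSpec(5)), "seed")
})

test_that("generated cohorts are deterministic under the seed", {
  sp <- cohortSpec(n = 80)
  expect_identical(generateCohort(sp, seed = 123),
                   generateCohort(sp, seed = 123))
  expect_false(identical(generateCohort(sp, seed = 123),
                         generateCohort(sp, seed = 124)))
})

test_that("staining profiles round-trip the assigned marker calls", {
  co <- generateCohort(cohortSpec(n = 300), seed = 71)
  sc <- scoreIHC(co)
  # every profile valid by construction
  expect_true(all(abs(sc$ecad_p0 + sc$ecad_p1 + sc$ecad_p2 + sc$ecad_p3
                      - 100) < 1e-6))
  # EMT+ iff ecad < 200 and vim > 30 holds by construction of the draws
  expect_identical(sc$emt_positive,
                   sc$h_score_ecad < 200 & sc$h_score_vim > 30)
  expect_identical(sc$pd_l1_positive, sc$pd_l1_score >= 1L)
})

test_that("realized marginals concentrate at the spec prevalences", {
  co <- generateCohort(cohortSpec(n = 10000), seed = 73)
  sc <- scoreIHC(co)
  # binomial SE at n = 10000 is < 0.005 for all these margins
  expect_equal(mean(sc$pd_l1_positive), 0.64, tolerance = 0.02)
  expect_equal(mean(sc$emt_positive), 0.34, tolerance = 0.02)
  expect_equal(mean(sc$p16_positive), 0.30, tolerance = 0.02)
  expect_equal(mean(sc$site == "oropharynx"), 0.32, tolerance = 0.02)
})

test_that("the EMT -> PD-L1 odds ratio is realized at large n", {
  sp <- cohortSpec(n = 5000,
                   oddsRatios = list(emt = 7.06))  # other ORs off
  co <- generateCohort(sp, seed = 79)
  sc <- scoreIHC(co)
  tab <- crossTab(data.frame(emt = factor(sc$emt_positive, c(TRUE, FALSE)),
                             pdl1 = factor(sc$pd_l1_positive,
                                           c(TRUE, FALSE))),
                  "emt", "pdl1")
  orHat <- oddsRatio(tab)$or
  expect_gte(orHat, 5.5)
  expect_lte(orHat, 9.0)
})

test_that("a null cohort generator yields uniform Fisher p-values", {
  ps <- vapply(1:200, function(i) {
    co <- generateCohort(cohortSpec(n = 1000,
                                    oddsRatios = list(emt = 1)),
                         seed = 7000 + i)
    sc <- scoreIHC(co)
    tab <- crossTab(data.frame(emt = factor(sc$emt_positive,
                                            c(TRUE, FALSE)),
                               pdl1 = factor(sc$pd_l1_positive,
                                             c(TRUE, FALSE))),
                    "emt", "pdl1")
    fisherExact2x2(tab)
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  tabs <- sapply(1:20, function(i) {
    co <- generateCohort(cohortSpec(n = 2000,
                                    oddsRatios = list(emt = 1)),
                         seed = 100 + i)
    sc <- scoreIHC(co)
    tab <- crossTab(data.frame(emt = factor(sc$emt_positive,
                                            c(TRUE, FALSE)),
                               pdl1 = factor(sc$pd_l1_positive,
                                             c(TRUE, FALSE))),
                    "emt", "pdl1")
    oddsRatio(tab)$or
  })
  expect_lt(abs(mean(tabs) - 1), 0.15)
})

test_that("expression generator: shift controls separability", {
  # delta = 0: LOOCV hovers at chance
  null <- generateExpression(expressionSpec(nPerClass = 20,
                                            nBackground = 0, delta = 0),
                             seed = 83)
  rate <- as.numeric(loocvMisclassification(null$matrix[null$signature, ],
                                            null$labels))
  expect_gt(rate, 0.3)
  expect_lt(rate, 0.7)
  # delta = 1.5 SD: held-out accuracy >= 0.95
  tr <- generateExpression(expressionSpec(), seed = 85)
  te <- generateExpression(expressionSpec(), seed = 86)
  fit <- fitBCCP(tr$matrix[tr$signature, ], tr$labels)
  pr <- predictEMT(fit, te$matrix[te$signature, ])
  acc <- mean((pr$posterior > 0.5) == (te$labels == "mesenchymal"))
  expect_gte(acc, 0.95)
})

test_that("reversed-direction signature genes still separate the classes", {
  sp <- expressionSpec(nPerClass = 20, nBackground = 0,
                       reversedFraction = 0.5)
  tr <- generateExpression(sp, seed = 87)
  te <- generateExpression(sp, seed = 88)
  fit <- fitBCCP(tr$matrix[tr$signature, ], tr$labels)
  pr <- predictEMT(fit, te$matrix[te$signature, ])
  acc <- mean((pr$posterior > 0.5) == (te$labels == "mesenchymal"))
  expect_gte(acc, 0.95)  # weights absorb the sign
})

test_that("count-table fixtures round-trip through crossTab exactly", {
  for (cohort in c("training", "validation")) {
    for (tab in hnsccCountTables(cohort)) {
      fx <- fixtureFromCounts(tab)
      vars <- names(dimnames(tab))
      back <- crossTab(fx, vars[1], vars[2])
      expect_equal(unclass(back), unclass(tab), ignore_attr = TRUE)
      expect_equal(dimnames(back), dimnames(tab))
    }
  }
  # data.frame form and empty counts
  df <- data.frame(a = c("x", "y"), b = c("u", "u"), n = c(2L, 0L))
  fx <- fixtureFromCounts(df)
  expect_equal(nrow(fx), 2L)
  expect_equal(nrow(fixtureFromCounts(data.frame(a = "x", n = 0L))), 0L)
  expect_error(fixtureFromCounts(matrix(c(1.5, 1, 1, 1), 2)),
               "non-negative integers")
})
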