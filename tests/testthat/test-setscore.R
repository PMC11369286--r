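test_that("spiked gene sets rank spiked samples above all others", {
  sim <- simulateExpressionCohort(nSamples = 30, nGenes = 200,
                                  shifts = rbind(c(0, 0, 0, 0),
                                                 c(0, 0, 3, 0)),
                                  proportions = c(0.5, 0.5), seed = 2)
  sc <- gsvaScores(sim$expr, sim$geneSets)
  spiked <- sim$labels == 2
  expect_gt(min(sc[spiked, "PUFA"]), max(sc[!spiked, "PUFA"]))
  expect_true(all(abs(sc) < 1))   # maxdiff statistic bounded
  # a "red"-like subgroup maximizes mean(PUFA score - defense score)
  red <- simulateExpressionCohort(nSamples = 45, nGenes = 200,
                                  shifts = rbind(c(0, 0, 0, 0),
                                                 c(-2, 0, 2, 0)),
                                  proportions = c(2 / 3, 1 / 3), seed = 4)
  rsc <- gsvaScores(red$expr, red$geneSets)
  contrast <- tapply(rsc[, "PUFA"] - rsc[, "defenses"], red$labels, mean)
  expect_equal(unname(which.max(contrast)), 2)
})

test_that("null scores are centred and input contracts are enforced", {
  set.seed(6)
  expr <- matrix(rnorm(150 * 20, 6, 1), 150, 20,
                 dimnames = list(sprintf("g%03d", 1:150), NULL))
  nullSets <- lapply(1:150, function(i) sample(rownames(expr), 10))
  names(nullSets) <- paste0("s", 1:150)
  sc <- gsvaScores(expr, nullSets)
  expect_lt(abs(mean(sc)), 0.02)
  expect_lt(abs(mean(sc > 0) - 0.5), 0.05)
  expect_error(gsvaScores(expr, list(a = character())), "empty")
  expect_error(gsvaScores(expr, list(a = c("NOPE1", "NOPE2"))), "NOPE1")
  expect_warning(gsvaScores(expr, list(a = c("g001", "MISSING"))), "MISSING")
  # constant gene rows score 0 and do not break the walk
  expr2 <- expr; expr2[1:10, ] <- 3
  expect_true(all(is.finite(gsvaScores(expr2, list(flat = rownames(expr)[1:5],
                                                   ok = rownames(expr)[20:29])))))
  # single sample, single set: finite output (degenerate but defined)
  expect_warning(s1 <- gsvaScores(expr[, 1, drop = FALSE],
                                  list(a = rownames(expr)[1:5])), "3 samples")
  expect_true(is.finite(s1[1, 1]))
})

test_that("scores are exactly invariant to a global shift and stable under a per-sample shift", {
  sim <- simulateExpressionCohort(nSamples = 20, nGenes = 150,
                                  shifts = matrix(0, 1, 4), proportions = 1,
                                  seed = 3)
  sc <- gsvaScores(sim$expr, sim$geneSets)
  expect_identical(sc, gsvaScores(sim$expr + 5, sim$geneSets))
  shifted <- sim$expr; shifted[, 5] <- shifted[, 5] + 1
  sc2 <- gsvaScores(shifted, sim$geneSets)
  expect_gt(cor(c(sc), c(sc2), method = "spearman"), 0.9)
})

test_that("EM selects the true component count and recovers weights", {
  sel <- integer(20); werr <- rep(NA_real_, 20)
  for (s in 1:20) {
    set.seed(s)
    n <- 500
    lab <- rbinom(n, 1, 0.4)
    x <- matrix(rnorm(4 * n), n, 4) + outer(lab, rep(6, 4))
    g <- fitGmm(x, kRange = 1:3, nInit = 3, seed = s)
    sel[s] <- nClusters(g)
    if (nClusters(g) == 2) {
      werr[s] <- max(abs(sort(g@weights) - sort(c(mean(lab), 1 - mean(lab)))))
      expect_equal(rowSums(g@responsibilities), rep(1, n), tolerance = 1e-9)
      # BIC dips at the true k and rises beyond it
      bic <- g@bicTable$bic
      expect_lt(bic[2], bic[1])
      expect_lt(bic[2], bic[3])
    }
  }
  expect_gte(sum(sel == 2), 18)
  expect_lt(max(werr, na.rm = TRUE), 0.05)
})

test_that("single-Gaussian data selects k = 1 in the majority of runs", {
  sel <- vapply(1:20, function(s) {
    sim <- simulateExpressionCohort(nSamples = 60, nGenes = 120,
                                    shifts = matrix(0, 1, 4), proportions = 1,
                                    seed = s)
    sc <- gsvaScores(sim$expr, sim$geneSets)
    nClusters(fitGmm(sc, kRange = 1:2, nInit = 3, seed = s))
  }, integer(1))
  expect_gt(mean(sel == 1), 0.5)
})

test_that("mixture fit agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(5)
  x <- rbind(matrix(rnorm(400), 100, 4),
             sweep(matrix(rnorm(400), 100, 4), 2, rep(5, 4), "+"))
  g <- fitGmm(x, kRange = 2, nInit = 5, seed = 1)
  m <- Mclust(scale(x), G = 2, modelNames = "VVV", verbose = FALSE)
  expect_equal(g@logLik, m$loglik, tolerance = 1e-3)
  expect_equal(adjustedRand(assignments(g), m$classification), 1)
})

test_that("precondition and phenotype labeling rules hold", {
  expect_error(fitGmm(matrix(rnorm(12), 3, 4), kRange = 1:4), "samples")
  set.seed(8)
  # two blobs: red-like (PUFA/Iron up, defenses/GSH down) and its mirror
  n <- 120
  lab <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(4 * n, sd = 0.5), n, 4) +
    cbind(-2 * lab + 1, -2 * lab + 1, 2 * lab - 1, 2 * lab - 1)
  colnames(x) <- c("defenses", "GSH", "PUFA", "Iron")
  g <- assignPhenotypeLabels(fitGmm(x, kRange = 2, nInit = 5, seed = 2))
  redComp <- which(phenotypeLabels(g) == "red")
  expect_length(redComp, 1)
  expect_gt(mean(lab[assignments(g) == redComp]), 0.9)
  expect_setequal(phenotypeLabels(g), c("red", "green"))
  # k = 1 -> gray
  g1 <- fitGmm(matrix(rnorm(200), 50, 4,
                      dimnames = list(NULL, colnames(x))), kRange = 1)
  expect_equal(phenotypeLabels(assignPhenotypeLabels(g1)), "gray")
})

test_that("subgroup report tabulates histology by phenotype", {
  set.seed(12)
  n <- 90
  lab <- rep(0:1, c(60, 30))
  x <- matrix(rnorm(4 * n, sd = 0.4), n, 4) +
    cbind(-2 * lab + 1, -2 * lab + 1, 2 * lab - 1, 2 * lab - 1)
  colnames(x) <- c("defenses", "GSH", "PUFA", "Iron")
  g <- assignPhenotypeLabels(fitGmm(x, kRange = 2, nInit = 5, seed = 3))
  meta <- rep(c("Control", "MASL"), length.out = n)
  rep1 <- subgroupReport(g, meta)
  expect_equal(sum(rep1$counts), n)
  expect_equal(unname(rowSums(rep1$rowPct)), rep(100, 2))
  # red fraction of disease close to truth when components align with labels
  truthRed <- mean(lab[meta == "MASL"] == 1)
  expect_lt(abs(rep1$redDiseaseFraction - truthRed), 0.15)
  expect_error(subgroupReport(g, meta[-1]), "length")
  expect_error(subgroupReport(g, rep(NA, n)), "empty")
  # all samples in one component -> that label holds 100% of every group
  g1 <- assignPhenotypeLabels(fitGmm(matrix(rnorm(4 * n, sd = 1), n, 4,
                                            dimnames = list(NULL, colnames(x))),
                                     kRange = 1))
  repAll <- subgroupReport(g1, meta)
  expect_true(all(repAll$rowPct[, "gray"] == 100))
})
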