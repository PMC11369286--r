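makeSeparatedCohort <- function(sep, sizes = c(10L, 10L, 10L), seed = 1) {
  def <- markerCohortDefaults()
  means <- rbind(rep(0, 4), rep(sep, 4), c(-sep, sep, -sep, sep))
  sds <- matrix(1, 3, 4)
  dimnames(means) <- dimnames(sds) <- dimnames(def$means)
  simulateMarkerCohort(sizes = sizes, means = means, sds = sds, seed = seed)
}

test_that("k-prototypes obeys its objective at k = 1 and matches exhaustive k-means at gamma 0", {
  co <- makeSeparatedCohort(3, seed = 2)
  fit1 <- kPrototypes(co$table, k = 1, nInit = 1, seed = 1)
  num <- scale(as.matrix(co$table[fit1@numericCols]))
  expect_equal(unname(fit1@centers[1, ]), unname(colMeans(num)))
  mismatch <- sum(co$table$iron != names(which.max(table(co$table$iron))))
  expect_equal(fit1@cost, sum(scale(num, center = colMeans(num),
                                    scale = FALSE)^2) + 0.5 * mismatch)
  # 10-point numeric-only toy set, k = 2, gamma = 0: exhaustive oracle
  set.seed(31)
  toy <- data.frame(a = c(rnorm(5, 0), rnorm(5, 4)),
                    b = c(rnorm(5, 0), rnorm(5, 4)))
  fit2 <- kPrototypes(toy, k = 2, gamma = 0, nInit = 20, seed = 3)
  oracle <- bruteKmeans2(scale(as.matrix(toy)))
  expect_equal(fit2@cost, oracle$cost)
  expect_equal(adjustedRand(assignments(fit2), oracle$assign), 1)
})

test_that("well-separated synthetic clusters are recovered exactly and monotonically", {
  co <- makeSeparatedCohort(6, seed = 5)
  fit <- kPrototypes(co$table, k = 3, nInit = 10, seed = 7)
  expect_equal(adjustedRand(assignments(fit), co$labels), 1)
  expect_true(all(diff(fit@costTrace) <= 1e-8))
  # ARI non-decreasing in separation (averaged over seeds)
  seps <- c(0.5, 2.5, 6)
  ari <- vapply(seps, function(s) {
    mean(vapply(1:8, function(sd) {
      cc <- makeSeparatedCohort(s, seed = sd)
      adjustedRand(assignments(kPrototypes(cc$table, k = 3, nInit = 10,
                                           seed = sd)), cc$labels)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ari) >= 0))
  expect_error(kPrototypes(co$table, k = 50), "exceeds")
  co$table$flat <- 1
  expect_warning(kPrototypes(co$table, k = 3, nInit = 2, seed = 1),
                 "constant")
})

test_that("exact Fisher r x c enumeration matches closed forms and sums to 1", {
  iron <- rbind(c(1, 7, 1), c(6, 3, 9))
  p <- fisherExactRxC(iron)
  expect_equal(as.numeric(p), 0.014, tolerance = 0.001 / 0.014)
  expect_equal(attr(p, "probTotal"), 1, tolerance = 1e-9)
  # 2x2 against the hypergeometric oracle
  for (tab in list(rbind(c(3, 7), c(8, 2)), rbind(c(1, 9), c(5, 5)),
                   rbind(c(0, 4), c(6, 1)))) {
    expect_equal(as.numeric(fisherExactRxC(tab)), fisher2x2Oracle(tab))
    expect_equal(as.numeric(fisherExactRxC(tab)),
                 fisher.test(tab)$p.value, tolerance = 1e-7)
  }
  expect_equal(as.numeric(fisherExactRxC(rbind(c(5, 5), c(5, 5)))), 1)
  # r x c cross-check against the independent network-algorithm implementation
  tab3 <- rbind(c(2, 5, 3), c(6, 1, 2), c(1, 4, 4))
  expect_equal(as.numeric(fisherExactRxC(tab3)),
               fisher.test(tab3)$p.value, tolerance = 1e-6)
  expect_error(fisherExactRxC(matrix(0, 2, 2)), "zero")
  expect_error(fisherExactRxC(rbind(c(1.5, 2), c(1, 1))), "integer")
})

test_that("Kruskal-Wallis/Dunn agrees with exact rank arithmetic", {
  expect_equal(kruskalWallisDunn(rep(2, 9), rep(1:3, 3))$H, 0)
  # 3 disjoint groups of 5: ranks 1-5 / 6-10 / 11-15, H at its maximum
  x <- c(1:5, 101:105, 201:205)
  g <- rep(c("a", "b", "c"), each = 5)
  res <- kruskalWallisDunn(x, g)
  expect_equal(res$H, 12.5)   # 12/(15*16) * 2 * 5 * 25
  # adjacent pairs: |z| = 5/sqrt(20 * 2/5); extreme pair doubles it
  expect_equal(abs(res$dunn$z), c(5, 10, 5) / sqrt(8), tolerance = 1e-12)
  extreme <- res$dunn$group1 == "a" & res$dunn$group2 == "c"
  expect_lt(res$dunn$p[extreme], 0.05)
  expect_equal(res$dunn$p[!extreme], rep(2 * pnorm(-5 / sqrt(8)), 2))
  expect_error(kruskalWallisDunn(1:5, rep("a", 5)), "2 groups")
  expect_equal(res$H, kruskal.test(x, factor(g))$statistic[[1]])
})

test_that("Kruskal-Wallis preserves type-I error under the null", {
  set.seed(99)
  rejections <- mean(vapply(1:2000, function(i) {
    kruskalWallisDunn(rnorm(15), sample(rep(1:3, 5)))$p < 0.05
  }, logical(1)))
  expect_gt(rejections, 0.03)
  expect_lt(rejections, 0.07)
})

test_that("BH adjustment matches the direct step-up oracle and its invariants", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(17)
  for (i in 1:5) {
    p <- runif(sample(3:20, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, bhOracle(p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))     # order-preserving
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cluster characterization reproduces counts, medians and degenerate IQRs", {
  co <- makeSeparatedCohort(6, sizes = c(1L, 12L, 12L), seed = 13)
  fit <- kPrototypes(co$table, k = 3, nInit = 10, seed = 3)
  summ <- characterizeClusters(fit, co$table)
  expect_true(all(c("characteristic", "p", "pAdj") %in% names(summ)))
  # a singleton cluster degenerates to median (x-x)
  single <- which(tabulate(assignments(fit), 3) == 1)
  tRow <- summ[summ$characteristic == "tunel", ]
  v <- co$table$tunel[assignments(fit) == single]
  expect_match(tRow[[paste0("cluster", single)]],
               sprintf("%.3g \\(%.3g-%.3g\\)", v, v, v))
  # recovered medians sit near generator means for a large separated cluster
  big <- makeSeparatedCohort(6, sizes = c(30L, 30L, 30L), seed = 21)
  bigFit <- kPrototypes(big$table, k = 3, nInit = 10, seed = 2)
  med <- sort(unname(tapply(big$table$tunel, assignments(bigFit), median)))
  expect_true(max(abs(med - sort(c(0, 6, -6)))) < 0.7)   # ~IQR/sqrt(n)
})
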