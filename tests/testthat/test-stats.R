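test_that("Kruskal-Wallis matches the hand-computed rank formula", {
  res <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$H, 3.857, tolerance = 1e-3)
  expect_equal(res$p, 0.0495, tolerance = 1e-2)
  # degenerate input: all values identical
  expect_equal(kruskalWallis(list(rep(2, 5), rep(2, 4))), list(H = 0, p = 1))
  # identical groups: H = 0, p = 1
  res2 <- kruskalWallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res2$H, 0)
  expect_equal(res2$p, 1)
  expect_error(kruskalWallis(list(1:3)), ">= 2")
  expect_error(kruskalWallis(list(1:3, numeric())), "nonempty")
})

test_that("chi-square p agrees with the exact permutation law in the tail", {
  # the exact permutation p for the textbook example is 2/20; the chi-square
  # reference is only an approximation at this n
  expect_equal(permutationKWP(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # in the rejection tail (strong separation) the two references agree closely
  pChi <- kruskalWallis(list(1:4, 5:8))$p
  expect_equal(permutationKWP(1:4, 5:8), 2 / 70)
  expect_lt(abs(pChi - 2 / 70), 0.02)
  # and the two p-values order data sets consistently
  set.seed(13)
  pairs <- replicate(12, {
    g1 <- sample(1:4, 4, replace = TRUE)
    g2 <- sample(1:5, 4, replace = TRUE)
    c(kruskalWallis(list(g1, g2))$p, permutationKWP(g1, g2))
  })
  expect_gt(cor(pairs[1, ], pairs[2, ], method = "spearman"), 0.9)
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  set.seed(21)
  g <- list(rnorm(8), rnorm(6, 0.5), rnorm(7, 1))
  r1 <- kruskalWallis(g)
  r2 <- kruskalWallis(lapply(g, function(x) exp(3 * x)))
  expect_equal(r1$H, r2$H)
  expect_equal(r1$p, r2$p)
})

test_that("Dunn/Bonferroni post hoc adjusts, caps, and reduces at m = 1", {
  set.seed(3)
  g <- list(rnorm(10), rnorm(10, 2))
  d1 <- dunnBonferroni(g, list(c(1L, 2L)), m = 1L)
  d5 <- dunnBonferroni(g, list(c(1L, 2L)), m = 5L)
  expect_equal(d5$pRaw, d1$pAdj)          # m = 1: unadjusted two-group test
  expect_equal(d5$pAdj, pmin(1, d1$pAdj * 5))
  # capping at 1 and ">0.99" reporting
  gNull <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  dn <- dunnBonferroni(gNull, list(c(1L, 2L)), m = 2L)
  expect_equal(dn$pAdj, 1)
  expect_equal(formatPValue(dn$pAdj), ">0.99")
  expect_equal(nrow(dunnBonferroni(g, list())), 0)
  expect_error(dunnBonferroni(g, list(c(1L, 2L)), m = 0L), "m must be")
})

test_that("Bonferroni post hoc controls the family-wise error", {
  set.seed(91)
  nSim <- 1500
  fwe <- mean(replicate(nSim, {
    g <- list(rnorm(8), rnorm(8), rnorm(8))
    d <- dunnBonferroni(g, list(c(1L, 2L), c(1L, 3L), c(2L, 3L)), m = 3L)
    any(d$pAdj < 0.05)
  }))
  expect_lte(fwe, 0.05 + 2 * sqrt(0.05 * 0.95 / nSim))
})

test_that("Glass' delta follows its closed form and scaling laws", {
  expect_equal(glassDelta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(glassDelta(c(1, 2, 3), c(0, 1, 2)), 1)   # sd(control) = 1
  set.seed(6)
  trt <- rnorm(20, 1); ctl <- rnorm(15)
  d <- glassDelta(trt, ctl)
  # shift invariance and inverse scaling
  expect_equal(glassDelta(trt + 5, ctl + 5), d)
  expect_equal(glassDelta(3 * trt, 3 * ctl), d)
  # role swap: sign flips, magnitude rescales by the sd ratio
  expect_equal(glassDelta(ctl, trt), -d * sd(ctl) / sd(trt))
  expect_warning(dz <- glassDelta(1:3, c(2, 2, 2)), "zero control spread")
  expect_true(is.nan(dz))
  expect_error(glassDelta(1:3, 2), ">= 2")
})

test_that("effect-size categories follow the rule-of-thumb thresholds", {
  expect_equal(effectSizeCategory(0), "negligible")
  expect_equal(effectSizeCategory(c(0.19, 0.2, 0.5, 0.79, 0.8, 1.2, -3.7)),
               c("negligible", "small", "medium", "medium", "large",
                 "very large", "huge"))
})

test_that("Grubbs test flags gross outliers and is iterative", {
  expect_length(grubbsOutliers(c(1, 2, 3)), 0)
  expect_equal(grubbsOutliers(c(1.0, 1.1, 0.9, 1.2, 8.0)), 5L)
  # two outliers removed one at a time
  x <- c(rnorm(20, 0, 0.1), 9, -7)
  expect_setequal(grubbsOutliers(x), c(21L, 22L))
  expect_error(grubbsOutliers(c(1, 2)), "n >= 3")
})

test_that("Grubbs test keeps near-nominal level on Gaussian nulls", {
  set.seed(33)
  hits <- replicate(1000, length(grubbsOutliers(rnorm(20))) > 0)
  expect_gte(mean(!hits), 0.94)
})

test_that("two-way ANOVA handles degenerate, additive, and noisy designs", {
  A <- rep(c("a1", "a2"), each = 20)
  B <- rep(rep(c("b1", "b2"), each = 10), 2)
  # all values equal
  t0 <- twoWayAnova(rep(1, 40), A, B)
  expect_equal(t0$F, c(0, 0, 0))
  expect_equal(t0$p, c(1, 1, 1))
  # additive cell means without noise: interaction F = 0
  mu <- ifelse(A == "a2", 2, 0) + ifelse(B == "b2", 3, 0)
  tAdd <- twoWayAnova(mu + rep(c(-0.1, 0.1), 20), A, B)
  expect_equal(tAdd["A:B", "F"], 0, tolerance = 1e-10)
  expect_lt(tAdd["A", "p"], 1e-10)
  expect_error(twoWayAnova(rnorm(10), rep("a", 10), rep(c("x", "y"), 5)),
               ">= 2 levels")
})

test_that("two-way ANOVA interaction power matches the noncentral-F law", {
  # balanced 2x2, n = 50 per cell, unit noise, interaction effect built in
  n <- 50
  A <- rep(c(0, 1), each = 2 * n)
  B <- rep(rep(c(0, 1), each = n), 2)
  inter <- 0.5
  mu <- 0.3 * A + 0.4 * B + inter * A * B
  # interaction contrast L = mu11 - mu10 - mu01 + mu00 has variance 4/n,
  # so the noncentrality is lambda = n * L^2 / 4
  lambda <- n * inter^2 / 4
  powerTheory <- 1 - pf(qf(0.95, 1, 4 * n - 4), 1, 4 * n - 4, ncp = lambda)
  set.seed(55)
  nSim <- 500
  powerSim <- mean(replicate(nSim, {
    twoWayAnova(mu + rnorm(4 * n), A, B)["A:B", "p"] < 0.05
  }))
  expect_lt(abs(powerSim - powerTheory), 0.05)
})

test_that("unbalanced designs use type-III sums of squares", {
  set.seed(77)
  # unbalanced cells like the empirical design (75/75/50/50)
  A <- c(rep("hi", 150), rep("lo", 100))
  B <- c(rep(c("s16", "s8"), each = 75), rep(c("s16", "s8"), each = 50))
  y <- rnorm(250) + ifelse(A == "lo" & B == "s16", 1, 0)
  tab <- twoWayAnova(y, A, B)
  fit <- stats::lm(y ~ Af * Bf,
                   data = data.frame(y = y, Af = factor(A), Bf = factor(B)),
                   contrasts = list(Af = "contr.sum", Bf = "contr.sum"))
  oracle <- car::Anova(fit, type = 3)
  expect_equal(tab["A:B", "F"], oracle["Af:Bf", "F value"])
  expect_lt(tab["A:B", "p"], 0.05)
})

test_that("genotype PCA reproduces the eigendecomposition of the similarity matrix", {
  set.seed(42)
  G <- matrix(sample(0:2, 20 * 50, replace = TRUE), 20, 50)
  res <- pcaGenotypes(G)
  C <- scale(G, center = TRUE, scale = FALSE)
  ev <- eigen(tcrossprod(C), symmetric = TRUE)$values
  ev <- ev[ev > 1e-8] / (nrow(G) - 1)
  expect_equal(sort(res$sdev^2, decreasing = TRUE), sort(ev, decreasing = TRUE),
               tolerance = 1e-8)
  # scores orthogonal; explained variance sums to 1
  cp <- crossprod(res$scores)
  expect_equal(cp[upper.tri(cp)], rep(0, sum(upper.tri(cp))), tolerance = 1e-8)
  expect_equal(sum(res$explainedVariance), 1, tolerance = 1e-12)
})

test_that("genotype PCA separates fixed clusters and flags monomorphic data", {
  G <- rbind(matrix(0L, 10, 30), matrix(2L, 10, 30))
  res <- pcaGenotypes(G)
  expect_gt(res$explainedVariance[1], 0.999)
  expect_true(all(res$scores[1:10, 1] * res$scores[11:20, 1] < 0))
  resMono <- pcaGenotypes(matrix(1L, 5, 10))
  expect_true(resMono$monomorphic)
  # locus reordering leaves scores unchanged up to sign
  set.seed(8)
  G2 <- matrix(sample(0:2, 15 * 20, replace = TRUE), 15, 20)
  s1 <- pcaGenotypes(G2)$scores[, 1]
  s2 <- pcaGenotypes(G2[, sample(20)])$scores[, 1]
  expect_equal(abs(cor(s1, s2)), 1, tolerance = 1e-10)
})
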