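twoClassFixture <- function(seed, n = 12L, p = 6L, shift = 0) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  g <- rep(c("control", "challenge"), each = n / 2)
  x[g == "challenge", 1] <- x[g == "challenge", 1] + shift
  list(x = scale(x), g = g)
}

test_that("a single separating variable absorbs the component-1 weight", {
  set.seed(10)
  n <- 14; p <- 8
  x <- matrix(rnorm(n * p, sd = 0.05), n, p)
  g <- rep(c("control", "challenge"), each = n / 2)
  x[g == "challenge", 1] <- x[g == "challenge", 1] + 5
  m <- fitPlsda(scale(x, scale = FALSE), g, 1)
  expect_gte(plsdaWeights(m)[1, 1]^2, 0.99)
})

test_that("component-1 weights equal the dominant left singular direction of X'Y", {
  for (s in 1:5) {
    fx <- twoClassFixture(s, shift = 1.5)
    Y <- scale(1 * outer(fx$g, unique(fx$g), "=="), scale = FALSE)
    sv <- svd(crossprod(fx$x, Y))
    w1 <- plsdaWeights(fitPlsda(fx$x, fx$g, 2))[, 1]
    oracle <- sv$u[, 1]
    if (sum(w1 * oracle) < 0) oracle <- -oracle
    expect_lt(max(abs(w1 - oracle)), 1e-6)
  }
})

test_that("scores are pairwise orthogonal on fitted models", {
  co <- generateCohort(cohortSpec(nMetabolites = 60, nEfficacy = 6,
                                  nBias = 6, seed = 11))
  pp <- preprocessFeatures(co$table)
  m <- fitPlsda(pp$x, groupLabels(co$table), 3)
  Tn <- sweep(plsdaScores(m), 2, sqrt(colSums(plsdaScores(m)^2)), "/")
  G <- crossprod(Tn)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("with two balanced classes the weight vector is the class-mean difference", {
  fx <- twoClassFixture(21, shift = 2)
  m <- fitPlsda(fx$x, fx$g, 1)
  d <- colMeans(fx$x[fx$g == "control", ]) -
       colMeans(fx$x[fx$g == "challenge", ])
  d <- d / sqrt(sum(d^2))
  w <- plsdaWeights(m)[, 1]
  if (sum(w * d) < 0) d <- -d
  expect_lt(max(abs(w - d)), 1e-6)
})

test_that("explained Y sum of squares is non-negative and bounded by total", {
  co <- generateCohort(cohortSpec(nMetabolites = 50, nEfficacy = 5,
                                  nBias = 5, seed = 12))
  pp <- preprocessFeatures(co$table)
  g <- groupLabels(co$table)
  m <- fitPlsda(pp$x, g, 3)
  expect_true(all(explainedYSS(m) >= 0))
  Y <- scale(1 * outer(g, classOrder(m), "=="), scale = FALSE)
  expect_lte(sum(explainedYSS(m)), sum(Y^2) + 1e-8)
})

test_that("fit validates groups and component counts", {
  fx <- twoClassFixture(1)
  expect_error(fitPlsda(fx$x, rep("control", 12), 1), "2 distinct groups")
  expect_error(fitPlsda(fx$x, fx$g, 7), "nComponents")
})

test_that("non-convergence reports the component and residual", {
  # X'Y with nearly tied leading singular values: the power iteration
  # contracts by ~(s2/s1)^2 per cycle, far too slowly for 50 iterations.
  x <- cbind(sqrt(3) * 1.0005 * c(1, 1, -1, -1, 0, 0),
             c(1, 1, 1, 1, -2, -2))
  g <- rep(c("control", "challenge", "treated"), each = 2)
  expect_error(fitPlsda(x, g, 1, maxIter = 50),
               "did not converge.*component 1")
})

test_that("VIP satisfies its algebraic identities", {
  co <- generateCohort(cohortSpec(nMetabolites = 45, nEfficacy = 5,
                                  nBias = 5, seed = 13))
  pp <- preprocessFeatures(co$table)
  m <- fitPlsda(pp$x, groupLabels(co$table), 2)
  vip <- computeVip(m)
  expect_lt(abs(mean(vip$VIP^2) - 1), 1e-8)
  expect_true(all(vip$VIP >= 0))
  # single-variable model: the formula collapses to exactly 1
  x1 <- matrix(c(rnorm(6, 0), rnorm(6, 3)), ncol = 1)
  m1 <- fitPlsda(scale(x1), rep(c("control", "challenge"), each = 6), 1)
  expect_identical(unname(computeVip(m1)$VIP), 1)
})

test_that("VIP matches a hand-evaluated formula on a fixed two-component model", {
  W <- cbind(c(0.8, 0.6, 0), c(0, 0.6, 0.8))
  ssy <- c(3, 1)
  m <- new("PlsdaModel",
           scores = qr.Q(qr(matrix(rnorm(12), 4, 3)))[, 1:2] * 2,
           weights = W, xLoadings = W, yLoadings = matrix(1, 2, 2),
           explainedYSS = ssy, classOrder = c("a", "b"), yCenter = c(0.5, 0.5))
  got <- computeVip(m)$VIP
  # independent evaluation: explicit scalar loops over the definition
  expected <- vapply(1:3, function(j) {
    num <- 0
    for (a in 1:2) num <- num + ssy[a] * (W[j, a] / sqrt(sum(W[, a]^2)))^2
    sqrt(3 * num / sum(ssy))
  }, 0)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_error(computeVip(`slot<-`(m, "explainedYSS", value = c(0, 0))),
               "zero")
})

test_that("VIP > 1 captures a variable carrying d >= 2 signal at n = 7 per group", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    x <- matrix(rnorm(14 * 30), 14, 30)
    g <- rep(c("control", "challenge"), each = 7)
    x[g == "challenge", 1] <- x[g == "challenge", 1] + 2
    m <- fitPlsda(scale(x), g, 1, maxIter = 5000)
    computeVip(m)$VIP[1] > 1
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("projection is self-consistent, linear at zero, and matches sequential deflation", {
  co <- generateCohort(cohortSpec(nMetabolites = 35, nEfficacy = 4,
                                  nBias = 4, seed = 14))
  pp <- preprocessFeatures(co$table)
  m <- fitPlsda(pp$x, groupLabels(co$table), 3)
  expect_equal(projectPlsda(m, pp$x), plsdaScores(m), tolerance = 1e-8)
  z <- matrix(0, 1, ncol(pp$x))
  expect_equal(unname(projectPlsda(m, z)), matrix(0, 1, 3))
  # two-implementation equivalence on new data: R-matrix projection vs
  # explicit per-component deflation
  set.seed(15)
  xn <- matrix(rnorm(5 * ncol(pp$x)), 5)
  seq_scores <- matrix(0, 5, 3)
  xd <- xn
  for (a in 1:3) {
    seq_scores[, a] <- xd %*% plsdaWeights(m)[, a]
    xd <- xd - seq_scores[, a] %*% t(plsdaLoadings(m)[, a])
  }
  expect_equal(unname(projectPlsda(m, xn)), seq_scores, tolerance = 1e-8)
  expect_error(projectPlsda(m, xn[, 1:10]), "variables")
})

test_that("the sign convention makes refits deterministic", {
  fx <- twoClassFixture(30, shift = 1)
  w1 <- plsdaWeights(fitPlsda(fx$x, fx$g, 2))
  w2 <- plsdaWeights(fitPlsda(fx$x, fx$g, 2))
  expect_identical(w1, w2)
  expect_true(all(apply(w1, 2, function(w) w[which.max(abs(w))] > 0)))
})
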