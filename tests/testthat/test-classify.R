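test_that("identical group values give statistic 0 and p = 1", {
  x <- cbind(M1 = rep(c(1, 2, 3), 2),        # same spread in both groups
             M2 = rep(5, 6))                 # no spread at all
  g <- rep(c("control", "challenge"), each = 3)
  res <- differentialTest(x, g, "control", "challenge", method = "t")
  expect_identical(res["M1", "statistic"], 0)
  expect_identical(res["M1", "p"], 1)
  expect_identical(res["M2", "p"], 1)
  expect_identical(res["M2", "flag"], "zero_variance_identical")
})

test_that("BH adjustment follows the step-up definition", {
  set.seed(5)
  x <- matrix(rnorm(6 * 12), 6, dimnames = list(NULL, paste0("M", 1:12)))
  g <- rep(c("control", "treated"), each = 3)
  res <- differentialTest(x, g, "control", "treated", method = "t")
  expect_equal(res$p_adj, bhOracle(res$p), tolerance = 1e-12)
  # the two hand-checkable fixed points of the procedure
  expect_equal(bhOracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(stats::p.adjust(rep(0.2, 5), "BH"), rep(0.2, 5))
})

test_that("method auto switches between t and Mann-Whitney per metabolite", {
  set.seed(6)
  n <- 8
  x <- cbind(Mnormal = rnorm(2 * n),
             Mskewed = exp(rnorm(2 * n, sd = 2)) + rep(c(0, 50), each = n))
  g <- rep(c("control", "challenge"), each = n)
  res <- differentialTest(x, g, "control", "challenge", method = "auto")
  expect_identical(res["Mnormal", "method"], "t")
  expect_identical(res["Mskewed", "method"], "mannwhitney")
})

test_that("groups below three samples are rejected", {
  x <- matrix(rnorm(10), 5, 2)
  g <- c("control", "control", "challenge", "challenge", "challenge")
  expect_error(differentialTest(x, g, "control", "challenge"),
               ">= 3 samples")
})

test_that("the interval rule labels the canonical cases", {
  expect_identical(classifyMetabolite(0, 2, 1, TRUE), "efficacy")
  expect_identical(classifyMetabolite(0, 2, 3, TRUE), "bias_up")
  expect_identical(classifyMetabolite(0, 2, -1, TRUE), "bias_down")
  expect_identical(classifyMetabolite(1, 1, 1, FALSE), "unclassified")
  # without a challenge effect there is nothing to restore
  expect_identical(classifyMetabolite(0, 2, 1, FALSE), "unclassified")
  # epsilon shrinks the efficacy interval and pads the bias boundaries
  expect_identical(classifyMetabolite(0, 2, 0.1, TRUE, epsilon = 0.2),
                   "unclassified")
  expect_identical(classifyMetabolite(0, 2, 2.1, TRUE, epsilon = 0.2),
                   "unclassified")
})

test_that("the interval rule is symmetric in control and challenge", {
  set.seed(7)
  for (i in 1:200) {
    mC <- rnorm(1); mA <- rnorm(1); mT <- rnorm(1)
    sig <- runif(1) < 0.5
    eps <- sample(c(0, 0.05), 1)
    expect_identical(classifyMetabolite(mC, mA, mT, sig, eps),
                     classifyMetabolite(mA, mC, mT, sig, eps))
  }
})

test_that("classifyAll gates on VIP and significance and partitions the gated set", {
  co <- generateCohort(cohortSpec(nMetabolites = 120, nEfficacy = 12,
                                  nBias = 12, seed = 21))
  an <- analyzeCohort(co)
  v <- an$verdicts
  expect_setequal(unique(v$class),
                  intersect(c("efficacy", "bias_up", "bias_down",
                              "unclassified"), unique(v$class)))
  expect_identical(nrow(v), length(an$pp$kept))
  # counts over the four labels sum to the metabolite count exactly
  expect_identical(sum(table(factor(v$class,
    levels = c("efficacy", "bias_up", "bias_down", "unclassified")))),
    nrow(v))
  # VIP at or below the gate forces unclassified regardless of the means
  vLow <- an$vip
  vLow$VIP[] <- 0.5
  forced <- classifyAll(an$pp$analysis, an$groups, vLow,
                        an$diffChallenge, an$diffTreatment)
  expect_true(all(forced$class == "unclassified"))
  # efficacy calls carry a significant challenge contrast
  expect_true(all(v$challenge_p_adj[v$class == "efficacy"] < 0.05))
  expect_true(all(v$treated_p_adj[v$class %in% c("bias_up", "bias_down")]
                  < 0.05))
})

test_that("classifyAll reports missing metabolite ids", {
  co <- generateCohort(cohortSpec(nMetabolites = 20, nEfficacy = 2,
                                  nBias = 2, seed = 22))
  an <- analyzeCohort(co)
  vipShort <- an$vip[-1, ]
  expect_error(classifyAll(an$pp$analysis, an$groups, vipShort,
                           an$diffChallenge, an$diffTreatment),
               an$vip$metabolite[1])
})

test_that("stronger planted bias never recovers fewer bias metabolites", {
  meanBias <- vapply(c(0, 1.5, 3), function(d) {
    counts <- vapply(1:60, function(s) {
      co <- generateCohort(cohortSpec(nPerGroup = 7, nMetabolites = 100,
                                      nEfficacy = 0, nBias = 10,
                                      challengeEffect = 0, biasEffect = d,
                                      seed = s))
      v <- analyzeCohort(co)$verdicts
      sum(v$class %in% c("bias_up", "bias_down"))
    }, 0)
    mean(counts)
  }, 0)
  expect_true(all(diff(meanBias) >= 0))
})
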