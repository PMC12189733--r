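test_that("identical specs give byte-identical cohorts and knowledge", {
  spec <- cohortSpec(nMetabolites = 60, nEfficacy = 6, nBias = 6, seed = 42)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(abundances(a$table), abundances(b$table))
  expect_identical(a$truth@efficacyIds, b$truth@efficacyIds)
  expect_identical(a$truth@groupMeans, b$truth@groupMeans)
  k1 <- generateKnowledge(a$truth, 6, seed = 9)
  k2 <- generateKnowledge(b$truth, 6, seed = 9)
  expect_identical(setMembers(k1$metaboliteSets), setMembers(k2$metaboliteSets))
  expect_identical(mappedGenes(k1$mapping), mappedGenes(k2$mapping))
  expect_identical(lapply(k1$graphs, edgeTable), lapply(k2$graphs, edgeTable))
})

test_that("invalid specs fail naming the offending field", {
  expect_error(cohortSpec(nMetabolites = 5, nEfficacy = 4, nBias = 4),
               "nEfficacy")
  expect_error(cohortSpec(restorationFraction = 1.5), "restorationFraction")
  expect_error(cohortSpec(challengeEffect = -1), "challengeEffect")
  expect_error(cohortSpec(baselineLogSd = 0), "baselineLogSd")
  expect_error(cohortSpec(missingRate = 1), "missingRate")
})

test_that("null spec yields uniform two-sample t-test p-values", {
  spec <- cohortSpec(nPerGroup = 7, nMetabolites = 500, nEfficacy = 0,
                     nBias = 0, challengeEffect = 0, biasEffect = 0,
                     missingRate = 0, seed = 7)
  co <- generateCohort(spec)
  x <- t(abundances(co$table))
  g <- groupLabels(co$table)
  p <- apply(x, 2L, function(v) {
    stats::t.test(log(v[g == "control"]), log(v[g == "challenge"]),
                  var.equal = TRUE)$p.value
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("treated means of planted efficacy metabolites sit between control and challenge", {
  # Monte-Carlo over 200 replicate cohorts at the planted design point
  hits <- 0L; total <- 0L
  for (s in 1:200) {
    co <- generateCohort(cohortSpec(nPerGroup = 7, nMetabolites = 20,
                                    nEfficacy = 5, nBias = 0,
                                    challengeEffect = 3,
                                    restorationFraction = 0.5,
                                    baselineLogSd = 0.3, missingRate = 0,
                                    seed = s))
    x <- log(t(abundances(co$table)))
    g <- groupLabels(co$table)
    for (id in co$truth@efficacyIds) {
      mC <- mean(x[g == "control", id])
      mA <- mean(x[g == "challenge", id])
      mT <- mean(x[g == "treated", id])
      total <- total + 1L
      if (mT > min(mC, mA) && mT < max(mC, mA)) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("log-scale group means converge to the planted expectations", {
  spec <- cohortSpec(nPerGroup = 500, nMetabolites = 12, nEfficacy = 3,
                     nBias = 3, missingRate = 0, seed = 3)
  co <- generateCohort(spec)
  x <- log(t(abundances(co$table)))
  g <- groupLabels(co$table)
  se <- spec$baselineLogSd / sqrt(spec$nPerGroup)
  # 48 simultaneous mean comparisons: a 4-se band keeps the familywise
  # false-alarm probability below ~0.3%
  for (grp in groupLevels()) {
    emp <- colMeans(x[g == grp, , drop = FALSE])
    expect_true(all(abs(emp - co$truth@groupMeans[, grp]) < 4 * se))
  }
})

test_that("planted bias metabolites shift treated and drug-alone to the recorded side", {
  co <- generateCohort(cohortSpec(nMetabolites = 80, nEfficacy = 8,
                                  nBias = 12, seed = 5))
  mu <- co$truth@groupMeans
  up <- co$truth@biasUpIds; dn <- co$truth@biasDownIds
  expect_true(all(mu[up, "treated"] > pmax(mu[up, "control"],
                                           mu[up, "challenge"])))
  expect_true(all(mu[dn, "treated"] < pmin(mu[dn, "control"],
                                           mu[dn, "challenge"])))
  expect_identical(mu[c(up, dn), "treated"], mu[c(up, dn), "drug_alone"])
  # unplanted metabolites are flat across groups
  flat <- setdiff(rownames(mu), c(co$truth@efficacyIds, up, dn))
  expect_true(all(mu[flat, ] == mu[flat, "control"]))
})

test_that("ground-truth sets are disjoint and masking matches the missing rate", {
  spec <- cohortSpec(nMetabolites = 300, nEfficacy = 30, nBias = 30,
                     missingRate = 0.1, seed = 8)
  co <- generateCohort(spec)
  tr <- co$truth
  expect_length(intersect(tr@efficacyIds,
                          c(tr@biasUpIds, tr@biasDownIds)), 0)
  obs <- mean(is.na(abundances(co$table)))
  expect_lt(abs(obs - 0.1), 0.01)
})

test_that("knowledge with no planted metabolites emits only decoys", {
  co <- generateCohort(cohortSpec(nMetabolites = 60, nEfficacy = 0,
                                  nBias = 0, seed = 2))
  k <- generateKnowledge(co$truth, 5, seed = 1)
  expect_length(k$graphs, 5)
  expect_true(all(grepl("^PW_DECOY", names(k$graphs))))
  expect_true(all(grepl("^MS_DECOY", setIds(k$metaboliteSets))))
})

test_that("knowledge validates nPathways against the planted structure", {
  co <- generateCohort(cohortSpec(nMetabolites = 60, nEfficacy = 6,
                                  nBias = 6, seed = 2))
  expect_error(generateKnowledge(co$truth, 1), "nPathways")
  expect_error(generateKnowledge(co$truth, 2), "nPathways")
})

test_that("the double pathway draws at least half its genes from planted metabolites", {
  co <- generateCohort(cohortSpec(seed = 4))
  k <- generateKnowledge(co$truth, 8, seed = 4)
  planted <- c(co$truth@efficacyIds, co$truth@biasUpIds,
               co$truth@biasDownIds)
  plantedGenes <- sub("^M", "G", planted)
  frac <- mean(nodeIds(k$graphs$PW_DOUBLE) %in% plantedGenes)
  expect_gte(frac, 0.5)
})

test_that("mapping covers every metabolite and pathway graphs are connected", {
  co <- generateCohort(cohortSpec(nMetabolites = 100, nEfficacy = 10,
                                  nBias = 10, seed = 6))
  k <- generateKnowledge(co$truth, 6, seed = 6)
  expect_setequal(names(mappedGenes(k$mapping)),
                  metaboliteIds(co$table))
  for (g in k$graphs) {
    ig <- igraph::graph_from_edgelist(edgeTable(g), directed = FALSE)
    expect_true(igraph::is_connected(ig))
    expect_setequal(igraph::V(ig)$name, nodeIds(g))
  }
})
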