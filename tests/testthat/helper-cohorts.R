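# Shared fixtures and the reference analysis chain used by the
# simulation-based tests.

# Tiny deterministic feature table: 4 groups x nPerGroup samples.
toyTable <- function(nPerGroup = 3L, nMet = 4L, seed = 1L) {
  set.seed(seed)
  g <- rep(groupLevels(), each = nPerGroup)
  m <- matrix(exp(stats::rnorm(nMet * length(g), 5, 0.4)),
              nrow = nMet,
              dimnames = list(sprintf("M%02d", seq_len(nMet)),
                              paste0("s", seq_along(g))))
  FeatureTable(m, g)
}

# The in-memory analysis chain on one generated cohort (mirrors the
# pipeline stages without file I/O). maxIter is raised because NIPALS can
# converge slowly on null cohorts where the leading singular values of the
# deflated cross-covariance nearly tie.
analyzeCohort <- function(cohort, nComponents = 2L, maxIter = 25000L) {
  pp <- preprocessFeatures(cohort$table)
  g <- groupLabels(cohort$table)
  model <- fitPlsda(pp$x, g, nComponents = nComponents, maxIter = maxIter)
  vip <- computeVip(model)
  dc <- differentialTest(pp$analysis, g, "control", "challenge")
  dt <- differentialTest(pp$analysis, g, "control", "treated")
  verdicts <- classifyAll(pp$analysis, g, vip, dc, dt)
  list(pp = pp, groups = g, model = model, vip = vip,
       diffChallenge = dc, diffTreatment = dt, verdicts = verdicts)
}

# Sensitivity / precision of recovered efficacy and bias classes.
classMetrics <- function(verdicts, truth) {
  eff <- truth@efficacyIds
  bias <- c(truth@biasUpIds, truth@biasDownIds)
  effCall <- verdicts$metabolite[verdicts$class == "efficacy"]
  biasCall <- verdicts$metabolite[verdicts$class %in% c("bias_up", "bias_down")]
  c(effSens = if (length(eff)) mean(eff %in% effCall) else NA_real_,
    effPrec = if (length(effCall)) mean(effCall %in% eff) else NA_real_,
    biasSens = if (length(bias)) mean(bias %in% biasCall) else NA_real_,
    biasPrec = if (length(biasCall)) mean(biasCall %in% bias) else NA_real_,
    unclassified = mean(verdicts$class == "unclassified"))
}
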