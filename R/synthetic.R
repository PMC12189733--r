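# Synthetic four-group cohorts with planted efficacy/bias structure.
#
# The generator defines the study conditions of every simulation in the
# package: log-normal abundances (multiplicative LC-MS noise, shared sigma
# across groups), a challenge effect on the efficacy subset, partial drug
# restoration of that subset, and a drug-intrinsic shift (treated and
# drug-alone together, same side) on the bias subset. Ground truth is
# recorded so downstream stages have a recoverable target.

#' Specification of a synthetic four-group cohort
#'
#' Effect sizes are standardized (Cohen's d) on the natural-log scale:
#' group means are shifted by \code{effect * baselineLogSd}. For an
#' efficacy metabolite the challenge moves its mean by
#' \code{challengeEffect} standard deviations (direction random per
#' metabolite), the treated mean moves back toward control by
#' \code{restorationFraction} of the gap, and drug alone has no effect.
#' For a bias metabolite the challenge has no effect and both treated and
#' drug-alone means are shifted by \code{biasEffect} standard deviations to
#' the same side (up or down, 50/50 per metabolite, recorded in the ground
#' truth). A \code{missingRate} fraction of cells is masked completely at
#' random.
#'
#' Defaults mirror a small-animal design: 7 samples per group, 400
#' metabolites of which 40 are planted efficacy and 40 planted bias
#' responders, strong effects (d = 3), half restoration, and 2\% missing
#' cells.
#'
#' @param nPerGroup samples per group (4 groups total).
#' @param nMetabolites number of metabolites.
#' @param nEfficacy,nBias planted subset sizes;
#'   \code{nEfficacy + nBias <= nMetabolites}.
#' @param challengeEffect,biasEffect standardized effect sizes (>= 0, log
#'   scale).
#' @param restorationFraction in [0, 1]; 1 = full restoration to control.
#' @param baselineLogMean log-scale baseline abundance.
#' @param baselineLogSd log-scale within-group standard deviation (> 0).
#' @param missingRate fraction of cells masked at random, in [0, 1).
#' @param seed integer RNG seed; identical specs give byte-identical
#'   cohorts.
#' @return a validated list of class \code{"CohortSpec"}.
#' @seealso \code{\link{generateCohort}}
#' @export
cohortSpec <- function(nPerGroup = 7L, nMetabolites = 400L, nEfficacy = 40L,
                       nBias = 40L, challengeEffect = 3, restorationFraction = 0.5,
                       biasEffect = 3, baselineLogMean = 10, baselineLogSd = 0.3,
                       missingRate = 0.02, seed = 1L) {
  spec <- list(nPerGroup = as.integer(nPerGroup),
               nMetabolites = as.integer(nMetabolites),
               nEfficacy = as.integer(nEfficacy), nBias = as.integer(nBias),
               challengeEffect = challengeEffect,
               restorationFraction = restorationFraction,
               biasEffect = biasEffect, baselineLogMean = baselineLogMean,
               baselineLogSd = baselineLogSd, missingRate = missingRate,
               seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  checkCohortSpec(spec)
  spec
}

checkCohortSpec <- function(spec) {
  chk <- function(ok, field, why) {
    if (!ok) validationError("invalid CohortSpec: %s %s", field, why)
  }
  chk(spec$nPerGroup >= 2L, "nPerGroup", "must be >= 2")
  chk(spec$nMetabolites >= 1L, "nMetabolites", "must be >= 1")
  chk(spec$nEfficacy >= 0L, "nEfficacy", "must be >= 0")
  chk(spec$nBias >= 0L, "nBias", "must be >= 0")
  chk(spec$nEfficacy + spec$nBias <= spec$nMetabolites, "nEfficacy",
      "+ nBias must not exceed nMetabolites")
  chk(spec$challengeEffect >= 0, "challengeEffect", "must be >= 0")
  chk(spec$biasEffect >= 0, "biasEffect", "must be >= 0")
  chk(spec$restorationFraction >= 0 && spec$restorationFraction <= 1,
      "restorationFraction", "must be in [0, 1]")
  chk(spec$baselineLogSd > 0, "baselineLogSd", "must be > 0")
  chk(spec$missingRate >= 0 && spec$missingRate < 1, "missingRate",
      "must be in [0, 1)")
  invisible(spec)
}

#' @export
print.CohortSpec <- function(x, ...) {
  cat("CohortSpec:", 4L * x$nPerGroup, "samples (4 x", x$nPerGroup, "),",
      x$nMetabolites, "metabolites (", x$nEfficacy, "efficacy,",
      x$nBias, "bias planted), seed", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws abundances \code{exp(Normal(mu_gj, sigma))} per metabolite j and
#' group g under the planted structure described in
#' \code{\link{cohortSpec}}. Planted metabolites are placed at random
#' positions; unplanted metabolites have identical means across groups.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return list with elements \code{table} (a \linkS4class{FeatureTable})
#'   and \code{truth} (a \linkS4class{GroundTruth}).
#' @examples
#' cohort <- generateCohort(cohortSpec(nMetabolites = 50, nEfficacy = 5,
#'                                     nBias = 5, seed = 7))
#' cohort$table
#' cohort$truth
#' @export
generateCohort <- function(spec) {
  if (!inherits(spec, "CohortSpec")) spec <- do.call(cohortSpec, spec)
  checkCohortSpec(spec)
  p <- spec$nMetabolites
  n <- spec$nPerGroup
  sigma <- spec$baselineLogSd
  metIds <- sprintf("M%0*d", max(3L, nchar(p)), seq_len(p))
  groups <- rep(groupLevels(), each = n)
  sampIds <- paste0(groups, "_", rep(seq_len(n), times = 4L))

  withSeed(spec$seed, {
    planted <- sample.int(p, spec$nEfficacy + spec$nBias)
    effIdx <- planted[seq_len(spec$nEfficacy)]
    biasIdx <- planted[spec$nEfficacy + seq_len(spec$nBias)]
    effSign <- sample(c(-1, 1), spec$nEfficacy, replace = TRUE)
    biasSign <- sample(c(-1, 1), spec$nBias, replace = TRUE)

    mu <- matrix(spec$baselineLogMean, nrow = p, ncol = 4L,
                 dimnames = list(metIds, groupLevels()))
    # efficacy: challenge shifts, treatment restores part of the gap,
    # drug alone mirrors control.
    mu[effIdx, "challenge"] <- mu[effIdx, "control"] +
      effSign * spec$challengeEffect * sigma
    mu[effIdx, "treated"] <- mu[effIdx, "challenge"] +
      spec$restorationFraction *
        (mu[effIdx, "control"] - mu[effIdx, "challenge"])
    # bias: drug-intrinsic shift, same side for treated and drug alone.
    mu[biasIdx, "treated"] <- mu[biasIdx, "control"] +
      biasSign * spec$biasEffect * sigma
    mu[biasIdx, "drug_alone"] <- mu[biasIdx, "treated"]

    vals <- matrix(NA_real_, nrow = p, ncol = 4L * n,
                   dimnames = list(metIds, sampIds))
    for (g in seq_along(groupLevels())) {
      cols <- (g - 1L) * n + seq_len(n)
      vals[, cols] <- exp(mu[, g] + sigma * matrix(stats::rnorm(p * n), p, n))
    }
    if (spec$missingRate > 0) {
      mask <- stats::runif(length(vals)) < spec$missingRate
      vals[mask] <- NA_real_
    }
    truth <- methods::new("GroundTruth",
                          efficacyIds = metIds[effIdx],
                          biasUpIds = metIds[biasIdx[biasSign > 0]],
                          biasDownIds = metIds[biasIdx[biasSign < 0]],
                          groupMeans = mu)
    methods::validObject(truth)
    list(table = FeatureTable(vals, groups), truth = truth)
  })
}

#' Generate pathway knowledge matched to a planted cohort
#'
#' Emits the three knowledge artifacts the enrichment stages consume, with
#' planted signal mirroring the cohort's ground truth: a metabolite-to-gene
#' mapping covering every metabolite, metabolite sets (for MSEA), and
#' connected pathway graphs (for the centrality-weighted stage). When
#' planted metabolites exist, one pathway is built from
#' efficacy-metabolite genes, one from bias-metabolite genes, and one
#' "double" pathway draws half from each (the jointly enriched target of
#' the dual-axis ranking); remaining pathways are size-matched decoys over
#' unplanted genes. With no planted metabolites only decoys are emitted.
#'
#' Each metabolite maps to one primary gene; a fraction also map to a
#' shared hub gene, giving the mapping realistic many-to-one overlap.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param nPathways total number of pathways/sets (>= 3 with planted
#'   metabolites, >= 2 otherwise).
#' @param seed integer RNG seed.
#' @param pathwaySize nodes per pathway (and members per metabolite set).
#' @param hubFraction fraction of metabolites given a second, shared hub
#'   gene.
#' @return list with \code{metaboliteSets}
#'   (\linkS4class{MetaboliteSetCollection}), \code{mapping}
#'   (\linkS4class{MappingTable}) and \code{graphs} (named list of
#'   \linkS4class{PathwayGraph}).
#' @export
generateKnowledge <- function(truth, nPathways = 8L, seed = 1L,
                              pathwaySize = 20L, hubFraction = 0.25) {
  stopifnot(methods::is(truth, "GroundTruth"))
  nPathways <- as.integer(nPathways)
  if (nPathways < 2L)
    validationError("nPathways must be >= 2, got %d", nPathways)
  metIds <- rownames(truth@groupMeans)
  effIds <- truth@efficacyIds
  biasIds <- c(truth@biasUpIds, truth@biasDownIds)
  planted <- length(effIds) > 0L || length(biasIds) > 0L
  if (planted && nPathways < 3L)
    validationError(
      "nPathways must be >= 3 when planted metabolites are present, got %d",
      nPathways)

  withSeed(seed, {
    # --- mapping: one primary gene per metabolite + shared hubs -----------
    primary <- stats::setNames(sub("^M", "G", metIds), metIds)
    nHub <- max(1L, round(length(metIds) / 20))
    hubs <- sprintf("HUB%02d", seq_len(nHub))
    genes <- lapply(metIds, function(m) primary[[m]])
    names(genes) <- metIds
    withHub <- stats::runif(length(metIds)) < hubFraction
    genes[withHub] <- Map(c, genes[withHub],
                          sample(hubs, sum(withHub), replace = TRUE))
    mapping <- MappingTable(genes)

    unplanted <- setdiff(metIds, c(effIds, biasIds))
    size <- min(pathwaySize, max(2L, length(metIds)))

    takeGenes <- function(ids, k) unname(primary[sampleVec(ids, min(k, length(ids)))])
    decoyGenes <- function() unname(primary[sampleVec(unplanted, min(size, length(unplanted)))])
    decoyMets <- function() sampleVec(unplanted, min(size, length(unplanted)))

    pwGenes <- list()
    msMembers <- list()
    if (planted) {
      half <- max(1L, size %/% 2L)
      if (length(effIds)) {
        pwGenes[["PW_EFFICACY"]] <- takeGenes(effIds, size)
        msMembers[["MS_EFFICACY"]] <- sampleVec(effIds, min(size, length(effIds)))
      }
      if (length(biasIds)) {
        pwGenes[["PW_BIAS"]] <- takeGenes(biasIds, size)
        msMembers[["MS_BIAS"]] <- sampleVec(biasIds, min(size, length(biasIds)))
      }
      if (length(effIds) && length(biasIds)) {
        pwGenes[["PW_DOUBLE"]] <- unique(c(takeGenes(effIds, half),
                                           takeGenes(biasIds, size - half)))
        msMembers[["MS_DOUBLE"]] <- unique(c(
          sampleVec(effIds, min(half, length(effIds))),
          sampleVec(biasIds, min(size - half, length(biasIds)))))
      }
    }
    nDecoy <- nPathways - length(pwGenes)
    for (i in seq_len(nDecoy)) {
      id <- sprintf("PW_DECOY%02d", i)
      pwGenes[[id]] <- decoyGenes()
      msMembers[[sprintf("MS_DECOY%02d", i)]] <- decoyMets()
    }

    graphs <- lapply(names(pwGenes), function(id) {
      randomConnectedGraph(id, pwGenes[[id]])
    })
    names(graphs) <- names(pwGenes)

    sets <- MetaboliteSetCollection(
      names(msMembers), msMembers,
      descriptions = rep("synthetic metabolite set", length(msMembers)))

    list(metaboliteSets = sets, mapping = mapping, graphs = graphs)
  })
}

# sample() without the length-1 surprise
sampleVec <- function(x, k) x[sample.int(length(x), k)]

# random connected simple graph: spanning tree plus ~n/2 extra edges
randomConnectedGraph <- function(id, nodes) {
  n <- length(nodes)
  if (n < 2L) return(PathwayGraph(id, nodes))
  ord <- sampleVec(nodes, n)
  tree <- cbind(ord[vapply(2:n, function(i) sample.int(i - 1L, 1L), 0L)],
                ord[2:n])
  extra <- if (n >= 3L) {
    t(replicate(max(1L, n %/% 2L), sampleVec(nodes, 2L)))
  } else NULL
  PathwayGraph(id, nodes, rbind(tree, extra))
}
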