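# Differential testing and the efficacy/bias classification rule.
#
# A differential metabolite whose treated-group mean falls strictly inside
# the control-challenge interval is efficacy-related (the drug restores it
# toward baseline); one whose treated mean lies outside the interval --
# above both or below both -- is drug-bias-related (a drug-intrinsic
# shift). Efficacy additionally requires a significant control-vs-challenge
# contrast (restoration is undefined without a challenge effect); bias
# requires a significant treated-vs-control contrast (the rule applies to
# differential metabolites, which keeps the null false-positive rate low).

#' Per-metabolite two-group differential testing
#'
#' Two-tailed test per metabolite with Benjamini-Hochberg step-up
#' adjustment across all tested metabolites. Method \code{"auto"} uses
#' Student's t-test when a Shapiro-Wilk normality check passes in both
#' groups at alpha = 0.05, otherwise the Mann-Whitney test. Metabolites
#' whose two groups are identical with zero spread get p = 1 by convention
#' and are flagged.
#'
#' @param x numeric matrix (samples x metabolites) on the analysis scale,
#'   or a \linkS4class{FeatureTable} (tested on stored abundances).
#' @param groups group label per sample (ignored when \code{x} is a
#'   \code{FeatureTable}).
#' @param groupA,groupB labels of the two groups to contrast; each must
#'   have at least 3 samples.
#' @param method \code{"t"}, \code{"mannwhitney"} or \code{"auto"}.
#' @return data.frame with one row per metabolite: \code{metabolite},
#'   \code{method} used, \code{statistic}, \code{p}, \code{p_adj} (BH) and
#'   \code{flag} (degenerate-case marker, \code{""} otherwise).
#' @examples
#' cohort <- generateCohort(cohortSpec(nMetabolites = 20, nEfficacy = 4,
#'                                     nBias = 0, seed = 3))
#' pp <- preprocessFeatures(cohort$table)
#' dt <- differentialTest(pp$analysis, groupLabels(cohort$table),
#'                        "control", "challenge")
#' head(dt[order(dt$p_adj), ])
#' @export
differentialTest <- function(x, groups, groupA, groupB,
                             method = c("auto", "t", "mannwhitney")) {
  method <- match.arg(method)
  if (methods::is(x, "FeatureTable")) {
    groups <- groupLabels(x)
    x <- t(abundances(x))
  }
  x <- as.matrix(x)
  groups <- as.character(groups)
  ia <- which(groups == groupA); ib <- which(groups == groupB)
  if (length(ia) < 3L || length(ib) < 3L)
    validationError("both groups need >= 3 samples (%s: %d, %s: %d)",
                    groupA, length(ia), groupB, length(ib))
  ids <- colnames(x) %||% paste0("V", seq_len(ncol(x)))

  res <- lapply(seq_len(ncol(x)), function(j) {
    a <- x[ia, j]; b <- x[ib, j]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
      return(list(method = NA_character_, statistic = NA_real_,
                  p = NA_real_, flag = "insufficient_data"))
    if (stats::sd(c(a, b)) == 0)
      return(list(method = "degenerate", statistic = 0, p = 1,
                  flag = "zero_variance_identical"))
    useT <- switch(method,
      t = TRUE,
      mannwhitney = FALSE,
      auto = shapiroPasses(a) && shapiroPasses(b))
    if (useT) {
      tst <- stats::t.test(a, b, var.equal = TRUE)
      list(method = "t", statistic = unname(tst$statistic),
           p = tst$p.value, flag = "")
    } else {
      # exact Mann-Whitney null when there are no ties; with ties R falls
      # back to the normal approximation with continuity correction.
      tst <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
      list(method = "mannwhitney", statistic = unname(tst$statistic),
           p = tst$p.value, flag = "")
    }
  })
  p <- vapply(res, function(r) r$p, 0)
  data.frame(metabolite = ids,
             method = vapply(res, function(r) as.character(r$method), ""),
             statistic = vapply(res, function(r) r$statistic, 0),
             p = p,
             p_adj = stats::p.adjust(p, method = "BH"),
             flag = vapply(res, function(r) r$flag, ""),
             row.names = ids, stringsAsFactors = FALSE)
}

# Shapiro-Wilk at alpha = 0.05; constant samples (test undefined) count as
# non-normal so "auto" falls back to the rank test.
shapiroPasses <- function(v, alpha = 0.05) {
  if (length(unique(v)) < 3L) return(FALSE)
  ok <- tryCatch(stats::shapiro.test(v)$p.value >= alpha,
                 error = function(e) FALSE)
  isTRUE(ok)
}

#' Classify one metabolite as efficacy- or bias-related
#'
#' The between/outside-interval rule on group means (analysis scale):
#' efficacy iff \code{min(mC, mA) + epsilon <= mT <= max(mC, mA) - epsilon}
#' and the challenge contrast is significant; bias_up iff
#' \code{mT > max(mC, mA) + epsilon}; bias_down iff
#' \code{mT < min(mC, mA) - epsilon}; otherwise unclassified. The rule is
#' symmetric in \code{mC} and \code{mA}.
#'
#' @param mControl,mChallenge,mTreated finite group means.
#' @param challengeSignificant was the control-vs-challenge contrast
#'   significant (BH-adjusted)? Without it "restoration" is undefined and
#'   the efficacy label is withheld.
#' @param epsilon non-negative dead-band around the interval boundaries
#'   (analysis-scale units); 0 by default, available because boundary ties
#'   do occur in real data.
#' @return one of \code{"efficacy"}, \code{"bias_up"}, \code{"bias_down"},
#'   \code{"unclassified"}.
#' @examples
#' classifyMetabolite(0, 2, 1, challengeSignificant = TRUE)   # efficacy
#' classifyMetabolite(0, 2, 3, challengeSignificant = TRUE)   # bias_up
#' classifyMetabolite(0, 2, -1, challengeSignificant = FALSE) # bias_down
#' @export
classifyMetabolite <- function(mControl, mChallenge, mTreated,
                               challengeSignificant, epsilon = 0) {
  stopifnot(is.finite(mControl), is.finite(mChallenge), is.finite(mTreated),
            epsilon >= 0)
  lo <- min(mControl, mChallenge)
  hi <- max(mControl, mChallenge)
  if (mTreated > hi + epsilon) return("bias_up")
  if (mTreated < lo - epsilon) return("bias_down")
  if (isTRUE(challengeSignificant) &&
      mTreated >= lo + epsilon && mTreated <= hi - epsilon)
    return("efficacy")
  "unclassified"
}

#' Classify all metabolites of a cohort
#'
#' Applies \code{\link{classifyMetabolite}} to every metabolite, gated on
#' VIP: only metabolites with \code{VIP > vipThreshold} can receive a
#' non-unclassified label. Efficacy requires the control-vs-challenge
#' BH-adjusted p below \code{alpha}; bias_up/bias_down require the
#' treated-vs-control BH-adjusted p below \code{alpha} (the classification
#' applies to differential metabolites). Every verdict carries the
#' evidence behind it.
#'
#' @param x numeric matrix (samples x metabolites) on the analysis scale,
#'   or a \linkS4class{FeatureTable}.
#' @param groups group label per sample (ignored for a
#'   \code{FeatureTable}).
#' @param vip VIP table from \code{\link{computeVip}}; \code{vipColumn}
#'   selects cumulative (\code{"VIP"}, default) or a per-component column.
#' @param diffChallenge control-vs-challenge results from
#'   \code{\link{differentialTest}}.
#' @param diffTreatment control-vs-treated results from
#'   \code{\link{differentialTest}}.
#' @param vipThreshold VIP gate (default 1).
#' @param epsilon dead-band of the interval rule (default 0).
#' @param alpha significance level on BH-adjusted p-values (default 0.05).
#' @param vipColumn column of \code{vip} used for gating.
#' @return data.frame of verdicts: \code{metabolite}, \code{class},
#'   group means \code{m_control}, \code{m_challenge}, \code{m_treated},
#'   \code{m_drug_alone} (recorded, not used by the rule), \code{vip},
#'   \code{challenge_p_adj}, \code{treated_p_adj}.
#' @export
classifyAll <- function(x, groups = NULL, vip, diffChallenge, diffTreatment,
                        vipThreshold = 1, epsilon = 0, alpha = 0.05,
                        vipColumn = "VIP") {
  if (methods::is(x, "FeatureTable")) {
    groups <- groupLabels(x)
    x <- t(abundances(x))
  }
  x <- as.matrix(x)
  groups <- as.character(groups)
  ids <- colnames(x) %||% paste0("V", seq_len(ncol(x)))

  for (nm in c("vip", "diffChallenge", "diffTreatment")) {
    tab <- get(nm)
    missing <- setdiff(ids, tab$metabolite)
    if (length(missing))
      validationError("%s lacks metabolite id(s): %s", nm,
                      paste(utils::head(missing, 5L), collapse = ", "))
  }
  vipVal <- vip[[vipColumn]][match(ids, vip$metabolite)]
  pChal <- diffChallenge$p_adj[match(ids, diffChallenge$metabolite)]
  pTrt <- diffTreatment$p_adj[match(ids, diffTreatment$metabolite)]

  gm <- function(g) colMeans(x[groups == g, , drop = FALSE], na.rm = TRUE)
  mC <- gm("control"); mA <- gm("challenge")
  mT <- gm("treated"); mD <- gm("drug_alone")

  cls <- vapply(seq_along(ids), function(j) {
    if (is.na(vipVal[j]) || vipVal[j] <= vipThreshold) return("unclassified")
    v <- classifyMetabolite(mC[j], mA[j], mT[j],
                            challengeSignificant =
                              !is.na(pChal[j]) && pChal[j] < alpha,
                            epsilon = epsilon)
    if (v %in% c("bias_up", "bias_down") &&
        (is.na(pTrt[j]) || pTrt[j] >= alpha)) return("unclassified")
    v
  }, "")

  data.frame(metabolite = ids, class = cls,
             m_control = unname(mC), m_challenge = unname(mA),
             m_treated = unname(mT), m_drug_alone = unname(mD),
             vip = vipVal, challenge_p_adj = pChal, treated_p_adj = pTrt,
             row.names = ids, stringsAsFactors = FALSE)
}
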