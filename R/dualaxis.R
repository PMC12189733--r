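# Dual-axis pathway ranking: per pathway, logP = -log10 of the bias-side
# enrichment p and foldP = ratio of the efficacy-side to the bias-side
# enrichment p. A pathway enriched on both axes (joint_flag) is a
# candidate shared mechanism -- the machine form of the scatter that
# singles out such pathways.

#' Combine bias- and efficacy-side enrichment into dual-axis coordinates
#'
#' @param recordsBias,recordsEfficacy enrichment tables (from
#'   \code{\link{cepaEnrichment}} or \code{\link{msea}}) keyed by
#'   \code{id}; pathways missing from one side are dropped with a warning.
#' @param alpha significance level for the joint flag (applied to the same
#'   p-values used for the axes).
#' @param useAdjusted use BH-adjusted p-values (\code{p_adj}, default) or
#'   raw \code{p}.
#' @return data.frame sorted by descending \code{logP}, ties by ascending
#'   \code{foldP}, then id: \code{pathway}, \code{p_bias},
#'   \code{p_efficacy}, \code{logP} (\code{-log10(p_bias)}), \code{foldP}
#'   (\code{p_efficacy / p_bias}) and \code{joint_flag}
#'   (\code{p_bias <= alpha & p_efficacy <= alpha}).
#' @seealso \code{\link{rankPathways}} for the joint-first ordering.
#' @export
dualAxis <- function(recordsBias, recordsEfficacy, alpha = 0.05,
                     useAdjusted = TRUE) {
  pcol <- if (useAdjusted) "p_adj" else "p"
  for (tab in list(recordsBias, recordsEfficacy))
    if (!all(c("id", pcol) %in% colnames(tab)))
      validationError("enrichment records need columns 'id' and '%s'", pcol)
  common <- intersect(recordsBias$id, recordsEfficacy$id)
  dropped <- setdiff(union(recordsBias$id, recordsEfficacy$id), common)
  if (length(dropped))
    warning("pathway(s) missing from one side dropped: ",
            paste(dropped, collapse = ", "))
  if (!length(common))
    validationError("no pathway is present on both sides")
  pB <- recordsBias[[pcol]][match(common, recordsBias$id)]
  pE <- recordsEfficacy[[pcol]][match(common, recordsEfficacy$id)]
  badP <- c(pB, pE)
  if (any(!is.finite(badP) | badP <= 0 | badP > 1))
    validationError("enrichment p-values must lie in (0, 1]")
  out <- data.frame(pathway = common, p_bias = pB, p_efficacy = pE,
                    logP = -log10(pB), foldP = pE / pB,
                    joint_flag = pB <= alpha & pE <= alpha,
                    stringsAsFactors = FALSE)
  out <- out[radixOrder(-out$logP, out$foldP, out$pathway), , drop = FALSE]
  rownames(out) <- out$pathway
  out
}

#' Rank pathways jointly by dual-axis enrichment
#'
#' Orders a \code{\link{dualAxis}} table so jointly enriched pathways come
#' first, then by descending \code{logP}, ascending \code{foldP}, and id;
#' a total, reproducible order.
#'
#' @param dual a \code{\link{dualAxis}} result.
#' @return the same data.frame with a \code{rank} column, reordered.
#' @export
rankPathways <- function(dual) {
  ord <- radixOrder(-dual$joint_flag, -dual$logP, dual$foldP, dual$pathway)
  out <- dual[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}
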