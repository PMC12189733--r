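# Over-representation analysis: hypergeometric ORA over metabolite sets
# (MSEA) and centrality-weighted pathway enrichment with a permutation
# null. The weighted statistic scores a pathway by the summed network
# centrality of its differential nodes, so topologically central genes
# count more than peripheral ones; with equal weights the statistic
# reduces to the overlap count and the permutation p converges to the
# hypergeometric tail.

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing an overlap at least as large as the
#' one seen between a selection of size n and a set of size K drawn inside
#' a universe of size N (the observed overlap k is included in the tail).
#'
#' @param selected character vector of selected ids (subset of
#'   \code{universe}).
#' @param set character vector of annotated ids (subset of
#'   \code{universe}).
#' @param universe character vector, the background.
#' @param id label recorded in the output row.
#' @return one-row data.frame: \code{id}, \code{N}, \code{K}, \code{n},
#'   \code{k}, \code{p}.
#' @examples
#' oraHypergeometric(letters[1:5], letters[c(1:3, 6)], letters[1:10])$p
#' # 66/252: 3 or more of the 4 set members among 5 of 10
#' @export
oraHypergeometric <- function(selected, set, universe, id = "set") {
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  set <- unique(as.character(set))
  if (!length(universe)) validationError("empty universe")
  if (!length(selected)) validationError("empty selection")
  stray <- setdiff(set, universe)
  if (length(stray))
    validationError("set member(s) outside the universe: %s",
                    paste(utils::head(stray, 5L), collapse = ", "))
  stray <- setdiff(selected, universe)
  if (length(stray))
    validationError("selected id(s) outside the universe: %s",
                    paste(utils::head(stray, 5L), collapse = ", "))
  N <- length(universe); K <- length(set); n <- length(selected)
  k <- length(intersect(selected, set))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  data.frame(id = id, N = N, K = K, n = n, k = k, p = min(p, 1),
             stringsAsFactors = FALSE)
}

#' Metabolite-set enrichment analysis (ORA over a set collection)
#'
#' Runs \code{\link{oraHypergeometric}} for every set in the collection.
#' Set members outside the universe are dropped before testing (sets that
#' become empty get overlap 0 against K = 0, i.e. p = 1); BH adjustment is
#' applied across all sets in the call.
#'
#' @param selected selected metabolite ids.
#' @param collection a \linkS4class{MetaboliteSetCollection}.
#' @param universe background metabolite ids (e.g. all metabolites kept
#'   after preprocessing).
#' @return data.frame, one row per set, with \code{p_adj} added.
#' @export
msea <- function(selected, collection, universe) {
  stopifnot(methods::is(collection, "MetaboliteSetCollection"))
  universe <- unique(as.character(universe))
  members <- setMembers(collection)
  rows <- lapply(names(members), function(id) {
    oraHypergeometric(selected, intersect(members[[id]], universe),
                      universe, id = id)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- out$id
  out
}

#' Node centrality weights for a pathway graph
#'
#' @param graph a \linkS4class{PathwayGraph}.
#' @param kind \code{"equal"} (all nodes weight 1), \code{"degree"}, or
#'   \code{"betweenness"} (unnormalized shortest-path betweenness).
#'   Isolated nodes get 1 under \code{"equal"} and 0 otherwise.
#' @return named numeric vector of non-negative weights, one per node.
#' @examples
#' pg <- PathwayGraph("P3", c("A", "B", "C"),
#'                    rbind(c("A", "B"), c("B", "C")))
#' computeCentrality(pg, "betweenness")  # 0, 1, 0
#' @export
computeCentrality <- function(graph,
                              kind = c("equal", "degree", "betweenness")) {
  stopifnot(methods::is(graph, "PathwayGraph"))
  kind <- match.arg(kind)
  nodes <- nodeIds(graph)
  if (!length(nodes)) validationError("empty pathway graph")
  if (kind == "equal")
    return(stats::setNames(rep(1, length(nodes)), nodes))
  ig <- asIgraph(graph)
  w <- switch(kind,
    degree = igraph::degree(ig),
    betweenness = igraph::betweenness(ig, directed = FALSE,
                                      normalized = FALSE))
  stats::setNames(as.numeric(w[nodes]), nodes)
}

#' Centrality-weighted pathway enrichment with a permutation null
#'
#' The observed score is the summed node weight of the pathway genes found
#' in the differential gene list. The null draws the same number of genes
#' uniformly without replacement from the universe and rescores,
#' \code{nPerm} times; the p-value uses the plus-one correction
#' \eqn{p = (1 + \#\{null \ge s\}) / (1 + nPerm)}, so p is never 0 and
#' never exceeds 1. Deterministic under a fixed seed.
#'
#' @param graph a \linkS4class{PathwayGraph}; nodes must lie in
#'   \code{universe}.
#' @param diffGenes differential gene ids (subset of \code{universe}, at
#'   most as many as the universe).
#' @param universe background gene ids (conventionally
#'   \code{\link{geneUniverse}} of the mapping table).
#' @param nPerm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @param centrality weighting scheme passed to
#'   \code{\link{computeCentrality}}; default \code{"equal"}, the most
#'   conservative choice.
#' @return one-row data.frame: \code{id}, \code{N}, \code{K}, \code{n},
#'   \code{k}, \code{score}, \code{p}, \code{n_perm}, \code{seed},
#'   \code{centrality}.
#' @export
cepaOra <- function(graph, diffGenes, universe, nPerm = 10000L, seed = 1L,
                    centrality = c("equal", "degree", "betweenness")) {
  stopifnot(methods::is(graph, "PathwayGraph"))
  centrality <- match.arg(centrality)
  universe <- unique(as.character(universe))
  diffGenes <- unique(as.character(diffGenes))
  nPerm <- as.integer(nPerm)
  if (nPerm < 100L) validationError("nPerm must be >= 100, got %d", nPerm)
  if (length(diffGenes) > length(universe))
    validationError("more differential genes (%d) than universe genes (%d)",
                    length(diffGenes), length(universe))
  stray <- setdiff(diffGenes, universe)
  if (length(stray))
    validationError("differential gene(s) outside the universe: %s",
                    paste(utils::head(stray, 5L), collapse = ", "))
  stray <- setdiff(nodeIds(graph), universe)
  if (length(stray))
    validationError("pathway node(s) outside the universe: %s",
                    paste(utils::head(stray, 5L), collapse = ", "))

  w <- computeCentrality(graph, centrality)
  wvec <- numeric(length(universe))
  wvec[match(names(w), universe)] <- w
  nSel <- length(diffGenes)
  sObs <- sum(wvec[match(diffGenes, universe)])
  N <- length(universe)
  nullGe <- withSeed(seed, {
    ge <- 0L
    for (i in seq_len(nPerm))
      if (sum(wvec[sample.int(N, nSel)]) >= sObs) ge <- ge + 1L
    ge
  })
  p <- (1 + nullGe) / (1 + nPerm)
  data.frame(id = pathwayId(graph), N = N, K = length(nodeIds(graph)),
             n = nSel, k = length(intersect(diffGenes, nodeIds(graph))),
             score = sObs, p = p, n_perm = nPerm, seed = as.integer(seed),
             centrality = centrality, stringsAsFactors = FALSE)
}

#' Pathway enrichment across a collection of graphs
#'
#' Runs \code{\link{cepaOra}} on every graph with a per-pathway seed fanned
#' out deterministically from \code{seed}, and BH-adjusts across pathways.
#'
#' @param graphs named list of \linkS4class{PathwayGraph}.
#' @inheritParams cepaOra
#' @return data.frame, one row per pathway, with \code{p_adj} added.
#' @export
cepaEnrichment <- function(graphs, diffGenes, universe, nPerm = 10000L,
                           seed = 1L,
                           centrality = c("equal", "degree", "betweenness")) {
  centrality <- match.arg(centrality)
  rows <- lapply(seq_along(graphs), function(i) {
    cepaOra(graphs[[i]], diffGenes, universe, nPerm = nPerm,
            seed = as.integer(seed) + i, centrality = centrality)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- out$id
  out
}

#' Map a verdict class to its interacting genes
#'
#' Union of the gene sets of all metabolites carrying one of the requested
#' class labels (\code{"bias"} expands to \code{bias_up} and
#' \code{bias_down}). Selected metabolites absent from the mapping are
#' counted and reported via the \code{"unmapped"} attribute; an empty
#' selection or an uncovered one yields an empty set with a warning.
#'
#' @param verdicts verdict data.frame from \code{\link{classifyAll}}.
#' @param mapping a \linkS4class{MappingTable}.
#' @param classFilter class label(s) to select: any of \code{"efficacy"},
#'   \code{"bias"}, \code{"bias_up"}, \code{"bias_down"}.
#' @return character vector of gene ids with attributes
#'   \code{"metabolites"} (selected metabolite ids) and \code{"unmapped"}
#'   (count).
#' @export
mapSelection <- function(verdicts, mapping, classFilter = "efficacy") {
  stopifnot(methods::is(mapping, "MappingTable"))
  classes <- unlist(lapply(classFilter, function(f) {
    if (f == "bias") c("bias_up", "bias_down") else f
  }))
  bad <- setdiff(classes, c("efficacy", "bias_up", "bias_down",
                            "unclassified"))
  if (length(bad))
    validationError("unknown class filter: %s", paste(bad, collapse = ", "))
  mets <- verdicts$metabolite[verdicts$class %in% classes]
  if (!length(mets)) {
    warning("no metabolites carry class ",
            paste(classFilter, collapse = "/"), "; empty gene selection")
    return(structure(character(0), metabolites = character(0),
                     unmapped = 0L))
  }
  gm <- mappedGenes(mapping)
  covered <- mets %in% names(gm)
  if (!any(covered))
    warning("mapping covers none of the ", length(mets),
            " selected metabolites")
  genes <- sort(unique(unlist(gm[mets[covered]], use.names = FALSE)))
  structure(genes, metabolites = mets, unmapped = sum(!covered))
}
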