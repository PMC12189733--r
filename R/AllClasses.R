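#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
NULL

# ---------------------------------------------------------------------------
# FeatureTable
# ---------------------------------------------------------------------------

#' FeatureTable: a samples-by-metabolites abundance table with group labels
#'
#' The pipeline's universal currency. Internally a
#' \linkS4class{SummarizedExperiment} with one assay, \code{"abundance"}
#' (metabolites as rows, samples as columns, non-negative values, \code{NA}
#' for missing cells), and a \code{group} column in \code{colData} holding
#' one of the four canonical labels (see \code{\link{groupLevels}}).
#'
#' @param abundance numeric matrix, metabolites x samples; non-negative or
#'   \code{NA}. Must carry row and column names (metabolite and sample ids).
#' @param groups character vector of group labels, one per sample (column).
#' @return \code{FeatureTable()} returns a validated \code{FeatureTable}.
#' @examples
#' m <- matrix(rexp(12) + 1, nrow = 3,
#'             dimnames = list(paste0("M", 1:3), paste0("S", 1:4)))
#' ft <- FeatureTable(m, c("control", "challenge", "treated", "drug_alone"))
#' groupLabels(ft)
#' @aliases FeatureTable groupLabels metaboliteIds sampleIds abundances
#'   groupLabels,FeatureTable-method metaboliteIds,FeatureTable-method
#'   sampleIds,FeatureTable-method abundances,FeatureTable-method
#' @export FeatureTable
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

validFeatureTable <- function(object) {
  msg <- character(0)
  if (!"abundance" %in% assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  if (!"group" %in% colnames(colData(object)))
    msg <- c(msg, "colData column 'group' is required")
  rn <- rownames(object); cn <- colnames(object)
  if (is.null(rn) || anyNA(rn) || any(rn == ""))
    msg <- c(msg, "metabolite ids (rownames) are required")
  if (is.null(cn) || anyNA(cn) || any(cn == ""))
    msg <- c(msg, "sample ids (colnames) are required")
  if (!is.null(rn) && anyDuplicated(rn))
    msg <- c(msg, paste0("duplicate metabolite ids: ",
                         paste(unique(rn[duplicated(rn)]), collapse = ", ")))
  if (!is.null(cn) && anyDuplicated(cn))
    msg <- c(msg, paste0("duplicate sample ids: ",
                         paste(unique(cn[duplicated(cn)]), collapse = ", ")))
  if ("group" %in% colnames(colData(object))) {
    g <- as.character(colData(object)$group)
    bad <- setdiff(unique(g), groupLevels())
    if (length(bad))
      msg <- c(msg, paste0("unrecognized group label(s): ",
                           paste(bad, collapse = ", ")))
  }
  if ("abundance" %in% assayNames(object)) {
    a <- assay(object, "abundance")
    if (!is.numeric(a)) msg <- c(msg, "abundance matrix must be numeric")
    else if (any(a < 0, na.rm = TRUE))
      msg <- c(msg, "abundance values must be non-negative")
  }
  if (length(msg)) msg else TRUE
}
setValidity("FeatureTable", validFeatureTable)

FeatureTable <- function(abundance, groups) {
  if (!is.matrix(abundance)) abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (length(groups) != ncol(abundance))
    validationError("groups: expected %d labels, got %d",
                    ncol(abundance), length(groups))
  se <- SummarizedExperiment(
    assays = list(abundance = abundance),
    colData = DataFrame(group = as.character(groups),
                        row.names = colnames(abundance)))
  ft <- methods::new("FeatureTable", se)
  methods::validObject(ft)
  ft
}

#' @export
setMethod("groupLabels", "FeatureTable",
          function(x) as.character(colData(x)$group))

#' @export
setMethod("metaboliteIds", "FeatureTable", function(x) rownames(x))

#' @export
setMethod("sampleIds", "FeatureTable", function(x) colnames(x))

#' @export
setMethod("abundances", "FeatureTable", function(x) assay(x, "abundance"))

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", nrow(object), "metabolites x",
      ncol(object), "samples\n")
  print(table(factor(groupLabels(object), levels = groupLevels())))
  miss <- mean(is.na(assay(object, "abundance")))
  cat(sprintf("missing cells: %.1f%%\n", 100 * miss))
})

# ---------------------------------------------------------------------------
# GroundTruth
# ---------------------------------------------------------------------------

#' GroundTruth: planted structure of a synthetic cohort
#'
#' Records which metabolites were planted as efficacy-related or as
#' drug-bias (up / down) responders, together with the log-scale expected
#' value of every metabolite in every group. The three planted id sets are
#' pairwise disjoint and every id appears in \code{groupMeans}.
#'
#' @slot efficacyIds character, planted restorative metabolites.
#' @slot biasUpIds,biasDownIds character, planted drug-intrinsic metabolites
#'   shifted above / below the control-challenge interval.
#' @slot groupMeans numeric matrix, metabolites x the four groups, log-scale
#'   expected values used by the generator.
#' @aliases GroundTruth
#' @exportClass GroundTruth
setClass("GroundTruth",
         representation(efficacyIds = "character",
                        biasUpIds = "character",
                        biasDownIds = "character",
                        groupMeans = "matrix"))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  sets <- list(object@efficacyIds, object@biasUpIds, object@biasDownIds)
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(sets[[i]], sets[[j]])))
      msg <- c(msg, "planted id sets must be pairwise disjoint")
  all_ids <- rownames(object@groupMeans)
  missing <- setdiff(unlist(sets), all_ids)
  if (length(missing))
    msg <- c(msg, paste0("planted ids absent from groupMeans: ",
                         paste(missing, collapse = ", ")))
  if (!identical(colnames(object@groupMeans), groupLevels()))
    msg <- c(msg, "groupMeans columns must be the four canonical groups")
  if (length(msg)) unique(msg) else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@groupMeans), "metabolites;",
      length(object@efficacyIds), "efficacy,",
      length(object@biasUpIds), "bias_up,",
      length(object@biasDownIds), "bias_down planted\n")
})

# ---------------------------------------------------------------------------
# PlsdaModel
# ---------------------------------------------------------------------------

#' PlsdaModel: a NIPALS-fitted PLS-DA model
#'
#' Latent-variable regression of the column-centered one-hot group indicator
#' matrix Y on the preprocessed abundance matrix X, fitted one component at
#' a time by NIPALS with deflation. Scores are pairwise orthogonal and each
#' weight column has unit norm; \code{explainedYSS} holds the drop in
#' \eqn{||Y||^2} achieved by each component, from which VIP scores are
#' derived (\code{\link{computeVip}}).
#'
#' @slot scores samples x A score matrix T.
#' @slot weights variables x A weight matrix W (unit-norm columns).
#' @slot xLoadings variables x A loading matrix P.
#' @slot yLoadings classes x A Y-loading matrix Q.
#' @slot explainedYSS numeric length A, Y sum of squares captured per
#'   component.
#' @slot classOrder group labels in Y column order.
#' @slot yCenter column means removed from the indicator matrix.
#' @aliases PlsdaModel plsdaScores plsdaWeights plsdaLoadings plsdaYLoadings
#'   explainedYSS classOrder nComponents
#'   plsdaScores,PlsdaModel-method plsdaWeights,PlsdaModel-method
#'   plsdaLoadings,PlsdaModel-method plsdaYLoadings,PlsdaModel-method
#'   explainedYSS,PlsdaModel-method classOrder,PlsdaModel-method
#'   nComponents,PlsdaModel-method
#' @seealso \code{\link{fitPlsda}}, \code{\link{projectPlsda}}
#' @exportClass PlsdaModel
setClass("PlsdaModel",
         representation(scores = "matrix", weights = "matrix",
                        xLoadings = "matrix", yLoadings = "matrix",
                        explainedYSS = "numeric", classOrder = "character",
                        yCenter = "numeric"))

setValidity("PlsdaModel", function(object) {
  msg <- character(0)
  A <- ncol(object@scores)
  if (A < 1L) msg <- c(msg, "at least one component is required")
  if (ncol(object@weights) != A || ncol(object@xLoadings) != A ||
      ncol(object@yLoadings) != A || length(object@explainedYSS) != A)
    msg <- c(msg, "component dimensions disagree across slots")
  wn <- sqrt(colSums(object@weights^2))
  if (any(abs(wn - 1) > 1e-6))
    msg <- c(msg, "weight columns must have unit norm")
  if (A >= 2) {
    Tn <- sweep(object@scores, 2L, sqrt(colSums(object@scores^2)), "/")
    G <- crossprod(Tn)
    if (max(abs(G[upper.tri(G)])) > 1e-8)
      msg <- c(msg, "score columns must be orthogonal")
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("plsdaScores", "PlsdaModel", function(x) x@scores)
#' @export
setMethod("plsdaWeights", "PlsdaModel", function(x) x@weights)
#' @export
setMethod("plsdaLoadings", "PlsdaModel", function(x) x@xLoadings)
#' @export
setMethod("plsdaYLoadings", "PlsdaModel", function(x) x@yLoadings)
#' @export
setMethod("explainedYSS", "PlsdaModel", function(x) x@explainedYSS)
#' @export
setMethod("classOrder", "PlsdaModel", function(x) x@classOrder)
#' @export
setMethod("nComponents", "PlsdaModel", function(x) ncol(x@scores))

setMethod("show", "PlsdaModel", function(object) {
  cat("PlsdaModel:", ncol(object@scores), "component(s),",
      nrow(object@weights), "variables,",
      nrow(object@scores), "samples\n")
  cat("classes:", paste(object@classOrder, collapse = ", "), "\n")
  cat("explained Y sum of squares:",
      paste(signif(object@explainedYSS, 4), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# PathwayGraph
# ---------------------------------------------------------------------------

#' PathwayGraph: an undirected pathway topology with node weights
#'
#' Gene nodes plus undirected simple edges read from a SIF-style edge list;
#' the optional per-node weights are network centralities
#' (\code{\link{computeCentrality}}) consumed by the permutation enrichment
#' stage (\code{\link{cepaOra}}).
#'
#' @slot pathwayId single pathway identifier.
#' @slot nodes character vector of node (gene) ids.
#' @slot edges character matrix with two columns (endpoints); undirected,
#'   deduplicated, no self-loops.
#' @slot weights named numeric, non-negative node weights (possibly empty).
#' @aliases PathwayGraph pathwayId nodeIds edgeTable nodeWeights
#'   nodeWeights<- pathwayId,PathwayGraph-method nodeIds,PathwayGraph-method
#'   edgeTable,PathwayGraph-method nodeWeights,PathwayGraph-method
#'   nodeWeights<-,PathwayGraph-method
#' @export PathwayGraph
#' @exportClass PathwayGraph
setClass("PathwayGraph",
         representation(pathwayId = "character", nodes = "character",
                        edges = "matrix", weights = "numeric"))

setValidity("PathwayGraph", function(object) {
  msg <- character(0)
  if (length(object@pathwayId) != 1L || object@pathwayId == "")
    msg <- c(msg, "pathwayId must be a single non-empty string")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node ids")
  if (nrow(object@edges) && ncol(object@edges) != 2L)
    msg <- c(msg, "edges must have two columns")
  if (nrow(object@edges)) {
    ends <- unique(as.vector(object@edges))
    stray <- setdiff(ends, object@nodes)
    if (length(stray))
      msg <- c(msg, paste0("edge endpoint(s) not in node set: ",
                           paste(stray, collapse = ", ")))
  }
  if (length(object@weights)) {
    if (any(object@weights < 0)) msg <- c(msg, "node weights must be >= 0")
    if (!all(names(object@weights) %in% object@nodes))
      msg <- c(msg, "weight names must be node ids")
  }
  if (length(msg)) msg else TRUE
})

#' @param pathwayId,nodes,edges,weights see slot descriptions.
#' @rdname PathwayGraph-class
#' @export
PathwayGraph <- function(pathwayId, nodes, edges = NULL, weights = numeric(0)) {
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    edges <- dedupEdges(edges)
  }
  nodes <- unique(c(as.character(nodes), as.vector(edges)))
  g <- methods::new("PathwayGraph", pathwayId = as.character(pathwayId),
                    nodes = nodes, edges = edges,
                    weights = weights)
  methods::validObject(g)
  g
}

# canonicalize undirected edges: sort endpoints within rows, drop self-loops
# and duplicates, keep first-seen order.
dedupEdges <- function(edges) {
  if (!nrow(edges)) return(edges)
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  keep <- a != b & !duplicated(paste(a, b, sep = "\r"))
  cbind(a[keep], b[keep])
}

#' @export
setMethod("pathwayId", "PathwayGraph", function(x) x@pathwayId)
#' @export
setMethod("nodeIds", "PathwayGraph", function(x) x@nodes)
#' @export
setMethod("edgeTable", "PathwayGraph", function(x) x@edges)
#' @export
setMethod("nodeWeights", "PathwayGraph", function(x) x@weights)
#' @export
setReplaceMethod("nodeWeights", "PathwayGraph", function(x, value) {
  x@weights <- value
  methods::validObject(x)
  x
})

setMethod("show", "PathwayGraph", function(object) {
  cat("PathwayGraph", object@pathwayId, ":", length(object@nodes),
      "nodes,", nrow(object@edges), "edges",
      if (length(object@weights)) "(weighted)" else "", "\n")
})

asIgraph <- function(pg) {
  igraph::graph_from_data_frame(
    d = as.data.frame(edgeTable(pg), stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodeIds(pg), stringsAsFactors = FALSE))
}

# ---------------------------------------------------------------------------
# MetaboliteSetCollection
# ---------------------------------------------------------------------------

#' MetaboliteSetCollection: named sets of metabolites (GMT content)
#'
#' In-memory form of a GMT file: each set has an id, a free-text
#' description and a deduplicated, non-empty member list. Used as the
#' annotation source for metabolite-set over-representation analysis
#' (\code{\link{msea}}).
#'
#' @slot setIds character vector of unique set ids.
#' @slot descriptions character vector, one per set.
#' @slot members list of character vectors, one per set.
#' @aliases MetaboliteSetCollection setIds setMembers setDescriptions
#'   setIds,MetaboliteSetCollection-method
#'   setMembers,MetaboliteSetCollection-method
#'   setDescriptions,MetaboliteSetCollection-method
#' @export MetaboliteSetCollection
#' @exportClass MetaboliteSetCollection
setClass("MetaboliteSetCollection",
         representation(setIds = "character", descriptions = "character",
                        members = "list"))

setValidity("MetaboliteSetCollection", function(object) {
  msg <- character(0)
  n <- length(object@setIds)
  if (length(object@descriptions) != n || length(object@members) != n)
    msg <- c(msg, "setIds, descriptions and members must have equal length")
  if (anyDuplicated(object@setIds)) msg <- c(msg, "duplicate set ids")
  sizes <- lengths(object@members)
  if (any(sizes == 0L)) msg <- c(msg, "empty sets are not allowed")
  if (any(vapply(object@members, anyDuplicated, 0L) > 0L))
    msg <- c(msg, "set members must be deduplicated")
  if (length(msg)) msg else TRUE
})

#' @param setIds,descriptions,members see slot descriptions; duplicates in
#'   member lists are collapsed.
#' @rdname MetaboliteSetCollection-class
#' @export
MetaboliteSetCollection <- function(setIds, members,
                                    descriptions = rep("", length(setIds))) {
  obj <- methods::new("MetaboliteSetCollection",
                      setIds = as.character(setIds),
                      descriptions = as.character(descriptions),
                      members = lapply(members,
                                       function(m) unique(as.character(m))))
  methods::validObject(obj)
  obj
}

#' @export
setMethod("setIds", "MetaboliteSetCollection", function(x) x@setIds)
#' @export
setMethod("setMembers", "MetaboliteSetCollection",
          function(x) stats::setNames(x@members, x@setIds))
#' @export
setMethod("setDescriptions", "MetaboliteSetCollection",
          function(x) stats::setNames(x@descriptions, x@setIds))
#' @export
setMethod("length", "MetaboliteSetCollection", function(x) length(x@setIds))

setMethod("show", "MetaboliteSetCollection", function(object) {
  cat("MetaboliteSetCollection:", length(object@setIds), "sets; sizes",
      paste(range(lengths(object@members)), collapse = "-"), "\n")
})

# ---------------------------------------------------------------------------
# MappingTable
# ---------------------------------------------------------------------------

#' MappingTable: metabolite-to-gene mapping
#'
#' Maps each metabolite id to the set of genes/proteins it interacts with,
#' as obtained from a local two-column lookup file. Duplicate pairs are
#' collapsed. The union of all mapped genes serves as the gene universe of
#' the pathway enrichment stage.
#'
#' @slot genes named list; names are metabolite ids, elements are character
#'   vectors of gene ids (deduplicated).
#' @aliases MappingTable mappedGenes mappedGenes,MappingTable-method
#' @export MappingTable
#' @exportClass MappingTable
setClass("MappingTable", representation(genes = "list"))

setValidity("MappingTable", function(object) {
  msg <- character(0)
  if (length(object@genes)) {
    if (is.null(names(object@genes)) || anyDuplicated(names(object@genes)))
      msg <- c(msg, "mapping must be keyed by unique metabolite ids")
    if (any(vapply(object@genes, anyDuplicated, 0L) > 0L))
      msg <- c(msg, "gene lists must be deduplicated")
  }
  if (length(msg)) msg else TRUE
})

#' @param genes named list of character vectors (metabolite id -> genes);
#'   duplicates collapsed.
#' @rdname MappingTable-class
#' @export
MappingTable <- function(genes) {
  obj <- methods::new("MappingTable",
                      genes = lapply(genes, function(g) unique(as.character(g))))
  methods::validObject(obj)
  obj
}

#' @export
setMethod("mappedGenes", "MappingTable", function(x) x@genes)
#' @export
setMethod("length", "MappingTable", function(x) length(x@genes))

setMethod("show", "MappingTable", function(object) {
  cat("MappingTable:", length(object@genes), "metabolites ->",
      length(unique(unlist(object@genes))), "genes\n")
})

#' Gene universe of a mapping table
#'
#' All distinct gene ids appearing in the mapping; the default universe of
#' the pathway enrichment stage (this choice changes enrichment p-values
#' and is therefore recorded in output metadata).
#'
#' @param mapping a \linkS4class{MappingTable}.
#' @return character vector of gene ids, sorted.
#' @export
geneUniverse <- function(mapping) {
  sort(unique(unlist(mappedGenes(mapping), use.names = FALSE)))
}
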