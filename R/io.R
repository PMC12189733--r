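# On-disk formats: feature-table CSV/TSV, GMT, SIF-style edge lists and the
# two-column metabolite->gene mapping. All readers validate strictly and
# report the offending line / id; all writers round-trip with the readers.

sepForPath <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a feature table from delimited text
#'
#' Expects samples as rows: the first column holds sample ids, a group
#' column holds the experimental group, and every remaining column is one
#' metabolite. The separator is inferred from the file extension
#' (\code{.csv} comma, \code{.tsv}/\code{.txt} tab) unless given.
#'
#' Raw tables often carry study-specific group names; \code{groupMap}
#' canonicalizes them, e.g. \code{c("vehicle" = "control",
#' "toxin" = "challenge", "toxin+drug" = "treated")}. After mapping,
#' labels must be one of
#' \code{\link{groupLevels}}.
#'
#' @param path file to read.
#' @param groupColumn name of the group column (default \code{"group"}).
#' @param groupMap optional named character vector mapping raw labels to
#'   canonical ones.
#' @param missingTokens cell values treated as missing (default empty cell
#'   and \code{"NA"}).
#' @param sep field separator; inferred from the extension when \code{NULL}.
#' @return a \linkS4class{FeatureTable}.
#' @seealso \code{\link{writeFeatureTable}}
#' @export
readFeatureTable <- function(path, groupColumn = "group", groupMap = NULL,
                             missingTokens = c("", "NA"), sep = NULL) {
  if (!file.exists(path)) validationError("file not found: %s", path)
  sep <- sepForPath(path, sep)
  # read.table silently collapses duplicate header names; validate the raw
  # header first
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  headerMet <- header[-1L][header[-1L] != groupColumn]
  if (anyDuplicated(headerMet))
    validationError("duplicate metabolite id(s): %s",
                    paste(unique(headerMet[duplicated(headerMet)]),
                          collapse = ", "))
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE,
                          na.strings = character(0))
  if (ncol(df) < 3L)
    validationError("%s: need sample id, group and >= 1 metabolite column",
                    path)
  if (!groupColumn %in% colnames(df))
    validationError("%s: group column '%s' not found", path, groupColumn)
  sampleIds <- df[[1L]]
  if (anyDuplicated(sampleIds))
    validationError("duplicate sample id(s): %s",
                    paste(unique(sampleIds[duplicated(sampleIds)]),
                          collapse = ", "))
  groups <- df[[groupColumn]]
  if (!is.null(groupMap)) {
    hit <- groups %in% names(groupMap)
    groups[hit] <- unname(groupMap[groups[hit]])
  }
  bad <- which(!groups %in% groupLevels())
  if (length(bad))
    validationError("unrecognized group label '%s' (row %d)",
                    groups[bad[1L]], bad[1L])
  metCols <- setdiff(colnames(df)[-1L], groupColumn)
  if (anyDuplicated(metCols))
    validationError("duplicate metabolite id(s): %s",
                    paste(unique(metCols[duplicated(metCols)]),
                          collapse = ", "))
  raw <- as.matrix(df[, metCols, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  isMissing <- matrix(raw %in% missingTokens, nrow = nrow(raw))
  badCell <- which(is.na(vals) & !isMissing, arr.ind = TRUE)
  if (nrow(badCell))
    validationError("non-numeric value '%s' (sample %s, metabolite %s)",
                    raw[badCell[1L, 1L], badCell[1L, 2L]],
                    sampleIds[badCell[1L, 1L]], metCols[badCell[1L, 2L]])
  vals[isMissing] <- NA_real_
  mat <- t(vals)
  dimnames(mat) <- list(metCols, sampleIds)
  FeatureTable(mat, groups)
}

#' Write a feature table as delimited text
#'
#' Samples as rows: sample id, group, then one column per metabolite.
#' Round-trips with \code{\link{readFeatureTable}} including missing-cell
#' positions.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param path destination file; extension selects the separator unless
#'   \code{sep} is given.
#' @param missingToken string written for missing cells (default
#'   \code{"NA"}).
#' @param sep field separator; inferred from the extension when \code{NULL}.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(table, path, missingToken = "NA", sep = NULL) {
  sep <- sepForPath(path, sep)
  m <- t(abundances(table))
  # %.17g preserves doubles exactly, so read(write(x)) == x bit for bit
  fm <- matrix(sprintf("%.17g", m), nrow = nrow(m), dimnames = dimnames(m))
  fm[is.na(m)] <- missingToken
  out <- data.frame(sample = sampleIds(table),
                    group = groupLabels(table),
                    fm, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = missingToken)
  invisible(path)
}

#' Read / write GMT metabolite- or gene-set files
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' \code{id<TAB>description<TAB>member1<TAB>member2...}. Lines with fewer
#' than three fields are rejected with their line number; member lists are
#' deduplicated.
#'
#' @param path GMT file.
#' @return \code{readGmt} returns a \linkS4class{MetaboliteSetCollection};
#'   \code{writeGmt} returns \code{path} invisibly.
#' @seealso \linkS4class{MetaboliteSetCollection}
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) validationError("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) validationError("%s: empty GMT file", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    validationError("%s: line %d has fewer than 3 tab-separated fields",
                    path, short[1L])
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) {
    m <- f[-(1:2)]
    m[nzchar(m)]
  })
  empty <- which(lengths(members) == 0L)
  if (length(empty))
    validationError("%s: line %d has an empty member list", path, empty[1L])
  if (anyDuplicated(ids))
    validationError("%s: duplicate set id(s): %s", path,
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  MetaboliteSetCollection(ids, members, desc)
}

#' @param collection a \linkS4class{MetaboliteSetCollection}.
#' @rdname readGmt
#' @export
writeGmt <- function(collection, path) {
  mem <- setMembers(collection)
  desc <- setDescriptions(collection)
  lines <- vapply(seq_along(mem), function(i) {
    paste(c(names(mem)[i], desc[i], mem[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write SIF-style edge lists
#'
#' Tab-separated lines \code{source<TAB>relation<TAB>target}. The relation
#' field is parsed and ignored: graphs are treated as undirected simple
#' graphs (centrality is computed on topology only). Duplicate edges and
#' self-loops are collapsed/dropped silently.
#'
#' @param path SIF file.
#' @param pathwayId identifier for the resulting graph; defaults to the file
#'   name without extension.
#' @param nodes optional full node set (adds isolated nodes not present in
#'   any edge).
#' @return \code{readEdgeList} returns a \linkS4class{PathwayGraph};
#'   \code{writeEdgeList} returns \code{path} invisibly.
#' @export
readEdgeList <- function(path,
                         pathwayId = tools::file_path_sans_ext(basename(path)),
                         nodes = character(0)) {
  if (!file.exists(path)) validationError("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    validationError("%s: line %d is not 'source<TAB>relation<TAB>target'",
                    path, which(keep)[bad[1L]])
  edges <- if (length(fields)) {
    cbind(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 3L))
  } else NULL
  PathwayGraph(pathwayId, nodes = nodes, edges = edges)
}

#' @param graph a \linkS4class{PathwayGraph}.
#' @param relation relation string written in the middle column.
#' @rdname readEdgeList
#' @export
writeEdgeList <- function(graph, path, relation = "interacts-with") {
  e <- edgeTable(graph)
  lines <- if (nrow(e)) paste(e[, 1L], relation, e[, 2L], sep = "\t")
           else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a metabolite-to-gene mapping table
#'
#' Two-column TSV (metabolite id, gene id), one pair per line; duplicate
#' pairs are collapsed silently. Emulates a local dump of an interaction
#' database lookup.
#'
#' @param path mapping TSV.
#' @return \code{readMapping} returns a \linkS4class{MappingTable};
#'   \code{writeMapping} returns \code{path} invisibly.
#' @export
readMapping <- function(path) {
  if (!file.exists(path)) validationError("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    validationError("%s: line %d is not 'metabolite<TAB>gene'",
                    path, which(keep)[bad[1L]])
  met <- vapply(fields, `[[`, "", 1L)
  gene <- vapply(fields, `[[`, "", 2L)
  MappingTable(split(gene, factor(met, levels = unique(met))))
}

#' @param mapping a \linkS4class{MappingTable}.
#' @rdname readMapping
#' @export
writeMapping <- function(mapping, path) {
  g <- mappedGenes(mapping)
  lines <- unlist(lapply(names(g), function(m) paste(m, g[[m]], sep = "\t")),
                  use.names = FALSE)
  writeLines(lines %||% character(0), path)
  invisible(path)
}
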