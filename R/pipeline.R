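# Orchestration: preprocess -> PLS-DA/VIP -> differential tests ->
# classification -> gene mapping -> MSEA + centrality-weighted pathway
# enrichment -> dual-axis ranking, with a run manifest for
# reproducibility. All randomness flows from one root seed fanned out
# deterministically to the enrichment stages.

#' Pipeline run configuration
#'
#' Validates input paths at construction time, so a misconfigured run
#' fails before any computation.
#'
#' @param featureTable path to the feature-table CSV/TSV.
#' @param metaboliteSets path to the metabolite-set GMT (MSEA stage).
#' @param mapping path to the metabolite-to-gene mapping TSV.
#' @param graphDir directory of per-pathway SIF edge-list files
#'   (\code{*.sif}).
#' @param membershipGmt optional path to a pathway-to-gene membership GMT;
#'   adds isolated nodes absent from the edge lists.
#' @param outDir output directory (created if needed).
#' @param groupColumn,groupMap passed to \code{\link{readFeatureTable}}.
#' @param preprocess a \code{\link{preprocessConfig}}.
#' @param nComponents PLS-DA components (default 2: the two leading axes
#'   carry the bias/efficacy contrast in this design).
#' @param vipThreshold VIP gate (default 1).
#' @param vipColumn \code{"VIP"} (cumulative, default) or a per-component
#'   column such as \code{"VIP1"}.
#' @param testMethod differential test method (\code{"auto"}, \code{"t"},
#'   \code{"mannwhitney"}).
#' @param epsilon dead-band of the classification rule.
#' @param centrality pathway node weighting (\code{"equal"},
#'   \code{"degree"}, \code{"betweenness"}).
#' @param nPerm permutations of the pathway-enrichment null.
#' @param alpha significance level (BH-adjusted) used throughout.
#' @param useAdjusted dual-axis on adjusted (default) or raw p-values.
#' @param seed root RNG seed, recorded in every output.
#' @return list of class \code{"RunConfig"}.
#' @export
runConfig <- function(featureTable, metaboliteSets, mapping, graphDir,
                      outDir, membershipGmt = NULL, groupColumn = "group",
                      groupMap = NULL, preprocess = preprocessConfig(),
                      nComponents = 2L, vipThreshold = 1, vipColumn = "VIP",
                      testMethod = "auto", epsilon = 0,
                      centrality = "equal", nPerm = 10000L, alpha = 0.05,
                      useAdjusted = TRUE, seed = 1L) {
  for (p in c(featureTable, metaboliteSets, mapping, graphDir,
              membershipGmt)) {
    if (!file.exists(p)) validationError("input path does not exist: %s", p)
  }
  cfg <- list(featureTable = featureTable, metaboliteSets = metaboliteSets,
              mapping = mapping, graphDir = graphDir,
              membershipGmt = membershipGmt, outDir = outDir,
              groupColumn = groupColumn, groupMap = groupMap,
              preprocess = preprocess, nComponents = as.integer(nComponents),
              vipThreshold = vipThreshold, vipColumn = vipColumn,
              testMethod = testMethod, epsilon = epsilon,
              centrality = centrality, nPerm = as.integer(nPerm),
              alpha = alpha, useAdjusted = useAdjusted,
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("RunConfig: table =", x$featureTable, "\n  out =", x$outDir,
      "\n  components =", x$nComponents, ", VIP >", x$vipThreshold,
      ", centrality =", x$centrality, ", nPerm =", x$nPerm,
      ", seed =", x$seed, "\n")
  invisible(x)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# Model as a single structured JSON artifact (all matrices + params).
serializePlsdaModel <- function(model, path) {
  m2l <- function(m) list(values = unname(m), rownames = rownames(m),
                          colnames = colnames(m))
  obj <- list(nComponents = nComponents(model),
              scores = m2l(plsdaScores(model)),
              weights = m2l(plsdaWeights(model)),
              xLoadings = m2l(plsdaLoadings(model)),
              yLoadings = m2l(plsdaYLoadings(model)),
              explainedYSS = unname(explainedYSS(model)),
              classOrder = classOrder(model),
              yCenter = unname(model@yCenter))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full decomposition pipeline
#'
#' Executes every stage on the configured inputs and writes, in order: the
#' preprocessed matrix, the serialized PLS-DA model and VIP table, the
#' differential-test table, the verdict table, per-class gene selections,
#' the MSEA table, the pathway-enrichment table, the dual-axis table, and
#' a machine-readable run manifest. Identical configuration (including
#' seed) gives identical numerical outputs. A stage failure writes a
#' FAILED marker naming the stage and re-raises; partial outputs are
#' retained.
#'
#' @param config a \code{\link{runConfig}}.
#' @return invisibly, a list with the in-memory results of every stage and
#'   \code{outDir}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(config$outDir, "run.log")
  cat(sprintf("# pipeline started %s\n", format(Sys.time())), file = logPath)
  note <- function(...) cat(sprintf(...), "\n", file = logPath,
                            append = TRUE, sep = "")
  currentStage <- "configure"
  stage <- function(name, code) {
    currentStage <<- name
    note("stage: %s", name)
    tryCatch(code, error = function(e) {
      msg <- sprintf("stage '%s' failed: %s", name, conditionMessage(e))
      writeLines(msg, file.path(config$outDir, "FAILED"))
      note("%s", msg)
      stop(errorCondition(msg, class = setdiff(class(e),
                                               c("simpleError", "condition",
                                                 "error"))))
    })
  }

  inputs <- stage("read_inputs", {
    graphFiles <- sort(list.files(config$graphDir, pattern = "\\.sif$",
                                  full.names = TRUE))
    if (!length(graphFiles))
      validationError("no .sif files found in %s", config$graphDir)
    membership <- if (!is.null(config$membershipGmt))
      setMembers(readGmt(config$membershipGmt)) else list()
    graphs <- lapply(graphFiles, function(f) {
      id <- tools::file_path_sans_ext(basename(f))
      readEdgeList(f, pathwayId = id,
                   nodes = membership[[id]] %||% character(0))
    })
    names(graphs) <- vapply(graphs, pathwayId, "")
    list(table = readFeatureTable(config$featureTable,
                                  groupColumn = config$groupColumn,
                                  groupMap = config$groupMap),
         sets = readGmt(config$metaboliteSets),
         mapping = readMapping(config$mapping),
         graphs = graphs)
  })

  pp <- stage("preprocess", preprocessFeatures(inputs$table,
                                               config$preprocess))
  writeTsv(data.frame(sample = rownames(pp$x), pp$x, check.names = FALSE),
           file.path(config$outDir, "preprocessed_matrix.tsv"))

  groups <- groupLabels(inputs$table)
  model <- stage("plsda",
                 fitPlsda(pp$x, groups, nComponents = config$nComponents))
  serializePlsdaModel(model, file.path(config$outDir, "plsda_model.json"))
  vip <- computeVip(model)
  writeTsv(vip, file.path(config$outDir, "vip.tsv"))

  diffs <- stage("differential_tests", {
    dc <- differentialTest(pp$analysis, groups, "control", "challenge",
                           method = config$testMethod)
    dt <- differentialTest(pp$analysis, groups, "control", "treated",
                           method = config$testMethod)
    list(challenge = dc, treatment = dt)
  })
  writeTsv(rbind(cbind(contrast = "control_vs_challenge", diffs$challenge),
                 cbind(contrast = "control_vs_treated", diffs$treatment)),
           file.path(config$outDir, "differential_tests.tsv"))

  verdicts <- stage("classification",
    classifyAll(pp$analysis, groups, vip, diffs$challenge, diffs$treatment,
                vipThreshold = config$vipThreshold,
                epsilon = config$epsilon, alpha = config$alpha,
                vipColumn = config$vipColumn))
  writeTsv(verdicts, file.path(config$outDir, "verdicts.tsv"))
  note("classified: %d efficacy, %d bias_up, %d bias_down",
       sum(verdicts$class == "efficacy"), sum(verdicts$class == "bias_up"),
       sum(verdicts$class == "bias_down"))

  selections <- stage("map_selection", {
    suppressWarnings(list(
      efficacy = mapSelection(verdicts, inputs$mapping, "efficacy"),
      bias = mapSelection(verdicts, inputs$mapping, "bias")))
  })
  writeLines(selections$efficacy,
             file.path(config$outDir, "selection_efficacy.txt"))
  writeLines(selections$bias, file.path(config$outDir, "selection_bias.txt"))

  mseaTab <- stage("msea", {
    run1 <- function(cls) {
      sel <- verdicts$metabolite[verdicts$class %in%
        (if (cls == "bias") c("bias_up", "bias_down") else cls)]
      if (!length(sel))
        return(NULL)
      cbind(class = cls, msea(sel, inputs$sets, pp$kept))
    }
    do.call(rbind, Filter(Negate(is.null), list(run1("efficacy"),
                                                run1("bias"))))
  })
  if (!is.null(mseaTab))
    writeTsv(mseaTab, file.path(config$outDir, "msea.tsv"))

  universe <- geneUniverse(inputs$mapping)
  cepaTabs <- stage("pathway_enrichment", {
    runClass <- function(genes, offset) {
      if (!length(genes)) return(NULL)
      cepaEnrichment(inputs$graphs, genes, universe,
                     nPerm = config$nPerm,
                     seed = config$seed + offset,
                     centrality = config$centrality)
    }
    list(bias = runClass(selections$bias, 1000L),
         efficacy = runClass(selections$efficacy, 2000L))
  })
  cepaOut <- do.call(rbind, Filter(Negate(is.null), list(
    if (!is.null(cepaTabs$bias)) cbind(class = "bias", cepaTabs$bias),
    if (!is.null(cepaTabs$efficacy))
      cbind(class = "efficacy", cepaTabs$efficacy))))
  if (!is.null(cepaOut))
    writeTsv(cepaOut, file.path(config$outDir, "cepa.tsv"))

  dual <- stage("dual_axis", {
    if (is.null(cepaTabs$bias) || is.null(cepaTabs$efficacy)) {
      note("dual axis skipped: one selection class is empty")
      NULL
    } else {
      rankPathways(dualAxis(cepaTabs$bias, cepaTabs$efficacy,
                            alpha = config$alpha,
                            useAdjusted = config$useAdjusted))
    }
  })
  if (!is.null(dual))
    writeTsv(dual, file.path(config$outDir, "dual_axis.tsv"))

  stage("manifest", {
    cfgPlain <- unclass(config)
    cfgPlain$preprocess <- unclass(cfgPlain$preprocess)
    cfgJson <- jsonlite::toJSON(cfgPlain, auto_unbox = TRUE,
                                digits = NA, null = "null")
    manifest <- list(
      configHash = unname(cheapHash(cfgJson)),
      seed = config$seed,
      packageVersion =
        as.character(utils::packageVersion("metaboDecomp")),
      rVersion = R.version.string,
      timestamp = format(Sys.time(), tz = "UTC"),
      config = jsonlite::fromJSON(cfgJson, simplifyVector = TRUE))
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  note("pipeline finished")

  invisible(list(outDir = config$outDir, table = inputs$table, pp = pp,
                 model = model, vip = vip, diffs = diffs,
                 verdicts = verdicts, selections = selections,
                 msea = mseaTab, cepa = cepaTabs, dual = dual))
}

# md5 of a string via a temp file (tools::md5sum is file-based)
cheapHash <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeChar(as.character(s), f, eos = NULL)
  tools::md5sum(f)
}

#' Write a ready-to-run synthetic input bundle
#'
#' Generates a cohort plus matched knowledge (\code{\link{generateCohort}},
#' \code{\link{generateKnowledge}}) and writes every file the pipeline
#' consumes -- feature table, metabolite-set GMT, mapping TSV, pathway
#' membership GMT and per-pathway SIF edge lists -- plus the ground truth
#' as JSON.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param outDir destination directory (created if needed).
#' @param nPathways,pathwaySize passed to \code{\link{generateKnowledge}};
#'   the knowledge seed is derived from \code{spec$seed}.
#' @return invisibly, a list with the written \code{paths}, the
#'   \code{truth} object and the in-memory \code{cohort} and
#'   \code{knowledge}.
#' @export
simulateCohortFiles <- function(spec, outDir, nPathways = 8L,
                                pathwaySize = 20L) {
  if (!inherits(spec, "CohortSpec")) spec <- do.call(cohortSpec, spec)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  graphDir <- file.path(outDir, "graphs")
  dir.create(graphDir, showWarnings = FALSE)

  cohort <- generateCohort(spec)
  knowledge <- generateKnowledge(cohort$truth, nPathways = nPathways,
                                 seed = spec$seed + 500L,
                                 pathwaySize = pathwaySize)

  paths <- list(
    featureTable = file.path(outDir, "feature_table.csv"),
    metaboliteSets = file.path(outDir, "metabolite_sets.gmt"),
    mapping = file.path(outDir, "mapping.tsv"),
    membershipGmt = file.path(outDir, "pathway_membership.gmt"),
    graphDir = graphDir,
    truth = file.path(outDir, "ground_truth.json"))

  writeFeatureTable(cohort$table, paths$featureTable)
  writeGmt(knowledge$metaboliteSets, paths$metaboliteSets)
  writeMapping(knowledge$mapping, paths$mapping)
  membership <- MetaboliteSetCollection(
    names(knowledge$graphs),
    lapply(knowledge$graphs, nodeIds),
    descriptions = rep("pathway gene membership", length(knowledge$graphs)))
  writeGmt(membership, paths$membershipGmt)
  for (g in knowledge$graphs)
    writeEdgeList(g, file.path(graphDir, paste0(pathwayId(g), ".sif")))

  truth <- cohort$truth
  jsonlite::write_json(
    list(efficacyIds = truth@efficacyIds, biasUpIds = truth@biasUpIds,
         biasDownIds = truth@biasDownIds,
         groupMeans = list(values = unname(truth@groupMeans),
                           metabolites = rownames(truth@groupMeans),
                           groups = colnames(truth@groupMeans))),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(paths = paths, truth = truth, cohort = cohort,
                 knowledge = knowledge))
}
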