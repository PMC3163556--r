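# End-to-end orchestration: structure arm per drug, expression arm per
# contrast, partitions, enrichments, concordance, and a reproducibility
# manifest. The pipeline itself is deterministic; the seed in the config is
# recorded so fixture generation and analysis share one provenance trail.

#' Validate a pipeline configuration
#'
#' Checks the schema and the existence of every referenced file before any
#' computation. The configuration is a list (or a JSON file) with elements:
#' \describe{
#'   \item{drugs}{path to a .smi file of query drug structures.}
#'   \item{db}{list with \code{structures} (.smi) and \code{interactions}
#'     (TSV).}
#'   \item{graph}{PPI edge-list path.}
#'   \item{ontologies}{character vector of GMT paths.}
#'   \item{expression}{list with \code{matrix}, \code{design}, and
#'     \code{contrasts}: a data.frame/list mapping each drug to its
#'     (treatment, control) group pair.}
#'   \item{rules}{optional rule TSV; default rules when absent.}
#'   \item{params}{optional overrides: \code{threshold}, \code{maxLength},
#'     \code{nbits}, \code{alpha}, \code{fdr}, \code{tAlpha}, \code{log2Cut},
#'     \code{topK}, \code{sigAlpha}, \code{depth}, \code{hops}.}
#'   \item{seed}{integer recorded in the manifest.}
#' }
#' @param config list or path to a JSON config.
#' @return the normalized config list, invisibly on success.
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  need <- c("drugs", "db", "graph", "ontologies", "expression")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config lacks element(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(c("structures", "interactions") %in% names(config$db)))
    stop("config$db needs 'structures' and 'interactions'", call. = FALSE)
  if (!all(c("matrix", "design", "contrasts") %in% names(config$expression)))
    stop("config$expression needs 'matrix', 'design', 'contrasts'",
         call. = FALSE)
  files <- c(config$drugs, config$db$structures, config$db$interactions,
             config$graph, unlist(config$ontologies), config$rules,
             config$expression$matrix, config$expression$design)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("config references missing file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  defaults <- list(threshold = 0.7, maxLength = 7L, nbits = 1024L,
                   alpha = 0.01, fdr = 0.05, tAlpha = 0.01, log2Cut = 1.1,
                   topK = 10L, sigAlpha = 0.05, depth = 1L, hops = 1L)
  p <- config$params
  for (nm in names(defaults)) if (is.null(p[[nm]])) p[[nm]] <- defaults[[nm]]
  config$params <- p
  if (is.null(config$seed)) config$seed <- NA_integer_
  invisible(config)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full prediction pipeline
#'
#' Executes, for every query drug: metabolite generation, fingerprinting,
#' similarity search, possible-target collection and first-neighbor
#' expansion; partitions the expanded target sets across drugs; runs the
#' expression arm (preprocessing, DEG cascade, fold threshold, DEG-list
#' partition); enriches both arms against every ontology; and writes
#' per-drug concordance reports plus a manifest (inputs with checksums,
#' parameters, seed, package version). Identical config and inputs give
#' byte-identical outputs.
#'
#' @param config list or JSON path (see \code{\link{validatePipelineConfig}}).
#' @param outDir run directory to create and fill.
#' @return invisible list with the main in-memory results.
#' @export
runPipeline <- function(config, outDir) {
  config <- validatePipelineConfig(config)
  p <- config$params
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  db <- .stage("load-db", suppressMessages(loadCompoundDb(
    config$db$structures, config$db$interactions,
    maxLength = p$maxLength, nbits = p$nbits)))
  graph <- .stage("load-graph", loadInteractionGraph(config$graph))
  onts <- .stage("load-ontologies",
                 lapply(config$ontologies, loadOntology))
  rules <- .stage("load-rules", if (is.null(config$rules))
    defaultMetabolicRules() else readMetabolicRules(config$rules))
  drugs <- .stage("load-drugs", readSmilesFile(config$drugs))

  # --- structure arm ---------------------------------------------------------
  expanded <- list(); possible <- list()
  structEnrich <- list()
  for (i in seq_len(nrow(drugs))) {
    did <- drugs$compound_id[i]
    mol <- .stage(paste0("parse-", did),
                  parseStructure(did, drugs$smiles[i]))
    mets <- .stage(paste0("metabolize-", did),
                   generateMetabolites(mol, rules, depth = p$depth))
    queries <- c(list(mol), mets)
    fps <- lapply(queries, computeFingerprint,
                  maxLength = p$maxLength, nbits = p$nbits)
    names(fps) <- vapply(queries, moleculeId, "")
    hits <- .stage(paste0("similarity-", did),
                   similaritySearch(fps, db, threshold = p$threshold))
    poss <- collectPossibleTargets(hits, db, did)
    expd <- expandByNeighbors(poss, graph, hops = p$hops)
    possible[[did]] <- poss; expanded[[did]] <- expd

    .writeTsv(data.frame(id = names(fps),
                         canonical = vapply(queries, canonicalForm, ""),
                         role = vapply(queries, function(m) m@role, ""),
                         rule = vapply(queries, function(m) m@ruleName, "")),
              file.path(outDir, sprintf("metabolites_%s.tsv", did)))
    .writeTsv(hits, file.path(outDir, sprintf("hits_%s.tsv", did)))
    .writeTsv(targetProvenance(poss),
              file.path(outDir, sprintf("targets_%s_possible.tsv", did)))
    .writeTsv(targetProvenance(expd),
              file.path(outDir, sprintf("targets_%s_expanded.tsv", did)))

    structEnrich[[did]] <- lapply(onts, function(ont) {
      res <- .stage(paste0("enrich-structure-", did),
                    enrichSet(targetMembers(expd), ont))
      .writeTsv(res, file.path(outDir, sprintf("enrichment_structure_%s_%s.tsv",
                                               did, ont@name)))
      res
    })
    names(structEnrich[[did]]) <- vapply(onts, function(o) o@name, "")
  }

  targetPart <- .stage("partition-targets",
                       partitionSets(lapply(expanded, targetMembers)))
  .writeTsv(partitionTable(targetPart), file.path(outDir, "partition_targets.tsv"))
  jsonlite::write_json(
    stats::setNames(as.list(partitionSummary(targetPart)$size),
                    partitionSummary(targetPart)$class),
    file.path(outDir, "partition_targets_summary.json"), auto_unbox = TRUE)

  # --- expression arm --------------------------------------------------------
  mat <- .stage("read-expression",
                readExpressionMatrix(config$expression$matrix))
  design <- .stage("read-design", readDesign(config$expression$design))
  design <- design[match(colnames(mat), design$sample), , drop = FALSE]
  if (anyNA(design$sample))
    stop("pipeline stage 'read-design' failed: design does not cover all samples",
         call. = FALSE)
  se <- .stage("preprocess", preprocessMatrix(mat, design$group))

  contrasts <- config$expression$contrasts
  if (is.data.frame(contrasts)) {
    contrasts <- lapply(seq_len(nrow(contrasts)), function(i)
      as.list(contrasts[i, ]))
  }
  upLists <- list(); downLists <- list(); exprEnrich <- list()
  degTables <- list()
  for (ct in contrasts) {
    did <- ct$drug
    degs <- .stage(paste0("call-degs-", did),
                   callDegs(se, c(ct$treatment, ct$control),
                            alpha = p$alpha, fdr = p$fdr, tAlpha = p$tAlpha))
    split_ <- applyFoldThreshold(degs, log2Cut = p$log2Cut)
    degTables[[did]] <- degs
    upLists[[did]] <- split_$up$gene
    downLists[[did]] <- split_$down$gene
    .writeTsv(degs, file.path(outDir, sprintf("degs_%s.tsv", did)))
    writeLines(split_$up$gene, file.path(outDir, sprintf("deg_up_%s.txt", did)))
    writeLines(split_$down$gene, file.path(outDir, sprintf("deg_down_%s.txt", did)))

    degGenes <- sort(c(split_$up$gene, split_$down$gene))
    exprEnrich[[did]] <- lapply(onts, function(ont) {
      res <- .stage(paste0("enrich-expression-", did),
                    enrichSet(degGenes, ont))
      .writeTsv(res, file.path(outDir, sprintf("enrichment_expression_%s_%s.tsv",
                                               did, ont@name)))
      res
    })
    names(exprEnrich[[did]]) <- vapply(onts, function(o) o@name, "")
  }
  degPartUp <- .stage("partition-degs", partitionDegLists(upLists))
  degPartDown <- .stage("partition-degs", partitionDegLists(downLists))
  .writeTsv(partitionTable(degPartUp), file.path(outDir, "partition_degs_up.tsv"))
  .writeTsv(partitionTable(degPartDown), file.path(outDir, "partition_degs_down.tsv"))

  # --- concordance -----------------------------------------------------------
  reports <- list()
  for (did in intersect(names(structEnrich), names(exprEnrich))) {
    for (ontName in names(structEnrich[[did]])) {
      rep_ <- .stage(paste0("concordance-", did),
                     compareArms(structEnrich[[did]][[ontName]],
                                 exprEnrich[[did]][[ontName]],
                                 k = p$topK, sigAlpha = p$sigAlpha,
                                 drugId = did))
      reports[[paste(did, ontName, sep = ".")]] <- rep_
    }
  }
  concord <- do.call(rbind, lapply(reports, concordanceSummary))
  rownames(concord) <- NULL
  .writeTsv(concord, file.path(outDir, "concordance.tsv"))

  # --- manifest --------------------------------------------------------------
  infiles <- c(config$drugs, config$db$structures, config$db$interactions,
               config$graph, unlist(config$ontologies), config$rules,
               config$expression$matrix, config$expression$design)
  manifest <- list(
    tool = "targetwise",
    version = as.character(utils::packageVersion("targetwise")),
    seed = config$seed,
    parameters = p,
    inputs = data.frame(path = infiles,
                        md5 = unname(tools::md5sum(infiles)),
                        stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(possible = possible, expanded = expanded,
                 targetPartition = targetPart, degTables = degTables,
                 degPartitionUp = degPartUp, degPartitionDown = degPartDown,
                 structureEnrichment = structEnrich,
                 expressionEnrichment = exprEnrich, concordance = reports))
}
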