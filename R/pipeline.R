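#' Assemble a pipeline configuration
#'
#' Collects input paths, thresholds and iteration counts for
#' \code{\link{runPipeline}}. Defaults are the analysis constants:
#' support filter at 2 databases, Z cutoff 2.33 (strict), 1-kb gene
#' promoter flank, 2-kb pre-miRNA upstream window, k = 5 clique
#' percolation, top 5 percent betweenness, alpha 0.05, 10,000 FFL
#' permutations and 1,000 GO randomizations.
#'
#' @param inputDir directory holding the input files under their
#'   canonical names (as written by \code{\link{writeBundle}}); any
#'   entry can be overridden via \code{paths}.
#' @param outDir output directory.
#' @param paths named list overriding individual input paths
#'   (sourceRecords, genesFile, mirnasFile, tfsFile, tfbsHits,
#'   promoterAnnots, obo, annotations, gmt, fflCatalog).
#' @param fflCatalog optional path to a pre-built FFL catalog TSV; when
#'   set, curation and enumeration are skipped and the network stages
#'   run from this catalog (the from-catalog entry point for published
#'   supplementary catalogs).
#' @param minSources,zMin,geneFlank,mirnaUpstream,k,topFraction,alpha
#'   stage thresholds.
#' @param fflPerm,goPerm iteration counts.
#' @param seed master seed; stage seeds are derived from it.
#' @return a list of class \code{fflPipelineConfig}.
#' @export
pipelineConfig <- function(inputDir, outDir,
                           paths = list(), fflCatalog = NULL,
                           minSources = 2L, zMin = 2.33,
                           geneFlank = 1000L, mirnaUpstream = 2000L,
                           k = 5L, topFraction = 0.05, alpha = 0.05,
                           fflPerm = 10000L, goPerm = 1000L, seed = 1L) {
  defaults <- list(sourceRecords = "source_records.tsv",
                   genesFile = "migenes.txt", mirnasFile = "mimirnas.txt",
                   tfsFile = "tfs.txt", tfbsHits = "tfbs_hits.tsv",
                   promoterAnnots = "promoter_annotations.tsv",
                   obo = "go.obo", annotations = "annotations.tsv",
                   gmt = "sets.gmt")
  files <- lapply(defaults, function(f) file.path(inputDir, f))
  files[names(paths)] <- paths
  files$fflCatalog <- fflCatalog
  stopifnot(minSources >= 1L, k >= 3L, topFraction > 0, topFraction <= 1,
            alpha > 0, alpha < 1, geneFlank >= 0, mirnaUpstream >= 0)
  structure(list(files = files, outDir = outDir,
                 minSources = as.integer(minSources), zMin = zMin,
                 geneFlank = as.integer(geneFlank),
                 mirnaUpstream = as.integer(mirnaUpstream),
                 k = as.integer(k), topFraction = topFraction,
                 alpha = alpha, fflPerm = as.integer(fflPerm),
                 goPerm = as.integer(goPerm), seed = as.integer(seed)),
            class = "fflPipelineConfig")
}

#' Validate pipeline inputs
#'
#' Schema checks on every configured input file: existence, required
#' columns, row counts, plus cross-file consistency warnings (ids used
#' in the edge records but absent from the catalogs).
#'
#' @param config an \code{fflPipelineConfig}.
#' @return list(errors, warnings, rowCounts); the run is viable iff
#'   \code{length(errors) == 0}.
#' @export
validateInputs <- function(config) {
  errors <- character(0); warns <- character(0); rows <- list()
  f <- config$files
  needFile <- function(p, what) {
    if (is.null(p) || !file.exists(p)) {
      errors <<- c(errors, paste0(what, " file missing: ", p))
      FALSE
    } else TRUE
  }
  if (is.null(f$fflCatalog)) {
    if (needFile(f$sourceRecords, "source records")) {
      rec <- tryCatch(readSourceRecords(f$sourceRecords),
                      error = function(e) e)
      if (inherits(rec, "error")) errors <- c(errors, conditionMessage(rec))
      else {
        rows$sourceRecords <- nrow(rec)
        for (cf in c("genesFile", "mirnasFile", "tfsFile"))
          needFile(f[[cf]], cf)
        if (!length(errors)) {
          catalog <- readNodeCatalog(f$genesFile, f$mirnasFile, f$tfsFile)
          known <- c(miGenes(catalog), miMirnas(catalog), tfIds(catalog))
          unknown <- setdiff(unique(c(rec$regulator_id, rec$target_id)),
                             known)
          if (length(unknown))
            warns <- c(warns, paste0(length(unknown),
                                     " record id(s) absent from catalogs"))
        }
      }
    }
    if (!is.null(f$tfbsHits) && file.exists(f$tfbsHits)) {
      hits <- tryCatch(readTfbsHits(f$tfbsHits), error = function(e) e)
      if (inherits(hits, "error")) errors <- c(errors, conditionMessage(hits))
      else rows$tfbsHits <- nrow(hits)
    }
  } else if (needFile(f$fflCatalog, "FFL catalog")) {
    cat <- tryCatch(readFflCatalog(f$fflCatalog), error = function(e) e)
    if (inherits(cat, "error")) errors <- c(errors, conditionMessage(cat))
    else rows$fflCatalog <- nFfls(cat)
  }
  list(errors = errors, warnings = warns, rowCounts = rows)
}

.stage <- function(name, expr, outDir) {
  tryCatch(expr, error = function(e) {
    dir.create(file.path(outDir, "failed"), showWarnings = FALSE,
               recursive = TRUE)
    writeLines(paste0(name, ": ", conditionMessage(e)),
               file.path(outDir, "failed", "STAGE_FAILURE"))
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes curation, FFL enumeration, permutation significance,
#' network merge and topology, clique-percolation modules and
#' functional evaluation, writing every artifact plus a manifest
#' (input checksums, seed, package version) under the configured
#' output directory. Re-running with identical inputs and seed
#' reproduces identical outputs. Any stage error aborts with the stage
#' name; partial outputs are retained with a \code{failed/} marker.
#'
#' @param config an \code{fflPipelineConfig}.
#' @return invisibly, a list with the per-stage results (summary,
#'   catalog, permutation, network, topology, modules, functional).
#' @export
runPipeline <- function(config) {
  val <- validateInputs(config)
  if (length(val$errors))
    stop("input validation failed:\n  ",
         paste(val$errors, collapse = "\n  "))
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  stageSeeds <- sample.int(.Machine$integer.max, 4L)
  f <- config$files
  res <- list()

  if (is.null(f$fflCatalog)) {
    res$curation <- .stage("curation", {
      catalog <- readNodeCatalog(f$genesFile, f$mirnasFile, f$tfsFile)
      rec <- readSourceRecords(f$sourceRecords)
      supported <- filterBySupport(rec, config$minSources)
      tf_edges <- EdgeTable(.empty_edges())
      if (!is.null(f$tfbsHits) && file.exists(f$tfbsHits) &&
          file.exists(f$promoterAnnots)) {
        hits <- readTfbsHits(f$tfbsHits)
        ann <- readPromoterAnnots(f$promoterAnnots)
        tf_edges <- combineEdges(
          mapTfbsToGenePromoters(hits, ann, config$zMin, config$geneFlank),
          mapTfbsToMirnaPromoters(hits, ann, config$zMin,
                                  config$mirnaUpstream))
      }
      restricted <- restrictToCatalog(combineEdges(supported, tf_edges),
                                      catalog)
      writeEdgeTable(restricted, file.path(outDir, "edges.tsv"))
      list(catalog = catalog, supported = supported,
           restricted = restricted,
           summary = summarizeEdges(restricted))
    }, outDir)

    res$ffl <- .stage("ffl", {
      cat <- enumerateFfls(res$curation$restricted)
      writeFflCatalog(cat, file.path(outDir, "ffl_catalog.tsv"))
      utils::write.table(tabulateCatalog(cat),
                         file.path(outDir, "ffl_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cat
    }, outDir)

    res$significance <- .stage("significance", {
      ed <- edges(res$curation$supported)
      mg <- ed[ed$class == "MIRNA_GENE", , drop = FALSE]
      universe <- data.frame(mirna = mg$regulator, gene = mg$target,
                             stringsAsFactors = FALSE)
      obs <- edges(res$curation$restricted)
      obsMg <- obs[obs$class == "MIRNA_GENE", , drop = FALSE]
      universe <- unique(rbind(universe,
                               data.frame(mirna = obsMg$regulator,
                                          gene = obsMg$target)))
      perm <- fflPermutationTest(universe, res$curation$restricted,
                                 nIter = config$fflPerm,
                                 seed = stageSeeds[1])
      targetsByMirna <- split(mg$target, mg$regulator)
      geneUniverse <- unique(c(mg$target,
                               miGenes(res$curation$catalog)))
      tgt <- mirnaTargetPermutation(targetsByMirna,
                                    miGenes(res$curation$catalog),
                                    geneUniverse,
                                    nIter = config$fflPerm,
                                    seed = stageSeeds[2])
      rep <- lapply(perm, function(p)
        list(observed = p@observed, nIter = p@nIter, pValue = p@pValue,
             nullSummary = list(mean = mean(p@nullCounts),
                                sd = stats::sd(p@nullCounts),
                                max = max(p@nullCounts))))
      jsonlite::write_json(rep, file.path(outDir, "ffl_permutation.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.table(tgt$perMirna,
                         file.path(outDir, "mirna_target_test.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(fflPerm = perm, targetTest = tgt)
    }, outDir)
    catalogForNet <- res$ffl
    nodeCatalog <- res$curation$catalog
  } else {
    catalogForNet <- .stage("ffl",
                            readFflCatalog(f$fflCatalog), outDir)
    nodeCatalog <- if (!is.null(f$genesFile) && file.exists(f$genesFile))
      readNodeCatalog(f$genesFile, f$mirnasFile, f$tfsFile)
    else {
      ff <- ffls(catalogForNet)
      NodeCatalog(unique(ff$gene), unique(ff$mirna), unique(ff$tf))
    }
  }

  res$network <- .stage("network", {
    net <- mergeFflsToNetwork(catalogForNet, nodeCatalog)
    writeNetworkEdgeList(net, file.path(outDir, "network_edges.tsv"))
    writeNetworkGraphml(net, file.path(outDir, "network.graphml"))
    writeNodeAttributes(net, file.path(outDir, "node_attributes.tsv"),
                        config$topFraction)
    topo <- list(
      nNodes = nrow(nodes(net)), nEdges = nrow(edges(net)),
      edgeClasses = as.list(table(edges(net)$class)),
      roles = as.list(table(nodes(net)$role)),
      degree = degreeSummary(net),
      powerLaw = tryCatch(fitPowerLaw(net), error = function(e)
        list(error = conditionMessage(e))))
    jsonlite::write_json(topo, file.path(outDir, "topology.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    list(net = net, topology = topo)
  }, outDir)

  res$modules <- .stage("communities", {
    mods <- cpmCommunities(res$network$net, config$k)
    writeModules(mods, file.path(outDir, "modules.tsv"))
    impact <- NULL
    if (length(mods) &&
        nrow(nodes(res$network$net)) - length(nodeIds(mods[[1]])) >= 3L) {
      impact <- moduleRemovalClosenessTest(res$network$net, mods[[1]])
      jsonlite::write_json(
        list(statistic = impact$statistic, pValue = impact$pValue,
             variant = impact$variant, alternative = impact$alternative),
        file.path(outDir, "module_impact.json"),
        auto_unbox = TRUE, digits = NA)
    }
    list(modules = mods, impact = impact)
  }, outDir)

  res$functional <- .stage("function_eval", {
    out <- list()
    net <- res$network$net
    netGenes <- nodes(net)$id[nodes(net)$role == "gene"]
    if (!is.null(f$gmt) && file.exists(f$gmt) && length(netGenes)) {
      enr <- hypergeometricEnrichment(netGenes, readGmt(f$gmt),
                                      alpha = config$alpha)
      utils::write.table(enr, file.path(outDir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$enrichment <- enr
    }
    if (!is.null(f$obo) && file.exists(f$obo) &&
        file.exists(f$annotations) && length(res$modules$modules)) {
      dag <- readOboDag(f$obo)
      ann <- readGeneAnnotations(f$annotations)
      pool <- miGenes(nodeCatalog)
      modGenes <- intersect(nodeIds(res$modules$modules[[1]]), pool)
      go <- tryCatch(
        moduleGoRandomization(modGenes, pool, ann, dag,
                              nIter = config$goPerm,
                              seed = stageSeeds[3]),
        error = function(e) list(error = conditionMessage(e)))
      jsonlite::write_json(
        lapply(go, function(x)
          if (is.character(x)) x
          else list(statistic = x$statistic, pValue = x$pValue,
                    nModulePairs = length(x$moduleScores))),
        file.path(outDir, "module_go.json"), auto_unbox = TRUE,
        digits = NA, force = TRUE)
      out$moduleGo <- go
    }
    out
  }, outDir)

  inFiles <- Filter(function(p) !is.null(p) && file.exists(p), f)
  manifest <- list(
    package = "fflNet",
    version = as.character(utils::packageVersion("fflNet")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("files", "outDir"))],
    inputs = lapply(inFiles, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    stages = names(res))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res)
}
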