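.edge_key <- function(reg, tgt, cls) paste(reg, tgt, cls, sep = "\r")

.empty_edges <- function() {
  data.frame(regulator = character(), target = character(),
             class = character(), support = integer(),
             anyVerified = logical(), stringsAsFactors = FALSE)
}

#' Construct an EdgeTable
#'
#' Rows are deduplicated on (regulator, target, class); when duplicates
#' are supplied the maximum support and the OR of the verified flags are
#' kept. Self-edges are rejected by the class validity check.
#'
#' @param regulator,target character vectors of node ids, or a
#'   data.frame in \code{regulator} with columns regulator, target,
#'   class (and optionally support, anyVerified).
#' @param class interaction class per edge.
#' @param support distinct-source support per edge (default 1).
#' @param anyVerified logical, whether any attestation is verified.
#' @return an EdgeTable.
#' @examples
#' et <- EdgeTable(c("tf1", "mir1"), c("g1", "g1"),
#'                 c("TF_GENE", "MIRNA_GENE"))
#' nEdges(et)
#' @export
EdgeTable <- function(regulator, target = NULL, class = NULL,
                      support = 1L, anyVerified = FALSE) {
  if (is.data.frame(regulator)) {
    df <- regulator
    if (is.null(df$support)) df$support <- rep(1L, nrow(df))
    if (is.null(df$anyVerified)) df$anyVerified <- rep(FALSE, nrow(df))
  } else {
    n <- length(regulator)
    df <- data.frame(regulator = as.character(regulator),
                     target = as.character(target),
                     class = as.character(class),
                     support = rep_len(as.integer(support), n),
                     anyVerified = rep_len(as.logical(anyVerified), n),
                     stringsAsFactors = FALSE)
  }
  df <- df[, c("regulator", "target", "class", "support", "anyVerified")]
  if (nrow(df)) {
    key <- .edge_key(df$regulator, df$target, df$class)
    if (anyDuplicated(key)) {
      sup <- tapply(df$support, key, max)
      ver <- tapply(df$anyVerified, key, any)
      df <- df[!duplicated(key), , drop = FALSE]
      k2 <- .edge_key(df$regulator, df$target, df$class)
      df$support <- as.integer(sup[k2])
      df$anyVerified <- as.logical(ver[k2])
    }
    df <- df[order(df$class, df$regulator, df$target), , drop = FALSE]
    rownames(df) <- NULL
  }
  new("EdgeTable", edges = df)
}

#' @describeIn EdgeTable number of edges
#' @param x an EdgeTable.
#' @export
nEdges <- function(x) nrow(x@edges)

#' @rdname edges
#' @export
setMethod("edges", "EdgeTable", function(x) x@edges)

setMethod("show", "EdgeTable", function(object) {
  ed <- object@edges
  cat("EdgeTable with", nrow(ed), "edges\n")
  if (nrow(ed)) {
    tab <- table(ed$class)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat("  support range:", min(ed$support), "-", max(ed$support), "\n")
  }
})

#' Concatenate edge tables
#'
#' @param ... EdgeTable objects.
#' @return a single deduplicated EdgeTable.
#' @export
combineEdges <- function(...) {
  parts <- lapply(list(...), edges)
  EdgeTable(do.call(rbind, c(parts, list(.empty_edges()))))
}

#' Construct a NodeCatalog
#'
#' @param miGenes,miMirnas,tfs character id vectors.
#' @return a NodeCatalog.
#' @export
NodeCatalog <- function(miGenes, miMirnas, tfs) {
  new("NodeCatalog",
      miGenes = sort(unique(as.character(miGenes))),
      miMirnas = sort(unique(as.character(miMirnas))),
      tfs = sort(unique(as.character(tfs))))
}

#' @describeIn NodeCatalog gene ids present in both the disease-gene and
#'   TF lists (dual-role nodes).
#' @param x a NodeCatalog.
#' @export
dualNodes <- function(x) intersect(x@miGenes, x@tfs)

#' @describeIn NodeCatalog accessors for the three id sets.
#' @export
miGenes <- function(x) x@miGenes

#' @rdname NodeCatalog
#' @export
miMirnas <- function(x) x@miMirnas

#' @rdname NodeCatalog
#' @export
tfIds <- function(x) x@tfs

setMethod("show", "NodeCatalog", function(object) {
  cat("NodeCatalog:", length(object@miGenes), "genes,",
      length(object@miMirnas), "miRNAs,", length(object@tfs), "TFs (",
      length(dualNodes(object)), "dual-role )\n")
})

#' Read raw source records
#'
#' Reads a TSV with header columns regulator_id, target_id,
#' interaction_class, source_db, evidence. Unknown interaction classes
#' raise an error naming the offending line.
#'
#' @param path TSV file path.
#' @return data.frame of source records.
#' @export
readSourceRecords <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("regulator_id", "target_id", "interaction_class",
            "source_db", "evidence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("source record file missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!df$interaction_class %in% .EDGE_CLASSES)
  if (length(bad))
    stop("unknown interaction_class '", df$interaction_class[bad[1]],
         "' at line ", bad[1] + 1L, " of ", path)
  df
}

#' Retain edges supported by enough source databases
#'
#' Groups source records by (regulator, target, class) and keeps an edge
#' iff it is attested by at least \code{minSources} distinct databases.
#' With \code{keepVerified = TRUE} an edge with any experimentally
#' verified attestation passes regardless of its support count.
#'
#' @param records data.frame of source records (see
#'   \code{\link{readSourceRecords}}).
#' @param minSources minimum number of distinct source databases
#'   (default 2).
#' @param keepVerified retain verified edges unconditionally (default
#'   FALSE, the strict mode).
#' @return an EdgeTable with support counts and verified flags.
#' @examples
#' rec <- data.frame(regulator_id = "mir1", target_id = "g1",
#'                   interaction_class = "MIRNA_GENE",
#'                   source_db = c("dbA", "dbB"),
#'                   evidence = c("verified", "predicted"))
#' edges(filterBySupport(rec))
#' @export
filterBySupport <- function(records, minSources = 2L, keepVerified = FALSE) {
  stopifnot(minSources >= 1L)
  bad <- which(!records$interaction_class %in% .EDGE_CLASSES)
  if (length(bad))
    stop("unknown interaction_class '", records$interaction_class[bad[1]],
         "' in record ", bad[1])
  if (!nrow(records)) return(EdgeTable(.empty_edges()))
  key <- .edge_key(records$regulator_id, records$target_id,
                   records$interaction_class)
  support <- vapply(split(records$source_db, key),
                    function(s) length(unique(s)), integer(1))
  verified <- vapply(split(records$evidence == "verified", key), any,
                     logical(1))
  first <- records[!duplicated(key), , drop = FALSE]
  fkey <- .edge_key(first$regulator_id, first$target_id,
                    first$interaction_class)
  df <- data.frame(regulator = first$regulator_id,
                   target = first$target_id,
                   class = first$interaction_class,
                   support = as.integer(support[fkey]),
                   anyVerified = as.logical(verified[fkey]),
                   stringsAsFactors = FALSE)
  keep <- df$support >= minSources
  if (keepVerified) keep <- keep | df$anyVerified
  keep <- keep & df$regulator != df$target
  EdgeTable(df[keep, , drop = FALSE])
}

#' Restrict an edge table to the analysis catalogs
#'
#' Keeps edges whose endpoints lie in the id universes appropriate for
#' their class: miRNA regulators must be disease miRNAs, gene targets
#' disease genes, TF endpoints known TFs. A dual-role id attested in two
#' classes appears in both.
#'
#' @param x an EdgeTable.
#' @param catalog a NodeCatalog.
#' @return the restricted EdgeTable.
#' @export
restrictToCatalog <- function(x, catalog) {
  ed <- edges(x)
  if (!nrow(ed)) return(x)
  keep <- rep(FALSE, nrow(ed))
  sel <- function(cls, regs, tgts)
    ed$class == cls & ed$regulator %in% regs & ed$target %in% tgts
  keep <- keep | sel("MIRNA_GENE", catalog@miMirnas, catalog@miGenes)
  keep <- keep | sel("MIRNA_TF", catalog@miMirnas, catalog@tfs)
  keep <- keep | sel("TF_GENE", catalog@tfs, catalog@miGenes)
  keep <- keep | sel("TF_MIRNA", catalog@tfs, catalog@miMirnas)
  EdgeTable(ed[keep, , drop = FALSE])
}

#' Summarize an edge table per interaction class
#'
#' Produces the per-class pair/regulator/target tallies (the shape of a
#' regulation-summary table) together with per-node regulator and target
#' degree tallies, from which extremes such as the miRNA with the most
#' targets can be read off.
#'
#' @param x an EdgeTable (typically already catalog-restricted).
#' @param catalog optional NodeCatalog (unused for counting, kept for
#'   interface symmetry).
#' @return list with \code{classSummary} (class, nPairs, nMirnas, nGenes,
#'   nTfs) and \code{nodeTallies} (node, class, role, count).
#' @export
summarizeEdges <- function(x, catalog = NULL) {
  ed <- edges(x)
  cs <- do.call(rbind, lapply(.EDGE_CLASSES, function(cls) {
    e <- ed[ed$class == cls, , drop = FALSE]
    regN <- length(unique(e$regulator))
    tgtN <- length(unique(e$target))
    data.frame(class = cls, nPairs = nrow(e),
               nMirnas = switch(cls, MIRNA_GENE = , MIRNA_TF = regN,
                                TF_MIRNA = tgtN, 0L),
               nGenes = switch(cls, MIRNA_GENE = , TF_GENE = tgtN, 0L),
               nTfs = switch(cls, MIRNA_TF = tgtN,
                             TF_GENE = , TF_MIRNA = regN, 0L),
               stringsAsFactors = FALSE)
  }))
  tally <- function(ids, role) {
    if (!nrow(ids))
      return(data.frame(node = character(), class = character(),
                        role = character(), count = integer()))
    t <- table(ids$node, ids$class)
    df <- as.data.frame(t, stringsAsFactors = FALSE)
    names(df) <- c("node", "class", "count")
    df$role <- role
    df[df$count > 0, c("node", "class", "role", "count")]
  }
  out <- tally(data.frame(node = ed$regulator, class = ed$class), "regulator")
  inn <- tally(data.frame(node = ed$target, class = ed$class), "target")
  nodeTallies <- rbind(out, inn)
  rownames(cs) <- rownames(nodeTallies) <- NULL
  list(classSummary = cs, nodeTallies = nodeTallies)
}

#' Write / read the canonical edge-table TSV
#'
#' Columns: regulator_id, target_id, interaction_class, support,
#' any_verified.
#'
#' @param x an EdgeTable.
#' @param path TSV path.
#' @return \code{readEdgeTable} returns an EdgeTable;
#'   \code{writeEdgeTable} returns \code{path} invisibly.
#' @export
writeEdgeTable <- function(x, path) {
  ed <- edges(x)
  out <- data.frame(regulator_id = ed$regulator, target_id = ed$target,
                    interaction_class = ed$class, support = ed$support,
                    any_verified = ed$anyVerified)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeTable
#' @export
readEdgeTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  EdgeTable(data.frame(regulator = df$regulator_id, target = df$target_id,
                       class = df$interaction_class,
                       support = df$support,
                       anyVerified = as.logical(df$any_verified),
                       stringsAsFactors = FALSE))
}

#' Read plain-text node catalogs
#'
#' Each file holds one id per line.
#'
#' @param genesFile,mirnasFile,tfsFile file paths.
#' @return a NodeCatalog.
#' @export
readNodeCatalog <- function(genesFile, mirnasFile, tfsFile) {
  rd <- function(p) {
    x <- readLines(p)
    x[nzchar(trimws(x))]
  }
  NodeCatalog(rd(genesFile), rd(mirnasFile), rd(tfsFile))
}
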