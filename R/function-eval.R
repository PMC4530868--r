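#' Read / write a two-column gene-to-term annotation TSV
#'
#' Columns \code{gene} and \code{term}.
#'
#' @param path file path.
#' @return data.frame with columns gene, term.
#' @export
readGeneAnnotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(df)))
    stop("annotation file must have columns gene, term")
  df
}

#' @rdname readGeneAnnotations
#' @param annotations data.frame to write.
#' @export
writeGeneAnnotations <- function(annotations, path) {
  utils::write.table(annotations[, c("gene", "term")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene sets
#'
#' Tab-delimited lines: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  sets
}

#' @rdname readGmt
#' @param sets named list of gene vectors.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' GO semantic-similarity coherence test for a module
#'
#' Compares the pairwise gene similarities inside a module against a
#' pooled null of pairwise similarities from random same-size gene sets
#' drawn from the candidate gene pool, per namespace. The one-sided
#' Kolmogorov-Smirnov test asks whether the module scores are
#' stochastically greater than the pooled random scores. Unannotated
#' genes are excluded from the score vectors (with a logged count).
#'
#' @param moduleGenes genes of the module (must be a subset of
#'   \code{poolGenes}).
#' @param poolGenes the pool random same-size sets are drawn from.
#' @param annotations data.frame with columns gene, term.
#' @param dag a GoDag.
#' @param namespaces namespaces to evaluate (default the three
#'   sub-ontologies present in the DAG).
#' @param nIter random draws (default 1000).
#' @param seed seed.
#' @return named list per namespace: moduleScores, nullScores,
#'   statistic (KS D), pValue, nExcluded.
#' @export
moduleGoRandomization <- function(moduleGenes, poolGenes, annotations, dag,
                                  namespaces = NULL, nIter = 1000L,
                                  seed = 1L) {
  moduleGenes <- unique(as.character(moduleGenes))
  poolGenes <- unique(as.character(poolGenes))
  if (!all(moduleGenes %in% poolGenes))
    stop("moduleGenes must be a subset of poolGenes")
  if (is.null(namespaces))
    namespaces <- intersect(c("BP", "MF", "CC"), unique(dag@terms$namespace))
  out <- list()
  for (ns in namespaces) {
    gsim <- .gene_sim_matrix(poolGenes, annotations, dag, ns)
    annotated <- poolGenes[!is.na(diag(gsim))]
    modA <- intersect(moduleGenes, annotated)
    nExcluded <- length(moduleGenes) - length(modA)
    if (length(modA) < 2L)
      stop("fewer than 2 annotated module genes in namespace ", ns)
    pairScores <- function(g) {
      m <- gsim[g, g, drop = FALSE]
      v <- m[upper.tri(m)]
      v[!is.na(v)]
    }
    modScores <- pairScores(modA)
    set.seed(seed)
    nullScores <- unlist(lapply(seq_len(nIter), function(i) {
      draw <- sample(poolGenes, length(moduleGenes))
      pairScores(intersect(draw, annotated))
    }), use.names = FALSE)
    ## alternative "less": CDF of x below CDF of y, i.e. module scores
    ## stochastically greater than the random pairs
    ks <- suppressWarnings(
      stats::ks.test(modScores, nullScores, alternative = "less"))
    out[[ns]] <- list(moduleScores = modScores, nullScores = nullScores,
                      statistic = unname(ks$statistic),
                      pValue = ks$p.value, nExcluded = nExcluded)
  }
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The multiple-testing correction applied across gene sets by
#' \code{\link{hypergeometricEnrichment}}.
#'
#' @param p vector of raw p-values.
#' @return adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' Hypergeometric gene-set enrichment with BH correction
#'
#' One-sided upper-tail hypergeometric test per gene set (probability of
#' an overlap at least as large as observed), with Benjamini-Hochberg
#' step-up adjustment across all tested sets. The universe defaults to
#' the union of all supplied sets.
#'
#' @param queryGenes the query gene list (restricted to the universe).
#' @param geneSets named list of gene sets (e.g. from
#'   \code{\link{readGmt}}).
#' @param universe optional universe; default union of the sets.
#' @param alpha significance threshold on the adjusted p (default
#'   0.05).
#' @return data.frame sorted by adjusted p with columns set, k (overlap),
#'   K (set size), n (query size), N (universe size), pValue, pAdjust,
#'   significant.
#' @export
hypergeometricEnrichment <- function(queryGenes, geneSets, universe = NULL,
                                     alpha = 0.05) {
  if (!length(geneSets)) stop("no gene sets supplied")
  if (is.null(universe)) universe <- unique(unlist(geneSets))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  query <- intersect(unique(as.character(queryGenes)), universe)
  if (!length(query)) stop("empty query after restriction to the universe")
  N <- length(universe); n <- length(query)
  rows <- do.call(rbind, lapply(names(geneSets), function(nm) {
    set <- intersect(geneSets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, pValue = p,
               stringsAsFactors = FALSE)
  }))
  rows$pAdjust <- bhAdjust(rows$pValue)
  rows$significant <- rows$pAdjust < alpha
  rows <- rows[order(rows$pAdjust, rows$pValue, rows$set), ]
  rownames(rows) <- NULL
  rows
}
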