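#' @rdname edges
#' @export
setMethod("edges", "RegNetwork", function(x) x@edges)

#' @rdname nodes
#' @export
setMethod("nodes", "RegNetwork", function(x) x@nodes)

setMethod("show", "RegNetwork", function(object) {
  rl <- table(factor(object@nodes$role, c("gene", "miRNA", "TF")))
  cat("RegNetwork:", nrow(object@nodes), "nodes (",
      paste(names(rl), rl, sep = "=", collapse = ", "), ") and",
      nrow(object@edges), "directed edges\n")
  if (nrow(object@edges)) {
    cl <- table(object@edges$class)
    cat("  edge classes:",
        paste(names(cl), cl, sep = "=", collapse = ", "), "\n")
  }
})

#' Merge an FFL catalog into the co-regulatory network
#'
#' The node set is the union of FFL member nodes and the edge set the
#' deduplicated union of the FFLs' constituent edges. Nodes present in
#' both the disease-gene and TF catalogs are reclassified: they take
#' role TF, and edges pointing at them are relabeled (TF_GENE becomes
#' TF_TF, MIRNA_GENE becomes MIRNA_TF).
#'
#' @param catalog an FflCatalog.
#' @param nodeCatalog the NodeCatalog used to assign roles and detect
#'   dual-role genes.
#' @return a \linkS4class{RegNetwork}.
#' @export
mergeFflsToNetwork <- function(catalog, nodeCatalog) {
  ff <- ffls(catalog)
  if (!nrow(ff)) stop("cannot build a network from an empty catalog")
  ce <- .ffl_constituent_edges(ff)
  ce <- ce[!duplicated(paste(ce$regulator, ce$target, ce$class, sep = "\r")), ]
  ids <- unique(c(ff$tf, ff$mirna, ff$gene))
  dual <- intersect(intersect(miGenes(nodeCatalog), tfIds(nodeCatalog)), ids)
  role <- ifelse(ids %in% miMirnas(nodeCatalog), "miRNA",
                 ifelse(ids %in% tfIds(nodeCatalog) | ids %in% dual, "TF",
                        "gene"))
  ## relabel edges whose target became a TF
  toTf <- ce$target %in% dual
  ce$class[toTf & ce$class == "TF_GENE"] <- "TF_TF"
  ce$class[toTf & ce$class == "MIRNA_GENE"] <- "MIRNA_TF"
  ce <- ce[!duplicated(paste(ce$regulator, ce$target, ce$class, sep = "\r")), ]
  nodesDf <- data.frame(id = ids, role = role, stringsAsFactors = FALSE)
  nodesDf <- nodesDf[order(nodesDf$id), ]; rownames(nodesDf) <- NULL
  edgesDf <- data.frame(from = ce$regulator, to = ce$target,
                        class = ce$class, stringsAsFactors = FALSE)
  edgesDf <- edgesDf[order(edgesDf$from, edgesDf$to, edgesDf$class), ]
  rownames(edgesDf) <- NULL
  new("RegNetwork", nodes = nodesDf, edges = edgesDf)
}

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "RegNetwork", function(x, mode = c("directed",
                                                         "undirected")) {
  mode <- match.arg(mode)
  g <- igraph::graph_from_data_frame(x@edges, directed = TRUE,
                                     vertices = x@nodes)
  if (mode == "undirected")
    g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"),
                          remove.multiple = TRUE, remove.loops = TRUE)
  g
})

.total_degree <- function(net) {
  g <- asIgraph(net, "directed")
  igraph::degree(g, mode = "all")   # in + out on the typed multigraph
}

#' Per-role degree summary
#'
#' Total degree (in + out) on the directed deduplicated multigraph,
#' summarized per node role.
#'
#' @param net a RegNetwork.
#' @return data.frame with columns role, n, meanDegree, minDegree,
#'   maxDegree.
#' @export
degreeSummary <- function(net) {
  if (!nrow(nodes(net))) stop("empty network")
  deg <- .total_degree(net)
  role <- stats::setNames(nodes(net)$role, nodes(net)$id)[names(deg)]
  do.call(rbind, lapply(c("gene", "miRNA", "TF"), function(r) {
    d <- deg[role == r]
    if (!length(d))
      return(data.frame(role = r, n = 0L, meanDegree = NA_real_,
                        minDegree = NA_integer_, maxDegree = NA_integer_))
    data.frame(role = r, n = length(d), meanDegree = mean(d),
               minDegree = min(d), maxDegree = max(d),
               stringsAsFactors = FALSE)
  }))
}

.fit_power_law_points <- function(k, freq) {
  keep <- k > 0 & freq > 0
  k <- k[keep]; freq <- freq[keep]
  if (length(unique(k)) < 3L) stop("insufficient degree support")
  fit <- stats::lm(log10(freq) ~ log10(k))
  ## suppressed: lm warns on numerically perfect fits
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rSquared = r2,
       nPoints = length(k))
}

#' @rdname fitPowerLaw
#' @export
setMethod("fitPowerLaw", "numeric", function(x, ...) {
  tab <- table(x)
  .fit_power_law_points(as.numeric(names(tab)), as.numeric(tab))
})

#' @rdname fitPowerLaw
#' @export
setMethod("fitPowerLaw", "data.frame", function(x, ...) {
  stopifnot(all(c("k", "freq") %in% names(x)))
  .fit_power_law_points(as.numeric(x$k), as.numeric(x$freq))
})

#' @rdname fitPowerLaw
#' @param role optional node role ("gene", "miRNA", "TF") to restrict
#'   the degree distribution to.
#' @export
setMethod("fitPowerLaw", "RegNetwork", function(x, role = NULL, ...) {
  deg <- .total_degree(x)
  if (!is.null(role)) {
    rl <- stats::setNames(nodes(x)$role, nodes(x)$id)[names(deg)]
    deg <- deg[rl == role]
  }
  fitPowerLaw(as.numeric(deg))
})

#' Betweenness-centrality report
#'
#' Betweenness is computed on the directed graph with unit edge lengths,
#' so pure target genes (sinks) score exactly zero. The top
#' \code{topFraction} of all network nodes (ceiling rounding, ties
#' broken by node id) is flagged.
#'
#' @param net a RegNetwork.
#' @param topFraction fraction of nodes to flag (default 0.05).
#' @return data.frame with columns id, role, degree, betweenness,
#'   topBetweenness, ordered by decreasing betweenness then id.
#' @export
betweennessReport <- function(net, topFraction = 0.05) {
  g <- asIgraph(net, "directed")
  btw <- igraph::betweenness(g, directed = TRUE)
  deg <- igraph::degree(g, mode = "all")
  df <- data.frame(id = names(btw),
                   role = stats::setNames(nodes(net)$role,
                                          nodes(net)$id)[names(btw)],
                   degree = as.integer(deg),
                   betweenness = as.numeric(btw),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$betweenness, df$id), ]
  nTop <- ceiling(topFraction * nrow(df))
  df$topBetweenness <- seq_len(nrow(df)) <= nTop
  rownames(df) <- NULL
  df
}

#' Identify hub nodes per role
#'
#' A hub is a node whose total degree reaches the per-role degree
#' quantile (default 0.90, rule >=), or, when \code{counts} is given,
#' one of the top-N nodes of its role (ties broken by id). The exact
#' hub-calling threshold of degree-based hub definitions varies across
#' studies, so both parameterizations are exposed.
#'
#' @param net a RegNetwork.
#' @param quantile per-role degree quantile (default 0.90).
#' @param counts optional named vector c(gene=, miRNA=, TF=) of top-N
#'   hub counts per role, overriding the quantile rule.
#' @return data.frame with columns id, role, degree, hub.
#' @export
findHubs <- function(net, quantile = 0.90, counts = NULL) {
  deg <- .total_degree(net)
  df <- data.frame(id = names(deg),
                   role = stats::setNames(nodes(net)$role,
                                          nodes(net)$id)[names(deg)],
                   degree = as.integer(deg), stringsAsFactors = FALSE)
  df$hub <- FALSE
  for (r in unique(df$role)) {
    ix <- which(df$role == r)
    if (!is.null(counts)) {
      if (!r %in% names(counts)) next
      n <- counts[[r]]
      ord <- ix[order(-df$degree[ix], df$id[ix])]
      df$hub[utils::head(ord, n)] <- TRUE
    } else {
      thr <- stats::quantile(df$degree[ix], quantile, names = FALSE)
      df$hub[ix][df$degree[ix] >= thr] <- TRUE
    }
  }
  df <- df[order(df$role, -df$degree, df$id), ]
  rownames(df) <- NULL
  df
}

#' Export a network
#'
#' \code{writeNetworkEdgeList} writes a source/target/class TSV;
#' \code{writeNetworkGraphml} a GraphML file with role and class
#' attributes; \code{writeNodeAttributes} the per-node role, degree,
#' betweenness and flag table.
#'
#' @param net a RegNetwork.
#' @param path output path.
#' @param topFraction,quantile forwarded to the topology reports.
#' @return the path, invisibly.
#' @export
writeNetworkEdgeList <- function(net, path) {
  utils::write.table(
    data.frame(source = edges(net)$from, target = edges(net)$to,
               class = edges(net)$class),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNetworkEdgeList
#' @export
writeNetworkGraphml <- function(net, path) {
  igraph::write_graph(asIgraph(net, "directed"), path, format = "graphml")
  invisible(path)
}

#' @rdname writeNetworkEdgeList
#' @export
writeNodeAttributes <- function(net, path, topFraction = 0.05,
                                quantile = 0.90) {
  btw <- betweennessReport(net, topFraction)
  hubs <- findHubs(net, quantile)
  df <- merge(btw, hubs[, c("id", "hub")], by = "id")
  df <- df[order(df$id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
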