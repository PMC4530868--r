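#' @rdname nodeIds
#' @export
setMethod("nodeIds", "Module", function(x) x@nodeIds)

#' @describeIn nodeIds clique size used to build the module
#' @export
moduleK <- function(x) x@k

setMethod("show", "Module", function(object) {
  cat("Module (k =", object@k, "):", length(object@nodeIds), "nodes\n")
  if (length(object@roles)) {
    tab <- table(factor(object@roles, c("gene", "miRNA", "TF")))
    cat(" ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' k-clique percolation communities
#'
#' Enumerates all k-cliques of the simple undirected projection of the
#' network (edge direction and class ignored), links two k-cliques when
#' they share exactly k-1 nodes, and returns the node unions of the
#' connected components of that clique-adjacency graph. Modules may
#' overlap and are ordered by their sorted member ids for determinism.
#'
#' @param x a RegNetwork or an undirected igraph graph.
#' @param k clique size (default 5; must be >= 3).
#' @return list of \linkS4class{Module} objects.
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::V(g)$name <- letters[1:5]
#' cpmCommunities(g, k = 5)
#' @export
cpmCommunities <- function(x, k = 5L) {
  if (k < 3L) stop("k must be >= 3")
  roles <- character(0)
  if (is(x, "RegNetwork")) {
    roles <- stats::setNames(nodes(x)$role, nodes(x)$id)
    g <- asIgraph(x, "undirected")
  } else {
    g <- igraph::as_undirected(x, mode = "collapse")
    g <- igraph::simplify(g)
  }
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  cl <- igraph::cliques(g, min = k, max = k)
  if (!length(cl)) return(list())
  members <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  nc <- length(members)
  ## clique adjacency: share exactly k-1 nodes
  adjFrom <- integer(0); adjTo <- integer(0)
  if (nc > 1L) {
    for (i in seq_len(nc - 1L)) {
      mi <- members[[i]]
      for (j in seq.int(i + 1L, nc)) {
        if (length(intersect(mi, members[[j]])) == k - 1L) {
          adjFrom <- c(adjFrom, i); adjTo <- c(adjTo, j)
        }
      }
    }
  }
  cg <- igraph::make_graph(rbind(adjFrom, adjTo), n = nc, directed = FALSE)
  comp <- igraph::components(cg)$membership
  mods <- unname(lapply(split(seq_len(nc), comp), function(ix)
    sort(unique(unlist(members[ix])))))
  ## communities may overlap, so order on the full member key
  mods <- mods[order(vapply(mods, paste, "", collapse = "\r"))]
  lapply(mods, function(ids)
    new("Module", nodeIds = ids, k = as.integer(k),
        roles = if (length(roles)) roles[ids] else character(0)))
}

.harmonic_closeness <- function(g) {
  ## sum of reciprocal shortest-path distances; unreachable pairs add 0
  igraph::harmonic_centrality(g, mode = "all", normalized = FALSE)
}

.classic_closeness <- function(g) {
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  igraph::closeness(sub, mode = "all")
}

#' Module-removal connectivity impact test
#'
#' Measures whether deleting a module's nodes lowers the closeness
#' centrality of the remaining network. Closeness is harmonic by default
#' (sum of reciprocal shortest-path distances on the undirected view;
#' unreachable pairs contribute 0, so the measure is well-defined when
#' removal disconnects the graph). The classic variant restricts to the
#' largest connected component. A Welch two-sample t-test compares the
#' reduced-network values of the remaining nodes against the
#' original-network values of all nodes, one-sided (reduced < original).
#'
#' @param net a RegNetwork or undirected igraph graph.
#' @param module a Module or character vector of node ids.
#' @param variant "harmonic" (default) or "classic".
#' @return list with baseline, reduced, statistic, pValue, alternative,
#'   variant.
#' @export
moduleRemovalClosenessTest <- function(net, module,
                                       variant = c("harmonic", "classic")) {
  variant <- match.arg(variant)
  ids <- if (is(module, "Module")) nodeIds(module) else as.character(module)
  g <- if (is(net, "RegNetwork")) asIgraph(net, "undirected")
       else igraph::simplify(igraph::as_undirected(net, mode = "collapse"))
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  miss <- setdiff(ids, igraph::V(g)$name)
  if (length(miss)) stop("module nodes not in network: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  if (igraph::vcount(g) - length(ids) < 3L)
    stop("removal leaves fewer than 3 nodes")
  fun <- if (variant == "harmonic") .harmonic_closeness else .classic_closeness
  baseline <- fun(g)
  reduced <- fun(igraph::delete_vertices(g, ids))
  if (stats::sd(baseline) == 0 && stats::sd(reduced) == 0) {
    warning("closeness constant in both samples; p from mean comparison only")
    p <- if (mean(reduced) < mean(baseline)) 0
         else if (mean(reduced) == mean(baseline)) 0.5 else 1
    return(list(baseline = baseline, reduced = reduced,
                statistic = NA_real_, pValue = p,
                alternative = "less", variant = variant))
  }
  tt <- stats::t.test(reduced, baseline, alternative = "less")
  list(baseline = baseline, reduced = reduced,
       statistic = unname(tt$statistic), pValue = tt$p.value,
       alternative = "less", variant = variant)
}

#' Write modules to a TSV
#'
#' One row per (module, node) with the module id, k and node role.
#'
#' @param modules list of Module objects.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeModules <- function(modules, path) {
  rows <- do.call(rbind, lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    data.frame(module_id = i, k = moduleK(m), node_id = nodeIds(m),
               role = if (length(m@roles)) unname(m@roles[nodeIds(m)])
                      else NA_character_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(module_id = integer(), k = integer(),
                       node_id = character(), role = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
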