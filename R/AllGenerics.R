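#' Access the edge table of an object
#' @param x an EdgeTable or RegNetwork.
#' @return data.frame of edges.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Access the node table of a network
#' @param x a RegNetwork.
#' @return data.frame of nodes (id, role).
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' Access the FFL triples of a catalog
#' @param x an FflCatalog.
#' @return data.frame with columns tf, mirna, gene, type.
#' @export
setGeneric("ffls", function(x) standardGeneric("ffls"))

#' Member node ids of a module
#' @param x a Module.
#' @return character vector.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' Empirical p-value of a permutation result
#' @param x a PermutationResult.
#' @return numeric p in [0, 1].
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Null sample of a permutation result
#' @param x a PermutationResult.
#' @return numeric vector of null counts.
#' @export
setGeneric("nullCounts", function(x) standardGeneric("nullCounts"))

#' Convert to an igraph graph
#'
#' @param x a RegNetwork.
#' @param mode "directed" keeps the typed multigraph (parallel classes
#'   between one ordered pair stay distinct edges); "undirected" returns
#'   the simple undirected projection used for clique percolation.
#' @return an igraph object; directed graphs carry a \code{class} edge
#'   attribute and both carry a \code{role} vertex attribute.
#' @export
setGeneric("asIgraph", function(x, mode = c("directed", "undirected"))
  standardGeneric("asIgraph"))

#' Fit a discrete power law to a degree distribution
#'
#' Ordinary least squares on (log10 k, log10 f(k)) over the unbinned
#' degree histogram, restricted to degrees k > 0 with frequency f(k) > 0.
#'
#' @param x a RegNetwork, a numeric vector of node degrees, or a
#'   data.frame with columns \code{k} and \code{freq}.
#' @param ... passed between methods (e.g. \code{role} to restrict a
#'   network fit to one node role).
#' @return list with elements slope, intercept, rSquared, nPoints.
#' @export
setGeneric("fitPowerLaw", function(x, ...) standardGeneric("fitPowerLaw"))
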