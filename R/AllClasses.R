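#' @import methods
NULL

## Interaction classes of the curated edge tables. TF_TF only appears after
## network merge, when a dual-role gene is reclassified as a TF.
.EDGE_CLASSES <- c("MIRNA_GENE", "MIRNA_TF", "TF_GENE", "TF_MIRNA")
.NET_CLASSES <- c(.EDGE_CLASSES, "TF_TF")
.FFL_TYPES <- c("TF_FFL", "MIRNA_FFL", "COMPOSITE")

#' EdgeTable: deduplicated typed regulatory edges with provenance
#'
#' A directed regulatory edge table in which every row is a unique
#' (regulator, target, class) triple. The class is one of
#' \code{MIRNA_GENE}, \code{MIRNA_TF}, \code{TF_GENE}, \code{TF_MIRNA}
#' (plus \code{TF_TF} inside merged networks). Provenance columns record
#' the number of distinct source databases supporting the edge and whether
#' any attestation was experimentally verified.
#'
#' @slot edges data.frame with columns \code{regulator}, \code{target},
#'   \code{class}, \code{support}, \code{anyVerified}.
#' @exportClass EdgeTable
setClass("EdgeTable", slots = c(edges = "data.frame"))

setValidity("EdgeTable", function(object) {
  ed <- object@edges
  need <- c("regulator", "target", "class", "support", "anyVerified")
  if (!all(need %in% names(ed)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(ed) == 0L) return(TRUE)
  if (!all(ed$class %in% .NET_CLASSES))
    return(paste("unknown interaction class:",
                 paste(unique(setdiff(ed$class, .NET_CLASSES)), collapse = ", ")))
  if (any(ed$regulator == ed$target))
    return("self-edges are not allowed")
  if (anyDuplicated(paste(ed$regulator, ed$target, ed$class, sep = "\r")))
    return("duplicate (regulator, target, class) triples")
  if (any(!nzchar(ed$regulator)) || any(!nzchar(ed$target)))
    return("empty node ids")
  TRUE
})

#' NodeCatalog: disease genes, disease miRNAs and known TFs
#'
#' Holds the three id universes the analysis is restricted to: disease
#' genes, disease mature miRNAs, and known transcription factors. A gene
#' present in both the gene and TF lists is a dual-role node.
#'
#' @slot miGenes character vector of disease gene ids.
#' @slot miMirnas character vector of disease mature miRNA ids.
#' @slot tfs character vector of TF gene ids.
#' @exportClass NodeCatalog
setClass("NodeCatalog",
         slots = c(miGenes = "character", miMirnas = "character",
                   tfs = "character"))

setValidity("NodeCatalog", function(object) {
  if (anyDuplicated(object@miGenes) || anyDuplicated(object@miMirnas) ||
      anyDuplicated(object@tfs))
    return("catalog id lists must be unique")
  if (length(intersect(object@miMirnas, c(object@miGenes, object@tfs))))
    return("miRNA ids must not collide with gene/TF ids")
  TRUE
})

#' FflCatalog: enumerated and typed feed-forward loops
#'
#' Every row is one (tf, mirna, gene) triple with an exclusive type:
#' \code{TF_FFL} (TF regulates the miRNA), \code{MIRNA_FFL} (miRNA
#' represses the TF) or \code{COMPOSITE} (mutual TF/miRNA regulation).
#' In all three the TF and the miRNA co-regulate the gene.
#'
#' @slot ffls data.frame with columns \code{tf}, \code{mirna},
#'   \code{gene}, \code{type}.
#' @exportClass FflCatalog
setClass("FflCatalog", slots = c(ffls = "data.frame"))

setValidity("FflCatalog", function(object) {
  ff <- object@ffls
  need <- c("tf", "mirna", "gene", "type")
  if (!all(need %in% names(ff)))
    return(paste("ffls must have columns:", paste(need, collapse = ", ")))
  if (nrow(ff) == 0L) return(TRUE)
  if (!all(ff$type %in% .FFL_TYPES))
    return("unknown FFL type")
  if (anyDuplicated(paste(ff$tf, ff$mirna, ff$gene, sep = "\r")))
    return("duplicate (tf, mirna, gene) triples")
  if (any(ff$gene == ff$tf) || any(ff$gene == ff$mirna))
    return("gene slot must differ from the tf and mirna slots")
  TRUE
})

#' RegNetwork: merged miRNA-TF co-regulatory network
#'
#' Directed typed graph obtained by merging the constituent edges of a
#' feed-forward-loop catalog. Node roles are \code{gene}, \code{miRNA} or
#' \code{TF}; after reclassification a node appearing in both the disease
#' gene and the TF catalog has role TF, and edges pointing at it are
#' relabeled (TF_GENE -> TF_TF, MIRNA_GENE -> MIRNA_TF).
#'
#' @slot nodes data.frame with columns \code{id}, \code{role}.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{class}.
#' @exportClass RegNetwork
setClass("RegNetwork",
         slots = c(nodes = "data.frame", edges = "data.frame"))

setValidity("RegNetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  if (!all(c("id", "role") %in% names(nd)))
    return("nodes must have columns id, role")
  if (!all(c("from", "to", "class") %in% names(ed)))
    return("edges must have columns from, to, class")
  if (anyDuplicated(nd$id)) return("duplicate node ids")
  if (nrow(ed)) {
    if (!all(nd$role %in% c("gene", "miRNA", "TF")))
      return("node role must be gene, miRNA or TF")
    if (!all(c(ed$from, ed$to) %in% nd$id))
      return("edge endpoint missing from node table")
    if (!all(ed$class %in% .NET_CLASSES))
      return("unknown edge class")
    if (anyDuplicated(paste(ed$from, ed$to, ed$class, sep = "\r")))
      return("duplicate directed edges")
  }
  TRUE
})

#' PermutationResult: observed statistic with its Monte-Carlo null
#'
#' @slot observed observed count.
#' @slot nullCounts vector of counts from the randomized null.
#' @slot pValue empirical p, the proportion of null counts >= observed
#'   (no smoothing; exactly 0 is representable).
#' @slot nIter number of iterations.
#' @slot seed seed used.
#' @exportClass PermutationResult
setClass("PermutationResult",
         slots = c(observed = "numeric", nullCounts = "numeric",
                   pValue = "numeric", nIter = "integer", seed = "integer"))

setValidity("PermutationResult", function(object) {
  if (length(object@nullCounts) != object@nIter)
    return("nullCounts length must equal nIter")
  p <- object@pValue
  if (p < 0 || p > 1) return("pValue outside [0, 1]")
  if (abs(p - mean(object@nullCounts >= object@observed)) > 1e-12)
    return("pValue inconsistent with null counts")
  TRUE
})

#' Module: a k-clique community
#'
#' @slot nodeIds member node ids (sorted).
#' @slot k clique size used by the percolation.
#' @slot roles named character vector of member roles (may be empty when
#'   the community was found on a bare graph).
#' @exportClass Module
setClass("Module",
         slots = c(nodeIds = "character", k = "integer", roles = "character"))

setValidity("Module", function(object) {
  if (length(object@nodeIds) < object@k)
    return("a k-clique community has at least k members")
  if (object@k < 3L) return("k must be >= 3")
  TRUE
})

#' GoDag: a Gene Ontology directed acyclic graph
#'
#' Child-to-parent edges typed \code{is_a} or \code{part_of}, terms
#' partitioned into the BP/MF/CC namespaces.
#'
#' @slot terms data.frame with columns \code{id}, \code{name},
#'   \code{namespace}.
#' @slot edges data.frame with columns \code{child}, \code{parent},
#'   \code{relation}.
#' @exportClass GoDag
setClass("GoDag", slots = c(terms = "data.frame", edges = "data.frame"))

setValidity("GoDag", function(object) {
  tm <- object@terms; ed <- object@edges
  if (!all(c("id", "name", "namespace") %in% names(tm)))
    return("terms must have columns id, name, namespace")
  if (!all(c("child", "parent", "relation") %in% names(ed)))
    return("edges must have columns child, parent, relation")
  if (anyDuplicated(tm$id)) return("duplicate term ids")
  if (nrow(ed)) {
    if (!all(ed$relation %in% c("is_a", "part_of")))
      return("relation must be is_a or part_of")
    if (!all(c(ed$child, ed$parent) %in% tm$id))
      return("edge references unknown term")
    g <- igraph::graph_from_data_frame(ed[, c("child", "parent")],
                                       directed = TRUE)
    if (!igraph::is_dag(g)) return("ontology graph contains a cycle")
  }
  TRUE
})

#' SynthConfig: parameters of the synthetic-data generator
#'
#' @slot nGenes,nTfs,nMirnas node universe sizes.
#' @slot nDual number of gene ids also placed on the TF list.
#' @slot plantedFfls named integer vector c(TF_FFL=, MIRNA_FFL=, COMPOSITE=).
#' @slot backgroundDensity named numeric of per-class background edge
#'   probabilities (names from MIRNA_GENE, MIRNA_TF, TF_GENE, TF_MIRNA);
#'   a single unnamed value is recycled to all four classes.
#' @slot nSources number of simulated source databases per class.
#' @slot supportDist categorical distribution over per-edge source counts
#'   1..length(supportDist); must sum to 1.
#' @slot plantedCommunities list of c(k=, n=) chain-of-cliques specs.
#' @slot goDepth depth of the toy GO tree under each namespace root.
#' @slot seed integer seed.
#' @exportClass SynthConfig
setClass("SynthConfig",
         slots = c(nGenes = "integer", nTfs = "integer", nMirnas = "integer",
                   nDual = "integer", plantedFfls = "integer",
                   backgroundDensity = "numeric", nSources = "integer",
                   supportDist = "numeric", plantedCommunities = "list",
                   goDepth = "integer", seed = "integer"))

setValidity("SynthConfig", function(object) {
  cnt <- c(object@nGenes, object@nTfs, object@nMirnas, object@nDual,
           object@plantedFfls, object@nSources, object@goDepth)
  if (any(cnt < 0L)) return("all counts must be >= 0")
  if (object@nDual > min(object@nGenes, object@nTfs))
    return("nDual exceeds min(nGenes, nTfs)")
  if (!setequal(names(object@plantedFfls), .FFL_TYPES))
    return("plantedFfls must be named TF_FFL, MIRNA_FFL, COMPOSITE")
  bd <- object@backgroundDensity
  if (!setequal(names(bd), .EDGE_CLASSES))
    return("backgroundDensity must be named by the four edge classes")
  if (any(bd < 0) || any(bd > 1))
    return("backgroundDensity must lie in [0, 1]")
  if (abs(sum(object@supportDist) - 1) > 1e-8)
    return("supportDist must sum to 1")
  if (length(object@supportDist) > object@nSources)
    return("supportDist has more support levels than nSources")
  ## planted FFLs need distinct (tf, mirna) anchor pairs
  if (sum(object@plantedFfls) > object@nTfs * object@nMirnas)
    return(sprintf(
      "planted FFL total %d exceeds the %d distinct (tf, mirna) pairs available",
      sum(object@plantedFfls), object@nTfs * object@nMirnas))
  if (sum(object@plantedFfls) > 0L && object@nGenes < 1L)
    return("planted FFLs require at least one gene")
  for (pc in object@plantedCommunities) {
    if (!all(c("k", "n") %in% names(pc)))
      return("each plantedCommunities entry needs k and n")
    if (pc[["k"]] < 3) return("community k must be >= 3")
  }
  TRUE
})

#' SynthBundle: generated inputs plus ground truth
#'
#' Everything the pipeline consumes, generated with known planted
#' structure: node catalogs, pre-filter source records, TFBS fixture, toy
#' GO DAG with gene annotations, GMT gene sets, planted community edges,
#' and a ground-truth list (planted FFL triples, community node sets,
#' coherent gene set, planted enriched set name, TFBS truth labels).
#'
#' @slot catalog NodeCatalog.
#' @slot sourceRecords pre-filter records (regulator_id, target_id,
#'   interaction_class, source_db, evidence).
#' @slot tfbs list(hits, tss, premirna, truth) from the TFBS fixture.
#' @slot goDag GoDag.
#' @slot annotations gene-to-term data.frame.
#' @slot geneSets named list of character vectors (GMT content).
#' @slot communityEdges undirected edge data.frame (from, to) realizing
#'   the planted k-clique communities.
#' @slot groundTruth list of planted structures.
#' @slot config the SynthConfig used.
#' @exportClass SynthBundle
setClass("SynthBundle",
         slots = c(catalog = "NodeCatalog", sourceRecords = "data.frame",
                   tfbs = "list", goDag = "GoDag",
                   annotations = "data.frame", geneSets = "list",
                   communityEdges = "data.frame", groundTruth = "list",
                   config = "SynthConfig"))
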