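#' Construct a GoDag
#'
#' @param terms data.frame(id, name, namespace).
#' @param edges data.frame(child, parent, relation) with relation
#'   \code{is_a} or \code{part_of}.
#' @return a GoDag.
#' @export
GoDag <- function(terms, edges) {
  new("GoDag", terms = terms, edges = edges)
}

setMethod("show", "GoDag", function(object) {
  ns <- table(object@terms$namespace)
  cat("GoDag:", nrow(object@terms), "terms (",
      paste(names(ns), ns, sep = "=", collapse = ", "), "),",
      nrow(object@edges), "edges\n")
})

#' @describeIn GoDag namespace of each term, named by term id.
#' @param x a GoDag.
#' @export
termNamespaces <- function(x) {
  stats::setNames(x@terms$namespace, x@terms$id)
}

#' Read a go-basic-dialect OBO file
#'
#' Parses \code{[Term]} stanzas with their id, name, namespace,
#' \code{is_a} and \code{relationship: part_of} lines. Obsolete terms
#' are skipped. This is the minimal subset sufficient for
#' semantic-similarity computation, not a general OBO parser.
#'
#' @param path OBO file path.
#' @return a \linkS4class{GoDag}.
#' @export
readOboDag <- function(path) {
  lines <- readLines(path)
  termStarts <- which(lines == "[Term]")
  ids <- names <- nss <- character(0)
  ch <- pa <- rel <- character(0)
  bounds <- c(termStarts, length(lines) + 1L)
  for (i in seq_along(termStarts)) {
    blk <- lines[seq.int(termStarts[i] + 1L, bounds[i + 1L] - 1L)]
    blk <- blk[nzchar(blk)]
    if (any(blk == "is_obsolete: true")) next
    take1 <- function(field) {
      v <- blk[startsWith(blk, paste0(field, ": "))]
      if (length(v)) sub(paste0("^", field, ": "), "", v[1]) else NA_character_
    }
    id <- take1("id")
    if (is.na(id)) next
    ids <- c(ids, id)
    names <- c(names, take1("name"))
    nss <- c(nss, take1("namespace"))
    isa <- blk[startsWith(blk, "is_a: ")]
    for (v in isa) {
      tgt <- sub("^is_a: +(\\S+).*$", "\\1", v)
      ch <- c(ch, id); pa <- c(pa, tgt); rel <- c(rel, "is_a")
    }
    po <- blk[startsWith(blk, "relationship: part_of ")]
    for (v in po) {
      tgt <- sub("^relationship: part_of +(\\S+).*$", "\\1", v)
      ch <- c(ch, id); pa <- c(pa, tgt); rel <- c(rel, "part_of")
    }
  }
  short <- c(biological_process = "BP", molecular_function = "MF",
             cellular_component = "CC")
  nss <- ifelse(nss %in% names(short), short[nss], nss)
  ed <- data.frame(child = ch, parent = pa, relation = rel,
                   stringsAsFactors = FALSE)
  ed <- ed[ed$parent %in% ids, , drop = FALSE]
  GoDag(data.frame(id = ids, name = names, namespace = unname(nss),
                   stringsAsFactors = FALSE), ed)
}

#' Write a GoDag to a go-basic-dialect OBO file
#'
#' @param dag a GoDag.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeOboDag <- function(dag, path) {
  long <- c(BP = "biological_process", MF = "molecular_function",
            CC = "cellular_component")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  byChild <- split(seq_len(nrow(dag@edges)), dag@edges$child)
  for (i in seq_len(nrow(dag@terms))) {
    id <- dag@terms$id[i]
    ns <- dag@terms$namespace[i]
    out <- c("[Term]", paste0("id: ", id),
             paste0("name: ", dag@terms$name[i]),
             paste0("namespace: ",
                    if (ns %in% names(long)) long[[ns]] else ns))
    for (j in byChild[[id]]) {
      out <- c(out, if (dag@edges$relation[j] == "is_a")
        paste0("is_a: ", dag@edges$parent[j])
        else paste0("relationship: part_of ", dag@edges$parent[j]))
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

## Wang S-values: propagate a contribution of 1 at the query term up the
## ancestor graph, multiplying by the edge weight and keeping the max
## over paths.
.svalues <- function(dag, term, weights = c(is_a = 0.8, part_of = 0.6)) {
  parents <- split(seq_len(nrow(dag@edges)), dag@edges$child)
  s <- c(stats::setNames(1, term))
  queue <- term
  while (length(queue)) {
    t0 <- queue[1]; queue <- queue[-1]
    for (j in parents[[t0]]) {
      p <- dag@edges$parent[j]
      cand <- unname(weights[[dag@edges$relation[j]]] * s[[t0]])
      if (is.na(s[p]) || cand > s[[p]]) {
        s[p] <- cand
        queue <- c(queue, p)
      }
    }
  }
  s
}

#' Wang semantic similarity between two GO terms
#'
#' Graph-based measure: each term's contribution (S-value) propagates up
#' its ancestor DAG with weight 0.8 per \code{is_a} edge and 0.6 per
#' \code{part_of} edge, taking the maximum over paths. The similarity is
#' the summed S-values of the shared ancestors (from both sides) over
#' the two terms' total semantic values, a number in [0, 1] with
#' sim(t, t) = 1.
#'
#' @param t1,t2 term ids in the same namespace.
#' @param dag a GoDag.
#' @param weights named edge-type weights (default is_a 0.8, part_of
#'   0.6).
#' @return numeric similarity in [0, 1].
#' @export
termSimilarity <- function(t1, t2, dag,
                           weights = c(is_a = 0.8, part_of = 0.6)) {
  ns <- termNamespaces(dag)
  if (is.na(ns[t1]) || is.na(ns[t2]))
    stop("unknown term id")
  if (ns[[t1]] != ns[[t2]])
    stop("terms are in different namespaces: ", ns[[t1]], " vs ", ns[[t2]])
  s1 <- .svalues(dag, t1, weights)
  s2 <- .svalues(dag, t2, weights)
  common <- intersect(names(s1), names(s2))
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

#' Gene-level semantic similarity (best-match average)
#'
#' Aggregates term-level Wang similarities over the two genes' term sets
#' by best-match averaging: every term of each gene is matched to its
#' best counterpart on the other side and the matches are averaged.
#' Genes with no annotation in the namespace yield \code{NA} (a
#' missing-value sentinel excluded from downstream score vectors).
#'
#' @param g1,g2 gene ids.
#' @param annotations data.frame with columns \code{gene}, \code{term}.
#' @param dag a GoDag.
#' @param namespace restrict terms to one namespace (default "BP").
#' @return numeric in [0, 1], or NA if either gene is unannotated.
#' @export
geneSimilarity <- function(g1, g2, annotations, dag, namespace = "BP") {
  ns <- termNamespaces(dag)
  ann <- annotations[annotations$term %in% names(ns)[ns == namespace], ]
  t1 <- unique(ann$term[ann$gene == g1])
  t2 <- unique(ann$term[ann$gene == g2])
  if (!length(t1) || !length(t2)) return(NA_real_)
  simMat <- outer(seq_along(t1), seq_along(t2),
                  Vectorize(function(i, j) termSimilarity(t1[i], t2[j], dag)))
  (sum(apply(simMat, 1, max)) + sum(apply(simMat, 2, max))) /
    (length(t1) + length(t2))
}

## Pairwise gene-similarity matrix with cached per-term S-values;
## the workhorse behind the module-coherence randomization.
.gene_sim_matrix <- function(genes, annotations, dag, namespace = "BP") {
  ns <- termNamespaces(dag)
  ann <- annotations[annotations$term %in% names(ns)[ns == namespace] &
                       annotations$gene %in% genes, ]
  termsByGene <- split(unique(ann[c("gene", "term")])$term,
                       unique(ann[c("gene", "term")])$gene)
  terms <- unique(ann$term)
  sv <- lapply(terms, function(t) .svalues(dag, t))
  names(sv) <- terms
  svTot <- vapply(sv, sum, numeric(1))
  tsim <- matrix(NA_real_, length(terms), length(terms),
                 dimnames = list(terms, terms))
  for (i in seq_along(terms)) for (j in seq.int(i, length(terms))) {
    common <- intersect(names(sv[[i]]), names(sv[[j]]))
    v <- sum(sv[[i]][common] + sv[[j]][common]) / (svTot[i] + svTot[j])
    tsim[i, j] <- tsim[j, i] <- v
  }
  n <- length(genes)
  gsim <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    ti <- termsByGene[[genes[i]]]
    gsim[i, i] <- if (length(ti)) 1 else NA_real_
    if (i == n) next
    for (j in seq.int(i + 1L, n)) {
      tj <- termsByGene[[genes[j]]]
      if (!length(ti) || !length(tj)) next
      m <- tsim[ti, tj, drop = FALSE]
      gsim[i, j] <- gsim[j, i] <-
        (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) /
        (length(ti) + length(tj))
    }
  }
  gsim
}
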