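#' Synthetic-data generator configuration
#'
#' Defaults emulate the shape of the disease universe the pipeline is
#' designed for: 854 disease genes, 78 disease mature miRNAs and 1,698
#' TFs with 19 dual-role genes; planted FFL counts of 236/902/94 per
#' type; per-class background densities chosen so that the post-filter
#' class tables have pair counts on the order of the curated tables
#' (roughly 1.4k/3.3k/4.4k/0.2k); and three planted k=5 communities of
#' 15, 5 and 6 nodes (clique chains of length 11, 1 and 2).
#'
#' @param nGenes,nTfs,nMirnas node universe sizes.
#' @param nDual number of gene ids shared with the TF list.
#' @param plantedFfls named counts c(TF_FFL=, MIRNA_FFL=, COMPOSITE=).
#' @param backgroundDensity per-class background edge probability;
#'   either a single value recycled to the four classes or a named
#'   vector.
#' @param nSources simulated source databases.
#' @param supportDist probability of 1, 2, ... supporting sources per
#'   background edge (planted edges always get support >= 2 so they
#'   survive the default filter).
#' @param plantedCommunities list of c(k=, n=) chain-of-cliques specs;
#'   a chain of n k-cliques yields a community of k + n - 1 nodes.
#' @param goDepth depth of the toy GO tree per namespace.
#' @param seed integer seed.
#' @return a \linkS4class{SynthConfig}.
#' @export
synthConfig <- function(nGenes = 854L, nTfs = 1698L, nMirnas = 78L,
                        nDual = 19L,
                        plantedFfls = c(TF_FFL = 236L, MIRNA_FFL = 902L,
                                        COMPOSITE = 94L),
                        backgroundDensity = c(MIRNA_GENE = 0.04,
                                              MIRNA_TF = 0.05,
                                              TF_GENE = 0.006,
                                              TF_MIRNA = 0.002),
                        nSources = 3L,
                        supportDist = c(0.5, 0.3, 0.2),
                        plantedCommunities = list(c(k = 5, n = 11),
                                                  c(k = 5, n = 1),
                                                  c(k = 5, n = 2)),
                        goDepth = 3L, seed = 42L) {
  if (length(backgroundDensity) == 1L && is.null(names(backgroundDensity)))
    backgroundDensity <- stats::setNames(rep(backgroundDensity, 4),
                                         .EDGE_CLASSES)
  pf <- stats::setNames(as.integer(plantedFfls[.FFL_TYPES]), .FFL_TYPES)
  new("SynthConfig", nGenes = as.integer(nGenes), nTfs = as.integer(nTfs),
      nMirnas = as.integer(nMirnas), nDual = as.integer(nDual),
      plantedFfls = pf,
      backgroundDensity = backgroundDensity[.EDGE_CLASSES],
      nSources = as.integer(nSources), supportDist = supportDist,
      plantedCommunities = plantedCommunities,
      goDepth = as.integer(goDepth), seed = as.integer(seed))
}

.synth_ids <- function(config) {
  genes <- sprintf("gene%04d", seq_len(config@nGenes))
  pureTf <- sprintf("tf%04d", seq_len(config@nTfs - config@nDual))
  tfs <- c(genes[seq_len(config@nDual)], pureTf)   # duals first
  mirs <- sprintf("mir%03d", seq_len(config@nMirnas))
  list(genes = genes, tfs = tfs, mirs = mirs)
}

.draw_support <- function(n, dist, atLeast2 = FALSE) {
  lv <- seq_along(dist)
  if (atLeast2) {
    if (length(dist) < 2L) stop("supportDist has no mass at support >= 2")
    p <- dist[-1] / sum(dist[-1])
    sample(lv[-1], n, replace = TRUE, prob = p)
  } else sample(lv, n, replace = TRUE, prob = dist)
}

## Plant FFL triples on distinct (tf, mirna) anchor pairs and repair
## any accidental extra triples created by shared tfs/mirnas/genes, so
## that with zero background enumeration recovers the planted catalog
## exactly.
.plant_ffls <- function(ids, planted) {
  total <- sum(planted)
  if (total == 0L)
    return(.empty_ffls())
  pairIdx <- sample.int(length(ids$tfs) * length(ids$mirs), total)
  tf <- ids$tfs[(pairIdx - 1L) %% length(ids$tfs) + 1L]
  mir <- ids$mirs[(pairIdx - 1L) %/% length(ids$tfs) + 1L]
  type <- rep(.FFL_TYPES, planted[.FFL_TYPES])
  pickGene <- function(tfId) {
    g <- sample(ids$genes, 1L)
    while (g == tfId) g <- sample(ids$genes, 1L)
    g
  }
  gene <- vapply(tf, pickGene, character(1))
  ff <- data.frame(tf = tf, mirna = mir, gene = gene, type = type,
                   stringsAsFactors = FALSE)
  for (rep in seq_len(100L)) {
    cat <- ffls(enumerateFfls(EdgeTable(.ffl_constituent_edges(ff))))
    key <- function(d) paste(d$tf, d$mirna, d$gene, sep = "\r")
    extra <- cat[!key(cat) %in% key(ff), , drop = FALSE]
    if (!nrow(extra)) break
    ## resample the gene of one planted FFL feeding each extra triple
    for (i in seq_len(nrow(extra))) {
      j <- which(ff$tf == extra$tf[i] & ff$gene == extra$gene[i])[1]
      if (is.na(j))
        j <- which(ff$mirna == extra$mirna[i] & ff$gene == extra$gene[i])[1]
      ff$gene[j] <- pickGene(ff$tf[j])
    }
  }
  ff
}

## Heavy-tailed per-node attachment propensities (Zipf over a random
## permutation of ranks) give the background a scale-free-like degree
## structure rather than a Poisson one.
.zipf_weights <- function(n, exponent = 0.9) {
  w <- seq_len(n)^(-exponent)
  sample(w / sum(w))
}

.background_edges <- function(ids, config, anchors) {
  out <- list()
  pairsOf <- function(cls) switch(cls,
    MIRNA_GENE = list(r = ids$mirs, t = ids$genes),
    MIRNA_TF   = list(r = ids$mirs, t = ids$tfs),
    TF_GENE    = list(r = ids$tfs,  t = ids$genes),
    TF_MIRNA   = list(r = ids$tfs,  t = ids$mirs))
  for (cls in .EDGE_CLASSES) {
    dens <- config@backgroundDensity[[cls]]
    if (dens <= 0) next
    p <- pairsOf(cls)
    nn <- length(p$r) * length(p$t)
    nEdges <- stats::rbinom(1L, nn, dens)
    if (!nEdges) next
    wr <- .zipf_weights(length(p$r))
    wt <- .zipf_weights(length(p$t))
    reg <- p$r[sample.int(length(p$r), nEdges, replace = TRUE, prob = wr)]
    tgt <- p$t[sample.int(length(p$t), nEdges, replace = TRUE, prob = wt)]
    keep <- reg != tgt & !duplicated(paste(reg, tgt))
    ## background must not flip a planted anchor's type: never add the
    ## reverse regulator-regulator edge of a planted one-directional pair
    if (cls == "MIRNA_TF")
      keep <- keep & !(paste(tgt, reg) %in% anchors$tfOnly)
    if (cls == "TF_MIRNA")
      keep <- keep & !(paste(reg, tgt) %in% anchors$mirOnly)
    if (!any(keep)) next
    out[[cls]] <- data.frame(regulator = reg[keep], target = tgt[keep],
                             class = cls, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(.empty_edges()[, 1:3])))
}

.make_source_records <- function(edgeDf, support, config) {
  srcs <- sprintf("src%02d", seq_len(config@nSources))
  n <- nrow(edgeDf)
  if (!n)
    return(data.frame(regulator_id = character(), target_id = character(),
                      interaction_class = character(),
                      source_db = character(), evidence = character(),
                      stringsAsFactors = FALSE))
  ## per edge, its `support` sources are the first columns of a random
  ## ranking of all source names (vectorized draw of distinct sources)
  rk <- matrix(stats::runif(n * length(srcs)), nrow = n)
  ord <- t(apply(rk, 1L, order))
  idx <- rep(seq_len(n), support)
  col <- unlist(lapply(support, seq_len))
  data.frame(
    regulator_id = edgeDf$regulator[idx], target_id = edgeDf$target[idx],
    interaction_class = edgeDf$class[idx],
    source_db = srcs[ord[cbind(idx, col)]],
    evidence = sample(c("verified", "predicted"), length(idx),
                      replace = TRUE),
    stringsAsFactors = FALSE)
}

.plant_communities <- function(ids, specs) {
  allIds <- c(ids$genes, ids$tfs, ids$mirs)
  used <- character(0)
  comms <- list()
  edgesFrom <- edgesTo <- character(0)
  for (s in seq_along(specs)) {
    k <- as.integer(specs[[s]][["k"]]); n <- as.integer(specs[[s]][["n"]])
    size <- k + n - 1L
    avail <- setdiff(allIds, used)
    if (length(avail) < size)
      stop("planted community of ", size,
           " nodes exceeds the remaining node pool (", length(avail), ")")
    memb <- sample(avail, size)
    used <- c(used, memb)
    for (w in seq_len(n)) {
      cliq <- memb[seq.int(w, w + k - 1L)]
      pr <- t(utils::combn(cliq, 2L))
      edgesFrom <- c(edgesFrom, pr[, 1]); edgesTo <- c(edgesTo, pr[, 2])
    }
    comms[[s]] <- list(k = k, nodes = sort(memb))
  }
  a <- pmin(edgesFrom, edgesTo); b <- pmax(edgesFrom, edgesTo)
  keep <- !duplicated(paste(a, b))
  list(communities = comms,
       edges = data.frame(from = a[keep], to = b[keep],
                          stringsAsFactors = FALSE))
}

.toy_go <- function(ids, config, coherentGenes) {
  branching <- 3L
  depth <- max(1L, config@goDepth)
  terms <- edges <- list()
  leafBy <- list()
  for (nsi in seq_along(c("BP", "MF", "CC"))) {
    ns <- c("BP", "MF", "CC")[nsi]
    counter <- 0L
    mk <- function() {
      counter <<- counter + 1L
      sprintf("GO:%d%06d", nsi, counter)
    }
    root <- mk()
    tm <- data.frame(id = root, name = paste(ns, "root"), namespace = ns,
                     stringsAsFactors = FALSE)
    ed <- data.frame(child = character(), parent = character(),
                     relation = character(), stringsAsFactors = FALSE)
    level <- root
    for (d in seq_len(depth)) {
      nxt <- character(0)
      for (p in level) for (b in seq_len(branching)) {
        id <- mk()
        tm <- rbind(tm, data.frame(id = id,
                                   name = sprintf("%s d%d", ns, d),
                                   namespace = ns))
        ed <- rbind(ed, data.frame(child = id, parent = p,
                                   relation = "is_a"))
        nxt <- c(nxt, id)
      }
      level <- nxt
    }
    ## a few part_of cross edges from leaves to a foreign shallow node
    shallow <- ed$child[ed$parent == root]
    for (cf in utils::head(level, 2L))
      ed <- rbind(ed, data.frame(child = cf, parent = shallow[length(shallow)],
                                 relation = "part_of"))
    leafBy[[ns]] <- level
    terms[[ns]] <- tm; edges[[ns]] <- ed
  }
  dag <- GoDag(do.call(rbind, terms), do.call(rbind, edges))
  ## coherent genes share sibling leaves of the first branch; diffuse
  ## pool genes get random leaves anywhere
  ann <- list()
  for (ns in c("BP", "MF", "CC")) {
    leaves <- leafBy[[ns]]
    sibs <- leaves[seq_len(min(branching, length(leaves)))]
    for (g in coherentGenes)
      ann[[length(ann) + 1L]] <-
        data.frame(gene = g, term = sample(sibs, min(2L, length(sibs))),
                   stringsAsFactors = FALSE)
    pool <- setdiff(utils::head(ids$genes, 60L), coherentGenes)
    for (g in pool)
      ann[[length(ann) + 1L]] <-
        data.frame(gene = g, term = sample(leaves, 2L),
                   stringsAsFactors = FALSE)
  }
  list(dag = dag, annotations = unique(do.call(rbind, ann)))
}

#' Generate a synthetic input bundle with known planted structure
#'
#' Produces every input the pipeline consumes: node catalogs,
#' pre-filter source records realizing planted FFLs (support >= 2) over
#' class-specific background edges (support drawn from the configured
#' distribution), planted chain-of-cliques communities, a toy GO DAG
#' with a functionally coherent gene group, GMT gene sets with one
#' planted enrichment, and a TFBS fixture. Deterministic for a fixed
#' seed. With zero background density, FFL enumeration on the filtered
#' records recovers the planted catalog exactly; background edges never
#' flip a planted anchor's FFL type, so per-type counts are monotone in
#' the background.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @return a \linkS4class{SynthBundle}.
#' @examples
#' cfg <- synthConfig(nGenes = 40, nTfs = 12, nMirnas = 8, nDual = 2,
#'                    plantedFfls = c(TF_FFL = 3, MIRNA_FFL = 5,
#'                                    COMPOSITE = 2),
#'                    backgroundDensity = 0, seed = 42)
#' bundle <- generateBundle(cfg)
#' @export
generateBundle <- function(config) {
  validObject(config)
  set.seed(config@seed)
  ids <- .synth_ids(config)
  catalog <- NodeCatalog(ids$genes, ids$mirs, ids$tfs)

  planted <- .plant_ffls(ids, config@plantedFfls)
  plantedEdges <- .ffl_constituent_edges(planted)
  plantedEdges <- plantedEdges[!duplicated(
    paste(plantedEdges$regulator, plantedEdges$target, plantedEdges$class,
          sep = "\r")), , drop = FALSE]
  anchors <- list(
    tfOnly = paste(planted$tf[planted$type == "TF_FFL"],
                   planted$mirna[planted$type == "TF_FFL"]),
    mirOnly = paste(planted$tf[planted$type == "MIRNA_FFL"],
                    planted$mirna[planted$type == "MIRNA_FFL"]))
  bg <- .background_edges(ids, config, anchors)
  bgKey <- paste(bg$regulator, bg$target, bg$class, sep = "\r")
  plKey <- paste(plantedEdges$regulator, plantedEdges$target,
                 plantedEdges$class, sep = "\r")
  bg <- bg[!bgKey %in% plKey, , drop = FALSE]

  support <- c(.draw_support(nrow(plantedEdges), config@supportDist,
                             atLeast2 = TRUE),
               .draw_support(nrow(bg), config@supportDist))
  allEdges <- rbind(plantedEdges, bg[, c("regulator", "target", "class")])
  records <- .make_source_records(allEdges, support, config)

  pc <- .plant_communities(ids, config@plantedCommunities)
  commGeneIds <- lapply(pc$communities, function(cm)
    intersect(cm$nodes, ids$genes))
  coherent <- unique(unlist(commGeneIds))
  if (length(coherent) < 4L)
    coherent <- unique(c(coherent, utils::head(ids$genes, 6L)))
  go <- .toy_go(ids, config, coherent)

  plantedSet <- unique(c(coherent,
                         sample(ids$genes, min(4L, config@nGenes))))
  sets <- list(set_planted = plantedSet)
  for (i in seq_len(19L))
    sets[[sprintf("set_random%02d", i)]] <-
      sample(ids$genes, min(length(plantedSet), config@nGenes))

  tfbs <- generateTfbsFixture(config)

  truth <- list(plantedFfls = planted,
                communities = pc$communities,
                coherentGenes = coherent,
                plantedSet = "set_planted",
                tfbsTruth = tfbs$truth)
  new("SynthBundle", catalog = catalog, sourceRecords = records,
      tfbs = tfbs, goDag = go$dag, annotations = go$annotations,
      geneSets = sets, communityEdges = pc$edges, groundTruth = truth,
      config = config)
}

#' TFBS promoter-mapping fixture
#'
#' Deterministically constructs TSS and pre-miRNA annotations plus
#' binding-site hits that exercise every mapping rule: hits inside and
#' outside promoter windows, straddling a window boundary, Z scores
#' above, below and exactly at the cutoff, both precursor strands, and
#' a precursor with two mature ids. The returned \code{truth} table
#' labels each hit with whether it should produce an edge.
#'
#' @param config a \linkS4class{SynthConfig} (ids are taken from its
#'   universe).
#' @return list(hits, tss, premirna, truth).
#' @export
generateTfbsFixture <- function(config) {
  ids <- .synth_ids(config)
  tf <- utils::head(setdiff(ids$tfs, ids$genes), 3L)
  gn <- utils::head(ids$genes, 3L)
  mir <- utils::head(ids$mirs, 3L)
  tssPos <- c(10000L, 50000L, 90000L)
  tss <- data.frame(feature_id = gn, feature_kind = "gene_tss",
                    chrom = "chr1", start = tssPos, end = tssPos + 1L,
                    strand = "+", mature_ids = "",
                    stringsAsFactors = FALSE)
  pre <- data.frame(
    feature_id = c("pre_plus", "pre_minus"),
    feature_kind = "pre_mirna", chrom = "chr1",
    start = c(200000L, 300000L), end = c(200100L, 300100L),
    strand = c("+", "-"),
    mature_ids = c(paste(mir[1], mir[2], sep = ","), mir[3]),
    stringsAsFactors = FALSE)
  h <- function(tfId, s, e, z) data.frame(tf_id = tfId, chrom = "chr1",
                                          start = s, end = e, strand = "+",
                                          z_score = z,
                                          stringsAsFactors = FALSE)
  hits <- rbind(
    h(tf[1], tssPos[1] + 10L, tssPos[1] + 30L, 3.0),    # inside, maps
    h(tf[1], tssPos[2] + 10L, tssPos[2] + 30L, 2.33),   # Z at cutoff: no
    h(tf[2], tssPos[2] - 50L, tssPos[2] + 50L, 2.0),    # Z below: no
    h(tf[2], tssPos[3] - 1200L, tssPos[3] - 1001L, 3.0),# outside: no
    h(tf[2], tssPos[1] - 1200L, tssPos[1] - 999L, 3.0), # straddles: maps
    h(tf[3], 200000L - 1500L, 200000L - 1400L, 3.0),    # + pre upstream
    h(tf[3], 300100L + 1400L, 300100L + 1500L, 3.0),    # - pre "upstream"
    h(tf[1], 300000L - 500L, 300000L - 400L, 3.0))      # 5' of - pre: no
  truth <- data.frame(
    tf_id = hits$tf_id,
    feature_id = c(gn[1], gn[2], gn[2], gn[3], gn[1],
                   "pre_plus", "pre_minus", "pre_minus"),
    should_map = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    reason = c("inside window, Z above", "Z equal to cutoff",
               "Z below cutoff", "outside window",
               "straddles window boundary", "plus-strand upstream",
               "minus-strand upstream (reference downstream)",
               "wrong side of minus-strand precursor"),
    stringsAsFactors = FALSE)
  list(hits = hits, tss = tss, premirna = pre, truth = truth)
}

#' Write a synthetic bundle to disk in the pipeline's input formats
#'
#' Emits source_records.tsv, catalog files (migenes.txt, mimirnas.txt,
#' tfs.txt), tfbs_hits.tsv, promoter_annotations.tsv, go.obo,
#' annotations.tsv, sets.gmt, community_edges.tsv and
#' ground_truth.json.
#'
#' @param bundle a SynthBundle.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  utils::write.table(bundle@sourceRecords, fp("source_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(miGenes(bundle@catalog), fp("migenes.txt"))
  writeLines(miMirnas(bundle@catalog), fp("mimirnas.txt"))
  writeLines(tfIds(bundle@catalog), fp("tfs.txt"))
  utils::write.table(bundle@tfbs$hits, fp("tfbs_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rbind(bundle@tfbs$tss, bundle@tfbs$premirna),
                     fp("promoter_annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeOboDag(bundle@goDag, fp("go.obo"))
  writeGeneAnnotations(bundle@annotations, fp("annotations.tsv"))
  writeGmt(bundle@geneSets, fp("sets.gmt"))
  utils::write.table(bundle@communityEdges, fp("community_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- bundle@groundTruth
  jsonlite::write_json(
    list(plantedFfls = gt$plantedFfls,
         communities = lapply(gt$communities, function(cm)
           list(k = cm$k, nodes = cm$nodes)),
         coherentGenes = gt$coherentGenes,
         plantedSet = gt$plantedSet,
         tfbsTruth = gt$tfbsTruth),
    fp("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

setMethod("show", "SynthBundle", function(object) {
  cat("SynthBundle (seed", object@config@seed, "):\n  ")
  show(object@catalog)
  cat("  ", nrow(object@sourceRecords), "source records,",
      nrow(ffls(FflCatalog(object@groundTruth$plantedFfls))),
      "planted FFLs,", length(object@groundTruth$communities),
      "planted communities\n")
})
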