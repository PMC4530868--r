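toyCatalog <- function() NodeCatalog(miGenes = c("g1", "g2", "dual"),
                                     miMirnas = c("m1", "m2"),
                                     tfs = c("T1", "T2", "dual"))

test_that("merging FFLs unions constituent edges and assigns roles", {
  cat1 <- enumerateFfls(et("T1>m1:TF_MIRNA", "T1>g1:TF_GENE",
                           "m1>g1:MIRNA_GENE"))
  net <- mergeFflsToNetwork(cat1, toyCatalog())
  expect_equal(nrow(nodes(net)), 3L)
  expect_setequal(edges(net)$class, c("TF_MIRNA", "TF_GENE", "MIRNA_GENE"))
  expect_equal(nodes(net)$role[nodes(net)$id == "T1"], "TF")
  expect_equal(nodes(net)$role[nodes(net)$id == "m1"], "miRNA")
  expect_equal(nodes(net)$role[nodes(net)$id == "g1"], "gene")

  # two FFLs sharing the TF->gene edge: counted once
  cat2 <- enumerateFfls(et("T1>m1:TF_MIRNA", "T1>m2:TF_MIRNA",
                           "T1>g1:TF_GENE", "m1>g1:MIRNA_GENE",
                           "m2>g1:MIRNA_GENE"))
  net2 <- mergeFflsToNetwork(cat2, toyCatalog())
  expect_equal(sum(edges(net2)$class == "TF_GENE"), 1L)
  expect_equal(nrow(edges(net2)), 5L)
})

test_that("dual-role genes become TFs and their incoming edges are relabeled", {
  cat <- enumerateFfls(et("T1>m1:TF_MIRNA", "T1>dual:TF_GENE",
                          "m1>dual:MIRNA_GENE",
                          "T1>g1:TF_GENE", "m1>g1:MIRNA_GENE"))
  net <- mergeFflsToNetwork(cat, toyCatalog())
  expect_equal(nodes(net)$role[nodes(net)$id == "dual"], "TF")
  ed <- edges(net)
  expect_equal(ed$class[ed$from == "T1" & ed$to == "dual"], "TF_TF")
  expect_equal(ed$class[ed$from == "m1" & ed$to == "dual"], "MIRNA_TF")
  expect_false(any(ed$class == "TF_GENE" & ed$to == "dual"))
})

test_that("role slots collapse to unique nodes by the slot-overlap law", {
  # unique nodes = gene-slot + miRNA-slot + TF-slot counts minus the
  # ids occupying both a gene and a TF slot
  for (seed in c(4L, 16L)) {
    bundle <- generateBundle(mediumConfig(seed = seed))
    cat <- enumerateFfls(filteredEdges(bundle))
    ff <- ffls(cat)
    net <- mergeFflsToNetwork(cat, bundle@catalog)
    tot <- tabulateCatalog(cat)
    tot <- tot[tot$type == "Total", ]
    overlap <- length(intersect(unique(ff$gene), unique(ff$tf)))
    expect_equal(nrow(nodes(net)),
                 tot$nGenes + tot$nMirnas + tot$nTfs - overlap)
  }
})

test_that("edge union of the catalog equals the pre-reclassification network", {
  bundle <- generateBundle(mediumConfig(seed = 4L))
  cat <- enumerateFfls(filteredEdges(bundle))
  net <- mergeFflsToNetwork(cat, bundle@catalog)
  ff <- ffls(cat)
  member <- unique(c(ff$tf, ff$mirna, ff$gene))
  expect_setequal(nodes(net)$id, member)
  # every network edge traces back to >= 1 FFL and vice versa
  ce <- fflNet:::.ffl_constituent_edges(ff)
  ceKey <- unique(paste(ce$regulator, ce$target))
  netKey <- unique(paste(edges(net)$from, edges(net)$to))
  expect_setequal(netKey, ceKey)
  # undirected handshake: degree sum is twice the edge count
  g <- asIgraph(net, "directed")
  expect_equal(sum(igraph::degree(g, mode = "all")), 2L * nrow(edges(net)))
})

test_that("degree summaries match hand counts", {
  cat <- enumerateFfls(et("T1>m1:TF_MIRNA", "T1>g1:TF_GENE",
                          "m1>g1:MIRNA_GENE"))
  net <- mergeFflsToNetwork(cat, toyCatalog())
  ds <- degreeSummary(net)
  expect_equal(ds$meanDegree[ds$role == "gene"], 2)   # g1: two incoming
  expect_equal(ds$meanDegree[ds$role == "miRNA"], 2)  # m1: one in, one out
  expect_equal(ds$meanDegree[ds$role == "TF"], 2)     # T1: two out
})

test_that("power-law fits are exact on exact input and reject degenerate input", {
  # f(k) = C k^-2 on a log-log grid is recovered to machine precision
  k <- c(1, 2, 5, 10, 20, 50)
  hist <- data.frame(k = k, freq = 1e6 * k^-2)
  fit <- fitPowerLaw(hist)
  expect_equal(fit$slope, -2, tolerance = 1e-12)
  expect_equal(fit$rSquared, 1, tolerance = 1e-12)
  # all-equal degrees: no support for a fit
  expect_error(fitPowerLaw(rep(4, 10)), "insufficient degree support")
  # preferential-attachment graphs land in the expected slope band
  set.seed(8)
  g <- igraph::sample_pa(2000, m = 2, directed = FALSE)
  fitPa <- fitPowerLaw(as.numeric(igraph::degree(g)))
  expect_gt(fitPa$slope, -3.5)
  expect_lt(fitPa$slope, -1.5)
})

test_that("betweenness is directed, flags the top fraction, and zeroes sinks", {
  # two FFLs sharing m1: T1 reaches g2 only through m1, so the miRNA
  # is path-interior while every gene is a sink
  cat <- enumerateFfls(et("T1>m1:TF_MIRNA", "T1>g1:TF_GENE",
                          "m1>g1:MIRNA_GENE", "m1>T2:MIRNA_TF",
                          "T2>g2:TF_GENE", "m1>g2:MIRNA_GENE"))
  net <- mergeFflsToNetwork(cat, toyCatalog())
  rep <- betweennessReport(net, topFraction = 0.25)
  expect_gt(rep$betweenness[rep$id == "m1"], 0)
  expect_true(all(rep$betweenness[rep$role == "gene"] == 0))
  expect_equal(sum(rep$topBetweenness), ceiling(0.25 * nrow(rep)))
  # star: no two-step paths, all betweenness zero
  star <- mergeFflsToNetwork(
    enumerateFfls(et("T1>m1:TF_MIRNA", "T1>g1:TF_GENE",
                     "m1>g1:MIRNA_GENE")), toyCatalog())
  # sinks can never be path-interior
  repS <- betweennessReport(star)
  expect_equal(repS$betweenness[repS$id == "g1"], 0)
})

test_that("hub calling supports quantile and per-role top-N rules", {
  bundle <- generateBundle(mediumConfig(seed = 12L))
  net <- mergeFflsToNetwork(enumerateFfls(filteredEdges(bundle)),
                            bundle@catalog)
  hq <- findHubs(net, quantile = 0.9)
  deg <- hq$degree
  for (r in unique(hq$role)) {
    thr <- quantile(deg[hq$role == r], 0.9, names = FALSE)
    expect_identical(hq$hub[hq$role == r], deg[hq$role == r] >= thr)
  }
  # tie saturation: equal degrees means everyone reaches the quantile
  tiny <- mergeFflsToNetwork(
    enumerateFfls(et("T1>m1:TF_MIRNA", "T1>g1:TF_GENE",
                     "m1>g1:MIRNA_GENE")), toyCatalog())
  expect_true(all(findHubs(tiny, quantile = 0.9)$hub))
  hc <- findHubs(net, counts = c(gene = 5, miRNA = 7, TF = 9))
  expect_equal(as.integer(table(hc$role[hc$hub])[c("gene", "miRNA", "TF")]),
               c(5L, 7L, 9L))
  # top-N picks the max-degree node first
  h1 <- findHubs(net, counts = c(gene = 1))
  gdeg <- h1[h1$role == "gene", ]
  expect_equal(gdeg$id[gdeg$hub], gdeg$id[which.max(gdeg$degree)])
})

test_that("network exports round-trip their content", {
  bundle <- generateBundle(smallConfig())
  net <- mergeFflsToNetwork(enumerateFfls(filteredEdges(bundle)),
                            bundle@catalog)
  p <- tempfile(fileext = ".tsv")
  writeNetworkEdgeList(net, p)
  back <- read.delim(p)
  expect_equal(nrow(back), nrow(edges(net)))
  gml <- tempfile(fileext = ".graphml")
  writeNetworkGraphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(nodes(net)))
  expect_equal(igraph::ecount(g), nrow(edges(net)))
})
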