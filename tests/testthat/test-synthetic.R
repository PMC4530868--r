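test_that("planted structure is recovered exactly with zero background", {
  cfg <- smallConfig(seed = 42L)
  bundle <- generateBundle(cfg)
  cat <- enumerateFfls(filteredEdges(bundle))
  tab <- table(factor(ffls(cat)$type, c("TF_FFL", "MIRNA_FFL", "COMPOSITE")))
  expect_equal(as.integer(tab), c(3L, 5L, 2L))
  # not just the counts: the exact planted triples come back
  expect_equal(fflKey(cat), fflKey(FflCatalog(bundle@groundTruth$plantedFfls)))
})

test_that("bundles are reproducible byte for byte under a fixed seed", {
  b1 <- generateBundle(smallConfig(seed = 42L))
  b2 <- generateBundle(smallConfig(seed = 42L))
  d1 <- tempfile(); d2 <- tempfile()
  writeBundle(b1, d1); writeBundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  b3 <- generateBundle(smallConfig(seed = 43L))
  expect_false(identical(b1@sourceRecords, b3@sourceRecords))
})

test_that("with background the planted FFLs survive and the oracle agrees", {
  cfg <- mediumConfig(seed = 19L, background = 0.01)
  bundle <- generateBundle(cfg)
  filt <- filteredEdges(bundle)
  cat <- enumerateFfls(filt)
  tab <- table(factor(ffls(cat)$type, c("TF_FFL", "MIRNA_FFL", "COMPOSITE")))
  expect_true(all(tab >= cfg@plantedFfls[names(tab)]))
  expect_equal(fflKey(cat), fflKey(bruteForceFfls(filt)))
  # every planted edge carries at least the filter support
  rec <- bundle@sourceRecords
  planted <- fflNet:::.ffl_constituent_edges(bundle@groundTruth$plantedFfls)
  key <- paste(rec$regulator_id, rec$target_id, rec$interaction_class)
  support <- vapply(split(rec$source_db, key),
                    function(s) length(unique(s)), integer(1))
  expect_true(all(support[paste(planted$regulator, planted$target,
                                planted$class)] >= 2L))
})

test_that("impossible configurations are rejected with the violated bound", {
  expect_error(
    synthConfig(nGenes = 5, nTfs = 2, nMirnas = 2, nDual = 0,
                plantedFfls = c(TF_FFL = 10, MIRNA_FFL = 0, COMPOSITE = 0)),
    "exceeds the 4 distinct")
  expect_error(
    synthConfig(nGenes = 5, nTfs = 2, nMirnas = 2, nDual = 3),
    "nDual")
  expect_error(
    synthConfig(backgroundDensity = c(MIRNA_GENE = 2, MIRNA_TF = 0,
                                      TF_GENE = 0, TF_MIRNA = 0)),
    "\\[0, 1\\]")
  expect_error(
    generateBundle(synthConfig(nGenes = 6, nTfs = 4, nMirnas = 3,
                               nDual = 0, supportDist = c(1),
                               plantedFfls = c(TF_FFL = 1, MIRNA_FFL = 0,
                                               COMPOSITE = 0))),
    "no mass")
})

test_that("ground-truth ids always exist in the catalogs", {
  bundle <- generateBundle(mediumConfig(seed = 23L))
  allIds <- c(miGenes(bundle@catalog), miMirnas(bundle@catalog),
              tfIds(bundle@catalog))
  gt <- bundle@groundTruth
  expect_true(all(unlist(lapply(gt$communities, `[[`, "nodes")) %in% allIds))
  expect_true(all(gt$coherentGenes %in% miGenes(bundle@catalog)))
  pf <- gt$plantedFfls
  expect_true(all(pf$tf %in% tfIds(bundle@catalog)))
  expect_true(all(pf$mirna %in% miMirnas(bundle@catalog)))
  expect_true(all(pf$gene %in% miGenes(bundle@catalog)))
})

test_that("written bundles are readable by the ingestion functions", {
  bundle <- generateBundle(smallConfig(seed = 8L))
  d <- tempfile()
  writeBundle(bundle, d)
  rec <- readSourceRecords(file.path(d, "source_records.tsv"))
  expect_equal(nrow(rec), nrow(bundle@sourceRecords))
  cat <- readNodeCatalog(file.path(d, "migenes.txt"),
                         file.path(d, "mimirnas.txt"),
                         file.path(d, "tfs.txt"))
  expect_equal(miGenes(cat), miGenes(bundle@catalog))
  hits <- readTfbsHits(file.path(d, "tfbs_hits.tsv"))
  expect_equal(nrow(hits), nrow(bundle@tfbs$hits))
  ann <- readPromoterAnnots(file.path(d, "promoter_annotations.tsv"))
  expect_equal(nrow(ann), nrow(bundle@tfbs$tss) + nrow(bundle@tfbs$premirna))
  dag <- readOboDag(file.path(d, "go.obo"))
  expect_setequal(dag@terms$id, bundle@goDag@terms$id)
  expect_equal(readGmt(file.path(d, "sets.gmt")), bundle@geneSets)
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"))
  expect_named(gt, c("plantedFfls", "communities", "coherentGenes",
                     "plantedSet", "tfbsTruth"), ignore.order = TRUE)
})
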