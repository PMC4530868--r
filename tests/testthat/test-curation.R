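test_that("support filtering keeps multi-database edges and counts sources", {
  rec <- data.frame(
    regulator_id = c("mir1", "mir1", "mir2", "mir3", "mir3", "mir3",
                     "mir3", "mir3"),
    target_id    = c("g1", "g1", "g2", "g3", "g3", "g3", "g3", "g3"),
    interaction_class = "MIRNA_GENE",
    source_db = c("tarbase", "targetscan", "mirdb",
                  "tarbase", "tarbase", "mirdb", "targetscan", "mirdb"),
    evidence = c("verified", "predicted", "predicted",
                 "verified", "verified", "predicted", "predicted",
                 "predicted"),
    stringsAsFactors = FALSE)
  ed <- edges(filterBySupport(rec, minSources = 2))
  # a verified+predicted two-database pair is retained with support 2
  expect_equal(ed$support[ed$regulator == "mir1"], 2L)
  expect_true(ed$anyVerified[ed$regulator == "mir1"])
  # one database only: dropped
  expect_false("mir2" %in% ed$regulator)
  # 5 records over 3 distinct databases: support is the distinct count
  expect_equal(ed$support[ed$regulator == "mir3"], 3L)

  # verified-pass mode rescues the single-source pair
  ed2 <- edges(filterBySupport(rec, minSources = 3, keepVerified = TRUE))
  expect_setequal(ed2$regulator, c("mir1", "mir3"))
})

test_that("support filter is idempotent and monotone in the threshold", {
  set.seed(11)
  rec <- data.frame(
    regulator_id = sample(paste0("mir", 1:6), 60, replace = TRUE),
    target_id = sample(paste0("g", 1:10), 60, replace = TRUE),
    interaction_class = sample(c("MIRNA_GENE", "MIRNA_TF"), 60,
                               replace = TRUE),
    source_db = sample(paste0("db", 1:4), 60, replace = TRUE),
    evidence = sample(c("verified", "predicted"), 60, replace = TRUE),
    stringsAsFactors = FALSE)
  rec <- rec[rec$regulator_id != rec$target_id, ]
  sizes <- integer(4)
  for (ms in 1:4) {
    e1 <- filterBySupport(rec, ms)
    sizes[ms] <- nEdges(e1)
    # re-filtering the already-filtered table changes nothing
    back <- edges(e1)
    rec2 <- data.frame(regulator_id = back$regulator,
                       target_id = back$target,
                       interaction_class = back$class,
                       source_db = rep("x", nrow(back)),
                       evidence = rep("predicted", nrow(back)))
    expect_equal(nEdges(filterBySupport(rec2, 1)), nEdges(e1))
  }
  expect_true(all(diff(sizes) <= 0))
})

test_that("unknown interaction classes are rejected with their position", {
  rec <- data.frame(regulator_id = c("a", "b"), target_id = c("x", "y"),
                    interaction_class = c("MIRNA_GENE", "BOGUS"),
                    source_db = "db", evidence = "predicted")
  expect_error(filterBySupport(rec), "BOGUS")
  tf <- tempfile(fileext = ".tsv")
  write.table(rec, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSourceRecords(tf), "line 3")
})

test_that("catalog restriction enforces per-class role membership", {
  catalog <- NodeCatalog(miGenes = c("g1", "dual"), miMirnas = "mir1",
                         tfs = c("tf1", "dual"))
  e <- et("mir1>g1:MIRNA_GENE", "mir1>gX:MIRNA_GENE",
          "mir1>dual:MIRNA_GENE", "mir1>dual:MIRNA_TF",
          "tf1>g1:TF_GENE", "tfX>g1:TF_GENE", "tf1>mir1:TF_MIRNA")
  r <- edges(restrictToCatalog(e, catalog))
  # out-of-catalog endpoints dropped
  expect_false("gX" %in% r$target)
  expect_false("tfX" %in% r$regulator)
  # a dual-role target attested in both classes appears in both
  expect_true(any(r$class == "MIRNA_GENE" & r$target == "dual"))
  expect_true(any(r$class == "MIRNA_TF" & r$target == "dual"))
  expect_equal(nrow(r), 5L)
})

test_that("edge summaries match a hand tally and handle empty tables", {
  s0 <- summarizeEdges(EdgeTable(data.frame(
    regulator = character(), target = character(), class = character())))
  expect_true(all(s0$classSummary$nPairs == 0))

  e <- et("mirA>g1:MIRNA_GENE", "mirA>g2:MIRNA_GENE",
          "mirB>g1:MIRNA_GENE", "mirA>tf1:MIRNA_TF")
  s <- summarizeEdges(e)
  cs <- s$classSummary
  expect_equal(cs$nPairs[cs$class == "MIRNA_GENE"], 3L)
  expect_equal(cs$nMirnas[cs$class == "MIRNA_GENE"], 2L)
  expect_equal(cs$nGenes[cs$class == "MIRNA_GENE"], 2L)
  expect_equal(cs$nTfs[cs$class == "MIRNA_TF"], 1L)
  nt <- s$nodeTallies
  expect_equal(nt$count[nt$node == "mirA" & nt$class == "MIRNA_GENE" &
                          nt$role == "regulator"], 2L)
})

test_that("edge tables deduplicate triples and reject self-edges", {
  e <- EdgeTable(c("a", "a"), c("b", "b"), c("TF_GENE", "TF_GENE"),
                 support = c(2L, 3L), anyVerified = c(FALSE, TRUE))
  expect_equal(nEdges(e), 1L)
  expect_equal(edges(e)$support, 3L)
  expect_true(edges(e)$anyVerified)
  expect_error(EdgeTable("a", "a", "TF_GENE"), "self-edges")
  rt <- tempfile(fileext = ".tsv")
  writeEdgeTable(e, rt)
  expect_equal(edges(readEdgeTable(rt)), edges(e))
})
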