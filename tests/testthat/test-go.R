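# A hand-sized DAG: root C with children A-branch and B-branch.
#   chain:  a2 -is_a-> a1 -is_a-> root;  b1 -is_a-> root
#   part_of: p1 -part_of-> a1
chainDag <- function() {
  GoDag(terms = data.frame(id = c("root", "a1", "a2", "b1", "p1"),
                           name = c("r", "a1", "a2", "b1", "p1"),
                           namespace = "BP"),
        edges = data.frame(child = c("a1", "a2", "b1", "p1"),
                           parent = c("root", "a1", "root", "a1"),
                           relation = c("is_a", "is_a", "is_a", "part_of")))
}

test_that("Wang term similarity matches hand-computed S-value tables", {
  dag <- chainDag()
  expect_equal(termSimilarity("a2", "a2", dag), 1)
  # S(a2) = {a2:1, a1:0.8, root:0.64}; S(a1) = {a1:1, root:0.8}
  # common {a1, root}: (0.8+1 + 0.64+0.8) / (2.44 + 1.8) = 3.24/4.24
  expect_equal(termSimilarity("a2", "a1", dag), 3.24 / 4.24,
               tolerance = 1e-6)
  # disjoint branches share only the root:
  # S(b1) = {b1:1, root:0.8}: (0.64+0.8)/(2.44+1.8) = 1.44/4.24
  expect_equal(termSimilarity("a2", "b1", dag), 1.44 / 4.24,
               tolerance = 1e-6)
  # part_of propagates with weight 0.6:
  # S(p1) = {p1:1, a1:0.6, root:0.48}
  expect_equal(termSimilarity("p1", "a1", dag),
               (0.6 + 1 + 0.48 + 0.8) / (2.08 + 1.8), tolerance = 1e-6)
  # cross-branch pairs score strictly below within-branch pairs
  expect_lt(termSimilarity("a2", "b1", dag),
            termSimilarity("a2", "a1", dag))
  expect_gt(termSimilarity("a2", "b1", dag), 0)
  # symmetry
  expect_equal(termSimilarity("a1", "b1", dag),
               termSimilarity("b1", "a1", dag))
  expect_error(termSimilarity("a1", "zz", dag), "unknown")
})

test_that("gene similarity aggregates by best-match average", {
  dag <- chainDag()
  ann <- data.frame(gene = c("gA", "gB", "gB", "gC"),
                    term = c("a2", "a2", "b1", "a2"))
  expect_equal(geneSimilarity("gA", "gC", ann, dag), 1)
  # gA={a2}, gB={a2,b1}: (rowmax 1) + (colmax 1, sim(a2,b1)) over 3
  s <- termSimilarity("a2", "b1", dag)
  expect_equal(geneSimilarity("gA", "gB", ann, dag), (2 + s) / 3,
               tolerance = 1e-9)
  expect_equal(geneSimilarity("gA", "gB", ann, dag),
               geneSimilarity("gB", "gA", ann, dag))
  # unannotated genes yield the missing-value sentinel
  expect_true(is.na(geneSimilarity("gA", "gX", ann, dag)))
})

test_that("ontology files round-trip through the OBO dialect", {
  bundle <- generateBundle(smallConfig())
  p <- tempfile(fileext = ".obo")
  writeOboDag(bundle@goDag, p)
  back <- readOboDag(p)
  expect_setequal(back@terms$id, bundle@goDag@terms$id)
  expect_equal(termNamespaces(back), termNamespaces(bundle@goDag))
  ek <- function(d) sort(paste(d@edges$child, d@edges$parent,
                               d@edges$relation))
  expect_equal(ek(back), ek(bundle@goDag))
  # cycles are rejected
  expect_error(GoDag(data.frame(id = c("x", "y"), name = "n",
                                namespace = "BP"),
                     data.frame(child = c("x", "y"), parent = c("y", "x"),
                                relation = "is_a")),
               "cycle")
})

test_that("coherent module genes score higher than random draws", {
  bundle <- generateBundle(smallConfig(seed = 5L))
  coherent <- bundle@groundTruth$coherentGenes
  pool <- unique(bundle@annotations$gene)
  res <- moduleGoRandomization(coherent, pool, bundle@annotations,
                               bundle@goDag, namespaces = "BP",
                               nIter = 200, seed = 11)
  expect_lt(res$BP$pValue, 0.01)
  expect_true(all(res$BP$moduleScores >= 0 & res$BP$moduleScores <= 1))
  # two genes with identical annotations: module vector is exactly {1}
  ann <- data.frame(gene = c("x", "y"), term = bundle@annotations$term[1])
  ann2 <- rbind(ann, bundle@annotations[bundle@annotations$gene %in% pool, ])
  res2 <- moduleGoRandomization(c("x", "y"), c("x", "y", pool), ann2,
                                bundle@goDag, namespaces = "BP",
                                nIter = 50, seed = 2)
  expect_equal(res2$BP$moduleScores, 1)
  expect_error(moduleGoRandomization("x", c("x", pool), ann2,
                                     bundle@goDag, namespaces = "BP"),
               "fewer than 2")
})

test_that("random modules are not called coherent", {
  bundle <- generateBundle(smallConfig(seed = 9L))
  pool <- unique(bundle@annotations$gene)
  ps <- vapply(1:8, function(i) {
    set.seed(200 + i)
    mod <- sample(pool, 5)
    moduleGoRandomization(mod, pool, bundle@annotations, bundle@goDag,
                          namespaces = "BP", nIter = 100,
                          seed = i)$BP$pValue
  }, numeric(1))
  expect_gt(mean(ps > 0.01), 0.6)
})
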