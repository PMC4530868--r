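tssAt <- function(pos, gene = "gA") {
  data.frame(feature_id = gene, feature_kind = "gene_tss", chrom = "chr1",
             start = pos, end = pos + 1L, strand = "+", mature_ids = "",
             stringsAsFactors = FALSE)
}
hitAt <- function(s, e, z = 3, tf = "tfA", chrom = "chr1") {
  data.frame(tf_id = tf, chrom = chrom, start = s, end = e, strand = "+",
             z_score = z, stringsAsFactors = FALSE)
}

test_that("Z cutoff is strict: just above maps, exactly 2.33 does not", {
  ann <- tssAt(5000L)
  expect_equal(nEdges(mapTfbsToGenePromoters(hitAt(5010, 5030, 2.34), ann)),
               1L)
  expect_equal(nEdges(mapTfbsToGenePromoters(hitAt(5010, 5030, 2.33), ann)),
               0L)
  expect_equal(nEdges(mapTfbsToGenePromoters(hitAt(5010, 5030, 2.0), ann)),
               0L)
})

test_that("promoter windows are half-open and match a brute-force overlap oracle", {
  tss <- 5000L
  ann <- tssAt(tss)
  # [TSS-1200, TSS-1001) misses; [TSS-1200, TSS-999) overlaps
  expect_equal(nEdges(mapTfbsToGenePromoters(hitAt(tss - 1200, tss - 1001),
                                             ann)), 0L)
  expect_equal(nEdges(mapTfbsToGenePromoters(hitAt(tss - 1200, tss - 999),
                                             ann)), 1L)
  # sweep hit positions across the window edge; compare with the oracle
  winStart <- tss - 1000L; winEnd <- tss + 1000L
  for (s in seq(tss - 1030, tss - 980, by = 7)) {
    got <- nEdges(mapTfbsToGenePromoters(hitAt(s, s + 20), ann)) == 1L
    expect_identical(got, overlapOracle(s, s + 20, winStart, winEnd),
                     info = paste("hit start", s))
  }
  # different chromosome never maps
  expect_equal(nEdges(mapTfbsToGenePromoters(
    hitAt(tss, tss + 20, chrom = "chr2"), ann)), 0L)
})

test_that("gene mapping is strand-independent and clips negative windows", {
  annMinus <- tssAt(5000L); annMinus$strand <- "-"
  expect_equal(nEdges(mapTfbsToGenePromoters(hitAt(5010, 5030), annMinus)),
               1L)
  # TSS close to the origin: window start clipped to 0, no error
  annNear <- tssAt(300L)
  expect_equal(nEdges(mapTfbsToGenePromoters(hitAt(5, 20), annNear)), 1L)
  expect_error(mapTfbsToGenePromoters(hitAt(50, 50), annNear), "interval")
})

preAt <- function(s, e, strand, mature, id = "preA") {
  data.frame(feature_id = id, feature_kind = "pre_mirna", chrom = "chr1",
             start = s, end = e, strand = strand, mature_ids = mature,
             stringsAsFactors = FALSE)
}

test_that("pre-miRNA windows reflect under strand flip and fan out to mature ids", {
  plus <- preAt(5000L, 5100L, "+", "mirX-5p")
  minus <- preAt(5000L, 5100L, "-", "mirX-5p")
  # + strand: upstream is [3000, 5000)
  expect_equal(nEdges(mapTfbsToMirnaPromoters(hitAt(3500, 3600), plus)), 1L)
  expect_equal(nEdges(mapTfbsToMirnaPromoters(hitAt(6500, 6600), plus)), 0L)
  # - strand: upstream in reference coordinates is [5100, 7100)
  expect_equal(nEdges(mapTfbsToMirnaPromoters(hitAt(6500, 6600), minus)), 1L)
  expect_equal(nEdges(mapTfbsToMirnaPromoters(hitAt(3500, 3600), minus)), 0L)
  # mirrored coordinates give identical edge sets under the flip
  L <- 10100L
  mirrored <- preAt(L - 5100L, L - 5000L, "-", "mirX-5p")
  hPlus <- hitAt(3500, 3600)
  hMirr <- hitAt(L - 3600, L - 3500)
  expect_equal(edges(mapTfbsToMirnaPromoters(hPlus, plus)),
               edges(mapTfbsToMirnaPromoters(hMirr, mirrored)))

  two <- preAt(5000L, 5100L, "+", "mirX-5p,mirX-3p")
  ed <- edges(mapTfbsToMirnaPromoters(hitAt(3500, 3600), two))
  expect_setequal(ed$target, c("mirX-5p", "mirX-3p"))
  expect_true(all(ed$class == "TF_MIRNA"))

  none <- preAt(5000L, 5100L, "+", "")
  expect_warning(res <- mapTfbsToMirnaPromoters(hitAt(3500, 3600), none),
                 "mature")
  expect_equal(nEdges(res), 0L)
})

test_that("the generated TFBS fixture reproduces its own truth labels", {
  fx <- generateTfbsFixture(smallConfig())
  gene <- edges(mapTfbsToGenePromoters(fx$hits, fx$tss))
  mir <- edges(mapTfbsToMirnaPromoters(fx$hits, fx$premirna))
  matMap <- strsplit(fx$premirna$mature_ids, ",")
  names(matMap) <- fx$premirna$feature_id
  for (i in seq_len(nrow(fx$truth))) {
    tr <- fx$truth[i, ]
    if (tr$feature_id %in% fx$tss$feature_id) {
      got <- any(gene$regulator == tr$tf_id & gene$target == tr$feature_id)
    } else {
      got <- all(matMap[[tr$feature_id]] %in%
                   mir$target[mir$regulator == tr$tf_id])
    }
    expect_identical(got, tr$should_map, info = tr$reason)
  }
})
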