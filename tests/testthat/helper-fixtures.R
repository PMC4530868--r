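# Small seeded configurations used across the suite.

smallConfig <- function(seed = 42L, background = 0,
                        planted = c(TF_FFL = 3L, MIRNA_FFL = 5L,
                                    COMPOSITE = 2L)) {
  synthConfig(nGenes = 40L, nTfs = 12L, nMirnas = 8L, nDual = 2L,
              plantedFfls = planted, backgroundDensity = background,
              plantedCommunities = list(c(k = 4, n = 2), c(k = 4, n = 1)),
              goDepth = 2L, seed = seed)
}

mediumConfig <- function(seed = 1L, background = 0.01) {
  synthConfig(nGenes = 120L, nTfs = 30L, nMirnas = 15L, nDual = 4L,
              plantedFfls = c(TF_FFL = 6L, MIRNA_FFL = 10L,
                              COMPOSITE = 4L),
              backgroundDensity = background,
              plantedCommunities = list(c(k = 5, n = 3)),
              goDepth = 2L, seed = seed)
}

# Edge table from terse triple strings "reg>tgt:CLASS"
et <- function(...) {
  triples <- strsplit(c(...), "[>:]")
  EdgeTable(vapply(triples, `[`, "", 1), vapply(triples, `[`, "", 2),
            vapply(triples, `[`, "", 3))
}

fflKey <- function(cat) {
  ff <- ffls(cat)
  sort(paste(ff$tf, ff$mirna, ff$gene, ff$type))
}

filteredEdges <- function(bundle, minSources = 2L) {
  restrictToCatalog(filterBySupport(bundle@sourceRecords, minSources),
                    bundle@catalog)
}
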