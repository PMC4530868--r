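#' @rdname pValue
#' @export
setMethod("pValue", "PermutationResult", function(x) x@pValue)

#' @rdname nullCounts
#' @export
setMethod("nullCounts", "PermutationResult", function(x) x@nullCounts)

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult: observed =", object@observed,
      "| null mean =", round(mean(object@nullCounts), 2),
      "| p =", object@pValue, "(", object@nIter, "iterations )\n")
})

.perm_result <- function(observed, null, seed) {
  new("PermutationResult", observed = as.numeric(observed),
      nullCounts = as.numeric(null),
      pValue = mean(null >= observed),
      nIter = length(null), seed = as.integer(seed))
}

## Count FFLs per type given fixed TF-side structure and a miRNA->gene
## target list; the fast inner kernel of the permutation test.
.count_ffls_by_type <- function(tgList, pairs, mgList) {
  counts <- c(TF_FFL = 0L, MIRNA_FFL = 0L, COMPOSITE = 0L)
  for (i in seq_len(nrow(pairs))) {
    tf <- pairs$tf[i]
    co <- intersect(tgList[[tf]], mgList[[pairs$mirna[i]]])
    n <- length(co) - sum(co == tf | co == pairs$mirna[i])
    if (n > 0L)
      counts[[pairs$type[i]]] <- counts[[pairs$type[i]]] + n
  }
  counts
}

## (tf, mirna, type) anchor pairs implied by the fixed edge classes.
.anchor_pairs <- function(edgeDf) {
  tm <- edgeDf[edgeDf$class == "TF_MIRNA", c("regulator", "target")]
  mt <- edgeDf[edgeDf$class == "MIRNA_TF", c("regulator", "target")]
  tmKey <- paste(tm$regulator, tm$target, sep = "\r")
  mtKey <- paste(mt$target, mt$regulator, sep = "\r")
  allKey <- unique(c(tmKey, mtKey))
  if (!length(allKey))
    return(data.frame(tf = character(), mirna = character(),
                      type = character(), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(allKey, "\r", fixed = TRUE))
  type <- ifelse(allKey %in% tmKey & allKey %in% mtKey, "COMPOSITE",
                 ifelse(allKey %in% tmKey, "TF_FFL", "MIRNA_FFL"))
  data.frame(tf = parts[, 1], mirna = parts[, 2], type = type,
             stringsAsFactors = FALSE)
}

#' Permutation test of FFL-count enrichment
#'
#' Tests whether the observed number of FFLs per type exceeds what random
#' miRNA-target assignment would give. Each iteration draws, uniformly
#' without replacement from \code{universePairs} (all miRNA-target pairs
#' of the focal miRNAs), the same number of pairs as the observed
#' miRNA->gene class, substitutes them for that class while holding the
#' TF-side classes fixed, and re-counts FFLs per type. The empirical p
#' per type is the proportion of null counts greater than or equal to
#' the observed count (no smoothing; p = 0 is representable).
#'
#' @param universePairs data.frame with columns \code{mirna},
#'   \code{gene}: the sampling universe, a superset of the observed
#'   miRNA->gene pairs.
#' @param observedEdges EdgeTable holding the observed four classes.
#' @param nIter iterations (default 10000).
#' @param seed master seed; per-iteration substream seeds are derived
#'   from it so results do not depend on evaluation order.
#' @return named list of \linkS4class{PermutationResult}, one per FFL
#'   type.
#' @export
fflPermutationTest <- function(universePairs, observedEdges,
                               nIter = 10000L, seed = 1L) {
  ed <- edges(observedEdges)
  mgObs <- ed[ed$class == "MIRNA_GENE", , drop = FALSE]
  m <- nrow(mgObs)
  uni <- unique(data.frame(mirna = as.character(universePairs$mirna),
                           gene = as.character(universePairs$gene),
                           stringsAsFactors = FALSE))
  if (m > nrow(uni))
    stop("observed miRNA-gene pairs (", m,
         ") exceed the sampling universe (", nrow(uni), ")")
  obsKey <- paste(mgObs$regulator, mgObs$target, sep = "\r")
  uniKey <- paste(uni$mirna, uni$gene, sep = "\r")
  if (!all(obsKey %in% uniKey))
    stop("universePairs must contain every observed miRNA-gene pair")

  fixed <- ed[ed$class != "MIRNA_GENE", , drop = FALSE]
  tgList <- split(fixed$target[fixed$class == "TF_GENE"],
                  fixed$regulator[fixed$class == "TF_GENE"])
  pairs <- .anchor_pairs(fixed)
  obsCounts <- .count_ffls_by_type(
    tgList, pairs, split(mgObs$target, mgObs$regulator))

  nullMat <- matrix(0L, nrow = nIter, ncol = 3,
                    dimnames = list(NULL, .FFL_TYPES))
  set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max, nIter)
  for (it in seq_len(nIter)) {
    set.seed(subSeeds[it])
    idx <- sample.int(nrow(uni), m)
    mgList <- split(uni$gene[idx], uni$mirna[idx])
    nullMat[it, ] <- .count_ffls_by_type(tgList, pairs, mgList)
  }
  out <- lapply(.FFL_TYPES, function(ty)
    .perm_result(obsCounts[[ty]], nullMat[, ty], seed))
  names(out) <- .FFL_TYPES
  out
}

#' Per-miRNA target-count enrichment against random gene sets
#'
#' For each miRNA, compares the number of its targets inside the focal
#' gene set (e.g. the disease genes) with the counts obtained in random
#' same-size gene sets drawn without replacement from the gene universe.
#' A one-sample t-test compares the null count sample against the
#' observed value (default alternative: null mean below the observed
#' count). A pooled test over the summed counts across miRNAs is
#' reported alongside the per-miRNA results.
#'
#' @param targetsByMirna named list mapping each miRNA to its full
#'   target gene set.
#' @param focalGenes the focal gene set.
#' @param geneUniverse the universe random sets are drawn from.
#' @param nIter iterations (default 10000).
#' @param seed master seed.
#' @param alternative "greater" (observed above the null, the default)
#'   or "two.sided".
#' @return list with elements \code{perMirna} (data.frame: mirna,
#'   observed, nullMean, nullSd, statistic, pValue, pEmpirical),
#'   \code{pooled} (same fields for the summed counts),
#'   \code{nullCounts} (nIter x n-miRNA matrix), \code{nIter},
#'   \code{seed}. \code{pValue} is the one-sample t-test against the
#'   observed count; \code{pEmpirical} is the calibrated
#'   proportion-of-null-at-least-observed p. Zero-variance null samples
#'   yield a t-test p of 1 with a warning.
#' @export
mirnaTargetPermutation <- function(targetsByMirna, focalGenes, geneUniverse,
                                   nIter = 10000L, seed = 1L,
                                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  focalGenes <- unique(as.character(focalGenes))
  geneUniverse <- unique(as.character(geneUniverse))
  if (!all(focalGenes %in% geneUniverse))
    stop("focalGenes must be a subset of geneUniverse")
  if (length(focalGenes) > length(geneUniverse))
    stop("focal set larger than universe")
  mirs <- names(targetsByMirna)
  tgtIdx <- lapply(targetsByMirna, function(t)
    which(geneUniverse %in% as.character(t)))
  observed <- vapply(targetsByMirna, function(t)
    sum(unique(as.character(t)) %in% focalGenes), integer(1))

  nullMat <- matrix(0L, nrow = nIter, ncol = length(mirs),
                    dimnames = list(NULL, mirs))
  inDraw <- logical(length(geneUniverse))
  set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max, nIter)
  for (it in seq_len(nIter)) {
    set.seed(subSeeds[it])
    draw <- sample.int(length(geneUniverse), length(focalGenes))
    inDraw[] <- FALSE; inDraw[draw] <- TRUE
    nullMat[it, ] <- vapply(tgtIdx, function(ix) sum(inDraw[ix]), integer(1))
  }

  tAlt <- if (alternative == "greater") "less" else "two.sided"
  nDegenerate <- 0L
  testOne <- function(null, obs) {
    if (stats::sd(null) == 0) {
      nDegenerate <<- nDegenerate + 1L
      return(c(statistic = NA_real_, pValue = 1))
    }
    tt <- stats::t.test(null, mu = obs, alternative = tAlt)
    c(statistic = unname(tt$statistic), pValue = tt$p.value)
  }
  per <- t(vapply(seq_along(mirs), function(j)
    testOne(nullMat[, j], observed[j]), c(statistic = 0, pValue = 0)))
  perMirna <- data.frame(mirna = mirs, observed = as.numeric(observed),
                         nullMean = colMeans(nullMat),
                         nullSd = apply(nullMat, 2, stats::sd),
                         statistic = per[, "statistic"],
                         pValue = per[, "pValue"],
                         pEmpirical = vapply(seq_along(mirs), function(j)
                           mean(nullMat[, j] >= observed[j]), numeric(1)),
                         stringsAsFactors = FALSE, row.names = NULL)
  pooledNull <- rowSums(nullMat)
  pp <- testOne(pooledNull, sum(observed))
  if (nDegenerate)
    warning(nDegenerate, " zero-variance null sample(s); t-test p ",
            "reported as 1 for those")
  pooled <- data.frame(observed = sum(observed),
                       nullMean = mean(pooledNull),
                       nullSd = stats::sd(pooledNull),
                       statistic = pp["statistic"], pValue = pp["pValue"],
                       pEmpirical = mean(pooledNull >= sum(observed)),
                       row.names = NULL)
  list(perMirna = perMirna, pooled = pooled, nullCounts = nullMat,
       nIter = as.integer(nIter), seed = as.integer(seed),
       alternative = alternative)
}
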