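## Coordinates are 0-based half-open (BED convention) at the interface;
## they are converted to 1-based closed IRanges internally.

.bed_to_granges <- function(chrom, start, end) {
  if (any(start >= end))
    stop("malformed interval: start must be < end (0-based half-open)")
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = start + 1L,
                                                   end = end))
}

#' Read a BED6-like TFBS hit table
#'
#' Tab-separated columns chrom, start, end, tf_id, z_score, strand
#' (either with this header or headerless in BED column order).
#'
#' @param path file path.
#' @return data.frame with columns tf_id, chrom, start, end, strand,
#'   z_score.
#' @export
readTfbsHits <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("chrom", first, fixed = TRUE)
  df <- utils::read.delim(path, header = hasHeader,
                          stringsAsFactors = FALSE)
  if (!hasHeader)
    names(df) <- c("chrom", "start", "end", "tf_id", "z_score", "strand")
  data.frame(tf_id = df$tf_id, chrom = df$chrom,
             start = as.integer(df$start), end = as.integer(df$end),
             strand = df$strand, z_score = as.numeric(df$z_score),
             stringsAsFactors = FALSE)
}

#' Read promoter annotations
#'
#' TSV with columns feature_id, feature_kind (gene_tss or pre_mirna),
#' chrom, start, end, strand, mature_ids (comma-separated; pre_mirna
#' only). For gene_tss rows the TSS is the \code{start} coordinate.
#'
#' @param path file path.
#' @return data.frame of annotations.
#' @export
readPromoterAnnots <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "feature_kind", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation file missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$mature_ids)) df$mature_ids <- ""
  df
}

.tfbs_edges <- function(hits, windows, featureIds, zMin, class) {
  ok <- is.finite(hits$z_score) & hits$z_score > zMin   # strict: > zMin
  hits <- hits[ok, , drop = FALSE]
  if (!nrow(hits) || !length(windows))
    return(EdgeTable(.empty_edges()))
  hg <- .bed_to_granges(hits$chrom, hits$start, hits$end)
  ## hits and annotations need not share a chromosome universe
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(hg, windows, ignore.strand = TRUE))
  if (!length(ov)) return(EdgeTable(.empty_edges()))
  df <- data.frame(regulator = hits$tf_id[S4Vectors::queryHits(ov)],
                   target = featureIds[S4Vectors::subjectHits(ov)],
                   class = class, stringsAsFactors = FALSE)
  df <- df[df$regulator != df$target, , drop = FALSE]
  EdgeTable(df)
}

#' Map TFBS hits to gene promoter windows
#'
#' A TF-gene edge is emitted when a binding-site interval shares at least
#' one base with the half-open promoter window
#' \code{[TSS - flank, TSS + flank)} on the same chromosome and its Z
#' score is strictly larger than \code{zMin}. Gene-promoter mapping is
#' strand-independent; negative window starts are clipped to 0. Multiple
#' qualifying hits for one (TF, gene) pair collapse to a single edge.
#'
#' @param hits TFBS hit data.frame (see \code{\link{readTfbsHits}}).
#' @param annots annotation data.frame restricted to
#'   \code{feature_kind == "gene_tss"}.
#' @param zMin Z-score cutoff, exceeded strictly (default 2.33).
#' @param flank promoter half-width in bases (default 1000).
#' @return an EdgeTable of TF_GENE edges.
#' @export
mapTfbsToGenePromoters <- function(hits, annots, zMin = 2.33, flank = 1000L) {
  annots <- annots[annots$feature_kind == "gene_tss", , drop = FALSE]
  if (!nrow(annots)) return(EdgeTable(.empty_edges()))
  tss <- as.integer(annots$start)
  ws <- pmax(0L, tss - as.integer(flank))
  we <- tss + as.integer(flank)
  win <- .bed_to_granges(annots$chrom, ws, we)
  .tfbs_edges(hits, win, annots$feature_id, zMin, "TF_GENE")
}

#' Map TFBS hits to pre-miRNA promoter windows
#'
#' The putative promoter is the \code{upstream} bases 5' of the
#' precursor: for a + strand precursor at \code{[start, end)} the window
#' is \code{[start - upstream, start)}; for a - strand precursor it is
#' \code{[end, end + upstream)} in reference coordinates. A mapped
#' precursor fans out to one TF-miRNA edge per mature id; precursors
#' with no mature ids are skipped with a warning. The Z rule is the same
#' strict cutoff as for genes.
#'
#' @param hits TFBS hit data.frame.
#' @param annots annotation data.frame restricted to
#'   \code{feature_kind == "pre_mirna"}; \code{mature_ids} is a
#'   comma-separated list.
#' @param zMin Z-score cutoff (default 2.33, strict).
#' @param upstream promoter length in bases (default 2000).
#' @return an EdgeTable of TF_MIRNA edges (targets are mature ids).
#' @export
mapTfbsToMirnaPromoters <- function(hits, annots, zMin = 2.33,
                                    upstream = 2000L) {
  annots <- annots[annots$feature_kind == "pre_mirna", , drop = FALSE]
  if (!nrow(annots)) return(EdgeTable(.empty_edges()))
  mats <- strsplit(as.character(annots$mature_ids), ",", fixed = TRUE)
  mats <- lapply(mats, function(m) m[nzchar(trimws(m))])
  empty <- lengths(mats) == 0L
  if (any(empty)) {
    warning(sum(empty), " precursor(s) with no mature ids skipped: ",
            paste(utils::head(annots$feature_id[empty], 3), collapse = ", "))
    annots <- annots[!empty, , drop = FALSE]
    mats <- mats[!empty]
    if (!nrow(annots)) return(EdgeTable(.empty_edges()))
  }
  plus <- annots$strand == "+"
  s <- as.integer(annots$start); e <- as.integer(annots$end)
  up <- as.integer(upstream)
  ws <- ifelse(plus, pmax(0L, s - up), e)
  we <- ifelse(plus, s, e + up)
  ok <- ws < we
  win <- .bed_to_granges(annots$chrom[ok], ws[ok], we[ok])
  pre <- .tfbs_edges(hits, win, annots$feature_id[ok], zMin, "TF_MIRNA")
  ed <- edges(pre)
  if (!nrow(ed)) return(pre)
  matMap <- stats::setNames(mats[ok], annots$feature_id[ok])
  fan <- do.call(rbind, lapply(seq_len(nrow(ed)), function(i) {
    data.frame(regulator = ed$regulator[i],
               target = matMap[[ed$target[i]]],
               class = "TF_MIRNA", stringsAsFactors = FALSE)
  }))
  fan <- fan[fan$regulator != fan$target, , drop = FALSE]
  EdgeTable(fan)
}
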