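#' Construct an FflCatalog
#'
#' @param ffls data.frame with columns tf, mirna, gene, type.
#' @return an FflCatalog (rows sorted by type, tf, mirna, gene).
#' @export
FflCatalog <- function(ffls) {
  if (nrow(ffls)) {
    ffls <- ffls[order(ffls$type, ffls$tf, ffls$mirna, ffls$gene), ,
                 drop = FALSE]
    rownames(ffls) <- NULL
  }
  new("FflCatalog", ffls = ffls)
}

.empty_ffls <- function() {
  data.frame(tf = character(), mirna = character(), gene = character(),
             type = character(), stringsAsFactors = FALSE)
}

#' @rdname ffls
#' @export
setMethod("ffls", "FflCatalog", function(x) x@ffls)

#' @describeIn FflCatalog number of FFLs
#' @param x an FflCatalog.
#' @export
nFfls <- function(x) nrow(x@ffls)

setMethod("show", "FflCatalog", function(object) {
  ff <- object@ffls
  cat("FflCatalog with", nrow(ff), "feed-forward loops\n")
  if (nrow(ff)) {
    tab <- table(factor(ff$type, levels = .FFL_TYPES))
    cat(" ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

## Split edge table into the four lookup structures used by enumeration.
.edge_lookup <- function(edgeDf) {
  sp <- function(cls, by) {
    e <- edgeDf[edgeDf$class == cls, , drop = FALSE]
    split(if (by == "regulator") e$target else e$regulator,
          if (by == "regulator") e$regulator else e$target)
  }
  list(tg = sp("TF_GENE", "regulator"),      # tf -> genes
       mg = sp("MIRNA_GENE", "regulator"),   # mirna -> genes
       tm = edgeDf[edgeDf$class == "TF_MIRNA", c("regulator", "target")],
       mt = edgeDf[edgeDf$class == "MIRNA_TF", c("regulator", "target")])
}

#' Enumerate all feed-forward loops
#'
#' For every (TF, miRNA) pair linked by TF->miRNA and/or miRNA->TF, each
#' gene targeted by both the TF (TF->gene) and the miRNA (miRNA->gene)
#' yields one FFL. Typing is exclusive: both regulator-regulator
#' directions present gives a composite FFL; only TF->miRNA a TF-FFL;
#' only miRNA->TF a miRNA-FFL. A triple whose gene slot equals the TF id
#' (a dual-role self-regulation) is excluded: a two-node loop is not a
#' three-node FFL.
#'
#' @param x an EdgeTable restricted to the analysis catalogs.
#' @return an FflCatalog.
#' @examples
#' et <- EdgeTable(c("T", "T", "m"), c("m", "g", "g"),
#'                 c("TF_MIRNA", "TF_GENE", "MIRNA_GENE"))
#' ffls(enumerateFfls(et))
#' @export
enumerateFfls <- function(x) {
  lk <- .edge_lookup(edges(x))
  tmKey <- paste(lk$tm$regulator, lk$tm$target, sep = "\r")
  mtKey <- paste(lk$mt$target, lk$mt$regulator, sep = "\r")  # as (tf, mirna)
  allKey <- unique(c(tmKey, mtKey))
  if (!length(allKey)) return(FflCatalog(.empty_ffls()))
  hasTm <- allKey %in% tmKey
  hasMt <- allKey %in% mtKey
  parts <- strsplit(allKey, "\r", fixed = TRUE)
  out <- vector("list", length(allKey))
  for (i in seq_along(allKey)) {
    tf <- parts[[i]][1]; m <- parts[[i]][2]
    g <- intersect(lk$tg[[tf]], lk$mg[[m]])
    g <- g[g != tf & g != m]
    if (!length(g)) next
    type <- if (hasTm[i] && hasMt[i]) "COMPOSITE"
            else if (hasTm[i]) "TF_FFL" else "MIRNA_FFL"
    out[[i]] <- data.frame(tf = tf, mirna = m, gene = g, type = type,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(FflCatalog(.empty_ffls()))
  FflCatalog(do.call(rbind, out))
}

#' Brute-force FFL oracle
#'
#' Independent reference implementation that sweeps every
#' (TF, miRNA, gene) triple of the edge table's node universe through
#' dense incidence matrices and applies the same exclusive typing rule.
#' Intended for small instances (up to a few hundred nodes); its output
#' is set-equal to \code{\link{enumerateFfls}}.
#'
#' @param x an EdgeTable.
#' @return an FflCatalog.
#' @export
bruteForceFfls <- function(x) {
  ed <- edges(x)
  tfs <- unique(c(ed$regulator[ed$class %in% c("TF_GENE", "TF_MIRNA")],
                  ed$target[ed$class == "MIRNA_TF"]))
  mirs <- unique(c(ed$regulator[ed$class %in% c("MIRNA_GENE", "MIRNA_TF")],
                   ed$target[ed$class == "TF_MIRNA"]))
  genes <- unique(ed$target[ed$class %in% c("TF_GENE", "MIRNA_GENE")])
  if (!length(tfs) || !length(mirs) || !length(genes))
    return(FflCatalog(.empty_ffls()))
  inc <- function(cls, rows, cols) {
    m <- matrix(FALSE, length(rows), length(cols),
                dimnames = list(rows, cols))
    e <- ed[ed$class == cls & ed$regulator %in% rows &
              ed$target %in% cols, , drop = FALSE]
    m[cbind(e$regulator, e$target)] <- TRUE
    m
  }
  TG <- inc("TF_GENE", tfs, genes)
  MG <- inc("MIRNA_GENE", mirs, genes)
  TM <- inc("TF_MIRNA", tfs, mirs)
  MT <- inc("MIRNA_TF", mirs, tfs)
  out <- list()
  for (tf in tfs) for (m in mirs) {
    a <- TM[tf, m]; b <- MT[m, tf]
    if (!a && !b) next
    co <- genes[TG[tf, ] & MG[m, ]]
    co <- co[co != tf & co != m]
    if (!length(co)) next
    type <- if (a && b) "COMPOSITE" else if (a) "TF_FFL" else "MIRNA_FFL"
    out[[length(out) + 1L]] <-
      data.frame(tf = tf, mirna = m, gene = co, type = type,
                 stringsAsFactors = FALSE)
  }
  if (!length(out)) return(FflCatalog(.empty_ffls()))
  FflCatalog(do.call(rbind, out))
}

## Constituent directed edges of each FFL row, one data.frame for all.
.ffl_constituent_edges <- function(ff) {
  if (!nrow(ff)) {
    return(data.frame(regulator = character(), target = character(),
                      class = character(), stringsAsFactors = FALSE))
  }
  piece <- function(reg, tgt, cls)
    data.frame(regulator = reg, target = tgt,
               class = rep(cls, length(reg)), stringsAsFactors = FALSE)
  hasTm <- ff$type %in% c("TF_FFL", "COMPOSITE")
  hasMt <- ff$type %in% c("MIRNA_FFL", "COMPOSITE")
  rbind(piece(ff$tf, ff$gene, "TF_GENE"),
        piece(ff$mirna, ff$gene, "MIRNA_GENE"),
        piece(ff$tf[hasTm], ff$mirna[hasTm], "TF_MIRNA"),
        piece(ff$mirna[hasMt], ff$tf[hasMt], "MIRNA_TF"))
}

#' Tabulate an FFL catalog per type
#'
#' Per-type FFL counts, distinct node counts per slot, and distinct
#' constituent links per interaction class (a link shared by several
#' FFLs of one type counts once within that type). The Total row holds
#' the unions across types: its node total is the sum of the three
#' slot-wise union sizes (so a dual-role id occupying both a gene and a
#' TF slot contributes to both).
#'
#' @param x an FflCatalog.
#' @return data.frame with one row per FFL type plus a Total row.
#' @export
tabulateCatalog <- function(x) {
  ff <- ffls(x)
  rowFor <- function(sub, label) {
    ce <- .ffl_constituent_edges(sub)
    ce <- ce[!duplicated(paste(ce$regulator, ce$target, ce$class, sep = "\r")), ]
    lk <- function(cls) sum(ce$class == cls)
    data.frame(type = label, nFfls = nrow(sub),
               nGenes = length(unique(sub$gene)),
               nMirnas = length(unique(sub$mirna)),
               nTfs = length(unique(sub$tf)),
               nNodes = length(unique(sub$gene)) +
                 length(unique(sub$mirna)) + length(unique(sub$tf)),
               linksMirnaGene = lk("MIRNA_GENE"),
               linksMirnaTf = lk("MIRNA_TF"),
               linksTfGene = lk("TF_GENE"),
               linksTfMirna = lk("TF_MIRNA"),
               linksTotal = nrow(ce), stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, lapply(.FFL_TYPES, function(ty)
    rowFor(ff[ff$type == ty, , drop = FALSE], ty)))
  rbind(rows, rowFor(ff, "Total"))
}

#' Write / read an FFL catalog TSV
#'
#' Columns tf_id, mirna_id, gene_id, ffl_type, mirroring the structure
#' of a published FFL supplementary table.
#'
#' @param x an FflCatalog.
#' @param path TSV path.
#' @return \code{readFflCatalog} returns an FflCatalog.
#' @export
writeFflCatalog <- function(x, path) {
  ff <- ffls(x)
  utils::write.table(
    data.frame(tf_id = ff$tf, mirna_id = ff$mirna, gene_id = ff$gene,
               ffl_type = ff$type),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFflCatalog
#' @export
readFflCatalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  FflCatalog(data.frame(tf = df$tf_id, mirna = df$mirna_id,
                        gene = df$gene_id, type = df$ffl_type,
                        stringsAsFactors = FALSE))
}
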