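#' Gene model set
#'
#' In-memory representation of a gene annotation: loci with biotypes, their
#' transcripts, and per-transcript exon and CDS segments. All coordinates are
#' 1-based inclusive (GFF3 convention).
#'
#' @param loci data.frame with columns `locus_id`, `chrom`, `start`, `end`,
#'   `strand` ("+"/"-"), `biotype` (one of mRNA, lncRNA, rRNA, snRNA, snoRNA,
#'   tRNA, pseudogene, misc_RNA).
#' @param transcripts data.frame with `tx_id`, `locus_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param exons data.frame with `tx_id`, `locus_id`, `chrom`, `start`, `end`.
#' @param cds data.frame with the same columns as `exons` (rows only for
#'   coding transcripts).
#' @return object of class `gene_model_set`.
#' @export
gene_model_set <- function(loci, transcripts, exons, cds) {
  loci <- as.data.frame(loci); transcripts <- as.data.frame(transcripts)
  exons <- as.data.frame(exons); cds <- as.data.frame(cds)

  biotypes <- c("mRNA", "lncRNA", "rRNA", "snRNA", "snoRNA", "tRNA",
                "pseudogene", "misc_RNA")
  if (nrow(loci)) {
    bad <- setdiff(unique(loci$biotype), biotypes)
    if (length(bad)) stop("unknown biotype(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(loci$locus_id)) stop("duplicated locus ids")
  }
  orphan_tx <- setdiff(transcripts$locus_id, loci$locus_id)
  if (length(orphan_tx))
    stop("orphan transcripts (unknown locus): ",
         paste(utils::head(orphan_tx, 5), collapse = ", "))
  orphan_seg <- setdiff(c(exons$tx_id, cds$tx_id), transcripts$tx_id)
  if (length(orphan_seg))
    stop("orphan exon/CDS segments (unknown transcript): ",
         paste(utils::head(orphan_seg, 5), collapse = ", "))

  # every CDS segment must lie within an exon of its transcript
  if (nrow(cds)) {
    ex_by_tx <- split(exons[, c("start", "end")], exons$tx_id)
    covered <- vapply(seq_len(nrow(cds)), function(i) {
      ex <- ex_by_tx[[cds$tx_id[i]]]
      if (is.null(ex)) return(FALSE)
      any(ex$start <= cds$start[i] & ex$end >= cds$end[i])
    }, logical(1))
    if (!all(covered))
      stop("CDS segment(s) outside exons for transcript(s): ",
           paste(unique(cds$tx_id[!covered]), collapse = ", "))
  }

  structure(list(loci = loci, transcripts = transcripts,
                 exons = exons, cds = cds),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("gene_model_set:", nrow(x$loci), "loci,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons,", nrow(x$cds), "CDS segments\n")
  if (nrow(x$loci))
    print(table(x$loci$biotype))
  invisible(x)
}

empty_models <- function() {
  df <- function(...) data.frame(..., stringsAsFactors = FALSE)
  gene_model_set(
    loci = df(locus_id = character(0), chrom = character(0),
              start = integer(0), end = integer(0), strand = character(0),
              biotype = character(0)),
    transcripts = df(tx_id = character(0), locus_id = character(0),
                     chrom = character(0), start = integer(0),
                     end = integer(0), strand = character(0)),
    exons = df(tx_id = character(0), locus_id = character(0),
               chrom = character(0), start = integer(0), end = integer(0)),
    cds = df(tx_id = character(0), locus_id = character(0),
             chrom = character(0), start = integer(0), end = integer(0))
  )
}

#' Read a GFF3 gene annotation
#'
#' Parses a GFF3 file (gene -> transcript -> exon/CDS hierarchy linked by
#' `Parent` attributes) into a [gene_model_set()]. Transcript feature types
#' are taken as biotypes; `lnc_RNA` is accepted as a synonym of `lncRNA` and
#' `pseudogenic_transcript` of `pseudogene`. Features whose `Parent` is
#' unknown are rejected.
#'
#' @param path path to a GFF3 file.
#' @return a [gene_model_set()].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_models())

  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- gr$Parent # CharacterList
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))

  syn <- c(lnc_RNA = "lncRNA", pseudogenic_transcript = "pseudogene")
  type_norm <- ifelse(type %in% names(syn), syn[type], type)
  tx_types <- c("mRNA", "lncRNA", "rRNA", "snRNA", "snoRNA", "tRNA",
                "pseudogene", "misc_RNA", "transcript")

  is_gene <- type_norm == "gene"
  is_tx <- type_norm %in% tx_types & !is_gene
  is_exon <- type_norm == "exon"
  is_cds <- type_norm == "CDS"
  known <- is_gene | is_tx | is_exon | is_cds
  if (!all(known))
    stop("unsupported feature type(s): ",
         paste(unique(type[!known]), collapse = ", "))

  biotype_attr <- if (!is.null(gr$gene_biotype))
    as.character(gr$gene_biotype) else rep(NA_character_, length(gr))

  loci <- data.frame(
    locus_id = id[is_gene], chrom = chrom[is_gene],
    start = start[is_gene], end = end[is_gene], strand = strand[is_gene],
    biotype = biotype_attr[is_gene], stringsAsFactors = FALSE)

  first_parent <- vapply(parent, function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  tx <- data.frame(
    tx_id = id[is_tx], locus_id = first_parent[is_tx],
    chrom = chrom[is_tx], start = start[is_tx], end = end[is_tx],
    strand = strand[is_tx], type = type_norm[is_tx],
    stringsAsFactors = FALSE)
  if (anyNA(tx$locus_id)) stop("transcript feature without Parent")

  # biotype: prefer the gene's gene_biotype attribute, else the tx type
  if (nrow(loci)) {
    m <- match(tx$locus_id, loci$locus_id)
    if (anyNA(m))
      stop("orphan transcript(s): ",
           paste(tx$tx_id[is.na(m)], collapse = ", "))
    fill <- is.na(loci$biotype)
    if (any(fill)) {
      bt_from_tx <- tapply(tx$type, tx$locus_id, function(t) t[[1]])
      loci$biotype[fill] <- unname(bt_from_tx[loci$locus_id[fill]])
    }
    loci$biotype[loci$biotype == "transcript"] <- "misc_RNA"
  }

  expand_segments <- function(sel) {
    ps <- parent[sel]
    n <- lengths(ps)
    if (any(n == 0L)) stop("exon/CDS feature without Parent")
    data.frame(
      tx_id = unlist(ps, use.names = FALSE),
      chrom = rep(chrom[sel], n),
      start = rep(start[sel], n),
      end = rep(end[sel], n),
      stringsAsFactors = FALSE)
  }
  exons <- expand_segments(is_exon)
  cdss <- expand_segments(is_cds)
  add_locus <- function(seg) {
    m <- match(seg$tx_id, tx$tx_id)
    if (anyNA(m))
      stop("orphan segment(s) with unknown transcript Parent: ",
           paste(unique(seg$tx_id[is.na(m)]), collapse = ", "))
    seg$locus_id <- tx$locus_id[m]
    seg[, c("tx_id", "locus_id", "chrom", "start", "end")]
  }
  exons <- if (nrow(exons)) add_locus(exons) else
    empty_models()$exons
  cdss <- if (nrow(cdss)) add_locus(cdss) else
    empty_models()$cds
  o <- function(d) d[order(d$tx_id, d$start), , drop = FALSE]
  gene_model_set(loci[order(loci$chrom, loci$start), , drop = FALSE],
                 tx[order(tx$chrom, tx$start),
                    c("tx_id", "locus_id", "chrom", "start", "end", "strand"),
                    drop = FALSE],
                 o(exons), o(cdss))
}

#' Write a gene model set as GFF3
#'
#' Emits a version-3 GFF with gene features (carrying a `gene_biotype`
#' attribute), transcript features typed by biotype, and exon/CDS children
#' linked through `Parent`. CDS phase is computed in transcript orientation.
#'
#' @param models a [gene_model_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  stopifnot(inherits(models, "gene_model_set"))
  if (nrow(models$loci) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  lo <- models$loci; tx <- models$transcripts
  ex <- models$exons; cd <- models$cds

  tx_strand <- tx$strand[match(cd$tx_id, tx$tx_id)]
  phase <- integer(nrow(cd))
  if (nrow(cd)) {
    for (t in unique(cd$tx_id)) {
      i <- which(cd$tx_id == t)
      s <- tx_strand[i[1]]
      i <- i[order(cd$start[i], decreasing = (s == "-"))]
      w <- cd$end[i] - cd$start[i] + 1
      phase[i] <- c(0, cumsum(w)[-length(w)]) %% 3
    }
  }

  mk <- function(chrom, src, type, start, end, strand, phase, attrs) {
    gr <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start, end), strand = strand)
    gr$source <- src; gr$type <- type; gr$phase <- phase
    for (a in names(attrs)) S4Vectors::mcols(gr)[[a]] <- attrs[[a]]
    gr
  }
  g1 <- mk(lo$chrom, "niltriage", "gene", lo$start, lo$end, lo$strand,
           NA_integer_,
           list(ID = lo$locus_id, gene_biotype = lo$biotype))
  bt <- lo$biotype[match(tx$locus_id, lo$locus_id)]
  g2 <- mk(tx$chrom, "niltriage", bt, tx$start, tx$end, tx$strand,
           NA_integer_, list(ID = tx$tx_id, Parent = tx$locus_id))
  seg_strand <- function(seg) tx$strand[match(seg$tx_id, tx$tx_id)]
  g3 <- if (nrow(ex)) mk(ex$chrom, "niltriage", "exon", ex$start, ex$end,
                         seg_strand(ex), NA_integer_,
                         list(Parent = ex$tx_id)) else NULL
  g4 <- if (nrow(cd)) mk(cd$chrom, "niltriage", "CDS", cd$start, cd$end,
                         seg_strand(cd), phase,
                         list(Parent = cd$tx_id)) else NULL
  all <- do.call(c, Filter(Negate(is.null), list(g1, g2, g3, g4)))
  all$type <- factor(all$type)
  # stable feature order: chrom, start, genes before children
  rank <- c(gene = 1L)[as.character(all$type)]
  rank[is.na(rank)] <- ifelse(as.character(all$type[is.na(rank)])
                              %in% c("exon", "CDS"), 3L, 2L)
  o <- order(as.character(GenomeInfoDb::seqnames(all)),
             GenomicRanges::start(all), rank, method = "radix")
  rtracklayer::export(all[o], path, format = "gff3")
  invisible(path)
}
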