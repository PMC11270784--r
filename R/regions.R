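# Classification of variants against the gene annotation into intragenic
# region types. A variant's footprint is its full REF span (a SNV occupies a
# single base, a deletion POS..POS+len(REF)-1, left-anchored). Assignment is
# per (variant, locus): a variant inside two overlapping loci receives two
# assignments; one outside every locus span is intergenic/flanking and
# receives none.

.region_biotype_label <- c(lncRNA = "LNCRNA", rRNA = "RRNA", snRNA = "SNRNA",
                           snoRNA = "SNORNA", tRNA = "TRNA",
                           pseudogene = "PSEUDO_MISC",
                           misc_RNA = "PSEUDO_MISC")

.footprint_granges <- function(records) {
  GenomicRanges::GRanges(
    records$chrom,
    IRanges::IRanges(records$pos, records$pos + nchar(records$ref) - 1))
}

#' Assign variants to overlapping loci and classify their region
#'
#' Overlaps each variant's REF footprint with every locus span and, for each
#' (variant, locus) pair, assigns one region type. For protein-coding (mRNA)
#' loci the precedence is total across isoforms: CDS if any overlapped base
#' intersects a CDS segment of any transcript, else EXON (non-coding exon,
#' i.e. UTR or non-coding isoform exon) if it intersects an exon, else
#' INTRON. Non-mRNA loci map to their biotype label (LNCRNA, RRNA, SNRNA,
#' SNORNA, TRNA, PSEUDO_MISC).
#'
#' @param records variant record data.frame (needs `chrom`, `pos`, `ref`,
#'   `alt`, `key`).
#' @param models a [gene_model_set()].
#' @return data.frame with one row per (variant, locus) assignment: `key`,
#'   `chrom`, `pos`, `ref`, `alt`, `locus_id`, `biotype`, `region`.
#' @export
assign_loci <- function(records, models) {
  empty <- data.frame(key = character(0), chrom = character(0),
                      pos = numeric(0), ref = character(0),
                      alt = character(0), locus_id = character(0),
                      biotype = character(0), region = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0L || nrow(models$loci) == 0L) return(empty)

  vgr <- .footprint_granges(records)
  lgr <- GenomicRanges::GRanges(
    models$loci$chrom,
    IRanges::IRanges(models$loci$start, models$loci$end))
  hits <- GenomicRanges::findOverlaps(vgr, lgr, ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)
  vi <- S4Vectors::queryHits(hits); li <- S4Vectors::subjectHits(hits)

  out <- data.frame(
    key = records$key[vi], chrom = records$chrom[vi], pos = records$pos[vi],
    ref = records$ref[vi], alt = records$alt[vi],
    locus_id = models$loci$locus_id[li],
    biotype = models$loci$biotype[li], stringsAsFactors = FALSE)

  out$region <- NA_character_
  non_mrna <- out$biotype != "mRNA"
  out$region[non_mrna] <- unname(.region_biotype_label[out$biotype[non_mrna]])

  mi <- which(!non_mrna)
  if (length(mi)) {
    pair_id <- paste(out$key, out$locus_id)
    seg_hit <- function(seg) {
      if (nrow(seg) == 0L) return(character(0))
      sgr <- GenomicRanges::GRanges(
        seg$chrom, IRanges::IRanges(seg$start, seg$end))
      h <- GenomicRanges::findOverlaps(vgr, sgr, ignore.strand = TRUE)
      unique(paste(records$key[S4Vectors::queryHits(h)],
                   seg$locus_id[S4Vectors::subjectHits(h)]))
    }
    cds_pairs <- seg_hit(models$cds)
    exon_pairs <- seg_hit(models$exons)
    out$region[mi] <- ifelse(pair_id[mi] %in% cds_pairs, "CDS",
                      ifelse(pair_id[mi] %in% exon_pairs, "EXON", "INTRON"))
  }
  rownames(out) <- NULL
  out
}

#' Classify one variant's region within one locus
#'
#' Single-pair convenience over the same rules as [assign_loci()]. The
#' variant footprint must intersect the locus span.
#'
#' @param variant list or one-row data.frame with `chrom`, `pos`, `ref`.
#' @param locus_id a locus id present in `models`.
#' @param models a [gene_model_set()].
#' @return the region type string.
#' @export
classify_region <- function(variant, locus_id, models) {
  lo <- models$loci[models$loci$locus_id == locus_id, , drop = FALSE]
  if (nrow(lo) != 1L) stop("unknown locus: ", locus_id)
  v_start <- variant$pos
  v_end <- variant$pos + nchar(variant$ref) - 1
  if (variant$chrom != lo$chrom || v_end < lo$start || v_start > lo$end)
    stop("variant does not overlap locus span")
  if (lo$biotype != "mRNA") {
    lab <- .region_biotype_label[[lo$biotype]]
    if (is.null(lab)) stop("unknown biotype: ", lo$biotype)
    return(lab)
  }
  touches <- function(seg) {
    seg <- seg[seg$locus_id == locus_id, , drop = FALSE]
    nrow(seg) > 0L && any(seg$start <= v_end & seg$end >= v_start)
  }
  if (touches(models$cds)) "CDS"
  else if (touches(models$exons)) "EXON"
  else "INTRON"
}

#' Tally CDS-only, exon-only and strand-dependent dual assignments
#'
#' Among variants with at least one CDS or EXON assignment at a
#' protein-coding locus, counts those classified CDS at every such locus,
#' EXON at every such locus, or CDS at one locus and EXON at another
#' (overlapping loci on opposite strands). The three counts sum to the
#' number of HHQ-I-C/E variants.
#'
#' @param assignments result of [assign_loci()].
#' @return list with `n_cds_only`, `n_exon_only`, `n_both`.
#' @export
cds_exon_both_tally <- function(assignments) {
  ce <- assignments[assignments$region %in% c("CDS", "EXON"), , drop = FALSE]
  if (nrow(ce) == 0L)
    return(list(n_cds_only = 0L, n_exon_only = 0L, n_both = 0L))
  has_cds <- tapply(ce$region == "CDS", ce$key, any)
  has_exon <- tapply(ce$region == "EXON", ce$key, any)
  both <- has_cds & has_exon
  list(n_cds_only = sum(has_cds & !has_exon),
       n_exon_only = sum(has_exon & !has_cds),
       n_both = sum(both))
}

#' Write locus assignments as TSV
#'
#' @param assignments result of [assign_loci()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
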