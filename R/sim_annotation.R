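# Synthetic gene annotation with a realistic gene -> transcript -> exon/CDS
# hierarchy. Loci are laid out without overlap except for one deliberately
# planted opposite-strand overlapping pair per chromosome (when it fits),
# used to exercise dual-locus variant assignment.

# Build exon widths / intron widths and CDS placement for one mRNA gene.
# Returns list(exon_w, intron_w, u5, u3) in transcript coordinates.
.mrna_structure <- function(max_iso) {
  n_ex <- sample(1:6, 1)
  exon_w <- round(stats::runif(n_ex, 150, 600))
  intron_w <- if (n_ex > 1) round(stats::runif(n_ex - 1, 100, 1500)) else
    integer(0)
  lx <- sum(exon_w)
  u5 <- sample(20:min(100, exon_w[1] - 10), 1)
  u3 <- sample(20:min(150, exon_w[n_ex] - 10), 1)
  u3 <- u3 + (lx - u5 - u3) %% 3
  if (lx - u5 - u3 < 9) { # keep at least three codons of CDS
    u5 <- 3; u3 <- 3 + (lx - 6) %% 3
  }
  n_iso <- sample(seq(max_iso[1], max_iso[2]), 1)
  list(exon_w = exon_w, intron_w = intron_w, u5 = u5, u3 = u3,
       n_iso = n_iso)
}

# Map a closed interval in transcript (exonic) coordinates to genomic
# segments, given genomic exon starts/ends sorted in transcript orientation.
.tx_to_genomic <- function(tx_from, tx_to, ex_start, ex_end, strand) {
  w <- ex_end - ex_start + 1
  cum <- cumsum(w)
  lo <- c(0, cum[-length(cum)]) + 1
  segs <- list()
  for (i in seq_along(w)) {
    a <- max(tx_from, lo[i]); b <- min(tx_to, cum[i])
    if (a > b) next
    if (strand == "+") {
      gs <- ex_start[i] + (a - lo[i]); ge <- ex_start[i] + (b - lo[i])
    } else {
      ge <- ex_end[i] - (a - lo[i]); gs <- ex_end[i] - (b - lo[i])
    }
    segs[[length(segs) + 1L]] <- c(gs, ge)
  }
  do.call(rbind, segs)
}

# Assemble one locus (all transcript/exon/CDS rows) at genomic start gstart.
.build_locus <- function(locus_id, chrom, gstart, strand, biotype, struct) {
  rows <- list(tx = NULL, ex = NULL, cds = NULL)
  if (biotype == "mRNA") {
    n_ex <- length(struct$exon_w)
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    p <- gstart
    for (i in seq_len(n_ex)) {
      ex_start[i] <- p
      ex_end[i] <- p + struct$exon_w[i] - 1
      p <- ex_end[i] + if (i < n_ex) struct$intron_w[i] + 1 else 1
    }
    gend <- ex_end[n_ex]
    # transcript orientation: exons sorted 5'->3'
    o <- if (strand == "+") order(ex_start) else order(-ex_start)
    lx <- sum(struct$exon_w)
    tx_rows <- ex_rows <- cds_rows <- list()
    for (j in seq_len(struct$n_iso)) {
      tx_id <- sprintf("%s.t%d", locus_id, j)
      u5 <- struct$u5 + 3L * (j - 1L)
      cds_len <- lx - u5 - struct$u3
      if (cds_len < 6) { u5 <- struct$u5; cds_len <- lx - u5 - struct$u3 }
      seg <- .tx_to_genomic(u5 + 1, lx - struct$u3,
                            ex_start[o], ex_end[o], strand)
      tx_rows[[j]] <- data.frame(tx_id = tx_id, locus_id = locus_id,
                                 chrom = chrom, start = gstart, end = gend,
                                 strand = strand)
      ex_rows[[j]] <- data.frame(tx_id = tx_id, locus_id = locus_id,
                                 chrom = chrom, start = ex_start,
                                 end = ex_end)
      cds_rows[[j]] <- data.frame(tx_id = tx_id, locus_id = locus_id,
                                  chrom = chrom, start = seg[, 1],
                                  end = seg[, 2])
    }
    rows$tx <- do.call(rbind, tx_rows)
    rows$ex <- do.call(rbind, ex_rows)
    rows$cds <- do.call(rbind, cds_rows)
  } else {
    n_ex <- length(struct$exon_w)
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    p <- gstart
    for (i in seq_len(n_ex)) {
      ex_start[i] <- p
      ex_end[i] <- p + struct$exon_w[i] - 1
      p <- ex_end[i] + if (i < n_ex) struct$intron_w[i] + 1 else 1
    }
    gend <- ex_end[n_ex]
    tx_id <- sprintf("%s.t1", locus_id)
    rows$tx <- data.frame(tx_id = tx_id, locus_id = locus_id, chrom = chrom,
                          start = gstart, end = gend, strand = strand)
    rows$ex <- data.frame(tx_id = tx_id, locus_id = locus_id, chrom = chrom,
                          start = ex_start, end = ex_end)
  }
  rows$locus <- data.frame(locus_id = locus_id, chrom = chrom,
                           start = gstart, end = rows$tx$end[1],
                           strand = strand, biotype = biotype,
                           overlapping = FALSE)
  rows
}

.ncrna_structure <- function(biotype) {
  if (biotype %in% c("snRNA", "snoRNA", "tRNA")) {
    list(exon_w = round(stats::runif(1, 70, 160)), intron_w = integer(0))
  } else if (biotype == "rRNA") {
    list(exon_w = round(stats::runif(1, 120, 3000)), intron_w = integer(0))
  } else { # lncRNA, pseudogene, misc_RNA
    n_ex <- sample(1:2, 1)
    list(exon_w = round(stats::runif(n_ex, 200, 800)),
         intron_w = if (n_ex > 1) round(stats::runif(1, 100, 1200)) else
           integer(0))
  }
}

#' Simulate a gene annotation
#'
#' Generates a [gene_model_set()] over the configured chromosomes: loci drawn
#' from the biotype mix, mRNA loci with 1-6 exons, UTRs and one or more
#' isoforms whose CDS segments always lie within exons, and (per chromosome
#' with at least 10 loci) one planted pair of overlapping opposite-strand
#' mRNA loci in which one locus' coding exon is covered by the other locus'
#' non-coding (UTR) exon — the configuration that produces strand-dependent
#' dual-locus region calls.
#'
#' @param config a [sim_config()].
#' @return a [gene_model_set()]; `models$loci$overlapping` flags the planted
#'   overlap pair members.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 1L), {
    per_chrom <- lapply(names(config$chrom_lengths), function(chrom) {
      n <- config$genes_per_chrom[[chrom]]
      L <- config$chrom_lengths[[chrom]]
      if (n == 0L) return(NULL)
      n_bt <- alloc_counts(n, config$biotype_mix)
      biotypes <- sample(rep(names(n_bt), n_bt))
      structs <- lapply(biotypes, function(b)
        if (b == "mRNA") .mrna_structure(config$isoforms_per_gene)
        else .ncrna_structure(b))
      lens <- vapply(structs, function(s)
        sum(s$exon_w) + sum(s$intron_w), numeric(1))
      min_gap <- 200
      slack <- L - sum(lens) - (n + 1) * min_gap
      if (slack < 0)
        stop(sprintf("chromosome %s too short for %d loci", chrom, n))
      u <- stats::runif(n + 1)
      gaps <- min_gap + floor(slack * u / sum(u))
      starts <- cumsum(gaps[seq_len(n)] + c(0, lens[-n])) + 1
      strands <- sample(c("+", "-"), n, replace = TRUE)
      built <- lapply(seq_len(n), function(i)
        .build_locus(sprintf("SYNG_%s_%04d", chrom, i), chrom,
                     starts[i], strands[i], biotypes[i], structs[[i]]))

      # planted overlapping opposite-strand pair
      if (n >= 10L) {
        host_idx <- which(biotypes == "mRNA")
        # pick an mRNA host with a CDS segment of >= 120 bp and room after it
        gap_after <- c(starts[-1], L) - vapply(built, function(b)
          b$locus$end, numeric(1)) - 1
        ok <- host_idx[vapply(host_idx, function(i) {
          cd <- built[[i]]$cds
          !is.null(cd) && any(cd$end - cd$start + 1 >= 120) &&
            gap_after[i] >= 600
        }, logical(1))]
        if (length(ok)) {
          i <- ok[[1]]
          host <- built[[i]]
          cd <- host$cds
          seg <- cd[which(cd$end - cd$start + 1 >= 120)[1], ]
          x <- seg$start + 20
          pstrand <- if (host$locus$strand[1] == "+") "-" else "+"
          pid <- sprintf("SYNG_%s_OVL", chrom)
          hend <- host$locus$end[1]
          ex1 <- c(x, x + 60)              # inside the host CDS segment
          ex2 <- c(hend + 50, hend + 350)  # beyond the host, in the gap
          ptx <- sprintf("%s.t1", pid)
          # CDS of the partner lives in the exon outside the host span, so
          # the overlap region is a non-coding (UTR) exon of the partner
          cds2 <- c(ex2[1] + 30, ex2[1] + 30 + 89) # 90 bp, multiple of 3
          built[[length(built) + 1L]] <- list(
            locus = data.frame(locus_id = pid, chrom = chrom,
                               start = ex1[1], end = ex2[2],
                               strand = pstrand, biotype = "mRNA",
                               overlapping = TRUE),
            tx = data.frame(tx_id = ptx, locus_id = pid, chrom = chrom,
                            start = ex1[1], end = ex2[2], strand = pstrand),
            ex = data.frame(tx_id = ptx, locus_id = pid, chrom = chrom,
                            start = c(ex1[1], ex2[1]),
                            end = c(ex1[2], ex2[2])),
            cds = data.frame(tx_id = ptx, locus_id = pid, chrom = chrom,
                             start = cds2[1], end = cds2[2]))
          built[[i]]$locus$overlapping <- TRUE
        }
      }
      built
    })
    built <- unlist(per_chrom, recursive = FALSE)
    if (length(built) == 0L) return(empty_models())
    cat_rows <- function(field) {
      rows <- Filter(Negate(is.null), lapply(built, `[[`, field))
      if (length(rows)) do.call(rbind, rows) else empty_models()[[
        c(locus = "loci", tx = "transcripts", ex = "exons",
          cds = "cds")[[field]]]]
    }
    gene_model_set(cat_rows("locus"), cat_rows("tx"),
                   cat_rows("ex"), cat_rows("cds"))
  })
}
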