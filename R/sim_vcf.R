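# Synthetic two-sample NIL VCF with planted triage-tier truth. Every record
# carries a truth label naming the deepest tier it should survive to, plus
# region/locus truth for intragenic plants, so downstream recovery can be
# checked exactly.

.reduce_intervals <- function(start, end) {
  ir <- IRanges::reduce(IRanges::IRanges(start, end))
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}

.rand_bases <- function(n, len = 1L) {
  if (n == 0L) return(character(0))
  b <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i)
    paste(sample(b, len, replace = TRUE), collapse = ""), character(1))
}

.rand_snv <- function(n) {
  b <- c("A", "C", "G", "T")
  ri <- sample.int(4L, n, replace = TRUE)
  ai <- ((ri - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
  list(ref = b[ri], alt = b[ai])
}

# genotype pools (gt1 = late line, gt2 = early line)
.gt_contrasting <- function(n) {
  flip <- stats::runif(n) < 0.1
  list(gt1 = ifelse(flip, "1/1", "0/0"), gt2 = ifelse(flip, "0/0", "1/1"))
}
.gt_non_contrasting <- function(n) {
  pool <- list(c("0/1", "1/1"), c("0/0", "0/1"), c("1/1", "1/1"),
               c("0/1", "0/1"))
  pick <- sample.int(length(pool), n, replace = TRUE)
  list(gt1 = vapply(pool[pick], `[`, "", 1L),
       gt2 = vapply(pool[pick], `[`, "", 2L))
}

.filters_hq <- function(n, vocab) {
  u <- stats::runif(n)
  ifelse(u < 0.60, "PASS",
  ifelse(u < 0.70, ".", sample(vocab, n, replace = TRUE)))
}
.filters_lowq <- function(n, vocab) {
  vapply(seq_len(n), function(i)
    paste(sample(vocab, sample(2:3, 1)), collapse = ";"), character(1))
}

#' Simulate the NIL-pair VCF with planted tier truth
#'
#' Plants, per chromosome, the configured number of variants at each triage
#' tier: HHQ-I-C/E variants inside exons/CDS of protein-coding loci (spread
#' over exactly the configured number of distinct genes), HHQ-I variants in
#' mRNA introns or non-coding RNA loci, HHQ variants in intergenic space,
#' plus high-quality non-homozygous records, low-quality records (two or more
#' failed FILTER criteria, including a few multi-allelic rows), records
#' failing the read-depth threshold, records with missing DP, and records on
#' unanchored scaffold contigs. Genotype and depth draws make every filter
#' decision deterministic given the truth label.
#'
#' @param config a [sim_config()].
#' @param models a [gene_model_set()] from [simulate_annotation()] with the
#'   same config.
#' @return list of class `nil_vcf_sim` with `rows` (one row per VCF line,
#'   ready for [write_vcf()]), `truth` (one row per biallelic record after
#'   splitting: `key`, `chrom`, `pos`, `ref`, `alt`, `tier`, `region`,
#'   `locus_id`), and `het` (`n_positions`, per-sample `n_het` counts drawn
#'   binomially at the configured heterozygosity rates).
#' @export
simulate_nil_vcf <- function(config, models) {
  stopifnot(inherits(config, "sim_config"),
            inherits(models, "gene_model_set"))
  vocab <- c("q10", "lowQD", "highFS", "snpcluster", "lowMQ")
  tc <- config$planted_tier_counts

  with_seed(child_seed(config$seed, 2L), {
    ovl <- models$loci$overlapping
    keep <- if (is.null(ovl)) rep(TRUE, nrow(models$loci)) else
      !(!is.na(ovl) & ovl)
    safe <- models$loci[keep, , drop = FALSE]
    per_chrom <- lapply(seq_len(nrow(tc)), function(ci) {
      chrom <- tc$chrom[ci]
      L <- config$chrom_lengths[[chrom]]
      n_ce <- tc$hhq_i_ce[ci]; g_ce <- tc$genes_ce[ci]
      n_i <- tc$hhq_i[ci] - n_ce
      n_hom <- tc$hhq[ci] - tc$hhq_i[ci]
      n_hq <- tc$hq[ci] - tc$hhq[ci]
      n_lq <- tc$detected[ci] - tc$hq[ci]
      n_df <- round(config$depth_fail_rate * tc$detected[ci])

      loci_c <- safe[safe$chrom == chrom, , drop = FALSE]
      mrna <- loci_c[loci_c$biotype == "mRNA", , drop = FALSE]
      ncrna <- loci_c[loci_c$biotype != "mRNA", , drop = FALSE]

      out <- list()
      # --- HHQ-I-C/E: exonic positions in g_ce distinct mRNA loci ---
      if (n_ce > 0L) {
        if (nrow(mrna) < g_ce)
          stop(sprintf("chromosome %s: %d protein-coding loci available, %d needed",
                       chrom, nrow(mrna), g_ce))
        chosen <- sample(mrna$locus_id, g_ce)
        ex <- models$exons[models$exons$locus_id %in% chosen, , drop = FALSE]
        un <- lapply(split(ex, ex$locus_id), function(e)
          .reduce_intervals(e$start, e$end))
        cap <- vapply(un, function(u) sum(u$end - u$start + 1), numeric(1))
        extra <- n_ce - g_ce
        counts <- stats::setNames(rep(1L, g_ce), names(un))
        if (extra > 0L) {
          pool <- rep(names(un), pmax(cap - 1, 0))
          if (length(pool) < extra)
            stop(sprintf("chromosome %s: not enough exonic space", chrom))
          add <- table(sample(pool, extra))
          counts[names(add)] <- counts[names(add)] + as.integer(add)
        }
        cds_by_locus <- split(models$cds[models$cds$locus_id %in% chosen, ,
                                         drop = FALSE],
                              models$cds$locus_id[
                                models$cds$locus_id %in% chosen])
        plants <- lapply(names(counts), function(lid) {
          u <- un[[lid]]
          pos <- sample_positions(u$start, u$end, counts[[lid]])
          cd <- cds_by_locus[[lid]]
          in_cds <- if (is.null(cd) || nrow(cd) == 0L) rep(FALSE, length(pos))
            else vapply(pos, function(p)
              any(cd$start <= p & cd$end >= p), logical(1))
          data.frame(pos = pos, locus_id = lid,
                     region = ifelse(in_cds, "CDS", "EXON"))
        })
        plants <- do.call(rbind, plants)
        n <- nrow(plants)
        sv <- .rand_snv(n)
        ref <- sv$ref; alt <- sv$alt
        # a few deletions, kept inside their exon segment
        del <- which(stats::runif(n) < 0.05)
        for (j in del) {
          lid <- plants$locus_id[j]
          u <- un[[lid]]
          seg <- which(u$start <= plants$pos[j] & u$end >= plants$pos[j])
          room <- u$end[seg] - plants$pos[j]
          len <- sample(1:11, 1)
          if (room >= len) {
            ref[j] <- paste0(ref[j], .rand_bases(1, len))
            alt[j] <- substr(ref[j], 1, 1)
          }
        }
        gt <- .gt_contrasting(n)
        out$ce <- data.frame(
          chrom = chrom, pos = plants$pos, ref = ref, alt = alt,
          filter = .filters_hq(n, vocab), gt1 = gt$gt1, gt2 = gt$gt2,
          dp1 = sample(10:60, n, TRUE), dp2 = sample(10:60, n, TRUE),
          tier = "HHQ_I_CE", region = plants$region,
          locus_id = plants$locus_id, stringsAsFactors = FALSE)
      }

      # --- HHQ-I (non-C/E): mRNA introns and non-coding RNA loci ---
      if (n_i > 0L) {
        iv <- list()
        if (nrow(mrna)) {
          ex_m <- models$exons[models$exons$locus_id %in% mrna$locus_id, ]
          for (k in seq_len(nrow(mrna))) {
            lid <- mrna$locus_id[k]
            e <- ex_m[ex_m$locus_id == lid, , drop = FALSE]
            red <- .reduce_intervals(e$start, e$end)
            # intron space: span minus exon union
            gaps <- complement_intervals(red$start - mrna$start[k] + 1,
                                         red$end - mrna$start[k] + 1,
                                         mrna$end[k] - mrna$start[k] + 1)
            if (nrow(gaps))
              iv[[length(iv) + 1L]] <- data.frame(
                start = gaps$start + mrna$start[k] - 1,
                end = gaps$end + mrna$start[k] - 1,
                locus_id = lid, region = "INTRON")
          }
        }
        if (nrow(ncrna)) {
          lab <- c(lncRNA = "LNCRNA", rRNA = "RRNA", snRNA = "SNRNA",
                   snoRNA = "SNORNA", tRNA = "TRNA",
                   pseudogene = "PSEUDO_MISC", misc_RNA = "PSEUDO_MISC")
          iv[[length(iv) + 1L]] <- data.frame(
            start = ncrna$start, end = ncrna$end,
            locus_id = ncrna$locus_id,
            region = unname(lab[ncrna$biotype]))
        }
        iv <- do.call(rbind, iv)
        if (is.null(iv) || nrow(iv) == 0L)
          stop(sprintf("chromosome %s: no intragenic non-exonic space", chrom))
        iv <- iv[order(iv$start), , drop = FALSE]
        pos <- sample_positions(iv$start, iv$end, n_i)
        hit <- findInterval(pos, iv$start)
        sv <- .rand_snv(n_i)
        gt <- .gt_contrasting(n_i)
        out$hhq_i <- data.frame(
          chrom = chrom, pos = pos, ref = sv$ref, alt = sv$alt,
          filter = .filters_hq(n_i, vocab), gt1 = gt$gt1, gt2 = gt$gt2,
          dp1 = sample(10:60, n_i, TRUE), dp2 = sample(10:60, n_i, TRUE),
          tier = "HHQ_I", region = iv$region[hit],
          locus_id = iv$locus_id[hit], stringsAsFactors = FALSE)
      }

      # --- intergenic classes: HHQ, HQ-only, low-quality, depth-fail ---
      spans <- models$loci[models$loci$chrom == chrom, , drop = FALSE]
      inter <- complement_intervals(spans$start, spans$end, L)
      n_misc <- n_hom + n_hq + n_lq + n_df
      if (n_misc > 0L) {
        pos <- sample_positions(inter$start, inter$end, n_misc)
        pos <- sample(pos) # decouple class from genomic order
        cnts <- c(n_hom, n_hq, n_lq, n_df)
        idx <- cumsum(cnts)
        take <- function(k) if (cnts[k] == 0L) numeric(0) else
          pos[(idx[k] - cnts[k] + 1):idx[k]]
        p_hom <- take(1L); p_hq <- take(2L); p_lq <- take(3L); p_df <- take(4L)

        if (n_hom > 0L) {
          sv <- .rand_snv(n_hom); gt <- .gt_contrasting(n_hom)
          out$hhq <- data.frame(
            chrom = chrom, pos = p_hom, ref = sv$ref, alt = sv$alt,
            filter = .filters_hq(n_hom, vocab), gt1 = gt$gt1, gt2 = gt$gt2,
            dp1 = sample(10:60, n_hom, TRUE), dp2 = sample(10:60, n_hom, TRUE),
            tier = "HHQ", region = NA_character_,
            locus_id = NA_character_, stringsAsFactors = FALSE)
        }
        if (n_hq > 0L) {
          sv <- .rand_snv(n_hq); gt <- .gt_non_contrasting(n_hq)
          out$hq <- data.frame(
            chrom = chrom, pos = p_hq, ref = sv$ref, alt = sv$alt,
            filter = .filters_hq(n_hq, vocab), gt1 = gt$gt1, gt2 = gt$gt2,
            dp1 = sample(10:60, n_hq, TRUE), dp2 = sample(10:60, n_hq, TRUE),
            tier = "HQ", region = NA_character_,
            locus_id = NA_character_, stringsAsFactors = FALSE)
        }
        if (n_lq > 0L) {
          # some records come in multi-allelic pairs sharing a position
          m <- min(10L, n_lq %/% 100L)
          n_single <- n_lq - 2L * m
          p_single <- p_lq[seq_len(n_single)]
          p_pairs <- p_lq[n_single + seq_len(m)]
          sv <- .rand_snv(n_single)
          gtpool <- c("0/1", "1/1", "0/0", "./.")
          lq1 <- data.frame(
            chrom = chrom, pos = p_single, ref = sv$ref, alt = sv$alt,
            filter = .filters_lowq(n_single, vocab),
            gt1 = sample(gtpool, n_single, TRUE),
            gt2 = sample(gtpool, n_single, TRUE),
            dp1 = sample(10:60, n_single, TRUE),
            dp2 = sample(10:60, n_single, TRUE),
            tier = "DETECTED", region = NA_character_,
            locus_id = NA_character_, stringsAsFactors = FALSE)
          lq2 <- if (m > 0L) {
            b <- c("A", "C", "G", "T")
            ri <- sample.int(4L, m, TRUE)
            alt2 <- vapply(ri, function(r)
              paste(sample(b[-r], 2L), collapse = ","), character(1))
            data.frame(
              chrom = chrom, pos = p_pairs, ref = b[ri], alt = alt2,
              filter = .filters_lowq(m, vocab),
              gt1 = "1/2", gt2 = "1/2",
              dp1 = sample(10:60, m, TRUE), dp2 = sample(10:60, m, TRUE),
              tier = "DETECTED", region = NA_character_,
              locus_id = NA_character_, stringsAsFactors = FALSE)
          } else NULL
          out$lq <- rbind(lq1, lq2)
        }
        if (n_df > 0L) {
          sv <- .rand_snv(n_df); gt <- .gt_non_contrasting(n_df)
          low_in_1 <- stats::runif(n_df) < 0.5
          dp_low <- sample(0:9, n_df, TRUE)
          dp_ok <- sample(10:60, n_df, TRUE)
          out$df <- data.frame(
            chrom = chrom, pos = p_df, ref = sv$ref, alt = sv$alt,
            filter = .filters_hq(n_df, vocab), gt1 = gt$gt1, gt2 = gt$gt2,
            dp1 = ifelse(low_in_1, dp_low, dp_ok),
            dp2 = ifelse(low_in_1, dp_ok, dp_low),
            tier = "DEPTH_FAIL", region = NA_character_,
            locus_id = NA_character_, stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, out)
    })
    rows <- do.call(rbind, per_chrom)

    # records with missing DP (excluded with a warning tally downstream)
    if (!is.null(rows) && nrow(rows) > 3L) {
      sv <- .rand_snv(3L)
      first_chrom <- tc$chrom[1]
      L1 <- config$chrom_lengths[[first_chrom]]
      spans1 <- models$loci[models$loci$chrom == first_chrom, , drop = FALSE]
      inter1 <- complement_intervals(spans1$start, spans1$end, L1)
      taken <- rows$pos[rows$chrom == first_chrom]
      p <- setdiff(sample_positions(inter1$start, inter1$end,
                                    3L + length(taken)), taken)[1:3]
      rows <- rbind(rows, data.frame(
        chrom = first_chrom, pos = p, ref = sv$ref, alt = sv$alt,
        filter = "PASS", gt1 = "0/0", gt2 = "1/1",
        dp1 = NA_integer_, dp2 = sample(10:60, 3L, TRUE),
        tier = "DP_MISSING", region = NA_character_,
        locus_id = NA_character_, stringsAsFactors = FALSE))
    }

    # unanchored scaffold records
    if (config$n_unanchored > 0L) {
      n <- config$n_unanchored
      sv <- .rand_snv(n); gt <- .gt_contrasting(n)
      scaf <- sprintf("scaffold_%04d", sample.int(200L, n, replace = TRUE))
      pos <- sample.int(100000L, n, replace = TRUE)
      un <- data.frame(
        chrom = scaf, pos = pos, ref = sv$ref, alt = sv$alt,
        filter = .filters_hq(n, vocab), gt1 = gt$gt1, gt2 = gt$gt2,
        dp1 = sample(10:60, n, TRUE), dp2 = sample(10:60, n, TRUE),
        tier = "UNANCHORED", region = NA_character_,
        locus_id = NA_character_, stringsAsFactors = FALSE)
      un <- un[!duplicated(paste(un$chrom, un$pos)), , drop = FALSE]
      rows <- rbind(rows, un)
    }

    if (is.null(rows))
      rows <- data.frame(chrom = character(0), pos = numeric(0),
                         ref = character(0), alt = character(0),
                         filter = character(0), gt1 = character(0),
                         gt2 = character(0), dp1 = integer(0),
                         dp2 = integer(0), tier = character(0),
                         region = character(0), locus_id = character(0),
                         stringsAsFactors = FALSE)
    if (nrow(rows)) {
      rows <- rows[order(rows$chrom, rows$pos, method = "radix"), ]
      rownames(rows) <- NULL
    }

    # truth: one row per biallelic record after multi-allelic splitting
    truth <- if (nrow(rows)) {
      alts <- strsplit(rows$alt, ",", fixed = TRUE)
      n_alt <- lengths(alts)
      i <- rep(seq_len(nrow(rows)), n_alt)
      data.frame(
        key = variant_key(rows$chrom[i], rows$pos[i], rows$ref[i],
                          unlist(alts)),
        chrom = rows$chrom[i], pos = rows$pos[i], ref = rows$ref[i],
        alt = unlist(alts), tier = rows$tier[i], region = rows$region[i],
        locus_id = rows$locus_id[i], stringsAsFactors = FALSE)
    } else data.frame(key = character(0), chrom = character(0),
                      pos = numeric(0), ref = character(0),
                      alt = character(0), tier = character(0),
                      region = character(0), locus_id = character(0))

    het <- list(
      n_positions = config$n_positions_read,
      n_het = c(stats::rbinom(1L, config$n_positions_read,
                              config$het_rate[1]),
                stats::rbinom(1L, config$n_positions_read,
                              config$het_rate[2])))

    structure(list(rows = rows[, c("chrom", "pos", "ref", "alt", "filter",
                                   "gt1", "gt2", "dp1", "dp2")],
                   truth = truth, het = het),
              class = "nil_vcf_sim")
  })
}

#' @export
print.nil_vcf_sim <- function(x, ...) {
  cat("nil_vcf_sim:", nrow(x$rows), "VCF rows,", nrow(x$truth),
      "biallelic records\n")
  print(table(x$truth$tier))
  invisible(x)
}
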