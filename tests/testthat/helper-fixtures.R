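# Fixtures built in code: a hand-laid toy annotation (used for oracle
# comparisons), a small simulation config, and ad-hoc record builders.

tdf <- function(...) data.frame(..., stringsAsFactors = FALSE)

# Hand-built toy annotation on a 100-kb chromosome "toy": multi-isoform and
# minus-strand mRNA loci, an overlapping opposite-strand pair in which one
# locus' CDS is covered by the other's UTR exon, and one locus of every
# non-coding biotype.
toy_models <- function() {
  loci <- tdf(
    locus_id = paste0("L", 1:10),
    chrom = "toy",
    start = c(1000, 12000, 20000, 40000, 40800, 50000, 60000, 70000,
              75000, 80000),
    end = c(9000, 14000, 30000, 46000, 42500, 50200, 61500, 70080,
            76000, 80150),
    strand = c("+", "+", "-", "+", "-", "+", "+", "+", "+", "+"),
    biotype = c("mRNA", "lncRNA", "mRNA", "mRNA", "mRNA", "snoRNA",
                "pseudogene", "tRNA", "rRNA", "snRNA"))
  transcripts <- tdf(
    tx_id = c("L1.t1", "L1.t2", "L2.t1", "L3.t1", "L4.t1", "L5.t1",
              "L6.t1", "L7.t1", "L8.t1", "L9.t1", "L10.t1"),
    locus_id = c("L1", "L1", "L2", "L3", "L4", "L5", "L6", "L7", "L8",
                 "L9", "L10"),
    chrom = "toy",
    start = c(1000, 1000, 12000, 20000, 40000, 40800, 50000, 60000,
              70000, 75000, 80000),
    end = c(9000, 9000, 14000, 30000, 46000, 42500, 50200, 61500,
            70080, 76000, 80150),
    strand = c("+", "+", "+", "-", "+", "-", "+", "+", "+", "+", "+"))
  exons <- tdf(
    tx_id = c("L1.t1", "L1.t1", "L1.t1", "L1.t2", "L1.t2",
              "L2.t1",
              "L3.t1", "L3.t1", "L3.t1",
              "L4.t1", "L4.t1",
              "L5.t1", "L5.t1",
              "L6.t1", "L7.t1", "L8.t1", "L9.t1", "L10.t1"),
    start = c(1000, 3000, 6000, 1000, 6000,
              12000,
              20000, 25000, 29000,
              40000, 45000,
              40800, 42000,
              50000, 60000, 70000, 75000, 80000),
    end = c(2000, 4500, 9000, 2000, 9000,
            14000,
            21000, 26000, 30000,
            41000, 46000,
            41500, 42500,
            50200, 61500, 70080, 76000, 80150))
  exons$locus_id <- transcripts$locus_id[match(exons$tx_id,
                                               transcripts$tx_id)]
  exons$chrom <- "toy"
  cds <- tdf(
    tx_id = c("L1.t1", "L1.t1", "L1.t1", "L1.t2", "L1.t2",
              "L3.t1", "L3.t1", "L3.t1",
              "L4.t1", "L4.t1",
              "L5.t1"),
    start = c(1500, 3000, 6000, 1500, 6000,
              20500, 25000, 29000,
              40200, 45000,
              42000),
    end = c(2000, 4500, 6800, 2000, 6500,
            21000, 26000, 29500,
            41000, 45400,
            42300))
  cds$locus_id <- transcripts$locus_id[match(cds$tx_id, transcripts$tx_id)]
  cds$chrom <- "toy"
  gene_model_set(loci, transcripts,
                 exons[, c("tx_id", "locus_id", "chrom", "start", "end")],
                 cds[, c("tx_id", "locus_id", "chrom", "start", "end")])
}

# small planted-tier table and config for fast generator tests
small_tier_counts <- function() {
  tdf(chrom = c("Ca1", "Ca2"),
      detected = c(300L, 120L), hq = c(200L, 80L), hhq = c(120L, 50L),
      hhq_i = c(60L, 20L), hhq_i_ce = c(30L, 8L), genes_ce = c(10L, 4L))
}

small_config <- function(seed = 7L, ...) {
  sim_config(seed = seed, chrom_lengths = c(Ca1 = 5e6, Ca2 = 3e6),
             planted_tier_counts = small_tier_counts(),
             n_unanchored = 20L, ...)
}

# random variant records shaped like read_vcf() output
random_records <- function(n, seed = 1L, chroms = c("Ca1", "Ca2", "sc1")) {
  withr::with_seed(seed, {
    gt_pool <- c("0/0", "0/1", "1/1", "./.")
    gt1 <- sample(gt_pool, n, replace = TRUE)
    gt2 <- sample(gt_pool, n, replace = TRUE)
    p1 <- lapply(strsplit(gt1, "/"), function(x)
      suppressWarnings(as.integer(x)))
    p2 <- lapply(strsplit(gt2, "/"), function(x)
      suppressWarnings(as.integer(x)))
    d <- tdf(
      chrom = sample(chroms, n, replace = TRUE),
      pos = sample.int(1e6, n),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt_index = 1L,
      filter = sample(c("PASS", ".", "q10", "q10;lowQD", "a;b;c"), n,
                      replace = TRUE),
      gt1_a = vapply(p1, `[`, NA_integer_, 1),
      gt1_b = vapply(p1, `[`, NA_integer_, 2),
      gt2_a = vapply(p2, `[`, NA_integer_, 1),
      gt2_b = vapply(p2, `[`, NA_integer_, 2),
      dp1 = sample(0:40, n, replace = TRUE),
      dp2 = sample(0:40, n, replace = TRUE))
    d$n_failed <- ifelse(d$filter %in% c("PASS", "."), 0L,
                         lengths(strsplit(d$filter, ";")))
    d$class1 <- niltriage:::gt_class(d$gt1_a, d$gt1_b)
    d$class2 <- niltriage:::gt_class(d$gt2_a, d$gt2_b)
    d$alt <- ifelse(d$alt == d$ref, "N", d$alt)
    d$key <- paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
    d[!duplicated(d$key), ]
  })
}

# one-locus single-transcript model set wrapping a transcript_sequence,
# with optional UTR flanks inside one exon
single_tx_models <- function(txseq, utr5 = 50L, utr3 = 50L) {
  gp <- range(txseq$genomic_pos)
  tdfm <- function(...) data.frame(..., stringsAsFactors = FALSE)
  gene_model_set(
    tdfm(locus_id = "L1", chrom = "demo", start = max(1, gp[1] - utr5 - 200),
         end = gp[2] + utr3 + 200, strand = txseq$strand, biotype = "mRNA"),
    tdfm(tx_id = txseq$tx_id, locus_id = "L1", chrom = "demo",
         start = max(1, gp[1] - utr5 - 200), end = gp[2] + utr3 + 200,
         strand = txseq$strand),
    tdfm(tx_id = txseq$tx_id, locus_id = "L1", chrom = "demo",
         start = gp[1] - utr5, end = gp[2] + utr3),
    tdfm(tx_id = txseq$tx_id, locus_id = "L1", chrom = "demo",
         start = gp[1], end = gp[2]))
}
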