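test_that("interval classification equals the exhaustive scan over the toy annotation", {
  m <- toy_models()
  pos <- seq(1, 100000, by = 7) # dense systematic sweep of the 100-kb toy
  rec <- tdf(chrom = "toy", pos = pos, ref = "A", alt = "T",
             key = paste0("toy:", pos, ":A:T"))
  got <- assign_loci(rec, m)
  want <- region_scan_oracle(m, "toy", pos)
  gk <- paste(got$pos, got$locus_id, got$region)
  wk <- paste(want$pos, want$locus_id, want$region)
  expect_setequal(gk, wk)
  # positions outside all spans have no assignment
  outside <- setdiff(pos, want$pos)
  expect_false(any(got$pos %in% outside))
})

test_that("region precedence CDS > EXON > INTRON is total across isoforms", {
  m <- toy_models()
  v <- function(p) list(chrom = "toy", pos = p, ref = "A")
  expect_equal(classify_region(v(1600), "L1", m), "CDS")    # CDS of both isoforms
  expect_equal(classify_region(v(1100), "L1", m), "EXON")   # 5' UTR exon
  expect_equal(classify_region(v(2500), "L1", m), "INTRON") # intron of t1 only
  # 3500 is exonic+coding in t1 but intronic in t2: CDS wins across isoforms
  expect_equal(classify_region(v(3500), "L1", m), "CDS")
  expect_equal(classify_region(v(7000), "L1", m), "EXON")   # 3' UTR region
  expect_equal(classify_region(v(13000), "L2", m), "LNCRNA")
  expect_equal(classify_region(v(50100), "L6", m), "SNORNA")
  expect_equal(classify_region(v(61000), "L7", m), "PSEUDO_MISC")
  expect_equal(classify_region(v(70040), "L8", m), "TRNA")
  expect_error(classify_region(v(99999), "L1", m), "overlap")
})

test_that("deletions classify by the highest-precedence region their footprint touches", {
  m <- toy_models()
  # footprint 1990..2052 spans CDS end of exon 1 into the intron
  v <- list(chrom = "toy", pos = 1990,
            ref = paste(rep("A", 63), collapse = ""))
  expect_equal(classify_region(v, "L1", m), "CDS")
  # footprint entirely intronic
  v2 <- list(chrom = "toy", pos = 2200, ref = "AAAA")
  expect_equal(classify_region(v2, "L1", m), "INTRON")
  # bulk path uses the same footprint rule
  rec <- tdf(chrom = "toy", pos = c(1990, 2200),
             ref = c(v$ref, "AAAA"), alt = "A",
             key = c("k1", "k2"))
  a <- assign_loci(rec, m)
  expect_equal(a$region[a$key == "k1"], "CDS")
  expect_equal(a$region[a$key == "k2"], "INTRON")
})

test_that("a complement-strand locus at Ca5:36,011,384-36,016,600 parses with strand -", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste("Ca5", "test", "gene", "36011384", "36016600", ".", "-", ".",
          "ID=LOCTEST;gene_biotype=mRNA", sep = "\t"),
    paste("Ca5", "test", "mRNA", "36011384", "36016600", ".", "-", ".",
          "ID=LOCTEST.t1;Parent=LOCTEST", sep = "\t"),
    paste("Ca5", "test", "exon", "36011384", "36016600", ".", "-", ".",
          "Parent=LOCTEST.t1", sep = "\t"),
    paste("Ca5", "test", "CDS", "36012000", "36016500", ".", "-", "0",
          "Parent=LOCTEST.t1", sep = "\t")), path)
  m <- read_gff3(path)
  expect_equal(m$loci$strand, "-")
  expect_equal(m$loci$start, 36011384)
  expect_equal(m$loci$end, 36016600)
})

test_that("variants in overlapping opposite-strand loci get two assignments", {
  m <- toy_models()
  # 40900 lies in L4's first CDS segment and in L5's non-coding exon
  rec <- tdf(chrom = "toy", pos = 40900, ref = "A", alt = "T", key = "dual")
  a <- assign_loci(rec, m)
  expect_equal(nrow(a), 2L)
  expect_setequal(a$locus_id, c("L4", "L5"))
  expect_equal(a$region[a$locus_id == "L4"], "CDS")
  expect_equal(a$region[a$locus_id == "L5"], "EXON")
  expect_equal(cds_exon_both_tally(a),
               list(n_cds_only = 0L, n_exon_only = 0L, n_both = 1L))
})

test_that("the CDS/exon/both tally conserves the HHQ-I-C/E total", {
  m <- toy_models()
  withr::with_seed(31, {
    pos <- sample(1000:46000, 400)
    rec <- tdf(chrom = "toy", pos = pos, ref = "A", alt = "T",
               key = paste0("toy:", pos))
    a <- assign_loci(rec, m)
    tal <- cds_exon_both_tally(a)
    n_ce <- length(unique(a$key[a$region %in% c("CDS", "EXON")]))
    expect_equal(tal$n_cds_only + tal$n_exon_only + tal$n_both, n_ce)
  })
  # a single-locus annotation can never produce "both"
  one <- toy_models()
  keep <- one$loci$locus_id == "L1"
  one <- gene_model_set(one$loci[keep, ],
                        one$transcripts[one$transcripts$locus_id == "L1", ],
                        one$exons[one$exons$locus_id == "L1", ],
                        one$cds[one$cds$locus_id == "L1", ])
  pos <- seq(1000, 9000, by = 13)
  rec <- tdf(chrom = "toy", pos = pos, ref = "A", alt = "T",
             key = paste0("k", pos))
  expect_equal(cds_exon_both_tally(assign_loci(rec, one))$n_both, 0L)
})

test_that("model validation rejects orphans and CDS outside exons", {
  m <- toy_models()
  bad_cds <- rbind(m$cds, tdf(tx_id = "L1.t1", locus_id = "L1",
                              chrom = "toy", start = 2500, end = 2600))
  expect_error(gene_model_set(m$loci, m$transcripts, m$exons, bad_cds),
               "outside exons")
  bad_tx <- rbind(m$transcripts,
                  tdf(tx_id = "ghost.t1", locus_id = "NOPE", chrom = "toy",
                      start = 1, end = 10, strand = "+"))
  expect_error(gene_model_set(m$loci, bad_tx, m$exons, m$cds), "orphan")
})
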