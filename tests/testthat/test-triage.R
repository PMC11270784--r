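test_that("depth filter keeps records iff both samples reach the threshold", {
  rec <- random_records(4)
  rec$dp1 <- c(9L, 10L, 50L, NA)
  rec$dp2 <- c(50L, 10L, 9L, 20L)
  out <- suppressWarnings(filter_depth(rec))
  expect_equal(out$key, rec$key[2])
  expect_equal(attr(out, "n_missing_dp"), 1L)
  expect_warning(filter_depth(rec), "missing DP")
})

test_that("depth and quality filters match a brute-force scan on random records", {
  rec <- random_records(1000, seed = 42)
  cfg <- triage_config()
  keep_depth <- vapply(seq_len(nrow(rec)), function(i) {
    !is.na(rec$dp1[i]) && !is.na(rec$dp2[i]) &&
      min(rec$dp1[i], rec$dp2[i]) >= 10
  }, logical(1))
  expect_equal(suppressWarnings(filter_depth(rec, cfg))$key,
               rec$key[keep_depth])
  keep_q <- vapply(seq_len(nrow(rec)), function(i) {
    f <- rec$filter[i]
    n <- if (f %in% c("PASS", ".")) 0L else
      length(strsplit(f, ";")[[1]])
    n <= 1L
  }, logical(1))
  expect_equal(filter_quality(rec, cfg)$key, rec$key[keep_q])
})

test_that("depth and quality filters commute", {
  rec <- random_records(500, seed = 9)
  cfg <- triage_config()
  a <- suppressWarnings(filter_quality(filter_depth(rec, cfg), cfg))
  b <- suppressWarnings(filter_depth(filter_quality(rec, cfg), cfg))
  expect_equal(a$key, b$key)
})

test_that("contrasting-homozygous selection follows the between-NIL variant definition", {
  rec <- random_records(5)
  rec$chrom <- c("Ca1", "Ca1", "Ca1", "sc1", "Ca1")
  g <- list(c(0L, 0L, 1L, 1L),   # 0/0 vs 1/1: contrast, keep
            c(0L, 1L, 1L, 1L),   # het in sample 1: drop
            c(1L, 1L, 1L, 1L),   # identical hom-alt: no contrast
            c(0L, 0L, 1L, 1L),   # contrast but unanchored: drop
            c(NA, NA, 1L, 1L))   # missing genotype: drop, tallied
  for (i in 1:5) {
    rec$gt1_a[i] <- g[[i]][1]; rec$gt1_b[i] <- g[[i]][2]
    rec$gt2_a[i] <- g[[i]][3]; rec$gt2_b[i] <- g[[i]][4]
  }
  rec$class1 <- niltriage:::gt_class(rec$gt1_a, rec$gt1_b)
  rec$class2 <- niltriage:::gt_class(rec$gt2_a, rec$gt2_b)
  out <- select_contrasting_homozygous(rec, triage_config())
  expect_equal(out$key, rec$key[1])
  expect_equal(attr(out, "n_missing_gt"), 1L)
})

test_that("tier report validates nesting and totals equal column sums", {
  rec <- random_records(50, chroms = c("Ca1", "Ca2"))
  tiers <- list(detected = rec, hq = rec[1:30, ], hhq = rec[1:20, ],
                hhq_i = rec[1:10, ], hhq_i_ce = rec[1:4, ])
  asg <- data.frame(key = rec$key[1:10], chrom = rec$chrom[1:10],
                    pos = rec$pos[1:10], ref = rec$ref[1:10],
                    alt = rec$alt[1:10],
                    locus_id = paste0("G", c(1, 1, 2, 2, 3, 4, 5, 6, 7, 8)),
                    biotype = "mRNA",
                    region = c(rep("CDS", 4), rep("INTRON", 6)))
  cfg <- triage_config(chromosome_set = c("Ca1", "Ca2"))
  rep <- tier_report(tiers, asg, cfg)
  tot <- rep[rep$chrom == "TOTAL", -1]
  expect_equal(unlist(tot), colSums(rep[rep$chrom != "TOTAL", -1]),
               ignore_attr = TRUE)
  expect_true(all(diff(t(as.matrix(
    rep[, c("detected", "hq", "hhq", "hhq_i", "hhq_i_ce")]))) <= 0))

  # a non-nested "subset" is an internal consistency error
  bad <- tiers
  bad$hq <- rec[31:40, ]
  expect_error(tier_report(bad, asg, cfg), "not a subset")
})

test_that("window densities bin by [k*W+1, (k+1)*W], conserve counts and flag hotspots", {
  cfg <- triage_config(window_bp = 1000L, hotspot_threshold = 200L)
  lens <- c(Ca1 = 10000)
  rec <- tdf(chrom = "Ca1", pos = c(1, 1000, 1001, 9999),
             key = paste0("k", 1:4))
  wd <- window_density(rec, lens, cfg)
  expect_equal(wd$count[1], 2L)  # positions 1 and 1000 in window 1
  expect_equal(wd$count[2], 1L)  # position 1001 opens window 2
  expect_equal(sum(wd$count), nrow(rec))

  # 250 variants in one window, 10 elsewhere: exactly that window flagged
  rec2 <- tdf(chrom = "Ca1",
              pos = c(3000 + seq_len(250) %% 1000, seq_len(10) * 7),
              key = paste0("r", 1:260))
  wd2 <- window_density(rec2, lens, cfg)
  expect_equal(wd2$win_start[wd2$hotspot], 3001)
  expect_equal(sum(wd2$count), 260L)

  hi <- hotspot_intervals(wd2)
  expect_equal(nrow(hi), 1L)
  expect_equal(c(hi$start, hi$end), c(3001, 4000))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_hotspots_bed(hi, bed)
  expect_equal(readLines(bed), "Ca1\t3000\t4000")

  expect_error(
    window_density(tdf(chrom = "Ca1", pos = 10001), lens, cfg),
    "beyond chromosome")
  # conservation on random input
  rr <- random_records(500, seed = 3, chroms = "Ca1")
  rr$pos <- sample.int(10000, nrow(rr))
  expect_equal(sum(window_density(rr, lens, cfg)$count), nrow(rr))
})

test_that("observed heterozygosity reproduces the NIL percentages", {
  expect_equal(observed_heterozygosity(209276, 393670345)$percent, 0.053)
  expect_equal(observed_heterozygosity(200084, 393670345)$percent, 0.051)
  expect_equal(observed_heterozygosity(0, 1000)$percent, 0)
  expect_error(observed_heterozygosity(5, 4), "exceed")
  expect_error(observed_heterozygosity(1, 0))
})

test_that("selfing expectation halves per generation and matches the pedigree value", {
  expect_equal(expected_selfing_heterozygosity(selfing_model(n_halvings = 0)),
               100)
  expect_equal(
    expected_selfing_heterozygosity(selfing_model(n_generations = 11)),
    0.098)
  vals <- vapply(1:20, function(h)
    expected_selfing_heterozygosity(selfing_model(n_halvings = h),
                                    digits = NULL), numeric(1))
  expect_true(all(vals[-1] / vals[-20] == 0.5))
  expect_error(selfing_model(n_halvings = -1), "non-negative")
})
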