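mk_refs <- function(S = 51) reference_haplotypes(rep(0L, S), rep(1L, S))

test_that("haplotype groups follow the H1 > H2 > H3 > H4 precedence rules", {
  S <- 51
  refs <- mk_refs(S)
  rows <- rbind(
    H1 = rep(0L, S),
    H2 = rep(1L, S),
    H3 = c(1L, rep(0L, S - 1)),                    # one mismatch to hapL
    H4 = c(rep(0L, 36), rep(1L, 15)),              # 36/51 like hapL
    OTHER = c(rep(0L, 20), rep(1L, 31)))           # 20/51: below the band
  lab <- assign_haplotype_groups(rows, refs)
  expect_equal(as.character(lab), c("H1", "H2", "H3", "H4", "OTHER"))
  expect_equal(unname(attr(lab, "match_frac")[4]), 36 / 51)
})

test_that("missing calls are ignored and low call-rate excludes the accession", {
  refs <- mk_refs(10)
  rows <- rbind(
    ok = c(rep(0L, 8), NA, NA),         # 8/10 called, all match hapL
    low = c(0L, 0L, rep(NA, 8)))        # 20% call rate: excluded
  lab <- assign_haplotype_groups(rows, refs)
  expect_equal(as.character(lab), c("H1", NA))
  expect_equal(attr(lab, "n_excluded"), 1L)
})

test_that("group frequencies reproduce the pangenome percentages", {
  labels <- factor(rep(c("H1", "H2", "H3", "H4", "OTHER"),
                       c(2219, 749, 120, 63, 20)),
                   levels = c("H1", "H2", "H3", "H4", "OTHER"))
  f <- group_frequencies(labels)
  expect_equal(f$percent[f$group == "H1"], 70.0)
  expect_equal(f$percent[f$group == "H2"], 23.6)
  expect_equal(sum(f$proportion), 1, tolerance = 1e-12)
  single <- group_frequencies(factor("H3", levels = levels(labels)))
  expect_equal(single$percent[single$group == "H3"], 100)
  expect_equal(sum(single$n), 1L)
})

test_that("summary t-test matches a raw-data Student t-test", {
  withr::with_seed(13, {
    for (i in 1:20) {
      x <- rnorm(sample(5:40, 1), mean = runif(1, 0, 100),
                 sd = runif(1, 0.5, 10))
      y <- rnorm(sample(5:40, 1), mean = runif(1, 0, 100),
                 sd = runif(1, 0.5, 10))
      got <- summary_ttest(mean(x), sd(x), length(x),
                           mean(y), sd(y), length(y))
      want <- t.test(x, y, var.equal = TRUE)
      expect_equal(got$t, unname(want$statistic), tolerance = 1e-10)
      expect_equal(got$p, want$p.value, tolerance = 1e-10)
      expect_equal(got$df, unname(want$parameter))
    }
  })
})

test_that("the phenotype-table DTF contrast is three-star significant", {
  tt <- summary_ttest(44.4, 2.8, 15, 58.0, 1.1, 15)
  expect_equal(tt$stars, "***")
  expect_equal(tt$df, 28)
  same <- summary_ttest(50, 2, 10, 50, 2, 10)
  expect_equal(same$t, 0)
  expect_equal(same$stars, "ns")
  degenerate <- summary_ttest(1, 0, 5, 2, 0, 5)
  expect_equal(degenerate$p, 0)
  expect_true("zero_variance" %in% degenerate$flags)
  flat <- summary_ttest(3, 0, 5, 3, 0, 5)
  expect_equal(flat$stars, "ns")
})

test_that("significance stars follow the printed thresholds", {
  expect_equal(niltriage:::star_category(c(0.2, 0.05, 0.04, 0.01, 0.009,
                                           0.001, 1e-6)),
               c("ns", "*", "*", "**", "**", "***", "***"))
})

test_that("DTF comparison has calibrated power on planted effects", {
  withr::with_seed(99, {
    # delta = 5 days, sd = 4, n = 200/group: analytic power ~ 1
    rejected <- 0L
    for (i in 1:50) {
      tt <- summary_ttest(mean(rnorm(200, 60, 4)), 4, 200,
                          mean(rnorm(200, 65, 4)), 4, 200)
      rejected <- rejected + (tt$p <= 0.05)
    }
    expect_gte(rejected, 50L * 0.99)
  })
})

test_that("dtf_compare contrasts groups within one location", {
  pheno <- tdf(
    accession = rep(paste0("a", 1:40), 2),
    location = rep(c("LOC_A", "LOC_B"), each = 40),
    dtf = c(rep(50, 20), rep(60, 20), rep(55, 40)) + rep(c(0, 0.5), 40))
  groups <- setNames(rep(c("H1", "H2"), each = 20), paste0("a", 1:40))
  cmp <- dtf_compare(pheno, groups, "LOC_A")
  expect_true(cmp$computable)
  expect_equal(cmp$ttest$stars, "***")
  expect_equal(unname(cmp$n), c(20L, 20L))
  expect_equal(cmp$global_mean, mean(pheno$dtf[pheno$location == "LOC_A"]))
  # a group empty in the location is flagged not computable
  g2 <- setNames(rep(c("H1", "H3"), each = 20), paste0("a", 1:40))
  cmp2 <- dtf_compare(pheno, g2, "LOC_A")
  expect_false(cmp2$computable)
  expect_error(dtf_compare(tdf(accession = "a", location = "L", dtf = -1),
                           groups, "L"), "positive")
})

test_that("single-SNP grouping keeps only homozygous calls", {
  g <- snp_groups(c("0/0", "1/1", "0/1", "./.", "0|0"))
  expect_equal(as.character(g), c("ref", "alt", NA, NA, "ref"))
  gn <- snp_groups(c(0, 2, 1, NA))
  expect_equal(as.character(gn), c("ref", "alt", NA, NA))
  gh <- snp_groups(c(0L, 1L, 0L)) # haploid-style coding
  expect_equal(as.character(gh), c("ref", "alt", "ref"))
})

test_that("branching index is the branch-to-plant length ratio", {
  expect_equal(branching_index(0, 50), 0)
  expect_equal(branching_index(72.5, 72.5), 1)
  expect_error(branching_index(10, 0), "positive")
  # groups generated at the phenotype-table index means are recovered
  withr::with_seed(12, {
    early <- branching_index(rnorm(15, 1.25 * 52.5, 8), 52.5)
    late <- branching_index(rnorm(15, 6.01 * 66.6, 30), 66.6)
    expect_equal(mean(early), 1.25, tolerance = 0.15)
    expect_equal(mean(late), 6.01, tolerance = 0.15)
    expect_equal(summary_ttest(mean(early), sd(early), 15,
                               mean(late), sd(late), 15)$stars, "***")
  })
})
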