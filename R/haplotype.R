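# Haplotype-group assignment of germplasm accessions relative to the two NIL
# reference haplotypes, group frequencies, and Student t-tests on
# days-to-flowering (raw data or summary statistics), plus the branching
# index used in plant phenotyping.

#' Reference haplotypes of the NIL pair
#'
#' @param hapL allele vector (0 = reference allele, 1 = alternate) of the
#'   late-flowering line over the defining sites.
#' @param hapE allele vector of the early-flowering line, same site order.
#' @return list of class `reference_haplotypes`.
#' @export
reference_haplotypes <- function(hapL, hapE) {
  if (length(hapL) != length(hapE))
    stop("hapL and hapE must cover the same sites")
  if (!any(hapL != hapE))
    stop("reference haplotypes must differ at >= 1 site")
  structure(list(hapL = as.integer(hapL), hapE = as.integer(hapE)),
            class = "reference_haplotypes")
}

#' Assign accessions to haplotype groups
#'
#' Compares each accession's calls over the defining sites with the two NIL
#' haplotypes. With precedence H1 > H2 > H3 > H4: H1 matches the
#' late-line haplotype at every called site; H2 matches the early-line
#' haplotype at every called site; H3 differs from the late haplotype at
#' exactly one called site; H4 has a match fraction to the late haplotype
#' within the intermediate band (default [0.6, 1)); everything else is
#' OTHER. Missing calls are ignored in the match computation; accessions
#' called at fewer than `min_call_rate` of the sites are excluded (label
#' `NA`) and tallied in the `"n_excluded"` attribute.
#'
#' @param geno accessions x sites matrix of allele indices (0 = ref,
#'   1 = alt, `NA` = missing), rownames = accession ids.
#' @param refs a [reference_haplotypes()] in the same site order.
#' @param min_call_rate minimum fraction of called sites (default 0.8).
#' @param intermediate_band numeric(2), half-open match-fraction band
#'   `[lo, hi)` defining H4 (default `c(0.6, 1)`).
#' @return factor of labels (levels H1, H2, H3, H4, OTHER; `NA` for
#'   excluded accessions) with attributes `match_frac` (fraction of called
#'   sites matching the late haplotype) and `n_excluded`.
#' @export
assign_haplotype_groups <- function(geno, refs, min_call_rate = 0.8,
                                    intermediate_band = c(0.6, 1)) {
  stopifnot(inherits(refs, "reference_haplotypes"))
  geno <- as.matrix(geno)
  if (ncol(geno) != length(refs$hapL))
    stop("genotype matrix and reference haplotypes disagree on site count")
  called <- !is.na(geno)
  n_called <- rowSums(called)
  eligible <- n_called >= min_call_rate * ncol(geno) & n_called > 0
  mL <- rowSums(sweep(geno, 2, refs$hapL, `==`), na.rm = TRUE)
  mE <- rowSums(sweep(geno, 2, refs$hapE, `==`), na.rm = TRUE)
  frac <- ifelse(n_called > 0, mL / n_called, NA_real_)

  lab <- rep(NA_character_, nrow(geno))
  lab[eligible & mL == n_called] <- "H1"
  lab[eligible & is.na(lab) & mE == n_called] <- "H2"
  lab[eligible & is.na(lab) & (n_called - mL) == 1] <- "H3"
  lab[eligible & is.na(lab) & frac >= intermediate_band[1] &
        frac < intermediate_band[2]] <- "H4"
  lab[eligible & is.na(lab)] <- "OTHER"

  out <- factor(lab, levels = c("H1", "H2", "H3", "H4", "OTHER"))
  names(out) <- rownames(geno)
  attr(out, "match_frac") <- frac
  attr(out, "n_excluded") <- sum(!eligible)
  out
}

#' Haplotype group frequencies
#'
#' Proportions per group over labeled (non-excluded) accessions; they sum
#' to 1. `percent` reports them to one decimal in percent.
#'
#' @param labels factor of group labels (as from
#'   [assign_haplotype_groups()]).
#' @return data.frame `group`, `n`, `proportion`, `percent`.
#' @export
group_frequencies <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) stop("no labeled accessions")
  t <- table(labels)
  data.frame(group = names(t), n = as.integer(t),
             proportion = as.numeric(t) / length(labels),
             percent = round(100 * as.numeric(t) / length(labels), 1),
             stringsAsFactors = FALSE)
}

#' Student t-test from summary statistics
#'
#' Pooled-variance two-sided Student t-test with
#' `df = n1 + n2 - 2`, computed from group means, SDs and sizes; the
#' significance stars follow the phenotype-table convention
#' (`*` 0.01 < P <= 0.05, `**` 0.001 < P <= 0.01, `***` P <= 0.001).
#' With zero pooled variance the result is `ns` with t = 0 for equal means,
#' and p = 0 flagged `"zero_variance"` for unequal means.
#'
#' @param mean1,sd1,n1 first group summary (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 second group summary.
#' @return list of class `ttest_result`: group summaries, `t`, `df`, `p`,
#'   `stars`, `flags`.
#' @export
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  flags <- character(0)
  if (sp2 == 0) {
    if (mean1 == mean2) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean1 - mean2) * Inf; p <- 0
      flags <- "zero_variance"
    }
  } else {
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(mean1 = mean1, sd1 = sd1, n1 = n1,
                 mean2 = mean2, sd2 = sd2, n2 = n2,
                 t = t, df = df, p = p, stars = star_category(p),
                 flags = flags),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf(
    "Student t-test: %.3g +/- %.3g (n=%d) vs %.3g +/- %.3g (n=%d)\n",
    x$mean1, x$sd1, x$n1, x$mean2, x$sd2, x$n2))
  cat(sprintf("  t = %.4g, df = %d, p = %.3g  [%s]\n",
              x$t, x$df, x$p, x$stars))
  invisible(x)
}

#' Group accessions by a single SNP's homozygous calls
#'
#' Maps per-accession diploid calls at one site to `"ref"`/`"alt"` groups,
#' excluding heterozygous and missing calls (`NA`). Accepts allele-index
#' strings ("0/0", "1/1", "0/1", "./.") or numeric alternate-allele dosages
#' (0, 1, 2 or 0/1 haploid-style calls).
#'
#' @param calls vector of genotype calls.
#' @return factor with levels `ref`, `alt`.
#' @export
snp_groups <- function(calls) {
  if (is.numeric(calls)) {
    lab <- ifelse(is.na(calls), NA_character_,
           ifelse(calls == 0, "ref",
           ifelse(calls == max(1, max(calls, na.rm = TRUE)), "alt",
                  NA_character_)))
    # dosage 1 (het) drops out; haploid 0/1 coding maps 1 -> alt
  } else {
    g <- .parse_gt(as.character(calls))
    lab <- ifelse(is.na(g$a) | is.na(g$b), NA_character_,
           ifelse(g$a != g$b, NA_character_,
           ifelse(g$a == 0, "ref", "alt")))
  }
  factor(lab, levels = c("ref", "alt"))
}

#' Compare days-to-flowering between two groups in one location
#'
#' Two-group Student t-test (pooled variance) on raw DTF values for one
#' location/season, with the group means and global mean needed for a
#' density-plot summary. Groups may be haplotype labels from
#' [assign_haplotype_groups()] or single-SNP groups from [snp_groups()].
#'
#' @param pheno data.frame with columns `accession`, `location`, `dtf`.
#' @param groups per-accession label vector, named by accession (or in
#'   `pheno` accession order).
#' @param location the location/season label to analyse.
#' @param pair character(2): the two group labels to contrast (default
#'   H1 vs H2).
#' @return list of class `dtf_comparison`: `location`, `pair`, `ttest` (a
#'   `ttest_result`, or `NULL` when a group is empty), `group_means`,
#'   `global_mean`, `n`; `computable` is FALSE when a group has fewer than
#'   2 observations in the location.
#' @export
dtf_compare <- function(pheno, groups, location, pair = c("H1", "H2")) {
  stopifnot(all(c("accession", "location", "dtf") %in% names(pheno)),
            length(pair) == 2L)
  if (any(pheno$dtf <= 0, na.rm = TRUE)) stop("DTF must be positive")
  sel <- pheno$location == location
  d <- pheno[sel, , drop = FALSE]
  g <- if (!is.null(names(groups))) groups[as.character(d$accession)]
  else if (length(groups) == nrow(pheno)) groups[sel]
  else stop("groups must be named by accession or parallel to pheno rows")
  x1 <- d$dtf[!is.na(g) & g == pair[1]]
  x2 <- d$dtf[!is.na(g) & g == pair[2]]
  computable <- length(x1) >= 2 && length(x2) >= 2
  tt <- if (computable)
    summary_ttest(mean(x1), stats::sd(x1), length(x1),
                  mean(x2), stats::sd(x2), length(x2)) else NULL
  structure(list(location = location, pair = pair, ttest = tt,
                 group_means = stats::setNames(
                   c(mean(x1), mean(x2)), pair),
                 global_mean = mean(d$dtf, na.rm = TRUE),
                 n = stats::setNames(c(length(x1), length(x2)), pair),
                 computable = computable),
            class = "dtf_comparison")
}

#' @export
print.dtf_comparison <- function(x, ...) {
  cat(sprintf("DTF %s vs %s at %s (n = %d/%d)\n", x$pair[1], x$pair[2],
              x$location, x$n[1], x$n[2]))
  if (x$computable) print(x$ttest) else cat("  not computable\n")
  invisible(x)
}

#' Branching index
#'
#' Ratio of total branch length to plant length, normalizing branching for
#' overall vigor.
#'
#' @param total_branch_length total branch length (same unit as
#'   `plant_length`).
#' @param plant_length plant length (> 0).
#' @return the index.
#' @export
branching_index <- function(total_branch_length, plant_length) {
  if (any(plant_length <= 0)) stop("plant_length must be positive")
  total_branch_length / plant_length
}
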