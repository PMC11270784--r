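# Independent brute-force oracles used to check the package's fast paths.

# Exact hypergeometric upper tail P(X >= a) computed by direct summation of
# binomial coefficients (independent of stats::fisher.test / phyper).
fisher_tail_oracle <- function(a, b, c, d) {
  s <- a + b          # study size
  k <- a + c          # term total in universe
  N <- a + b + c + d
  xs <- seq(max(0, k - (N - s)), min(k, s))
  xs <- xs[xs >= a]
  if (length(xs) == 0L) return(0)
  sum(choose(k, xs) * choose(N - k, s - xs)) / choose(N, s)
}

# Exhaustive per-position region scan over an annotation: for every given
# position, loop over loci and classify by linear scan of the segment
# tables. Returns data.frame(pos, locus_id, region).
region_scan_oracle <- function(models, chrom, positions) {
  lab <- c(lncRNA = "LNCRNA", rRNA = "RRNA", snRNA = "SNRNA",
           snoRNA = "SNORNA", tRNA = "TRNA", pseudogene = "PSEUDO_MISC",
           misc_RNA = "PSEUDO_MISC")
  out <- list()
  loci <- models$loci[models$loci$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(loci))) {
    lo <- loci[i, ]
    p <- positions[positions >= lo$start & positions <= lo$end]
    if (length(p) == 0L) next
    if (lo$biotype == "mRNA") {
      in_any <- function(seg) {
        seg <- seg[seg$locus_id == lo$locus_id, , drop = FALSE]
        hit <- rep(FALSE, length(p))
        for (j in seq_len(nrow(seg)))
          hit <- hit | (p >= seg$start[j] & p <= seg$end[j])
        hit
      }
      in_cds <- in_any(models$cds)
      in_ex <- in_any(models$exons)
      region <- ifelse(in_cds, "CDS", ifelse(in_ex, "EXON", "INTRON"))
    } else {
      region <- rep(unname(lab[lo$biotype]), length(p))
    }
    out[[length(out) + 1L]] <- data.frame(
      pos = p, locus_id = lo$locus_id, region = region,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(pos = numeric(0), locus_id = character(0),
                      region = character(0)))
  do.call(rbind, out)
}

# Naive O(n^3) agglomerative complete-linkage clustering on the rows of x.
# Returns merge heights (ascending) and the partition after each merge.
naive_complete_linkage <- function(x) {
  n <- nrow(x)
  D <- as.matrix(stats::dist(x))
  groups <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  labels <- seq_len(n)
  while (length(groups) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(groups) - 1L)) {
      for (j in seq(i + 1L, length(groups))) {
        d <- max(D[groups[[i]], groups[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
    heights <- c(heights, best_d)
    part <- integer(n)
    for (g in seq_along(groups)) part[groups[[g]]] <- g
    partitions[[length(partitions) + 1L]] <- part
  }
  list(heights = heights, partitions = partitions)
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
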