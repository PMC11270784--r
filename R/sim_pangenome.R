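# Synthetic germplasm pangenome: accession x SNP genotype matrix over the
# haplotype-defining sites, planted group structure (H1..H4, OTHER) relative
# to the two NIL haplotypes, and per-location days-to-flowering phenotypes
# with a planted group effect in the configured "significant" locations.

#' Simulate a pangenome genotype/phenotype panel
#'
#' Plants the configured number of accessions per haplotype group: H1
#' accessions carry the late-line haplotype at every site; H2 the early-line
#' haplotype; H3 the late haplotype except at one designated site; H4
#' matches the late haplotype at the configured intermediate number of sites
#' (default 36 of 51); OTHER accessions match at 20-50% of sites. Missing
#' calls are planted at the configured rate (capped so that no group's
#' defining pattern can be destroyed). DTF is drawn per accession and
#' location from normals with a planted shift for the early-haplotype group
#' in the significant locations.
#'
#' @param config a [sim_config()].
#' @return list of class `pangenome_sim`: `geno` (accessions x sites integer
#'   matrix, 0 ref / 1 alt / NA missing), `sites` (chrom, pos), `refs`
#'   ([reference_haplotypes()]), `pheno` (accession, location, dtf), `truth`
#'   (accession, group).
#' @export
simulate_pangenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pg <- config$pangenome
  with_seed(child_seed(config$seed, 3L), {
    n <- pg$n_accessions
    S <- pg$n_sites
    hapL <- rep(0L, S)
    hapE <- rep(1L, S)
    refs <- reference_haplotypes(hapL, hapE)

    labels <- sample(rep(names(pg$group_counts), pg$group_counts))
    acc <- sprintf("ACC%05d", seq_len(n))
    geno <- matrix(NA_integer_, n, S, dimnames = list(acc, NULL))

    for (i in seq_len(n)) {
      row <- switch(labels[i],
        H1 = hapL,
        H2 = hapE,
        H3 = { r <- hapL; r[pg$h3_site] <- hapE[pg$h3_site]; r },
        H4 = {
          r <- hapE
          r[sample.int(S, pg$h4_matches)] <- 0L
          r
        },
        OTHER = {
          k <- sample(seq(ceiling(0.2 * S), floor(0.5 * S)), 1)
          r <- hapE
          r[sample.int(S, k)] <- 0L
          r
        })
      # plant missing calls, capped at 10% of sites, never at the single
      # site that defines H3
      n_miss <- min(stats::rbinom(1L, S, pg$missing_rate), floor(0.1 * S))
      if (n_miss > 0L) {
        pool <- if (labels[i] == "H3") setdiff(seq_len(S), pg$h3_site)
          else seq_len(S)
        row[sample(pool, n_miss)] <- NA_integer_
      }
      geno[i, ] <- row
    }

    sites <- data.frame(
      chrom = "Ca1",
      pos = sort(sample(seq(2285600L, 2298900L), S)),
      stringsAsFactors = FALSE)

    locs <- pg$locations
    mu <- pg$dtf$base_mean +
      seq(-1, 1, length.out = length(locs)) * pg$dtf$location_spread
    names(mu) <- locs
    pheno <- do.call(rbind, lapply(locs, function(loc) {
      shift <- ifelse(labels == "H2" & loc %in% pg$sig_locations,
                      pg$dtf$delta, 0)
      data.frame(accession = acc, location = loc,
                 dtf = pmax(1, stats::rnorm(n, mu[[loc]] + shift,
                                            pg$dtf$sd)),
                 stringsAsFactors = FALSE)
    }))

    structure(list(
      geno = geno, sites = sites, refs = refs, pheno = pheno,
      truth = data.frame(accession = acc, group = labels,
                         stringsAsFactors = FALSE)),
      class = "pangenome_sim")
  })
}

#' @export
print.pangenome_sim <- function(x, ...) {
  cat("pangenome_sim:", nrow(x$geno), "accessions x", ncol(x$geno),
      "sites\n")
  print(table(x$truth$group))
  invisible(x)
}
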