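#' Reference chromosome sizes for the simulated chickpea genome
#'
#' Chromosome lengths (bp) of the eight *Cicer arietinum* pseudomolecules
#' Ca1..Ca8 used as the default coordinate system of the synthetic genome.
#'
#' @return named numeric vector of chromosome lengths in bp.
#' @export
nil_chrom_lengths <- function() {
  c(Ca1 = 48360000, Ca2 = 36600000, Ca3 = 39990000, Ca4 = 49190000,
    Ca5 = 48170000, Ca6 = 59460000, Ca7 = 48960000, Ca8 = 16480000)
}

#' Reference per-chromosome triage tier counts
#'
#' The per-chromosome variant counts of the NIL-pair study used as the default
#' planted truth of the synthetic VCF generator: detected variants, high
#' quality (HQ), homozygous high quality (HHQ), intragenic HHQ (HHQ-I),
#' HHQ-I in CDS or exon of mRNA (HHQ-I-C/E), and the number of distinct
#' protein-coding genes carrying at least one HHQ-I-C/E variant.
#'
#' @return data.frame with one row per chromosome.
#' @export
nil_reference_tier_counts <- function() {
  data.frame(
    chrom      = paste0("Ca", 1:8),
    detected   = c(31790L, 7012L, 5311L, 5371L, 6843L, 12594L, 6598L, 1651L),
    hq         = c(23428L, 3774L, 2095L, 2259L, 2936L,  7507L, 2625L,  858L),
    hhq        = c(12585L,  673L,    9L,   23L,  106L,  2232L,   15L,   47L),
    hhq_i      = c( 4185L,  134L,    0L,    4L,   17L,   575L,    3L,   14L),
    hhq_i_ce   = c( 1334L,   35L,    0L,    2L,    4L,   230L,    1L,    4L),
    genes_ce   = c(  165L,   30L,    0L,    2L,    4L,    40L,    1L,    4L),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the fixture generators. The defaults emulate the
#' study conditions of a chickpea early/late-flowering NIL pair: the eight
#' pseudomolecules with their sizes, the per-chromosome triage tier counts
#' planted into the NIL VCF, a 3,171-accession pangenome with haplotype groups
#' H1..H4 defined over 51 SNP sites, and a 132-gene x 7-tissue expression
#' atlas with five planted co-expression clusters.
#'
#' @param seed master integer seed; each submodule (annotation, VCF,
#'   pangenome, expression) derives an independent child stream from it.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param genes_per_chrom named integer vector of loci per chromosome;
#'   default is sized so every chromosome has enough protein-coding loci to
#'   host its planted affected-gene count.
#' @param biotype_mix proportions over gene biotypes (must sum to 1).
#' @param isoforms_per_gene length-2 integer range of mRNA isoform counts.
#' @param planted_tier_counts data.frame as [nil_reference_tier_counts()];
#'   tier columns must weakly decrease left to right within each chromosome.
#' @param het_rate per-sample probability that a read position is
#'   heterozygous (length 1 or 2; default emulates the two NILs' observed
#'   rates of 0.053% and 0.051%).
#' @param n_positions_read total genome positions read in both lines.
#' @param depth_fail_rate fraction (of detected count) of extra records
#'   planted with read depth below threshold in at least one sample.
#' @param n_unanchored extra records placed on unanchored scaffold contigs.
#' @param pangenome list: `n_accessions`, `group_counts` (named H1,H2,H3,H4,
#'   OTHER; overrides `group_proportions` when given), `group_proportions`,
#'   `n_sites`, `h4_matches` (sites matching the late haplotype for H4),
#'   `h3_site` (index of the single mismatching site of H3),
#'   `missing_rate`, `locations`, `sig_locations`, and `dtf` (list with
#'   `base_mean`, `location_spread`, `sd`, `delta` = DTF shift of the early
#'   haplotype group in significant locations, days).
#' @param expression list: `n_genes`, `n_clusters`, `cluster_separation`
#'   (log2 units between cluster profile means), `noise_sd` (log2 units),
#'   `tissues`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = nil_chrom_lengths(),
                       genes_per_chrom = NULL,
                       biotype_mix = c(mRNA = 0.80, lncRNA = 0.06,
                                       rRNA = 0.01, snRNA = 0.02,
                                       snoRNA = 0.01, tRNA = 0.03,
                                       pseudogene = 0.07),
                       isoforms_per_gene = c(1L, 3L),
                       planted_tier_counts = nil_reference_tier_counts(),
                       het_rate = c(5.3e-4, 5.1e-4),
                       n_positions_read = 393670345,
                       depth_fail_rate = 0.05,
                       n_unanchored = 500L,
                       pangenome = list(),
                       expression = list()) {
  if (length(chrom_lengths) == 0 || any(chrom_lengths <= 0))
    stop("chrom_lengths must be positive and non-empty")
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named")
  if (abs(sum(biotype_mix) - 1) > 1e-9)
    stop("biotype_mix must sum to 1")
  if (!all(c("mRNA") %in% names(biotype_mix)))
    stop("biotype_mix must include mRNA")

  tc <- planted_tier_counts
  need <- c("chrom", "detected", "hq", "hhq", "hhq_i", "hhq_i_ce", "genes_ce")
  if (!all(need %in% names(tc))) stop("planted_tier_counts missing columns")
  if (!all(tc$chrom %in% names(chrom_lengths)))
    stop("planted_tier_counts chromosomes not in chrom_lengths")
  mono <- with(tc, detected >= hq & hq >= hhq & hhq >= hhq_i &
                   hhq_i >= hhq_i_ce & hhq_i_ce >= 0 & genes_ce <= hhq_i_ce)
  if (!all(mono))
    stop("tier counts must weakly decrease across tiers per chromosome")

  if (is.null(genes_per_chrom)) {
    genes_per_chrom <- pmax(
      ceiling(tc$genes_ce / unname(biotype_mix["mRNA"])) + 20L, 40L)
    names(genes_per_chrom) <- tc$chrom
    # chromosomes with no planted tier row still get a default complement
    extra <- setdiff(names(chrom_lengths), tc$chrom)
    if (length(extra))
      genes_per_chrom[extra] <- 40L
  }
  if (!all(names(chrom_lengths) %in% names(genes_per_chrom)))
    stop("genes_per_chrom must cover every chromosome")

  pg_default <- list(
    n_accessions = 3171L,
    group_counts = c(H1 = 2219L, H2 = 749L, H3 = 120L, H4 = 63L, OTHER = 20L),
    group_proportions = NULL,
    n_sites = 51L,
    h4_matches = 36L,
    h3_site = 26L,
    missing_rate = 0.01,
    locations = c("ICARDA_2015_16", "ICRISAT_2015_16", "RARI_2014_15",
                  "ICARDA_2014_15", "ICRISAT_2014_15", "RARI_2015_16"),
    sig_locations = c("ICARDA_2015_16", "ICRISAT_2015_16", "RARI_2014_15"),
    dtf = list(base_mean = 70, location_spread = 8, sd = 10, delta = -6)
  )
  pg <- utils::modifyList(pg_default, pangenome)
  if (!is.null(pg$group_proportions)) {
    if (abs(sum(pg$group_proportions) - 1) > 1e-9)
      stop("group_proportions must sum to 1")
    pg$group_counts <- alloc_counts(pg$n_accessions, pg$group_proportions)
  }
  if (sum(pg$group_counts) != pg$n_accessions)
    stop("group counts must sum to n_accessions")
  if (pg$n_sites < 2L)
    stop("pangenome n_sites must be at least 2")
  if (pg$h4_matches >= pg$n_sites || pg$h4_matches < 1L)
    stop("h4_matches must lie strictly between 0 and n_sites")

  ex_default <- list(
    n_genes = 132L, n_clusters = 5L, cluster_separation = 4, noise_sd = 0.5,
    tissues = c("YL", "ML", "SAM", "FB1", "FB2", "FB3", "FB4")
  )
  ex <- utils::modifyList(ex_default, expression)
  if (length(ex$tissues) == 0) stop("expression tissues must be non-empty")
  if (ex$n_clusters < 1L) stop("n_clusters must be >= 1")
  if (ex$n_clusters > ex$n_genes) stop("n_clusters cannot exceed n_genes")

  if (!length(het_rate) %in% 1:2 || any(het_rate < 0 | het_rate > 1))
    stop("het_rate must be one or two probabilities")
  if (length(het_rate) == 1L) het_rate <- rep(het_rate, 2L)

  structure(list(
    seed = as.integer(seed),
    chrom_lengths = chrom_lengths,
    genes_per_chrom = genes_per_chrom,
    biotype_mix = biotype_mix,
    isoforms_per_gene = as.integer(isoforms_per_gene),
    planted_tier_counts = tc,
    het_rate = het_rate,
    n_positions_read = n_positions_read,
    depth_fail_rate = depth_fail_rate,
    n_unanchored = as.integer(n_unanchored),
    pangenome = pg,
    expression = ex
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", length(x$chrom_lengths), "chromosomes,",
      sum(x$genes_per_chrom[names(x$chrom_lengths)]), "loci,",
      sum(x$planted_tier_counts$detected), "planted detected variants\n")
  cat("  pangenome:", x$pangenome$n_accessions, "accessions x",
      x$pangenome$n_sites, "sites\n")
  cat("  expression:", x$expression$n_genes, "genes x",
      length(x$expression$tissues), "tissues,",
      x$expression$n_clusters, "clusters\n")
  invisible(x)
}
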