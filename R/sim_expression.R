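# Synthetic gene x tissue FPKM atlas with planted co-expression clusters.
# Cluster profiles are distinct binary on/off patterns over tissues scaled
# by the separation parameter in log2 space; gene profiles add Gaussian
# log-space noise, so FPKM values are strictly positive.

#' Simulate a gene x tissue FPKM matrix with planted clusters
#'
#' Draws one profile per cluster as a distinct even-parity binary pattern
#' over the tissues (any two patterns differ in at least two tissues, so
#' cluster means are separated by at least `cluster_separation * sqrt(2)` in
#' log2 space) and genes as noisy copies of their cluster profile.
#'
#' @param config a [sim_config()].
#' @return list of class `expression_sim`: `fpkm` (matrix), `truth` (named
#'   integer vector of planted cluster ids).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ex <- config$expression
  with_seed(child_seed(config$seed, 4L), {
    nt <- length(ex$tissues)
    k <- ex$n_clusters
    # even-parity binary patterns over tissues: pairwise Hamming >= 2
    pool_size <- 2^(nt - 1)
    if (k > pool_size)
      stop("too many clusters for the tissue count")
    patterns <- matrix(0L, k, nt)
    idx <- sample.int(pool_size, k)
    for (j in seq_len(k)) {
      bits <- as.integer(intToBits(idx[j] - 1L))[seq_len(nt - 1)]
      patterns[j, ] <- c(bits, sum(bits) %% 2L)
    }
    sizes <- alloc_counts(ex$n_genes, rep(1 / k, k))
    cl <- sample(rep(seq_len(k), sizes))
    base <- 3
    mu <- base + ex$cluster_separation * patterns
    logv <- mu[cl, , drop = FALSE] +
      matrix(stats::rnorm(ex$n_genes * nt, 0, ex$noise_sd), ex$n_genes, nt)
    fpkm <- 2^logv
    genes <- sprintf("SYNEXP_%04d", seq_len(ex$n_genes))
    dimnames(fpkm) <- list(genes, ex$tissues)
    structure(list(fpkm = fpkm,
                   truth = stats::setNames(cl, genes)),
              class = "expression_sim")
  })
}

#' @export
print.expression_sim <- function(x, ...) {
  cat("expression_sim:", nrow(x$fpkm), "genes x", ncol(x$fpkm),
      "tissues,", length(unique(x$truth)), "planted clusters\n")
  invisible(x)
}

#' Generate every synthetic fixture into a directory
#'
#' Runs the four generators (annotation, NIL VCF, pangenome, expression)
#' from one config and writes: `annotation.gff3`, `nil_pair.vcf`,
#' `vcf_truth.tsv`, `genotypes.tsv`, `sites.tsv`, `phenotypes.tsv`,
#' `haplotype_truth.tsv`, `fpkm.tsv`, `expression_truth.tsv`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
simulate_study <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  models <- simulate_annotation(config)
  write_gff3(models, file.path(outdir, "annotation.gff3"))
  vcf <- simulate_nil_vcf(config, models)
  write_vcf(vcf$rows, file.path(outdir, "nil_pair.vcf"),
            contigs = config$chrom_lengths)
  tsv <- function(d, f) utils::write.table(
    d, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(vcf$truth, "vcf_truth.tsv")
  pan <- simulate_pangenome(config)
  gd <- data.frame(accession = rownames(pan$geno), pan$geno,
                   check.names = FALSE)
  names(gd)[-1] <- paste(pan$sites$chrom, pan$sites$pos, sep = ":")
  tsv(gd, "genotypes.tsv")
  tsv(pan$sites, "sites.tsv")
  tsv(pan$pheno, "phenotypes.tsv")
  tsv(pan$truth, "haplotype_truth.tsv")
  expr <- simulate_expression(config)
  write_expression_tsv(expr$fpkm, file.path(outdir, "fpkm.tsv"))
  tsv(data.frame(gene_id = names(expr$truth), cluster = expr$truth),
      "expression_truth.tsv")
  invisible(list(models = models, vcf = vcf, pangenome = pan,
                 expression = expr))
}
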