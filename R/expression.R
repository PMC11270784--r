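# Expression-atlas utilities: FPKM -> TPM conversion, complete-linkage
# Euclidean hierarchical clustering of gene expression profiles, and the
# co-clustered-gene report for candidate loci.

#' Convert an FPKM matrix to TPM
#'
#' `tpm[g, t] = fpkm[g, t] / sum_g' fpkm[g', t] * 1e6`: each tissue column is
#' rescaled to sum to one million, making expression comparable across
#' tissues and genes.
#'
#' @param fpkm non-negative genes x tissues matrix (rownames = gene ids).
#' @return TPM matrix of the same shape.
#' @export
fpkm_to_tpm <- function(fpkm) {
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  cs <- colSums(fpkm)
  zero <- cs == 0
  if (any(zero))
    stop("all-zero tissue column(s): ",
         paste(colnames(fpkm)[zero] %||% which(zero), collapse = ", "))
  sweep(fpkm, 2, cs, `/`) * 1e6
}

#' Cluster expression profiles (complete linkage, Euclidean)
#'
#' Agglomerative hierarchical clustering of gene rows with complete linkage
#' on Euclidean distances, computed on transformed values (default
#' `log2(TPM + 1)`), cut into `k` clusters. Cluster ids are contiguous from
#' 1 in order of first appearance by gene order; merge ties are resolved by
#' the deterministic ordering of [stats::hclust()]. A constant matrix with
#' `k > 1` emits a warning (every merge height is zero and the cut is
#' determined by tie-breaking alone).
#'
#' @param tpm genes x tissues matrix (>= 2 genes).
#' @param k number of clusters (1..n_genes; default 5).
#' @param transform "log2" (default, `log2(x + 1)`), "raw", or "zscore"
#'   (row-standardized log2).
#' @return list of class `expression_clusters` with `assignment` (named
#'   integer vector), `tree` (the `hclust` object), `k`, `transform`.
#' @export
cluster_expression <- function(tpm, k = 5L, transform = c("log2", "raw",
                                                          "zscore")) {
  transform <- match.arg(transform)
  tpm <- as.matrix(tpm)
  if (nrow(tpm) < 2L) stop("need at least 2 genes to cluster")
  if (k < 1L || k > nrow(tpm)) stop("k must be in 1..n_genes")
  x <- switch(transform,
    raw = tpm,
    log2 = log2(tpm + 1),
    zscore = {
      lx <- log2(tpm + 1)
      sds <- apply(lx, 1, stats::sd)
      sds[sds == 0] <- 1
      (lx - rowMeans(lx)) / sds
    })
  d <- stats::dist(x, method = "euclidean")
  if (all(d == 0) && k > 1L)
    warning("constant expression matrix: clusters determined by ties only")
  tree <- stats::hclust(d, method = "complete")
  assignment <- stats::cutree(tree, k = k)
  structure(list(assignment = assignment, tree = tree, k = k,
                 transform = transform),
            class = "expression_clusters")
}

#' @export
print.expression_clusters <- function(x, ...) {
  cat("expression_clusters:", length(x$assignment), "genes in", x$k,
      "clusters (", x$transform, "transform )\n")
  print(table(x$assignment))
  invisible(x)
}

#' Co-clustered-gene report for candidate loci
#'
#' For each candidate gene, lists the full membership of its cluster with
#' optional per-gene variant counts and term annotations, ordered by cluster
#' then gene id. The row count equals the summed sizes of the clusters that
#' contain at least one candidate.
#'
#' @param clusters an [cluster_expression()] result.
#' @param candidate_ids gene ids of interest (must be clustered).
#' @param variant_counts optional named vector of per-gene variant counts.
#' @param annotations optional named character vector (or list) of per-gene
#'   term annotations.
#' @return data.frame `cluster`, `gene_id`, `is_candidate`, `n_variants`,
#'   `terms`.
#' @export
candidate_cluster_report <- function(clusters, candidate_ids,
                                     variant_counts = NULL,
                                     annotations = NULL) {
  stopifnot(inherits(clusters, "expression_clusters"))
  asg <- clusters$assignment
  unknown <- setdiff(candidate_ids, names(asg))
  if (length(unknown))
    stop("unknown candidate id(s): ", paste(unknown, collapse = ", "))
  keep_clusters <- sort(unique(asg[candidate_ids]))
  members <- names(asg)[asg %in% keep_clusters]
  out <- data.frame(
    cluster = unname(asg[members]),
    gene_id = members,
    is_candidate = members %in% candidate_ids,
    n_variants = if (is.null(variant_counts)) NA_integer_ else
      as.integer(variant_counts[members]),
    terms = if (is.null(annotations)) NA_character_ else
      vapply(members, function(g)
        paste(unlist(annotations[g]), collapse = "; "), character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$cluster, out$gene_id, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Read / write gene x tissue expression matrices as TSV
#'
#' @param path TSV with gene ids in the first column and tissue columns.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' @rdname read_expression_tsv
#' @param mat genes x tissues matrix.
#' @export
write_expression_tsv <- function(mat, path) {
  d <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
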