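# GO-term over-representation of variant-bearing genes against a genome
# background, and candidate selection by membership in flowering-associated
# enriched terms. The annotation (gene -> GO-slim terms) and the enriched
# term list are inputs; GO DAG handling is out of scope.

#' Gene-to-term annotation table
#'
#' @param mapping data.frame with columns `gene` and `term` (one row per
#'   gene/term pair).
#' @param universe background gene universe; every annotated gene must be a
#'   member.
#' @return list of class `annotation_table` with `mapping`, `universe` and
#'   `genes_by_term`.
#' @export
annotation_table <- function(mapping, universe) {
  mapping <- as.data.frame(mapping)
  stopifnot(all(c("gene", "term") %in% names(mapping)))
  universe <- unique(as.character(universe))
  extra <- setdiff(unique(mapping$gene), universe)
  if (length(extra))
    stop("annotated gene(s) missing from universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  mapping <- unique(mapping[, c("gene", "term")])
  structure(list(mapping = mapping, universe = universe,
                 genes_by_term = split(mapping$gene, mapping$term)),
            class = "annotation_table")
}

#' Read a two-column gene/term TSV into an annotation table
#'
#' @param path TSV with columns `gene`, `term`.
#' @param universe background gene universe (default: the annotated genes).
#' @return an [annotation_table()].
#' @export
read_annotation_tsv <- function(path, universe = NULL) {
  mapping <- utils::read.delim(path, stringsAsFactors = FALSE)
  annotation_table(mapping, universe %||% unique(mapping$gene))
}

#' One-sided Fisher exact p for over-representation
#'
#' Exact hypergeometric upper tail for the 2x2 table (study genes with term,
#' study genes without, background-only with term, background-only without).
#'
#' @param a,b,c,d non-negative table cells; `a + b` is the study size.
#' @param alternative "greater" (over-representation, default) or
#'   "two.sided".
#' @return the p-value.
#' @export
fisher_p <- function(a, b, c, d, alternative = "greater") {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                     alternative = alternative)$p.value
}

#' Fisher exact GO-term enrichment of a study gene set
#'
#' For every term annotated to at least one study gene, tests
#' over-representation of the term among the study genes against the rest of
#' the gene universe with a one-sided Fisher exact test. No multiple-testing
#' correction is applied by default; Benjamini-Hochberg adjusted p-values
#' are added when `adjust = "BH"`.
#'
#' @param study_genes character vector of study gene ids (must be a subset
#'   of the annotation universe).
#' @param annotation an [annotation_table()].
#' @param alternative passed to [fisher_p()].
#' @param adjust "none" (default) or "BH".
#' @return data.frame with one row per term: `term`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_value` (and `p_adjust` when requested), ordered by
#'   p-value then term.
#' @export
fisher_enrichment <- function(study_genes, annotation,
                              alternative = "greater",
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(annotation, "annotation_table"))
  study_genes <- unique(as.character(study_genes))
  out_cols <- data.frame(term = character(0), a = integer(0), b = integer(0),
                         c = integer(0), d = integer(0),
                         odds_ratio = numeric(0), p_value = numeric(0))
  if (length(study_genes) == 0L) {
    warning("empty study set")
    return(out_cols)
  }
  bad <- setdiff(study_genes, annotation$universe)
  if (length(bad))
    stop("study gene(s) outside universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  n_study <- length(study_genes)
  n_univ <- length(annotation$universe)
  terms <- names(annotation$genes_by_term)
  a <- vapply(annotation$genes_by_term, function(g)
    sum(g %in% study_genes), integer(1))
  keep <- a > 0L
  terms <- terms[keep]; a <- a[keep]
  if (length(terms) == 0L) return(out_cols)
  k <- lengths(annotation$genes_by_term)[keep] # term total in universe
  b <- n_study - a
  c <- k - a
  d <- n_univ - n_study - c
  or <- ifelse(b * c == 0 & a * d == 0, 1,
        ifelse(b * c == 0, Inf, (a * d) / (b * c)))
  p <- vapply(seq_along(terms), function(i)
    fisher_p(a[i], b[i], c[i], d[i], alternative), numeric(1))
  out <- data.frame(term = terms, a = as.integer(a), b = as.integer(b),
                    c = as.integer(c), d = as.integer(d),
                    odds_ratio = or, p_value = p,
                    stringsAsFactors = FALSE)
  if (adjust == "BH") out$p_adjust <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value, out$term, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Select candidate genes by membership in enriched terms
#'
#' Candidates are the variant-bearing genes annotated with at least one of
#' the supplied enriched terms (e.g. a flowering-gene-derived GO-slim list),
#' in deterministic (sorted) order.
#'
#' @param variant_genes genes carrying triaged variants.
#' @param enriched_terms character vector of term ids.
#' @param annotation an [annotation_table()].
#' @return sorted character vector of candidate gene ids.
#' @export
select_candidates <- function(variant_genes, enriched_terms, annotation) {
  stopifnot(inherits(annotation, "annotation_table"))
  if (length(enriched_terms) == 0L) return(character(0))
  hit <- unique(unlist(
    annotation$genes_by_term[
      names(annotation$genes_by_term) %in% enriched_terms],
    use.names = FALSE))
  sort(intersect(unique(variant_genes), hit))
}
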