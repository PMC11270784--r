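# VCF input for the two-sample NIL pair. Parsing is delegated to vcfR; this
# layer splits multi-allelic rows, decodes genotypes/depths and normalizes
# FILTER into a failed-criterion count.

# classify one sample call given allele indices (NA = missing)
gt_class <- function(a, b) {
  ifelse(is.na(a) | is.na(b), "missing",
  ifelse(a != b, "het",
  ifelse(a == 0L, "hom_ref", "hom_alt")))
}

.parse_gt <- function(gt) {
  # "0/1", "0|1", ".", "./."
  gt[is.na(gt)] <- "."
  parts <- strsplit(gt, "[/|]")
  a <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  b <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 2L) p[[2L]] else p[[1L]], "")))
  list(a = a, b = b)
}

.n_failed_filters <- function(filter) {
  filter[is.na(filter)] <- "."
  ifelse(filter %in% c("PASS", "."), 0L,
         lengths(strsplit(filter, ";", fixed = TRUE)))
}

#' Read a two-sample NIL VCF
#'
#' Parses a VCF 4.2 file with exactly two sample columns into one record per
#' (position, alternate allele): multi-allelic rows are split into biallelic
#' records that share the position and keep the original per-sample allele
#' indices. FILTER is decoded into a count of failed criteria (`PASS` and `.`
#' both mean zero). Per-sample DP is taken from FORMAT.
#'
#' @param path path to a VCF file.
#' @return data.frame of variant records ordered by (chrom, pos) with columns
#'   `chrom`, `pos`, `ref`, `alt`, `alt_index`, `filter`, `n_failed`,
#'   `gt1_a`, `gt1_b`, `gt2_a`, `gt2_b`, `class1`, `class2`, `dp1`, `dp2`,
#'   `key`; sample names in `attr(,"samples")`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  if (length(samples) != 2L)
    stop("expected exactly 2 samples, found ", length(samples))
  fix <- v@fix
  if (nrow(fix) == 0L) {
    out <- data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      alt_index = integer(0), filter = character(0),
                      n_failed = integer(0), gt1_a = integer(0),
                      gt1_b = integer(0), gt2_a = integer(0),
                      gt2_b = integer(0), class1 = character(0),
                      class2 = character(0), dp1 = integer(0),
                      dp2 = integer(0), key = character(0))
    attr(out, "samples") <- samples
    return(out)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = 2)
  if (is.null(dim(dp))) dp <- matrix(dp, ncol = 2)

  g1 <- .parse_gt(gt[, 1]); g2 <- .parse_gt(gt[, 2])
  bad <- which(xor(is.na(g1$a), is.na(g1$b)) | xor(is.na(g2$a), is.na(g2$b)))
  if (length(bad))
    stop("malformed genotype at VCF record ", bad[1])

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  i <- rep(seq_len(nrow(fix)), n_alt)
  alt_index <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  out <- data.frame(
    chrom = fix[i, "CHROM"],
    pos = as.numeric(fix[i, "POS"]),
    ref = fix[i, "REF"],
    alt = unlist(alts, use.names = FALSE),
    alt_index = alt_index,
    filter = ifelse(is.na(fix[i, "FILTER"]), ".", fix[i, "FILTER"]),
    n_failed = .n_failed_filters(fix[, "FILTER"])[i],
    gt1_a = g1$a[i], gt1_b = g1$b[i],
    gt2_a = g2$a[i], gt2_b = g2$b[i],
    dp1 = as.integer(dp[i, 1]), dp2 = as.integer(dp[i, 2]),
    stringsAsFactors = FALSE)
  out$class1 <- gt_class(out$gt1_a, out$gt1_b)
  out$class2 <- gt_class(out$gt2_a, out$gt2_b)
  if (any(out$ref == out$alt))
    stop("REF equal to ALT at record ", which(out$ref == out$alt)[1])
  out$key <- variant_key(out$chrom, out$pos, out$ref, out$alt)
  out <- out[order(out$chrom, out$pos, out$alt_index, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  out
}

#' Write NIL variant rows as VCF 4.2
#'
#' Serializes a row table (one row per VCF line; multi-allelic ALT as a
#' comma-separated string) into a minimal VCF 4.2 with GT:DP FORMAT and two
#' sample columns.
#'
#' @param rows data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `filter`, `gt1`, `gt2`, `dp1`, `dp2` (`dp` may be NA for a missing DP).
#' @param path output path.
#' @param samples character(2) sample names.
#' @param contigs named vector of contig lengths for the header (optional).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(rows, path, samples = c("NIL_L", "NIL_E"),
                      contigs = NULL) {
  stopifnot(length(samples) == 2L)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=niltriage",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              as.integer(contigs)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- if (nrow(rows)) {
    o <- order(rows$chrom, rows$pos, method = "radix")
    rows <- rows[o, ]
    dp_fmt <- function(dp) ifelse(is.na(dp), ".", as.character(dp))
    paste(rows$chrom, format(rows$pos, scientific = FALSE, trim = TRUE),
          ".", rows$ref, rows$alt, ".", rows$filter, ".", "GT:DP",
          paste0(rows$gt1, ":", dp_fmt(rows$dp1)),
          paste0(rows$gt2, ":", dp_fmt(rows$dp2)),
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
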