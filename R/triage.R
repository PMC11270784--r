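# Tiered triage of NIL-pair variants: depth filter, quality-criterion filter,
# contrasting-homozygosity selection with chromosome anchoring, per-chromosome
# tier report, window densities, and selfing-heterozygosity arithmetic.

#' Triage configuration
#'
#' @param min_depth minimum per-sample read depth; records with a depth below
#'   this in at least one sample are excluded (default 10).
#' @param max_failed_filters maximum number of failed FILTER criteria a
#'   retained record may carry: records pass all criteria or fail at most
#'   this many (default 1).
#' @param chromosome_set chromosome names treated as anchored; records
#'   elsewhere (unanchored scaffolds) never reach the homozygous tier.
#' @param window_bp density window size in bp (default 1 Mb).
#' @param hotspot_threshold a window is a hotspot when its variant count
#'   strictly exceeds this (default 200 per window).
#' @return list of class `triage_config`.
#' @export
triage_config <- function(min_depth = 10L, max_failed_filters = 1L,
                          chromosome_set = paste0("Ca", 1:8),
                          window_bp = 1000000L, hotspot_threshold = 200L) {
  stopifnot(min_depth >= 0, window_bp > 0, max_failed_filters >= 0)
  structure(list(min_depth = as.integer(min_depth),
                 max_failed_filters = as.integer(max_failed_filters),
                 chromosome_set = chromosome_set,
                 window_bp = as.integer(window_bp),
                 hotspot_threshold = as.integer(hotspot_threshold)),
            class = "triage_config")
}

#' Exclude records with insufficient read depth
#'
#' Retains a record iff both samples have depth `>= min_depth`. Records with
#' a missing DP in either sample are excluded and counted in the
#' `"n_missing_dp"` attribute of the result (with a warning).
#'
#' @param records variant record data.frame from [read_vcf()].
#' @param config a [triage_config()].
#' @return the retained records.
#' @export
filter_depth <- function(records, config = triage_config()) {
  miss <- is.na(records$dp1) | is.na(records$dp2)
  if (any(miss))
    warning(sum(miss), " record(s) excluded for missing DP")
  keep <- !miss & pmin(records$dp1, records$dp2) >= config$min_depth
  out <- records[keep, , drop = FALSE]
  attr(out, "samples") <- attr(records, "samples")
  attr(out, "n_missing_dp") <- sum(miss)
  out
}

#' Keep records passing all quality criteria or failing at most one
#'
#' Retains a record iff its number of failed FILTER criteria is at most
#' `max_failed_filters`; `PASS` and `.` count as zero failed criteria.
#'
#' @inheritParams filter_depth
#' @return the retained records.
#' @export
filter_quality <- function(records, config = triage_config()) {
  out <- records[records$n_failed <= config$max_failed_filters, ,
                 drop = FALSE]
  attr(out, "samples") <- attr(records, "samples")
  out
}

#' Select contrasting homozygous variants on anchored chromosomes
#'
#' A between-NIL variant is a position where the lines actually differ:
#' both samples homozygous, for different alleles, on an anchored chromosome.
#' Heterozygous calls, identical homozygous calls (no contrast) and missing
#' genotypes are excluded; missing genotypes are tallied in the
#' `"n_missing_gt"` attribute.
#'
#' @inheritParams filter_depth
#' @return the retained records.
#' @export
select_contrasting_homozygous <- function(records, config = triage_config()) {
  hom1 <- records$class1 %in% c("hom_ref", "hom_alt")
  hom2 <- records$class2 %in% c("hom_ref", "hom_alt")
  miss <- records$class1 == "missing" | records$class2 == "missing"
  contrast <- hom1 & hom2 & records$gt1_a != records$gt2_a
  keep <- !miss & contrast & records$chrom %in% config$chromosome_set
  keep[is.na(keep)] <- FALSE
  out <- records[keep, , drop = FALSE]
  attr(out, "samples") <- attr(records, "samples")
  attr(out, "n_missing_gt") <- sum(miss)
  out
}

#' Run the full triage cascade
#'
#' Applies, in order: depth filter; chromosome grouping (DETECTED tier =
#' depth-passing records); quality filter (HQ); contrasting-homozygous
#' selection on anchored chromosomes (HHQ); intragenic assignment (HHQ-I);
#' and restriction to CDS/exon of protein-coding loci (HHQ-I-C/E). Tiers are
#' nested record sets, not just counts.
#'
#' @param records variant records from [read_vcf()].
#' @param models a [gene_model_set()].
#' @param config a [triage_config()].
#' @return list of class `triage_result` with `tiers` (named list of record
#'   data.frames `detected`, `hq`, `hhq`, `hhq_i`, `hhq_i_ce`),
#'   `assignments` (locus/region assignments of the HHQ records, from
#'   [assign_loci()]) and `report` (a [tier_report()]).
#' @export
run_triage <- function(records, models, config = triage_config()) {
  detected <- filter_depth(records, config)
  hq <- filter_quality(detected, config)
  hhq <- select_contrasting_homozygous(hq, config)
  asg <- assign_loci(hhq, models)
  intragenic_keys <- unique(asg$key)
  hhq_i <- hhq[hhq$key %in% intragenic_keys, , drop = FALSE]
  ce_keys <- unique(asg$key[asg$region %in% c("CDS", "EXON")])
  hhq_i_ce <- hhq[hhq$key %in% ce_keys, , drop = FALSE]
  tiers <- list(detected = detected, hq = hq, hhq = hhq,
                hhq_i = hhq_i, hhq_i_ce = hhq_i_ce)
  structure(list(tiers = tiers, assignments = asg,
                 report = tier_report(tiers, asg, config)),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Per-chromosome tier report
#'
#' Counts each triage tier per anchored chromosome, plus the number of
#' distinct protein-coding loci carrying at least one HHQ-I-C/E variant, and
#' appends a TOTAL row equal to the column sums. Validates that the tiers
#' are nested record sets.
#'
#' @param tiers named list of record data.frames (`detected`, `hq`, `hhq`,
#'   `hhq_i`, `hhq_i_ce`), each a subset of the previous.
#' @param assignments assignment table from [assign_loci()] covering the
#'   `hhq` tier.
#' @param config a [triage_config()] (supplies the chromosome set).
#' @return data.frame of class `tier_report`: `chrom`, `detected`, `hq`,
#'   `hhq`, `hhq_i`, `hhq_i_ce`, `genes_ce`.
#' @export
tier_report <- function(tiers, assignments, config = triage_config()) {
  need <- c("detected", "hq", "hhq", "hhq_i", "hhq_i_ce")
  stopifnot(all(need %in% names(tiers)))
  for (i in seq_len(length(need) - 1)) {
    sup <- tiers[[need[i]]]$key; sub <- tiers[[need[i + 1]]]$key
    if (!all(sub %in% sup))
      stop("tier ", need[i + 1], " is not a subset of ", need[i])
  }
  chroms <- config$chromosome_set
  cnt <- function(d) {
    t <- table(factor(d$chrom, levels = chroms))
    as.integer(t)
  }
  rep <- data.frame(chrom = chroms,
                    detected = cnt(tiers$detected), hq = cnt(tiers$hq),
                    hhq = cnt(tiers$hhq), hhq_i = cnt(tiers$hhq_i),
                    hhq_i_ce = cnt(tiers$hhq_i_ce),
                    stringsAsFactors = FALSE)
  ce <- assignments[assignments$region %in% c("CDS", "EXON") &
                      assignments$key %in% tiers$hhq_i_ce$key, , drop = FALSE]
  genes <- unique(ce[, c("chrom", "locus_id")])
  gt <- table(factor(genes$chrom, levels = chroms))
  rep$genes_ce <- as.integer(gt)
  total <- data.frame(chrom = "TOTAL", t(colSums(rep[, -1])))
  rep <- rbind(rep, total)
  rownames(rep) <- NULL
  class(rep) <- c("tier_report", "data.frame")
  rep
}

#' @export
print.tier_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a tier report as TSV
#'
#' @param report a [tier_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tier_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Variant density in fixed windows
#'
#' Bins variants into consecutive windows `[k*W+1, (k+1)*W]` (1-based,
#' inclusive) per chromosome and flags windows whose count strictly exceeds
#' the hotspot threshold.
#'
#' @param records variant records.
#' @param chrom_lengths named vector of chromosome lengths (bp); every
#'   record's chromosome must be present and no position may exceed its
#'   length.
#' @param config a [triage_config()].
#' @return data.frame of class `window_density`: `chrom`, `win_start`,
#'   `win_end`, `count`, `hotspot`.
#' @export
window_density <- function(records, chrom_lengths,
                           config = triage_config()) {
  W <- config$window_bp
  chroms <- names(chrom_lengths)
  missing_chrom <- setdiff(unique(records$chrom), chroms)
  if (length(missing_chrom))
    stop("unknown chromosome(s): ", paste(missing_chrom, collapse = ", "))
  out <- lapply(chroms, function(ch) {
    L <- chrom_lengths[[ch]]
    n_win <- ceiling(L / W)
    pos <- records$pos[records$chrom == ch]
    if (length(pos) && max(pos) > L)
      stop("position beyond chromosome ", ch, " length")
    win <- (pos - 1) %/% W + 1
    counts <- tabulate(win, nbins = n_win)
    data.frame(chrom = ch,
               win_start = (seq_len(n_win) - 1) * W + 1,
               win_end = pmin(seq_len(n_win) * W, L),
               count = counts,
               hotspot = counts > config$hotspot_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("window_density", "data.frame")
  out
}

#' Merge hotspot windows into intervals
#'
#' @param track a [window_density()] result.
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive) of merged
#'   runs of hotspot windows.
#' @export
hotspot_intervals <- function(track) {
  hs <- track[track$hotspot, , drop = FALSE]
  if (nrow(hs) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  out <- lapply(split(hs, hs$chrom), function(d) {
    d <- d[order(d$win_start), ]
    new_run <- c(TRUE, d$win_start[-1] != d$win_end[-nrow(d)] + 1)
    run <- cumsum(new_run)
    data.frame(chrom = d$chrom[1],
               start = tapply(d$win_start, run, min),
               end = tapply(d$win_end, run, max))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write hotspot intervals as BED
#'
#' BED is 0-based, half-open: a 1-based inclusive interval `[s, e]` is
#' written as `s-1, e`.
#'
#' @param intervals result of [hotspot_intervals()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hotspots_bed <- function(intervals, path) {
  bed <- data.frame(intervals$chrom,
                    format(intervals$start - 1, scientific = FALSE,
                           trim = TRUE),
                    format(intervals$end, scientific = FALSE, trim = TRUE))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Observed heterozygosity
#'
#' Percentage of read positions called heterozygous in one sample:
#' `100 * n_het / n_positions`, reported rounded to 3 decimals.
#'
#' @param n_het count of heterozygous positions.
#' @param n_positions total positions read (> 0).
#' @return list of class `het_stat`: `n_het`, `n_positions`, `percent`.
#' @export
observed_heterozygosity <- function(n_het, n_positions) {
  stopifnot(n_positions > 0)
  if (n_het > n_positions) stop("n_het cannot exceed n_positions")
  if (n_het < 0) stop("n_het must be non-negative")
  structure(list(n_het = n_het, n_positions = n_positions,
                 percent = round(100 * n_het / n_positions, 3)),
            class = "het_stat")
}

#' @export
print.het_stat <- function(x, ...) {
  cat(sprintf("observed heterozygosity: %s / %s positions = %.3f%%\n",
              format(x$n_het, big.mark = ","),
              format(x$n_positions, big.mark = ","), x$percent))
  invisible(x)
}

#' Selfing-decay model for residual heterozygosity
#'
#' Under Mendelian inheritance the heterozygous fraction of a selfing lineage
#' halves every generation from a fully heterozygous founder. The default
#' convention counts `n_generations` stated generations of self-fertilization
#' as `n_generations - 1` effective halvings (the founder generation
#' establishes, rather than halves, heterozygosity).
#'
#' @param n_generations stated generations of self-fertilization.
#' @param n_halvings effective halvings; overrides the convention if given.
#' @return list of class `selfing_model`.
#' @export
selfing_model <- function(n_generations = NULL, n_halvings = NULL) {
  if (is.null(n_halvings)) {
    stopifnot(!is.null(n_generations), n_generations >= 1)
    n_halvings <- n_generations - 1
  }
  if (n_halvings < 0) stop("n_halvings must be non-negative")
  structure(list(n_generations = n_generations, n_halvings = n_halvings),
            class = "selfing_model")
}

#' Expected residual heterozygosity under selfing
#'
#' `100 * (1/2)^n_halvings` percent, rounded to 3 decimals for reporting by
#' default (`digits = NULL` returns the exact value, which halves exactly
#' with each additional generation).
#'
#' @param model a [selfing_model()].
#' @param digits decimals for reporting, or `NULL` for the exact value.
#' @return expected residual heterozygosity in percent.
#' @export
expected_selfing_heterozygosity <- function(model, digits = 3) {
  stopifnot(inherits(model, "selfing_model"))
  x <- 100 * 0.5^model$n_halvings
  if (is.null(digits)) x else round(x, digits)
}
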