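# Minimal coding-effect classifier. Deliberately covers only the effect-term
# vocabulary needed for NIL triage reporting (frameshift, in-frame deletions
# and insertions, synonymous/missense/stop SNVs, UTR, intron and non-coding
# exon terms) with snpEff-style impact tiers; splice-site, start-lost and
# regulatory terms are out of scope.

.effect_impact_map <- c(
  frameshift_variant = "HIGH", stop_gained = "HIGH", stop_lost = "HIGH",
  missense_variant = "MODERATE", disruptive_inframe_deletion = "MODERATE",
  inframe_deletion = "MODERATE", disruptive_inframe_insertion = "MODERATE",
  inframe_insertion = "MODERATE", synonymous_variant = "LOW",
  `5_prime_UTR_variant` = "MODIFIER", `3_prime_UTR_variant` = "MODIFIER",
  intron_variant = "MODIFIER",
  non_coding_transcript_exon_variant = "MODIFIER",
  intergenic_or_flank = "MODIFIER")

.severity_rank <- c(MODIFIER = 1L, LOW = 2L, MODERATE = 3L, HIGH = 4L)

#' Construct an effect call
#'
#' @param term effect term; the impact tier is fixed by the term.
#' @return list of class `effect_call` with `term` and `impact`.
#' @export
effect_call <- function(term) {
  impact <- .effect_impact_map[[term]]
  if (is.null(impact)) stop("unknown effect term: ", term)
  structure(list(term = term, impact = impact), class = "effect_call")
}

#' @export
print.effect_call <- function(x, ...) {
  cat(sprintf("%s [%s]\n", x$term, x$impact))
  invisible(x)
}

# Decompose REF/ALT into a shape: snv, mnv, del, ins or complex, with the
# common-prefix length and the net length change. VCF indels are assumed
# left-anchored; no re-normalization is attempted.
.variant_shape <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  p <- 0L
  while (p < min(nr, na) &&
         substr(ref, p + 1, p + 1) == substr(alt, p + 1, p + 1)) p <- p + 1L
  type <- if (nr == 1L && na == 1L) "snv"
    else if (nr == na) "mnv"
    else if (p == na && nr > na) "del"
    else if (p == nr && na > nr) "ins"
    else "complex"
  list(type = type, prefix = p, dlen = na - nr,
       del_from = if (type %in% c("del", "complex")) p else NA_integer_,
       ins_seq = if (type %in% c("ins", "complex"))
         substr(alt, p + 1, na) else NULL)
}

# Genomic positions of each CDS base of a transcript, in transcript
# (5'->3') orientation.
.tx_cds_positions <- function(models, tx_id) {
  cd <- models$cds[models$cds$tx_id == tx_id, , drop = FALSE]
  if (nrow(cd) == 0L) return(numeric(0))
  strand <- models$transcripts$strand[models$transcripts$tx_id == tx_id][1]
  cd <- cd[order(cd$start, decreasing = (strand == "-")), , drop = FALSE]
  unlist(lapply(seq_len(nrow(cd)), function(i)
    if (strand == "-") seq(cd$end[i], cd$start[i]) else
      seq(cd$start[i], cd$end[i])), use.names = FALSE)
}

.comp_base <- function(b) {
  chartr("ACGTacgt", "TGCAtgca", b)
}

.translate_chars <- function(seq_chr) {
  n <- floor(nchar(seq_chr) / 3) * 3
  if (n == 0L) return(character(0))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq_chr, 1, n)),
    if.fuzzy.codon = "X"))
  strsplit(aa, "")[[1]]
}

# protein up to (not including) the first stop; NULL stop index if none
.protein_to_stop <- function(seq_chr) {
  aa <- .translate_chars(seq_chr)
  stop_at <- which(aa == "*")[1]
  if (is.na(stop_at)) list(protein = aa, has_stop = FALSE)
  else list(protein = aa[seq_len(stop_at - 1)], has_stop = TRUE)
}

#' Transcript CDS sequence with genomic coordinate map
#'
#' @param tx_id transcript id.
#' @param cds_seq spliced CDS nucleotide sequence (5'->3', starting at the
#'   start codon; length must be a multiple of 3).
#' @param genomic_pos integer vector, same length as `cds_seq`, giving the
#'   genomic coordinate of each CDS base in transcript orientation
#'   (descending for minus-strand transcripts).
#' @param strand "+" or "-".
#' @return object of class `transcript_sequence`.
#' @export
transcript_sequence <- function(tx_id, cds_seq, genomic_pos, strand = "+") {
  cds_seq <- toupper(cds_seq)
  if (nchar(cds_seq) %% 3 != 0)
    stop("CDS length must be divisible by 3")
  if (nchar(cds_seq) != length(genomic_pos))
    stop("genomic_pos must map every CDS base")
  stopifnot(strand %in% c("+", "-"))
  structure(list(tx_id = tx_id, cds_seq = cds_seq,
                 genomic_pos = as.numeric(genomic_pos), strand = strand),
            class = "transcript_sequence")
}

#' Extract a transcript's CDS sequence from a genome
#'
#' @param models a [gene_model_set()].
#' @param genome a [Biostrings::DNAStringSet] named by chromosome.
#' @param tx_id transcript id with CDS segments in `models`.
#' @return a [transcript_sequence()].
#' @export
extract_transcript_sequence <- function(models, genome, tx_id) {
  tx <- models$transcripts[models$transcripts$tx_id == tx_id, , drop = FALSE]
  if (nrow(tx) != 1L) stop("unknown transcript: ", tx_id)
  gpos <- .tx_cds_positions(models, tx_id)
  if (length(gpos) == 0L) stop("transcript has no CDS: ", tx_id)
  chrom_seq <- genome[[tx$chrom]]
  bases <- strsplit(as.character(chrom_seq), "")[[1]][sort(gpos)]
  seq_plus <- paste(bases, collapse = "")
  seq_tx <- if (tx$strand == "-")
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq_plus)))
  else seq_plus
  transcript_sequence(tx_id, seq_tx, gpos, tx$strand)
}

# Apply a variant to the spliced CDS; returns the alternate CDS string.
.apply_variant_cds <- function(txseq, variant) {
  bases <- strsplit(txseq$cds_seq, "")[[1]]
  map <- txseq$genomic_pos
  minus <- txseq$strand == "-"
  sh <- .variant_shape(variant$ref, variant$alt)
  nr <- nchar(variant$ref)

  if (sh$type %in% c("snv", "mnv")) {
    g <- variant$pos + seq_len(nr) - 1
    newb <- strsplit(variant$alt, "")[[1]]
    for (k in seq_along(g)) {
      i <- match(g[k], map)
      if (is.na(i)) next
      bases[i] <- if (minus) .comp_base(newb[k]) else newb[k]
    }
    return(paste(bases, collapse = ""))
  }

  del_g <- if (sh$type %in% c("del", "complex"))
    variant$pos + seq(sh$del_from, nr - 1) else numeric(0)
  del_i <- stats::na.omit(match(del_g, map))
  anchor_g <- variant$pos + sh$prefix - 1
  anchor_i <- match(anchor_g, map)

  ins <- sh$ins_seq
  if (!is.null(ins) && minus)
    ins <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ins)))

  keep <- setdiff(seq_along(bases), del_i)
  if (is.null(ins) || is.na(anchor_i)) {
    return(paste(bases[keep], collapse = ""))
  }
  # insertion goes 3' of the anchor in transcript orientation
  at <- if (minus) anchor_i - 1L else anchor_i
  left <- keep[keep <= at]; right <- keep[keep > at]
  paste(c(bases[left], strsplit(ins, "")[[1]], bases[right]), collapse = "")
}

#' Predict the protein consequence of a variant
#'
#' Applies the variant to the spliced CDS, translates reference and
#' alternate sequences with the standard code up to the first stop codon,
#' and reports the reference and alternate protein lengths together with the
#' number of novel residues preceding the (premature) stop — e.g. a
#' frameshifting deletion that leaves 7 original residues, 6 novel residues
#' and then a stop yields lengths (ref, 13) with 6 novel residues. If the
#' alternate sequence reaches its end without a stop codon the call is
#' flagged `"no_stop"` (stop-lost/readthrough) and the alternate length is
#' the full translated length.
#'
#' @param txseq a [transcript_sequence()].
#' @param variant list or one-row data.frame with `pos`, `ref`, `alt`;
#'   `NULL` for the identity (no variant).
#' @return list of class `protein_consequence`: `ref_protein_length`,
#'   `alt_protein_length`, `n_missense_before_stop`, `flags`.
#' @export
translate_consequence <- function(txseq, variant = NULL) {
  stopifnot(inherits(txseq, "transcript_sequence"))
  ref <- .protein_to_stop(txseq$cds_seq)
  alt_seq <- if (is.null(variant)) txseq$cds_seq else
    .apply_variant_cds(txseq, variant)
  alt <- .protein_to_stop(alt_seq)
  flags <- character(0)
  if (!alt$has_stop) flags <- c(flags, "no_stop")
  np <- 0L
  m <- min(length(ref$protein), length(alt$protein))
  while (np < m && ref$protein[np + 1] == alt$protein[np + 1]) np <- np + 1L
  structure(list(
    ref_protein_length = length(ref$protein),
    alt_protein_length = length(alt$protein),
    n_missense_before_stop = length(alt$protein) - np,
    flags = flags), class = "protein_consequence")
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat(sprintf("protein %d -> %d aa (%d novel residue(s) before stop)%s\n",
              x$ref_protein_length, x$alt_protein_length,
              x$n_missense_before_stop,
              if (length(x$flags)) paste0(" [", x$flags, "]") else ""))
  invisible(x)
}

#' Classify a variant's coding effect on one transcript
#'
#' CDS indels whose net length change is not a multiple of 3 are
#' frameshifts (HIGH); in-frame deletions are `inframe_deletion` when they
#' remove whole codons on codon boundaries and `disruptive_inframe_deletion`
#' when they break codon boundaries (MODERATE; in-frame insertions
#' analogously). CDS SNVs are classified by codon translation
#' (synonymous/missense/stop_gained; requires `txseq`). Non-CDS exon
#' positions get a UTR term by side relative to the CDS in transcript
#' orientation (or `non_coding_transcript_exon_variant` for transcripts
#' without CDS); intronic positions get `intron_variant`.
#'
#' @param variant list or one-row data.frame with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param tx_id transcript id.
#' @param models a [gene_model_set()].
#' @param txseq optional [transcript_sequence()] for `tx_id`; required for
#'   CDS SNV/MNV classification.
#' @return an [effect_call()].
#' @export
classify_effect <- function(variant, tx_id, models, txseq = NULL) {
  tx <- models$transcripts[models$transcripts$tx_id == tx_id, , drop = FALSE]
  if (nrow(tx) != 1L) stop("unknown transcript: ", tx_id)
  sh <- .variant_shape(variant$ref, variant$alt)
  nr <- nchar(variant$ref)

  affected <- if (sh$type %in% c("del", "complex"))
    variant$pos + seq(sh$del_from, nr - 1)
  else variant$pos + seq_len(nr) - 1

  if (variant$chrom != tx$chrom ||
      max(affected) < tx$start || min(affected) > tx$end)
    stop("variant outside transcript ", tx_id)

  seg_touch <- function(seg) {
    seg <- seg[seg$tx_id == tx_id, , drop = FALSE]
    nrow(seg) > 0L &&
      any(vapply(affected, function(p)
        any(seg$start <= p & seg$end >= p), logical(1)))
  }
  in_cds <- seg_touch(models$cds)
  in_exon <- seg_touch(models$exons)

  if (in_cds) {
    if (sh$type == "snv" || sh$type == "mnv") {
      if (is.null(txseq))
        stop("CDS substitution requires a transcript_sequence")
      ref_p <- .protein_to_stop(txseq$cds_seq)
      alt_p <- .protein_to_stop(.apply_variant_cds(txseq, variant))
      term <- if (identical(ref_p$protein, alt_p$protein) &&
                  alt_p$has_stop == ref_p$has_stop) "synonymous_variant"
        else if (length(alt_p$protein) < length(ref_p$protein))
          "stop_gained"
        else if (!alt_p$has_stop && ref_p$has_stop) "stop_lost"
        else "missense_variant"
      return(effect_call(term))
    }
    if (sh$dlen %% 3 != 0) return(effect_call("frameshift_variant"))
    gpos <- .tx_cds_positions(models, tx_id)
    if (sh$type == "del" || sh$type == "complex") {
      del_g <- variant$pos + seq(sh$del_from, nr - 1)
      del_i <- sort(stats::na.omit(match(del_g, gpos)))
      aligned <- length(del_i) %% 3 == 0 &&
        length(del_i) > 0 && (del_i[1] - 1) %% 3 == 0
      term <- if (sh$type == "complex") "disruptive_inframe_deletion"
        else if (aligned) "inframe_deletion"
        else "disruptive_inframe_deletion"
      return(effect_call(term))
    }
    # in-frame insertion: between codons iff the anchor ends a codon
    anchor_i <- match(variant$pos + sh$prefix - 1, gpos)
    aligned <- !is.na(anchor_i) && anchor_i %% 3 == 0
    return(effect_call(
      if (aligned) "inframe_insertion" else "disruptive_inframe_insertion"))
  }

  if (in_exon) {
    cd <- models$cds[models$cds$tx_id == tx_id, , drop = FALSE]
    if (nrow(cd) == 0L)
      return(effect_call("non_coding_transcript_exon_variant"))
    gmin <- min(cd$start); gmax <- max(cd$end)
    five <- if (tx$strand == "+") max(affected) < gmin else
      min(affected) > gmax
    return(effect_call(
      if (five) "5_prime_UTR_variant" else "3_prime_UTR_variant"))
  }

  effect_call("intron_variant")
}

#' Roll up per-transcript effect calls to the worst impact
#'
#' Returns the maximum-severity call under HIGH > MODERATE > LOW > MODIFIER;
#' ties are broken by lexicographic term order for determinism.
#'
#' @param calls non-empty list of [effect_call()] objects.
#' @return the selected [effect_call()].
#' @export
impact_rollup <- function(calls) {
  if (length(calls) == 0L) stop("empty call list")
  sev <- vapply(calls, function(cl) .severity_rank[[cl$impact]], integer(1))
  terms <- vapply(calls, `[[`, "", "term")
  top <- which(sev == max(sev))
  calls[[top[order(terms[top])[1]]]]
}
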