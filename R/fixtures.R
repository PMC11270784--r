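# Engineered sequence-bearing fixtures for the effect classifier. The
# sequences are fixed constants (verified against an independent translator
# when they were designed), not generated at run time, so tests exercise the
# classifier against known protein consequences.

#' Engineered frameshift fixture (ELF3-type truncating deletion)
#'
#' A 42-codon CDS (plus stop) carrying an 11-bp deletion that leaves 7
#' original residues, 6 frameshifted missense residues and then a premature
#' stop, truncating the 42-aa protein to 13 aa — the same shape as the
#' ELF3-type truncation seen in early-flowering chickpea, where an 11-bp
#' first-exon deletion collapses a 699-aa protein to 13 aa.
#'
#' @param offset genomic coordinate of the base before the CDS start
#'   (default 100; the CDS occupies `offset + 1 .. offset + 129`).
#' @return list with `txseq` (a [transcript_sequence()] on the plus strand),
#'   `variant` (chrom/pos/ref/alt of the deletion), `ref_protein_length`
#'   (42), `alt_protein_length` (13) and `n_missense_before_stop` (6).
#' @export
make_frameshift_fixture <- function(offset = 100L) {
  cds <- paste0(
    "ATGGCTATAGCTATTCCCCCCGCGGCCCACCCAGTATTCCTAACGGAGCATAAATCCCAC",
    "CCGAACGTTTGTCGAACCTTGGTCCAAGATCGGGACTCGGTCTCCAGGGACGGGCTCATT",
    "CATAAATAA")
  txseq <- transcript_sequence("FSDEMO.t1", cds,
                               offset + seq_len(nchar(cds)), "+")
  # anchor at CDS base 14; deletes CDS bases 15..25
  variant <- list(chrom = "demo", pos = offset + 14L,
                  ref = substr(cds, 14, 25), alt = substr(cds, 14, 14))
  list(txseq = txseq, variant = variant,
       ref_protein_length = 42L, alt_protein_length = 13L,
       n_missense_before_stop = 6L)
}

#' Tandem-duplication deletion fixture
#'
#' A CDS in which an 11-bp block is immediately followed by a 10-bp repeat
#' of its own first 10 bases — the sequence context that makes such
#' deletions arise naturally and makes their left-aligned VCF representation
#' ambiguous. Deleting the block at either equivalent anchor yields the same
#' alternate sequence, so classification must not depend on the anchor
#' choice.
#'
#' @param offset genomic coordinate of the base before the CDS start.
#' @return list with `txseq`, `variant_a` and `variant_b` (two equivalent
#'   11-bp deletions at anchors one base apart).
#' @export
make_tandem_deletion_fixture <- function(offset = 100L) {
  block <- "GATTACAGGCT"                         # 11 bp
  cds <- paste0("ATGGCTGCA",                     # 3 codons
                block, substr(block, 1, 10),     # tandem context
                "CCTGGTGCATCATAA")               # filler + stop (45 nt tot.)
  stopifnot(nchar(cds) %% 3 == 0)
  txseq <- transcript_sequence("TDDEMO.t1", cds,
                               offset + seq_len(nchar(cds)), "+")
  v <- function(anchor) list(
    chrom = "demo", pos = offset + anchor,
    ref = substr(cds, anchor, anchor + 11L),
    alt = substr(cds, anchor, anchor))
  list(txseq = txseq, variant_a = v(9L), variant_b = v(10L))
}
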