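# Gene and transcript models: validated containers for exon/intron/CDS/UTR
# structure, independent of the file format they came from.

#' Construct a transcript model
#'
#' Exons, CDS segments and UTRs are interval data frames
#' (`seq_id`/`start`/`end`/`strand`, 0-based half-open) in transcription
#' (5'->3') order: on the `-` strand that is descending genomic order.
#' Validation enforces the structural invariants every downstream step
#' relies on: disjoint exons, each CDS segment inside exactly one exon, and
#' a total CDS length divisible by three.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds,utr5,utr3 Interval data frames (any row order; they are
#'   re-sorted 5'->3').
#' @return A list of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, strand, exons, cds,
                             utr5 = interval_df(), utr3 = interval_df()) {
  if (!strand %in% c("+", "-")) err_input("bad strand '%s'", strand)
  exons <- order_5to3(exons, strand)
  cds   <- order_5to3(cds, strand)
  utr5  <- order_5to3(utr5, strand)
  utr3  <- order_5to3(utr3, strand)
  if (!nrow(exons)) err_input("transcript %s has no exons", transcript_id)
  if (!intervals_disjoint(exons))
    err_input("transcript %s: exons overlap on the genome", transcript_id)
  if (!intervals_disjoint(cds))
    err_input("transcript %s: CDS segments overlap", transcript_id)
  if (nrow(cds)) {
    within <- intervals_contained(cds, exons)
    if (!all(within))
      err_input("transcript %s: CDS segment %d not contained in any exon",
                transcript_id, which(!within)[1L])
    if (sum(interval_widths(cds)) %% 3L != 0L)
      err_input("transcript %s: total CDS length %d is not a multiple of 3",
                transcript_id, sum(interval_widths(cds)))
  }
  structure(list(transcript_id = as.character(transcript_id),
                 gene_id = as.character(gene_id),
                 strand = strand, exons = exons, cds = cds,
                 utr5 = utr5, utr3 = utr3),
            class = "transcript_model")
}

#' Construct a gene model
#'
#' @param gene_id Identifier.
#' @param symbol Display name (defaults to `gene_id`).
#' @param species Species name (may be `NA` when unknown at parse time).
#' @param interval A [genomic_interval()] spanning the gene.
#' @param transcript The canonical [transcript_model()].
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(gene_id, symbol = gene_id, species = NA_character_,
                       interval, transcript) {
  if (!identical(transcript$gene_id, as.character(gene_id)))
    err_input("transcript %s does not belong to gene %s",
              transcript$transcript_id, gene_id)
  ex <- transcript$exons
  if (any(ex$start < interval$start | ex$end > interval$end))
    err_input("gene %s: exon outside the gene interval", gene_id)
  structure(list(gene_id = as.character(gene_id),
                 symbol = as.character(symbol),
                 species = as.character(species),
                 interval = interval, transcript = transcript),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d (%s), %d exons, %d CDS segments\n",
              x$gene_id, x$species, x$interval$seq_id, x$interval$start,
              x$interval$end, x$transcript$strand,
              nrow(x$transcript$exons), nrow(x$transcript$cds)))
  invisible(x)
}

# Total CDS length in nucleotides.
cds_length <- function(transcript) sum(interval_widths(transcript$cds))
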