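# Coordinate mapping between protein residues, CDS nucleotide positions and
# genomic intervals. CDS coordinate 0 is the first coding base in
# transcription order; on the '-' strand increasing CDS coordinates run down
# the genome. All genomic coordinates 0-based half-open.

#' Build a CDS coordinate map for a transcript
#'
#' @param transcript A [transcript_model()] with at least one CDS segment.
#' @return A list of class `cds_map` with `transcript_id`, `strand`,
#'   `cds_len`, and `pieces`: a data frame with one row per CDS segment
#'   (5'->3') holding `cds_start`, `cds_end` (half-open CDS nucleotide
#'   coordinates), and the genomic `seq_id`, `g_start`, `g_end`.
#' @export
build_cds_map <- function(transcript) {
  cds <- transcript$cds
  if (!nrow(cds)) err_input("transcript %s has no CDS", transcript$transcript_id)
  if (!intervals_disjoint(cds))
    err_input("transcript %s: overlapping CDS segments", transcript$transcript_id)
  w <- interval_widths(cds)
  ends <- cumsum(w)
  cds_len <- ends[length(ends)]
  if (cds_len %% 3L != 0L)
    err_input("transcript %s: CDS length %d not divisible by 3",
              transcript$transcript_id, cds_len)
  pieces <- data.frame(cds_start = c(0L, ends[-length(ends)]),
                       cds_end = ends,
                       seq_id = cds$seq_id, g_start = cds$start,
                       g_end = cds$end, stringsAsFactors = FALSE)
  structure(list(transcript_id = transcript$transcript_id,
                 strand = transcript$strand,
                 cds_len = as.integer(cds_len), pieces = pieces),
            class = "cds_map")
}

# genomic interval for CDS nucleotide range [lo, hi) within one piece
piece_to_genomic <- function(map, i, lo, hi) {
  p <- map$pieces[i, ]
  if (map$strand == "+") {
    interval_df(p$seq_id, p$g_start + (lo - p$cds_start),
                p$g_start + (hi - p$cds_start), map$strand)
  } else {
    interval_df(p$seq_id, p$g_end - (hi - p$cds_start),
                p$g_end - (lo - p$cds_start), map$strand)
  }
}

# CDS nucleotide range [nt_lo, nt_hi) -> genomic intervals, 5'->3'
cds_nt_to_genomic <- function(map, nt_lo, nt_hi) {
  p <- map$pieces
  out <- list()
  for (i in seq_len(nrow(p))) {
    lo <- max(nt_lo, p$cds_start[i]); hi <- min(nt_hi, p$cds_end[i])
    if (lo < hi) out[[length(out) + 1L]] <- piece_to_genomic(map, i, lo, hi)
  }
  do.call(rbind, c(out, list(interval_df())))
}

#' Map a protein residue range to genomic intervals
#'
#' @param map A [build_cds_map()] result.
#' @param aa_start,aa_end 0-based half-open residue range; `aa_end` at most
#'   `cds_len / 3`.
#' @return An interval data frame covering exactly nucleotides
#'   `[3 * aa_start, 3 * aa_end)` of the CDS, split at exon boundaries and
#'   listed 5'->3'.
#' @export
protein_to_genomic <- function(map, aa_start, aa_end) {
  n_aa <- map$cds_len %/% 3L
  if (aa_start < 0L || aa_start >= aa_end || aa_end > n_aa)
    err_input("residue range [%d, %d) outside protein of length %d",
              aa_start, aa_end, n_aa)
  cds_nt_to_genomic(map, 3L * aa_start, 3L * aa_end)
}

# a single genomic point (as used for deletion marks) at CDS nt position
cds_nt_point <- function(map, nt) {
  p <- map$pieces
  i <- which(p$cds_start <= nt & nt <= p$cds_end)[1L]
  if (map$strand == "+") p$g_start[i] + (nt - p$cds_start[i])
  else p$g_end[i] - (nt - p$cds_start[i])
}

#' Residue range covered by a coding exon
#'
#' @param map A `cds_map`.
#' @param exon_index 1-based index among the coding exons (the map's
#'   pieces, 5'->3').
#' @return A list with `aa_lo`, `aa_hi` (0-based half-open codon range such
#'   that every CDS base of the exon falls inside it) and `shared_lo`,
#'   `shared_hi`: flags marking boundary codons split with the neighbouring
#'   exon.
#' @export
residue_ranges_of_exon <- function(map, exon_index) {
  p <- map$pieces
  if (exon_index < 1L || exon_index > nrow(p))
    err_input("exon index %d does not address a coding exon (1..%d)",
              exon_index, nrow(p))
  s <- p$cds_start[exon_index]; e <- p$cds_end[exon_index]
  list(aa_lo = s %/% 3L, aa_hi = as.integer(ceiling(e / 3)),
       shared_lo = s %% 3L != 0L, shared_hi = e %% 3L != 0L)
}

#' Assign each residue to one coding exon
#'
#' A codon split across an exon junction belongs to the exon containing its
#' middle base — equivalently, the exon holding at least two of its three
#' bases whenever no exon holds exactly one base of the codon.
#'
#' @param map A `cds_map`.
#' @return Integer vector of length `cds_len / 3`: the owning coding-exon
#'   index (1-based) per residue.
#' @export
exon_of_residue <- function(map) {
  base_exon <- rep(seq_len(nrow(map$pieces)),
                   map$pieces$cds_end - map$pieces$cds_start)
  base_exon[seq(2L, map$cds_len, by = 3L)]
}
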