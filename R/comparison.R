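# Comparison tracks: project the column classification of a homologue
# against the guide back onto the homologue's own gene structure, producing
# drawable segments in the target's genomic coordinates. MATCH blocks carry
# the guide-exon colour they align to (split where a run of aligned residues
# straddles a guide exon boundary — the visual signature of a fused or
# mis-annotated exon), insertions become their own segments, deletions
# collapse to zero-width genomic marks, and UTRs/introns are emitted
# explicitly so the renderer never re-derives structure.

SEGMENT_KINDS <- c("MATCH", "INSERTION", "UTR5", "UTR3", "NONCODING")

#' Colour indices for the guide's coding exons
#'
#' Coding exon i (5'->3') gets colour index i - 1; cycling a finite palette
#' over these indices is the renderer's concern.
#'
#' @param transcript The guide's [transcript_model()].
#' @return Integer vector `0:(n_coding_exons - 1)`.
#' @export
guide_exon_palette <- function(transcript) {
  n <- nrow(transcript$cds)
  if (!n) err_input("transcript %s has no coding exons; cannot colour",
                    transcript$transcript_id)
  0:(n - 1L)
}

segment_df <- function(kind = character(), seq_id = character(),
                       start = integer(), end = integer(),
                       color_index = integer()) {
  data.frame(kind = as.character(kind), seq_id = as.character(seq_id),
             start = as.integer(start), end = as.integer(end),
             color_index = as.integer(color_index), stringsAsFactors = FALSE)
}

iv_to_segments <- function(iv, kind, color = NA_integer_) {
  if (!nrow(iv)) return(segment_df())
  segment_df(rep(kind, nrow(iv)), iv$seq_id, iv$start, iv$end,
             rep(color, nrow(iv)))
}

# introns: gaps between consecutive exons in genomic order
intron_df <- function(transcript) {
  ex <- transcript$exons[order(transcript$exons$start), , drop = FALSE]
  if (nrow(ex) < 2L) return(interval_df())
  interval_df(ex$seq_id[-1L], ex$end[-nrow(ex)], ex$start[-1L],
              ex$strand[-1L])
}

# Coalesce genomically contiguous MATCH segments of the same colour and
# contiguous INSERTION segments. Such fragments arise when alignment runs
# are interrupted only by NEITHER columns (gaps in both members, e.g. a
# third family member's private insertion) or by a deletion of the guide:
# on the target's genome they are one uninterrupted block.
merge_contiguous_segments <- function(segments, strand) {
  if (nrow(segments) < 2L) return(segments)
  keep <- rep(TRUE, nrow(segments))
  prev <- 1L
  for (i in 2:nrow(segments)) {
    a <- segments[prev, ]; b <- segments[i, ]
    contig <- if (identical(strand, "-")) a$start == b$end else a$end == b$start
    if (a$kind == b$kind && a$kind %in% c("MATCH", "INSERTION") &&
        identical(a$color_index, b$color_index) &&
        a$seq_id == b$seq_id && contig) {
      if (identical(strand, "-")) segments$start[prev] <- b$start
      else segments$end[prev] <- b$end
      keep[i] <- FALSE
    } else {
      prev <- i
    }
  }
  segments[keep, , drop = FALSE]
}

#' Build the comparison track of a target gene against the guide
#'
#' Classifies alignment columns of the two CIGARs, then maps each class run
#' to the target's genome: `BOTH` runs become MATCH segments coloured by the
#' guide exon their guide-side residues occupy (split at guide exon
#' boundaries; a codon shared between two guide exons belongs to the exon
#' holding its middle base), `INSERTION` runs become INSERTION segments, and
#' each maximal `DELETION` run becomes one zero-width deletion mark placed
#' between the flanking aligned target residues (at the target CDS 5' end
#' when there is no left flank). Consecutive deletion runs separated only by
#' `NEITHER` columns merge into a single mark. UTRs and introns of the
#' target are appended as UTR5/UTR3/NONCODING segments.
#'
#' @param guide,target [gene_model()] objects (canonical transcripts used).
#' @param guide_cigar,target_cigar `alignment_cigar`s over the shared family
#'   alignment; M totals must equal each gene's CDS length / 3.
#' @return A list of class `comparison_track` with `gene_id`, `species`,
#'   `seq_id`, `strand`, `guide_flag`, `segments` (5'->3' data frame with
#'   `kind`, `seq_id`, `start`, `end`, `color_index`), `deletion_marks`
#'   (genomic point positions, 5'->3'), and the target `transcript`.
#' @export
build_comparison_track <- function(guide, guide_cigar, target, target_cigar) {
  gmap <- build_cds_map(guide$transcript)
  tmap <- build_cds_map(target$transcript)
  n_gm <- sum(guide_cigar$lengths[guide_cigar$ops == "M"])
  n_tm <- sum(target_cigar$lengths[target_cigar$ops == "M"])
  if (3L * n_gm != gmap$cds_len)
    err_input("guide %s: CIGAR M total %d inconsistent with CDS length %d",
              guide$gene_id, n_gm, gmap$cds_len)
  if (3L * n_tm != tmap$cds_len)
    err_input("target %s: CIGAR M total %d inconsistent with CDS length %d",
              target$gene_id, n_tm, tmap$cds_len)
  cc <- classify_columns(guide_cigar, target_cigar)
  geor <- exon_of_residue(gmap)  # guide exon (1-based) per guide residue

  segs <- list(iv_to_segments(target$transcript$utr5, "UTR5"),
               iv_to_segments(target$transcript$utr3, "UTR3"),
               iv_to_segments(intron_df(target$transcript), "NONCODING"))
  marks <- numeric(0)
  gres <- 0L; tres <- 0L
  for (k in seq_along(cc$classes)) {
    len <- cc$lengths[k]; cls <- cc$classes[k]
    if (cls == "BOTH") {
      exon_run <- rle(geor[(gres + 1L):(gres + len)])
      off <- 0L
      for (j in seq_along(exon_run$lengths)) {
        l <- exon_run$lengths[j]
        iv <- protein_to_genomic(tmap, tres + off, tres + off + l)
        segs[[length(segs) + 1L]] <-
          iv_to_segments(iv, "MATCH", exon_run$values[j] - 1L)
        off <- off + l
      }
      gres <- gres + len; tres <- tres + len
    } else if (cls == "INSERTION") {
      iv <- protein_to_genomic(tmap, tres, tres + len)
      segs[[length(segs) + 1L]] <- iv_to_segments(iv, "INSERTION")
      tres <- tres + len
    } else if (cls == "DELETION") {
      pos <- cds_nt_point(tmap, 3L * tres)
      if (!length(marks) || marks[length(marks)] != pos)
        marks <- c(marks, pos)
      gres <- gres + len
    }
    # NEITHER: nothing to draw
  }
  segments <- do.call(rbind, segs)
  o <- order(segments$start, segments$end,
              decreasing = identical(target$transcript$strand, "-"))
  segments <- segments[o, , drop = FALSE]
  segments <- merge_contiguous_segments(segments, target$transcript$strand)
  rownames(segments) <- NULL
  structure(list(gene_id = target$gene_id, species = target$species,
                 seq_id = target$interval$seq_id,
                 strand = target$transcript$strand,
                 guide_flag = identical(target$gene_id, guide$gene_id),
                 segments = segments, deletion_marks = marks,
                 transcript = target$transcript,
                 gene_start = target$interval$start,
                 gene_end = target$interval$end),
            class = "comparison_track")
}

#' Export a comparison track as BED-like text
#'
#' Tab-separated, 0-based half-open: `seq_id`, `start`, `end`, `kind`,
#' `color_index` (`.` when none), `gene_id`. Deletion marks appear as
#' zero-width `DELETION` records.
#'
#' @param track A `comparison_track`.
#' @param path Optional output file.
#' @return The lines (invisibly when `path` is given).
#' @export
track_to_bed <- function(track, path = NULL) {
  s <- track$segments
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", s$seq_id, s$start, s$end,
                   s$kind, ifelse(is.na(s$color_index), ".",
                                  as.character(s$color_index)),
                   track$gene_id)
  if (length(track$deletion_marks))
    lines <- c(lines,
               sprintf("%s\t%d\t%d\tDELETION\t.\t%s", track$seq_id,
                       as.integer(track$deletion_marks),
                       as.integer(track$deletion_marks), track$gene_id))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
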