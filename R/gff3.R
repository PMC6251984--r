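# GFF3 reading and writing. Attribute parsing is delegated to
# rtracklayer::readGFF(); a preliminary line scan enforces the record-level
# contract (9 tab-separated fields, numeric coordinates, start <= end) so
# malformed records are reported with their line number.

GFF_TYPES <- c("gene", "mRNA", "exon", "CDS",
               "five_prime_UTR", "three_prime_UTR")

#' Parse a GFF3 file into gene models
#'
#' Reads `gene`/`mRNA`/`exon`/`CDS`/`five_prime_UTR`/`three_prime_UTR`
#' features linked through `ID`/`Parent` attributes. Coordinates are
#' converted from GFF3's 1-based inclusive convention to the package-wide
#' 0-based half-open convention, and exons/CDS/UTRs are ordered 5'->3'.
#'
#' When a gene carries several mRNAs, the canonical transcript is the one
#' with the longest total CDS, ties broken by the lexicographically smallest
#' transcript ID (plain GFF3 has no canonical flag).
#'
#' An optional `species=` attribute on gene records is honoured; otherwise
#' species is `NA` and is typically joined in later from the gene tree's
#' NHX `S` tags.
#'
#' @param path Path to a GFF3 file.
#' @return A named list of [gene_model()] objects (class `gene_model_set`),
#'   keyed and ordered by gene ID as encountered in the file.
#' @export
parse_gff3 <- function(path) {
  if (!file.exists(path)) err_input("GFF3 file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  feat <- which(!grepl("^\\s*(#|$)", lines))
  for (i in feat) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      err_input("malformed GFF3 record at line %d: expected 9 fields, got %d",
                i, length(f))
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e))
      err_input("malformed GFF3 record at line %d: non-numeric coordinates", i)
    if (s > e)
      err_input("malformed GFF3 record at line %d: start %d > end %d", i, s, e)
  }
  df <- as.data.frame(rtracklayer::readGFF(path))
  df$type <- as.character(df$type)
  df <- df[df$type %in% GFF_TYPES, , drop = FALSE]
  df$seqid <- as.character(df$seqid)
  df$strand <- as.character(df$strand)
  parent1 <- function(p) if (length(p)) as.character(p)[1L] else NA_character_
  df$parent1 <- vapply(df$Parent, parent1, character(1))
  get_attr <- function(rows, name) {
    if (name %in% names(df)) as.character(df[[name]][rows]) else
      rep(NA_character_, length(rows))
  }

  genes <- which(df$type == "gene")
  mrnas <- which(df$type == "mRNA")
  parts <- which(!df$type %in% c("gene", "mRNA"))
  gene_ids <- as.character(df$ID[genes])
  mrna_ids <- as.character(df$ID[mrnas])
  if (anyNA(gene_ids)) err_input("gene record without an ID attribute")
  if (anyNA(mrna_ids)) err_input("mRNA record without an ID attribute")
  bad <- which(!(df$parent1[mrnas] %in% gene_ids))
  if (length(bad))
    err_input("linkage error: mRNA %s references unknown gene '%s'",
              mrna_ids[bad[1L]], df$parent1[mrnas][bad[1L]])
  bad <- which(!(df$parent1[parts] %in% mrna_ids))
  if (length(bad))
    err_input("linkage error: %s record references unknown mRNA '%s'",
              df$type[parts][bad[1L]], df$parent1[parts][bad[1L]])

  out <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    gid <- gene_ids[gi]
    g_iv <- genomic_interval(df$seqid[g], df$start[g] - 1L, df$end[g],
                             df$strand[g])
    tx_rows <- mrnas[df$parent1[mrnas] == gid]
    if (!length(tx_rows)) err_input("gene %s has no mRNA", gid)
    txs <- lapply(tx_rows, function(m) {
      tid <- as.character(df$ID[m])
      kids <- parts[df$parent1[parts] == tid]
      sub <- function(ty) {
        r <- kids[df$type[kids] == ty]
        interval_df(df$seqid[r], df$start[r] - 1L, df$end[r], df$strand[r])
      }
      transcript_model(tid, gid, df$strand[m], sub("exon"), sub("CDS"),
                       sub("five_prime_UTR"), sub("three_prime_UTR"))
    })
    lens <- vapply(txs, cds_length, numeric(1))
    ids <- vapply(txs, `[[`, character(1), "transcript_id")
    canon <- txs[[order(-lens, ids)[1L]]]
    sym <- get_attr(g, "Name"); if (is.na(sym)) sym <- gid
    out[[gid]] <- gene_model(gid, sym, get_attr(g, "species"), g_iv, canon)
  }
  structure(out, class = "gene_model_set")
}

#' Write gene models as GFF3
#'
#' Inverse of [parse_gff3()] for the canonical transcript: emits
#' gene/mRNA/exon/CDS/UTR records with 1-based inclusive coordinates and
#' correct CDS phases. `parse_gff3(write_gff3(models))` reproduces the
#' models exactly.
#'
#' @param models A `gene_model_set` (or list of [gene_model()]).
#' @param path Optional output file; when `NULL` the GFF3 text is returned
#'   as a character vector of lines.
#' @return Invisibly (or visibly when `path` is `NULL`) the GFF3 lines.
#' @export
write_gff3 <- function(models, path = NULL) {
  rows <- function(df_iv, type, parent, phases = NULL) {
    if (!nrow(df_iv)) return(character(0))
    g <- df_iv[order(df_iv$start), , drop = FALSE]
    ph <- if (is.null(phases)) rep(".", nrow(g)) else phases[order(df_iv$start)]
    sprintf("%s\tgenetreeviz\t%s\t%d\t%d\t.\t%s\t%s\tID=%s.%s%d;Parent=%s",
            g$seq_id, type, g$start + 1L, g$end, g$strand, ph,
            parent, tolower(type), seq_len(nrow(g)), parent)
  }
  lines <- "##gff-version 3"
  for (gm in models) {
    tx <- gm$transcript
    iv <- gm$interval
    attrs <- sprintf("ID=%s;Name=%s", gm$gene_id, gm$symbol)
    if (!is.na(gm$species)) attrs <- paste0(attrs, ";species=", gm$species)
    lines <- c(lines, sprintf("%s\tgenetreeviz\tgene\t%d\t%d\t.\t%s\t.\t%s",
                              iv$seq_id, iv$start + 1L, iv$end, iv$strand, attrs))
    tx_span <- range(c(tx$exons$start, tx$exons$end))
    lines <- c(lines,
               sprintf("%s\tgenetreeviz\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       iv$seq_id, tx_span[1L] + 1L, tx_span[2L], tx$strand,
                       tx$transcript_id, gm$gene_id))
    # CDS phase: leading bases of this segment that complete the previous codon
    w <- interval_widths(tx$cds)
    phases <- as.character((3L - cumsum(c(0L, w[-length(w)])) %% 3L) %% 3L)
    lines <- c(lines,
               rows(tx$exons, "exon", tx$transcript_id),
               rows(tx$cds, "CDS", tx$transcript_id, phases),
               rows(tx$utr5, "five_prime_UTR", tx$transcript_id),
               rows(tx$utr3, "three_prime_UTR", tx$transcript_id))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
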