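# Gene-order (synteny) view: windows of neighbouring genes around a focal
# gene and its homologues, coloured by homology with the reference row.
# Colouring is via the reference row only: a gene in another species takes
# the colour of its reference-row homologue when that homologue is inside
# the visible window, and stays white otherwise.

gene_list_df <- function(gene_id, seq_id, start, end, strand) {
  data.frame(gene_id = as.character(gene_id), seq_id = as.character(seq_id),
             start = as.integer(start), end = as.integer(end),
             strand = as.character(strand), stringsAsFactors = FALSE)
}

#' Window of neighbouring genes around a focal gene
#'
#' @param genes Data frame of genes on one sequence (`gene_id`, `seq_id`,
#'   `start`, `end`, `strand`).
#' @param focal_gene Gene ID that must be present in `genes`.
#' @param k Number of neighbours to keep on each side (window truncated at
#'   the sequence ends; `k = 0` keeps only the focal gene).
#' @return The window as a data frame in genomic order.
#' @export
neighborhood <- function(genes, focal_gene, k = 10) {
  if (k < 0) err_input("k must be >= 0")
  genes <- genes[order(genes$start), , drop = FALSE]
  i <- match(focal_gene, genes$gene_id)
  if (is.na(i)) err_input("focal gene '%s' not on this sequence", focal_gene)
  idx <- max(1L, i - k):min(nrow(genes), i + k)
  out <- genes[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_synteny_row <- function(species, seq_id, genes, focal_gene) {
  if (sum(genes$gene_id == focal_gene) != 1L)
    err_input("row for %s must contain its focal gene exactly once", species)
  genes$focal <- genes$gene_id == focal_gene
  structure(list(species = species, seq_id = seq_id, genes = genes),
            class = "synteny_row")
}

#' Colour synteny rows by homology with the reference row
#'
#' Reference-row genes get sequential colour indices (0, 1, ...) in genomic
#' order. A gene in another row takes the colour index of its reference-row
#' homologue when that homologue is inside the reference window; genes with
#' no homologue in the window get `NA` (drawn white). When a gene has
#' several in-window homologues the left-most one decides.
#'
#' @param reference List with `species`, `seq_id`, `genes` (window data
#'   frame from [neighborhood()]), `focal_gene`.
#' @param others List of the same structure for the other species' rows.
#' @param pairs Data frame of homologous gene pairs (`gene_a`, `gene_b`,
#'   undirected).
#' @return List of `synteny_row` objects (reference first), each with a
#'   `genes` data frame carrying `color_index` (NA = white) and `focal`.
#' @export
color_synteny <- function(reference, others, pairs) {
  ref <- new_synteny_row(reference$species, reference$seq_id,
                         reference$genes, reference$focal_gene)
  ref$genes$color_index <- seq_len(nrow(ref$genes)) - 1L
  partners <- function(g) unique(c(pairs$gene_b[pairs$gene_a == g],
                                   pairs$gene_a[pairs$gene_b == g]))
  rows <- lapply(others, function(row) {
    r <- new_synteny_row(row$species, row$seq_id, row$genes, row$focal_gene)
    r$genes$color_index <- vapply(r$genes$gene_id, function(g) {
      hit <- match(partners(g), ref$genes$gene_id)
      hit <- hit[!is.na(hit)]
      if (length(hit)) ref$genes$color_index[min(hit)] else NA_integer_
    }, integer(1))
    r
  })
  c(list(ref), rows)
}

#' Render the gene-order view as SVG
#'
#' One horizontal row per species; genes as strand-oriented arrow boxes
#' filled by their colour index (white when `NA`); the focal gene of every
#' row outlined red (`genebox focal`).
#'
#' @param rows List of `synteny_row`s, as returned by [color_synteny()].
#' @param options A [view_options()].
#' @return SVG text.
#' @export
render_gene_order_svg <- function(rows, options = view_options()) {
  if (!length(rows)) err_input("no synteny rows to draw")
  rh <- options$row_height
  np <- length(options$palette)
  top <- 6
  labw <- 90
  width <- labw + options$canvas_width + 10
  height <- top * 2 + length(rows) * round(1.5 * rh)
  out <- character(0)
  for (ri in seq_along(rows)) {
    row <- rows[[ri]]
    g <- row$genes
    y0 <- top + (ri - 1L) * round(1.5 * rh)
    ymid <- y0 + 0.5 * rh
    span0 <- min(g$start); span1 <- max(g$end)
    sc <- options$canvas_width / (span1 - span0)
    out <- c(out, sprintf(
      "<text class=\"label\" x=\"2.00\" y=\"%s\">%s</text>",
      fmt(ymid + 3), xml_escape(row$species)))
    out <- c(out, sprintf(
      "<line class=\"intron\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\"/>",
      fmt(labw), fmt(ymid), fmt(labw + options$canvas_width), fmt(ymid)))
    for (i in seq_len(nrow(g))) {
      x1 <- labw + (g$start[i] - span0) * sc
      x2 <- labw + (g$end[i] - span0) * sc
      ah <- min(6, (x2 - x1) / 3)
      y1 <- y0 + 0.1 * rh; y2 <- y0 + 0.9 * rh
      pts <- if (g$strand[i] == "+")
        sprintf("%s,%s %s,%s %s,%s %s,%s %s,%s",
                fmt(x1), fmt(y1), fmt(x2 - ah), fmt(y1), fmt(x2), fmt(ymid),
                fmt(x2 - ah), fmt(y2), fmt(x1), fmt(y2))
      else
        sprintf("%s,%s %s,%s %s,%s %s,%s %s,%s",
                fmt(x2), fmt(y1), fmt(x1 + ah), fmt(y1), fmt(x1), fmt(ymid),
                fmt(x1 + ah), fmt(y2), fmt(x2), fmt(y2))
      cls <- if (is.na(g$color_index[i])) "genebox white"
             else sprintf("genebox c%d", g$color_index[i] %% np)
      if (g$focal[i]) cls <- paste(cls, "focal")
      out <- c(out, sprintf("<polygon class=\"%s\" points=\"%s\"/>", cls, pts))
    }
  }
  paste0(svg_open(width, height, options), "\n",
         paste(out, collapse = "\n"), "\n</svg>\n")
}

#' Export synteny rows as tab-separated text
#'
#' Columns: `species`, `seq_id`, `gene_id`, `start`, `end`, `strand`,
#' `color_index` (`.` for white), `focal` (0/1).
#'
#' @param rows List of `synteny_row`s.
#' @param path Optional output file.
#' @return The lines (invisibly when `path` is given).
#' @export
synteny_rows_tsv <- function(rows, path = NULL) {
  lines <- unlist(lapply(rows, function(row) {
    g <- row$genes
    ci <- if ("color_index" %in% names(g))
      ifelse(is.na(g$color_index), ".", as.character(g$color_index))
    else rep(".", nrow(g))
    fc <- if ("focal" %in% names(g)) as.integer(g$focal) else rep(0L, nrow(g))
    sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%d", row$species, row$seq_id,
            g$gene_id, g$start, g$end, g$strand, ci, fc)
  }))
  lines <- c("species\tseq_id\tgene_id\tstart\tend\tstrand\tcolor_index\tfocal",
             lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
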