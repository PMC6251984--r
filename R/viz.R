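# Deterministic layout and static SVG rendering. Two layout modes mirror the
# browser's "Introns" setting: exon-focused (every intron collapsed to a
# fixed pixel width, exons proportional to nucleotide length) and
# proportional (one global nt->px scale, longest gene spanning the canvas).
# All rendering is a pure function of its inputs: identical inputs give
# byte-identical SVG.

DEFAULT_PALETTE <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
                     "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf",
                     "#aec7e8", "#ffbb78")

#' View options for layout and rendering
#'
#' @param mode `"exon_focused"` (default) or `"proportional"`.
#' @param fixed_intron_px Pixel width of every intron in exon-focused mode.
#' @param canvas_width Width in pixels available to the widest gene row.
#' @param row_height Height in pixels of one gene row.
#' @param palette Ordered colour vector, cycled by `color_index %% length`.
#' @param show_labels Draw gene labels.
#' @param wrap_columns Monospace column count for the textual pairwise
#'   alignment panel.
#' @param tree_width Pixel width of the tree panel in the gene-tree view.
#' @param label_width Pixel width reserved for row labels.
#' @param phylogram Use branch lengths for tree x-positions (default is a
#'   cladogram, which ignores them).
#' @return A list of class `view_options`.
#' @export
view_options <- function(mode = c("exon_focused", "proportional"),
                         fixed_intron_px = 6, canvas_width = 1200,
                         row_height = 24, palette = DEFAULT_PALETTE,
                         show_labels = TRUE, wrap_columns = 60,
                         tree_width = 250, label_width = 150,
                         phylogram = FALSE) {
  mode <- match.arg(mode)
  if (fixed_intron_px <= 0) err_input("fixed_intron_px must be positive")
  if (canvas_width <= 0) err_input("canvas_width must be positive")
  structure(list(mode = mode, fixed_intron_px = fixed_intron_px,
                 canvas_width = canvas_width, row_height = row_height,
                 palette = palette, show_labels = show_labels,
                 wrap_columns = wrap_columns, tree_width = tree_width,
                 label_width = label_width, phylogram = phylogram),
            class = "view_options")
}

track_span <- function(track) {
  c(min(track$segments$start), max(track$segments$end))
}

track_intron_stats <- function(track) {
  sp <- track_span(track)
  introns <- intron_df(track$transcript)
  list(span = sp, n_introns = nrow(introns),
       intron_nt = sum(interval_widths(introns)),
       exonic_nt = (sp[2L] - sp[1L]) - sum(interval_widths(introns)))
}

#' Common nt->px scale for a set of tracks
#'
#' Exon-focused: the scale is chosen so the widest row (exonic nucleotides
#' at scale plus its introns at `fixed_intron_px` each) spans exactly
#' `canvas_width`. Proportional: `canvas_width` divided by the longest gene
#' span, so the longest gene spans the canvas exactly.
#'
#' @param tracks List of `comparison_track`s.
#' @param options A [view_options()].
#' @return The scale in pixels per nucleotide.
#' @export
view_scale <- function(tracks, options) {
  stats <- lapply(tracks, track_intron_stats)
  if (options$mode == "exon_focused") {
    s <- vapply(stats, function(st) {
      avail <- options$canvas_width - st$n_introns * options$fixed_intron_px
      if (avail <= 0)
        err_input("canvas too narrow for %d fixed-width introns", st$n_introns)
      avail / st$exonic_nt
    }, numeric(1))
    min(s)
  } else {
    spans <- vapply(stats, function(st) st$span[2L] - st$span[1L], numeric(1))
    options$canvas_width / max(spans)
  }
}

# piecewise-linear genomic -> pixel map with introns compressed
make_g2px_exon_focused <- function(track, options, scale) {
  sp <- track_span(track)
  introns <- intron_df(track$transcript)
  introns <- introns[order(introns$start), , drop = FALSE]
  g0 <- sp[1L]; px0 <- 0
  gs <- numeric(0); pxs <- numeric(0); rates <- numeric(0)
  add <- function(gstart, gend, rate) {
    gs <<- c(gs, gstart); pxs <<- c(pxs, px0); rates <<- c(rates, rate)
    px0 <<- px0 + (gend - gstart) * rate
    g0 <<- gend
  }
  for (i in seq_len(nrow(introns))) {
    if (introns$start[i] > g0) add(g0, introns$start[i], scale)
    add(introns$start[i], introns$end[i],
        options$fixed_intron_px / (introns$end[i] - introns$start[i]))
  }
  if (sp[2L] > g0) add(g0, sp[2L], scale)
  function(g) {
    i <- findInterval(g, gs)
    i[i < 1L] <- 1L
    pxs[i] + (g - gs[i]) * rates[i]
  }
}

make_g2px_proportional <- function(track, scale) {
  sp <- track_span(track)
  function(g) (g - sp[1L]) * scale
}

shape_df <- function(shape = character(), x = numeric(), y = numeric(),
                     width = numeric(), height = numeric(),
                     class = character(), color_index = integer(),
                     text = character()) {
  data.frame(shape = as.character(shape), x = as.numeric(x),
             y = as.numeric(y), width = as.numeric(width),
             height = as.numeric(height), class = as.character(class),
             color_index = as.integer(color_index),
             text = as.character(text), stringsAsFactors = FALSE)
}

layout_track <- function(track, options, g2px) {
  rh <- options$row_height
  np <- length(options$palette)
  shapes <- list()
  add <- function(...) shapes[[length(shapes) + 1L]] <<- shape_df(...)
  s <- track$segments
  for (i in seq_len(nrow(s))) {
    x1 <- g2px(s$start[i]); x2 <- g2px(s$end[i])
    kind <- s$kind[i]
    if (kind == "MATCH") {
      add("rect", x1, 0.2 * rh, x2 - x1, 0.6 * rh,
          sprintf("exon c%d", s$color_index[i] %% np), s$color_index[i], NA)
    } else if (kind == "INSERTION") {
      add("rect", x1, 0.3 * rh, x2 - x1, 0.4 * rh, "insertion", NA, NA)
    } else if (kind %in% c("UTR5", "UTR3")) {
      add("rect", x1, 0.3 * rh, x2 - x1, 0.4 * rh, "utr", NA, NA)
    } else { # NONCODING (intron): horizontal line at mid-height
      add("line", x1, 0.5 * rh, x2 - x1, 0, "intron", NA, NA)
    }
  }
  for (pos in track$deletion_marks)
    add("line", g2px(pos), 0.15 * rh, 0, 0.7 * rh, "deletion", NA, NA)
  sp <- track_span(track)
  roww <- g2px(sp[2L])
  # strand arrow at the 3' end of the gene, inside the row
  if (track$strand == "+")
    add("arrow", max(0, roww - 7), 0.5 * rh, 6, 6, "strand-arrow fwd", NA, NA)
  else
    add("arrow", min(1, roww), 0.5 * rh, 6, 6, "strand-arrow rev", NA, NA)
  if (isTRUE(options$show_labels))
    add("text", min(roww + 6, options$canvas_width - 1), 0.7 * rh, 0, 0,
        if (isTRUE(track$guide_flag)) "label guide" else "label",
        NA, track$gene_id)
  structure(list(gene_id = track$gene_id, guide_flag = track$guide_flag,
                 width = roww, shapes = do.call(rbind, shapes)),
            class = "screen_track")
}

#' Exon-focused layout of a comparison track
#'
#' Every intron occupies exactly `fixed_intron_px` pixels; exon (and UTR)
#' widths are proportional to their nucleotide lengths.
#'
#' @param track A `comparison_track`.
#' @param options A [view_options()].
#' @param scale nt->px scale shared across the view; computed for this track
#'   alone when `NULL`.
#' @return A `screen_track`: `gene_id`, `width`, and a `shapes` data frame
#'   (`shape`, `x`, `y`, `width`, `height`, `class`, `color_index`, `text`)
#'   in 5'->3' segment order.
#' @export
layout_exon_focused <- function(track, options = view_options(),
                                scale = NULL) {
  if (is.null(scale))
    scale <- view_scale(list(track),
                        within_options(options, mode = "exon_focused"))
  layout_track(track, options, make_g2px_exon_focused(track, options, scale))
}

#' Proportional layout of a comparison track
#'
#' All features share one nt->px scale; introns are drawn to their true
#' relative size.
#'
#' @inheritParams layout_exon_focused
#' @return A `screen_track`; see [layout_exon_focused()].
#' @export
layout_proportional <- function(track, options = view_options("proportional"),
                                scale = NULL) {
  if (is.null(scale))
    scale <- view_scale(list(track),
                        within_options(options, mode = "proportional"))
  layout_track(track, options, make_g2px_proportional(track, scale))
}

within_options <- function(options, ...) {
  mods <- list(...)
  options[names(mods)] <- mods
  options
}

layout_by_mode <- function(track, options, scale) {
  if (options$mode == "exon_focused") layout_exon_focused(track, options, scale)
  else layout_proportional(track, options, scale)
}

## ---- SVG emission ----------------------------------------------------

fmt <- function(x) sprintf("%.2f", x)

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub("\"", "&quot;", s, fixed = TRUE)
}

svg_style <- function(options) {
  pal <- vapply(seq_along(options$palette), function(i)
    sprintf(".c%d { fill: %s; }", i - 1L, options$palette[i]), character(1))
  paste(c("<style>",
          pal,
          ".white { fill: #ffffff; }",
          ".exon { stroke: #333333; stroke-width: 0.5; }",
          ".insertion { fill: #000000; }",
          ".deletion { stroke: #cc0000; stroke-width: 1.5; }",
          ".intron { stroke: #999999; stroke-width: 1; }",
          ".utr { fill: #bbbbbb; }",
          ".label { font: 10px sans-serif; fill: #555555; }",
          ".label.guide { fill: #cc0000; font-weight: bold; }",
          ".branch { stroke: #444444; fill: none; }",
          ".node.speciation { fill: #1f77b4; }",
          ".node.duplication { fill: #d62728; }",
          ".node.gene_split { fill: #17becf; }",
          ".node.leaf { fill: #777777; }",
          ".node.leaf.guide { fill: #000000; }",
          ".strand-arrow { fill: #333333; }",
          ".connector { fill-opacity: 0.35; stroke: none; }",
          ".genebox { stroke: #333333; stroke-width: 1; }",
          ".genebox.focal { stroke: #cc0000; stroke-width: 2; }",
          ".aln-text { font: 12px monospace; }",
          "</style>"),
        collapse = "\n")
}

svg_open <- function(width, height, options) {
  paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" width=\"",
         fmt(width), "\" height=\"", fmt(height), "\" viewBox=\"0 0 ",
         fmt(width), " ", fmt(height), "\">\n", svg_style(options))
}

svg_shape <- function(row) {
  cls <- row$class
  if (row$shape == "rect") {
    sprintf("<rect class=\"%s\" x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\"/>",
            cls, fmt(row$x), fmt(row$y), fmt(max(row$width, 0.5)),
            fmt(row$height))
  } else if (row$shape == "line") {
    if (row$height == 0)
      sprintf("<line class=\"%s\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\"/>",
              cls, fmt(row$x), fmt(row$y), fmt(row$x + row$width), fmt(row$y))
    else
      sprintf("<line class=\"%s\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\"/>",
              cls, fmt(row$x), fmt(row$y), fmt(row$x), fmt(row$y + row$height))
  } else if (row$shape == "arrow") {
    h <- row$height / 2
    pts <- if (grepl("fwd", cls))
      sprintf("%s,%s %s,%s %s,%s", fmt(row$x), fmt(row$y - h),
              fmt(row$x + row$width), fmt(row$y), fmt(row$x), fmt(row$y + h))
    else
      sprintf("%s,%s %s,%s %s,%s", fmt(row$x + row$width), fmt(row$y - h),
              fmt(row$x), fmt(row$y), fmt(row$x + row$width), fmt(row$y + h))
    sprintf("<polygon class=\"%s\" points=\"%s\"/>", cls, pts)
  } else { # text
    sprintf("<text class=\"%s\" x=\"%s\" y=\"%s\" xml:space=\"preserve\">%s</text>",
            cls, fmt(row$x), fmt(row$y), xml_escape(row$text))
  }
}

svg_screen_track <- function(st, dx, dy) {
  body <- vapply(seq_len(nrow(st$shapes)), function(i)
    svg_shape(st$shapes[i, ]), character(1))
  paste0("<g transform=\"translate(", fmt(dx), ",", fmt(dy), ")\">\n",
         paste(body, collapse = "\n"), "\n</g>")
}

# node x/y positions for the tree panel
tree_layout <- function(tree, options, top) {
  phy <- tree$phylo
  rh <- options$row_height
  tw <- options$tree_width
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  y <- numeric(ntip + nnode)
  y[seq_len(ntip)] <- top + (seq_len(ntip) - 0.5) * rh
  x <- numeric(ntip + nnode)
  fill_y <- function(node) {
    if (node <= ntip) return(y[node])
    ys <- vapply(tree_children(phy, node), fill_y, numeric(1))
    y[node] <<- mean(ys)
    y[node]
  }
  fill_y(ntip + 1L)
  if (isTRUE(options$phylogram) && !is.null(phy$edge.length)) {
    depth <- numeric(ntip + nnode)
    walk <- function(node, d) {
      depth[node] <<- d
      for (ch in tree_children(phy, node)) {
        i <- which(phy$edge[, 2L] == ch)
        walk(ch, d + phy$edge.length[i])
      }
    }
    walk(ntip + 1L, 0)
    x <- 12 + depth / max(depth) * (tw - 30)
  } else {
    lvl <- numeric(ntip + nnode) # levels above the nearest-to-root leaf path
    fill_h <- function(node) {
      if (node <= ntip) { lvl[node] <<- 0; return(0) }
      h <- 1 + max(vapply(tree_children(phy, node), fill_h, numeric(1)))
      lvl[node] <<- h
      h
    }
    hmax <- max(1, fill_h(ntip + 1L))
    x <- (tw - 18) - lvl / hmax * (tw - 30)
  }
  list(x = x, y = y)
}

svg_tree_panel <- function(tree, options, top, guide_gene) {
  if (is.null(tree$phylo)) {
    y <- top + 0.5 * options$row_height
    cls <- if (identical(tree$tips[1L], guide_gene)) "node leaf guide"
           else "node leaf"
    r <- if (identical(tree$tips[1L], guide_gene)) 4.5 else 2.5
    return(sprintf("<circle class=\"%s\" cx=\"%s\" cy=\"%s\" r=\"%s\"/>",
                   cls, fmt(options$tree_width - 18), fmt(y), fmt(r)))
  }
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  lay <- tree_layout(tree, options, top)
  out <- character(0)
  for (node in (ntip + 1L):(ntip + phy$Nnode)) {
    for (ch in tree_children(phy, node)) {
      out <- c(out, sprintf(
        "<path class=\"branch\" d=\"M %s %s V %s H %s\"/>",
        fmt(lay$x[node]), fmt(lay$y[node]), fmt(lay$y[ch]), fmt(lay$x[ch])))
    }
    out <- c(out, sprintf(
      "<circle class=\"node %s\" cx=\"%s\" cy=\"%s\" r=\"3.00\"/>",
      tree_event(tree, node), fmt(lay$x[node]), fmt(lay$y[node])))
  }
  for (i in seq_len(ntip)) {
    guide <- identical(phy$tip.label[i], guide_gene)
    out <- c(out, sprintf(
      "<circle class=\"%s\" cx=\"%s\" cy=\"%s\" r=\"%s\"/>",
      if (guide) "node leaf guide" else "node leaf",
      fmt(lay$x[i]), fmt(lay$y[i]), fmt(if (guide) 4.5 else 2.5)))
  }
  paste(out, collapse = "\n")
}

#' Render the gene-tree view as SVG
#'
#' Phylogenetic tree on the left (nodes coloured by evolutionary event, the
#' guide leaf as a larger black circle), one gene-structure row per leaf on
#' the right, with exon blocks coloured by matching guide exon, black
#' insertion bars, red deletion lines, gray UTR blocks and strand arrows.
#' The guide row's label carries the red `label guide` style.
#'
#' @param tree A `gene_tree`.
#' @param tracks Named list of `comparison_track`s covering every leaf.
#' @param options A [view_options()].
#' @return SVG text (a single string).
#' @export
render_genetree_svg <- function(tree, tracks, options = view_options()) {
  leaves <- leaf_order(tree)
  missing <- setdiff(leaves, names(tracks))
  if (length(missing))
    err_input("track/leaf mismatch: no track for %s", missing[1L])
  tracks <- tracks[leaves]
  guide_gene <- leaves[which(vapply(tracks, function(t)
    isTRUE(t$guide_flag), logical(1)))[1L]]
  scale <- view_scale(tracks, options)
  sts <- lapply(tracks, layout_by_mode, options = options, scale = scale)
  top <- 6
  height <- top * 2 + length(leaves) * options$row_height
  width <- options$tree_width + options$canvas_width + options$label_width
  rowsvg <- vapply(seq_along(sts), function(i)
    svg_screen_track(sts[[i]], options$tree_width,
                     top + (i - 1L) * options$row_height), character(1))
  paste0(svg_open(width, height, options), "\n",
         svg_tree_panel(tree, options, top, guide_gene), "\n",
         paste(rowsvg, collapse = "\n"), "\n</svg>\n")
}

#' Render the pairwise (1-to-1) view as SVG
#'
#' Upper panel: the guide and target gene structures with connector polygons
#' joining each target MATCH fragment to the guide exon it aligns to. Lower
#' panel: the textual pairwise alignment wrapped at
#' `options$wrap_columns` monospace columns, three lines per block (guide,
#' match line — `|` identity, `+` positive score — and target).
#'
#' @param guide_track,target_track `comparison_track`s (the guide's is its
#'   self-comparison).
#' @param msa Named character vector with the two aligned rows (guide first).
#' @param options A [view_options()].
#' @param matrix Scoring matrix for the match line (default BLOSUM62).
#' @return SVG text.
#' @export
render_pairwise_svg <- function(guide_track, target_track, msa,
                                options = view_options(),
                                matrix = blosum62()) {
  if (length(msa) != 2L)
    err_input("pairwise view needs exactly 2 aligned sequences, got %d",
              length(msa))
  rh <- options$row_height
  tracks <- list(guide_track, target_track)
  scale <- view_scale(tracks, options)
  sts <- lapply(tracks, layout_by_mode, options = options, scale = scale)
  gy <- 8; ty <- gy + 3 * rh
  # connectors: one per target MATCH fragment, to the guide exon of the
  # same colour index
  gshapes <- sts[[1L]]$shapes
  tshapes <- sts[[2L]]$shapes
  gm <- gshapes[grepl("^exon ", gshapes$class), , drop = FALSE]
  tm <- tshapes[grepl("^exon ", tshapes$class), , drop = FALSE]
  np <- length(options$palette)
  conn <- character(0)
  for (i in seq_len(nrow(tm))) {
    ci <- tm$color_index[i]
    g <- gm[gm$color_index == ci, , drop = FALSE]
    if (!nrow(g)) next
    gx1 <- min(g$x); gx2 <- max(g$x + g$width)
    tx1 <- tm$x[i]; tx2 <- tm$x[i] + tm$width[i]
    conn <- c(conn, sprintf(
      "<polygon class=\"connector c%d\" points=\"%s,%s %s,%s %s,%s %s,%s\"/>",
      ci %% np,
      fmt(gx1), fmt(gy + 0.8 * rh), fmt(gx2), fmt(gy + 0.8 * rh),
      fmt(tx2), fmt(ty + 0.2 * rh), fmt(tx1), fmt(ty + 0.2 * rh)))
  }
  # textual alignment blocks
  a <- strsplit(msa[[1L]], "")[[1]]
  b <- strsplit(msa[[2L]], "")[[1]]
  if (length(a) != length(b))
    err_input("aligned rows differ in length (%d vs %d)", length(a), length(b))
  mid <- vapply(seq_along(a), function(i) {
    if (a[i] == "-" || b[i] == "-") return(" ")
    if (a[i] == b[i]) return("|")
    if (a[i] %in% rownames(matrix) && b[i] %in% rownames(matrix) &&
        matrix[a[i], b[i]] > 0) "+" else " "
  }, character(1))
  wrap <- options$wrap_columns
  nblock <- ceiling(length(a) / wrap)
  lineh <- 14
  texty <- ty + 2 * rh + 10
  blocks <- character(0)
  for (bi in seq_len(nblock)) {
    idx <- ((bi - 1L) * wrap + 1L):min(bi * wrap, length(a))
    y0 <- texty + (bi - 1L) * (3 * lineh + 8)
    lines <- c(paste(a[idx], collapse = ""), paste(mid[idx], collapse = ""),
               paste(b[idx], collapse = ""))
    blocks <- c(blocks, paste0(
      "<g class=\"aln-block\">\n",
      paste(sprintf(
        "<text class=\"aln-text\" x=\"10.00\" y=\"%s\" xml:space=\"preserve\">%s</text>",
        fmt(y0 + seq_along(lines) * lineh), xml_escape(lines)),
        collapse = "\n"),
      "\n</g>"))
  }
  height <- texty + nblock * (3 * lineh + 8) + 10
  width <- max(options$canvas_width + options$label_width,
               wrap * 7.5 + 20)
  paste0(svg_open(width, height, options), "\n",
         paste(conn, collapse = "\n"), "\n",
         svg_screen_track(sts[[1L]], 0, gy), "\n",
         svg_screen_track(sts[[2L]], 0, ty), "\n",
         paste(blocks, collapse = "\n"), "\n</svg>\n")
}
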