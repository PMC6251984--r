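# Gene trees: Newick parsing via ape, extended with NHX comment handling so
# per-node evolutionary events (speciation / duplication / gene split) and
# leaf species survive the round trip. A `gene_tree` wraps an ape "phylo"
# object plus an event label per internal node and a species per leaf.

EVENTS <- c("speciation", "duplication", "gene_split")

parse_nhx_tags <- function(comment) {
  body <- sub("^\\[", "", sub("\\]$", "", comment))
  if (!startsWith(body, "&&NHX")) return(character(0))
  body <- sub("^&&NHX:?", "", body)
  if (!nzchar(body)) return(character(0))
  kv <- strsplit(strsplit(body, ":", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) if (length(x) > 1L) x[2L] else "",
                         character(1)),
                  vapply(kv, `[[`, character(1), 1L))
}

event_from_tags <- function(tags) {
  if (!length(tags)) return("speciation")
  if (identical(unname(tags["Ev"]), "gene_split")) return("gene_split")
  if (identical(unname(tags["D"]), "Y")) return("duplication")
  "speciation"
}

#' Parse a Newick/NHX gene tree
#'
#' Internal nodes default to `speciation`; an NHX `D=Y` tag marks
#' `duplication` and a custom `Ev=gene_split` tag marks `gene_split`
#' (standard NHX has no gene-split flag). Leaf species come from NHX `S`
#' tags, falling back to `species_map`. Branch lengths are preserved.
#'
#' @param text Newick text (NHX comments may follow either the node label or
#'   the branch length).
#' @param species_map Optional named character vector mapping leaf gene IDs
#'   to species names, used where no `S` tag is present.
#' @return A list of class `gene_tree` with elements `phylo` (ape tree, or
#'   `NULL` for a single-leaf tree), `tips`, `species` (named by tip),
#'   `events` (one per internal node, indexed by ape node number minus the
#'   tip count).
#' @export
parse_newick_nhx <- function(text, species_map = NULL) {
  text <- trimws(paste(text, collapse = ""))
  if (!nzchar(text)) err_input("empty Newick text")
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        err_input("Newick parse error: unmatched ')' at character %d", i)
    }
  }
  if (depth != 0L)
    err_input("Newick parse error: %d unclosed '(' at end of input", depth)

  # Replace bracket comments with sentinel label suffixes ape will keep.
  m <- gregexpr("\\[[^]]*\\]", text)[[1]]
  tags <- list()
  if (m[1L] != -1L) {
    starts <- as.integer(m); lens <- attr(m, "match.length")
    pieces <- character(0); pos <- 1L
    for (k in seq_along(starts)) {
      com <- substr(text, starts[k], starts[k] + lens[k] - 1L)
      before <- substr(text, pos, starts[k] - 1L)
      token <- sprintf("NHXTAG%dx", k)
      # a comment placed after the branch length belongs to the node label
      bl <- regexpr(":[-+0-9.eE]+$", before)
      before <- if (bl != -1L)
        paste0(substr(before, 1L, bl - 1L), token,
               substr(before, bl, nchar(before)))
      else paste0(before, token)
      pieces <- c(pieces, before)
      tags[[k]] <- parse_nhx_tags(com)
      pos <- starts[k] + lens[k]
    }
    text <- paste(c(pieces, substr(text, pos, nchar(text))), collapse = "")
  }

  split_label <- function(lab) {
    # returns list(label, tag_indices)
    idx <- integer(0)
    mm <- gregexpr("NHXTAG([0-9]+)x", lab)[[1]]
    if (mm[1L] != -1L) {
      toks <- regmatches(lab, gregexpr("NHXTAG([0-9]+)x", lab))[[1]]
      idx <- as.integer(sub("NHXTAG([0-9]+)x", "\\1", toks))
      lab <- gsub("NHXTAG[0-9]+x", "", lab)
    }
    list(label = lab, idx = idx)
  }
  node_tags <- function(idx) {
    if (!length(idx)) character(0) else do.call(c, tags[idx])
  }

  if (!grepl("(", text, fixed = TRUE)) {
    # degenerate single-leaf tree; ape cannot represent it
    lab <- sub(";\\s*$", "", text)
    lab <- sub(":[-+0-9.eE]+$", "", lab)
    sl <- split_label(lab)
    tg <- node_tags(sl$idx)
    sp <- if ("S" %in% names(tg)) unname(tg["S"])
      else if (!is.null(species_map) && sl$label %in% names(species_map))
        unname(species_map[sl$label])
      else NA_character_
    return(structure(list(phylo = NULL, tips = sl$label,
                          species = stats::setNames(as.character(sp), sl$label),
                          events = character(0)),
                     class = "gene_tree"))
  }

  phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy)) err_input("Newick parse error: ape could not parse tree")

  ntip <- length(phy$tip.label)
  tip_sl <- lapply(phy$tip.label, split_label)
  tips <- vapply(tip_sl, `[[`, character(1), "label")
  if (anyDuplicated(tips))
    err_input("duplicate leaf name '%s' in tree", tips[duplicated(tips)][1L])
  species <- vapply(seq_len(ntip), function(i) {
    tg <- node_tags(tip_sl[[i]]$idx)
    if ("S" %in% names(tg)) return(unname(tg["S"]))
    if (!is.null(species_map) && tips[i] %in% names(species_map))
      return(unname(species_map[tips[i]]))
    NA_character_
  }, character(1))
  events <- rep("speciation", phy$Nnode)
  if (!is.null(phy$node.label)) {
    for (j in seq_len(phy$Nnode)) {
      sl <- split_label(phy$node.label[j])
      events[j] <- event_from_tags(node_tags(sl$idx))
    }
    phy$node.label <- NULL
  }
  phy$tip.label <- tips
  structure(list(phylo = phy, tips = tips,
                 species = stats::setNames(species, tips),
                 events = events),
            class = "gene_tree")
}

n_tips <- function(tree) length(tree$tips)

tree_event <- function(tree, node) tree$events[node - n_tips(tree)]

# children of an internal node, in edge-matrix (input) order
tree_children <- function(phy, node) phy$edge[phy$edge[, 1L] == node, 2L]

# tip indices under a node (the node itself if it is a tip)
tips_under <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    ch <- tree_children(phy, nd)
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

#' Serialize a gene tree to Newick/NHX
#'
#' Duplication and gene-split nodes are written as `[&&NHX:D=Y]` and
#' `[&&NHX:Ev=gene_split]` comments after the branch length; leaf species as
#' `[&&NHX:S=...]`. Re-parsing the output gives back an isomorphic tree with
#' branch lengths preserved to better than 1e-9.
#'
#' @param tree A `gene_tree`.
#' @param path Optional output file.
#' @return The Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  lenstr <- function(x) if (is.na(x)) "" else sprintf(":%.12g", x)
  if (is.null(tree$phylo)) {
    sp <- tree$species[[1L]]
    s <- paste0(tree$tips[1L],
                if (!is.na(sp)) sprintf("[&&NHX:S=%s]", sp) else "", ";")
  } else {
    phy <- tree$phylo
    ntip <- length(phy$tip.label)
    elen <- function(node) {
      if (is.null(phy$edge.length)) return(NA_real_)
      i <- which(phy$edge[, 2L] == node)
      if (length(i)) phy$edge.length[i] else NA_real_
    }
    rec <- function(node) {
      if (node <= ntip) {
        lab <- phy$tip.label[node]
        sp <- tree$species[[lab]]
        paste0(lab, lenstr(elen(node)),
               if (!is.na(sp)) sprintf("[&&NHX:S=%s]", sp) else "")
      } else {
        inner <- paste(vapply(tree_children(phy, node), rec, character(1)),
                       collapse = ",")
        ev <- tree_event(tree, node)
        nhx <- switch(ev, duplication = "[&&NHX:D=Y]",
                      gene_split = "[&&NHX:Ev=gene_split]", "")
        paste0("(", inner, ")", lenstr(elen(node)), nhx)
      }
    }
    s <- paste0(rec(ntip + 1L), ";")
  }
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Convert a gene tree to a nested-list JSON dialect
#'
#' Each node becomes an object with `event`, `branch_length` and `children`;
#' leaves additionally carry `gene_id` and `species`. This mirrors the
#' Newick/NHX content one-to-one.
#'
#' @param tree A `gene_tree`.
#' @param path Optional output file.
#' @return JSON text (invisibly when `path` is given).
#' @export
tree_to_json <- function(tree, path = NULL) {
  if (is.null(tree$phylo)) {
    x <- list(event = "leaf", gene_id = tree$tips[1L],
              species = tree$species[[1L]], branch_length = NULL,
              children = list())
  } else {
    phy <- tree$phylo
    ntip <- length(phy$tip.label)
    elen <- function(node) {
      if (is.null(phy$edge.length)) return(NULL)
      i <- which(phy$edge[, 2L] == node)
      if (length(i)) phy$edge.length[i] else NULL
    }
    rec <- function(node) {
      if (node <= ntip) {
        lab <- phy$tip.label[node]
        list(event = "leaf", gene_id = lab, species = tree$species[[lab]],
             branch_length = elen(node), children = list())
      } else {
        list(event = tree_event(tree, node), branch_length = elen(node),
             children = lapply(tree_children(phy, node), rec))
      }
    }
    x <- rec(ntip + 1L)
  }
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(path)) {
    writeLines(as.character(js), path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Test whether two gene trees are isomorphic
#'
#' Compares topology, leaf labels and species, internal-node events, and
#' branch lengths (to 1e-9), ignoring child order.
#'
#' @param a,b `gene_tree` objects.
#' @return `TRUE` or `FALSE`.
#' @export
tree_isomorphic <- function(a, b) {
  canon <- function(tree) {
    fmtlen <- function(x) if (is.na(x)) "NA" else sprintf("%.9f", x)
    if (is.null(tree$phylo))
      return(sprintf("L(%s|%s|NA)", tree$tips[1L], tree$species[[1L]]))
    phy <- tree$phylo
    ntip <- length(phy$tip.label)
    elen <- function(node) {
      if (is.null(phy$edge.length)) return(NA_real_)
      i <- which(phy$edge[, 2L] == node)
      if (length(i)) phy$edge.length[i] else NA_real_
    }
    rec <- function(node) {
      if (node <= ntip) {
        lab <- phy$tip.label[node]
        sprintf("L(%s|%s|%s)", lab, tree$species[[lab]], fmtlen(elen(node)))
      } else {
        kids <- sort(vapply(tree_children(phy, node), rec, character(1)))
        sprintf("N(%s|%s|%s)", tree_event(tree, node), fmtlen(elen(node)),
                paste(kids, collapse = ","))
      }
    }
    rec(ntip + 1L)
  }
  identical(canon(a), canon(b))
}
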