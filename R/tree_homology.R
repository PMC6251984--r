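# Homology typing from an event-labelled gene tree. The type of a gene pair
# follows from the event at their last common ancestor: a duplication LCA
# makes paralogs; a speciation LCA makes orthologs whose one2one / one2many
# / many2many flavour is decided by how many copies each species kept in
# the two subtrees under the LCA. Gene-split nodes are treated as
# speciation for typing (they mark fragmented annotation, not a copy-number
# event) but keep their own label for rendering.

HOMOLOGY_TYPES <- c("ortholog_one2one", "ortholog_one2many",
                    "ortholog_many2many", "within_species_paralog",
                    "between_species_paralog")

#' Leaf order of a gene tree
#'
#' Depth-first left-to-right order — the row order of the gene-tree view.
#'
#' @param tree A `gene_tree`.
#' @return Character vector of leaf gene IDs.
#' @export
leaf_order <- function(tree) tree$tips

#' Classify the homology type of a leaf pair
#'
#' Same-species pairs are `within_species_paralog`. Otherwise the LCA event
#' decides: duplication gives `between_species_paralog`; speciation (or
#' gene split) gives an ortholog type from the per-species copy counts in
#' the LCA's child subtrees — (1,1) one2one, exactly one side > 1 one2many,
#' both > 1 many2many.
#'
#' @param tree A `gene_tree`.
#' @param leaf_a,leaf_b Gene IDs of two distinct leaves.
#' @return One of `r paste(HOMOLOGY_TYPES, collapse=", ")`.
#' @export
classify_pair <- function(tree, leaf_a, leaf_b) {
  ia <- match(leaf_a, tree$tips); ib <- match(leaf_b, tree$tips)
  if (is.na(ia)) err_input("unknown leaf '%s'", leaf_a)
  if (is.na(ib)) err_input("unknown leaf '%s'", leaf_b)
  if (ia == ib) err_input("guide and target must differ (got '%s' twice)", leaf_a)
  sp_a <- tree$species[[leaf_a]]; sp_b <- tree$species[[leaf_b]]
  if (is.na(sp_a) || is.na(sp_b))
    err_input("leaf without a species label (%s / %s)", leaf_a, leaf_b)
  if (sp_a == sp_b) return("within_species_paralog")
  phy <- tree$phylo
  lca <- ape::getMRCA(phy, c(ia, ib))
  ev <- tree_event(tree, lca)
  if (ev == "duplication") return("between_species_paralog")
  kids <- tree_children(phy, lca)
  child_of <- function(tip) {
    for (k in kids) if (tip %in% tips_under(phy, k)) return(k)
    stop("tip not under its own LCA") # unreachable
  }
  count_species <- function(node, sp)
    sum(tree$species[tree$tips[tips_under(phy, node)]] == sp, na.rm = TRUE)
  n_a <- count_species(child_of(ia), sp_a)
  n_b <- count_species(child_of(ib), sp_b)
  if (n_a == 1L && n_b == 1L) return("ortholog_one2one")
  if (n_a > 1L && n_b > 1L) return("ortholog_many2many")
  "ortholog_one2many"
}

coarse_type <- function(type) {
  if (grepl("^ortholog", type)) "ortholog" else "paralog"
}

#' Build the homology table for a guide gene
#'
#' One record per non-guide leaf, in tree leaf order, carrying the homology
#' type and the bidirectional identity / positivity / coverage statistics of
#' the pair (guide first: the `_guide` columns are percentages of the guide
#' sequence length, `_target` of the target's).
#'
#' @param tree A `gene_tree`.
#' @param guide_gene Gene ID of the guide leaf.
#' @param cigars Named list of `alignment_cigar`, one per leaf.
#' @param seqs Named character vector of ungapped protein sequences.
#' @param matrix Positivity scoring matrix (default BLOSUM62).
#' @return A data frame of class `homology_table` with columns
#'   `guide_gene`, `target_gene`, `target_species`, `homology_type`,
#'   `coarse_type`, `perc_id_guide`, `perc_pos_guide`, `perc_cov_guide`,
#'   `perc_id_target`, `perc_pos_target`, `perc_cov_target`.
#' @export
homology_table <- function(tree, guide_gene, cigars, seqs,
                           matrix = blosum62()) {
  tips <- leaf_order(tree)
  if (!guide_gene %in% tips) err_input("guide gene '%s' not in tree", guide_gene)
  targets <- setdiff(tips, guide_gene)
  for (g in c(guide_gene, targets)) {
    if (is.null(cigars[[g]]))
      err_input("no alignment member for gene '%s'", g)
    if (!g %in% names(seqs))
      err_input("no sequence for gene '%s'", g)
  }
  rows <- lapply(targets, function(tg) {
    st <- pairwise_stats(cigars[[guide_gene]], seqs[[guide_gene]],
                         cigars[[tg]], seqs[[tg]], matrix)
    ty <- classify_pair(tree, guide_gene, tg)
    data.frame(guide_gene = guide_gene, target_gene = tg,
               target_species = tree$species[[tg]],
               homology_type = ty, coarse_type = coarse_type(ty),
               perc_id_guide = st$perc_id_a, perc_pos_guide = st$perc_pos_a,
               perc_cov_guide = st$perc_cov_a,
               perc_id_target = st$perc_id_b, perc_pos_target = st$perc_pos_b,
               perc_cov_target = st$perc_cov_b,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(empty_homology_table())))
  class(out) <- c("homology_table", "data.frame")
  out
}

empty_homology_table <- function() {
  data.frame(guide_gene = character(), target_gene = character(),
             target_species = character(), homology_type = character(),
             coarse_type = character(),
             perc_id_guide = numeric(), perc_pos_guide = numeric(),
             perc_cov_guide = numeric(),
             perc_id_target = numeric(), perc_pos_target = numeric(),
             perc_cov_target = numeric(), stringsAsFactors = FALSE)
}

#' Write a homology table as CSV
#'
#' Percentages are rounded to one decimal place in the file; the in-memory
#' table keeps full precision. An empty table yields a header-only CSV.
#'
#' @param table A [homology_table()] result.
#' @param path Optional output file; when `NULL` the CSV lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the CSV lines.
#' @export
write_homology_csv <- function(table, path = NULL) {
  tab <- as.data.frame(table)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.1f", x))
  con <- textConnection("csv_out", "w", local = TRUE)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  close(con)
  if (!is.null(path)) {
    writeLines(csv_out, path)
    return(invisible(csv_out))
  }
  csv_out
}
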