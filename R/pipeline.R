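# Family-level plumbing shared by the CLI, the vignette and the tests:
# derive CIGARs from the MSA and build one comparison track per tree leaf
# against the chosen guide.

#' Build all comparison tracks for a gene family
#'
#' @param models A `gene_model_set` covering every tree leaf.
#' @param tree A `gene_tree`.
#' @param msa Named aligned protein rows (one per leaf).
#' @param guide Guide gene ID (must be a leaf).
#' @return A list with `tracks` (named by leaf, in leaf order; the guide's
#'   track is its self-comparison with `guide_flag` set), `cigars` and
#'   `seqs` (ungapped).
#' @export
family_tracks <- function(models, tree, msa, guide) {
  leaves <- leaf_order(tree)
  if (!guide %in% leaves) err_input("guide gene '%s' is not a tree leaf", guide)
  mm <- setdiff(leaves, names(models))
  if (length(mm)) err_input("no gene model for tree leaf '%s'", mm[1L])
  ma <- setdiff(leaves, names(msa))
  if (length(ma)) err_input("no alignment member for tree leaf '%s'", ma[1L])
  cm <- cigars_from_msa(msa[leaves])
  tracks <- lapply(leaves, function(leaf)
    build_comparison_track(models[[guide]], cm$cigars[[guide]],
                           models[[leaf]], cm$cigars[[leaf]]))
  names(tracks) <- leaves
  list(tracks = tracks, cigars = cm$cigars, seqs = cm$seqs)
}
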