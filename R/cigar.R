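# CIGAR algebra. A protein-space CIGAR encodes one member's row of a family
# MSA as runs of M (residue occupies the column) and D (gap in this member),
# the per-member convention used by Ensembl Compara homology alignments.
# The alphabet is deliberately restricted to {M, D}: nucleotide-space ops
# ("I", "N", ...) are rejected rather than reinterpreted.

new_cigar <- function(member_id, lengths, ops) {
  lengths <- as.integer(lengths)
  if (length(lengths) != length(ops)) stop("lengths/ops mismatch")
  # normalize: merge adjacent runs with the same op
  if (length(ops) > 1L) {
    keep <- c(TRUE, ops[-1L] != ops[-length(ops)])
    grp <- cumsum(keep)
    lengths <- as.integer(tapply(lengths, grp, sum))
    ops <- ops[keep]
  }
  structure(list(member_id = as.character(member_id),
                 lengths = lengths, ops = ops,
                 alignment_length = sum(lengths)),
            class = "alignment_cigar")
}

#' Parse a protein-space CIGAR string
#'
#' @param text A CIGAR such as `"4M2D3M"`; a missing count means 1.
#' @param member_id Identifier attached to the result.
#' @return An `alignment_cigar`: run lengths, ops (`M`/`D`), and
#'   `alignment_length` (total column count).
#' @export
parse_cigar <- function(text, member_id = NA_character_) {
  text <- trimws(text)
  if (!nzchar(text)) err_input("empty CIGAR string")
  toks <- regmatches(text, gregexpr("[0-9]*[^0-9]", text))[[1]]
  if (sum(nchar(toks)) != nchar(text))
    err_input("malformed CIGAR '%s'", text)
  ops <- substr(toks, nchar(toks), nchar(toks))
  bad <- setdiff(unique(ops), c("M", "D"))
  if (length(bad))
    err_input("unsupported CIGAR op '%s' (only M and D are allowed)", bad[1L])
  counts <- sub("[MD]$", "", toks)
  counts <- ifelse(counts == "", "1", counts)
  n <- as.integer(counts)
  if (any(is.na(n) | n <= 0L)) err_input("bad CIGAR run count in '%s'", text)
  new_cigar(member_id, n, ops)
}

#' Render an `alignment_cigar` back to its string form
#'
#' Run counts of 1 are written explicitly (e.g. `"1M"`).
#'
#' @param cigar An `alignment_cigar`.
#' @return A CIGAR string.
#' @export
cigar_string <- function(cigar) {
  paste0(cigar$lengths, cigar$ops, collapse = "")
}

# logical mask over alignment columns: TRUE where this member has a residue
cigar_mask <- function(cigar) rep(cigar$ops == "M", cigar$lengths)

#' Reconstruct an aligned row from a CIGAR and its unaligned sequence
#'
#' @param cigar An `alignment_cigar`.
#' @param seq The member's unaligned protein sequence; its length must equal
#'   the total M count of `cigar`.
#' @return The aligned row with `-` at gap columns.
#' @export
apply_cigar <- function(cigar, seq) {
  mask <- cigar_mask(cigar)
  if (sum(mask) != nchar(seq))
    err_input("CIGAR M total (%d) does not match sequence length (%d) for %s",
              sum(mask), nchar(seq), cigar$member_id)
  out <- rep("-", length(mask))
  out[mask] <- strsplit(seq, "")[[1]]
  paste(out, collapse = "")
}

#' Derive per-member CIGARs from an aligned protein MSA
#'
#' @param msa Named character vector of equal-length aligned rows with `-`
#'   as the gap character.
#' @return A list with `cigars` (named list of `alignment_cigar`) and `seqs`
#'   (named character vector of ungapped sequences).
#' @export
cigars_from_msa <- function(msa) {
  if (!length(msa)) err_input("empty MSA")
  if (is.null(names(msa)) || any(!nzchar(names(msa))))
    err_input("MSA rows must be named by member ID")
  w <- nchar(msa)
  if (length(unique(w)) != 1L)
    err_input("ragged MSA: row lengths %s", paste(unique(w), collapse = ", "))
  cigars <- list(); seqs <- character(0)
  for (id in names(msa)) {
    gap <- strsplit(msa[[id]], "")[[1]] == "-"
    if (all(gap)) err_input("all-gap MSA row for member %s", id)
    r <- rle(gap)
    cigars[[id]] <- new_cigar(id, r$lengths, ifelse(r$values, "D", "M"))
    seqs[[id]] <- gsub("-", "", msa[[id]], fixed = TRUE)
  }
  list(cigars = cigars, seqs = seqs)
}

COLUMN_CLASSES <- c("BOTH", "INSERTION", "DELETION", "NEITHER")

#' Classify alignment columns of a homologue against the guide
#'
#' Column-wise over the shared alignment length: residue in both -> `BOTH`;
#' target-only residue -> `INSERTION`; guide-only residue -> `DELETION`;
#' gap in both -> `NEITHER`. Classes describe the target relative to the
#' guide, matching the browser glyphs (black insertion bars, red deletion
#' lines).
#'
#' Runs are merged without expanding columns, so this is linear in the
#' number of runs, not in alignment length.
#'
#' @param guide,target `alignment_cigar` objects of equal
#'   `alignment_length`.
#' @return A list of class `column_classification` with `lengths`, `classes`
#'   (normalized runs) and `total_columns`.
#' @export
classify_columns <- function(guide, target) {
  if (guide$alignment_length != target$alignment_length)
    err_input("alignment length mismatch: guide %d vs target %d",
              guide$alignment_length, target$alignment_length)
  cg <- cumsum(guide$lengths)
  ct <- cumsum(target$lengths)
  b <- sort(unique(c(cg, ct)))
  gop <- guide$ops[findInterval(b - 0.5, cg) + 1L]
  top <- target$ops[findInterval(b - 0.5, ct) + 1L]
  cls <- ifelse(gop == "M",
                ifelse(top == "M", "BOTH", "DELETION"),
                ifelse(top == "M", "INSERTION", "NEITHER"))
  lens <- diff(c(0L, b))
  if (length(cls) > 1L) {
    keep <- c(TRUE, cls[-1L] != cls[-length(cls)])
    grp <- cumsum(keep)
    lens <- as.integer(tapply(lens, grp, sum))
    cls <- cls[keep]
  }
  structure(list(lengths = as.integer(lens), classes = cls,
                 total_columns = guide$alignment_length),
            class = "column_classification")
}

# expand a column_classification to one class per column
expand_classes <- function(cc) rep(cc$classes, cc$lengths)

#' Bidirectional pairwise alignment statistics
#'
#' Over the `BOTH` (mutually aligned) columns of two members' CIGARs, counts
#' identical residues, positively scoring residue pairs (substitution-matrix
#' score > 0), and aligned columns, and expresses each as a percentage of
#' each member's own ungapped sequence length — the bidirectional
#' identity/positivity/coverage convention of Compara homology tables.
#'
#' @param cigar_a,cigar_b `alignment_cigar`s with equal alignment length.
#' @param seq_a,seq_b Ungapped protein sequences (lengths must match the
#'   CIGARs' M totals).
#' @param matrix Scoring matrix (residues as dimnames); defaults to
#'   BLOSUM62.
#' @return A list of class `pair_stats` with fields `perc_id_a`,
#'   `perc_pos_a`, `perc_cov_a` and the `_b` counterparts, in percent
#'   (full precision; rounding is a presentation concern).
#' @export
pairwise_stats <- function(cigar_a, seq_a, cigar_b, seq_b,
                           matrix = blosum62()) {
  la <- nchar(seq_a); lb <- nchar(seq_b)
  mask_a <- cigar_mask(cigar_a); mask_b <- cigar_mask(cigar_b)
  if (length(mask_a) != length(mask_b))
    err_input("alignment length mismatch: %d vs %d",
              length(mask_a), length(mask_b))
  if (sum(mask_a) != la)
    err_input("sequence/CIGAR mismatch for member a (%s)", cigar_a$member_id)
  if (sum(mask_b) != lb)
    err_input("sequence/CIGAR mismatch for member b (%s)", cigar_b$member_id)
  both <- mask_a & mask_b
  ra <- strsplit(seq_a, "")[[1]][cumsum(mask_a)[both]]
  rb <- strsplit(seq_b, "")[[1]][cumsum(mask_b)[both]]
  missing <- setdiff(unique(c(ra, rb)), rownames(matrix))
  if (length(missing))
    err_input("residue '%s' absent from the scoring matrix", missing[1L])
  n_cov <- sum(both)
  n_id <- sum(ra == rb)
  n_pos <- if (n_cov) sum(matrix[cbind(ra, rb)] > 0) else 0L
  structure(list(perc_id_a = 100 * n_id / la, perc_pos_a = 100 * n_pos / la,
                 perc_cov_a = 100 * n_cov / la,
                 perc_id_b = 100 * n_id / lb, perc_pos_b = 100 * n_pos / lb,
                 perc_cov_b = 100 * n_cov / lb),
            class = "pair_stats")
}

.matrix_cache <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#'
#' @return The BLOSUM62 matrix shipped with Biostrings, used as the default
#'   positivity scoring matrix (score > 0 defines a "positive" pair).
#' @export
blosum62 <- function() {
  if (is.null(.matrix_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .matrix_cache$blosum62 <- e$BLOSUM62
  }
  .matrix_cache$blosum62
}

#' Read an NCBI-format substitution matrix
#'
#' Parses the plain-text matrix layout used by NCBI BLAST (`#` comments, a
#' header row of residues, one labelled row per residue).
#'
#' @param path Path to the matrix file.
#' @return A numeric matrix with residue dimnames.
#' @export
read_scoring_matrix <- function(path) {
  if (!file.exists(path)) err_input("scoring matrix file not found: %s", path)
  m <- as.matrix(utils::read.table(path, comment.char = "#",
                                   check.names = FALSE))
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    err_input("scoring matrix in %s is not square with matching labels", path)
  m
}
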