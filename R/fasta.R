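# FASTA I/O, thin wrappers over Biostrings. Aligned and unaligned protein
# FASTA share the same reader; '-' is the gap character.

#' Read a protein FASTA file
#'
#' @param path Path to a FASTA file (aligned rows may contain `-`).
#' @return Named character vector; names are truncated at the first
#'   whitespace.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) err_input("FASTA file not found: %s", path)
  x <- tryCatch(Biostrings::readAAStringSet(path),
                error = function(e) err_input("cannot read FASTA %s: %s",
                                              path, conditionMessage(e)))
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as FASTA
#'
#' One sequence per line (no wrapping), for byte-stable output.
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @return The paths, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    err_input("sequences must be named")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}
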