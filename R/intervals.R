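# Genomic intervals. All coordinates in this package are 0-based half-open
# [start, end); GFF3's 1-based inclusive coordinates are converted at the
# parsing boundary and converted back on write.

#' Create a genomic interval
#'
#' @param seq_id Chromosome or scaffold name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return A list of class `genomic_interval`.
#' @export
genomic_interval <- function(seq_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    err_input("invalid interval [%s, %s) on %s: need 0 <= start < end",
              start, end, seq_id)
  if (!strand %in% c("+", "-"))
    err_input("invalid strand '%s' (must be '+' or '-')", strand)
  structure(list(seq_id = as.character(seq_id), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

# Data frame of intervals (columns seq_id/start/end/strand), the working
# representation for exon/CDS/UTR lists.
interval_df <- function(seq_id = character(), start = integer(),
                        end = integer(), strand = character()) {
  df <- data.frame(seq_id = as.character(seq_id), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$start < 0L | df$start >= df$end))
    err_input("interval list contains start >= end or negative start")
  df
}

interval_widths <- function(df) df$end - df$start

# TRUE when each row of `inner` is contained in some row of `outer`.
intervals_contained <- function(inner, outer) {
  if (!nrow(inner)) return(logical(0))
  vapply(seq_len(nrow(inner)), function(i) {
    any(outer$seq_id == inner$seq_id[i] &
        outer$start <= inner$start[i] &
        outer$end >= inner$end[i])
  }, logical(1))
}

intervals_disjoint <- function(df) {
  if (nrow(df) < 2L) return(TRUE)
  o <- order(df$seq_id, df$start)
  s <- df[o, , drop = FALSE]
  all(s$start[-1L] >= s$end[-nrow(s)] | s$seq_id[-1L] != s$seq_id[-nrow(s)])
}

# Sort an interval df into transcription (5'->3') order for a strand.
order_5to3 <- function(df, strand) {
  if (!nrow(df)) return(df)
  o <- order(df$start, decreasing = identical(strand, "-"))
  df[o, , drop = FALSE]
}
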