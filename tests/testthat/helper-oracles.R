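# Independent brute-force oracles and small fixture builders. Oracles work
# by explicit per-column / per-base expansion and never reuse the run-length
# code paths they are used to check.

expand_cigar_ops <- function(cigar) rep(cigar$ops, cigar$lengths)

# elementwise column classification over expanded op strings
oracle_classify <- function(guide, target) {
  go <- expand_cigar_ops(guide)
  to <- expand_cigar_ops(target)
  ifelse(go == "M" & to == "M", "BOTH",
         ifelse(go == "D" & to == "M", "INSERTION",
                ifelse(go == "M", "DELETION", "NEITHER")))
}

# per-column stats from the two aligned rows directly
oracle_stats <- function(row_a, row_b, mat = blosum62()) {
  a <- strsplit(row_a, "")[[1]]
  b <- strsplit(row_b, "")[[1]]
  la <- sum(a != "-"); lb <- sum(b != "-")
  n_id <- 0L; n_pos <- 0L; n_cov <- 0L
  for (i in seq_along(a)) {
    if (a[i] == "-" || b[i] == "-") next
    n_cov <- n_cov + 1L
    if (a[i] == b[i]) n_id <- n_id + 1L
    if (mat[a[i], b[i]] > 0) n_pos <- n_pos + 1L
  }
  list(perc_id_a = 100 * n_id / la, perc_pos_a = 100 * n_pos / la,
       perc_cov_a = 100 * n_cov / la,
       perc_id_b = 100 * n_id / lb, perc_pos_b = 100 * n_pos / lb,
       perc_cov_b = 100 * n_cov / lb)
}

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_cigar <- function(L, id = "x") {
  ops <- sample(c("M", "D"), L, replace = TRUE, prob = c(0.7, 0.3))
  if (!any(ops == "M")) ops[sample(L, 1L)] <- "M"
  r <- rle(ops)
  parse_cigar(paste0(r$lengths, r$values, collapse = ""), id)
}

random_aligned_row <- function(L) {
  ch <- sample(c(AA, "-"), L, replace = TRUE, prob = c(rep(0.045, 20), 0.1))
  if (!any(ch != "-")) ch[sample(L, 1L)] <- sample(AA, 1L)
  paste(ch, collapse = "")
}

# per-base CDS -> genome lookup table built by explicit enumeration
oracle_base_table <- function(tx) {
  unlist(lapply(seq_len(nrow(tx$cds)), function(i) {
    s <- tx$cds$start[i]; e <- tx$cds$end[i]
    if (tx$strand == "+") s:(e - 1L) else (e - 1L):s
  }))
}

# fully coding transcript from exon widths (nt) and intron widths
make_tx <- function(widths, introns = integer(0), strand = "+", g0 = 100L,
                    seq_id = "chr1", id = "tx1", gene = "g1") {
  n <- length(widths)
  stopifnot(length(introns) == n - 1L)
  starts <- g0 + cumsum(c(0L, widths[-n])) + cumsum(c(0L, introns))
  ex <- data.frame(seq_id = seq_id, start = starts, end = starts + widths,
                   strand = strand, stringsAsFactors = FALSE)
  transcript_model(id, gene, strand, ex, ex)
}

make_gene <- function(widths, introns = integer(0), strand = "+", g0 = 100L,
                      seq_id = "chr1", gene = "g1", species = "spX") {
  tx <- make_tx(widths, introns, strand, g0, seq_id, paste0(gene, "_t"), gene)
  span <- range(c(tx$exons$start, tx$exons$end))
  gene_model(gene, gene, species,
             genomic_interval(seq_id, span[1L], span[2L], strand), tx)
}

# self-comparison track of a fully coding gene (all-M cigar)
self_track <- function(gene) {
  P <- sum(gene$transcript$cds$end - gene$transcript$cds$start) / 3L
  cig <- parse_cigar(sprintf("%dM", P), gene$gene_id)
  build_comparison_track(gene, cig, gene, cig)
}

count_svg_nodes <- function(svg, xpath) {
  length(xml2::xml_find_all(xml2::read_xml(svg), xpath))
}
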