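# Gene-order windows, homology colouring, and the gene-order SVG.

demo_genes <- function(n, sp = "spA", gap = 1000L, width = 2000L) {
  start <- 10000L + (seq_len(n) - 1L) * (gap + width)
  data.frame(gene_id = sprintf("%s_n%d", sp, seq_len(n)),
             seq_id = paste0("chr_", sp), start = start,
             end = start + width, strand = "+", stringsAsFactors = FALSE)
}

test_that("neighborhood windows clip at the sequence ends", {
  g <- demo_genes(11L)
  w <- neighborhood(g, "spA_n6", k = 2)
  expect_equal(w$gene_id, sprintf("spA_n%d", 4:8))
  w2 <- neighborhood(g, "spA_n1", k = 3)
  expect_equal(w2$gene_id, sprintf("spA_n%d", 1:4))
  w3 <- neighborhood(g, "spA_n6", k = 0)
  expect_equal(w3$gene_id, "spA_n6")
  expect_error(neighborhood(g, "zz", k = 2), "focal gene")
})

test_that("neighbors take the colour of their in-window reference homologue", {
  ga <- demo_genes(5L, "spA")
  gb <- demo_genes(5L, "spB")
  ref <- list(species = "spA", seq_id = "chr_spA", genes = ga,
              focal_gene = "spA_n3")
  oth <- list(species = "spB", seq_id = "chr_spB", genes = gb,
              focal_gene = "spB_n3")
  pairs <- data.frame(gene_a = sprintf("spA_n%d", c(1, 3, 5)),
                      gene_b = sprintf("spB_n%d", c(1, 3, 5)),
                      stringsAsFactors = FALSE)
  rows <- color_synteny(ref, list(oth), pairs)
  expect_equal(rows[[1]]$genes$color_index, 0:4)
  expect_equal(rows[[2]]$genes$color_index,
               c(0L, NA, 2L, NA, 4L))
  expect_equal(rows[[1]]$genes$focal, c(F, F, T, F, F))
  expect_equal(rows[[2]]$genes$focal, c(F, F, T, F, F))
})

test_that("a homologue outside the visible window stays white", {
  ga <- demo_genes(9L, "spA")
  gb <- demo_genes(9L, "spB")
  ref <- list(species = "spA", seq_id = "chr_spA",
              genes = neighborhood(ga, "spA_n5", k = 2),   # window n3..n7
              focal_gene = "spA_n5")
  oth <- list(species = "spB", seq_id = "chr_spB",
              genes = neighborhood(gb, "spB_n5", k = 2),
              focal_gene = "spB_n5")
  pairs <- data.frame(gene_a = c("spA_n5", "spA_n9"),
                      gene_b = c("spB_n5", "spB_n4"),
                      stringsAsFactors = FALSE)
  rows <- color_synteny(ref, list(oth), pairs)
  g <- rows[[2]]$genes
  # spB_n4's only homologue (spA_n9) is outside the reference window
  expect_true(is.na(g$color_index[g$gene_id == "spB_n4"]))
  expect_equal(g$color_index[g$gene_id == "spB_n5"], 2L)
})

test_that("colouring ignores the order of non-reference rows", {
  fx <- simulate_synteny(sim_params(seed = 21, n_species = 4))
  ref <- fx$rows[[1]]; others <- fx$rows[-1]
  r1 <- color_synteny(ref, others, fx$pairs)
  r2 <- color_synteny(ref, rev(others), fx$pairs)
  key <- function(rows) {
    x <- lapply(rows, function(r) r$genes[, c("gene_id", "color_index")])
    x[order(vapply(rows, `[[`, character(1), "species"))]
  }
  expect_equal(key(r1[-1]), key(r2[-1]))
})

test_that("simulated conserved blocks share colours across species", {
  for (seed in c(5, 15, 25)) {
    fx <- simulate_synteny(sim_params(seed = seed, n_species = 3,
                                      loss_prob = 0.15))
    ref <- fx$rows[[1]]
    rows <- color_synteny(ref, fx$rows[-1], fx$pairs)
    ref_col <- stats::setNames(rows[[1]]$genes$color_index,
                               rows[[1]]$genes$anc)
    for (r in rows[-1]) {
      for (i in seq_len(nrow(r$genes))) {
        anc <- as.character(r$genes$anc[i])
        expected <- if (anc %in% names(ref_col)) ref_col[[anc]] else NA_integer_
        expect_equal(r$genes$color_index[i], expected)
      }
      # no colour outside the reference row's palette
      used <- r$genes$color_index[!is.na(r$genes$color_index)]
      expect_true(all(used %in% rows[[1]]$genes$color_index))
    }
  }
})

test_that("zero losses keep identical gene order across species", {
  fx <- simulate_synteny(sim_params(seed = 2, n_species = 3, loss_prob = 0))
  counts <- vapply(fx$rows, function(r) nrow(r$genes), numeric(1))
  expect_equal(unique(counts), fx$params$neighborhood_size)
  ancs <- lapply(fx$rows, function(r) r$genes$anc)
  expect_length(unique(ancs), 1L)
})

test_that("the gene-order SVG draws every gene and outlines focals in red", {
  fx <- simulate_synteny(sim_params(seed = 8, n_species = 3, loss_prob = 0,
                                    neighborhood_size = 5))
  rows <- color_synteny(fx$rows[[1]], fx$rows[-1], fx$pairs)
  svg <- render_gene_order_svg(rows, view_options())
  expect_silent(xml2::read_xml(svg))
  expect_equal(count_svg_nodes(svg, "//*[starts-with(@class, 'genebox')]"),
               15L)
  expect_equal(count_svg_nodes(svg, "//*[contains(@class, 'focal')]"), 3L)
  expect_identical(svg, render_gene_order_svg(rows, view_options()))
})

test_that("synteny rows export as TSV", {
  fx <- simulate_synteny(sim_params(seed = 8, n_species = 2, loss_prob = 0,
                                    neighborhood_size = 3))
  rows <- color_synteny(fx$rows[[1]], fx$rows[-1], fx$pairs)
  tsv <- synteny_rows_tsv(rows)
  expect_length(tsv, 1L + 6L)
  expect_match(tsv[1], "^species\tseq_id\tgene_id")
})
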