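# Layout geometry and SVG rendering.

test_that("exon-focused layout keeps exon widths proportional to length", {
  tr <- self_track(make_gene(c(300L, 150L), 5000L))
  st <- layout_exon_focused(tr, view_options())
  ex <- st$shapes[grepl("^exon", st$shapes$class), , drop = FALSE]
  expect_equal(ex$width[1] / ex$width[2], 2)
})

test_that("exon-focused layout gives every intron the same fixed width", {
  opts <- view_options(fixed_intron_px = 6)
  tr <- self_track(make_gene(c(90L, 90L, 90L), c(500L, 50000L)))
  st <- layout_exon_focused(tr, opts)
  introns <- st$shapes[st$shapes$class == "intron", , drop = FALSE]
  expect_equal(nrow(introns), 2L)
  expect_equal(introns$width, c(6, 6))
})

test_that("single-exon genes lay out as one rect with no intron gap", {
  st <- layout_exon_focused(self_track(make_gene(300L)), view_options())
  expect_equal(sum(grepl("^exon", st$shapes$class)), 1L)
  expect_equal(sum(st$shapes$class == "intron"), 0L)
})

test_that("proportional layout shares one global scale", {
  opts <- view_options("proportional", canvas_width = 1000)
  # longest gene 10,000 nt (incl. introns), second 5,000 nt
  t1 <- self_track(make_gene(c(402L, 398L * 3L + 6L), 10000L - 402L - 398L * 3L - 6L))
  t2 <- self_track(make_gene(c(2400L, 2400L), 200L))
  sc <- view_scale(list(t1, t2), opts)
  expect_equal(sc, 0.1)
  s1 <- layout_proportional(t1, opts, sc)
  s2 <- layout_proportional(t2, opts, sc)
  expect_equal(s1$width, 1000)
  expect_equal(s2$width, 500)
  # a 402 nt exon at 0.1 px/nt is 40.2 px
  ex <- s1$shapes[grepl("^exon", s1$shapes$class), , drop = FALSE]
  expect_equal(ex$width[1], 40.2)
})

test_that("proportional pixel ratios equal nucleotide ratios", {
  set.seed(5)
  for (i in 1:10) {
    fx <- simulate_family(sim_params(seed = i))
    fd <- family_tracks(fx$models, fx$tree, fx$msa, fx$guide)
    opts <- view_options("proportional")
    sc <- view_scale(fd$tracks, opts)
    for (tr in fd$tracks) {
      st <- layout_proportional(tr, opts, sc)
      sh <- st$shapes[grepl("^exon", st$shapes$class) |
                      st$shapes$class %in% c("intron", "insertion"), ,
                      drop = FALSE]
      nts <- (tr$segments$end - tr$segments$start)[
        tr$segments$kind %in% c("MATCH", "INSERTION", "NONCODING")]
      expect_equal(sh$width / sc, nts, tolerance = 1e-9)
      expect_true(all(sh$x >= -1e-9))
      expect_true(all(sh$x + sh$width <= opts$canvas_width + 1e-9))
    }
  }
})

test_that("both layout modes preserve exon order and count", {
  fx <- simulate_family(sim_params(seed = 9, insertion_rate = 1))
  fd <- family_tracks(fx$models, fx$tree, fx$msa, fx$guide)
  for (tr in fd$tracks) {
    a <- layout_exon_focused(tr, view_options())
    b <- layout_proportional(tr, view_options("proportional"))
    ea <- a$shapes[grepl("^exon", a$shapes$class), , drop = FALSE]
    eb <- b$shapes[grepl("^exon", b$shapes$class), , drop = FALSE]
    expect_equal(nrow(ea), nrow(eb))
    expect_equal(ea$color_index, eb$color_index)
  }
})

test_that("the gene-tree SVG is valid XML with the expected elements", {
  fx <- simulate_family(sim_params(seed = 12, insertion_rate = 1,
                                   deletion_rate = 1, duplication_prob = 0.3))
  fd <- family_tracks(fx$models, fx$tree, fx$msa, fx$guide)
  svg <- render_genetree_svg(fx$tree, fd$tracks, view_options())
  n_match <- sum(vapply(fd$tracks, function(t)
    sum(t$segments$kind == "MATCH"), numeric(1)))
  expect_equal(count_svg_nodes(svg, "//*[starts-with(@class, 'exon ')]"),
               n_match)
  # one red guide label, guide leaf node, event circles per internal node
  expect_equal(count_svg_nodes(svg, "//*[@class='label guide']"), 1L)
  expect_equal(count_svg_nodes(svg, "//*[@class='node leaf guide']"), 1L)
  n_internal <- fx$tree$phylo$Nnode
  expect_equal(count_svg_nodes(
    svg, paste0("//*[@class='node speciation' or @class='node duplication'",
                " or @class='node gene_split']")), n_internal)
  ndel <- sum(vapply(fd$tracks, function(t) length(t$deletion_marks),
                     numeric(1)))
  expect_equal(count_svg_nodes(svg, "//*[@class='deletion']"), ndel)
})

test_that("rendering is deterministic and mode changes only widths", {
  fx <- simulate_family(sim_params(seed = 3))
  fd <- family_tracks(fx$models, fx$tree, fx$msa, fx$guide)
  s1 <- render_genetree_svg(fx$tree, fd$tracks, view_options())
  s2 <- render_genetree_svg(fx$tree, fd$tracks, view_options())
  expect_identical(s1, s2)
  s3 <- render_genetree_svg(fx$tree, fd$tracks, view_options("proportional"))
  expect_false(identical(s1, s3))
  expect_silent(xml2::read_xml(s3))
})

test_that("tracks missing for a leaf are reported", {
  fx <- simulate_family(sim_params(seed = 3))
  fd <- family_tracks(fx$models, fx$tree, fx$msa, fx$guide)
  expect_error(render_genetree_svg(fx$tree, fd$tracks[-1], view_options()),
               "track/leaf mismatch")
})

test_that("pairwise view joins identical genes exon by exon", {
  g <- make_gene(c(90L, 60L, 120L), c(300L, 200L), gene = "guide")
  tr <- self_track(g)
  msa <- c(guide = strrep("M", 90L), target = strrep("M", 90L))
  svg <- render_pairwise_svg(tr, tr, msa, view_options())
  expect_silent(xml2::read_xml(svg))
  expect_equal(count_svg_nodes(svg, "//*[starts-with(@class, 'connector')]"),
               3L)
})

test_that("the textual alignment wraps into blocks of wrap_columns", {
  g <- make_gene(180L, gene = "guide")  # 60 residues
  tr <- self_track(g)
  msa <- c(a = strrep("K", 60L), b = strrep("K", 60L))
  svg <- render_pairwise_svg(tr, tr, msa, view_options(wrap_columns = 30))
  expect_equal(count_svg_nodes(svg, "//*[@class='aln-block']"), 2L)
  svg2 <- render_pairwise_svg(tr, tr, msa, view_options(wrap_columns = 60))
  expect_equal(count_svg_nodes(svg2, "//*[@class='aln-block']"), 1L)
})

test_that("pairwise rendering on random simulated pairs is well-formed XML", {
  for (seed in 4:8) {
    fx <- simulate_family(sim_params(seed = seed, insertion_rate = 1,
                                     deletion_rate = 1))
    tips <- leaf_order(fx$tree)
    if (length(tips) < 2L) next
    fd <- family_tracks(fx$models, fx$tree, fx$msa, fx$guide)
    tgt <- tips[tips != fx$guide][1L]
    msa <- fx$msa[c(fx$guide, tgt)]
    svg <- render_pairwise_svg(fd$tracks[[fx$guide]], fd$tracks[[tgt]],
                               msa, view_options())
    expect_silent(xml2::read_xml(svg))
    expect_identical(svg, render_pairwise_svg(fd$tracks[[fx$guide]],
                                              fd$tracks[[tgt]], msa,
                                              view_options()))
  }
})
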