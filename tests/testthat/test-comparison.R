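# Comparison tracks: projection of column classes onto target structure.

test_that("guide exon palette is sequential over coding exons", {
  expect_equal(guide_exon_palette(make_tx(c(9L, 12L, 9L), c(10L, 10L))),
               c(0L, 1L, 2L))
  expect_equal(guide_exon_palette(make_tx(30L)), 0L)
  noncoding <- make_tx(30L)
  noncoding$cds <- noncoding$cds[0, , drop = FALSE]
  expect_error(guide_exon_palette(noncoding), "no coding exons")
})

test_that("self-comparison reproduces the guide's coding exons exactly", {
  g <- make_gene(c(9L, 12L, 15L), c(50L, 80L))
  tr <- self_track(g)
  m <- tr$segments[tr$segments$kind == "MATCH", , drop = FALSE]
  expect_equal(nrow(m), 3L)
  expect_equal(m$start, g$transcript$cds$start)
  expect_equal(m$end, g$transcript$cds$end)
  expect_equal(m$color_index, c(0L, 1L, 2L))
  expect_equal(sum(tr$segments$kind == "INSERTION"), 0L)
  expect_length(tr$deletion_marks, 0L)
  expect_true(tr$guide_flag)
})

test_that("one target exon matching two adjacent guide exons splits in two", {
  # guide: two coding exons (2 + 3 residues); target: one 5-residue exon
  guide <- make_gene(c(6L, 9L), 100L, gene = "guide")
  target <- make_gene(15L, gene = "target", g0 = 500L)
  cig <- parse_cigar("5M")
  tr <- build_comparison_track(guide, cig, target, cig)
  m <- tr$segments[tr$segments$kind == "MATCH", , drop = FALSE]
  expect_equal(nrow(m), 2L)
  expect_equal(m$color_index, c(0L, 1L))           # consecutive indices
  expect_equal(m$start, c(500L, 506L))
  expect_equal(m$end, c(506L, 515L))
  expect_false(tr$guide_flag)
})

test_that("planted indels surface as single segments at the right place", {
  for (seed in 1:20) {
    fx <- simulate_family(sim_params(seed = seed, insertion_rate = 1.5,
                                     deletion_rate = 1.5))
    fd <- family_tracks(fx$models, fx$tree, fx$msa, fx$guide)
    for (gid in leaf_order(fx$tree)) {
      tr <- fd$tracks[[gid]]
      ev <- fx$truth$events[[gid]]
      ti <- ev[ev$kind == "insertion", , drop = FALSE]
      td <- ev[ev$kind == "deletion", , drop = FALSE]
      ins <- tr$segments[tr$segments$kind == "INSERTION", , drop = FALSE]
      expect_equal(nrow(ins), nrow(ti))
      if (nrow(ti)) {
        expect_equal(sort(ins$start), sort(ti$g_start))
        expect_equal(sort(ins$end), sort(ti$g_end))
        expect_equal(sum(ins$end - ins$start), 3L * sum(ti$len))
      }
      expect_equal(length(tr$deletion_marks), nrow(td))
      if (nrow(td))
        expect_equal(sort(tr$deletion_marks), sort(td$g_start))
    }
  }
})

test_that("match and insertion lengths conserve the column counts", {
  for (seed in 1:10) {
    fx <- simulate_family(sim_params(seed = seed, insertion_rate = 2,
                                     deletion_rate = 2))
    fd <- family_tracks(fx$models, fx$tree, fx$msa, fx$guide)
    gcig <- fd$cigars[[fx$guide]]
    for (gid in leaf_order(fx$tree)) {
      cc <- classify_columns(gcig, fd$cigars[[gid]])
      n_both <- sum(cc$lengths[cc$classes == "BOTH"])
      n_ins <- sum(cc$lengths[cc$classes == "INSERTION"])
      s <- fd$tracks[[gid]]$segments
      expect_equal(sum((s$end - s$start)[s$kind == "MATCH"]), 3L * n_both)
      expect_equal(sum((s$end - s$start)[s$kind == "INSERTION"]), 3L * n_ins)
      # segments never overlap within a track
      o <- s[order(s$start), , drop = FALSE]
      if (nrow(o) > 1L)
        expect_true(all(o$start[-1L] >= o$end[-nrow(o)]))
    }
  }
})

test_that("swapping guide and target exchanges insertion and deletion roles", {
  for (seed in 1:10) {
    fx <- simulate_family(sim_params(seed = seed, insertion_rate = 1.5,
                                     deletion_rate = 1.5))
    tips <- leaf_order(fx$tree)
    if (length(tips) < 2L) next
    cm <- cigars_from_msa(fx$msa)
    a <- tips[1L]; b <- tips[2L]
    fwd <- build_comparison_track(fx$models[[a]], cm$cigars[[a]],
                                  fx$models[[b]], cm$cigars[[b]])
    rev <- build_comparison_track(fx$models[[b]], cm$cigars[[b]],
                                  fx$models[[a]], cm$cigars[[a]])
    expect_equal(sum(fwd$segments$kind == "INSERTION"),
                 length(rev$deletion_marks))
    expect_equal(sum(rev$segments$kind == "INSERTION"),
                 length(fwd$deletion_marks))
  }
})

test_that("deletion at the target 5' end marks the first CDS base", {
  guide <- make_gene(9L, gene = "guide")           # 3 residues
  target <- make_gene(6L, gene = "target", g0 = 300L)  # 2 residues
  tr <- build_comparison_track(guide, parse_cigar("3M"),
                               target, parse_cigar("1D2M"))
  expect_equal(tr$deletion_marks, 300)
  rev_t <- make_gene(6L, gene = "t2", g0 = 300L, strand = "-")
  tr2 <- build_comparison_track(guide, parse_cigar("3M"),
                                rev_t, parse_cigar("1D2M"))
  expect_equal(tr2$deletion_marks, 306)
})

test_that("UTRs and introns are emitted as explicit segments", {
  fx <- simulate_family(sim_params(seed = 2))
  fd <- family_tracks(fx$models, fx$tree, fx$msa, fx$guide)
  tr <- fd$tracks[[fx$guide]]
  expect_equal(sum(tr$segments$kind == "UTR5"), 1L)
  expect_equal(sum(tr$segments$kind == "UTR3"), 1L)
  n_ex <- nrow(tr$transcript$exons)
  expect_equal(sum(tr$segments$kind == "NONCODING"), n_ex - 1L)
  # 5'->3' order: on '-' strand starts are descending
  s <- tr$segments
  if (tr$strand == "-") expect_true(all(diff(s$start) < 0))
  else expect_true(all(diff(s$start) > 0))
})

test_that("tracks export as BED-like text", {
  g <- make_gene(c(9L, 12L), 40L)
  bed <- track_to_bed(self_track(g))
  expect_length(bed, 3L)  # 2 MATCH + 1 intron
  f <- strsplit(bed[1], "\t")[[1]]
  expect_length(f, 6L)
  expect_equal(f[1], "chr1")
  expect_equal(f[6], "g1")
})

test_that("inconsistent cigar/sequence lengths are rejected", {
  g <- make_gene(c(9L, 12L), 40L)  # 21 nt CDS = 7 residues
  cig <- parse_cigar("6M")
  expect_error(build_comparison_track(g, cig, g, cig), "inconsistent")
})
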