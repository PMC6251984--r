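# CIGAR parsing, MSA conversion, column classification, pairwise stats.

test_that("CIGAR strings parse to normalized runs", {
  c1 <- parse_cigar("4M2D3M")
  expect_equal(c1$lengths, c(4L, 2L, 3L))
  expect_equal(c1$ops, c("M", "D", "M"))
  expect_equal(c1$alignment_length, 9L)
  c2 <- parse_cigar("MDM")
  expect_equal(c2$lengths, c(1L, 1L, 1L))
  expect_equal(c2$ops, c("M", "D", "M"))
  # adjacent same-op runs are merged
  expect_equal(parse_cigar("2M3M")$lengths, 5L)
  expect_error(parse_cigar("5X"), "unsupported CIGAR op 'X'")
  expect_error(parse_cigar(""), "empty")
  expect_error(parse_cigar("4M2"), "malformed")
})

test_that("MSA rows convert to CIGARs and reconstruct exactly", {
  cm <- cigars_from_msa(c(a = "MK--VL", b = "MKVLAW"))
  expect_equal(cigar_string(cm$cigars$a), "2M2D2M")
  expect_equal(cm$seqs[["a"]], "MKVL")
  expect_equal(cigar_string(cm$cigars$b), "6M")
  expect_equal(apply_cigar(cm$cigars$a, cm$seqs[["a"]]), "MK--VL")
  expect_error(cigars_from_msa(c(a = "MK-", b = "MKVL")), "ragged")
  expect_error(cigars_from_msa(c(a = "---", b = "MKV")), "all-gap.*a")
})

test_that("random MSA rows survive the cigar round trip", {
  set.seed(42)
  for (i in 1:50) {
    rows <- vapply(1:4, function(j) random_aligned_row(sample(10:80, 1)[1] * 0 + 40),
                   character(1))
    names(rows) <- paste0("m", 1:4)
    cm <- cigars_from_msa(rows)
    for (id in names(rows))
      expect_equal(apply_cigar(cm$cigars[[id]], cm$seqs[[id]]), unname(rows[[id]]))
  }
})

test_that("column classification follows the four-way mapping", {
  cc <- classify_columns(parse_cigar("2M2D2M"), parse_cigar("6M"))
  expect_equal(cc$classes, c("BOTH", "INSERTION", "BOTH"))
  expect_equal(cc$lengths, c(2L, 2L, 2L))
  cc2 <- classify_columns(parse_cigar("5M"), parse_cigar("5M"))
  expect_equal(cc2$classes, "BOTH")
  expect_equal(cc2$lengths, 5L)
  cc3 <- classify_columns(parse_cigar("3M"), parse_cigar("3D"))
  expect_equal(cc3$classes, "DELETION")
  expect_error(classify_columns(parse_cigar("3M"), parse_cigar("4M")),
               "3.*4")
})

test_that("classification matches the brute-force oracle and swaps cleanly", {
  set.seed(7)
  for (i in 1:200) {
    L <- sample(5:120, 1)
    g <- random_cigar(L, "g"); t <- random_cigar(L, "t")
    cc <- classify_columns(g, t)
    expect_equal(rep(cc$classes, cc$lengths), oracle_classify(g, t))
    # normalized: no two adjacent runs share a class
    if (length(cc$classes) > 1L)
      expect_true(all(cc$classes[-1] != cc$classes[-length(cc$classes)]))
    # swapping guide and target exchanges INSERTION and DELETION
    sw <- classify_columns(t, g)
    remap <- c(BOTH = "BOTH", INSERTION = "DELETION",
               DELETION = "INSERTION", NEITHER = "NEITHER")
    expect_equal(unname(remap[cc$classes]), sw$classes)
    expect_equal(cc$lengths, sw$lengths)
  }
})

test_that("pairwise stats match the worked examples", {
  m <- blosum62()
  s1 <- pairwise_stats(parse_cigar("3M"), "MKV", parse_cigar("3M"), "MKV", m)
  expect_equal(unlist(unclass(s1)), rep(100, 6), ignore_attr = TRUE)
  s2 <- pairwise_stats(parse_cigar("3M1D"), "MKV", parse_cigar("4M"), "MKVL", m)
  expect_equal(s2$perc_cov_a, 100)
  expect_equal(s2$perc_cov_b, 75)
  expect_equal(s2$perc_id_a, 100)
  expect_equal(s2$perc_id_b, 75)
  # single aligned column M vs L: not identical but positive (BLOSUM62 = 2)
  expect_gt(m["M", "L"], 0)
  s3 <- pairwise_stats(parse_cigar("1M"), "M", parse_cigar("1M"), "L", m)
  expect_equal(s3$perc_id_a, 0)
  expect_equal(s3$perc_pos_a, 100)
  expect_equal(s3$perc_pos_b, 100)
  expect_error(pairwise_stats(parse_cigar("1M"), "j", parse_cigar("1M"), "L", m),
               "residue 'j'")
})

test_that("stats are symmetric under member swap and ordered id<=pos<=cov", {
  set.seed(11)
  for (i in 1:60) {
    L <- sample(6:60, 1)
    ra <- random_aligned_row(L); rb <- random_aligned_row(L)
    cm <- cigars_from_msa(c(a = ra, b = rb))
    st <- pairwise_stats(cm$cigars$a, cm$seqs[["a"]],
                         cm$cigars$b, cm$seqs[["b"]])
    sw <- pairwise_stats(cm$cigars$b, cm$seqs[["b"]],
                         cm$cigars$a, cm$seqs[["a"]])
    expect_equal(st$perc_id_a, sw$perc_id_b)
    expect_equal(st$perc_pos_a, sw$perc_pos_b)
    expect_equal(st$perc_cov_a, sw$perc_cov_b)
    expect_true(st$perc_id_a <= st$perc_pos_a + 1e-12)
    expect_true(st$perc_pos_a <= st$perc_cov_a + 1e-12)
    expect_true(st$perc_cov_a <= 100 + 1e-12)
    expect_true(st$perc_id_b <= st$perc_pos_b + 1e-12)
    expect_true(st$perc_pos_b <= st$perc_cov_b + 1e-12)
  }
})

test_that("NCBI-format scoring matrices load and agree with BLOSUM62", {
  b <- blosum62()
  keep <- c("A", "R", "N", "D", "C", "M", "L", "K")
  sub <- b[keep, keep]
  f <- tempfile(fileext = ".mat")
  writeLines(c("# test matrix",
               paste(" ", paste(keep, collapse = "  ")),
               vapply(keep, function(r)
                 paste(r, paste(sub[r, ], collapse = " ")), character(1))),
             f)
  m <- read_scoring_matrix(f)
  expect_equal(m, sub, ignore_attr = TRUE)
  expect_equal(rownames(m), keep)
})
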