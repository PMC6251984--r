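# Seeded simulator for complete, internally consistent gene families:
# a species tree, a gene tree grown over it with duplications, an ancestral
# exon/intron structure, and per-gene planted insertions/deletions. The
# family MSA is built by construction (gaps exactly at the planted events),
# gene structures are adjusted per gene, and a ground-truth log records
# every event with its expected genomic footprint — computed by direct
# arithmetic during emission, independently of the CIGAR-projection path it
# is used to test.
#
# Proteins are random sequences over the 20 standard residues with no
# substitution model: structural change, not sequence divergence, is the
# test surface. Ancestral exon lengths are whole codons, so planted indels
# (whole residues, interior to one exon) always project to a single genomic
# segment.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Simulation parameters
#'
#' @param n_species Number of species.
#' @param duplication_prob Probability that a gene lineage duplicates on
#'   entering a species-tree node (internal or terminal).
#' @param n_exons Range (min, max) of ancestral exon count.
#' @param exon_len Range of ancestral exon length in nucleotides (rounded
#'   down to whole codons).
#' @param intron_len Range of intron length in nucleotides.
#' @param utr_len Range of UTR length in nucleotides.
#' @param insertion_rate,deletion_rate Expected planted events per gene
#'   (Poisson).
#' @param indel_len Range of event length in residues.
#' @param neighborhood_size Genes per chromosome in synteny fixtures.
#' @param loss_prob Per-gene loss probability in synteny fixtures.
#' @param guide_pristine Keep the first leaf (the default guide) free of
#'   planted events, so it carries the ancestral structure.
#' @param seed RNG seed; the same seed gives byte-identical fixtures.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_species = 4, duplication_prob = 0.15,
                       n_exons = c(3, 8), exon_len = c(60, 300),
                       intron_len = c(200, 2000), utr_len = c(50, 200),
                       insertion_rate = 0.5, deletion_rate = 0.5,
                       indel_len = c(1, 8), neighborhood_size = 11,
                       loss_prob = 0.1, guide_pristine = TRUE, seed = 1) {
  chk_range <- function(x, nm, lo = 1) {
    if (length(x) != 2L || x[1] > x[2] || x[1] < lo)
      err_input("invalid range for %s", nm)
  }
  if (n_species < 1) err_input("n_species must be >= 1")
  if (duplication_prob < 0 || duplication_prob > 1)
    err_input("duplication_prob must be in [0, 1]")
  if (loss_prob < 0 || loss_prob > 1) err_input("loss_prob must be in [0, 1]")
  if (insertion_rate < 0 || deletion_rate < 0)
    err_input("event rates must be >= 0")
  chk_range(n_exons, "n_exons"); chk_range(exon_len, "exon_len", 3)
  chk_range(intron_len, "intron_len"); chk_range(utr_len, "utr_len")
  chk_range(indel_len, "indel_len")
  if (floor(exon_len[2] / 3) < indel_len[2] + 2)
    err_input("exon_len too small to host indels of length %d (CDS %% 3 == 0 cannot hold)",
              indel_len[2])
  structure(list(n_species = as.integer(n_species),
                 duplication_prob = duplication_prob, n_exons = n_exons,
                 exon_len = exon_len, intron_len = intron_len,
                 utr_len = utr_len, insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate, indel_len = indel_len,
                 neighborhood_size = as.integer(neighborhood_size),
                 loss_prob = loss_prob,
                 guide_pristine = isTRUE(guide_pristine),
                 seed = as.integer(seed)),
            class = "sim_params")
}

rint <- function(rng, n = 1) sample(rng[1]:rng[2], n, replace = TRUE)

# random species tree by successive joins; leaves are species names
random_species_tree <- function(species) {
  nodes <- as.list(species)
  while (length(nodes) > 1L) {
    i <- sample(length(nodes), 2L)
    nodes <- c(nodes[-i], list(list(left = nodes[[i[1L]]],
                                    right = nodes[[i[2L]]])))
  }
  nodes[[1L]]
}

# grow a gene tree over the species tree; one optional duplication per
# lineage entering each species-tree node (terminal nodes included)
grow_gene_tree <- function(sp_node, dup_prob) {
  grow <- function(sp) {
    if (stats::runif(1) < dup_prob)
      list(event = "duplication", children = list(speciate(sp), speciate(sp)))
    else speciate(sp)
  }
  speciate <- function(sp) {
    if (is.character(sp)) return(list(event = "leaf", species = sp))
    list(event = "speciation",
         children = list(grow(sp$left), grow(sp$right)))
  }
  grow(sp_node)
}

# flatten: assign leaf gene ids, per-node species counts, root->leaf paths
index_gene_tree <- function(root) {
  uid <- 0L
  leaves <- list()
  sp_count <- new.env(parent = emptyenv())
  per_sp <- integer(0)
  walk <- function(node, path) {
    uid <<- uid + 1L
    node$uid <- uid
    path <- c(path, uid)
    if (node$event == "leaf") {
      k <- if (node$species %in% names(per_sp)) per_sp[[node$species]] + 1L else 1L
      per_sp[[node$species]] <<- k
      node$gene_id <- sprintf("%s_g%d", node$species, k)
      cnt <- stats::setNames(1L, node$species)
      leaves[[length(leaves) + 1L]] <<-
        list(uid = node$uid, gene_id = node$gene_id,
             species = node$species, path = path)
    } else {
      node$children <- lapply(node$children, walk, path = path)
      cnt <- integer(0)
      for (ch in node$children) {
        c2 <- get(as.character(ch$uid), envir = sp_count)
        for (s in names(c2))
          cnt[s] <- (if (s %in% names(cnt)) cnt[s] else 0L) + c2[s]
      }
    }
    assign(as.character(node$uid), cnt, envir = sp_count)
    node
  }
  root <- walk(root, integer(0))
  events <- new.env(parent = emptyenv())
  collect <- function(node) {
    assign(as.character(node$uid), node$event, envir = events)
    if (node$event != "leaf") lapply(node$children, collect)
    invisible(NULL)
  }
  collect(root)
  list(root = root, leaves = leaves, sp_count = sp_count, events = events)
}

# ground-truth homology types straight from the generative structure
truth_pair_types <- function(idx) {
  leaves <- idx$leaves
  n <- length(leaves)
  if (n < 2L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      type = character(), stringsAsFactors = FALSE))
  }
  get_count <- function(uid, sp) {
    cnt <- get(as.character(uid), envir = idx$sp_count)
    if (sp %in% names(cnt)) cnt[[sp]] else 0L
  }
  rows <- list()
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    a <- leaves[[i]]; b <- leaves[[j]]
    shared <- intersect(a$path, b$path)
    lca <- shared[length(shared)]
    ty <- if (a$species == b$species) {
      "within_species_paralog"
    } else if (get(as.character(lca), envir = idx$events) == "duplication") {
      "between_species_paralog"
    } else {
      ca <- a$path[match(lca, a$path) + 1L]
      cb <- b$path[match(lca, b$path) + 1L]
      na <- get_count(ca, a$species); nb <- get_count(cb, b$species)
      if (na == 1L && nb == 1L) "ortholog_one2one"
      else if (na > 1L && nb > 1L) "ortholog_many2many"
      else "ortholog_one2many"
    }
    rows[[length(rows) + 1L]] <-
      data.frame(gene_a = a$gene_id, gene_b = b$gene_id, type = ty,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

emit_nhx <- function(node, is_root = FALSE) {
  blen <- sprintf(":%.4f", stats::runif(1, 0.05, 0.5))
  if (node$event == "leaf") {
    sprintf("%s%s[&&NHX:S=%s]", node$gene_id, blen, node$species)
  } else {
    inner <- paste(vapply(node$children, emit_nhx, character(1)),
                   collapse = ",")
    tag <- if (node$event == "duplication") "[&&NHX:D=Y]" else ""
    paste0("(", inner, ")", if (is_root) "" else blen, tag)
  }
}

# draw planted events for one gene; `ex_lo`/`ex_hi` are ancestral exon
# residue spans (0-based half-open)
draw_events <- function(params, ex_lo, ex_hi) {
  P <- ex_hi[length(ex_hi)]
  ex_res <- ex_hi - ex_lo
  taken <- rep(FALSE, P + 1L) # residue r occupies slot r + 1
  events <- list()
  n_del <- stats::rpois(1, params$deletion_rate)
  n_ins <- stats::rpois(1, params$insertion_rate)
  for (d in seq_len(n_del)) {
    L <- rint(params$indel_len)
    ok <- which(ex_res >= L + 2L)
    if (!length(ok)) next
    for (try in 1:50) {
      e <- ok[sample(length(ok), 1L)]
      a0 <- sample((ex_lo[e] + 1L):(ex_hi[e] - 1L - L), 1L)
      slots <- (a0 - 1L):(a0 + L) + 1L
      if (!any(taken[slots])) {
        taken[slots] <- TRUE
        events[[length(events) + 1L]] <-
          list(kind = "deletion", exon = e, anc_pos = a0, len = L)
        break
      }
    }
  }
  for (d in seq_len(n_ins)) {
    L <- rint(params$indel_len)
    ok <- which(ex_res >= 2L)
    for (try in 1:50) {
      e <- ok[sample(length(ok), 1L)]
      p <- sample((ex_lo[e] + 1L):(ex_hi[e] - 1L), 1L)
      slots <- (p - 1L):p + 1L
      if (!any(taken[slots])) {
        taken[slots] <- TRUE
        events[[length(events) + 1L]] <-
          list(kind = "insertion", exon = e, anc_pos = p, len = L,
               residues = paste(sample(AA20, L, replace = TRUE),
                                collapse = ""))
        break
      }
    }
  }
  if (length(events))
    events <- events[order(vapply(events, `[[`, integer(1), "anc_pos"))]
  events
}

#' Simulate a complete gene family fixture
#'
#' Builds an ancestral gene (codon-aligned exons), grows a gene tree over a
#' random species tree with duplications, plants per-gene insertions and
#' deletions, and emits mutually consistent GFF3 gene models, an aligned
#' protein FASTA (gaps exactly at the planted events), an NHX Newick tree,
#' and a ground-truth log. Deterministic for a given seed.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `family_fixture`: `params`, `guide` (first leaf),
#'   `models` (a `gene_model_set`), `gff3` (lines), `msa` (named aligned
#'   rows), `newick`, `tree` (parsed `gene_tree`), and `truth` with
#'   `pairs` (ground-truth homology types), `events` (per gene: kind, host
#'   exon, ancestor position, length, target-protein start and the expected
#'   genomic footprint), `leaf_order`, `species`, and the ancestral exon
#'   residue counts.
#' @export
simulate_family <- function(params = sim_params()) {
  set.seed(params$seed)
  species <- sprintf("sp%02d", seq_len(params$n_species))
  sp_tree <- random_species_tree(species)
  idx <- index_gene_tree(grow_gene_tree(sp_tree, params$duplication_prob))
  leaves <- idx$leaves
  leaf_ids <- vapply(leaves, `[[`, character(1), "gene_id")
  leaf_sp <- stats::setNames(vapply(leaves, `[[`, character(1), "species"),
                             leaf_ids)

  # ancestral structure (exon lengths in whole codons)
  n_ex <- rint(params$n_exons)
  res_rng <- c(max(params$indel_len[2] + 2L, params$exon_len[1] %/% 3L),
               params$exon_len[2] %/% 3L)
  ex_res <- rint(res_rng, n_ex)
  ex_hi <- cumsum(ex_res); ex_lo <- c(0L, ex_hi[-n_ex])
  P <- ex_hi[n_ex]
  anc_prot <- sample(AA20, P, replace = TRUE)

  # planted events per gene (the guide stays pristine by default)
  gene_events <- lapply(seq_along(leaf_ids), function(j) {
    if (j == 1L && params$guide_pristine) list()
    else draw_events(params, ex_lo, ex_hi)
  })
  names(gene_events) <- leaf_ids

  # MSA columns: ancestor positions with member-specific insertion blocks
  blocks <- list() # (member j, anc_pos, len, residues)
  for (j in seq_along(leaf_ids)) for (ev in gene_events[[j]])
    if (ev$kind == "insertion")
      blocks[[length(blocks) + 1L]] <- c(ev, list(member = j))
  bpos <- vapply(blocks, `[[`, integer(1), "anc_pos")
  bmem <- vapply(blocks, function(b) b$member, integer(1))
  border <- order(bpos, bmem)
  blocks <- blocks[border]

  deleted <- lapply(seq_along(leaf_ids), function(j) {
    del <- rep(FALSE, P)
    for (ev in gene_events[[j]]) if (ev$kind == "deletion")
      del[(ev$anc_pos + 1L):(ev$anc_pos + ev$len)] <- TRUE
    del
  })

  msa <- vapply(seq_along(leaf_ids), function(j) {
    row <- character(0)
    bi <- 1L
    for (r in 0:(P - 1L)) {
      while (bi <= length(blocks) && blocks[[bi]]$anc_pos == r) {
        b <- blocks[[bi]]
        row <- c(row, if (b$member == j) b$residues
                 else strrep("-", b$len))
        bi <- bi + 1L
      }
      row <- c(row, if (deleted[[j]][r + 1L]) "-" else anc_prot[r + 1L])
    }
    paste(row, collapse = "")
  }, character(1))
  names(msa) <- leaf_ids

  # per-gene structures, genomic placement, and event ground truth
  models <- list()
  truth_events <- list()
  cursor <- new.env(parent = emptyenv()) # per-chromosome placement cursor
  for (j in seq_along(leaf_ids)) {
    gid <- leaf_ids[j]
    sp <- leaf_sp[[gid]]
    evs <- gene_events[[j]]
    ins_in_exon <- del_in_exon <- integer(n_ex)
    for (ev in evs) {
      if (ev$kind == "insertion") ins_in_exon[ev$exon] <- ins_in_exon[ev$exon] + ev$len
      else del_in_exon[ev$exon] <- del_in_exon[ev$exon] + ev$len
    }
    ex_res_m <- ex_res + ins_in_exon - del_in_exon
    mhi <- cumsum(ex_res_m); mlo <- c(0L, mhi[-n_ex])
    u5 <- rint(params$utr_len); u3 <- rint(params$utr_len)
    introns <- if (n_ex > 1L) rint(params$intron_len, n_ex - 1L) else integer(0)
    strand <- sample(c("+", "-"), 1L)

    # transcript-coordinate layout (0 = transcript 5' end, includes UTRs)
    chunk <- 3L * ex_res_m
    cds_t_lo <- u5 + cumsum(c(0L, chunk[-n_ex])) + cumsum(c(0L, introns))
    cds_t_hi <- cds_t_lo + chunk
    exon_t_lo <- cds_t_lo; exon_t_hi <- cds_t_hi
    exon_t_lo[1L] <- 0L
    exon_t_hi[n_ex] <- exon_t_hi[n_ex] + u3
    total <- exon_t_hi[n_ex]

    chrom <- paste0("chr_", sp)
    g0 <- if (exists(chrom, envir = cursor)) get(chrom, envir = cursor)
          else 10000L
    assign(chrom, g0 + total + sample(5000:20000, 1L), envir = cursor)
    t2g <- function(a, b) {
      if (strand == "+") c(g0 + a, g0 + b) else c(g0 + total - b, g0 + total - a)
    }
    iv <- function(tlo, thi) {
      gg <- t(mapply(t2g, tlo, thi))
      interval_df(rep(chrom, length(tlo)), gg[, 1L], gg[, 2L],
                  rep(strand, length(tlo)))
    }
    tx <- transcript_model(paste0(gid, "_t1"), gid, strand,
                           exons = iv(exon_t_lo, exon_t_hi),
                           cds = iv(cds_t_lo, cds_t_hi),
                           utr5 = iv(0L, u5),
                           utr3 = iv(cds_t_hi[n_ex], exon_t_hi[n_ex]))
    models[[gid]] <- gene_model(gid, gid, sp,
                                genomic_interval(chrom, g0, g0 + total, strand),
                                tx)

    # ground-truth genomic footprint per event, by direct arithmetic
    mask <- strsplit(msa[[gid]], "")[[1]] != "-"
    own_ins_pos <- vapply(evs, function(e)
      if (e$kind == "insertion") e$anc_pos else NA_integer_, integer(1))
    own_ins_len <- vapply(evs, function(e)
      if (e$kind == "insertion") e$len else 0L, integer(1))
    res_before <- function(anc_r) {
      # member residues strictly before ancestor position anc_r
      sum(!deleted[[j]][seq_len(anc_r)]) +
        sum(own_ins_len[!is.na(own_ins_pos) & own_ins_pos < anc_r])
    }
    tr <- lapply(evs, function(ev) {
      e <- ev$exon
      if (ev$kind == "insertion") {
        t0 <- res_before(ev$anc_pos)
        tc <- cds_t_lo[e] + 3L * (t0 - mlo[e])
        gg <- t2g(tc, tc + 3L * ev$len)
        data.frame(gene_id = gid, kind = "insertion", exon = e,
                   anc_pos = ev$anc_pos, len = ev$len, target_res_start = t0,
                   seq_id = chrom, g_start = gg[1L], g_end = gg[2L],
                   stringsAsFactors = FALSE)
      } else {
        t0 <- res_before(ev$anc_pos)
        tc <- cds_t_lo[e] + 3L * (t0 - mlo[e])
        gp <- if (strand == "+") g0 + tc else g0 + total - tc
        data.frame(gene_id = gid, kind = "deletion", exon = e,
                   anc_pos = ev$anc_pos, len = ev$len, target_res_start = t0,
                   seq_id = chrom, g_start = gp, g_end = gp,
                   stringsAsFactors = FALSE)
      }
    })
    truth_events[[gid]] <- do.call(rbind, c(tr, list(
      data.frame(gene_id = character(), kind = character(), exon = integer(),
                 anc_pos = integer(), len = integer(),
                 target_res_start = integer(), seq_id = character(),
                 g_start = integer(), g_end = integer(),
                 stringsAsFactors = FALSE))))
  }
  models <- structure(models, class = "gene_model_set")

  newick <- paste0(emit_nhx(idx$root, is_root = TRUE), ";")
  tree <- parse_newick_nhx(newick)
  gff3 <- write_gff3(models)
  truth <- list(guide = leaf_ids[1L], leaf_order = leaf_ids,
                species = as.list(leaf_sp), pairs = truth_pair_types(idx),
                events = truth_events,
                ancestor = list(n_exons = n_ex, exon_residues = ex_res))
  structure(list(params = params, guide = leaf_ids[1L], models = models,
                 gff3 = gff3, msa = msa, newick = newick, tree = tree,
                 truth = truth),
            class = "family_fixture")
}

#' Write a family fixture to disk
#'
#' Emits `family.gff3`, `family_msa.fa` (aligned FASTA), `family.nhx` and
#' `truth.json` into `dir`.
#'
#' @param fixture A [simulate_family()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_family_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gff3 = file.path(dir, "family.gff3"),
             msa = file.path(dir, "family_msa.fa"),
             newick = file.path(dir, "family.nhx"),
             truth = file.path(dir, "truth.json"))
  writeLines(fixture$gff3, paths[["gff3"]])
  write_fasta(fixture$msa, paths[["msa"]])
  writeLines(fixture$newick, paths[["newick"]])
  writeLines(as.character(jsonlite::toJSON(fixture$truth, auto_unbox = TRUE,
                                           digits = NA)),
             paths[["truth"]])
  invisible(paths)
}

#' Simulate a conserved gene neighbourhood across species
#'
#' A block of `neighborhood_size` ancestral genes is propagated to every
#' species in conserved order; each non-focal gene is independently lost
#' with probability `loss_prob`. The focal gene (middle of the block) is
#' never lost.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `synteny_fixture`: `rows` (per species: species,
#'   seq_id, genes data frame with ancestral index `anc`, `focal_gene`),
#'   `pairs` (cross-species homologous gene pairs), and `focal_anc`.
#' @export
simulate_synteny <- function(params = sim_params()) {
  set.seed(params$seed)
  n <- params$neighborhood_size
  focal_anc <- (n + 1L) %/% 2L
  species <- sprintf("sp%02d", seq_len(params$n_species))
  rows <- lapply(species, function(sp) {
    keep <- stats::runif(n) >= params$loss_prob
    keep[focal_anc] <- TRUE
    anc <- which(keep)
    m <- length(anc)
    widths <- sample(2000:8000, m, replace = TRUE)
    gaps <- sample(1000:5000, m, replace = TRUE)
    start <- 10000L + cumsum(c(0L, (widths + gaps)[-m]))
    genes <- gene_list_df(sprintf("%s_n%d", sp, anc), paste0("chr_", sp),
                          start, start + widths,
                          sample(c("+", "-"), m, replace = TRUE))
    genes$anc <- anc
    list(species = sp, seq_id = paste0("chr_", sp), genes = genes,
         focal_gene = sprintf("%s_n%d", sp, focal_anc))
  })
  pairs <- list()
  for (i in seq_along(rows)) for (k in seq_along(rows)) {
    if (i >= k) next
    a <- rows[[i]]$genes; b <- rows[[k]]$genes
    shared <- intersect(a$anc, b$anc)
    if (length(shared))
      pairs[[length(pairs) + 1L]] <-
        data.frame(gene_a = a$gene_id[match(shared, a$anc)],
                   gene_b = b$gene_id[match(shared, b$anc)],
                   stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, c(pairs, list(
    data.frame(gene_a = character(), gene_b = character(),
               stringsAsFactors = FALSE))))
  structure(list(rows = rows, pairs = pairs, focal_anc = focal_anc,
                 params = params),
            class = "synteny_fixture")
}

#' Write a synteny fixture to disk
#'
#' Emits `synteny_genes.tsv` (species, seq_id, gene_id, start, end, strand,
#' anc) and `synteny_pairs.tsv` (gene_a, gene_b) into `dir`.
#'
#' @param fixture A [simulate_synteny()] result.
#' @param dir Output directory.
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_synteny_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genes = file.path(dir, "synteny_genes.tsv"),
             pairs = file.path(dir, "synteny_pairs.tsv"))
  lines <- c("species\tseq_id\tgene_id\tstart\tend\tstrand\tanc",
             unlist(lapply(fixture$rows, function(row) {
               g <- row$genes
               sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%d", row$species, row$seq_id,
                       g$gene_id, g$start, g$end, g$strand, g$anc)
             })))
  writeLines(lines, paths[["genes"]])
  writeLines(c("gene_a\tgene_b",
               sprintf("%s\t%s", fixture$pairs$gene_a, fixture$pairs$gene_b)),
             paths[["pairs"]])
  invisible(paths)
}

#' Random transcript model for coordinate-mapping tests
#'
#' Draws exon/intron structure from the current RNG stream. Exon lengths
#' are not codon-aligned, so codons regularly span introns; the total CDS
#' length is adjusted to a multiple of three. The transcript is fully
#' coding (no UTRs).
#'
#' @param id Transcript identifier.
#' @param n_exon_range,exon_len_range,intron_len_range Ranges for structure
#'   draws (exon lengths in nucleotides).
#' @return A [transcript_model()].
#' @export
random_transcript <- function(id = "tx", n_exon_range = c(1, 6),
                              exon_len_range = c(4, 200),
                              intron_len_range = c(20, 500)) {
  n <- rint(n_exon_range)
  w <- rint(exon_len_range, n)
  rem <- sum(w) %% 3L
  w[n] <- w[n] - rem
  if (w[n] < 1L) w[n] <- w[n] + 3L
  introns <- if (n > 1L) rint(intron_len_range, n - 1L) else integer(0)
  strand <- sample(c("+", "-"), 1L)
  g0 <- sample(1000:100000, 1L)
  starts <- g0 + cumsum(c(0L, w[-n])) + cumsum(c(0L, introns))
  ex <- interval_df(rep("chrT", n), starts, starts + w, rep(strand, n))
  transcript_model(id, paste0(id, "_gene"), strand, ex, ex)
}
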