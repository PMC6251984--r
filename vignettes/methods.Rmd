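---
title: "Comparing gene structures across a family: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing gene structures across a family: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genetreeviz)
```

`genetreeviz` answers a structural question about gene families: relative
to one chosen *guide gene*, where has each homologue gained or lost coding
sequence, and how do the exon boundaries correspond? This vignette explains
the underlying models, the choices made where the design was genuinely
open, and what the test suite does and does not establish.

## Coordinate conventions

All internal coordinates are 0-based half-open intervals; GFF3's 1-based
inclusive convention is converted exactly once, at the I/O boundary. A
transcript's CDS has its own coordinate axis: position 0 is the first
coding base in transcription order, so on the `-` strand increasing CDS
coordinates run *down* the genome. Residue *r* of the protein occupies CDS
nucleotides `[3r, 3r+3)`. A codon whose bases span an intron maps to two
genomic fragments, and both are drawn — the alternative (snapping to one
exon) would silently misplace up to two bases.

For colouring, each residue must belong to exactly one exon. A split codon
is assigned to the exon containing its **middle base**, which equals the
"exon holding at least two of the three bases" rule whenever no exon holds
exactly one base of the codon, and stays deterministic in the degenerate
1+1+1 case (an exon of length one).

## CIGAR algebra

A member's alignment row is run-length encoded over `{M, D}` in protein
space, the per-member convention of Ensembl Compara homology alignments.
The alphabet is deliberately closed: `I` (and any nucleotide-space op) is
rejected rather than reinterpreted, because a silent misreading of a
SAM-style CIGAR would corrupt every downstream coordinate. Classification
of a target against the guide merges the two run lists with a two-pointer
sweep — linear in the number of runs, never expanding columns — into
`BOTH` / `INSERTION` / `DELETION` / `NEITHER` runs; the test suite checks
this against literal column expansion on thousands of random pairs.

Pairwise statistics follow the bidirectional homology-table convention:
over mutually aligned (`BOTH`) columns, identical residues, positively
scoring pairs, and the aligned-column count are each expressed as a
percentage of *each member's own* ungapped length. "Positive" means a
substitution-matrix score strictly greater than zero; the matrix defaults
to BLOSUM62 (shipped with Biostrings) and is injectable, including from
NCBI-format text files. `NEITHER` columns — gaps in both members, typically
a third member's private insertion — contribute to no statistic.
Percentages are kept at full precision internally and rounded to one
decimal only in CSV output.

## Building comparison tracks

For each homologue, classification runs are projected onto that
homologue's genome:

* `BOTH` runs are split wherever the guide-side residues change guide
  exon, and each piece is mapped through the target's CDS map; each MATCH
  fragment therefore carries exactly one guide-exon colour index. This is
  what makes a target exon aligning across two adjacent guide exons appear
  as two consecutively coloured fragments — the visual signature of a gene
  split or mis-annotation.
* `INSERTION` runs map to target genomic intervals of length `3 × run`.
* Each maximal `DELETION` run collapses to a zero-width genomic mark
  between the flanking aligned target residues; with no left flank the
  mark sits at the target CDS 5' end (on the `-` strand that is the
  highest-coordinate CDS edge). Runs separated only by `NEITHER` columns
  produce the same flank and merge into one mark, avoiding mark pile-up.
* Segments of the same kind and colour that end up genomically contiguous
  (their separator was only `NEITHER` columns or a guide-side deletion)
  are coalesced: on the target's genome they are one uninterrupted block.
* UTRs and introns are emitted explicitly (`UTR5`/`UTR3`/`NONCODING`), so
  renderers never re-derive structure.

Two conservation identities hold by construction and are asserted on random
families: total MATCH length is `3 ×` the `BOTH` column count, total
INSERTION length `3 ×` the `INSERTION` column count; and swapping guide and
target exchanges insertion segments with deletion marks.

## Homology typing

Internal tree nodes carry one of three events. Newick/NHX input maps
`D=Y` to duplication and defaults everything else to speciation; a custom
`Ev=gene_split` tag carries the third event, since standard NHX has no
gene-split flag. For a leaf pair, the event at the last common ancestor
decides: same species → within-species paralog; duplication →
between-species paralog (kept as an explicit fifth type, following the
Ensembl convention, with a coarse `ortholog`/`paralog` column alongside for
three-bucket filtering); speciation → ortholog, with the one2one /
one2many / many2many flavour decided by counting each species' genes in the
LCA's two child subtrees. Gene-split nodes type like speciation — they mark
an annotation artefact, not a copy-number event — but keep their own node
colour in the tree view; this is a documented package decision, as is
treating the canonical transcript of a multi-transcript gene as the one
with the longest total CDS (ties to the lexicographically smallest
transcript ID), since plain GFF3 carries no canonical flag.

## Layout and rendering

Two layout modes mirror the "collapse introns?" choice every structure
browser faces. **Exon-focused** (default) gives every intron a fixed pixel
width (`fixed_intron_px`, default 6) and scales exons to their nucleotide
length, with the common scale chosen so the widest row spans exactly
`canvas_width` (default 1200 px). **Proportional** uses one global nt→px
scale with the longest gene spanning the canvas exactly. Rows are 24 px
high; the palette has 12 distinct colours cycled by
`color_index mod 12`. Tree x-positions are cladogram by default (branch
lengths ignored; a `phylogram` flag uses them), since structure rows, not
branch lengths, are the focus of the view. Event colours are speciation
blue, duplication red, gene split cyan; the guide leaf is a larger black
circle and its label is red.

SVG output is a pure function of inputs and options: styling lives in an
embedded stylesheet keyed by class attributes (so downstream tools can
restyle), all numbers are printed with a fixed two-decimal format, and no
timestamps or randomness enter the output — identical inputs give
byte-identical files, which the tests assert.

## Gene order (synteny)

A window of up to *k* neighbours per side (default 10) is cut around the
focal gene and around each of its homologues in the other species.
Reference-row genes get sequential colour indices; a gene in another row
takes the colour of its reference-row homologue *only if that homologue is
inside the visible window*, and is drawn white otherwise. Colouring is via
the reference row only, not transitively — transitive colouring could
propagate a colour through a homologue the user cannot see. When a gene has
several in-window reference homologues the left-most decides, a
deterministic tie-break.

## The simulator: what it emulates, and what it does not

`simulate_family()` constructs a family top-down so that every emitted file
is consistent by construction: a random species tree (successive joins), a
gene tree grown over it where each lineage entering a species-tree node
duplicates with probability `duplication_prob` (0.15 by default, terminal
branches included, which yields recent within-species paralogs), an
ancestral gene of 3–8 exons of 60–300 nt with 200–2000 nt introns and
50–200 nt UTRs, and per-gene planted indels (Poisson with mean 0.5 each
for insertions and deletions, lengths 1–8 residues). These defaults were
chosen once as typical vertebrate-like gene geometry at moderate
divergence; problem sizes in the test suite (hundreds of random structures,
on the order of a hundred seeded families) were likewise fixed up front as
comfortably large for property checks while keeping the default suite
quick.

Three structural simplifications are deliberate:

* **Ancestral exons are whole codons**, so planted indels (whole residues,
  interior to one exon, non-adjacent within a gene) always project to a
  single genomic segment — giving the sharp "one event, one segment"
  ground truth the recovery tests need. Split codons are exercised
  separately by `random_transcript()`, whose exons are *not*
  codon-aligned.
* **The first leaf (default guide) carries no planted events**
  (`guide_pristine`), so it represents the ancestral structure that
  guide-relative glyphs assume.
* **No substitution model**: members inherit ancestral residues unchanged
  except at planted events. Structure, not sequence divergence, is the
  test surface; identity percentages in simulated families are therefore
  near 100 and carry no biological meaning.

Consequently, green tests demonstrate correctness of the coordinate
algebra, the event projection, the tree classification and the renderers —
not robustness to real-world annotation noise (ragged orthology, partial
genes, frame-breaking indels, trans-splicing), which is out of scope.

## Numerical and degenerate-input choices

CDS lengths must divide by 3 and are never silently trimmed; violations are
errors naming the transcript. A single-leaf tree is representable (ape
cannot hold one, so it is special-cased) and yields an empty homology
table. Empty homology tables export as header-only CSV. Newick branch
lengths are written with 12 significant digits, preserving round trips to
well under 1e-9. Deletion marks at the extreme 5' end of a target are drawn
at the first CDS base; there is no established convention for a gap with
no left flank, so the choice is documented here. The `view_scale` helper fails loudly if the
canvas cannot fit a row's introns at the fixed width rather than producing
negative scales.

## Known limitations

One canonical transcript per gene is drawn; alternative isoforms are not
compared. BAM/SAM nucleotide CIGARs are rejected by design. The tabular
view's statistics depend on the upstream MSA being a faithful family
alignment — the package visualizes alignments, it never infers them. The
SVG views are static; interactivity belongs to downstream consumers of the
class-annotated SVG.
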