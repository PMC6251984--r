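# genetreeviz

Comparative genomics browsers usually stop at the gene level: they will show
you which genes are homologous, but not *how* their internal structure —
exon/intron boundaries, UTRs, insertions and deletions — has changed across
a gene family. `genetreeviz` fills that gap as a file-based R library and
command-line tool. Given a gene family's protein alignment, its
event-labelled gene tree, and the genomic annotation of each member, it
compares every homologue against a user-chosen **guide gene** at the
alignment-column level, maps the differences back onto each homologue's own
gene structure, and renders static, deterministic SVG views: a gene-tree
view (phylogeny plus per-gene structure rows), a 1-to-1 pairwise view, and
a gene-order (synteny) view. It is aimed at researchers inspecting exon
boundary conservation, suspected gene splits or mis-annotations in both
model and non-model genomes.

## The core method

Each family member's row of the multiple sequence alignment is encoded as a
protein-space **CIGAR string** over `{M, D}` (`M` = residue present in the
column, `D` = gap in this member — the per-member convention of Ensembl
Compara homology alignments). For a guide *g* and target *t* the columns
are classified run-length-wise:

| guide | target | class       | rendered as                         |
|-------|--------|-------------|-------------------------------------|
| M     | M      | `BOTH`      | exon block coloured by guide exon   |
| D     | M      | `INSERTION` | black bar inside the target's exon  |
| M     | D      | `DELETION`  | red line at the gap position        |
| D     | D      | `NEITHER`   | nothing                             |

`BOTH` runs are mapped through the target's CDS coordinate map
(protein index → CDS nucleotide → genomic interval, strand-aware and split
at exon boundaries) and coloured by the guide exon their guide-side
residues occupy; a run straddling a guide exon boundary is split, which is
how a single target exon matching two adjacent guide exons — a classic
gene-split / mis-annotation signature — becomes visible.

Homology types are inferred from the gene tree: for leaves *a*, *b* with
last common ancestor *x*, a same-species pair is a within-species paralog;
a duplication at *x* makes a between-species paralog; a speciation at *x*
makes orthologs, with one2one / one2many / many2many decided by the copy
number of each species in *x*'s two child subtrees. Pairwise statistics are
the bidirectional Compara-style percentages over mutually aligned columns:
identity (identical residues), positivity (BLOSUM62 score > 0) and coverage
(aligned columns), each relative to the member's own sequence length, so
`id ≤ pos ≤ cov ≤ 100` per member.

A seeded simulator generates complete families — species tree, gene tree
with duplications, ancestral exon/intron structure, planted insertions and
deletions with their exact expected genomic footprints — so the entire
pipeline is testable without any external data.

## Worked example

```r
library(genetreeviz)

fx <- simulate_family(sim_params(seed = 42, insertion_rate = 1,
                                 deletion_rate = 1, duplication_prob = 0.3))
fd  <- family_tracks(fx$models, fx$tree, fx$msa, fx$guide)
tab <- homology_table(fx$tree, fx$guide, fd$cigars, fd$seqs)
tab[, c("target_gene", "homology_type", "perc_id_guide", "perc_cov_guide")]
```

```
  target_gene           homology_type perc_id_guide perc_cov_guide
1     sp01_g1        ortholog_one2one        100.00         100.00
2     sp04_g1        ortholog_one2one        100.00         100.00
3     sp02_g2  within_species_paralog         96.72          96.72
4     sp01_g2 between_species_paralog         95.63          95.63
...
9     sp03_g1       ortholog_one2many         92.90          92.90
```

The guide here is `sp02_g1`; each row is one homologue with its tree-derived
type and the percentage of the guide's residues that are identical to /
aligned with it. The per-gene drawing instructions are plain intervals:

```r
head(track_to_bed(fd$tracks[["sp01_g1"]]), 6)
```

```
chr_sp01  10000  10181  UTR5       .  sp01_g1
chr_sp01  10181  10202  MATCH      0  sp01_g1
chr_sp01  10202  10223  INSERTION  .  sp01_g1
chr_sp01  10223  10259  MATCH      0  sp01_g1
chr_sp01  10259  10265  INSERTION  .  sp01_g1
chr_sp01  10265  10274  MATCH      0  sp01_g1
```

`sp01_g1` carries two planted insertions (21 and 6 nt) inside its first
exon; the flanking `MATCH` blocks all carry colour index 0 because they
align to guide exon 0. Rendering is one call:

```r
svg <- render_genetree_svg(fx$tree, fd$tracks, view_options())
```

The same pipeline runs from the shell (`exec/genetreeviz` after install):

```sh
genetreeviz simulate --seed 42 --out-dir fam
genetreeviz view     --gff3 fam/family.gff3 --tree fam/family.nhx \
                     --msa fam/family_msa.fa --guide sp02_g1 --out tree.svg
genetreeviz homologs --gff3 fam/family.gff3 --tree fam/family.nhx \
                     --msa fam/family_msa.fa --guide sp02_g1 \
                     --type ortholog_one2one --out one2one.csv
```

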