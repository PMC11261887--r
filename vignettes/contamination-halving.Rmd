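---
title: "Scoring, halving and re-classifying putatively contaminated genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, halving and re-classifying putatively contaminated genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Draft prokaryotic genomes — metagenome-assembled genomes especially — can
carry contigs that belong to another organism. Gene-level contamination
screens classify every gene of a genome against a reference database and
flag genomes whose genes split into distinct taxonomic clades, reporting the
rank at which the separation is strongest (here called the *CSS rank*).
Such screens judge whole genomes; they do not say *which contigs* carry the
contamination, nor whether the contamination actually changes the genome's
placement in a reference taxonomy whose species are defined by a 95 %
average nucleotide identity (ANI) radius around representative genomes.

`contamhalf` implements a contig-level answer: score each contig of a
flagged genome by how strongly its gene-level taxonomy deviates from the
genome consensus, remove the most contaminated half of the genome, and ask
whether the surviving clean half still classifies with its original species
representative. A synthetic chimera generator with known ground truth makes
every stage testable without any reference downloads.

## The contig contamination score

For one genome with per-gene closest-hit lineages (seven GTDB-style ranks,
domain to species):

1. **Genome consensus**: at each rank independently, the most commonly
   inferred taxon name over all genes. Per-rank independence matters — the
   consensus is a rank-wise mode, not the modal whole lineage.
2. **Contig taxonomy**: majority vote at each rank over the contig's genes.
   A rank whose top count is shared by two or more names is *dropped*: a
   tied rank carries no evidence either way and is skipped everywhere
   downstream.
3. **Truncation**: both taxonomies are truncated at the genome's CSS rank;
   deeper ranks are noise by the screen's own account.
4. **Score**: the *divergence depth* is the index (domain = 0) of the first
   rank, scanning domain towards the CSS rank, where contig and genome
   taxonomy disagree (ranks unnamed on either side, or dropped by ties, are
   skipped); a fully congruent contig gets `css_index + 1`. The *congruent
   fraction* is the share of the contig's genes whose lineage matches the
   truncated consensus at every named rank.

Contigs are ordered most-to-least contaminated by the deterministic key
(divergence depth ascending, congruent fraction ascending, longer contig
first, contig id). The first two components express "the greater the
deviation, the higher the contamination"; the last two only make the order
total and reproducible.

Design choices the method description leaves open, fixed here once:

* **Consensus ties** are broken lexicographically (the tie rule in the
  source method is stated only for contig votes). Deterministic, and
  irrelevant whenever a genome has a clear majority.
* **Gene-less contigs** score as least contaminated (`css_index + 1`,
  fraction 1): absence of genes is absence of evidence.
* **Unnamed ranks match anything**: a truncated reference lineage is
  taxonomic novelty, not incongruence.

## Halving

Contigs are consumed whole from the most contaminated end of the order
until half the genome is removed. By nucleotides, exactly
`floor(total_nt / 2)` nt go to the contaminant half (the clean half keeps
the odd base — the conservative side of an "exactly half" rule that odd
totals cannot satisfy); at most one contig is divided. A divided contig is
first *oriented*: incongruent genes are counted in the leading and trailing
halves of its gene list (middle gene of an odd count in neither), the end
with more incongruent genes is declared contaminated and pruned; a tie
keeps the original orientation. By markers, `floor(total_markers / 2)`
marker genes are removed walking the same order, markers within a divided
contig consumed from its contaminated end. The random baseline permutes
contigs with a seeded Mersenne-Twister and applies the nucleotide split to
that order; the seed is recorded in the result.

## ANI re-classification

The clean half is assigned to a species representative the way the
reference taxonomy defines species:

* **MinHash prefilter**: bottom-`s` sketches over canonical 16-mers
  (`s` = 5000), Mash distance `d = -ln(2j/(1+j))/k`, representatives kept
  when the implied ANI `100(1-d)` is strictly above 80 % and `d <= 0.2`.
  The p-value ceiling `v = 1.0` disables the p-value filter and is carried
  as a pass-through parameter. The hash is a fixed, seeded 64-bit splitmix
  finaliser, so sketches are identical across platforms.
* **Taxonomic context**: all representatives of the expected genus; if that
  is fewer than 100 genomes, the context widens rank by rank (family,
  order, class, phylum) until at least 100 genomes *beyond the genus set*
  have been added or the phylum is exhausted. This anticipates clean halves
  drifting away from their original neighbourhood.
* **Fragment ANI**, bidirectional: each direction cuts the query into
  consecutive 3000-nt fragments, anchors each fragment on the reference by
  shared 15-mers voting over diagonals (anchors sampled every 3 bp — they
  only locate the mapping), and scores the anchored window. ANI is the mean
  identity of mapped fragments, the alignment fraction (AF) the mapped
  share of all fragments; the two directions are combined by taking the
  maximum ANI and maximum AF, making the result symmetric. Results are
  *not* bit-compatible with the published sketching/ANI tools they
  emulate; all acceptance here is internal and synthetic.
* **Categories**: the best hit by ANI (ties: higher AF, then accession)
  yields *same species* (expected representative, criteria ≥ 95 % ANI and
  ≥ 0.5 AF met), *changed species* (another representative, criteria met)
  or *new species* (criteria unmet). Alongside the raw best hit the result
  records `assigned_ref`, the best hit that actually *satisfies* the
  criteria — the cluster whose ANI radius the query falls in. For mixed
  sequences (a contaminant half carrying a sliver of host) the raw
  best-by-ANI between two ~equally identical references is a coin flip
  decided by fragment noise, while the AF criterion resolves it the way
  the species-assignment rule itself does; lineage comparisons between
  genome halves therefore use `assigned_ref`.

### Numerical choices

Fragment identity is exact Hamming identity on the winning diagonal when
that reaches 0.9, else a banded (half-width 16 nt) match-maximising DP with
linear gap penalty. Under the default substitution-only sequence model the
two are identical; the DP tolerates the generator's optional indels. A
full affine-gap aligner was considered and rejected: at these divergences
the linear-gap banded DP gives the same identities and keeps the
200-replicate acceptance runs within a single-CPU budget. Fragments
sharing fewer than 2 anchors with any reference window are unmapped, which
keeps random sequence from acquiring spurious ~25 % identities.

## Taxonomy congruency

Two classifications of the same genome are compared phylum to genus, in
that order; the first rank where both carry a name and the names differ is
the *highest incongruent rank*. Species-level agreement is the province of
the ANI categories; a domain mismatch is reported at a sentinel rank with a
warning. Tree inference itself (maximum-likelihood trees, bootstrapping,
taxonomy decoration) is out of scope: observed strings come from the
caller, or from synthetic ground truth in tests. The MSA helpers
(row substitution, column masking, marker concatenation with gap fill)
cover the alignment bookkeeping of that workflow and commute in the order
substitution/masking are applied.

## The synthetic world

`sim_config()` states the world once; tests never tune it:

| parameter | default | meaning |
|---|---|---|
| `taxa_per_rank` | 2 per rank, phylum–species | balanced taxonomy, 64 species |
| `genome_len` | 50 000 nt | total genome size (desk-scale stand-in for Mb genomes) |
| `n_contigs` | 10 (min 2 000 nt) | gamma-weighted length spread |
| `genes_per_kb` | 1 | one gene per kb, placed on a regular grid |
| `contamination_fraction` | 0.3 | target contaminant share of total nt |
| `contamination_rank` | family | rank where host and donor lineages split |
| `assignment_error` | 0.05 | per-gene chance of a random sibling-lineage swap |
| `divergence_per_rank` | 0.05 | substitutions per rank step between taxa |
| `mutation_rate` | 0.005 | genome vs its species representative |
| `marker_every` | 10 | every 10th gene is a marker |

Phyla are independent random roots; descendants accumulate
`divergence_per_rank` substitutions per rank step, so sibling species sit
near 90 % identity (clearly inside their own representative's 95 % radius,
clearly outside the sibling's) and different families near 80 %, the
prefilter boundary. Contaminant contigs are drawn by a greedy random fill
towards the target fraction with one best-fit top-up. Two constraints were
found the hard way and are deliberate: contig lengths use gamma (shape 4)
weights, and the gross-contamination scenario uses a fraction of 0.45 —
at exactly half-and-half the majority-vote consensus is mathematically
undefined and the method's own presumption (contamination is *no more*
than 50 %) is violated, so the stated world stays strictly below that
boundary.

What the generator does *not* emulate: real gene calling (genes sit on a
regular grid), codon structure, horizontal gene transfer, rearrangements,
and reference databases with uneven taxon sampling. A green recovery test
therefore establishes that the pipeline's logic recovers planted signal
under calibrated noise — not that any particular real genome is or is not
contaminated.

## What the tests establish

The acceptance suite (`tests/testthat/test-acceptance.R`) checks: the
printed count→percentage arithmetic of the aggregation module at its exact
rounding convention (half-up); brute-force-oracle equivalence for contig
ordering and halving accumulation; exhaustive-set agreement of the MinHash
Jaccard estimator; the closed-form Mash distance; Monte-Carlo recovery of
configured mutation rates by the fragment-ANI kernel; and, on 200 seeded
chimeras of the default world, ≥ 99 % same-species categorisation of clean
halves, ≥ 95 % contaminant removal, the directed-versus-random removal
contrast, and host/donor lineage separation on a 50-replicate
gross-contamination batch. Every number those tests assert is computed at
test time.

## Known limitations

* The CSS rank consumed from real screen output is replaced in synthetic
  mode by a simple congruence-fraction proxy; the proxy's arg-max can land
  below the injected rank when assignment noise accumulates with depth,
  which the scoring path tolerates by construction.
* Fragment anchoring is strand-naive (the generator emits forward-strand
  contigs); sketching, by contrast, is canonical and strand-proof.
* `taxonomic_context` counts genomes, not taxa; with the tiny synthetic
  taxonomy it routinely exhausts the phylum, which mirrors the published
  rule's behaviour on small clades.
* Percentages are reproduced at half-up rounding; one printed value in the
  source material (an intersection rate of 29.2 %) is not reproducible
  under any standard rounding of its own counts and is deliberately not a
  test target.
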