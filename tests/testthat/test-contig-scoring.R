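# Consensus taxonomy, per-contig majority votes, scoring and ordering.

test_that("genome consensus is modal per rank, independently", {
  a <- mk_assign(c(c1 = "d__B;p__X", c1 = "d__B;p__X", c1 = "d__B;p__X"))
  expect_identical(genome_consensus_taxonomy(a), c(d = "B", p = "X"))

  a <- mk_assign(c(c1 = "d__B;p__X", c1 = "d__B;p__X", c1 = "d__B;p__Y"))
  expect_identical(genome_consensus_taxonomy(a)[["p"]], "X")

  # modal per rank, not per whole lineage: {B;X, B;Y, A;Y} -> B;Y
  a <- mk_assign(c(c1 = "d__B;p__X", c1 = "d__B;p__Y", c1 = "d__A;p__Y"))
  expect_identical(genome_consensus_taxonomy(a), c(d = "B", p = "Y"))

  # ranks with no named hits stay unnamed; absent ranks stay absent
  a <- mk_assign(c(c1 = "d__B;p__", c1 = "d__B;p__"))
  expect_identical(genome_consensus_taxonomy(a), c(d = "B", p = ""))
  expect_error(genome_consensus_taxonomy(a[0, ]), "no gene")
})

test_that("contig taxonomy drops tied ranks", {
  g <- mk_assign(c(c1 = lineage7(g = "A"), c1 = lineage7(g = "A"),
                   c1 = lineage7(g = "B"), c1 = lineage7(g = "B")))
  expect_false("g" %in% names(contig_taxonomy(g)))
  expect_true("f" %in% names(contig_taxonomy(g)))

  g <- mk_assign(c(c1 = lineage7(g = "A"), c1 = lineage7(g = "A"),
                   c1 = lineage7(g = "A"), c1 = lineage7(g = "B")))
  expect_identical(contig_taxonomy(g)[["g"]], "A")

  single <- mk_assign(c(c1 = lineage7()))
  expect_identical(format_taxonomy(contig_taxonomy(single)), lineage7())
})

test_that("score_contig measures divergence depth and congruent fraction", {
  genome <- parse_taxonomy(lineage7())
  clean <- mk_assign(c(c1 = lineage7(), c1 = lineage7()))
  sc <- score_contig(contig_taxonomy(clean), genome, clean, "s")
  expect_identical(sc$divergence_depth, 7L)
  expect_identical(sc$congruent_fraction, 1.0)

  bad_p <- mk_assign(c(c1 = lineage7(p = "Z", c = "Zc")))
  sc <- score_contig(contig_taxonomy(bad_p), genome, bad_p, "s")
  expect_identical(sc$divergence_depth, 1L)
  expect_identical(sc$congruent_fraction, 0.0)

  # tie-dropped ranks are skipped, not counted as disagreement
  tied <- mk_assign(c(c1 = lineage7(g = "A"), c1 = lineage7(g = "B")))
  ctax <- contig_taxonomy(tied)
  sc <- score_contig(ctax, genome, tied, "g")
  expect_identical(sc$divergence_depth, rank_index0("g") + 1L)

  # gene-less contig is least contaminated by convention
  sc <- score_contig(character(0), genome, clean[0, ], "s")
  expect_identical(sc$congruent_fraction, 1.0)
  expect_identical(sc$n_genes, 0L)
})

test_that("rank_contigs reproduces the brute-force ordering oracle", {
  # toy from the contract: A fully congruent (4/4), B diverges at family
  # (1/3 congruent), C diverges at genus (2/4) -> order B, C, A
  a <- mk_assign(c(
    A = lineage7(), A = lineage7(), A = lineage7(), A = lineage7(),
    B = lineage7(f = "Fx", g = "Gx", s = "Sx"),
    B = lineage7(f = "Fx", g = "Gx", s = "Sy"), B = lineage7(),
    C = lineage7(g = "Gz", s = "Sz"), C = lineage7(g = "Gz", s = "Sz"),
    C = lineage7(), C = "d__B;p__X;c__C;o__O;f__F"))
  # B: majority family Fx (2 of 3) vs genome family F -> depth 4, frac 1/3
  # C: genus majority Gz (2 Gz vs 1 G, one gene unnamed past family)
  #    -> depth 5; congruent genes = the clean one + the truncated one = 2/4
  sc <- rank_contigs(a, "s")
  expect_identical(sc$contig_id, c("B", "C", "A"))
  expect_identical(sc$contig_id, oracle_sort_contigs(sc))
  expect_equal(sc$congruent_fraction, c(1 / 3, 2 / 4, 1))

  # randomised instances: produced order equals oracle sort, and scores are
  # invariant to gene-row and contig permutations
  withr::local_seed(7)
  for (rep in 1:20) {
    taxa <- character(0)
    for (cid in paste0("k", 1:6)) {
      n <- sample(1:5, 1)
      lin <- replicate(n, lineage7(p = sample(c("X", "P2"), 1),
                                   f = sample(c("F", "F2"), 1),
                                   g = sample(c("G", "G2", "G3"), 1)))
      names(lin) <- rep(cid, n)
      taxa <- c(taxa, lin)
    }
    a <- mk_assign(taxa)
    lens <- setNames(sample(1000:9000, 6), paste0("k", 1:6))
    sc <- rank_contigs(a, "g", lens)
    expect_identical(sc$contig_id, oracle_sort_contigs(sc))
    perm <- a[sample(nrow(a)), ]
    expect_identical(rank_contigs(perm, "g", lens), sc)
  }
})

test_that("clade separation proxy scores match direct computation", {
  a <- mk_assign(c(c1 = lineage7(), c1 = lineage7(), c2 = lineage7()))
  prox <- clade_separation_proxy(a)
  expect_equal(prox$table$score, rep(0, 7))
  expect_identical(prox$css_rank, "d")  # shallowest wins ties

  # 50/50 two-family chimera, perfect assignments: score hits 0.5 at family
  fam <- c(rep(lineage7(f = "F1", g = "G1", s = "S1"), 5),
           rep(lineage7(f = "F2", g = "G2", s = "S2"), 5))
  names(fam) <- rep(c("c1", "c2"), each = 5)
  prox <- clade_separation_proxy(mk_assign(fam))
  expect_equal(prox$table$score[prox$table$rank == "o"], 0)
  expect_equal(prox$table$score[prox$table$rank == "f"], 0.5)
  expect_identical(prox$css_rank, "f")

  # 70/30 two-genus chimera: argmax genus, score 0.3
  gen <- c(rep(lineage7(g = "G1", s = "S1"), 7),
           rep(lineage7(g = "G2", s = "S2"), 3))
  names(gen) <- rep("c1", 10)
  prox <- clade_separation_proxy(mk_assign(gen))
  expect_identical(prox$css_rank, "g")
  expect_equal(max(prox$table$score), 0.3)
})
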