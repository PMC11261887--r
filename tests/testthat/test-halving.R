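# Genome halving: orientation, nucleotide and marker splits, random baseline.

genome_tax <- parse_taxonomy(lineage7())
bad <- lineage7(p = "Z")   # incongruent at phylum
good <- lineage7()

test_that("orient_contig picks the end with more incongruent genes", {
  g <- mk_assign(setNames(c(bad, bad, good, good), rep("c1", 4)))
  expect_identical(orient_contig(g, genome_tax, "s"), "5p")
  g <- mk_assign(setNames(c(good, good, bad), rep("c1", 3)))
  expect_identical(orient_contig(g, genome_tax, "s"), "3p")
  # symmetric pattern keeps original orientation (tie rule)
  g <- mk_assign(setNames(c(bad, good, bad), rep("c1", 3)))
  expect_identical(orient_contig(g, genome_tax, "s"), "5p")
  expect_identical(orient_contig(g[0, ], genome_tax, "s"), "5p")
})

test_that("split_by_nucleotides removes floor(total/2) from the front", {
  withr::local_seed(3)
  two <- Biostrings::DNAStringSet(c(a = rand_dna(5000), b = rand_dna(5000)))
  h <- split_by_nucleotides(two)
  expect_identical(names(h$contaminant), "a")   # whole first contig, no split
  expect_identical(names(h$clean), "b")
  expect_true(is.na(h$split_contig_id))

  one <- Biostrings::DNAStringSet(c(x = rand_dna(10000)))
  h <- split_by_nucleotides(one)
  expect_identical(h$split_contig_id, "x")
  expect_identical(sum(Biostrings::width(h$contaminant)), 5000L)
  expect_identical(as.character(h$clean[[1]]),
                   substr(as.character(one[[1]]), 5001, 10000))

  two <- Biostrings::DNAStringSet(c(a = rand_dna(6000), b = rand_dna(4000)))
  h <- split_by_nucleotides(two)
  expect_identical(h$split_contig_id, "a")
  expect_identical(sum(Biostrings::width(h$contaminant)), 5000L)
  expect_identical(as.character(h$clean[names(h$clean) == "a"][[1]]),
                   substr(as.character(two[[1]]), 5001, 6000))
  expect_identical(sum(Biostrings::width(h$clean)), 5000L)

  expect_error(split_by_nucleotides(two[0]), "empty")
})

test_that("a split contig is pruned from its contaminated end", {
  withr::local_seed(4)
  seqs <- Biostrings::DNAStringSet(c(c1 = rand_dna(6000), c2 = rand_dna(4000)))
  # genes on c1: incongruent genes concentrated at the trailing end
  g <- mk_assign(setNames(c(good, good, bad, bad), rep("c1", 4)))
  h <- split_by_nucleotides(seqs, g, genome_tax, "s")
  expect_identical(h$split_end, "3p")
  expect_identical(as.character(h$clean[names(h$clean) == "c1"][[1]]),
                   substr(as.character(seqs[[1]]), 1, 1000))
})

test_that("nucleotide conservation holds on random instances", {
  withr::local_seed(9)
  for (rep in 1:15) {
    n <- sample(1:6, 1)
    widths <- sample(500:5000, n)
    seqs <- Biostrings::DNAStringSet(
      setNames(vapply(widths, rand_dna, character(1)), paste0("c", 1:n)))
    h <- split_by_nucleotides(seqs)
    expect_identical(sum(Biostrings::width(h$clean)) +
                       sum(Biostrings::width(h$contaminant)),
                     sum(widths))
    expect_identical(sum(Biostrings::width(h$contaminant)),
                     sum(widths) %/% 2L)
    # whole-contig membership matches the accumulation oracle
    o <- oracle_split_nt(setNames(as.integer(widths), names(seqs)))
    expect_identical(setdiff(names(h$contaminant), h$split_contig_id),
                     o$whole)
    expect_identical(h$split_contig_id, o$split_id)
  }
})

test_that("split_by_markers removes floor-half markers from the front", {
  withr::local_seed(5)
  seqs <- Biostrings::DNAStringSet(c(c1 = rand_dna(4000), c2 = rand_dna(4000)))
  # four markers, two per contig
  a <- mk_assign(setNames(c(bad, bad, good, good), c("c1", "c1", "c2", "c2")),
                 markers = rep(TRUE, 4))
  h <- split_by_markers(seqs, a, genome_tax, "s")
  expect_setequal(h$removed_markers, a$gene_id[a$contig_id == "c1"])
  expect_setequal(h$kept_markers, a$gene_id[a$contig_id == "c2"])
  expect_true(is.na(h$split_contig_id))

  # three markers on one contig: floor rule removes one, from the bad end
  a <- mk_assign(setNames(c(bad, good, good), rep("c1", 3)),
                 markers = rep(TRUE, 3))
  h <- split_by_markers(seqs["c1"], a, genome_tax, "s")
  expect_identical(h$removed_markers, "c1_g00")
  expect_identical(length(h$kept_markers), 2L)

  # five markers over three contigs, boundary mid-contig: oracle walk
  seqs3 <- Biostrings::DNAStringSet(c(c1 = rand_dna(2000), c2 = rand_dna(2000),
                                      c3 = rand_dna(2000)))
  a <- mk_assign(setNames(c(bad, bad, bad, good, good),
                          c("c1", "c2", "c2", "c3", "c3")),
                 markers = rep(TRUE, 5))
  h <- split_by_markers(seqs3, a, genome_tax, "s")
  # ordered walk removes floor(5/2) = 2: c1's marker then c2's first marker
  expect_identical(sort(h$removed_markers), c("c1_g00", "c2_g00"))
  expect_identical(h$split_contig_id, "c2")
  expect_identical(sort(c(h$removed_markers, h$kept_markers)),
                   sort(a$gene_id))
  expect_error(split_by_markers(seqs3, a[a$is_marker == FALSE, ],
                                genome_tax, "s"), "marker")
})

test_that("random_half is seeded, reproducible and conserves nucleotides", {
  withr::local_seed(6)
  seqs <- Biostrings::DNAStringSet(
    setNames(vapply(c(3000, 2000, 1000), rand_dna, character(1)),
             c("a", "b", "c")))
  h1 <- random_half(seqs, 123L)
  h2 <- random_half(seqs, 123L)
  expect_identical(as.character(h1$clean), as.character(h2$clean))
  expect_identical(h1$seed, 123L)
  expect_identical(h1$mode, "random")
  expect_identical(sum(Biostrings::width(h1$clean)) +
                     sum(Biostrings::width(h1$contaminant)), 6000L)

  # single contig always splits at half length, any seed
  one <- Biostrings::DNAStringSet(c(z = rand_dna(999)))
  for (s in 1:5) {
    h <- random_half(one, s)
    expect_identical(sum(Biostrings::width(h$contaminant)), 499L)
    expect_identical(sum(Biostrings::width(h$clean)), 500L)
  }

  # over 10 seeds on a 3-contig toy, different orderings change the
  # retained half (all 6 permutations give >= 2 distinct clean sets)
  cleans <- vapply(1:10, function(s)
    paste(sort(paste(names(random_half(seqs, s)$clean),
                     Biostrings::width(random_half(seqs, s)$clean))),
          collapse = "|"), character(1))
  expect_gt(length(unique(cleans)), 1L)
})
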