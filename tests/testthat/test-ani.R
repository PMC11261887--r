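# MinHash sketches, Mash distances, candidate selection, fragment ANI and
# the category decision.

test_that("sketches are canonical and deterministic", {
  withr::local_seed(21)
  sq <- rand_dna(5000)
  p <- minhash_params(k = 16, s = 500)
  expect_identical(sketch(sq, p)$hashes, sketch(sq, p)$hashes)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", sq), "")[[1]]),
              collapse = "")
  expect_identical(sketch(sq, p)$hashes, sketch(rc, p)$hashes)
  expect_error(sketch("ACGT", p), "shorter")
})

test_that("sketch Jaccard tracks the exhaustive k-mer oracle", {
  withr::local_seed(22)
  k <- 16L
  a <- rand_dna(5000)
  b <- paste0(substr(a, 1, 2500), rand_dna(2500))  # ~50 % shared k-mers
  true_j <- oracle_jaccard(a, b, k)
  expect_gt(true_j, 0.3); expect_lt(true_j, 0.6)
  s <- 1000L
  p <- minhash_params(k = k, s = s)
  est <- sketch_jaccard(sketch(a, p), sketch(b, p))
  se <- sqrt(true_j * (1 - true_j) / s)
  expect_lt(abs(est - true_j), 3 * se)

  # exact equality once s exceeds the number of distinct k-mers
  big <- minhash_params(k = k, s = 20000L)
  expect_equal(sketch_jaccard(sketch(a, big), sketch(b, big)), true_j,
               tolerance = 1e-12)
})

test_that("mash distance follows the closed form", {
  mk <- function(h, k = 16L, s = 1000L)
    structure(list(hashes = as.numeric(h), k = k, s = s, seed = 1L),
              class = "minhash_sketch")
  a <- mk(1:1000)
  expect_identical(mash_distance(a, a), 0)
  expect_identical(ani_estimate(mash_distance(a, a)), 100)
  disjoint <- mk(2001:3000)
  expect_identical(mash_distance(a, disjoint), 1)
  expect_identical(ani_estimate(1), 0)
  # j = 0.5: bottom-1000 of the union is 1..1000, 500 shared
  half <- mk(c(1:500, 1501:2000))
  expect_equal(sketch_jaccard(a, half), 0.5)
  expect_equal(mash_distance(a, half), -log(2 * 0.5 / 1.5) / 16,
               tolerance = 1e-12)
  expect_equal(mash_distance(a, half), 0.02534157, tolerance = 1e-7)
  b <- mk(1:1000, k = 21L)
  expect_error(mash_distance(a, b), "different")
})

test_that("prefilter honours the ANI floor and distance cap", {
  mk <- function(h) structure(list(hashes = as.numeric(h), k = 16L,
                                   s = 1000L, seed = 1L),
                              class = "minhash_sketch")
  q <- mk(1:1000)
  # j = 21/1000 -> d = 0.1994 (ANI 80.06, kept); j = 20/1000 -> d = 0.2024
  # (ANI 79.76, dropped); identical -> kept; disjoint -> dropped
  refs <- list(keep = mk(c(1:21, 2000:2978)),
               drop = mk(c(1:20, 2000:2979)),
               self = mk(1:1000),
               far = mk(5001:6000))
  got <- prefilter_references(q, refs, minhash_params(k = 16, s = 1000))
  expect_setequal(got, c("keep", "self"))
  expect_identical(prefilter_references(q, list(far = refs$far),
                                        minhash_params(k = 16, s = 1000)),
                   character(0))
})

test_that("taxonomic context widens until 100 additional genomes", {
  mk_meta <- function(spec) {
    # spec: named vector genus_size per (family, genus) path
    rows <- list()
    i <- 0
    for (nm in names(spec)) {
      parts <- strsplit(nm, "/")[[1]]  # phylum/class/order/family/genus
      for (j in seq_len(spec[[nm]])) {
        i <- i + 1
        rows[[i]] <- data.frame(
          accession = sprintf("R%04d", i),
          taxonomy = sprintf("d__B;p__%s;c__%s;o__%s;f__%s;g__%s;s__S%d",
                             parts[1], parts[2], parts[3], parts[4],
                             parts[5], i),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  tax <- function(g, f = "F1") sprintf("d__B;p__P;c__C;o__O;f__%s;g__%s", f, g)

  # genus with 150 representatives: exactly the genus set
  meta <- mk_meta(c("P/C/O/F1/G1" = 150, "P/C/O/F1/G2" = 30))
  got <- taxonomic_context(tax("G1"), meta)
  expect_identical(sort(got), sort(meta$accession[1:150]))

  # genus 10, family adds 120 (>= 100 additional): genus-union-family = 130
  meta <- mk_meta(c("P/C/O/F1/G1" = 10, "P/C/O/F1/G2" = 120,
                    "P/C/O/F2/G3" = 40))
  got <- taxonomic_context(tax("G1"), meta)
  expect_identical(length(got), 130L)

  # genus 60, family adds only 70: must keep widening to order
  meta <- mk_meta(c("P/C/O/F1/G1" = 60, "P/C/O/F1/G2" = 70,
                    "P/C/O/F2/G3" = 80))
  got <- taxonomic_context(tax("G1"), meta)
  expect_identical(length(got), 210L)

  # whole phylum smaller than the threshold: exhaustion returns all of it
  meta <- mk_meta(c("P/C/O/F1/G1" = 25, "P/C/O/F2/G2" = 15))
  expect_identical(length(taxonomic_context(tax("G1"), meta)), 40L)

  # genus absent: warning, context built from family upwards
  meta <- mk_meta(c("P/C/O/F1/G2" = 50, "P/C/O/F2/G3" = 60))
  expect_warning(got <- taxonomic_context(tax("G9"), meta), "absent")
  expect_identical(length(got), 110L)
  expect_error(taxonomic_context("d__B;p__P", meta), "genus")
})

test_that("fragment ANI recovers identity, mutation load and chimeric AF", {
  withr::local_seed(23)
  ref <- rand_dna(30000)
  f <- fragment_ani(ref, ref)
  expect_identical(f$ani, 100)
  expect_identical(f$af, 1)

  # configured mutation rates recovered over 10 seeds
  for (rate in c(0.05)) {
    anis <- vapply(1:10, function(s) {
      withr::with_seed(s, fragment_ani(mutate_dna(ref, rate), ref)$ani)
    }, numeric(1))
    expect_true(all(abs(anis - 100 * (1 - rate)) < 1))
    expect_lt(abs(mean(anis) - 100 * (1 - rate)), 0.3)
  }

  # half reference, half unrelated sequence: AF ~ 0.5 by construction
  q <- paste0(substr(ref, 1, 15000), rand_dna(15000))
  f <- fragment_ani(q, ref)
  expect_equal(f$af, 0.5, tolerance = 0.11)
  expect_gt(f$ani, 99)

  expect_error(fragment_ani(rand_dna(100), ref), "shorter")
  expect_error(fragment_ani(ref, rand_dna(100)), "shorter")

  # prebuilt index gives identical results
  idx <- anchor_index(ref)
  expect_identical(fragment_ani(q, ref), fragment_ani(q, ref_index = idx))
  expect_error(fragment_ani(q, ref_index = anchor_index(ref, 13L)),
               "k_anchor")
})

test_that("bidirectional best is symmetric and applies the tie-breaks", {
  withr::local_seed(24)
  a <- rand_dna(24000)
  b <- mutate_dna(a, 0.03)
  refs <- Biostrings::DNAStringSet(c(A = a, B = b))
  r_ab <- bidirectional_best(a, refs["B"], expected_rep = "B")
  r_ba <- bidirectional_best(b, refs["A"], expected_rep = "A")
  expect_equal(r_ab$ani, r_ba$ani, tolerance = 1e-9)   # max-rule symmetry
  expect_equal(r_ab$af, r_ba$af, tolerance = 1e-9)

  # self-exclusion: next best returned
  r <- bidirectional_best(a, refs, expected_rep = "A", self_exclude = "A")
  expect_identical(r$best_ref, "B")

  # AF tie-break: exact copy beats a truncated copy at equal ANI
  refs2 <- Biostrings::DNAStringSet(
    c(full = a, partial = paste0(substr(a, 1, 12000), rand_dna(12000))))
  r <- bidirectional_best(a, refs2, expected_rep = "full")
  expect_identical(r$best_ref, "full")
  expect_identical(r$category, "same_species")

  # accession tie-break on identical candidates
  refs3 <- Biostrings::DNAStringSet(c(B = a, A = a))
  r <- bidirectional_best(a, refs3, expected_rep = "Z")
  expect_identical(r$best_ref, "A")
  expect_identical(r$category, "changed_species")

  # no candidates at all
  r <- bidirectional_best(a, refs[0], expected_rep = "A")
  expect_identical(r$category, "new_species")
  expect_true(is.na(r$best_ref))
})

test_that("categorize implements the three-way decision", {
  crit <- species_criteria()
  expect_identical(categorize(96, 0.6, "R1", "R1", crit), "same_species")
  expect_identical(categorize(96, 0.6, "R2", "R1", crit), "changed_species")
  expect_identical(categorize(94, 0.9, "R1", "R1", crit), "new_species")
  expect_identical(categorize(99, 0.4, "R1", "R1", crit), "new_species")
  expect_identical(categorize(95, 0.5, "R1", "R1", crit), "same_species")
  expect_identical(categorize(NA, NA, NA_character_, "R1", crit),
                   "new_species")
})
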