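# Shared fixture builders and independent brute-force oracles. Oracles are
# deliberately naive (enumeration / exhaustive sets / pairwise comparators)
# and never call the code paths they check.

# -- gene assignment tables --------------------------------------------------

# build an assignment data.frame from compact per-gene specs:
#   mk_assign(c("c1" = "d__B;p__X", "c1" = "d__B;p__Y"))
# gene_index increments per contig in the order given.
mk_assign <- function(taxa_by_contig, accession = "G1", markers = NULL) {
  contigs <- names(taxa_by_contig)
  idx <- stats::ave(seq_along(contigs), contigs, FUN = seq_along) - 1L
  n <- length(contigs)
  data.frame(accession = accession,
             gene_id = sprintf("%s_g%02d", contigs, idx),
             contig_id = contigs,
             gene_index = idx,
             hit_taxonomy = unname(taxa_by_contig),
             is_marker = if (is.null(markers)) rep(FALSE, n) else markers,
             stringsAsFactors = FALSE)
}

lineage7 <- function(p = "X", c = "C", o = "O", f = "F", g = "G", s = "S") {
  sprintf("d__B;p__%s;c__%s;o__%s;f__%s;g__%s;s__%s", p, c, o, f, g, s)
}

# -- random sequences --------------------------------------------------------

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

mutate_dna <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  nm <- rbinom(1L, length(v), rate)
  if (nm > 0) {
    pos <- sample.int(length(v), nm)
    shift <- sample.int(3L, nm, replace = TRUE)
    v[pos] <- c("A", "C", "G", "T")[((match(v[pos], c("A", "C", "G", "T")) - 1L
                                      + shift) %% 4L) + 1L]
  }
  paste(v, collapse = "")
}

# -- oracles -----------------------------------------------------------------

# exhaustive canonical k-mer set of a sequence (string operations only)
oracle_kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  rc <- vapply(kmers, function(x)
    paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = ""),
    character(1), USE.NAMES = FALSE)
  unique(pmin(kmers, rc))
}

oracle_jaccard <- function(a, b, k) {
  A <- oracle_kmer_set(a, k); B <- oracle_kmer_set(b, k)
  length(intersect(A, B)) / length(union(A, B))
}

# selection sort of contig score rows by the documented contamination key;
# independent of rank_contigs' order() call
oracle_sort_contigs <- function(df) {
  more_contaminated <- function(a, b) {
    if (a$divergence_depth != b$divergence_depth)
      return(a$divergence_depth < b$divergence_depth)
    if (a$congruent_fraction != b$congruent_fraction)
      return(a$congruent_fraction < b$congruent_fraction)
    la <- ifelse(is.na(a$length), 0L, a$length)
    lb <- ifelse(is.na(b$length), 0L, b$length)
    if (la != lb) return(la > lb)
    a$contig_id < b$contig_id
  }
  rows <- split(df, seq_len(nrow(df)))
  out <- character(0)
  while (length(rows)) {
    best <- 1L
    for (j in seq_along(rows))
      if (j != best && more_contaminated(rows[[j]], rows[[best]])) best <- j
    out <- c(out, rows[[best]]$contig_id)
    rows <- rows[-best]
  }
  out
}

# walk-based halving oracle: which whole contigs land in the contaminant
# half, and how many nt are pruned from the straddling contig
oracle_split_nt <- function(widths) {
  remove <- sum(widths) %/% 2L
  acc <- 0L; whole <- character(0); split_id <- NA_character_; split_nt <- 0L
  for (id in names(widths)) {
    if (acc + widths[[id]] <= remove) {
      whole <- c(whole, id); acc <- acc + widths[[id]]
    } else {
      if (remove - acc > 0) { split_id <- id; split_nt <- remove - acc }
      break
    }
  }
  list(whole = whole, split_id = split_id, split_nt = split_nt,
       removed = remove)
}

# -- synthetic batches (computed once, shared across acceptance tests) -------

e2e_cache <- new.env(parent = emptyenv())

e2e_batch <- function() {
  if (is.null(e2e_cache$main)) {
    # the stated world: 30 % contamination at the family rank, 5 % assignment
    # noise, 200 replicate chimeras, 10-seed random-removal baseline
    cfg <- sim_config(seed = 1L)
    e2e_cache$main <- run_pipeline(cfg, n_genomes = 200L, n_random = 10L)
  }
  e2e_cache$main
}

gross_batch <- function() {
  if (is.null(e2e_cache$gross)) {
    # grossly contaminated world: inter-phylum donor, contamination just
    # below the 50 % presumption ceiling (see methods vignette)
    cfg <- sim_config(seed = 2L, contamination_fraction = 0.45,
                      contamination_rank = "p")
    e2e_cache$gross <- run_pipeline(cfg, n_genomes = 50L,
                                    classify_contaminant = TRUE)
  }
  e2e_cache$gross
}
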