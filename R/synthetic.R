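# Synthetic world: a balanced rank-structured taxonomy, one representative
# genome per species (sequences diverging with taxonomic distance), chimeric
# query genomes with known injected contamination, and noisy per-gene
# assignments standing in for gene-calling + closest-reference-hit output.
# Everything is bit-reproducible under a fixed seed.

#' Simulation configuration
#'
#' Defaults describe the simulated world: a balanced taxonomy with fan-out 2
#' from phylum to species (64 species in one domain), 50 kb genomes in 10
#' contigs of at least 2 kb, one gene per kb, 30 % contamination injected at
#' the family rank, 5 % gene-assignment noise, 5 % sequence divergence per
#' rank step, 0.5 % mutation between a genome and its species
#' representative, and every 10th gene flagged as a marker.
#'
#' @param seed integer master seed
#' @param taxa_per_rank named fan-out per rank (`d`,`p`,`c`,`o`,`f`,`g`,`s`)
#' @param genome_len total genome length in nt
#' @param n_contigs number of contigs per genome
#' @param genes_per_kb gene density (genes per 1000 nt)
#' @param contamination_fraction target contaminant fraction of total nt,
#'   in [0, 0.5] (contamination is presumed to be at most half a genome)
#' @param contamination_rank rank at which host and donor lineages diverge
#' @param assignment_error probability a gene's hit lineage is perturbed
#' @param divergence_per_rank substitution rate added per rank step
#' @param mutation_rate substitution rate between a genome's contigs and its
#'   source representative
#' @param min_contig_len minimum contig length in nt
#' @param marker_every every n-th gene is flagged as a marker
#' @param indel_rate per-site indel rate applied with the substitutions
#'   (off by default; the sequence model is i.i.d. substitutions)
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       taxa_per_rank = c(d = 1L, p = 2L, c = 2L, o = 2L,
                                         f = 2L, g = 2L, s = 2L),
                       genome_len = 50000L,
                       n_contigs = 10L,
                       genes_per_kb = 1,
                       contamination_fraction = 0.3,
                       contamination_rank = "f",
                       assignment_error = 0.05,
                       divergence_per_rank = 0.05,
                       mutation_rate = 0.005,
                       min_contig_len = 2000L,
                       marker_every = 10L,
                       indel_rate = 0) {
  stopifnot(contamination_fraction >= 0, contamination_fraction <= 0.5,
            contamination_rank %in% RANK_CODES,
            assignment_error >= 0, assignment_error < 1,
            n_contigs >= 1L, genome_len >= n_contigs * min_contig_len,
            all(RANK_CODES %in% names(taxa_per_rank)))
  structure(list(seed = as.integer(seed),
                 taxa_per_rank = taxa_per_rank[RANK_CODES],
                 genome_len = as.integer(genome_len),
                 n_contigs = as.integer(n_contigs),
                 genes_per_kb = genes_per_kb,
                 contamination_fraction = contamination_fraction,
                 contamination_rank = contamination_rank,
                 assignment_error = assignment_error,
                 divergence_per_rank = divergence_per_rank,
                 mutation_rate = mutation_rate,
                 min_contig_len = as.integer(min_contig_len),
                 marker_every = as.integer(marker_every),
                 indel_rate = indel_rate),
            class = "sim_config")
}

DNA_BASES <- c("A", "C", "G", "T")

random_seq_vec <- function(len) sample(DNA_BASES, len, replace = TRUE)

# i.i.d. substitutions (always to a different base) plus optional single-base
# indels; operates on character vectors of bases.
mutate_seq_vec <- function(v, sub_rate, indel_rate = 0) {
  n <- length(v)
  nmut <- rbinom(1L, n, sub_rate)
  if (nmut > 0L) {
    pos <- sample.int(n, nmut)
    shift <- sample.int(3L, nmut, replace = TRUE)
    cur <- match(v[pos], DNA_BASES)
    v[pos] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  if (indel_rate > 0) {
    nind <- rbinom(1L, n, indel_rate)
    if (nind > 0L) {
      pos <- sort(sample.int(length(v), nind))
      del <- runif(nind) < 0.5
      keep <- setdiff(seq_along(v), pos[del])
      v <- v[keep]
      ins_at <- pos[!del]
      if (length(ins_at)) {
        out <- vector("list", 2L * length(ins_at) + 1L)
        prev <- 1L
        pieces <- character(0)
        for (k in seq_along(ins_at)) {
          pieces <- c(pieces, v[prev:min(ins_at[k], length(v))],
                      sample(DNA_BASES, 1L))
          prev <- min(ins_at[k], length(v)) + 1L
        }
        if (prev <= length(v)) pieces <- c(pieces, v[prev:length(v)])
        v <- pieces
      }
    }
  }
  v
}

#' Generate a balanced synthetic taxonomy
#'
#' A complete tree over the configured per-rank fan-outs; each species gets
#' a deterministic path-encoded name at every rank and one representative
#' accession. The table is identical for identical configurations.
#'
#' @param config a [sim_config()]
#' @return data.frame with `accession`, `taxonomy`, and one column per rank
#'   code holding the taxon name at that rank
#' @export
generate_taxonomy <- function(config = sim_config()) {
  fan <- config$taxa_per_rank
  paths <- do.call(expand.grid,
                   c(rev(lapply(fan, seq_len)), KEEP.OUT.ATTRS = FALSE))
  paths <- paths[, rev(seq_len(ncol(paths))), drop = FALSE]  # d first
  names(paths) <- RANK_CODES
  paths <- paths[do.call(order, paths), , drop = FALSE]
  name_at <- function(j) {
    key <- apply(paths[, seq_len(j), drop = FALSE], 1L, paste, collapse = "")
    paste0(toupper(RANK_CODES[j]), key)
  }
  nm <- do.call(cbind, lapply(seq_along(RANK_CODES), name_at))
  colnames(nm) <- RANK_CODES
  tax <- apply(nm, 1L, function(r)
    paste0(RANK_CODES, "__", r, collapse = ";"))
  out <- data.frame(accession = sprintf("REP%04d", seq_len(nrow(paths))),
                    taxonomy = tax, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(nm, stringsAsFactors = FALSE))
}

#' Generate representative genomes for a synthetic taxonomy
#'
#' One independent random root sequence per phylum; every descendant node
#' derives from its parent by i.i.d. substitutions at `divergence_per_rank`,
#' so expected sequence identity decreases monotonically with taxonomic
#' distance. Each species' leaf sequence is its representative genome.
#'
#' @param taxonomy table from [generate_taxonomy()]
#' @param config a [sim_config()]
#' @return a `ref_db` list: `seqs` ([Biostrings::DNAStringSet] named by
#'   accession), `metadata` (accession + taxonomy), `config`
#' @export
generate_reference_db <- function(taxonomy, config = sim_config()) {
  seqs <- withr::with_seed(config$seed, {
    node_seq <- new.env(parent = emptyenv())
    key_through <- function(j) apply(taxonomy[, RANK_CODES[seq_len(j)],
                                              drop = FALSE],
                                     1L, paste, collapse = ";")
    # roots at phylum (domains carry no sequence of their own)
    pk <- key_through(2L)
    for (k in unique(pk))
      assign(k, random_seq_vec(config$genome_len), envir = node_seq)
    for (j in 3L:7L) {
      kk <- key_through(j); pk <- key_through(j - 1L)
      for (i in which(!duplicated(kk))) {
        parent <- get(pk[i], envir = node_seq)
        assign(kk[i],
               mutate_seq_vec(parent, config$divergence_per_rank,
                              config$indel_rate),
               envir = node_seq)
      }
    }
    sk <- key_through(7L)
    vapply(sk, function(k) paste(get(k, envir = node_seq), collapse = ""),
           character(1))
  })
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- taxonomy$accession
  structure(list(seqs = set,
                 metadata = taxonomy[, c("accession", "taxonomy")],
                 config = config),
            class = "ref_db")
}

# species rows of `taxonomy` lying under a donor taxon that shares the host
# lineage above `rank` but differs at `rank`
donor_candidates <- function(taxonomy, host_row, rank) {
  j <- rank_index0(rank) + 1L
  same_above <- rep(TRUE, nrow(taxonomy))
  if (j > 1L)
    for (jj in seq_len(j - 1L))
      same_above <- same_above &
        taxonomy[[RANK_CODES[jj]]] == host_row[[RANK_CODES[jj]]]
  which(same_above & taxonomy[[RANK_CODES[j]]] != host_row[[RANK_CODES[j]]])
}

#' Build a chimeric query genome with known contamination
#'
#' Contigs are carved from the host species representative (with light
#' mutation at `mutation_rate`); a randomly chosen subset of contigs is
#' instead carved from a donor representative whose lineage diverges from
#' the host's at `contamination_rank`. The contaminant contig set is drawn
#' by a greedy random fill towards the target contaminant nt with a final
#' best-fit top-up, so the realised fraction stays within one contig length
#' of `contamination_fraction` (and close to it in practice).
#'
#' @param ref_db from [generate_reference_db()]
#' @param taxonomy from [generate_taxonomy()]
#' @param host_accession species representative to use as host (default:
#'   seeded random choice)
#' @param config a [sim_config()]
#' @param seed per-genome seed (default `config$seed`)
#' @param accession accession given to the generated genome
#' @return list with `seqs` (contigs), `truth` (host/donor lineages,
#'   contaminant contig ids, `true_css_rank` = the injected rank), and
#'   `accession`
#' @export
make_chimera <- function(ref_db, taxonomy, host_accession = NULL,
                         config = sim_config(), seed = config$seed,
                         accession = "CHIM0001") {
  withr::with_seed(as.integer(seed), {
    if (is.null(host_accession))
      host_accession <- sample(taxonomy$accession, 1L)
    hrow <- taxonomy[taxonomy$accession == host_accession, , drop = FALSE]
    if (nrow(hrow) != 1L) stop("unknown host accession: ", host_accession)
    f <- config$contamination_fraction
    donor_acc <- NA_character_
    if (f > 0) {
      cand <- donor_candidates(taxonomy, hrow, config$contamination_rank)
      if (length(cand) == 0L)
        stop("taxonomy has no sibling taxon at rank ",
             config$contamination_rank)
      donor_acc <- taxonomy$accession[sample(rep(cand, 2L), 1L)[1L]]
    }
    # contig lengths: min length plus a gamma-weighted share of the rest
    # (shape 4 keeps lengths variable without letting one contig approach
    # half the genome, which would push the realised contamination to the
    # 50 % boundary where the majority-vote consensus is undefined)
    n <- config$n_contigs
    w <- stats::rgamma(n, shape = 4)
    extra <- config$genome_len - n * config$min_contig_len
    lens <- config$min_contig_len + floor(extra * w / sum(w))
    short <- config$genome_len - sum(lens)
    if (short > 0L) {
      add <- sample.int(n, short, replace = TRUE)
      lens <- lens + tabulate(add, nbins = n)
    }
    # contaminant contigs: greedy random fill below the nt target, then one
    # best-fit top-up; keeps the realised fraction close to the target so a
    # sub-half target cannot drift to the 50 % boundary where the
    # majority-vote consensus is undefined
    contam <- logical(n)
    if (f > 0) {
      target <- round(f * config$genome_len)
      perm <- sample.int(n)
      tot <- 0L
      for (i in perm) {
        if (tot + lens[i] <= target) { contam[i] <- TRUE; tot <- tot + lens[i] }
      }
      rem <- which(!contam)
      if (length(rem) && tot < target) {
        err <- abs(tot + lens[rem] - target)
        if (min(err) < target - tot) contam[rem[which.min(err)]] <- TRUE
      }
      if (!any(contam)) contam[perm[1L]] <- TRUE  # degenerate tiny targets
    }
    host_seq <- strsplit(as.character(ref_db$seqs[[host_accession]]), "")[[1]]
    donor_seq <- if (!is.na(donor_acc))
      strsplit(as.character(ref_db$seqs[[donor_acc]]), "")[[1]]
    cursor_h <- 0L; cursor_d <- 0L
    contigs <- character(n)
    for (i in seq_len(n)) {
      if (contam[i]) {
        src <- donor_seq; at <- cursor_d; cursor_d <- cursor_d + lens[i]
      } else {
        src <- host_seq; at <- cursor_h; cursor_h <- cursor_h + lens[i]
      }
      piece <- src[((at + seq_len(lens[i]) - 1L) %% length(src)) + 1L]
      contigs[i] <- paste(mutate_seq_vec(piece, config$mutation_rate,
                                         config$indel_rate),
                          collapse = "")
    }
    seqs <- Biostrings::DNAStringSet(contigs)
    names(seqs) <- sprintf("ctg%02d", seq_len(n))
    truth <- list(host_accession = host_accession,
                  donor_accession = donor_acc,
                  host_taxon = hrow$taxonomy,
                  donor_taxon = if (!is.na(donor_acc))
                    taxonomy$taxonomy[taxonomy$accession == donor_acc]
                  else NA_character_,
                  contaminant_contigs = names(seqs)[contam],
                  true_css_rank = if (f > 0) config$contamination_rank
                  else NA_character_)
    list(seqs = seqs, truth = truth, accession = accession)
  }, .rng_kind = "Mersenne-Twister")
}

# replace a lineage with a uniformly chosen species under a uniformly chosen
# sibling taxon at a uniformly chosen rank (phylum..species)
perturb_lineage <- function(species_row, taxonomy) {
  ranks <- c("p", "c", "o", "f", "g", "s")
  avail <- ranks[vapply(ranks, function(r)
    length(donor_candidates(taxonomy, species_row, r)) > 0L, logical(1))]
  if (length(avail) == 0L) return(species_row$taxonomy)
  r <- sample(rep(avail, 2L), 1L)[1L]
  cand <- donor_candidates(taxonomy, species_row, r)
  taxonomy$taxonomy[sample(rep(cand, 2L), 1L)[1L]]
}

#' Emulate per-gene taxonomic assignments for a synthetic genome
#'
#' Genes are placed every `1000 / genes_per_kb` nt along each contig. Each
#' gene's hit lineage is its contig's true source lineage (host or donor
#' species), independently replaced, with probability `assignment_error`, by
#' the lineage of a random species under a random sibling taxon at a random
#' rank. Every `marker_every`-th gene (genome-wide) is flagged as a marker.
#' The genome summary's CSS rank is the [clade_separation_proxy()] arg-max.
#'
#' @param chimera output of [make_chimera()]
#' @param taxonomy from [generate_taxonomy()]
#' @param config a [sim_config()]
#' @param seed per-genome seed
#' @return list with `assignments` (gene table) and `summary` (one-row
#'   genome summary data.frame)
#' @export
emulate_gene_assignments <- function(chimera, taxonomy,
                                     config = sim_config(),
                                     seed = config$seed) {
  step <- as.integer(round(1000 / config$genes_per_kb))
  truth <- chimera$truth
  host_row <- taxonomy[taxonomy$accession == truth$host_accession, ,
                       drop = FALSE]
  donor_row <- if (!is.na(truth$donor_accession))
    taxonomy[taxonomy$accession == truth$donor_accession, , drop = FALSE]
  df <- withr::with_seed(as.integer(seed), {
    rows <- list()
    gene_counter <- 0L
    for (cid in names(chimera$seqs)) {
      len <- Biostrings::width(chimera$seqs[cid])
      ng <- len %/% step
      if (ng == 0L) next
      is_donor <- cid %in% truth$contaminant_contigs
      src_row <- if (is_donor) donor_row else host_row
      lineages <- rep(src_row$taxonomy, ng)
      err <- runif(ng) < config$assignment_error
      for (k in which(err)) lineages[k] <- perturb_lineage(src_row, taxonomy)
      idx <- seq_len(ng) - 1L
      gidx <- gene_counter + seq_len(ng)
      rows[[cid]] <- data.frame(
        accession = chimera$accession,
        gene_id = sprintf("%s_g%03d", cid, idx),
        contig_id = cid,
        gene_index = idx,
        hit_taxonomy = lineages,
        is_marker = (gidx %% config$marker_every) == 0L,
        stringsAsFactors = FALSE)
      gene_counter <- gene_counter + ng
    }
    do.call(rbind, rows)
  }, .rng_kind = "Mersenne-Twister")
  rownames(df) <- NULL
  css <- clade_separation_proxy(df)$css_rank
  summary <- data.frame(accession = chimera$accession, css_rank = css,
                        is_failed = TRUE, genome_type = "MAG",
                        stringsAsFactors = FALSE)
  list(assignments = df, summary = summary)
}
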