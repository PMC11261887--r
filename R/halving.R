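# Splitting a genome into clean and contaminant halves. Contigs must already
# be ordered most-to-least contaminated (see rank_contigs); the contaminant
# half accumulates whole contigs from the front of that order and at most one
# contig is divided, pruned from its more contaminated end.

#' Orient a contig from most to least contaminated
#'
#' Counts incongruent genes (relative to the truncated genome consensus) in
#' the leading and trailing halves of the contig's gene list; the end with
#' more incongruent genes is the contaminated ("leading") end. The middle
#' gene of an odd-length list belongs to neither half. Ties, and contigs
#' without genes, keep the original orientation (5' leading).
#'
#' @param genes the contig's gene assignments, any order (sorted internally)
#' @param genome_tax genome consensus taxonomy truncated at the CSS rank
#' @param css_rank rank code of maximal clade separation
#' @return `"5p"` or `"3p"`: which end of the original sequence is most
#'   contaminated
#' @export
orient_contig <- function(genes, genome_tax, css_rank) {
  n <- NROW(genes)
  if (n == 0L) return("5p")
  genes <- genes[order(genes$gene_index), , drop = FALSE]
  cong <- lineage_congruent(tax_matrix(genes$hit_taxonomy), genome_tax, css_rank)
  h <- n %/% 2L
  if (h == 0L) return("5p")
  lead <- sum(!cong[seq_len(h)])
  trail <- sum(!cong[seq.int(n - h + 1L, n)])
  if (trail > lead) "3p" else "5p"
}

new_halving_result <- function(clean, contaminant, split_contig_id, mode,
                               seed = NULL, extra = list()) {
  structure(c(list(clean = clean, contaminant = contaminant,
                   split_contig_id = split_contig_id, mode = mode,
                   seed = seed), extra),
            class = "halving_result")
}

#' @export
print.halving_result <- function(x, ...) {
  cat("Genome halving (mode: ", x$mode, ")\n", sep = "")
  if (inherits(x$clean, "DNAStringSet"))
    cat("  clean: ", length(x$clean), " contig(s), ",
        sum(Biostrings::width(x$clean)), " nt\n",
        "  contaminant: ", length(x$contaminant), " contig(s), ",
        sum(Biostrings::width(x$contaminant)), " nt\n", sep = "")
  if (!is.null(x$kept_markers))
    cat("  markers kept/removed: ", length(x$kept_markers), "/",
        length(x$removed_markers), "\n", sep = "")
  if (!is.na(x$split_contig_id))
    cat("  split contig:", x$split_contig_id, "\n")
  invisible(x)
}

#' Split a genome in half by nucleotides
#'
#' Removes `floor(total_nt / 2)` nucleotides into the contaminant half,
#' taking whole contigs from the most contaminated end of the supplied
#' order. If the boundary falls inside a contig, that single contig is
#' oriented with [orient_contig()] and its most contaminated end is pruned
#' to the required length; the clean half keeps the complementary fragment
#' (and the extra base when the total is odd).
#'
#' @param seqs [Biostrings::DNAStringSet] of contigs, ordered most to least
#'   contaminated
#' @param assignments gene assignment table of this genome (used only to
#'   orient a split contig); may be `NULL` to force 5' pruning
#' @param genome_tax truncated genome consensus taxonomy (with `assignments`)
#' @param css_rank CSS rank code (with `assignments`)
#' @return a `halving_result` with `clean` and `contaminant` DNAStringSets;
#'   a divided contig keeps its id in both halves and is named in
#'   `split_contig_id`
#' @export
split_by_nucleotides <- function(seqs, assignments = NULL, genome_tax = NULL,
                                 css_rank = NULL) {
  if (length(seqs) == 0L) stop("empty genome")
  w <- Biostrings::width(seqs)
  remove_nt <- sum(w) %/% 2L
  cum <- 0L
  contam_idx <- integer(0)
  split_id <- NA_character_
  clean <- character(0); contam <- character(0)
  for (i in seq_along(seqs)) {
    if (cum + w[i] <= remove_nt && length(contam_idx) + 0L == i - 1L) {
      contam_idx <- c(contam_idx, i)
      cum <- cum + w[i]
    } else break
  }
  need <- remove_nt - cum
  rest <- setdiff(seq_along(seqs), contam_idx)
  contam <- as.character(seqs[contam_idx])
  clean_ids <- names(seqs)[rest]
  clean <- as.character(seqs[rest])
  contam_ids <- names(seqs)[contam_idx]
  if (need > 0L) {
    i <- rest[1L]
    split_id <- names(seqs)[i]
    end <- "5p"
    if (!is.null(assignments)) {
      genes <- assignments[assignments$contig_id == split_id, , drop = FALSE]
      end <- orient_contig(genes, genome_tax, css_rank)
    }
    s <- as.character(seqs[[i]])
    len <- nchar(s)
    if (end == "5p") {
      frag_bad <- substr(s, 1L, need)
      frag_clean <- substr(s, need + 1L, len)
    } else {
      frag_bad <- substr(s, len - need + 1L, len)
      frag_clean <- substr(s, 1L, len - need)
    }
    contam <- c(contam, frag_bad)
    contam_ids <- c(contam_ids, split_id)
    clean[1L] <- frag_clean
    extra <- list(split_end = end, split_offset = need)
  } else {
    extra <- list()
  }
  clean_set <- Biostrings::DNAStringSet(clean); names(clean_set) <- clean_ids
  contam_set <- Biostrings::DNAStringSet(contam); names(contam_set) <- contam_ids
  new_halving_result(clean_set, contam_set, split_id, "nucleotide",
                     extra = extra)
}

#' Split a genome in half by marker genes
#'
#' Removes `floor(total_markers / 2)` marker genes, walking contigs from the
#' most contaminated end of the order; within a contig the markers are
#' consumed from its contaminated end (per [orient_contig()]) towards the
#' clean end.
#'
#' @param seqs contigs ordered most to least contaminated
#' @param assignments gene assignment table with `is_marker` flags
#' @param genome_tax truncated genome consensus taxonomy
#' @param css_rank CSS rank code
#' @return a `halving_result`; `removed_markers` / `kept_markers` hold gene
#'   ids, `clean` / `contaminant` the contigs wholly on each side, and
#'   `split_contig_id` the contig (if any) with markers on both sides
#' @export
split_by_markers <- function(seqs, assignments, genome_tax, css_rank) {
  if (length(seqs) == 0L) stop("empty genome")
  markers <- assignments[assignments$is_marker, , drop = FALSE]
  if (NROW(markers) == 0L) stop("genome has no marker genes")
  remove_n <- NROW(markers) %/% 2L
  removed <- character(0)
  split_id <- NA_character_
  contam_contigs <- character(0)
  taken <- 0L
  for (cid in names(seqs)) {
    mc <- markers[markers$contig_id == cid, , drop = FALSE]
    genes <- assignments[assignments$contig_id == cid, , drop = FALSE]
    end <- orient_contig(genes, genome_tax, css_rank)
    mc <- mc[order(mc$gene_index, decreasing = (end == "3p")), , drop = FALSE]
    if (taken + NROW(mc) <= remove_n) {
      removed <- c(removed, mc$gene_id)
      taken <- taken + NROW(mc)
      contam_contigs <- c(contam_contigs, cid)
      if (taken == remove_n) break
    } else {
      k <- remove_n - taken
      if (k > 0L) {
        removed <- c(removed, mc$gene_id[seq_len(k)])
        split_id <- cid
      }
      break
    }
  }
  kept <- setdiff(markers$gene_id, removed)
  clean_contigs <- setdiff(names(seqs), c(contam_contigs, split_id))
  new_halving_result(seqs[clean_contigs], seqs[contam_contigs], split_id,
                     "marker",
                     extra = list(removed_markers = removed,
                                  kept_markers = kept))
}

#' Random-order halving baseline
#'
#' Draws a uniform random permutation of the contigs from a seeded
#' Mersenne-Twister generator, then applies the nucleotide split on that
#' order (no contamination-based orientation: a divided contig is pruned
#' from its leading end). Reproducible for a fixed seed, which is recorded
#' in the result.
#'
#' @param seqs contigs in any order
#' @param seed integer seed
#' @return a `halving_result` with `mode = "random"` and `seed` set
#' @export
random_half <- function(seqs, seed) {
  if (length(seqs) == 0L) stop("empty genome")
  perm <- withr::with_seed(as.integer(seed),
                           sample.int(length(seqs)),
                           .rng_kind = "Mersenne-Twister")
  res <- split_by_nucleotides(seqs[perm])
  res$mode <- "random"
  res$seed <- as.integer(seed)
  res
}
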