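# Per-contig contamination scoring. A genome consensus taxonomy is the modal
# taxon at each rank over all gene-level hits; each contig gets a majority-vote
# taxonomy (tied ranks dropped), both are truncated at the rank of maximal
# clade separation (CSS rank), and contigs are ordered from most to least
# contaminated by (divergence depth ascending, congruent gene fraction
# ascending, longer contig first, contig id).

#' Genome consensus taxonomy from gene-level assignments
#'
#' At each rank independently, the most commonly inferred taxon name across
#' all genes of the genome (not the modal whole lineage). Ranks carried by
#' some gene but never named stay unnamed; a count tie is broken
#' lexicographically for determinism.
#'
#' @param assignments data.frame of one genome's gene assignments
#'   (see [read_gene_assignments()])
#' @return named character vector (parsed taxonomy)
#' @export
genome_consensus_taxonomy <- function(assignments) {
  if (NROW(assignments) == 0L) stop("no gene assignments supplied")
  M <- tax_matrix(assignments$hit_taxonomy)
  modal_per_rank(M, drop_ties = FALSE)
}

#' Majority-vote taxonomy of one contig
#'
#' Modal taxon name at each rank over the contig's genes; any rank whose top
#' count is shared by two or more names is dropped from the result entirely
#' (the tied rank is not considered downstream).
#'
#' @param genes data.frame of the contig's gene assignments
#' @return named character vector (parsed taxonomy, possibly with gaps)
#' @export
contig_taxonomy <- function(genes) {
  if (NROW(genes) == 0L) stop("no genes supplied for contig")
  M <- tax_matrix(genes$hit_taxonomy)
  modal_per_rank(M, drop_ties = TRUE)
}

modal_per_rank <- function(M, drop_ties) {
  out <- character(0)
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    carried <- !is.na(v)
    if (!any(carried)) next
    named <- v[carried & nzchar(v)]
    if (length(named) == 0L) {
      val <- ""
    } else {
      tab <- table(named)
      winners <- sort(names(tab)[tab == max(tab)])
      if (drop_ties && length(winners) > 1L) next
      val <- winners[1L]
    }
    out[RANK_CODES[j]] <- val
  }
  out
}

#' Truncate a taxonomy at the genome's CSS rank
#'
#' Alias of [truncate_taxonomy()] named for its role in the scoring path.
#' @inheritParams truncate_taxonomy
#' @export
truncate_to_css_rank <- function(tax, css_rank) truncate_taxonomy(tax, css_rank)

#' Score one contig against the genome consensus
#'
#' `divergence_depth` is the 0-based index (domain = 0) of the first rank,
#' scanning domain to the CSS rank, at which the contig taxonomy disagrees
#' with the genome taxonomy; ranks dropped by ties or unnamed on either side
#' are skipped. A fully congruent contig gets `css_rank_index + 1`.
#' `congruent_fraction` is the proportion of the contig's genes whose hit
#' lineage matches the truncated genome taxonomy at every named rank through
#' the CSS rank. Smaller values of either mean more contaminated.
#'
#' @param contig_tax contig taxonomy, truncated at the CSS rank
#' @param genome_tax genome consensus taxonomy, truncated at the CSS rank
#' @param genes the contig's gene assignments (may have zero rows)
#' @param css_rank rank code of maximal clade separation
#' @return list with `divergence_depth`, `congruent_fraction`, `n_genes`
#' @export
score_contig <- function(contig_tax, genome_tax, genes, css_rank) {
  css1 <- rank_index0(css_rank) + 1L
  depth <- css1
  for (j in seq_len(css1)) {
    a <- unname(contig_tax[RANK_CODES[j]])
    b <- unname(genome_tax[RANK_CODES[j]])
    if (is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) next
    if (a != b) { depth <- j - 1L; break }
  }
  n <- NROW(genes)
  frac <- if (n == 0L) 1.0 else {
    M <- tax_matrix(genes$hit_taxonomy)
    mean(lineage_congruent(M, genome_tax, css_rank))
  }
  list(divergence_depth = depth, congruent_fraction = frac, n_genes = n)
}

#' Order a genome's contigs from most to least contaminated
#'
#' Applies the full scoring path (consensus, per-contig majority vote with
#' tie dropping, CSS-rank truncation, scoring) and sorts by the deterministic
#' key (divergence depth asc, congruent fraction asc, contig length desc,
#' contig id asc). Contigs without genes are treated as least contaminated
#' (depth `css_rank_index + 1`, fraction 1).
#'
#' @param assignments one genome's gene assignment table
#' @param css_rank rank code of maximal clade separation for this genome
#' @param contig_lengths optional named integer vector of contig lengths;
#'   contigs present here but absent from `assignments` are scored gene-less
#' @return data.frame of per-contig scores, most contaminated first, with a
#'   `rank` column giving the order position (1 = most contaminated)
#' @export
rank_contigs <- function(assignments, css_rank, contig_lengths = NULL) {
  cons <- truncate_taxonomy(genome_consensus_taxonomy(assignments), css_rank)
  ids <- unique(c(assignments$contig_id, names(contig_lengths)))
  rows <- lapply(ids, function(cid) {
    genes <- assignments[assignments$contig_id == cid, , drop = FALSE]
    genes <- genes[order(genes$gene_index), , drop = FALSE]
    ctax <- if (NROW(genes)) truncate_taxonomy(contig_taxonomy(genes), css_rank)
            else character(0)
    sc <- score_contig(ctax, cons, genes, css_rank)
    data.frame(contig_id = cid,
               divergence_depth = sc$divergence_depth,
               congruent_fraction = sc$congruent_fraction,
               n_genes = sc$n_genes,
               length = if (!is.null(contig_lengths) && cid %in% names(contig_lengths))
                          as.integer(contig_lengths[[cid]]) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  len_key <- ifelse(is.na(df$length), 0L, df$length)
  df <- df[order(df$divergence_depth, df$congruent_fraction, -len_key,
                 df$contig_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Simplified clade-separation proxy (synthetic mode only)
#'
#' For each rank r, `score(r) = 1 - fraction of genes congruent with the
#' genome consensus through rank r`; returns the per-rank table and the
#' arg-max rank, with the shallowest rank winning ties. A stand-in for the
#' entropy-based clade separation score of contamination detectors, used only
#' to give synthetic genomes a CSS rank.
#'
#' @param assignments one genome's gene assignment table
#' @return list with `table` (data.frame rank/score) and `css_rank`
#' @export
clade_separation_proxy <- function(assignments) {
  if (NROW(assignments) == 0L) stop("no gene assignments supplied")
  cons <- genome_consensus_taxonomy(assignments)
  M <- tax_matrix(assignments$hit_taxonomy)
  scores <- vapply(RANK_CODES,
                   function(r) 1 - mean(lineage_congruent(M, cons, r)),
                   numeric(1))
  list(table = data.frame(rank = RANK_CODES, score = unname(scores),
                          stringsAsFactors = FALSE),
       css_rank = RANK_CODES[which.max(scores)])
}
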