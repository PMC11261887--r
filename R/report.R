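# Aggregation of per-genome outcomes into summary statistics: printed
# percentages, three-way category tallies, taxon-inflation accounting and
# the taxonomic-novelty failure profile.

#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up at the requested number
#' of decimals (the convention for all printed percentages; base R `round`
#' is banker's rounding and disagrees on exact halves).
#'
#' @param numerator,denominator counts; `denominator` must be positive
#' @param decimals decimals to keep
#' @return the rounded percentage
#' @export
#' @examples
#' percentage(35723, 317542, 2)  # 11.25
percentage <- function(numerator, denominator, decimals = 2L) {
  if (length(denominator) != 1L || is.na(denominator) || denominator <= 0)
    stop("denominator must be a single positive number")
  round_half_up(100 * numerator / denominator, decimals)
}

round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  floor(x * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

#' Tally the three ANI categories (plus tree incongruencies)
#'
#' @param categories character vector of per-genome categories
#'   (`same_species` / `changed_species` / `new_species`)
#' @param n_tree_incongruent count of tree-based incongruencies (not part of
#'   the ANI partition)
#' @return a `category_tally` list with `n_same`, `n_changed`, `n_new`,
#'   `n_tree_incongruent`, `n_total`; the three ANI counts always sum to
#'   `n_total`
#' @export
tally_categories <- function(categories, n_tree_incongruent = 0L) {
  bad <- setdiff(unique(categories),
                 c("same_species", "changed_species", "new_species"))
  if (length(bad)) stop("unknown category: ", bad[1L])
  out <- list(n_same = sum(categories == "same_species"),
              n_changed = sum(categories == "changed_species"),
              n_new = sum(categories == "new_species"),
              n_tree_incongruent = as.integer(n_tree_incongruent),
              n_total = length(categories))
  stopifnot(out$n_same + out$n_changed + out$n_new == out$n_total)
  structure(out, class = "category_tally")
}

#' @export
print.category_tally <- function(x, ...) {
  if (x$n_total > 0)
    cat(sprintf("same %d (%.2f%%)  changed %d (%.2f%%)  new %d (%.2f%%)  of %d\n",
                x$n_same, percentage(x$n_same, x$n_total),
                x$n_changed, percentage(x$n_changed, x$n_total),
                x$n_new, percentage(x$n_new, x$n_total), x$n_total))
  else cat("empty tally\n")
  invisible(x)
}

#' Taxon inflation table
#'
#' For each rank from phylum to species, counts the taxa composed entirely
#' of failed genomes and the inflation percentage
#' `100 * n_failed_only / (total_taxa - n_failed_only)`, rounded half-up to
#' one decimal. Taxa are keyed by their full lineage through the rank, so
#' identically named taxa under different parents stay distinct. Genomes
#' lacking a name at a rank are skipped at that rank with a warning.
#'
#' @param genomes data.frame with columns `accession`, `taxonomy` (7-rank
#'   string) and `failed` (logical)
#' @return data.frame with one row per rank: `rank`, `n_failed_only_taxa`,
#'   `total_taxa`, `inflation_pct`
#' @export
inflation_table <- function(genomes) {
  stopifnot(all(c("accession", "taxonomy", "failed") %in% names(genomes)))
  M <- tax_matrix(genomes$taxonomy)
  rows <- lapply(c("p", "c", "o", "f", "g", "s"), function(r) {
    j <- rank_index0(r) + 1L
    named <- !is.na(M[, j]) & nzchar(M[, j])
    if (any(!named))
      warning(sum(!named), " genome(s) lack a name at rank ", r,
              "; skipped at that rank")
    key <- apply(M[named, seq_len(j), drop = FALSE], 1L, paste, collapse = ";")
    failed <- genomes$failed[named]
    all_failed <- tapply(failed, key, all)
    nf <- sum(all_failed)
    total <- length(all_failed)
    data.frame(rank = r, n_failed_only_taxa = nf, total_taxa = total,
               inflation_pct = if (total > nf)
                 round_half_up(100 * nf / (total - nf), 1L) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Failure rates by degree of taxonomic novelty
#'
#' A genome's novelty is the highest rank (phylum towards species) at which
#' it is the sole representative of its taxon; genomes belonging to a
#' species with more than one member are novel only at strain level.
#'
#' @param genomes data.frame with `accession`, `taxonomy`, `failed`
#' @return data.frame per novelty level (`p` ... `s`, `strain`) with
#'   `n_total`, `n_failed` and `failure_pct` (unrounded)
#' @export
novelty_failure_profile <- function(genomes) {
  stopifnot(all(c("accession", "taxonomy", "failed") %in% names(genomes)))
  M <- tax_matrix(genomes$taxonomy)
  novelty <- rep("strain", nrow(M))
  assigned <- rep(FALSE, nrow(M))
  for (r in c("p", "c", "o", "f", "g", "s")) {
    j <- rank_index0(r) + 1L
    key <- apply(M[, seq_len(j), drop = FALSE], 1L, paste, collapse = ";")
    counts <- table(key)
    sole <- counts[key] == 1L
    hit <- !assigned & sole & !is.na(M[, j]) & nzchar(M[, j])
    novelty[hit] <- r
    assigned <- assigned | hit
  }
  levels <- c("p", "c", "o", "f", "g", "s", "strain")
  do.call(rbind, lapply(levels, function(lv) {
    idx <- novelty == lv
    n <- sum(idx); nf <- sum(genomes$failed[idx])
    data.frame(novelty = lv, n_total = n, n_failed = nf,
               failure_pct = if (n > 0) 100 * nf / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
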