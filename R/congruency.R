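# Taxonomy-string congruency (phylum to genus) between two classifications
# of the same genome, plus the MSA row-substitution and column-masking steps
# of the tree-based analysis. Tree inference itself is external: "observed"
# strings come from the caller or from synthetic ground truth.

#' Compare two classifications of one genome, phylum to genus
#'
#' Scans phylum, class, order, family, genus in order and records the first
#' (i.e. highest) rank at which both strings carry a name and the names
#' differ. Unnamed or absent ranks are skipped. A domain mismatch is outside
#' the phylum-genus scan and is reported as incongruent at the sentinel rank
#' `"d"` with a warning. Species-level agreement is the province of the ANI
#' categories, not this comparison.
#'
#' @param original original classification (string or parsed taxonomy)
#' @param observed observed classification (string or parsed taxonomy)
#' @param accession genome accession carried into the result
#' @return a `congruency_result` list: `accession`, `congruent`,
#'   `highest_incongruent_rank` (`NA` when congruent), `original`, `observed`
#' @export
compare_taxonomies <- function(original, observed, accession = NA_character_) {
  o <- if (is.character(original)) parse_taxonomy(original) else original
  b <- if (is.character(observed)) parse_taxonomy(observed) else observed
  res <- function(rank) {
    structure(list(accession = accession, congruent = is.na(rank),
                   highest_incongruent_rank = rank,
                   original = format_taxonomy(o),
                   observed = format_taxonomy(b)),
              class = "congruency_result")
  }
  od <- unname(o["d"]); bd <- unname(b["d"])
  if (!is.na(od) && !is.na(bd) && nzchar(od) && nzchar(bd) && od != bd) {
    warning("domain mismatch for ", accession, ": ", od, " vs ", bd)
    return(res("d"))
  }
  for (r in c("p", "c", "o", "f", "g")) {
    a1 <- unname(o[r]); a2 <- unname(b[r])
    if (is.na(a1) || is.na(a2) || !nzchar(a1) || !nzchar(a2)) next
    if (a1 != a2) return(res(r))
  }
  res(NA_character_)
}

#' @export
print.congruency_result <- function(x, ...) {
  if (x$congruent) cat(x$accession, ": congruent\n")
  else cat(x$accession, ": incongruent at rank ",
           x$highest_incongruent_rank, "\n", sep = "")
  invisible(x)
}

msa_width <- function(msa) {
  w <- unique(nchar(msa))
  if (length(w) > 1L) stop("MSA rows have unequal widths")
  w
}

#' Substitute rows of an MSA
#'
#' Replaces the rows named in `replacements` in place; every other row is
#' untouched. Replacement sequences must match the alignment width and every
#' replaced accession must exist in the MSA.
#'
#' @param msa named character vector of aligned rows
#' @param replacements named character vector, accession to aligned sequence
#' @return the modified MSA
#' @export
substitute_msa_rows <- function(msa, replacements) {
  w <- msa_width(msa)
  unknown <- setdiff(names(replacements), names(msa))
  if (length(unknown))
    stop("accession absent from MSA: ", unknown[1L])
  bad <- nchar(replacements) != w
  if (any(bad))
    stop("replacement width mismatch for ", names(replacements)[bad][1L],
         " (expected ", w, ", got ", nchar(replacements)[bad][1L], ")")
  msa[names(replacements)] <- unname(replacements)
  msa
}

#' Apply a column mask to an MSA
#'
#' Keeps the columns flagged `TRUE`, preserving order; row count and row
#' names are unchanged.
#'
#' @param msa named character vector of aligned rows
#' @param mask logical vector, one element per column (see [read_msa_mask()])
#' @return the masked MSA
#' @export
apply_mask <- function(msa, mask) {
  w <- msa_width(msa)
  if (length(mask) != w)
    stop("mask length ", length(mask), " != MSA width ", w)
  keep <- which(mask)
  vapply(msa, function(s)
    paste(strsplit(s, "", fixed = TRUE)[[1]][keep], collapse = ""),
    character(1))
}

#' Concatenate per-marker aligned fragments into one MSA row
#'
#' Joins marker fragments in the canonical order given by
#' `names(marker_widths)`; a missing marker contributes a gap run of that
#' marker's width. Fragment widths must match the per-marker widths.
#'
#' @param marker_alignments named list/vector of aligned fragments (a subset
#'   of the markers)
#' @param marker_widths named integer vector, canonical marker order and the
#'   aligned width of each marker
#' @param gap_char gap character
#' @return a single aligned row of width `sum(marker_widths)`
#' @export
concat_markers <- function(marker_alignments, marker_widths, gap_char = "-") {
  unknown <- setdiff(names(marker_alignments), names(marker_widths))
  if (length(unknown)) stop("unknown marker: ", unknown[1L])
  parts <- vapply(names(marker_widths), function(m) {
    w <- marker_widths[[m]]
    if (m %in% names(marker_alignments)) {
      frag <- marker_alignments[[m]]
      if (nchar(frag) != w)
        stop("fragment width mismatch for marker ", m,
             " (expected ", w, ", got ", nchar(frag), ")")
      frag
    } else strrep(gap_char, w)
  }, character(1))
  paste(parts, collapse = "")
}
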