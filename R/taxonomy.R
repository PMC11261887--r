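# GTDB-style 7-rank taxonomy strings, e.g.
#   d__Bacteria;p__Pseudomonadota;...;s__Escherichia coli
# Internally a taxonomy is a named character vector whose names are the rank
# codes in canonical order. A rank may be absent (truncated lineage, or a rank
# dropped by a majority-vote tie) or present with an empty name ("s__").

#' Canonical rank codes, domain to species
#' @export
RANK_CODES <- c("d", "p", "c", "o", "f", "g", "s")

RANK_NAMES <- c(d = "domain", p = "phylum", c = "class", o = "order",
                f = "family", g = "genus", s = "species")

#' Zero-based index of a rank code (domain = 0, species = 6)
#' @param rank a single rank code in `RANK_CODES`
#' @return integer index
#' @export
rank_index0 <- function(rank) {
  i <- match(rank, RANK_CODES)
  if (anyNA(i)) stop("unknown rank code: ", paste(rank[is.na(i)], collapse = ", "))
  i - 1L
}

#' Parse a GTDB-style taxonomy string
#'
#' Splits on `;`, requires three-character prefixes (`d__` ... `s__`) in
#' canonical domain-to-species order. Empty names (`"s__"`) are recorded as
#' unnamed ranks; ranks may be missing (truncation or a dropped tie).
#'
#' @param text a single taxonomy string
#' @return named character vector; names are rank codes, values taxon names
#' @export
#' @examples
#' parse_taxonomy("d__Bacteria;p__Pseudomonadota")
parse_taxonomy <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("taxonomy must be a single character string")
  toks <- trimws(strsplit(trimws(text), ";", fixed = TRUE)[[1]])
  if (length(toks) == 0L || all(!nzchar(toks)))
    stop("empty taxonomy string")
  codes <- substr(toks, 1L, 1L)
  if (any(substr(toks, 2L, 3L) != "__") || !all(codes %in% RANK_CODES))
    stop("malformed rank token (expected <code>__<name>): ",
         toks[which(substr(toks, 2L, 3L) != "__" | !codes %in% RANK_CODES)[1L]])
  idx <- match(codes, RANK_CODES)
  if (is.unsorted(idx, strictly = TRUE))
    stop("ranks out of canonical d->s order in: ", text)
  setNames(substring(toks, 4L), codes)
}

#' Format a parsed taxonomy back to its string form
#' @param tax named character vector as returned by [parse_taxonomy()]
#' @return a single string; `format_taxonomy(parse_taxonomy(x)) == x` for
#'   canonical inputs
#' @export
format_taxonomy <- function(tax) {
  if (length(tax) == 0L) return("")
  paste0(names(tax), "__", unname(tax), collapse = ";")
}

#' Truncate a taxonomy at a rank
#'
#' Removes all ranks deeper than `css_rank`; idempotent on lineages already
#' shorter than the cut.
#'
#' @param tax named character vector (parsed taxonomy)
#' @param css_rank rank code at which to cut (inclusive)
#' @return truncated named character vector
#' @export
truncate_taxonomy <- function(tax, css_rank) {
  keep <- rank_index0(names(tax)) <= rank_index0(css_rank)
  tax[keep]
}

# Parse a vector of taxonomy strings into an n x 7 character matrix
# (columns RANK_CODES; NA = rank absent, "" = unnamed). Unique strings are
# parsed once, so repeated lineages over thousands of genes are cheap.
tax_matrix <- function(strings) {
  u <- unique(strings)
  cols <- vapply(u, function(s) {
    t <- parse_taxonomy(s)
    out <- rep(NA_character_, 7L)
    out[match(names(t), RANK_CODES)] <- unname(t)
    out
  }, character(7L))
  M <- t(cols)[match(strings, u), , drop = FALSE]
  colnames(M) <- RANK_CODES
  rownames(M) <- NULL
  M
}

# Logical vector over rows of M: does each lineage agree with `ref_tax` at
# every rank through `css_rank` where both sides carry a name? Unnamed or
# absent ranks on either side are never counted as disagreement.
lineage_congruent <- function(M, ref_tax, css_rank) {
  ok <- rep(TRUE, nrow(M))
  for (j in seq_len(rank_index0(css_rank) + 1L)) {
    b <- unname(ref_tax[RANK_CODES[j]])
    if (is.na(b) || !nzchar(b)) next
    a <- M[, j]
    ok <- ok & (is.na(a) | !nzchar(a) | a == b)
  }
  ok
}
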