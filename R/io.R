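# Readers/writers for the external formats the pipeline touches: FASTA,
# per-gene assignment TSVs, genome summaries, representative metadata,
# alignment column masks and report tables. TSV dialects are minimal and
# documented on each reader; all coordinates are 0-based half-open.

IUPAC_DNA_RE <- "^[ACGTNRYSWKMBDHV-]*$"

#' Read a (multi-)FASTA of contigs
#'
#' Sequences are uppercased and line wrapping is normalised. Record ids are
#' the first whitespace-delimited token of each header and must be unique.
#'
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet] named by contig id
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("malformed FASTA ", path, ": ",
                                         conditionMessage(e)))
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(x))
  bad <- !grepl(IUPAC_DNA_RE, seqs)
  if (any(bad))
    stop("non-IUPAC character in record ", ids[which(bad)[1L]])
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write contigs to FASTA
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector)
#' @param path output file
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

ASSIGNMENT_COLS <- c("accession", "gene_id", "contig_id", "gene_index",
                     "hit_taxonomy", "is_marker")

#' Read a per-gene taxonomic assignment table
#'
#' Tab-separated with a header; required columns `accession`, `gene_id`,
#' `contig_id`, `gene_index` (0-based order of the gene along its contig),
#' `hit_taxonomy` (GTDB-style string of the closest reference hit) and
#' `is_marker` (TRUE/FALSE, membership of the concatenated marker set).
#' Genes without any reference hit are simply absent from the table, and a
#' contig may legitimately have no rows at all.
#'
#' @param path TSV file
#' @return data.frame ordered by accession, contig_id, gene_index
#' @export
read_gene_assignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(ASSIGNMENT_COLS, names(df))
  if (length(missing))
    stop("assignment table missing column(s): ", paste(missing, collapse = ", "))
  df <- df[ASSIGNMENT_COLS]
  df$gene_index <- as.integer(df$gene_index)
  df$is_marker <- as.logical(df$is_marker)
  if (anyNA(df$gene_index)) stop("non-integer gene_index in ", path)
  key <- paste(df$accession, df$contig_id, df$gene_index, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (contig_id, gene_index) within a genome: ",
         sub("\r", "/", key[duplicated(key)][1L]))
  invisible(tax_matrix(df$hit_taxonomy))  # validates every lineage string
  df <- df[order(df$accession, df$contig_id, df$gene_index), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a per-gene assignment table
#' @param df data.frame with the columns of [read_gene_assignments()]
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_gene_assignments <- function(df, path) {
  write.table(df[ASSIGNMENT_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read per-genome summaries
#'
#' TSV with columns `accession`, `css_rank` (rank code of the maximal clade
#' separation score), `is_failed` and `genome_type`.
#'
#' @param path TSV file
#' @return data.frame
#' @export
read_genome_summary <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(c("accession", "css_rank"), names(df))
  if (length(missing))
    stop("summary table missing column(s): ", paste(missing, collapse = ", "))
  if (!all(df$css_rank %in% RANK_CODES))
    stop("invalid css_rank value: ",
         df$css_rank[!df$css_rank %in% RANK_CODES][1L])
  if (!is.null(df$is_failed)) df$is_failed <- as.logical(df$is_failed)
  df
}

#' Read species-representative metadata
#' @param path TSV with columns `accession` and `taxonomy` (7-rank string)
#' @return data.frame
#' @export
read_rep_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(c("accession", "taxonomy"), names(df))
  if (length(missing))
    stop("metadata table missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$accession))
    stop("duplicate representative accession: ",
         df$accession[duplicated(df$accession)][1L])
  df
}

#' Read an alignment column mask
#'
#' A single line of `0`/`1` symbols (whitespace ignored), one per alignment
#' column; `1` marks a kept column.
#'
#' @param path mask file
#' @return logical vector, `TRUE` = keep
#' @export
read_msa_mask <- function(path) {
  txt <- gsub("[[:space:]]", "", paste(readLines(path, warn = FALSE), collapse = ""))
  if (!nzchar(txt)) stop("empty mask file: ", path)
  ch <- strsplit(txt, "")[[1]]
  bad <- setdiff(unique(ch), c("0", "1"))
  if (length(bad))
    stop("mask symbol outside the 0/1 alphabet: '", bad[1L], "'")
  keep <- ch == "1"
  if (!any(keep)) warning("mask keeps zero columns")
  keep
}

#' Read an aligned FASTA (MSA) as a named character vector
#' @param path aligned FASTA; all rows must have equal width
#' @return named character vector of aligned rows
#' @export
read_msa <- function(path) {
  x <- Biostrings::readBStringSet(path)
  rows <- setNames(as.character(x), sub("\\s.*$", "", names(x)))
  if (length(unique(nchar(rows))) > 1L)
    stop("MSA rows have unequal widths in ", path)
  rows
}
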