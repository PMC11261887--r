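# End-to-end drivers: reference indexing (sketches), classification of a
# genome half against a representative database, and the synthetic pipeline
# simulate -> score -> split -> classify used by the recovery experiments.

#' Pre-sketch a representative database
#'
#' @param ref_db a `ref_db` (from [generate_reference_db()]) or a list with
#'   `seqs` (named DNAStringSet) and `metadata` (accession, taxonomy)
#' @param params a [minhash_params()]
#' @param k_anchor anchor k-mer size for the prebuilt fragment-ANI tables
#' @return `ref_index` list: `seqs`, `metadata`, `sketches`, `anchors`,
#'   `params`
#' @export
build_reference_index <- function(ref_db, params = minhash_params(),
                                  k_anchor = 15L) {
  sketches <- lapply(seq_along(ref_db$seqs), function(i)
    sketch(ref_db$seqs[[i]], params))
  names(sketches) <- names(ref_db$seqs)
  anchors <- lapply(seq_along(ref_db$seqs), function(i)
    anchor_index(ref_db$seqs[[i]], k_anchor))
  names(anchors) <- names(ref_db$seqs)
  structure(list(seqs = ref_db$seqs, metadata = ref_db$metadata,
                 sketches = sketches, anchors = anchors,
                 k_anchor = as.integer(k_anchor), params = params),
            class = "ref_index")
}

#' Classify a genome half against species representatives
#'
#' Candidate references are the union of the MinHash prefilter (> 80 %
#' estimated ANI, distance <= d_max) and the taxonomic context of the
#' expected lineage; the best bidirectional fragment-ANI hit is categorised
#' against the expected representative.
#'
#' @param half_seqs contigs of the half ([Biostrings::DNAStringSet])
#' @param ref_index from [build_reference_index()]
#' @param expected_tax expected (original) classification of the genome
#' @param expected_rep accession of the expected species representative
#' @param criteria a [species_criteria()]
#' @param self_exclude accessions excluded as self-hits
#' @param query_id id recorded in the result
#' @param ... passed to [fragment_ani()]
#' @return an `ani_result`
#' @export
classify_half <- function(half_seqs, ref_index, expected_tax, expected_rep,
                          criteria = species_criteria(),
                          self_exclude = character(0), query_id = "query",
                          ...) {
  qsk <- sketch(half_seqs, ref_index$params)
  pre <- prefilter_references(qsk, ref_index$sketches, ref_index$params)
  ctx <- taxonomic_context(expected_tax, ref_index$metadata)
  cand <- union(pre, ctx)
  bidirectional_best(half_seqs, ref_index$seqs[cand], expected_rep,
                     criteria = criteria, self_exclude = self_exclude,
                     query_id = query_id,
                     ref_anchors = ref_index$anchors[cand],
                     k_anchor = ref_index$k_anchor, ...)
}

derive_seed <- function(seed, i, salt = 0L) {
  as.integer((as.numeric(seed) %% 1e6) * 1013 + salt * 7919 + i)
}

#' Run the synthetic pipeline end-to-end
#'
#' For each replicate: build a chimera, emulate gene assignments, locate the
#' CSS rank, order contigs by contamination, split by nucleotides, classify
#' the clean (and optionally contaminant) half, and record recovery
#' statistics against the injected truth, including the directed-vs-random
#' contaminant-gene removal contrast.
#'
#' @param config a [sim_config()]; `config$seed` drives everything
#' @param n_genomes number of replicate chimeras
#' @param ref_db optional pre-built reference database (rebuilt otherwise)
#' @param classify run the ANI classification stage
#' @param classify_contaminant also classify the contaminant half
#' @param n_random random-removal baseline replicates per genome (0 = skip)
#' @return data.frame with one row per genome: category, best hit, ANI/AF,
#'   ordering and removal diagnostics, and the truth lineages
#' @export
run_pipeline <- function(config = sim_config(), n_genomes = 1L,
                         ref_db = NULL, classify = TRUE,
                         classify_contaminant = FALSE, n_random = 0L) {
  taxonomy <- generate_taxonomy(config)
  if (is.null(ref_db)) ref_db <- generate_reference_db(taxonomy, config)
  ref_index <- if (classify) build_reference_index(ref_db) else NULL
  rows <- vector("list", n_genomes)
  for (i in seq_len(n_genomes)) {
    acc <- sprintf("CHIM%04d", i)
    chim <- make_chimera(ref_db, taxonomy, config = config,
                         seed = derive_seed(config$seed, i, 1L),
                         accession = acc)
    emu <- emulate_gene_assignments(chim, taxonomy, config,
                                    seed = derive_seed(config$seed, i, 2L))
    css <- emu$summary$css_rank
    scores <- rank_contigs(emu$assignments, css,
                           setNames(Biostrings::width(chim$seqs),
                                    names(chim$seqs)))
    cons <- truncate_taxonomy(genome_consensus_taxonomy(emu$assignments), css)
    ordered <- chim$seqs[scores$contig_id]
    halves <- split_by_nucleotides(ordered, emu$assignments, cons, css)
    truth <- chim$truth
    contam_ids <- truth$contaminant_contigs
    host_ids <- setdiff(names(chim$seqs), contam_ids)
    # ordering recovery: every contaminant contig before every host contig
    pos <- setNames(scores$rank, scores$contig_id)
    ordering_ok <- length(contam_ids) == 0L ||
      max(pos[contam_ids]) < min(c(pos[host_ids], Inf))
    # nt-level contaminant removal
    contam_nt <- sum(Biostrings::width(chim$seqs[contam_ids]))
    removed_contam_nt <- removed_nt_of(halves, contam_ids, chim$seqs)
    # gene-level removal (directed vs random baseline)
    genes <- emu$assignments
    contam_gene <- genes$contig_id %in% contam_ids
    directed_genes <- sum(contam_gene &
                            gene_removed(genes, halves, chim$seqs))
    random_genes <- if (n_random > 0L) {
      vapply(seq_len(n_random), function(r) {
        rh <- random_half(chim$seqs, derive_seed(config$seed, i, 10L + r))
        sum(contam_gene & gene_removed(genes, rh, chim$seqs))
      }, numeric(1))
    } else numeric(0)
    res <- if (classify)
      classify_half(halves$clean, ref_index, truth$host_taxon,
                    truth$host_accession, query_id = acc)
    else NULL
    contam_res <- if (classify && classify_contaminant &&
                      length(halves$contaminant) > 0L)
      classify_half(halves$contaminant, ref_index, truth$host_taxon,
                    truth$host_accession, query_id = paste0(acc, "_contam"))
    else NULL
    # lineage of the representative the half was assigned to (criteria met);
    # raw best hit as fallback for halves joining no cluster
    ref_lineage <- function(r) {
      if (is.null(r)) return(NA_character_)
      acc <- if (!is.na(r$assigned_ref)) r$assigned_ref else r$best_ref
      if (is.na(acc)) return(NA_character_)
      ref_db$metadata$taxonomy[ref_db$metadata$accession == acc]
    }
    rows[[i]] <- data.frame(
      accession = acc,
      css_rank = css,
      category = if (!is.null(res)) res$category else NA_character_,
      best_ref = if (!is.null(res)) res$best_ref else NA_character_,
      ani = if (!is.null(res)) res$ani else NA_real_,
      af = if (!is.null(res)) res$af else NA_real_,
      clean_lineage = ref_lineage(res),
      contam_best_ref = if (!is.null(contam_res)) contam_res$best_ref
        else NA_character_,
      contam_lineage = ref_lineage(contam_res),
      ordering_ok = ordering_ok,
      contam_nt = contam_nt,
      removed_contam_nt = removed_contam_nt,
      n_contam_genes = sum(contam_gene),
      directed_genes_removed = directed_genes,
      random_genes_removed_median = if (length(random_genes))
        stats::median(random_genes) else NA_real_,
      host_taxon = truth$host_taxon,
      donor_taxon = truth$donor_taxon,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# nt of the listed contigs that ended up in the contaminant half
removed_nt_of <- function(halves, contig_ids, original) {
  if (length(contig_ids) == 0L) return(0L)
  w <- Biostrings::width(halves$contaminant)
  ids <- names(halves$contaminant)
  sum(w[ids %in% contig_ids])
}

# logical per gene row: does the gene's start position fall in the removed
# (contaminant-half) portion of its contig? Gene k starts at k * step where
# step is inferred from the densest spacing seen on the contig.
gene_removed <- function(genes, halves, original) {
  contam_ids <- names(halves$contaminant)
  full_removed <- genes$contig_id %in%
    setdiff(contam_ids, halves$split_contig_id)
  out <- full_removed
  sid <- halves$split_contig_id
  if (!is.na(sid) && sid %in% genes$contig_id) {
    orig_len <- Biostrings::width(original[sid])
    kept_len <- sum(Biostrings::width(
      halves$clean[names(halves$clean) == sid]))
    need <- orig_len - kept_len
    g <- genes$contig_id == sid
    ng <- sum(g)
    step <- orig_len %/% max(1L, max(genes$gene_index[g]) + 1L)
    startpos <- genes$gene_index[g] * step
    end <- if (!is.null(halves$split_end)) halves$split_end else "5p"
    rem <- if (end == "5p") startpos < need else startpos >= (orig_len - need)
    out[g] <- rem
  }
  out
}
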