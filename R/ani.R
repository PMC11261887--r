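# Species re-assignment of genome halves: MinHash sketch prefilter against
# the representative database, taxonomic-context expansion from the expected
# lineage, bidirectional fragment-based ANI/AF against the union of both
# candidate sets, and the three-way category decision.

#' MinHash sketching parameters
#'
#' Defaults follow the Mash screening settings used for the >80 % ANI
#' representative prefilter: k-mer size 16, sketch size 5000, maximum
#' retained distance 0.2 and maximum p-value 1.0 (with `v_max = 1` the
#' p-value filter is a no-op and is carried as a pass-through parameter).
#'
#' @param k k-mer size
#' @param s sketch size (number of retained hashes)
#' @param d_max maximum Mash distance retained by the prefilter
#' @param v_max maximum p-value (pass-through; 1.0 disables the filter)
#' @return a `minhash_params` list
#' @export
minhash_params <- function(k = 16L, s = 5000L, d_max = 0.2, v_max = 1.0) {
  stopifnot(k >= 1L, k <= 32L, s >= 1L, d_max >= 0, d_max <= 1)
  structure(list(k = as.integer(k), s = as.integer(s),
                 d_max = d_max, v_max = v_max),
            class = "minhash_params")
}

#' Species assignment criteria
#' @param ani_min minimum ANI in percent (default 95)
#' @param af_min minimum alignment fraction (default 0.5)
#' @return a `species_criteria` list
#' @export
species_criteria <- function(ani_min = 95.0, af_min = 0.5) {
  stopifnot(ani_min > 0, ani_min <= 100, af_min > 0, af_min <= 1)
  structure(list(ani_min = ani_min, af_min = af_min),
            class = "species_criteria")
}

SKETCH_HASH_SEED <- 0x5eed

as_char_seqs <- function(seqs) {
  if (inherits(seqs, "XStringSet") || inherits(seqs, "XString"))
    as.character(seqs)
  else seqs
}

concat_contigs <- function(seqs, sep_n = 60L) {
  paste(as_char_seqs(seqs), collapse = strrep("N", sep_n))
}

#' Bottom-s MinHash sketch of a sequence
#'
#' Retains the `s` smallest distinct hash values over canonical k-mers (the
#' minimum of each k-mer and its reverse complement); k-mer windows touching
#' non-ACGT characters are skipped. Multi-contig inputs are sketched jointly
#' (contigs are separated by N runs, which never form k-mers). The hash is a
#' fixed, seeded 64-bit splitmix finaliser, so sketches are reproducible
#' across platforms; the seed is recorded in the sketch.
#'
#' @param seqs a [Biostrings::DNAStringSet] or character vector of sequences
#' @param params a [minhash_params()] object
#' @param hash_seed integer hash seed (fixed default)
#' @return a `minhash_sketch` list with sorted `hashes`, `k`, `s`, `seed`
#' @export
sketch <- function(seqs, params = minhash_params(), hash_seed = SKETCH_HASH_SEED) {
  seq1 <- concat_contigs(seqs, sep_n = 1L)
  if (nchar(seq1) < params$k) stop("sequence shorter than k")
  structure(list(hashes = cpp_minhash_sketch(seq1, params$k, params$s,
                                             as.double(hash_seed)),
                 k = params$k, s = params$s, seed = as.integer(hash_seed)),
            class = "minhash_sketch")
}

check_sketch_compat <- function(a, b) {
  if (a$k != b$k || a$s != b$s || a$seed != b$seed)
    stop("sketches built with different parameters (k/s/seed)")
}

#' Jaccard estimate from two sketches
#' @param a,b `minhash_sketch` objects with identical parameters
#' @return estimated Jaccard index in [0,1]
#' @export
sketch_jaccard <- function(a, b) {
  check_sketch_compat(a, b)
  cpp_sketch_jaccard(a$hashes, b$hashes, a$s)
}

#' Mash distance between two sketches
#'
#' `d = -(1/k) * log(2j / (1 + j))` with `j` the sketch Jaccard estimate;
#' `j = 0` maps to `d = 1` by convention and distances are clamped to [0,1].
#'
#' @inheritParams sketch_jaccard
#' @return distance in [0,1]
#' @export
mash_distance <- function(a, b) {
  j <- sketch_jaccard(a, b)
  if (j <= 0) return(1.0)
  min(1.0, -log(2 * j / (1 + j)) / a$k)
}

#' ANI estimate implied by a Mash distance
#' @param d Mash distance
#' @return `100 * (1 - d)` in percent
#' @export
ani_estimate <- function(d) 100 * (1 - d)

#' MinHash prefilter of the representative database
#'
#' Retains representatives with an estimated ANI strictly above 80 % and a
#' Mash distance at most `d_max`.
#'
#' @param query_sketch sketch of the query (e.g. a clean genome half)
#' @param ref_sketches named list of representative sketches
#' @param params the [minhash_params()] used to build the sketches
#' @param ani_floor ANI cutoff in percent (strict `>`)
#' @return character vector of candidate accessions (possibly empty)
#' @export
prefilter_references <- function(query_sketch, ref_sketches,
                                 params = minhash_params(), ani_floor = 80) {
  d <- vapply(ref_sketches, function(r) mash_distance(query_sketch, r),
              numeric(1))
  names(d)[ani_estimate(d) > ani_floor & d <= params$d_max]
}

#' Taxonomic-context candidate set
#'
#' Starts from all representatives of the expected genus; if that adds fewer
#' than `n_min` genomes, widens rank by rank (family, order, class, phylum)
#' until at least `n_min` genomes beyond the genus set have been added, or
#' the phylum is exhausted. A genus absent from the metadata triggers a
#' warning and the widening starts from the family.
#'
#' @param expected_tax expected lineage (string or parsed), must reach genus
#' @param rep_metadata data.frame with `accession` and `taxonomy` columns
#' @param n_min additional-genome threshold (100 in the published protocol)
#' @return character vector of accessions
#' @export
taxonomic_context <- function(expected_tax, rep_metadata, n_min = 100L) {
  if (is.character(expected_tax)) expected_tax <- parse_taxonomy(expected_tax)
  if (!"g" %in% names(expected_tax) || !nzchar(expected_tax[["g"]]))
    stop("expected taxonomy must carry a genus")
  M <- tax_matrix(rep_metadata$taxonomy)
  members_through <- function(rank) {
    rep_metadata$accession[apply_named(M, expected_tax, rank)]
  }
  genus_set <- members_through("g")
  if (length(genus_set) == 0L) {
    warning("expected genus absent from representative metadata; ",
            "starting context at family")
  } else if (length(genus_set) >= n_min) {
    return(genus_set)
  }
  out <- genus_set
  for (r in c("f", "o", "c", "p")) {
    out <- union(genus_set, members_through(r))
    if (length(out) - length(genus_set) >= n_min) break
  }
  out
}

# rows of M that actually carry the expected name at every named rank through
# `rank` (lineage_congruent alone lets absent ranks match anything, which is
# right for gene congruence but too loose for picking database members).
apply_named <- function(M, ref_tax, rank) {
  ok <- rep(TRUE, nrow(M))
  for (j in seq_len(rank_index0(rank) + 1L)) {
    b <- unname(ref_tax[RANK_CODES[j]])
    if (is.na(b) || !nzchar(b)) next
    a <- M[, j]
    ok <- ok & !is.na(a) & a == b
  }
  ok
}

#' Fragment-based ANI and alignment fraction
#'
#' The query is cut into consecutive non-overlapping fragments of
#' `fragment_len` nt (per contig; trailing partial fragments are not used).
#' Each fragment is anchored to its best reference position by shared
#' `k_anchor`-mers and scored by banded alignment identity. ANI is the mean
#' identity of mapped fragments (percent), AF the mapped fraction of all
#' fragments. Fragments sharing fewer than `min_anchors` anchors with any
#' reference window are unmapped.
#'
#' @param query_seqs query contigs ([Biostrings::DNAStringSet] or character)
#' @param ref_seq reference sequence (single string or DNAStringSet, joined);
#'   alternatively a prebuilt [anchor_index()] may be passed as `ref_index`
#' @param fragment_len fragment length in nt (3000 by convention)
#' @param k_anchor anchor k-mer size
#' @param band alignment band half-width in nt
#' @param min_anchors minimum shared anchors for a fragment to map
#' @param hamming_accept identity level at which the exact-diagonal score is
#'   accepted without running the gapped DP (1 never accepts, 0 always does)
#' @param ref_index optional prebuilt anchor index of the reference
#' @return list with `ani` (percent, `NA` if nothing mapped), `af`,
#'   `n_fragments`, `n_mapped`
#' @export
fragment_ani <- function(query_seqs, ref_seq = NULL, fragment_len = 3000L,
                         k_anchor = 15L, band = 16L, min_anchors = 2L,
                         hamming_accept = 0.9, ref_index = NULL) {
  query_seqs <- as_char_seqs(query_seqs)
  if (max(nchar(query_seqs)) < fragment_len)
    stop("sequence shorter than fragment length")
  if (is.null(ref_index)) {
    ref <- concat_contigs(ref_seq)
    if (nchar(ref) < fragment_len)
      stop("sequence shorter than fragment length")
    r <- cpp_fragment_ani(unname(query_seqs), ref, as.integer(fragment_len),
                          as.integer(k_anchor), as.integer(band),
                          as.integer(min_anchors), hamming_accept)
  } else {
    if (cpp_anchor_index_k(ref_index) != k_anchor)
      stop("anchor index built with a different k_anchor")
    r <- cpp_fragment_ani_indexed(unname(query_seqs), ref_index,
                                  as.integer(fragment_len),
                                  as.integer(band), as.integer(min_anchors),
                                  hamming_accept)
  }
  list(ani = if (r$n_mapped > 0) 100 * r$identity_sum / r$n_mapped else NA_real_,
       af = if (r$n_fragments > 0) r$n_mapped / r$n_fragments else 0,
       n_fragments = r$n_fragments, n_mapped = r$n_mapped)
}

#' Prebuild a reference anchor table for repeated [fragment_ani()] calls
#' @param seqs reference sequence(s); contigs are joined with N spacers
#' @param k_anchor anchor k-mer size (must match later calls)
#' @return an external pointer usable as `ref_index`
#' @export
anchor_index <- function(seqs, k_anchor = 15L) {
  cpp_anchor_index(concat_contigs(seqs), as.integer(k_anchor))
}

#' Bidirectional best ANI hit and category
#'
#' Runs [fragment_ani()] in both directions (query vs reference and
#' reference vs query) for every candidate, takes the maximum ANI and the
#' maximum AF of the two directions as one result, and picks the best
#' candidate by highest ANI, ties broken by higher AF then accession.
#' Accessions in `self_exclude` are skipped. With no candidates (or none
#' mapping at all) the result is category `new_species` with no best hit.
#'
#' @param query_seqs query contigs
#' @param refs named list/[Biostrings::DNAStringSet] of candidate sequences
#' @param expected_rep accession of the expected species representative
#' @param criteria a [species_criteria()] object
#' @param self_exclude accessions to skip (self-hits)
#' @param query_id id recorded in the result
#' @param ref_anchors optional named list of prebuilt [anchor_index()]es for
#'   the candidates (avoids re-indexing each reference per query)
#' @param k_anchor,... passed to [fragment_ani()]
#' @return an `ani_result` list: `query`, `best_ref`, `ani`, `af`,
#'   `category`, `assigned_ref` (the best candidate actually satisfying the
#'   species criteria — the cluster the query joins; `NA` when none does)
#'   and `expected_rep`
#' @export
bidirectional_best <- function(query_seqs, refs, expected_rep,
                               criteria = species_criteria(),
                               self_exclude = character(0),
                               query_id = "query", ref_anchors = NULL,
                               k_anchor = 15L, ...) {
  accs <- setdiff(names(refs), self_exclude)
  best <- NULL
  assigned <- NULL  # best among candidates satisfying the species criteria
  q_index <- if (length(accs)) anchor_index(query_seqs, k_anchor) else NULL
  better <- function(ani, af, acc, cur) {
    is.null(cur) || ani > cur$ani ||
      (ani == cur$ani && (af > cur$af || (af == cur$af && acc < cur$best_ref)))
  }
  for (acc in accs) {
    fwd <- fragment_ani(query_seqs, refs[[acc]], k_anchor = k_anchor,
                        ref_index = if (!is.null(ref_anchors))
                          ref_anchors[[acc]] else NULL, ...)
    rev <- fragment_ani(refs[[acc]], k_anchor = k_anchor,
                        ref_index = q_index, ...)
    ani <- suppressWarnings(max(c(fwd$ani, rev$ani), na.rm = TRUE))
    if (!is.finite(ani)) next
    af <- max(fwd$af, rev$af)
    if (better(ani, af, acc, best))
      best <- list(best_ref = acc, ani = ani, af = af)
    if (ani >= criteria$ani_min && af >= criteria$af_min &&
        better(ani, af, acc, assigned))
      assigned <- list(best_ref = acc, ani = ani, af = af)
  }
  if (is.null(best)) {
    return(structure(list(query = query_id, best_ref = NA_character_,
                          ani = NA_real_, af = NA_real_,
                          category = "new_species",
                          assigned_ref = NA_character_,
                          expected_rep = expected_rep),
                     class = "ani_result"))
  }
  structure(list(query = query_id, best_ref = best$best_ref, ani = best$ani,
                 af = best$af,
                 category = categorize(best$ani, best$af, best$best_ref,
                                       expected_rep, criteria),
                 assigned_ref = if (!is.null(assigned)) assigned$best_ref
                 else NA_character_,
                 expected_rep = expected_rep),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("%s -> %s  ANI %.2f%%  AF %.3f  [%s, expected %s]\n",
              x$query, x$best_ref, x$ani, x$af, x$category, x$expected_rep))
  invisible(x)
}

#' Three-way species category decision
#'
#' `same_species` when the best hit is the expected representative and meets
#' the criteria; `changed_species` when a different representative is
#' closest and meets the criteria; `new_species` when the best hit fails the
#' criteria (or there is no hit).
#'
#' @param ani best-hit ANI in percent (`NA` = no hit)
#' @param af best-hit alignment fraction
#' @param best_ref best-hit accession (`NA` = no hit)
#' @param expected_rep expected representative accession
#' @param criteria a [species_criteria()] object
#' @return one of `"same_species"`, `"changed_species"`, `"new_species"`
#' @export
categorize <- function(ani, af, best_ref, expected_rep,
                       criteria = species_criteria()) {
  if (is.na(best_ref) || is.na(ani) || ani < criteria$ani_min ||
      af < criteria$af_min)
    return("new_species")
  if (identical(best_ref, expected_rep)) "same_species" else "changed_species"
}
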