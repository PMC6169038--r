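#' Screen reads for candidate 16S rRNA sequences
#'
#' Stage one of the read pipeline: every read (up to `max_reads`) is aligned
#' against the reduced centroid database and called a candidate when the
#' e-value of its best hit is at or below the cutoff. The e-value uses the
#' total nucleotide count of the centroid set as the database length.
#'
#' Screening is a yes/no decision on the best raw score, so the fast
#' score-only engine pass is used for every read; full alignment details
#' (identity, spans) are recovered only for candidate reads.
#'
#' @param reads a `read_set` or named `DNAStringSet`. An empty read set
#'   yields an empty result, not an error.
#' @param reduced a `reduced_db` from [greedy_cluster()] (non-empty).
#' @param evalue_cutoff candidate threshold; default 1e-5.
#' @param max_reads examine at most this many reads (default 1e7); data sets
#'   with fewer reads are used in full.
#' @param scheme a [scoring_scheme()].
#' @return data.frame with one row per examined read: read_id, centroid_id,
#'   raw_score, e_value, identity_pct, aln_length, strand, passed_screen.
#' @export
screen_reads <- function(reads, reduced, evalue_cutoff = 1e-5,
                         max_reads = 1e7, scheme = scoring_scheme()) {
  stopifnot(is(reduced, "reduced_db"))
  if (length(reduced$centroids) == 0L) stop("empty reduced database")
  seqs <- if (is(reads, "read_set")) reads$reads else reads
  if (length(seqs) == 0L) {
    return(data.frame(read_id = character(), centroid_id = character(),
                      raw_score = integer(), e_value = numeric(),
                      identity_pct = numeric(), aln_length = integer(),
                      strand = character(), passed_screen = logical()))
  }
  if (length(seqs) > max_reads) seqs <- seqs[seq_len(max_reads)]
  hits <- best_hits(seqs, reduced$centroids, scheme = scheme,
                    details = FALSE)
  passed <- hits$e_value <= evalue_cutoff
  # recover alignment details for candidates only
  if (any(passed)) {
    det <- best_hits(seqs[passed], reduced$centroids, scheme = scheme,
                     details = TRUE)
    hits[passed, names(det)] <- det
  }
  out <- data.frame(read_id = hits$query_id, centroid_id = hits$subject_id,
                    raw_score = hits$raw_score, e_value = hits$e_value,
                    identity_pct = hits$identity_pct,
                    aln_length = hits$aln_length, strand = hits$strand,
                    passed_screen = passed, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assign candidate reads to a ribosomal domain
#'
#' Stage two: candidates are compared against pooled representative
#' full-length rRNA sets for the three domains, and each read takes the
#' domain of its best-scoring hit provided that hit passes the e-value
#' threshold; reads with no adequate hit are called `non_rrna`. Reads whose
#' archaeal and bacterial best scores tie exactly are resolved to the
#' alphabetically first domain and flagged in the `tie` column.
#'
#' @param reads a `read_set` or named `DNAStringSet` of candidate reads.
#' @param domain_refs named list with components `archaeal`, `bacterial`,
#'   `eukaryotic`, each a `DNAStringSet` (or character vector) of
#'   representative rRNA sequences; all three must be present and non-empty.
#' @param evalue_cutoff minimal-hit threshold; default 1e-5.
#' @param scheme a [scoring_scheme()].
#' @return data.frame: read_id, domain_call (`archaeal`, `bacterial`,
#'   `eukaryotic` or `non_rrna`), best_ref, raw_score, e_value, tie.
#' @export
validate_domain <- function(reads, domain_refs, evalue_cutoff = 1e-5,
                            scheme = scoring_scheme()) {
  needed <- c("archaeal", "bacterial", "eukaryotic")
  if (!all(needed %in% names(domain_refs)))
    stop("`domain_refs` must have components: ",
         paste(needed, collapse = ", "))
  sets <- lapply(domain_refs[needed], as_dna_character)
  if (any(lengths(sets) == 0L)) stop("every domain reference set must be non-empty")
  seqs <- if (is(reads, "read_set")) reads$reads else reads
  pool <- unlist(sets, use.names = FALSE)
  pool_dom <- rep(needed, lengths(sets))
  pool_ids <- paste0(pool_dom, "_", unlist(lapply(lengths(sets), seq_len)))
  names(pool) <- pool_ids
  if (length(seqs) == 0L)
    return(data.frame(read_id = character(), domain_call = character(),
                      best_ref = character(), raw_score = integer(),
                      e_value = numeric(), tie = logical()))
  rid <- names(seqs)
  if (is.null(rid)) rid <- paste0("read_", seq_along(seqs))

  db_len <- sum(nchar(pool))
  # per-read best score against each domain's references
  rseq <- as_dna_character(seqs)
  rrc <- revcomp_chr(rseq)
  best_score <- matrix(0L, length(rseq), 3,
                       dimnames = list(NULL, needed))
  best_ref <- matrix(NA_character_, length(rseq), 3)
  for (j in seq_along(pool)) {
    sc <- pmax(sw_score_batch(rseq, pool[j], scheme)[, 1],
               sw_score_batch(rrc, pool[j], scheme)[, 1])
    d <- pool_dom[j]
    better <- sc > best_score[, d]
    best_score[better, d] <- sc[better]
    best_ref[better, match(d, needed)] <- pool_ids[j]
  }
  top <- apply(best_score, 1, max)
  ev <- evalue(top, nchar(rseq), db_len, scheme)
  call_idx <- apply(best_score, 1, which.max) # first max: alphabetical order
  tie <- apply(best_score, 1, function(x) sum(x == max(x)) > 1L) & ev <= evalue_cutoff
  domain_call <- ifelse(ev <= evalue_cutoff, needed[call_idx], "non_rrna")
  data.frame(read_id = rid, domain_call = domain_call,
             best_ref = ifelse(domain_call == "non_rrna", NA_character_,
                               best_ref[cbind(seq_along(rid), call_idx)]),
             raw_score = as.integer(top), e_value = ev, tie = tie,
             stringsAsFactors = FALSE)
}

#' Classify validated prokaryotic reads against the full reference database
#'
#' Each archaeal/bacterial read is compared against the complete reference
#' database; the winning hit (highest bit score, ties by higher identity
#' then lexicographic subject id) assigns the read to the reference's
#' lineage, provided the alignment is at least `min_aln` columns long and at
#' least `min_identity` percent identical. Reads failing a threshold are
#' discarded with a reason (`short_alignment` is checked before
#' `low_identity`); eukaryotic and non-rRNA reads are discarded as
#' `non_prokaryotic`.
#'
#' @param reads a `read_set` or named `DNAStringSet` (the screened
#'   candidates).
#' @param validated the data.frame from [validate_domain()] for the same
#'   reads.
#' @param full_db a `reference_db` (non-empty).
#' @param min_identity minimum percent identity of the winning alignment;
#'   default 80.
#' @param min_aln minimum alignment length in columns; default 90.
#' @param scheme a [scoring_scheme()].
#' @return data.frame with one row per read: read_id, domain_call,
#'   assigned (logical), discard_reason (NA when assigned), subject_id,
#'   identity_pct, aln_length, bit_score, e_value, and the winning lineage
#'   columns (domain, phylum, class, cluster; NA when discarded).
#' @export
classify_reads <- function(reads, validated, full_db, min_identity = 80,
                           min_aln = 90, scheme = scoring_scheme()) {
  stopifnot(is(full_db, "reference_db"))
  if (length(full_db$sequences) == 0L) stop("empty reference database")
  seqs <- if (is(reads, "read_set")) reads$reads else reads
  rid <- names(seqs)
  stopifnot(!is.null(rid), all(validated$read_id %in% rid))

  prok <- validated$read_id[validated$domain_call %in% c("archaeal", "bacterial")]
  out <- data.frame(read_id = validated$read_id,
                    domain_call = validated$domain_call,
                    assigned = FALSE, discard_reason = NA_character_,
                    subject_id = NA_character_, identity_pct = NA_real_,
                    aln_length = NA_integer_, bit_score = NA_real_,
                    e_value = NA_real_, domain = NA_character_,
                    phylum = NA_character_, class = NA_character_,
                    cluster = NA_character_, stringsAsFactors = FALSE)
  out$discard_reason[!out$read_id %in% prok] <- "non_prokaryotic"
  if (length(prok)) {
    hits <- best_hits(seqs[prok], full_db$sequences, scheme = scheme,
                      details = TRUE)
    m <- match(hits$query_id, out$read_id)
    out$subject_id[m] <- hits$subject_id
    out$identity_pct[m] <- hits$identity_pct
    out$aln_length[m] <- hits$aln_length
    out$bit_score[m] <- hits$bit_score
    out$e_value[m] <- hits$e_value
    no_hit <- is.na(hits$identity_pct) | hits$raw_score <= 0L
    short <- !no_hit & hits$aln_length < min_aln
    low <- !no_hit & !short & hits$identity_pct < min_identity
    ok <- !no_hit & !short & !low
    out$discard_reason[m[no_hit]] <- "low_identity"
    out$discard_reason[m[short]] <- "short_alignment"
    out$discard_reason[m[low]] <- "low_identity"
    out$assigned[m[ok]] <- TRUE
    lin <- full_db$lineage[match(hits$subject_id[ok], full_db$lineage$id), ]
    out[m[ok], c("domain", "phylum", "class", "cluster")] <-
      lin[, c("domain", "phylum", "class", "cluster")]
  }
  out
}

#' Community profile from read assignments
#'
#' Expresses each taxon as a percentage of the prokaryotic 16S read pool:
#' the denominator is the number of reads that were called archaeal or
#' bacterial *and* received a taxon (discarded reads are excluded). Reads of
#' the focal phylum are additionally broken down by their best-hit
#' sub-cluster label; the sub-cluster counts sum exactly to the focal phylum
#' count.
#'
#' @param assignments the data.frame from [classify_reads()].
#' @param focal_phylum phylum label to resolve at sub-cluster level.
#' @param rank taxonomic rank for the main profile; default `"phylum"`.
#' @return A `community_profile`: list with `profile` (taxon, reads,
#'   pct_of_prokaryotes), `focal` (cluster, reads, pct_of_prokaryotes),
#'   `focal_phylum` and `denominator`. A zero denominator yields empty
#'   tables rather than an error.
#' @export
community_profile <- function(assignments, focal_phylum = NULL,
                              rank = c("phylum", "class", "cluster")) {
  rank <- match.arg(rank)
  asg <- assignments[assignments$assigned, , drop = FALSE]
  denom <- nrow(asg)
  if (denom == 0L) {
    return(structure(list(
      profile = data.frame(taxon = character(), reads = integer(),
                           pct_of_prokaryotes = numeric()),
      focal = data.frame(cluster = character(), reads = integer(),
                         pct_of_prokaryotes = numeric()),
      focal_phylum = focal_phylum, denominator = 0L),
      class = "community_profile"))
  }
  counts <- table(asg[[rank]])
  profile <- data.frame(taxon = names(counts),
                        reads = as.integer(counts),
                        pct_of_prokaryotes = 100 * as.integer(counts) / denom,
                        stringsAsFactors = FALSE)
  profile <- profile[order(-profile$reads, profile$taxon), ]
  rownames(profile) <- NULL
  focal <- data.frame(cluster = character(), reads = integer(),
                      pct_of_prokaryotes = numeric())
  if (!is.null(focal_phylum)) {
    sub <- asg[asg$phylum == focal_phylum, , drop = FALSE]
    if (nrow(sub)) {
      fc <- table(sub$cluster)
      focal <- data.frame(cluster = names(fc), reads = as.integer(fc),
                          pct_of_prokaryotes = 100 * as.integer(fc) / denom,
                          stringsAsFactors = FALSE)
      focal <- focal[order(-focal$reads, focal$cluster), ]
      rownames(focal) <- NULL
    }
  }
  structure(list(profile = profile, focal = focal,
                 focal_phylum = focal_phylum, denominator = denom),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf("<community_profile> %d prokaryotic reads assigned\n",
              x$denominator))
  print(x$profile, row.names = FALSE)
  if (nrow(x$focal)) {
    cat(sprintf("focal phylum %s by sub-cluster:\n", x$focal_phylum))
    print(x$focal, row.names = FALSE)
  }
  invisible(x)
}

#' Run the full read-classification pipeline
#'
#' Convenience wrapper chaining [screen_reads()], [validate_domain()] on the
#' candidates, [classify_reads()] and [community_profile()], with per-stage
#' counts reported.
#'
#' @inheritParams screen_reads
#' @inheritParams validate_domain
#' @inheritParams classify_reads
#' @inheritParams community_profile
#' @param verbose print a log line per stage.
#' @return list with `screen`, `validated`, `assignments`, `profile`,
#'   `counts`.
#' @export
classify_pipeline <- function(reads, reduced, domain_refs, full_db,
                              evalue_cutoff = 1e-5, min_identity = 80,
                              min_aln = 90, max_reads = 1e7,
                              focal_phylum = NULL,
                              scheme = scoring_scheme(), verbose = FALSE) {
  seqs <- if (is(reads, "read_set")) reads$reads else reads
  scr <- screen_reads(seqs, reduced, evalue_cutoff = evalue_cutoff,
                      max_reads = max_reads, scheme = scheme)
  cand <- seqs[scr$read_id[scr$passed_screen]]
  if (verbose)
    message(sprintf("screen: %d/%d reads are 16S candidates",
                    length(cand), nrow(scr)))
  val <- validate_domain(cand, domain_refs, evalue_cutoff = evalue_cutoff,
                         scheme = scheme)
  if (verbose)
    message(sprintf("validate: %s",
                    paste(names(table(val$domain_call)),
                          table(val$domain_call), sep = "=", collapse = ", ")))
  asg <- classify_reads(cand, val, full_db, min_identity = min_identity,
                        min_aln = min_aln, scheme = scheme)
  if (verbose)
    message(sprintf("classify: %d assigned, %d discarded",
                    sum(asg$assigned), sum(!asg$assigned)))
  prof <- community_profile(asg, focal_phylum = focal_phylum)
  counts <- c(examined = nrow(scr), candidates = length(cand),
              assigned = sum(asg$assigned),
              discarded = sum(!asg$assigned),
              non_candidates = nrow(scr) - length(cand))
  list(screen = scr, validated = val, assignments = asg, profile = prof,
       counts = counts)
}
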