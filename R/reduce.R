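#' Greedy centroid clustering of a reference database
#'
#' Builds the reduced screening database: sequences are processed in
#' length-descending order (ties by id), and each sequence joins the first
#' previously created centroid it matches at or above the identity
#' threshold, otherwise it founds a new centroid. This is the classic greedy
#' centroid strategy used to shrink a large 16S reference set (e.g. to an
#' 85%-identity representative set) before read screening.
#'
#' Identity between a sequence and a centroid is computed from the local
#' alignment engine as identical columns divided by the length of the
#' shorter sequence, so a perfect containment counts as identity 1. By
#' construction every centroid has identity below the threshold to all
#' centroids created before it.
#'
#' @param db a `reference_db` (non-empty).
#' @param threshold identity threshold in `(0, 1)`; default 0.85.
#' @param scheme a [scoring_scheme()] for the underlying alignments.
#' @param both_strands also try the reverse complement when matching.
#' @return A `reduced_db`: list with `centroids` (named `DNAStringSet`),
#'   `membership` (data.frame: member_id, centroid_id, identity), `threshold`
#'   and the centroid `lineage` rows.
#' @examples
#' db <- evolve_reference_db(600, 3, 0.02, 5, seed = 1)
#' greedy_cluster(db, threshold = 0.85)
#' @export
greedy_cluster <- function(db, threshold = 0.85, scheme = scoring_scheme(),
                           both_strands = TRUE) {
  stopifnot(is(db, "reference_db"))
  if (length(db$sequences) == 0L) stop("empty reference database")
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  seqs <- as.character(db$sequences)
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  ids <- names(seqs)

  centroid_ids <- character(0)
  centroid_seqs <- character(0)
  member <- character(length(seqs))
  identity <- numeric(length(seqs))

  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    assigned <- FALSE
    for (k in seq_along(centroid_ids)) {
      idn <- cluster_identity(s, centroid_seqs[[k]], scheme, both_strands)
      if (idn >= threshold) {
        member[i] <- centroid_ids[[k]]
        identity[i] <- idn
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      centroid_ids <- c(centroid_ids, ids[[i]])
      centroid_seqs <- c(centroid_seqs, s)
      member[i] <- ids[[i]]
      identity[i] <- 1
    }
  }
  membership <- data.frame(member_id = ids, centroid_id = member,
                           identity = identity, stringsAsFactors = FALSE)
  lineage <- db$lineage[match(centroid_ids, db$lineage$id), , drop = FALSE]
  rownames(lineage) <- NULL
  structure(list(centroids = Biostrings::DNAStringSet(
                   stats::setNames(centroid_seqs, centroid_ids)),
                 membership = membership, threshold = threshold,
                 lineage = lineage),
            class = "reduced_db")
}

# Clustering identity: identical columns of the best local alignment divided
# by the length of the shorter sequence.
cluster_identity <- function(a, b, scheme = scoring_scheme(),
                             both_strands = TRUE) {
  hit <- local_align(a, b, scheme, both_strands = both_strands)
  if (is.null(hit)) return(0)
  hit$n_ident / min(nchar(a), nchar(b))
}

#' @export
print.reduced_db <- function(x, ...) {
  cat(sprintf("<reduced_db> %d centroids from %d sequences at %.0f%% identity\n",
              length(x$centroids), nrow(x$membership), 100 * x$threshold))
  invisible(x)
}

#' Write a reduced database to disk
#'
#' Centroid FASTA plus a membership TSV (member_id, centroid_id, identity).
#'
#' @param reduced a `reduced_db`.
#' @param fasta_path,membership_path output files.
#' @return `fasta_path`, invisibly.
#' @export
write_reduced_db <- function(reduced, fasta_path, membership_path) {
  write_fasta(reduced$centroids, fasta_path)
  write_tsv(reduced$membership, membership_path)
  invisible(fasta_path)
}
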