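#' Fragment-based average nucleotide identity between two genomes
#'
#' The query genome is cut into consecutive non-overlapping fragments of
#' `frag_len` nt (a trailing piece shorter than `frag_len` is discarded) and
#' each fragment is aligned locally against the other genome. A fragment
#' contributes when its best alignment reaches at least `min_id` percent
#' identity over at least `min_cov` of the fragment length; the directed ANI
#' is the mean identity of contributing fragments. The reported ANI is the
#' arithmetic mean of the two directed values, and is undefined (`NA`) when
#' either direction keeps no fragment.
#'
#' @param genome_a,genome_b [sim_genome()] objects or plain sequences, each
#'   at least `frag_len` nt long.
#' @param frag_len fragment length in nt; default 1020.
#' @param min_id minimum percent identity for a fragment to count; default
#'   70.
#' @param min_cov minimum alignable fraction of the fragment; default 0.7.
#' @param scheme a [scoring_scheme()].
#' @param both_strands also search the reverse strand of each fragment.
#' @return list with `ani` (symmetric, percent or `NA`), `ani_ab`, `ani_ba`
#'   (directed values), `n_frag_ab`, `n_frag_ba` (fragments kept per
#'   direction).
#' @examples
#' g <- random_genome(5000, seed = 1)
#' ani_pair(g, g, frag_len = 500)$ani # 100
#' @export
ani_pair <- function(genome_a, genome_b, frag_len = 1020L, min_id = 70,
                     min_cov = 0.7, scheme = scoring_scheme(),
                     both_strands = TRUE) {
  a <- if (is(genome_a, "sim_genome")) genome_a$sequence else as_dna_character(genome_a)
  b <- if (is(genome_b, "sim_genome")) genome_b$sequence else as_dna_character(genome_b)
  if (nchar(a) < frag_len || nchar(b) < frag_len)
    stop("both genomes must be at least `frag_len` nt long")
  ab <- directed_ani(a, b, frag_len, min_id, min_cov, scheme, both_strands)
  ba <- directed_ani(b, a, frag_len, min_id, min_cov, scheme, both_strands)
  ani <- if (is.na(ab$ani) || is.na(ba$ani)) NA_real_ else mean(c(ab$ani, ba$ani))
  list(ani = ani, ani_ab = ab$ani, ani_ba = ba$ani,
       n_frag_ab = ab$n_kept, n_frag_ba = ba$n_kept)
}

directed_ani <- function(query, subject, frag_len, min_id, min_cov, scheme,
                         both_strands) {
  n_frag <- nchar(query) %/% frag_len
  starts <- (seq_len(n_frag) - 1L) * frag_len
  frags <- substring(query, starts + 1L, starts + frag_len)
  sc_f <- sw_score_batch(frags, subject, scheme)
  if (both_strands) {
    frc <- revcomp_chr(frags)
    sc_r <- sw_score_batch(frc, subject, scheme)
  }
  idents <- numeric(0)
  for (i in seq_len(n_frag)) {
    use_rev <- both_strands && sc_r[i, "score"] > sc_f[i, "score"]
    sc <- if (use_rev) sc_r[i, ] else sc_f[i, ]
    if (sc[["score"]] <= 0L) next
    ext <- hit_from_end(if (use_rev) frc[i] else frags[i], subject,
                        sc[["q_end"]], sc[["s_end"]], scheme)
    if (ext$aln_length >= min_cov * frag_len &&
        100 * ext$n_ident / ext$aln_length >= min_id)
      idents <- c(idents, 100 * ext$n_ident / ext$aln_length)
  }
  list(ani = if (length(idents)) mean(idents) else NA_real_,
       n_kept = length(idents))
}

#' Pairwise ANI matrix over a set of genomes
#'
#' Computes [ani_pair()] for every unordered pair; the diagonal is 100 by
#' definition and the matrix is symmetric by construction.
#'
#' @param genomes named list of [sim_genome()] objects or sequences (or a
#'   named `DNAStringSet`).
#' @inheritParams ani_pair
#' @return An `ani_matrix`: list with `ani` (symmetric numeric matrix,
#'   percent, `NA` where undefined) and `n_fragments` (kept fragments per
#'   ordered pair).
#' @export
ani_matrix <- function(genomes, frag_len = 1020L, min_id = 70, min_cov = 0.7,
                       scheme = scoring_scheme(), both_strands = TRUE) {
  if (is(genomes, "XStringSet")) genomes <- as.list(as.character(genomes))
  ids <- names(genomes)
  if (is.null(ids)) {
    ids <- vapply(genomes, function(g)
      if (is(g, "sim_genome")) g$id else NA_character_, "")
    if (anyNA(ids)) ids <- paste0("genome_", seq_along(genomes))
  }
  n <- length(genomes)
  ani <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  nf <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(ani) <- 100
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      p <- ani_pair(genomes[[i]], genomes[[j]], frag_len = frag_len,
                    min_id = min_id, min_cov = min_cov, scheme = scheme,
                    both_strands = both_strands)
      ani[i, j] <- ani[j, i] <- p$ani
      nf[i, j] <- p$n_frag_ab
      nf[j, i] <- p$n_frag_ba
    }
  }
  structure(list(ani = ani, n_fragments = nf), class = "ani_matrix")
}

#' @export
print.ani_matrix <- function(x, ...) {
  cat(sprintf("<ani_matrix> %d genomes\n", nrow(x$ani)))
  print(round(x$ani, 2))
  invisible(x)
}

#' Species clusters from an ANI matrix
#'
#' Groups genomes into species by single-linkage transitive closure over
#' pairs whose ANI strictly exceeds the threshold (conventionally 95%):
#' any chain of >95% pairs shares a species, matching how genomes are boxed
#' together in recruitment figures. Undefined (`NA`) pairs contribute no
#' link. The partition is exhaustive: every genome appears in exactly one
#' cluster.
#'
#' @param mat an `ani_matrix` (or plain symmetric matrix of percent ANI).
#' @param threshold percent ANI; pairs strictly above it are linked.
#'   Default 95.
#' @return A `species_clusters`: list with `clusters` (list of character
#'   vectors of genome ids), `membership` (named integer vector) and
#'   `threshold`.
#' @export
species_clusters <- function(mat, threshold = 95) {
  ani <- if (is(mat, "ani_matrix")) mat$ani else mat
  ids <- rownames(ani)
  if (is.null(ids)) ids <- paste0("genome_", seq_len(nrow(ani)))
  n <- length(ids)
  # union-find over >threshold links
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (!is.na(ani[i, j]) && ani[i, j] > threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  membership <- match(roots, unique(roots))
  names(membership) <- ids
  clusters <- split(ids, membership)
  names(clusters) <- paste0("species_", seq_along(clusters))
  structure(list(clusters = clusters, membership = membership,
                 threshold = threshold),
            class = "species_clusters")
}

#' @export
print.species_clusters <- function(x, ...) {
  cat(sprintf("<species_clusters> %d cluster(s) at >%g%% ANI\n",
              length(x$clusters), x$threshold))
  for (nm in names(x$clusters))
    cat(" ", nm, ":", paste(x$clusters[[nm]], collapse = ", "), "\n")
  invisible(x)
}
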