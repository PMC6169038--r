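#' Scoring scheme for the local-alignment engine
#'
#' Bundles the match/mismatch/gap scores used by the Smith-Waterman engine
#' together with the Karlin-Altschul parameters used to turn raw scores into
#' e-values. The defaults (match +1, mismatch penalty 2, gap open 2, gap
#' extend 1, lambda = 1.28, K = 0.46) are fixed, documented constants chosen
#' to behave like a megablast-style nucleotide search; they make e-values
#' reproducible across machines and runs.
#'
#' A gap of length L costs `gap_open + L * gap_extend`. `N` (or any non-ACGT
#' character) never matches, not even itself.
#'
#' @param match match reward (positive integer).
#' @param mismatch mismatch penalty (non-negative integer; subtracted).
#' @param gap_open gap opening penalty (non-negative integer).
#' @param gap_extend gap extension penalty, per gap column (non-negative).
#' @param lambda,K Karlin-Altschul parameters for e-value computation.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()
#' @export
scoring_scheme <- function(match = 1L, mismatch = 2L, gap_open = 2L,
                           gap_extend = 1L, lambda = 1.28, K = 0.46) {
  match <- as.integer(match)
  mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  if (match <= 0L) stop("`match` must be a positive reward")
  if (mismatch < 0L || gap_open < 0L || gap_extend < 0L)
    stop("penalties must be non-negative")
  if (lambda <= 0 || K <= 0) stop("`lambda` and `K` must be positive")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "<scoring_scheme> match +%d, mismatch -%d, gap open %d, gap extend %d; lambda = %g, K = %g\n",
    x$match, x$mismatch, x$gap_open, x$gap_extend, x$lambda, x$K))
  invisible(x)
}

as_dna_character <- function(x) {
  if (is(x, "XStringSet") || is(x, "XString")) x <- as.character(x)
  if (!is.character(x)) stop("sequences must be character or Biostrings objects")
  toupper(x)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Raw local-alignment scores for a batch of queries against one subject
#'
#' Score-only Smith-Waterman pass; much faster than a full alignment and
#' sufficient for screening decisions that depend only on score/e-value.
#' Forward strand only; callers handle the reverse strand by passing
#' reverse-complemented queries.
#'
#' @param queries character vector or `DNAStringSet`.
#' @param subject a single sequence.
#' @param scheme a [scoring_scheme()].
#' @return integer matrix with columns `score`, `q_end`, `s_end` (1-based
#'   inclusive ends of the best-scoring cell; 0 when no positive score).
#' @keywords internal
#' @export
sw_score_batch <- function(queries, subject, scheme = scoring_scheme()) {
  queries <- as_dna_character(queries)
  subject <- as_dna_character(subject)
  if (length(subject) != 1L || nchar(subject) == 0L)
    stop("`subject` must be a single non-empty sequence")
  if (any(nchar(queries) == 0L)) stop("empty query sequence")
  .sw_scores(queries, subject, scheme$match, scheme$mismatch,
             scheme$gap_open, scheme$gap_extend)
}

empty_hit_table <- function() {
  data.frame(query_id = character(), subject_id = character(),
             identity_pct = numeric(), aln_length = integer(),
             n_ident = integer(), mismatch = integer(), gapopen = integer(),
             raw_score = integer(), bit_score = numeric(), e_value = numeric(),
             q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

# Full alignment details for one query/subject pair given the end cell of the
# optimal local alignment on the already-chosen strand. `query` must be the
# oriented (possibly reverse-complemented) sequence.
hit_from_end <- function(query, subject, q_end, s_end, scheme) {
  .sw_extend(query, subject, as.integer(q_end), as.integer(s_end),
             scheme$match, scheme$mismatch, scheme$gap_open,
             scheme$gap_extend)
}

#' Best local alignment between two sequences
#'
#' Finds the maximal-scoring local alignment under affine gap penalties
#' (Smith-Waterman semantics), searching both strands of the query and
#' returning the better one. Percent identity uses the BLAST convention:
#' identical columns divided by total alignment columns, gap columns
#' included. Coordinates are 0-based half-open on the original (input)
#' sequences; for a minus-strand hit the query coordinates refer to the
#' original query, with the alignment covering its reverse complement.
#'
#' Equal scores between strands resolve to the forward strand; within a
#' strand, ties between alignment placements resolve to the earliest
#' alignment end in (query, subject) scan order, which makes results
#' deterministic.
#'
#' @param query,subject sequences (character or Biostrings). `N` never
#'   matches.
#' @param scheme a [scoring_scheme()].
#' @param db_len database length (nt) used for the e-value; defaults to the
#'   subject length, but callers searching a multi-sequence database should
#'   pass the database's total nucleotide count.
#' @param both_strands search the reverse complement of the query as well.
#' @param query_id,subject_id labels copied into the hit row.
#' @return A one-row data.frame (an alignment hit), or `NULL` when no
#'   alignment attains a positive score.
#' @examples
#' local_align("ACGTACGTAC", "TTTACGTACGTACTTT")
#' @export
local_align <- function(query, subject, scheme = scoring_scheme(),
                        db_len = NULL, both_strands = TRUE,
                        query_id = "query", subject_id = "subject") {
  query <- as_dna_character(query)
  subject <- as_dna_character(subject)
  if (length(query) != 1L || length(subject) != 1L)
    stop("`query` and `subject` must each be a single sequence")
  if (nchar(query) == 0L || nchar(subject) == 0L)
    stop("empty sequence")
  if (is.null(db_len)) db_len <- nchar(subject)

  fwd <- sw_score_batch(query, subject, scheme)
  strand <- "+"
  best <- fwd[1, ]
  oriented <- query
  if (both_strands) {
    qrc <- revcomp_chr(query)
    rev <- sw_score_batch(qrc, subject, scheme)
    if (rev[1, "score"] > best[["score"]]) {
      best <- rev[1, ]
      strand <- "-"
      oriented <- qrc
    }
  }
  if (best[["score"]] <= 0L) return(NULL)

  ext <- hit_from_end(oriented, subject, best[["q_end"]], best[["s_end"]],
                      scheme)
  qlen <- nchar(query)
  q0 <- ext$q_start
  q1 <- ext$q_end
  if (strand == "-") {
    tmp <- qlen - q1
    q1 <- qlen - q0
    q0 <- tmp
  }
  score <- ext$score
  data.frame(
    query_id = query_id, subject_id = subject_id,
    identity_pct = 100 * ext$n_ident / ext$aln_length,
    aln_length = ext$aln_length, n_ident = ext$n_ident,
    mismatch = ext$n_mismatch, gapopen = ext$n_gapopen,
    raw_score = score, bit_score = bit_score(score, scheme),
    e_value = evalue(score, qlen, db_len, scheme),
    q_start = q0, q_end = q1, s_start = ext$s_start, s_end = ext$s_end,
    strand = strand, stringsAsFactors = FALSE)
}

#' Karlin-Altschul e-value of a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length, `n` the
#' total database length, and `S` the raw score. Monotonically decreasing in
#' `S` and exactly linear in `n`.
#'
#' @param raw_score raw alignment score(s).
#' @param query_len query length in nt (positive).
#' @param db_len database length in nt (positive).
#' @param scheme a [scoring_scheme()] supplying `lambda` and `K`.
#' @return e-value(s), same length as `raw_score`.
#' @examples
#' evalue(30, 100, 1e6)
#' @export
evalue <- function(raw_score, query_len, db_len, scheme = scoring_scheme()) {
  if (any(query_len <= 0) || any(db_len <= 0))
    stop("`query_len` and `db_len` must be positive")
  scheme$K * query_len * db_len * exp(-scheme$lambda * raw_score)
}

#' Bit score of a raw alignment score
#'
#' `S' = (lambda * S - ln K) / ln 2`; monotone in the raw score, so ranking
#' hits by bit score or raw score is equivalent under a fixed scheme.
#'
#' @inheritParams evalue
#' @return bit score(s).
#' @export
bit_score <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' Export alignment hits in BLAST outfmt-6 layout
#'
#' Converts an internal hit table (0-based half-open coordinates) to the
#' conventional 12-column tabular layout with 1-based closed coordinates;
#' minus-strand hits have their subject coordinates swapped so that
#' `sstart > send`, as BLAST prints them.
#'
#' @param hits a hit table as returned by [local_align()] (rows bindable).
#' @return data.frame with columns qseqid, sseqid, pident, length, mismatch,
#'   gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' @export
hits_as_outfmt6 <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) {
    out <- data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      mismatch = integer(), gapopen = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric())
    return(out)
  }
  sstart <- hits$s_start + 1L
  send <- hits$s_end
  minus <- hits$strand == "-"
  tmp <- sstart[minus]
  sstart[minus] <- send[minus]
  send[minus] <- tmp
  data.frame(qseqid = hits$query_id, sseqid = hits$subject_id,
             pident = round(hits$identity_pct, 3), length = hits$aln_length,
             mismatch = hits$mismatch, gapopen = hits$gapopen,
             qstart = hits$q_start + 1L, qend = hits$q_end,
             sstart = sstart, send = send,
             evalue = hits$e_value, bitscore = round(hits$bit_score, 1),
             stringsAsFactors = FALSE)
}

# Best hit per read against a multi-sequence database.
#
# For every read, scores both strands against every subject with the fast
# score-only pass, keeps the top-scoring subject/strand, and (optionally)
# recovers the full alignment for the winner only. Ties between subjects at
# equal raw score are broken by higher percent identity, then lexicographic
# subject id; strand ties resolve to "+".
#
# Returns a data.frame with one row per read (reads with no positive score
# get raw_score 0 and NA details).
best_hits <- function(reads, subjects, scheme = scoring_scheme(),
                      db_len = NULL, both_strands = TRUE, details = TRUE) {
  rseq <- as_dna_character(reads)
  rid <- names(reads)
  if (is.null(rid)) rid <- paste0("read_", seq_along(rseq))
  sseq <- as_dna_character(subjects)
  sid <- names(subjects)
  if (is.null(sid)) sid <- paste0("subject_", seq_along(sseq))
  if (is.null(db_len)) db_len <- sum(nchar(sseq))
  nr <- length(rseq)
  ns <- length(sseq)
  if (nr == 0L)
    return(cbind(empty_hit_table(), tie = logical()))

  rrc <- if (both_strands) revcomp_chr(rseq) else NULL
  # score matrices: reads x subjects
  sc_f <- matrix(0L, nr, ns)
  qe_f <- matrix(0L, nr, ns)
  se_f <- matrix(0L, nr, ns)
  if (both_strands) {
    sc_r <- matrix(0L, nr, ns); qe_r <- matrix(0L, nr, ns); se_r <- matrix(0L, nr, ns)
  }
  for (j in seq_len(ns)) {
    m <- sw_score_batch(rseq, sseq[j], scheme)
    sc_f[, j] <- m[, 1]; qe_f[, j] <- m[, 2]; se_f[, j] <- m[, 3]
    if (both_strands) {
      m <- sw_score_batch(rrc, sseq[j], scheme)
      sc_r[, j] <- m[, 1]; qe_r[, j] <- m[, 2]; se_r[, j] <- m[, 3]
    }
  }
  sc_best <- if (both_strands) pmax(sc_f, sc_r) else sc_f

  rows <- vector("list", nr)
  for (i in seq_len(nr)) {
    smax <- max(sc_best[i, ])
    if (smax <= 0L) {
      row <- empty_hit_table()[1, ]
      row$query_id <- rid[i]
      row$raw_score <- 0L
      row$e_value <- Inf
      row$tie <- FALSE
      rows[[i]] <- row
      next
    }
    cand <- which(sc_best[i, ] == smax)
    tie <- length(cand) > 1L
    cand_rows <- lapply(cand, function(j) {
      use_rev <- both_strands && sc_r[i, j] > sc_f[i, j]
      oriented <- if (use_rev) rrc[i] else rseq[i]
      qe <- if (use_rev) qe_r[i, j] else qe_f[i, j]
      se <- if (use_rev) se_r[i, j] else se_f[i, j]
      if (details || tie) {
        ext <- hit_from_end(oriented, sseq[j], qe, se, scheme)
        qlen <- nchar(rseq[i])
        q0 <- ext$q_start; q1 <- ext$q_end
        if (use_rev) { tmp <- qlen - q1; q1 <- qlen - q0; q0 <- tmp }
        data.frame(query_id = rid[i], subject_id = sid[j],
                   identity_pct = 100 * ext$n_ident / ext$aln_length,
                   aln_length = ext$aln_length, n_ident = ext$n_ident,
                   mismatch = ext$n_mismatch, gapopen = ext$n_gapopen,
                   raw_score = ext$score,
                   bit_score = bit_score(ext$score, scheme),
                   e_value = evalue(ext$score, qlen, db_len, scheme),
                   q_start = q0, q_end = q1,
                   s_start = ext$s_start, s_end = ext$s_end,
                   strand = if (use_rev) "-" else "+",
                   stringsAsFactors = FALSE)
      } else {
        data.frame(query_id = rid[i], subject_id = sid[j],
                   identity_pct = NA_real_, aln_length = NA_integer_,
                   n_ident = NA_integer_, mismatch = NA_integer_,
                   gapopen = NA_integer_, raw_score = as.integer(smax),
                   bit_score = bit_score(smax, scheme),
                   e_value = evalue(smax, nchar(rseq[i]), db_len, scheme),
                   q_start = NA_integer_, q_end = NA_integer_,
                   s_start = NA_integer_, s_end = NA_integer_,
                   strand = if (both_strands && sc_r[i, j] > sc_f[i, j]) "-" else "+",
                   stringsAsFactors = FALSE)
      }
    })
    tab <- do.call(rbind, cand_rows)
    ord <- order(-tab$identity_pct, tab$subject_id)
    row <- tab[if (tie) ord[1] else 1L, , drop = FALSE]
    row$tie <- tie
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
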