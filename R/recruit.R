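#' Mask rRNA intervals in a genome
#'
#' Replaces every base inside the genome's rRNA intervals with `N`,
#' preserving total length. Because highly conserved rRNA genes recruit
#' reads from unrelated organisms, they are masked before fragment
#' recruitment so that hit counts reflect genome-specific sequence only;
#' `N` never matches in the alignment engine, so masked regions cannot
#' recruit.
#'
#' @param genome a [sim_genome()] (or a plain sequence plus `intervals`).
#' @param intervals optional data.frame (`start`, `end`, 0-based half-open)
#'   overriding the genome's own annotation.
#' @return the masked sequence as a single character string.
#' @export
mask_rrna <- function(genome, intervals = NULL) {
  if (is(genome, "sim_genome")) {
    seq <- genome$sequence
    if (is.null(intervals)) intervals <- genome$rrna_intervals
  } else {
    seq <- as_dna_character(genome)
    if (is.null(intervals)) intervals <- data.frame(start = integer(),
                                                    end = integer())
  }
  L <- nchar(seq)
  if (nrow(intervals) == 0L) return(seq)
  if (any(intervals$start < 0 | intervals$end > L |
          intervals$start > intervals$end))
    stop("mask intervals out of genome bounds")
  for (i in seq_len(nrow(intervals))) {
    w <- intervals$end[i] - intervals$start[i]
    if (w > 0)
      substr(seq, intervals$start[i] + 1L, intervals$end[i]) <- strrep("N", w)
  }
  seq
}

#' Recruit metagenomic reads to a (masked) genome
#'
#' Fragment recruitment: each read's best local alignment against the
#' genome is kept only when it is at least `min_len` columns long, strictly
#' more than `min_identity` percent identical, and has an e-value at or
#' below `evalue_cutoff` -- thresholds that approximate species-level
#' divergence. At most one hit is counted per read (RPKG counts reads, not
#' alignments). The genome's rRNA intervals are masked first unless
#' `mask = FALSE`.
#'
#' The RPKG normalization uses the full genome length including masked
#' bases, and the metagenome size is the total base count of the read set
#' before any screening.
#'
#' @param reads a `read_set` or named `DNAStringSet`.
#' @param genome a [sim_genome()] or single sequence.
#' @param min_len minimum alignment length in columns; default 50.
#' @param min_identity identity threshold in percent, exclusive (a hit must
#'   exceed it); default 95.
#' @param evalue_cutoff maximum e-value; default 1e-5.
#' @param mask mask rRNA intervals before aligning.
#' @param scheme a [scoring_scheme()].
#' @param genome_id,metagenome_id labels for the profile row.
#' @return A `recruitment_profile`: list with `hits` (per-read hit table of
#'   recruited reads), `n_hits`, `genome_length`, `metagenome_size`, `rpkg`,
#'   and the ids.
#' @export
recruit_reads <- function(reads, genome, min_len = 50, min_identity = 95,
                          evalue_cutoff = 1e-5, mask = TRUE,
                          scheme = scoring_scheme(),
                          genome_id = NULL, metagenome_id = "metagenome") {
  seqs <- if (is(reads, "read_set")) reads$reads else reads
  if (is(genome, "sim_genome")) {
    if (is.null(genome_id)) genome_id <- genome$id
    gseq <- if (mask) mask_rrna(genome) else genome$sequence
  } else {
    if (is.null(genome_id)) genome_id <- "genome"
    gseq <- as_dna_character(genome)
  }
  if (nchar(gseq) == 0L) stop("empty genome sequence")
  genome_length <- nchar(gseq)
  metagenome_size <- sum(Biostrings::width(seqs))
  subj <- Biostrings::DNAStringSet(stats::setNames(gseq, genome_id))
  hits <- best_hits(seqs, subj, scheme = scheme, db_len = genome_length,
                    details = TRUE)
  keep <- !is.na(hits$aln_length) &
    hits$aln_length >= min_len &
    hits$identity_pct > min_identity &
    hits$e_value <= evalue_cutoff
  hits <- hits[keep, setdiff(names(hits), "tie"), drop = FALSE]
  rownames(hits) <- NULL
  n_hits <- nrow(hits)
  structure(list(hits = hits, n_hits = n_hits,
                 genome_id = genome_id, metagenome_id = metagenome_id,
                 genome_length = genome_length,
                 metagenome_size = metagenome_size,
                 rpkg = rpkg(n_hits, genome_length, metagenome_size)),
            class = "recruitment_profile")
}

#' @export
print.recruitment_profile <- function(x, ...) {
  cat(sprintf("<recruitment_profile> %s vs %s: %d hits, RPKG %.4g\n",
              x$genome_id, x$metagenome_id, x$n_hits, x$rpkg))
  invisible(x)
}

#' Reads recruited per kilobase of genome per gigabase of metagenome
#'
#' `RPKG = n_hits / (genome_length / 1000) / (metagenome_size / 1e9)`: a
#' size-normalized abundance measure comparable across genomes and
#' metagenomes of different sizes. Doubling the metagenome (hits and size
#' both double) leaves it unchanged.
#'
#' @param n_hits recruited read count (>= 0).
#' @param genome_length genome length in bp (> 0).
#' @param metagenome_size metagenome size in bp (> 0).
#' @return RPKG value in hits per kb per Gb.
#' @examples
#' rpkg(500, 2e6, 5e9) # 0.05
#' @export
rpkg <- function(n_hits, genome_length, metagenome_size) {
  if (any(genome_length <= 0) || any(metagenome_size <= 0))
    stop("`genome_length` and `metagenome_size` must be positive")
  n_hits / (genome_length / 1000) / (metagenome_size / 1e9)
}
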