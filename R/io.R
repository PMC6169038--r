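#' Write sequences to FASTA
#'
#' @param x named character vector, `DNAStringSet`, `reference_db` or
#'   `sim_genome`.
#' @param path output file.
#' @param header_comment optional comment line(s) written as `; `-prefixed
#'   header (used to record seeds).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, header_comment = NULL) {
  if (is(x, "reference_db")) {
    names(x$sequences) <- sprintf(
      "%s %s;%s;%s;%s", x$lineage$id, x$lineage$domain, x$lineage$phylum,
      x$lineage$class, x$lineage$cluster)
    x <- x$sequences
  }
  if (is(x, "sim_genome")) x <- stats::setNames(x$sequence, x$id)
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (!is.null(header_comment)) {
    writeLines(paste0("; ", header_comment), path)
    Biostrings::writeXStringSet(x, path, append = TRUE)
  } else {
    Biostrings::writeXStringSet(x, path)
  }
  invisible(path)
}

#' Read a FASTA file into a named DNAStringSet
#'
#' Lineage-annotated headers of the form `id domain;phylum;class;cluster`
#' (as written by [write_fasta()] for a `reference_db`) are recognised and
#' returned as a `reference_db`; otherwise a plain `DNAStringSet` is
#' returned.
#'
#' @param path FASTA file.
#' @param as_reference_db parse lineage annotations from headers.
#' @return `DNAStringSet` or `reference_db`.
#' @export
read_fasta <- function(path, as_reference_db = FALSE) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!as_reference_db) {
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    return(seqs)
  }
  hdr <- names(seqs)
  id <- sub("\\s.*$", "", hdr)
  lin <- sub("^\\S+\\s+", "", hdr)
  parts <- strsplit(lin, ";", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop("headers do not carry domain;phylum;class;cluster annotations")
  lineage <- data.frame(id = id,
                        domain = vapply(parts, `[`, "", 1L),
                        phylum = vapply(parts, `[`, "", 2L),
                        class = vapply(parts, `[`, "", 3L),
                        cluster = vapply(parts, `[`, "", 4L),
                        stringsAsFactors = FALSE)
  names(seqs) <- id
  structure(list(sequences = seqs, lineage = lineage, seed = NA_integer_,
                 params = list()),
            class = "reference_db")
}

#' Write reads as FASTQ with constant quality
#'
#' Sanger Phred+33 encoding with a constant quality character (`"I"`,
#' Q40); the generator does not model quality, so a flat profile is the
#' honest choice.
#'
#' @param read_set a `read_set` (or named `DNAStringSet`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(read_set, path) {
  reads <- if (is(read_set, "read_set")) read_set$reads else read_set
  qual <- Biostrings::BStringSet(vapply(Biostrings::width(reads),
                                        function(w) strrep("I", w), ""))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read reads from FASTQ or FASTA
#' @param path input file; format sniffed from the first character.
#' @return named `DNAStringSet`.
#' @export
read_reads <- function(path) {
  first <- substr(readLines(path, n = 1L), 1, 1)
  fmt <- if (first == "@") "fastq" else "fasta"
  seqs <- Biostrings::readDNAStringSet(path, format = fmt)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a data frame as TSV
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a read-set truth table with the fixed column order
#'
#' Columns are `read_id, source_id, domain, phylum, class, cluster`,
#' in that order, which downstream tools and tests rely on.
#'
#' @param read_set a `read_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(read_set, path) {
  write_tsv(read_set$truth[, c("read_id", "source_id", "domain", "phylum",
                               "class", "cluster")], path)
}

#' Write rRNA intervals as BED
#'
#' Three-column BED (`chrom`, `start`, `end`), 0-based half-open -- the same
#' convention used internally, so coordinates pass through unchanged.
#'
#' @param genome a [sim_genome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rrna_bed <- function(genome, path) {
  iv <- genome$rrna_intervals
  bed <- data.frame(chrom = rep(genome$id, nrow(iv)), start = iv$start,
                    end = iv$end)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a 3-column BED file of rRNA intervals
#' @param path BED file.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_rrna_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  bed
}
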