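#' Synthetic inputs for pipeline validation
#'
#' The generators in this file produce every input the pipeline consumes --
#' lineage-annotated 16S reference databases, metagenomic read sets with a
#' known taxonomic composition, genome pairs at a controlled nucleotide
#' divergence, and cell-size populations -- together with ground-truth tables,
#' so that each downstream stage can be validated against known answers.
#'
#' The substitution model throughout is deliberately simple so that it has an
#' analytic oracle: each selected site is replaced by one of the three
#' alternative bases chosen uniformly (a Jukes-Cantor-like process). Two
#' sequences independently mutated from a common ancestor at per-site rate
#' `d` are then identical at a site with probability `(1-d)^2 + d^2/3`.
#'
#' @name synthetic-community
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

# Substitute each site independently with probability `d`; a substituted site
# receives one of the 3 alternative bases uniformly. Returns the mutated
# string with the realized substitution count as attribute "n_sub".
mutate_sequence <- function(seq, d) {
  if (d < 0 || d >= 0.5) stop("divergence must be in [0, 0.5)")
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < d)
  if (length(hit)) {
    cur <- match(v[hit], DNA_BASES4)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- DNA_BASES4[((cur - 1L + shift) %% 4L) + 1L]
  }
  structure(paste(v, collapse = ""), n_sub = length(hit))
}

#' Evolve a lineage-annotated synthetic 16S reference database
#'
#' Builds a taxonomically structured reference set by descent: a random root
#' sequence spawns one ancestor per cluster (mutated from the root at
#' `between_class_divergence`), and each cluster ancestor spawns
#' `seqs_per_class` sequences mutated at `per_class_divergence`. Clusters are
#' grouped into phyla (`clusters_per_phylum` consecutive clusters per
#' phylum), and each cluster carries its own class label, so lineages nest
#' cleanly: cluster implies class implies phylum implies domain.
#'
#' Within-cluster pairwise identity is higher in expectation than
#' between-cluster identity whenever `per_class_divergence <
#' between_class_divergence`; with the uniform-replacement substitution
#' model, two sequences at rate `d` from a common ancestor match at a site
#' with probability `(1-d)^2 + d^2/3`.
#'
#' @param root_length sequence length in nt (>= 500 for a 16S-like gene).
#' @param n_classes number of clusters (>= 2).
#' @param per_class_divergence per-site substitution rate from the cluster
#'   ancestor, in `[0, 0.5)`.
#' @param seqs_per_class sequences per cluster.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @param between_class_divergence per-site rate from root to each cluster
#'   ancestor, in `[0, 0.5)`.
#' @param domain domain label for every lineage.
#' @param clusters_per_phylum how many consecutive clusters share a phylum.
#' @return A `reference_db`: list with `sequences` (named `DNAStringSet`) and
#'   `lineage` (data.frame: id, domain, phylum, class, cluster).
#' @examples
#' db <- evolve_reference_db(600, 3, 0.02, 4, seed = 1)
#' db
#' @export
evolve_reference_db <- function(root_length = 1500L, n_classes, per_class_divergence,
                                seqs_per_class, seed,
                                between_class_divergence = 0.2,
                                domain = "Bacteria",
                                clusters_per_phylum = 2L) {
  if (n_classes < 2L) stop("`n_classes` must be >= 2")
  if (per_class_divergence < 0 || per_class_divergence >= 0.5)
    stop("`per_class_divergence` must be in [0, 0.5)")
  if (between_class_divergence < 0 || between_class_divergence >= 0.5)
    stop("`between_class_divergence` must be in [0, 0.5)")
  if (root_length < 500L)
    warning("synthetic 16S references are usually >= 500 nt")
  with_seed(seed, {
    root <- random_dna(root_length)
    seqs <- character(0)
    lin <- list()
    for (ci in seq_len(n_classes)) {
      cluster <- sprintf("CL%02d", ci)
      cls <- sprintf("Class%02d", ci)
      phy <- sprintf("Phylum%s", LETTERS[(ci - 1L) %/% clusters_per_phylum + 1L])
      anc <- mutate_sequence(root, between_class_divergence)
      for (si in seq_len(seqs_per_class)) {
        id <- sprintf("%s_%03d", cluster, si)
        seqs[[id]] <- as.character(mutate_sequence(anc, per_class_divergence))
        lin[[id]] <- data.frame(id = id, domain = domain, phylum = phy,
                                class = cls, cluster = cluster,
                                stringsAsFactors = FALSE)
      }
    }
    structure(list(sequences = Biostrings::DNAStringSet(unlist(seqs)),
                   lineage = do.call(rbind, c(lin, make.row.names = FALSE)),
                   seed = as.integer(seed),
                   params = list(root_length = root_length,
                                 n_classes = n_classes,
                                 per_class_divergence = per_class_divergence,
                                 between_class_divergence = between_class_divergence,
                                 seqs_per_class = seqs_per_class)),
              class = "reference_db")
  })
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %d sequences, %d clusters, %d phyla (seed %d)\n",
              length(x$sequences), length(unique(x$lineage$cluster)),
              length(unique(x$lineage$phylum)), x$seed))
  invisible(x)
}

#' Specify a synthetic community
#'
#' @param fractions named numeric vector: cluster label -> fraction of reads;
#'   must sum to 1 (tolerance 1e-9).
#' @param n_reads number of reads to draw (> 0).
#' @param read_length read length in nt.
#' @param error_rate per-base substitution probability in `[0, 0.25)`.
#' @param seed integer seed.
#' @param both_strands if `TRUE`, each read is reverse-complemented with
#'   probability 1/2; the default keeps all reads on the forward strand.
#' @return A `community_spec` object.
#' @export
community_spec <- function(fractions, n_reads, read_length = 100L,
                           error_rate = 0, seed = 1L, both_strands = FALSE) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("`fractions` must be a named vector of cluster labels")
  if (abs(sum(fractions) - 1) > 1e-9) stop("`fractions` must sum to 1")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (n_reads <= 0) stop("`n_reads` must be positive")
  if (error_rate < 0 || error_rate >= 0.25)
    stop("`error_rate` must be in [0, 0.25)")
  structure(list(fractions = fractions, n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, seed = as.integer(seed),
                 both_strands = isTRUE(both_strands)),
            class = "community_spec")
}

#' Simulate a metagenomic 16S read set with known composition
#'
#' Draws per-cluster read counts from a multinomial over `spec$fractions`,
#' picks a source sequence uniformly within each cluster, cuts a read at a
#' uniform start position on the forward strand, and applies i.i.d.
#' substitution errors at `spec$error_rate` (uniform replacement by one of
#' the 3 alternative bases). Read order is randomly permuted so downstream
#' stages cannot rely on grouping. Every read is recorded in a truth table.
#'
#' @param db a `reference_db` from [evolve_reference_db()].
#' @param spec a [community_spec()]. Every fraction label must be a cluster
#'   in `db`, and `read_length` must not exceed the shortest reference.
#' @return A `read_set`: list with `reads` (named `DNAStringSet`) and
#'   `truth` (data.frame: read_id, source_id, domain, phylum, class, cluster,
#'   start, strand, n_errors).
#' @export
simulate_reads <- function(db, spec) {
  stopifnot(is(db, "reference_db"), is(spec, "community_spec"))
  labs <- names(spec$fractions)
  known <- unique(db$lineage$cluster)
  missing <- setdiff(labs, known)
  if (length(missing))
    stop("unknown cluster label(s) in fractions: ", paste(missing, collapse = ", "))
  if (spec$read_length > min(Biostrings::width(db$sequences)))
    stop("`read_length` exceeds the shortest reference sequence")
  refs <- as.character(db$sequences)
  with_seed(spec$seed, {
    counts <- as.vector(rmultinom(1, spec$n_reads, spec$fractions))
    src_cluster <- rep(labs, counts)
    reads <- character(spec$n_reads)
    truth <- vector("list", spec$n_reads)
    rl <- spec$read_length
    by_cluster <- split(db$lineage$id, db$lineage$cluster)
    for (i in seq_len(spec$n_reads)) {
      ids <- by_cluster[[src_cluster[i]]]
      sid <- ids[sample.int(length(ids), 1L)]
      ref <- refs[[sid]]
      start <- sample.int(nchar(ref) - rl + 1L, 1L) - 1L # 0-based
      frag <- substr(ref, start + 1L, start + rl)
      n_err <- 0L
      if (spec$error_rate > 0) {
        mut <- mutate_sequence(frag, spec$error_rate)
        n_err <- attr(mut, "n_sub")
        frag <- as.character(mut)
      }
      strand <- "+"
      if (spec$both_strands && runif(1) < 0.5) {
        frag <- revcomp_chr(frag)
        strand <- "-"
      }
      reads[i] <- frag
      truth[[i]] <- data.frame(read_id = NA_character_, source_id = sid,
                               start = start, strand = strand,
                               n_errors = n_err, stringsAsFactors = FALSE)
    }
    perm <- sample.int(spec$n_reads)
    reads <- reads[perm]
    truth <- do.call(rbind, truth[perm])
    truth$read_id <- sprintf("read_%06d", seq_len(spec$n_reads))
    names(reads) <- truth$read_id
    truth <- merge(truth, db$lineage, by.x = "source_id", by.y = "id",
                   sort = FALSE)
    truth <- truth[order(truth$read_id),
                   c("read_id", "source_id", "domain", "phylum", "class",
                     "cluster", "start", "strand", "n_errors")]
    rownames(truth) <- NULL
    structure(list(reads = Biostrings::DNAStringSet(reads), truth = truth,
                   spec = spec),
              class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads of %d nt, error rate %g (seed %d)\n",
              length(x$reads), x$spec$read_length, x$spec$error_rate,
              x$spec$seed))
  invisible(x)
}

#' Construct a simulated genome with annotated intervals
#'
#' All intervals are 0-based half-open. rRNA intervals must be pairwise
#' disjoint and inside the sequence; gene intervals carry the true taxon of
#' each gene (used by the contig-taxonomy stage).
#'
#' @param id genome identifier.
#' @param sequence DNA string.
#' @param rrna_intervals data.frame with columns `start`, `end`, or `NULL`.
#' @param gene_intervals data.frame with `start`, `end`, `taxon`, or `NULL`.
#' @return A `sim_genome` object.
#' @export
sim_genome <- function(id, sequence, rrna_intervals = NULL,
                       gene_intervals = NULL) {
  sequence <- as_dna_character(sequence)
  L <- nchar(sequence)
  chk <- function(iv, what) {
    if (is.null(iv)) return(data.frame(start = integer(), end = integer()))
    if (any(iv$start < 0 | iv$end > L | iv$start > iv$end))
      stop(what, " intervals out of genome bounds")
    iv
  }
  rr <- chk(rrna_intervals, "rRNA")
  if (nrow(rr) > 1L) {
    o <- order(rr$start)
    if (any(rr$start[o][-1] < rr$end[o][-nrow(rr)]))
      stop("rRNA intervals must be pairwise disjoint")
  }
  gn <- if (is.null(gene_intervals))
    data.frame(start = integer(), end = integer(), taxon = character())
  else chk(gene_intervals, "gene")
  structure(list(id = id, sequence = sequence, rrna_intervals = rr,
                 gene_intervals = gn),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %s: %d bp, %d rRNA interval(s), %d gene(s)\n",
              x$id, nchar(x$sequence), nrow(x$rrna_intervals),
              nrow(x$gene_intervals)))
  invisible(x)
}

#' Generate a random genome, optionally with rRNA intervals
#'
#' @param length genome length in bp.
#' @param seed integer seed.
#' @param id genome identifier.
#' @param n_rrna number of evenly spaced rRNA intervals to annotate.
#' @param rrna_length length of each rRNA interval.
#' @return A [sim_genome()].
#' @export
random_genome <- function(length, seed, id = "genome", n_rrna = 0L,
                          rrna_length = 1500L) {
  with_seed(seed, {
    seq <- random_dna(length)
    rr <- NULL
    if (n_rrna > 0L) {
      if (n_rrna * rrna_length > length)
        stop("rRNA intervals do not fit in the genome")
      gap <- length %/% n_rrna
      start <- (seq_len(n_rrna) - 1L) * gap
      rr <- data.frame(start = start, end = start + rrna_length)
    }
    sim_genome(id, seq, rrna_intervals = rr)
  })
}

#' Mutate a genome at a controlled per-site substitution rate
#'
#' Applies the uniform-replacement substitution process to every site
#' independently. Sequence length and all interval annotations are preserved
#' exactly; the realized substitution count is recorded.
#'
#' @param genome a [sim_genome()].
#' @param divergence per-site substitution probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @param id identifier for the mutated genome.
#' @return A `sim_genome` whose attribute `"n_sub"` holds the realized
#'   substitution count.
#' @export
mutate_genome <- function(genome, divergence, seed,
                          id = paste0(genome$id, "_mut")) {
  stopifnot(is(genome, "sim_genome"))
  if (divergence < 0 || divergence >= 0.5)
    stop("divergence must be in [0, 0.5)")
  with_seed(seed, {
    mut <- mutate_sequence(genome$sequence, divergence)
    out <- sim_genome(id, as.character(mut),
                      rrna_intervals = if (nrow(genome$rrna_intervals)) genome$rrna_intervals,
                      gene_intervals = if (nrow(genome$gene_intervals)) genome$gene_intervals)
    attr(out, "n_sub") <- attr(mut, "n_sub")
    out
  })
}

#' Specify a cell population for morphometric simulation
#'
#' Distributions are given as `list(dist = "lognormal", meanlog =, sdlog =)`,
#' `list(dist = "normal", mean =, sd =)` or `list(dist = "fixed", value =)`;
#' all dimensions are in micrometers. For spheres only `length_dist` is used
#' (the diameter); width is set equal to length.
#'
#' @param label population label.
#' @param shape one of `"rod"`, `"sphere"`, `"ovoid"`.
#' @param n_cells number of cells (> 0).
#' @param length_dist,width_dist distribution specifications.
#' @param seed integer seed.
#' @return A `cell_population_spec`.
#' @export
cell_population_spec <- function(label, shape = c("rod", "sphere", "ovoid"),
                                 n_cells, length_dist, width_dist = NULL,
                                 seed = 1L) {
  shape <- match.arg(shape)
  if (n_cells <= 0) stop("`n_cells` must be positive")
  if (shape != "sphere" && is.null(width_dist))
    stop("rod/ovoid populations need a `width_dist`")
  structure(list(label = label, shape = shape, n_cells = as.integer(n_cells),
                 length_dist = length_dist, width_dist = width_dist,
                 seed = as.integer(seed)),
            class = "cell_population_spec")
}

sample_dist <- function(dist, n) {
  switch(dist$dist,
         lognormal = rlnorm(n, dist$meanlog, dist$sdlog),
         normal = rnorm(n, dist$mean, dist$sd),
         fixed = rep(dist$value, n),
         stop("unknown distribution: ", dist$dist))
}

#' Simulate a cell-measurement table
#'
#' Draws length and width for each cell from the population's distributions.
#' Draws that violate the shape constraints (non-positive dimensions, or
#' width exceeding length for rods/ovoids) are resampled up to 100 rounds;
#' if invalid draws remain, an error is raised.
#'
#' @param pops a list of [cell_population_spec()] objects (at least one).
#' @return data.frame with columns cell_id, population, shape, length_um,
#'   width_um; one row per cell.
#' @export
simulate_cells <- function(pops) {
  if (is(pops, "cell_population_spec")) pops <- list(pops)
  if (length(pops) == 0L) stop("at least one population is required")
  tabs <- lapply(pops, function(p) {
    with_seed(p$seed, {
      n <- p$n_cells
      len <- sample_dist(p$length_dist, n)
      wid <- if (p$shape == "sphere") len else sample_dist(p$width_dist, n)
      bad <- which(len <= 0 | wid <= 0 | (p$shape != "sphere" & wid > len))
      tries <- 0L
      while (length(bad) && tries < 100L) {
        len[bad] <- sample_dist(p$length_dist, length(bad))
        wid[bad] <- if (p$shape == "sphere") len[bad]
                    else sample_dist(p$width_dist, length(bad))
        bad <- which(len <= 0 | wid <= 0 | (p$shape != "sphere" & wid > len))
        tries <- tries + 1L
      }
      if (length(bad))
        stop("could not sample valid dimensions for population ", p$label)
      data.frame(cell_id = sprintf("%s_%04d", p$label, seq_len(n)),
                 population = p$label, shape = p$shape,
                 length_um = len, width_um = wid, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
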