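#' Default end-to-end run configuration
#'
#' One nested list with a section per stage. All thresholds default to the
#' pipeline's canonical values: screening e-value 1e-5 with at most 1e7
#' reads, classification at >= 80% identity over >= 90 bp, contigs strictly
#' longer than 5 kb, recruitment at >= 50 bp / > 95% identity / e-value
#' <= 1e-5, ANI on 1020-nt fragments at >= 70% identity over >= 70%
#' coverage with species linked above 95%, and database reduction at 85%
#' identity. Every stage draws its randomness from a seed derived
#' deterministically from the single master seed, so toggling one stage off
#' does not change another stage's stream.
#'
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, reduce_db = TRUE, classify = TRUE,
                  contig_tax = TRUE, recruit = TRUE, ani = TRUE,
                  morphometrics = TRUE),
    reference = list(root_length = 1200L, n_classes = 4L,
                     per_class_divergence = 0.02,
                     between_class_divergence = 0.2, seqs_per_class = 4L),
    community = list(fractions = NULL, # NULL: uniform over clusters
                     n_reads = 400L, read_length = 100L, error_rate = 0.005),
    reduce_db = list(threshold = 0.85),
    classify = list(evalue = 1e-5, min_identity = 80, min_aln = 90,
                    max_reads = 1e7, focal_phylum = "PhylumA"),
    contig_tax = list(target_phylum = "Chloroflexi", min_length = 5000,
                      n_contigs = 40L),
    recruit = list(min_len = 50, min_identity = 95, evalue = 1e-5,
                   genome_length = 20000L, n_rrna = 1L, rrna_length = 1500L,
                   n_reads = 300L, read_length = 100L, divergence = 0.01),
    ani = list(frag_len = 1020L, min_id = 70, min_cov = 0.7,
               species_threshold = 95, genome_length = 10000L,
               divergences = c(0.02, 0.08)),
    morphometrics = list(
      focal = list(label = "CL500-11", shape = "rod", n_cells = 277L,
                   length_dist = list(dist = "lognormal",
                                      meanlog = log(0.92) - 0.3^2 / 2,
                                      sdlog = 0.3),
                   width_dist = list(dist = "lognormal",
                                     meanlog = log(0.28) - 0.15^2 / 2,
                                     sdlog = 0.15)),
      background = list(label = "all_prokaryotes", shape = "rod",
                        n_cells = 3789L,
                        length_dist = list(dist = "lognormal",
                                           meanlog = log(0.6) - 0.35^2 / 2,
                                           sdlog = 0.35),
                        width_dist = list(dist = "lognormal",
                                          meanlog = log(0.35) - 0.2^2 / 2,
                                          sdlog = 0.2))))
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the configured stages in dependency order on synthetic inputs,
#' writing each stage's outputs into its own subdirectory of `out_dir`
#' (FASTA/FASTQ/TSV) plus a YAML `manifest.yaml` recording the package
#' version, master and derived seeds, per-stage counts and an md5 digest of
#' every output file. Identical configuration and seed give byte-identical
#' outputs; stages never modify another stage's files.
#'
#' @param config a configuration list ([default_config()]), or the path of
#'   a YAML file holding one.
#' @param out_dir run directory (created if needed).
#' @param verbose print a log line per stage.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         verbose = TRUE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(package_version = as.character(utils::packageVersion("metalineage")),
                   seed = cfg$seed, stages = list())
  stage_dir <- function(name) {
    d <- file.path(out_dir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }
  outputs <- character(0)

  db <- NULL; reads <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    d <- stage_dir("simulate")
    sseed <- derive_seed(cfg$seed, "simulate")
    rf <- cfg$reference
    db <- evolve_reference_db(rf$root_length, rf$n_classes,
                              rf$per_class_divergence, rf$seqs_per_class,
                              seed = sseed,
                              between_class_divergence = rf$between_class_divergence)
    cm <- cfg$community
    fr <- cm$fractions
    if (is.null(fr)) {
      cl <- unique(db$lineage$cluster)
      fr <- stats::setNames(rep(1 / length(cl), length(cl)), cl)
    } else {
      fr <- unlist(fr)
    }
    reads <- simulate_reads(db, community_spec(fr, cm$n_reads,
                                               cm$read_length, cm$error_rate,
                                               seed = derive_seed(cfg$seed, "reads")))
    write_fasta(db, file.path(d, "reference_db.fasta"),
                header_comment = sprintf("seed=%d", sseed))
    write_reads_fastq(reads, file.path(d, "reads.fastq"))
    write_truth_tsv(reads, file.path(d, "truth.tsv"))
    outputs <- c(outputs, file.path(d, c("reference_db.fasta", "reads.fastq",
                                         "truth.tsv")))
    manifest$stages$simulate <- list(seed = sseed,
                                     n_references = length(db$sequences),
                                     n_reads = length(reads$reads))
    say("simulate: %d references, %d reads", length(db$sequences),
        length(reads$reads))
  }

  reduced <- NULL
  if (isTRUE(cfg$stages$reduce_db) && !is.null(db)) {
    d <- stage_dir("reduce_db")
    reduced <- greedy_cluster(db, threshold = cfg$reduce_db$threshold)
    write_reduced_db(reduced, file.path(d, "centroids.fasta"),
                     file.path(d, "membership.tsv"))
    outputs <- c(outputs, file.path(d, c("centroids.fasta", "membership.tsv")))
    manifest$stages$reduce_db <- list(n_centroids = length(reduced$centroids),
                                      threshold = cfg$reduce_db$threshold)
    say("reduce_db: %d centroids", length(reduced$centroids))
  }

  if (isTRUE(cfg$stages$classify) && !is.null(reduced)) {
    d <- stage_dir("classify")
    domain_refs <- synthetic_domain_refs(derive_seed(cfg$seed, "domains"),
                                         bacterial_db = db)
    cl <- cfg$classify
    res <- classify_pipeline(reads, reduced, domain_refs, db,
                             evalue_cutoff = cl$evalue,
                             min_identity = cl$min_identity,
                             min_aln = cl$min_aln, max_reads = cl$max_reads,
                             focal_phylum = cl$focal_phylum)
    write_tsv(res$assignments, file.path(d, "assignments.tsv"))
    write_tsv(res$profile$profile, file.path(d, "profile.tsv"))
    write_tsv(res$profile$focal, file.path(d, "focal_subclusters.tsv"))
    outputs <- c(outputs, file.path(d, c("assignments.tsv", "profile.tsv",
                                         "focal_subclusters.tsv")))
    manifest$stages$classify <- as.list(res$counts)
    say("classify: %d/%d reads assigned", res$counts[["assigned"]],
        res$counts[["examined"]])
  }

  if (isTRUE(cfg$stages$contig_tax)) {
    d <- stage_dir("contig_tax")
    ct <- cfg$contig_tax
    hits <- simulate_contig_hits(n_contigs = ct$n_contigs,
                                 target_phylum = ct$target_phylum,
                                 seed = derive_seed(cfg$seed, "contigs"))
    dec <- assign_contigs(hits, ct$target_phylum, min_length = ct$min_length)
    write_tsv(hits, file.path(d, "gene_hits.tsv"))
    write_tsv(dec, file.path(d, "contig_taxonomy.tsv"))
    outputs <- c(outputs, file.path(d, c("gene_hits.tsv", "contig_taxonomy.tsv")))
    manifest$stages$contig_tax <- as.list(table(dec$decision))
    say("contig_tax: %s", paste(names(table(dec$decision)),
                                table(dec$decision), sep = "=", collapse = ", "))
  }

  if (isTRUE(cfg$stages$recruit)) {
    d <- stage_dir("recruit")
    rc <- cfg$recruit
    g <- random_genome(rc$genome_length, derive_seed(cfg$seed, "recruit_genome"),
                       id = "target_genome", n_rrna = rc$n_rrna,
                       rrna_length = rc$rrna_length)
    gdb <- structure(list(sequences = Biostrings::DNAStringSet(
                            stats::setNames(g$sequence, g$id)),
                          lineage = data.frame(id = g$id, domain = "Bacteria",
                                               phylum = "SimPhylum",
                                               class = "SimClass",
                                               cluster = "SIM"),
                          seed = NA_integer_, params = list()),
                     class = "reference_db")
    rreads <- simulate_reads(gdb, community_spec(c(SIM = 1), rc$n_reads,
                                                 rc$read_length,
                                                 error_rate = rc$divergence,
                                                 seed = derive_seed(cfg$seed, "recruit_reads")))
    prof <- recruit_reads(rreads, g, min_len = rc$min_len,
                          min_identity = rc$min_identity,
                          evalue_cutoff = rc$evalue)
    write_fasta(g, file.path(d, "genome.fasta"))
    write_rrna_bed(g, file.path(d, "rrna.bed"))
    write_reads_fastq(rreads, file.path(d, "reads.fastq"))
    write_tsv(hits_as_outfmt6(prof$hits), file.path(d, "hits.tsv"))
    write_tsv(data.frame(genome_id = prof$genome_id,
                         metagenome_id = prof$metagenome_id,
                         n_hits = prof$n_hits,
                         genome_length = prof$genome_length,
                         metagenome_size = prof$metagenome_size,
                         rpkg = prof$rpkg),
              file.path(d, "rpkg.tsv"))
    outputs <- c(outputs, file.path(d, c("genome.fasta", "rrna.bed",
                                         "reads.fastq", "hits.tsv", "rpkg.tsv")))
    manifest$stages$recruit <- list(n_hits = prof$n_hits, rpkg = prof$rpkg)
    say("recruit: %d hits, RPKG %.4g", prof$n_hits, prof$rpkg)
  }

  if (isTRUE(cfg$stages$ani)) {
    d <- stage_dir("ani")
    an <- cfg$ani
    base <- random_genome(an$genome_length, derive_seed(cfg$seed, "ani_genome"),
                          id = "genome_A")
    genomes <- c(list(genome_A = base),
                 stats::setNames(lapply(seq_along(an$divergences), function(i)
                   mutate_genome(base, an$divergences[i],
                                 seed = derive_seed(cfg$seed, paste0("ani_mut", i)),
                                 id = sprintf("genome_%s", LETTERS[i + 1]))),
                   sprintf("genome_%s", LETTERS[seq_along(an$divergences) + 1])))
    m <- ani_matrix(genomes, frag_len = an$frag_len, min_id = an$min_id,
                    min_cov = an$min_cov)
    sp <- species_clusters(m, threshold = an$species_threshold)
    write_tsv(as.data.frame(m$ani), file.path(d, "ani_matrix.tsv"))
    write_tsv(data.frame(genome_id = names(sp$membership),
                         species = sp$membership),
              file.path(d, "species_clusters.tsv"))
    outputs <- c(outputs, file.path(d, c("ani_matrix.tsv",
                                         "species_clusters.tsv")))
    manifest$stages$ani <- list(n_genomes = length(genomes),
                                n_species = length(sp$clusters))
    say("ani: %d genomes -> %d species", length(genomes), length(sp$clusters))
  }

  if (isTRUE(cfg$stages$morphometrics)) {
    d <- stage_dir("morphometrics")
    mo <- cfg$morphometrics
    pops <- lapply(mo, function(p)
      cell_population_spec(p$label, p$shape, p$n_cells, p$length_dist,
                           p$width_dist,
                           seed = derive_seed(cfg$seed, paste0("cells_", p$label))))
    cells <- simulate_cells(pops)
    bm <- biomass_share(cells, mo$focal$label)
    write_tsv(cells, file.path(d, "cells.tsv"))
    write_tsv(data.frame(population = bm$focal_population,
                         abundance_pct = bm$abundance_pct,
                         biomass_pct = bm$biomass_pct, ratio = bm$ratio,
                         volume_median = bm$focal$volume_median,
                         volume_p5 = bm$focal$volume_p5,
                         volume_p95 = bm$focal$volume_p95),
              file.path(d, "biomass.tsv"))
    outputs <- c(outputs, file.path(d, c("cells.tsv", "biomass.tsv")))
    manifest$stages$morphometrics <- list(n_cells = nrow(cells),
                                          ratio = bm$ratio)
    say("morphometrics: %d cells, biomass/abundance ratio %.2f",
        nrow(cells), bm$ratio)
  }

  digests <- tools::md5sum(outputs)
  manifest$outputs <- as.list(stats::setNames(unname(digests),
                                              sub(paste0("^", out_dir, "/?"), "",
                                                  outputs)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Synthetic domain reference sets for read validation
#'
#' Builds small archaeal / bacterial / eukaryotic representative rRNA sets.
#' Each domain descends from an independent random root (independent random
#' sequences are ~25% identical, far beyond the divergence at which domain
#' assignment is reliable). When a bacterial `reference_db` is supplied, one
#' representative per cluster is taken from it, so reads simulated from any
#' part of that database validate as bacterial.
#'
#' @param seed integer seed.
#' @param n_per_domain representatives per domain.
#' @param ref_length reference length in nt.
#' @param bacterial_db optional `reference_db` whose sequences (first
#'   `n_per_domain`) become the bacterial representatives.
#' @return named list of `DNAStringSet`s: `archaeal`, `bacterial`,
#'   `eukaryotic`.
#' @export
synthetic_domain_refs <- function(seed, n_per_domain = 3L, ref_length = 1500L,
                                  bacterial_db = NULL) {
  mk <- function(dseed, prefix) {
    db <- evolve_reference_db(ref_length, 2L, 0.05,
                              ceiling(n_per_domain / 2), seed = dseed)
    seqs <- db$sequences[seq_len(n_per_domain)]
    names(seqs) <- paste0(prefix, seq_len(n_per_domain))
    seqs
  }
  bact <- if (!is.null(bacterial_db)) {
    reps <- vapply(split(bacterial_db$lineage$id, bacterial_db$lineage$cluster),
                   `[`, "", 1L)
    bacterial_db$sequences[reps]
  } else {
    mk(derive_seed(seed, "bacterial"), "bact_")
  }
  list(archaeal = mk(derive_seed(seed, "archaeal"), "arch_"),
       bacterial = bact,
       eukaryotic = mk(derive_seed(seed, "eukaryotic"), "euk_"))
}
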