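#' Majority-vote taxonomy for one contig
#'
#' A contig is assigned to the target phylum when strictly more than half of
#' its genes *with hits* give their best hit to that phylum. Contigs at or
#' below the length cutoff are set aside as `too_short` ("longer than 5 kb"
#' is read strictly: a 5000-nt contig is too short, a 5001-nt contig is
#' considered). Genes without any hit are excluded from the denominator; the
#' vote counts are returned so that choice is auditable per contig.
#'
#' @param contig_length contig length in nt (> 0).
#' @param gene_hits character vector of best-hit phylum per gene, `NA` for
#'   genes without a hit.
#' @param target_phylum phylum label to vote for.
#' @param min_length length cutoff in nt; default 5000 (strictly greater
#'   passes).
#' @return list with `decision` (`"assigned"`, `"unassigned"` or
#'   `"too_short"`), `n_genes`, `n_with_hits`, `n_target`.
#' @examples
#' assign_contig(10000, c("Chloroflexi", "Chloroflexi", "Chloroflexi",
#'                        "Proteobacteria", NA), "Chloroflexi")
#' @export
assign_contig <- function(contig_length, gene_hits, target_phylum,
                          min_length = 5000) {
  if (contig_length <= 0) stop("`contig_length` must be positive")
  n_genes <- length(gene_hits)
  with_hits <- !is.na(gene_hits) & nzchar(gene_hits)
  n_with <- sum(with_hits)
  n_target <- sum(gene_hits[with_hits] == target_phylum)
  decision <- if (contig_length <= min_length) {
    "too_short"
  } else if (n_with > 0L && n_target > n_with / 2) {
    "assigned"
  } else {
    "unassigned"
  }
  list(decision = decision, n_genes = n_genes, n_with_hits = n_with,
       n_target = n_target)
}

#' Majority-vote taxonomy for a table of contigs
#'
#' Vectorised driver for [assign_contig()] over a long-format gene-hit table
#' (one row per gene), the shape produced by protein homology searches of
#' predicted genes.
#'
#' @param hits data.frame with columns `contig_id`, `contig_length`,
#'   `gene_id`, `best_hit_phylum` (`NA` or `""` for hitless genes). Gene ids
#'   must be unique within a contig.
#' @inheritParams assign_contig
#' @return data.frame with one row per contig: contig_id, contig_length,
#'   n_genes, n_with_hits, n_target, decision.
#' @export
assign_contigs <- function(hits, target_phylum, min_length = 5000) {
  needed <- c("contig_id", "contig_length", "gene_id", "best_hit_phylum")
  if (!all(needed %in% names(hits)))
    stop("`hits` must have columns: ", paste(needed, collapse = ", "))
  dup <- tapply(hits$gene_id, hits$contig_id, anyDuplicated)
  if (any(dup > 0)) stop("gene ids must be unique within a contig")
  res <- lapply(split(hits, hits$contig_id), function(h) {
    a <- assign_contig(h$contig_length[1], h$best_hit_phylum, target_phylum,
                       min_length = min_length)
    data.frame(contig_id = h$contig_id[1], contig_length = h$contig_length[1],
               n_genes = a$n_genes, n_with_hits = a$n_with_hits,
               n_target = a$n_target, decision = a$decision,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Simulate a contig gene-hit table with known phylum composition
#'
#' Generates contigs whose genes hit the target phylum with a per-contig
#' probability, emulating the input of the contig-taxonomy stage with a
#' known ground truth.
#'
#' @param n_contigs number of contigs.
#' @param target_phylum label used for target hits.
#' @param other_phyla labels sampled for non-target hits.
#' @param p_target_range range of the per-contig probability that a gene
#'   hits the target phylum.
#' @param p_no_hit probability that a gene has no hit at all.
#' @param length_range contig length range in nt.
#' @param genes_range number of genes per contig.
#' @param seed integer seed.
#' @return data.frame in the layout expected by [assign_contigs()], plus a
#'   `p_target` truth column.
#' @export
simulate_contig_hits <- function(n_contigs = 50, target_phylum = "Chloroflexi",
                                 other_phyla = c("Proteobacteria",
                                                 "Actinobacteria",
                                                 "Bacteroidetes"),
                                 p_target_range = c(0.1, 0.9),
                                 p_no_hit = 0.1,
                                 length_range = c(2000, 20000),
                                 genes_range = c(3, 15), seed = 1L) {
  with_seed(seed, {
    tabs <- lapply(seq_len(n_contigs), function(i) {
      ng <- sample(genes_range[1]:genes_range[2], 1)
      p <- runif(1, p_target_range[1], p_target_range[2])
      hit <- ifelse(runif(ng) < p_no_hit, NA_character_,
                    ifelse(runif(ng) < p, target_phylum,
                           sample(other_phyla, ng, replace = TRUE)))
      data.frame(contig_id = sprintf("contig_%03d", i),
                 contig_length = sample(length_range[1]:length_range[2], 1),
                 gene_id = sprintf("gene_%03d_%02d", i, seq_len(ng)),
                 best_hit_phylum = hit, p_target = p,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, tabs)
  })
}
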