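# Shared fixtures: a 4-cluster database (clusters CL01..CL04, phyla
# PhylumA/PhylumB), its 85% reduced set, and domain references seeded from it.
cls_db <- make_test_db(seed = 11)
cls_red <- greedy_cluster(cls_db, 0.85)
cls_domains <- synthetic_domain_refs(99, ref_length = 800,
                                     bacterial_db = cls_db)

test_that("reads matching a centroid are candidates; unalignable reads are not", {
  cent <- as.character(cls_red$centroids[[1]])
  reads <- Biostrings::DNAStringSet(c(
    hit = substr(cent, 101, 200),
    miss = random_seq(100)))
  set.seed(31)
  scr <- screen_reads(reads, cls_red)
  expect_true(scr$passed_screen[scr$read_id == "hit"])
  expect_false(scr$passed_screen[scr$read_id == "miss"])
  # empty input is a result, not an error
  expect_equal(nrow(screen_reads(Biostrings::DNAStringSet(), cls_red)), 0L)
})

test_that("screening recovers true 16S reads and matches a full-database oracle on impostors", {
  rs <- simulate_reads(cls_db, community_spec(
    c(CL01 = 0.25, CL02 = 0.25, CL03 = 0.25, CL04 = 0.25), 200, 100, 0.01,
    seed = 32))
  set.seed(33)
  noise <- Biostrings::DNAStringSet(stats::setNames(
    replicate(200, random_seq(100)), sprintf("noise_%03d", 1:200)))
  reads <- c(rs$reads, noise)
  scr <- screen_reads(reads, cls_red)
  true_ids <- names(rs$reads)
  recovered <- mean(scr$passed_screen[match(true_ids, scr$read_id)])
  expect_gte(recovered, 0.99)
  # oracle: screen impostors against the complete, unreduced database
  full_hits <- metalineage:::best_hits(noise, cls_db$sequences,
                         db_len = sum(Biostrings::width(cls_db$sequences)),
                         details = FALSE)
  oracle_false <- sum(full_hits$e_value <= 1e-5)
  got_false <- sum(scr$passed_screen[match(names(noise), scr$read_id)])
  expect_equal(got_false, oracle_false)
})

test_that("max_reads caps the number of reads examined", {
  rs <- simulate_reads(cls_db, community_spec(c(CL01 = 1), 30, 80, 0,
                                              seed = 34))
  scr <- screen_reads(rs, cls_red, max_reads = 10)
  expect_equal(nrow(scr), 10L)
})

test_that("domain validation separates the three domains and flags noise", {
  # 60 reads per domain, simulated from each domain's own reference pool
  mk_reads <- function(refs, prefix, seed) {
    db <- single_genome_db(sim_genome(prefix, as.character(refs[[1]])))
    rs <- simulate_reads(db, community_spec(c(SIM = 1), 60, 100, 0.01,
                                            seed = seed))
    stats::setNames(rs$reads, paste0(prefix, "_", names(rs$reads)))
  }
  reads <- c(mk_reads(cls_domains$archaeal, "arch", 41),
             mk_reads(cls_domains$bacterial, "bact", 42),
             mk_reads(cls_domains$eukaryotic, "euk", 43))
  val <- validate_domain(reads, cls_domains)
  truth <- sub("_read.*$", "", val$read_id)
  map <- c(arch = "archaeal", bact = "bacterial", euk = "eukaryotic")
  expect_gte(mean(val$domain_call == map[truth]), 0.95)
  # uniformly random sequence -> non_rrna
  set.seed(44)
  v <- validate_domain(Biostrings::DNAStringSet(c(r1 = random_seq(100))),
                       cls_domains)
  expect_equal(v$domain_call, "non_rrna")
  expect_error(validate_domain(reads, cls_domains[c("archaeal", "bacterial")]),
               "domain_refs")
})

test_that("classification assigns error-free reads to their source class", {
  rs <- simulate_reads(cls_db, community_spec(
    c(CL01 = 0.5, CL03 = 0.5), 60, 100, 0, seed = 51))
  val <- validate_domain(rs$reads, cls_domains)
  asg <- classify_reads(rs$reads, val, cls_db)
  m <- match(rs$truth$read_id, asg$read_id)
  expect_true(all(asg$assigned[m]))
  expect_equal(asg$cluster[m], rs$truth$cluster)
})

test_that("short alignments and low identities are discarded with reasons", {
  src <- as.character(cls_db$sequences[[1]])
  short_read <- substr(src, 1, 80) # full-length alignment of only 80 columns
  set.seed(52)
  far <- sim_genome("far", src)
  diverged <- substr(mutate_genome(far, 0.25, seed = 53)$sequence, 1, 300)
  reads <- Biostrings::DNAStringSet(c(short = short_read, far = diverged))
  val <- validate_domain(reads, cls_domains)
  # force both through to the classifier regardless of the validation call
  val$domain_call <- "bacterial"
  asg <- classify_reads(reads, val, cls_db)
  expect_false(asg$assigned[asg$read_id == "short"])
  expect_equal(asg$discard_reason[asg$read_id == "short"], "short_alignment")
  expect_false(asg$assigned[asg$read_id == "far"])
  expect_equal(asg$discard_reason[asg$read_id == "far"], "low_identity")
})

test_that("profiles conserve counts, sum to 100%, and ignore read order", {
  rs <- simulate_reads(cls_db, community_spec(
    c(CL01 = 0.2, CL02 = 0.3, CL03 = 0.5), 150, 100, 0.005, seed = 61))
  res <- classify_pipeline(rs, cls_red, cls_domains, cls_db,
                           focal_phylum = "PhylumA")
  prof <- res$profile
  expect_equal(sum(prof$profile$pct_of_prokaryotes), 100, tolerance = 1e-9)
  # sub-cluster counts sum to the focal phylum count
  focal_total <- prof$profile$reads[prof$profile$taxon == "PhylumA"]
  expect_equal(sum(prof$focal$reads), focal_total)
  # read partition: assigned + discarded = candidates; + non-candidates = all
  expect_equal(res$counts[["assigned"]] + res$counts[["discarded"]],
               res$counts[["candidates"]])
  expect_equal(res$counts[["candidates"]] + res$counts[["non_candidates"]],
               res$counts[["examined"]])
  # permuting reads leaves the profile unchanged
  set.seed(62)
  perm <- sample(length(rs$reads))
  asg2 <- classify_pipeline(
    rs$reads[perm], cls_red, cls_domains, cls_db,
    focal_phylum = "PhylumA")$profile
  expect_equal(asg2$profile[order(asg2$profile$taxon), ],
               prof$profile[order(prof$profile$taxon), ],
               ignore_attr = TRUE)
  # zero denominator yields an explicit empty profile
  empty <- community_profile(res$assignments[0, ], focal_phylum = "PhylumA")
  expect_equal(empty$denominator, 0L)
  expect_equal(nrow(empty$profile), 0L)
})

test_that("a 10% focal cluster is recovered within binomial error", {
  n <- 2000
  rs <- simulate_reads(cls_db, community_spec(
    c(CL01 = 0.10, CL02 = 0.30, CL03 = 0.30, CL04 = 0.30), n, 100, 0.005,
    seed = 63))
  res <- classify_pipeline(rs, cls_red, cls_domains, cls_db,
                           focal_phylum = "PhylumA")
  est <- res$profile$focal$pct_of_prokaryotes[res$profile$focal$cluster == "CL01"]
  se <- 100 * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(est - 10), 3 * se)
})
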