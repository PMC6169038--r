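test_that("zero within-class divergence gives identical sequences per cluster", {
  db <- evolve_reference_db(600, 3, 0, 4, seed = 2)
  for (cl in unique(db$lineage$cluster)) {
    ids <- db$lineage$id[db$lineage$cluster == cl]
    seqs <- as.character(db$sequences[ids])
    expect_length(unique(seqs), 1L)
  }
})

test_that("the reference generator is byte-identical under a fixed seed", {
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(evolve_reference_db(1500, 4, 0.10, 5, seed = 7), f1)
  write_fasta(evolve_reference_db(1500, 4, 0.10, 5, seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed changes the output
  f3 <- tempfile(fileext = ".fasta")
  write_fasta(evolve_reference_db(1500, 4, 0.10, 5, seed = 8), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("within-class identity matches the substitution-process expectation", {
  # two sequences independently mutated from a common ancestor at rate d
  # agree at a site with probability (1-d)^2 + d^2/3
  d <- 0.10
  db <- evolve_reference_db(1500, 5, d, 20, seed = 13)
  # 50 disjoint within-class pairs, measured by direct Hamming counts
  idents <- unlist(lapply(split(db$lineage$id, db$lineage$cluster), function(ids) {
    vapply(seq(1, 19, by = 2), function(i) {
      hamming_identity(as.character(db$sequences[[ids[i]]]),
                       as.character(db$sequences[[ids[i + 1]]]))
    }, 1)
  }))
  expect_length(idents, 50L)
  p <- (1 - d)^2 + d^2 / 3
  se <- sqrt(p * (1 - p) / (1500 * 50))
  expect_lt(abs(mean(idents) - p), 3 * se)
  # and within-class identity exceeds between-class identity
  by_cl <- split(db$lineage$id, db$lineage$cluster)
  between <- hamming_identity(as.character(db$sequences[[by_cl[[1]][1]]]),
                              as.character(db$sequences[[by_cl[[2]][1]]]))
  expect_gt(mean(idents), between)
})

test_that("generator rejects out-of-range divergences", {
  expect_error(evolve_reference_db(600, 3, 0.6, 4, seed = 1), "0.5")
  expect_error(evolve_reference_db(600, 1, 0.1, 4, seed = 1), "n_classes")
})

test_that("a single-taxon community yields an all-X truth table of the right size", {
  db <- make_test_db()
  rs <- simulate_reads(db, community_spec(c(CL01 = 1), 100, 80, 0, seed = 3))
  expect_equal(nrow(rs$truth), 100L)
  expect_equal(length(rs$reads), 100L)
  expect_true(all(rs$truth$cluster == "CL01"))
})

test_that("error-free reads are exact substrings of their source references", {
  db <- make_test_db()
  rs <- simulate_reads(db, community_spec(c(CL01 = 0.5, CL02 = 0.5), 50, 90,
                                          0, seed = 4))
  refs <- as.character(db$sequences)
  for (i in seq_len(50)) {
    src <- refs[[rs$truth$source_id[i]]]
    expect_true(grepl(as.character(rs$reads[[rs$truth$read_id[i]]]), src,
                      fixed = TRUE))
  }
})

test_that("realized taxon counts follow the multinomial within 3 SE", {
  db <- make_test_db()
  fr <- c(CL01 = 0.10, CL02 = 0.90)
  rs <- simulate_reads(db, community_spec(fr, 10000, 80, 0, seed = 5))
  n1 <- sum(rs$truth$cluster == "CL01")
  expect_lt(abs(n1 - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
})

test_that("read simulation rejects unknown taxa and over-long reads", {
  db <- make_test_db()
  expect_error(simulate_reads(db, community_spec(c(NOPE = 1), 10, 80, 0)),
               "unknown cluster")
  expect_error(simulate_reads(db, community_spec(c(CL01 = 1), 10, 5000, 0)),
               "read_length")
})

test_that("genome mutation hits the requested rate and preserves structure", {
  g <- random_genome(100000, seed = 6, n_rrna = 2)
  d <- 0.03
  m <- mutate_genome(g, d, seed = 7)
  expect_equal(nchar(m$sequence), nchar(g$sequence))
  expect_identical(m$rrna_intervals, g$rrna_intervals)
  frac <- hamming(g$sequence, m$sequence) / 1e5
  # observed substitutions exclude the d/3 silent replacements; compare to
  # the realized draw count instead of the visible difference
  expect_lt(abs(attr(m, "n_sub") / 1e5 - d), 3 * sqrt(d * (1 - d) / 1e5))
  expect_lte(frac, attr(m, "n_sub") / 1e5)
  # determinism and the zero-divergence identity
  m2 <- mutate_genome(g, d, seed = 7)
  expect_identical(m$sequence, m2$sequence)
  expect_identical(mutate_genome(g, 0, seed = 1)$sequence, g$sequence)
})

test_that("interval validation catches malformed genomes", {
  expect_error(sim_genome("g", "ACGTACGT",
                          rrna_intervals = data.frame(start = 0, end = 100)),
               "bounds")
  expect_error(sim_genome("g", "ACGTACGTAC",
                          rrna_intervals = data.frame(start = c(0, 3),
                                                      end = c(5, 8))),
               "disjoint")
})

test_that("cell simulation honours degenerate and mixed populations", {
  sph <- cell_population_spec("s", "sphere", 50,
                              list(dist = "fixed", value = 1.0), seed = 1)
  cells <- simulate_cells(list(sph))
  expect_true(all(cells$length_um == 1.0 & cells$width_um == 1.0))

  two <- simulate_cells(list(
    cell_population_spec("a", "rod", 100,
                         list(dist = "lognormal", meanlog = 0, sdlog = 0.2),
                         list(dist = "lognormal", meanlog = -1, sdlog = 0.2),
                         seed = 2),
    cell_population_spec("b", "sphere", 900,
                         list(dist = "lognormal", meanlog = -0.5, sdlog = 0.3),
                         seed = 3)))
  expect_equal(nrow(two), 1000L)
  expect_equal(sum(two$population == "a"), 100L)
  expect_true(all(two$width_um <= two$length_um + 1e-12))
  expect_true(all(two$length_um > 0))
})

test_that("rod lengths recover the target mean within 3 SE", {
  mu <- 0.92; cv <- 0.25
  sdlog <- sqrt(log(1 + cv^2))
  pop <- cell_population_spec("r", "rod", 400,
                              list(dist = "lognormal",
                                   meanlog = log(mu) - sdlog^2 / 2,
                                   sdlog = sdlog),
                              list(dist = "fixed", value = 0.01), seed = 9)
  cells <- simulate_cells(list(pop))
  se <- sd(cells$length_um) / sqrt(nrow(cells))
  expect_lt(abs(mean(cells$length_um) - mu), 3 * se)
})

test_that("truth tables round-trip through TSV with the fixed column order", {
  db <- make_test_db()
  rs <- simulate_reads(db, community_spec(c(CL01 = 1), 20, 80, 0, seed = 8))
  f <- tempfile(fileext = ".tsv")
  write_truth_tsv(rs, f)
  tab <- read_tsv(f)
  expect_identical(names(tab), c("read_id", "source_id", "domain", "phylum",
                                 "class", "cluster"))
  expect_equal(nrow(tab), 20L)
})
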