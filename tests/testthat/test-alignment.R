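test_that("identical sequences align perfectly over their full span", {
  set.seed(1)
  q <- random_seq(100)
  hit <- local_align(q, q)
  expect_equal(hit$identity_pct, 100)
  expect_equal(hit$aln_length, 100L)
  expect_equal(hit$raw_score, 100L)
  expect_equal(c(hit$q_start, hit$q_end, hit$s_start, hit$s_end),
               c(0L, 100L, 0L, 100L))
  expect_equal(hit$strand, "+")
})

test_that("reverse-complement queries are found on the minus strand with the same score", {
  set.seed(2)
  s <- random_seq(400)
  sub <- substr(s, 101, 200)
  fwd <- local_align(sub, s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  rev <- local_align(rc, s)
  expect_equal(rev$strand, "-")
  expect_equal(rev$raw_score, fwd$raw_score)
  expect_equal(rev$identity_pct, fwd$identity_pct)
  expect_equal(c(rev$s_start, rev$s_end), c(fwd$s_start, fwd$s_end))
})

test_that("engine scores match an exhaustive DP oracle on random pairs", {
  set.seed(3)
  for (k in 1:30) {
    q <- random_seq(sample(30:80, 1))
    s <- random_seq(sample(30:100, 1))
    expect_equal(sw_score_batch(q, s)[1, "score"],
                 sw_oracle_score(q, s),
                 ignore_attr = TRUE,
                 label = sprintf("case %d", k))
  }
})

test_that("alignment score is symmetric under query/subject swap", {
  set.seed(4)
  for (k in 1:10) {
    a <- random_seq(60); b <- random_seq(90)
    expect_equal(local_align(a, b)$raw_score, local_align(b, a)$raw_score)
  }
})

test_that("mutating one copy of a pair never raises, and statistically lowers, the score", {
  set.seed(5)
  q <- random_seq(200)
  self_score <- local_align(q, q)$raw_score
  score_at <- function(d, seeds) vapply(seeds, function(s) {
    g <- sim_genome("g", q)
    local_align(q, mutate_genome(g, d, seed = s)$sequence)$raw_score
  }, 1)
  lo <- score_at(0.05, 1:8)
  hi <- score_at(0.15, 1:8)
  expect_true(all(lo <= self_score))
  expect_true(mean(hi) < mean(lo))
})

test_that("gap-free alignments report identity equal to the direct Hamming identity", {
  set.seed(6)
  for (k in 1:10) {
    a <- random_seq(300)
    # mutate only the interior so the optimal alignment keeps the full span
    inner <- substr(a, 21, 280)
    g <- sim_genome("g", inner)
    b <- paste0(substr(a, 1, 20),
                mutate_genome(g, 0.03, seed = k)$sequence,
                substr(a, 281, 300))
    hit <- local_align(a, b)
    expect_equal(hit$aln_length, 300L)
    expect_equal(hit$gapopen, 0L)
    expect_equal(hit$identity_pct, 100 * hamming_identity(a, b))
  }
})

test_that("N never matches, not even against N", {
  hit <- local_align("ACGTNNNNACGT", "ACGTNNNNACGT")
  # the two ACGT blocks match; the N block contributes only penalty
  expect_true(hit$n_ident <= 8)
  expect_null(local_align("NNNNNNNN", "NNNNNNNN"))
})

test_that("empty sequences are rejected", {
  expect_error(local_align("", "ACGT"), "empty")
  expect_error(local_align("ACGT", ""), "empty")
})

test_that("e-values follow the Karlin-Altschul closed form", {
  sch <- scoring_scheme()
  # S chosen so that lambda * S = ln(K * m * n) gives E = 1
  m <- 100; n <- 1e6
  S <- log(sch$K * m * n) / sch$lambda
  expect_equal(sch$K * m * n * exp(-sch$lambda * S), 1.0)
  expect_equal(evalue(S, m, n, sch), 1.0)
  # linear in database size
  expect_equal(evalue(30, m, 2 * n, sch), 2 * evalue(30, m, n, sch))
  # direct evaluation of the formula at stated inputs
  expect_equal(evalue(30, 100, 1e6, scoring_scheme(lambda = 1.28, K = 0.46)),
               0.46 * 100 * 1e6 * exp(-1.28 * 30))
  # monotone decreasing in score
  expect_true(all(diff(evalue(1:50, m, n, sch)) < 0))
})

test_that("outfmt-6 export converts to 1-based closed coordinates", {
  set.seed(7)
  s <- random_seq(200)
  hit <- local_align(substr(s, 51, 100), s)
  tab <- hits_as_outfmt6(hit)
  expect_equal(tab$qstart, 1L)
  expect_equal(tab$qend, 50L)
  expect_equal(tab$sstart, 51L)
  expect_equal(tab$send, 100L)
  # minus-strand hits print subject coordinates reversed
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(s, 51, 100))))
  tabm <- hits_as_outfmt6(local_align(rc, s))
  expect_true(tabm$sstart > tabm$send)
})
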