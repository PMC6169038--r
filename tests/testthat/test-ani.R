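test_that("self-ANI is exactly 100 and unrelated genomes are undefined", {
  g <- random_genome(8000, seed = 91)
  self <- ani_pair(g, g, frag_len = 1020)
  expect_identical(self$ani, 100)
  expect_equal(self$n_frag_ab, 7L)
  other <- random_genome(8000, seed = 92)
  un <- ani_pair(g, other, frag_len = 1020)
  expect_true(is.na(un$ani))
  expect_error(ani_pair(g, random_genome(500, seed = 93)), "frag_len")
})

test_that("ANI of a mutated genome matches the per-fragment Hamming oracle", {
  g <- random_genome(20000, seed = 94)
  m <- mutate_genome(g, 0.03, seed = 95)
  got <- ani_pair(g, m, frag_len = 1020)
  # gap-free construction: fragment i of one genome aligns to the same
  # coordinates of the other, so per-fragment identity is a direct Hamming
  # count over those coordinates
  oracle_dir <- function(a, b) {
    n_frag <- nchar(a) %/% 1020
    idents <- vapply(seq_len(n_frag), function(i) {
      fa <- substr(a, (i - 1) * 1020 + 1, i * 1020)
      fb <- substr(b, (i - 1) * 1020 + 1, i * 1020)
      100 * hamming_identity(fa, fb)
    }, 1)
    mean(idents[idents >= 70])
  }
  oracle <- mean(c(oracle_dir(g$sequence, m$sequence),
                   oracle_dir(m$sequence, g$sequence)))
  expect_lt(abs(got$ani - oracle), 0.5)
  expect_equal(got$n_frag_ab, 19L)
})

test_that("ANI decreases with simulated divergence and the matrix is symmetric", {
  g <- random_genome(6000, seed = 96)
  genomes <- list(A = g,
                  B = mutate_genome(g, 0.02, seed = 97, id = "B"),
                  C = mutate_genome(g, 0.10, seed = 98, id = "C"))
  m <- ani_matrix(genomes, frag_len = 1020)
  expect_identical(m$ani, t(m$ani))
  expect_true(all(diag(m$ani) == 100))
  expect_gt(m$ani["A", "B"], m$ani["A", "C"])
  # 2% divergence stays above the species line, 10% falls below it
  expect_gt(m$ani["A", "B"], 95)
  expect_lt(m$ani["A", "C"], 95)
  sp <- species_clusters(m, 95)
  expect_equal(sp$membership[["A"]], sp$membership[["B"]])
  expect_false(sp$membership[["A"]] == sp$membership[["C"]])
})

test_that("species clustering is a single-linkage closure over >95% pairs", {
  ids <- c("A", "B", "C")
  mat <- matrix(c(100, 96, 94, 96, 100, 96, 94, 96, 100), 3, 3,
                dimnames = list(ids, ids))
  sp <- species_clusters(mat, 95)
  expect_length(sp$clusters, 1L)
  # all pairs at or below threshold: every genome is its own species
  low <- matrix(92, 3, 3, dimnames = list(ids, ids)); diag(low) <- 100
  expect_length(species_clusters(low, 95)$clusters, 3L)
})

test_that("random matrices partition exactly as a connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (k in 1:25) {
    n <- sample(2:8, 1)
    ids <- paste0("g", seq_len(n))
    vals <- matrix(runif(n * n, 90, 100), n, n, dimnames = list(ids, ids))
    vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
    diag(vals) <- 100
    vals[sample(which(upper.tri(vals)), size = n %/% 2)] <- NA
    vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
    got <- species_clusters(vals, 95)$membership
    adj <- !is.na(vals) & vals > 95
    diag(adj) <- TRUE
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
    # same partition up to label renaming
    expect_true(all(outer(got, got, "==") ==
                      outer(comp$membership, comp$membership, "==")))
    expect_equal(length(unique(got)), comp$no)
  }
})

test_that("clustering is invariant under genome relabeling", {
  set.seed(100)
  ids <- paste0("g", 1:5)
  vals <- matrix(runif(25, 90, 100), 5, 5, dimnames = list(ids, ids))
  vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
  diag(vals) <- 100
  sp1 <- species_clusters(vals, 95)
  perm <- c(3, 1, 5, 2, 4)
  sp2 <- species_clusters(vals[perm, perm], 95)
  for (i in 1:5) for (j in 1:5) {
    same1 <- sp1$membership[[ids[i]]] == sp1$membership[[ids[j]]]
    same2 <- sp2$membership[[ids[i]]] == sp2$membership[[ids[j]]]
    expect_equal(same1, same2)
  }
})
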