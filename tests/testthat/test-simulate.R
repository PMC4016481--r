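# The K2P mutator and the truth-tracked genome simulator.

test_that("mutate_k2p honours its limits and composes with the estimator", {
  set.seed(121)
  s <- random_dna(500, 0.5)
  expect_equal(mutate_k2p(s, 0, 2)$seq, s)
  expect_error(mutate_k2p(s, -0.1, 2), "d must be")
  expect_error(mutate_k2p(s, 0.1, 0), "kappa")
  # estimator consistency at L = 10000
  m <- mutate_k2p(random_dna(10000, 0.5), 0.10, 2, seed = 122)
  expect_lt(abs(m$realized_distance - 0.10), 0.01)
  expect_equal(as.numeric(k2p_distance(s, mutate_k2p(s, 0, 2)$seq)), 0)
})

test_that("realized distance equals the estimator applied to the output", {
  set.seed(123)
  for (d in c(0.02, 0.1, 0.3)) {
    s <- random_dna(2000, 0.5)
    m <- mutate_k2p(s, d, 2)
    expect_equal(as.numeric(k2p_distance(s, m$seq)), m$realized_distance,
                 tolerance = 1e-12)
  }
})

test_that("large kappa suppresses transversions at small divergence", {
  set.seed(124)
  m <- mutate_k2p(random_dna(5000, 0.5), 0.05, 1e6)
  expect_equal(m$transversions, 0)
  expect_gt(m$transitions, 0)
})

test_that("the same seed reproduces genome and truth byte for byte", {
  fams <- list(sim_family("A", n_copies = 20, length = 300,
                          divergence = 0.08,
                          truncation = list(fraction = 0.3, min_frac = 0.1,
                                            max_frac = 0.9)))
  s1 <- simulate_genome(fams, genome_length = 20000, gc = 0.35, seed = 125)
  s2 <- simulate_genome(fams, genome_length = 20000, gc = 0.35, seed = 125)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_genome(fams, genome_length = 20000, gc = 0.35, seed = 126)
  expect_false(identical(s1$genome, s3$genome))
})

test_that("zero copies gives pure background and an empty truth table", {
  sim <- simulate_genome(list(), genome_length = 5000, gc = 0.35,
                         seed = 127)
  expect_equal(nchar(sim$genome[[1]]), 5000)
  expect_equal(nrow(sim$truth), 0)
})

test_that("truth intervals are consistent with the emitted genome", {
  set.seed(128)
  fams <- list(sim_family("A", n_copies = 25, length = 300,
                          divergence = 0.10, minus_prob = 0.5))
  sim <- simulate_genome(fams, genome_length = 30000, gc = 0.35, seed = 128)
  master <- sim$library[["A"]]
  for (r in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[r, ]
    copy <- substr(sim$genome[[tr$seq_id]], tr$start, tr$end)
    if (tr$strand == "-") copy <- TElandscape:::revcomp(copy)
    expect_equal(as.numeric(k2p_distance(master, copy)),
                 tr$realized_distance, tolerance = 1e-12)
  }
})

test_that("a too-small genome errors with the required minimum", {
  fams <- list(sim_family("A", n_copies = 500, length = 100,
                          divergence = 0))
  expect_error(simulate_genome(fams, genome_length = 1000, gc = 0.35,
                               seed = 129), "genome too small")
})

test_that("nesting splits the host into linked truth records", {
  fams <- list(
    sim_family("Host", n_copies = 5, length = 600, divergence = 0,
               epoch = 1, minus_prob = 0),
    sim_family("Inner", n_copies = 5, length = 300, divergence = 0,
               epoch = 2, minus_prob = 0))
  sim <- simulate_genome(fams, genome_length = 20000, gc = 0.35, seed = 130,
                         nesting = list(list(inner = "Inner",
                                             outer = "Host", count = 3,
                                             min_host_flank = 100)))
  tr <- sim$truth
  nested <- tr[tr$family == "Inner" & !is.na(tr$parent_id), ]
  expect_equal(nrow(nested), 3)
  for (r in seq_len(nrow(nested))) {
    halves <- tr[tr$parent_id %in% nested$parent_id[r] &
                 tr$family == "Host", ]
    expect_equal(nrow(halves), 2)
    # host halves tile the full consensus contiguously
    spans <- sort(c(halves$consensus_start, halves$consensus_end))
    expect_equal(spans[1], 1)
    expect_equal(spans[4], 600)
    expect_equal(spans[3], spans[2] + 1)
    expect_equal(halves$end[1] + 1, nested$start[r])
    expect_equal(nested$end[r] + 1, halves$start[2])
    # the inner sequence is the exact master
    inner_seq <- substr(sim$genome[[1]], nested$start[r], nested$end[r])
    expect_equal(inner_seq, sim$library[["Inner"]])
  }
})

test_that("truncation and deletion bookkeeping matches the sequences", {
  set.seed(131)
  fams <- list(sim_family("A", n_copies = 40, length = 500,
                          divergence = 0,
                          truncation = list(fraction = 0.5, min_frac = 0.2,
                                            max_frac = 0.8),
                          deletion = list(fraction = 0.5, min_len = 50,
                                          max_len = 120, end3_bias = 0.5),
                          minus_prob = 0))
  sim <- simulate_genome(fams, genome_length = 50000, gc = 0.35, seed = 131)
  master <- sim$library[["A"]]
  for (r in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[r, ]
    copy <- substr(sim$genome[[1]], tr$start, tr$end)
    # reconstruct the expected sequence from the truth fields
    keep <- seq_len(nchar(master))
    if (!is.na(tr$truncation_point)) {
      keep <- keep[keep >= tr$truncation_point]
    }
    if (nzchar(tr$deletions)) {
      for (iv in strsplit(tr$deletions, ";")[[1]]) {
        se <- as.integer(strsplit(iv, "-")[[1]])
        keep <- keep[keep < se[1] | keep > se[2]]
      }
    }
    expected <- paste(strsplit(master, "")[[1]][keep], collapse = "")
    expect_equal(copy, expected)
  }
})
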