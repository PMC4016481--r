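# K2P distances, the per-column counting oracle, and activity windows.

test_that("k2p_distance matches direct evaluation of the closed form", {
  # one transition among 7 comparable sites: -1/2 ln(5/7)
  expect_equal(as.numeric(k2p_distance("AAAAAAA", "GAAAAAA")),
               -0.5 * log(5 / 7), tolerance = 1e-12)
  # two transversions among 10 sites: P=0, Q=0.2
  expect_equal(as.numeric(k2p_distance("AAAAAAAAAA", "CCAAAAAAAA")),
               -0.5 * log(0.8 * sqrt(0.6)), tolerance = 1e-12)
  expect_equal(as.numeric(k2p_distance("ACGTACGT", "ACGTACGT")), 0)
})

test_that("k2p_distance agrees with the per-column counting oracle", {
  set.seed(17)
  for (rep in 1:200) {
    p <- random_aligned_pair(sample(20:120, 1))
    mine <- tryCatch(as.numeric(k2p_distance(p$a, p$b)),
                     error = function(e) NA_real_)
    oracle <- brute_force_k2p(p$a, p$b)
    if (is.na(mine) || is.nan(oracle)) next
    expect_equal(mine, oracle, tolerance = 1e-12)
  }
})

test_that("k2p_distance agrees with ape's K80 distance", {
  skip_if_not_installed("ape")
  set.seed(23)
  for (rep in 1:20) {
    a <- random_dna(300, 0.5)
    b <- mutate_k2p(a, runif(1, 0.01, 0.4), 2)$seq
    m <- rbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]])
    ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80"))
    expect_equal(as.numeric(k2p_distance(a, b)), ref, tolerance = 1e-9)
  }
})

test_that("k2p distance dominates p-distance (Jensen bound)", {
  set.seed(29)
  for (rep in 1:50) {
    a <- random_dna(200, 0.5)
    b <- mutate_k2p(a, runif(1, 0, 0.5), runif(1, 0.5, 5))$seq
    k <- tryCatch(as.numeric(k2p_distance(a, b)), error = function(e) NA)
    if (is.na(k)) next
    p <- mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_gte(k + 1e-12, p)
  }
})

test_that("saturation raises a classed error and gaps/N are excluded", {
  expect_error(k2p_distance("AAAAAA", "GGGGGG"), class = "k2p_saturation")
  expect_true(is.nan(k2p_distance("AAAAAA", "GGGGGG",
                                  on_saturation = "nan")))
  d <- k2p_distance("AAC--GNT", "AGC--GAT")
  expect_equal(attr(d, "sites"), 5)  # two gap columns and one N excluded
  expect_error(k2p_distance("NNN", "AAA"), "no comparable")
  expect_error(k2p_distance("AC", "ACG"), "equal length")
})

test_that("divergence_to_time reproduces printed activity windows", {
  expect_equal(unname(divergence_to_time(0.20747, 0.06289)), c(7.6, 14.2))
  expect_equal(unname(divergence_to_time(0.24241, 0.06665)), c(9.2, 16.2))
  expect_equal(unname(divergence_to_time(0, 0)), c(0, 0))
  # lower bound clamps at zero
  expect_equal(unname(divergence_to_time(0.01, 0.05))[1], 0)
})

test_that("family divergence summarises cohorts correctly", {
  set.seed(37)
  master <- random_dna(400, 0.5)
  copies <- vapply(1:20, function(i) mutate_k2p(master, 0.10, 2)$seq, "")
  bg <- random_dna(30000, 0.4)
  planted <- plant_copies(bg, copies, sort(sample(seq(500, 29000, 40), 20)))
  genome <- c(chr1 = planted$genome)
  hits <- do.call(rbind, lapply(seq_len(20), function(i) {
    make_hit(gs = planted$intervals[i, 1], ge = planted$intervals[i, 2],
             cs = 1, ce = 400, score = 300)
  }))
  fd <- family_divergence(hits, genome, c(F = master))
  expect_equal(fd$n, 20)
  expect_lt(abs(fd$mean_distance - 0.10), 0.015)
  expect_equal(fd$range_low, fd$mean_distance - fd$sd)
  expect_equal(fd$range_high, fd$mean_distance + fd$sd)
  expect_equal(fd$time_low_mya,
               unname(divergence_to_time(fd$mean_distance, fd$sd))[1])

  # identical copies: zero distance, zero window
  hits2 <- hits[1:5, ]
  copies_exact <- plant_copies(bg, rep(master, 5),
                               sort(sample(seq(500, 25000, 500), 5)))
  genome2 <- c(chr1 = copies_exact$genome)
  hits2 <- do.call(rbind, lapply(1:5, function(i) {
    make_hit(gs = copies_exact$intervals[i, 1],
             ge = copies_exact$intervals[i, 2], cs = 1, ce = 400)
  }))
  fd2 <- family_divergence(hits2, genome2, c(F = master))
  expect_equal(fd2$mean_distance, 0)
  expect_equal(fd2$sd, 0)
  expect_equal(c(fd2$time_low_mya, fd2$time_high_mya), c(0, 0))
})

test_that("mixed-age cohorts broaden the divergence summary", {
  set.seed(43)
  master <- random_dna(400, 0.5)
  copies <- c(vapply(1:15, function(i) mutate_k2p(master, 0.05, 2)$seq, ""),
              vapply(1:15, function(i) mutate_k2p(master, 0.20, 2)$seq, ""))
  bg <- random_dna(40000, 0.4)
  planted <- plant_copies(bg, copies, sort(sample(seq(500, 39000, 45), 30)))
  hits <- do.call(rbind, lapply(seq_len(30), function(i) {
    make_hit(gs = planted$intervals[i, 1], ge = planted$intervals[i, 2],
             cs = 1, ce = 400)
  }))
  fd <- family_divergence(hits, c(chr1 = planted$genome), c(F = master))
  expect_gt(fd$mean_distance, 0.05)
  expect_lt(fd$mean_distance, 0.20)
  expect_gt(fd$sd, 0.05)
})
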