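# Fragment classification, decay profiles and deletion evidence.

test_that("fragment classes follow the end-presence rules", {
  L <- 1000
  expect_equal(classify_fragment(601, 1000, L), "FIVE_PRIME_TRUNCATED")
  expect_equal(classify_fragment(1, 400, L), "THREE_PRIME_ABSENT")
  expect_equal(classify_fragment(300, 700, L), "INTERNAL_ONLY")
  expect_equal(classify_fragment(10, 995, L), "FULL_LENGTH")
  # vectorised and exhaustive: every random span lands in exactly one class
  set.seed(81)
  s <- sample(1:900, 50); e <- pmin(1000, s + sample(50:900, 50, TRUE))
  cls <- classify_fragment(s, e, L)
  expect_true(all(cls %in% c("FULL_LENGTH", "FIVE_PRIME_TRUNCATED",
                             "THREE_PRIME_ABSENT", "INTERNAL_ONLY")))
})

test_that("decay profiles order fragments longest-first", {
  hits <- rbind(make_hit(gs = 1, ge = 900, cs = 50, ce = 949, score = 1),
                make_hit(gs = 2000, ge = 2399, cs = 601, ce = 1000),
                make_hit(gs = 5000, ge = 5199, cs = 1, ce = 200))
  pr <- decay_profile(hits, 1000)
  expect_equal(pr$intervals$consensus_end - pr$intervals$consensus_start + 1,
               c(900, 400, 200))
  expect_equal(pr$n, 3)
  expect_equal(sum(pr$class_counts), 3)
  expect_true(all(pr$intervals$norm_end <= 1))
  single <- decay_profile(make_hit(gs = 1, ge = 1000, cs = 1, ce = 1000),
                          1000)
  expect_equal(single$n, 1)
  expect_equal(as.integer(single$class_counts["FULL_LENGTH"]), 1)
})

test_that("nested-split fragments are re-joined, unrelated pairs are not", {
  # A split around a nested B copy: consensus spans continue
  hits <- rbind(
    make_hit(gs = 1000, ge = 1300, cs = 1, ce = 300, family = "A"),
    make_hit(gs = 1301, ge = 1600, cs = 1, ce = 300, family = "B"),
    make_hit(gs = 1601, ge = 1900, cs = 301, ce = 600, family = "A"))
  joined <- rejoin_split_fragments(hits)
  a <- joined[joined$family == "A", ]
  expect_equal(nrow(a), 1)
  expect_equal(c(a$consensus_start, a$consensus_end), c(1, 600))
  expect_equal(a$n_segments, 2)

  # two tandem full copies: spans both 1-300, no continuation -> no join
  hits2 <- rbind(
    make_hit(gs = 1000, ge = 1300, cs = 1, ce = 300, family = "A"),
    make_hit(gs = 1301, ge = 1600, cs = 1, ce = 300, family = "B"),
    make_hit(gs = 1601, ge = 1900, cs = 1, ce = 300, family = "A"))
  expect_equal(nrow(rejoin_split_fragments(hits2)), 3)

  # continuation but an unoccupied gap (deletion, not nesting) -> no join
  hits3 <- rbind(
    make_hit(gs = 1000, ge = 1300, cs = 1, ce = 300, family = "A"),
    make_hit(gs = 1601, ge = 1900, cs = 301, ce = 600, family = "A"))
  expect_equal(nrow(rejoin_split_fragments(hits3)), 2)
})

test_that("deletion summary ratios behave on constructed tables", {
  L <- c(F = 1000L)
  full <- do.call(rbind, lapply(seq(1000, 10000, 1000), function(g)
    make_hit(gs = g, ge = g + 999, cs = 1, ce = 1000)))
  ds <- deletion_evidence_summary(full, L)
  expect_equal(ds$retro_ratio, 10)  # all full length: ratio = n
  mixed <- rbind(make_hit(gs = 1000, ge = 1999, cs = 1, ce = 1000),
                 make_hit(gs = 4000, ge = 4399, cs = 601, ce = 1000),
                 make_hit(gs = 6000, ge = 6399, cs = 1, ce = 400),
                 make_hit(gs = 8000, ge = 8399, cs = 300, ce = 699))
  ds2 <- deletion_evidence_summary(mixed, L)
  expect_equal(ds2$retro_ratio, 1.0)
  expect_equal(ds2$frac_deletion_classes, 0.5)
})

test_that("truncation-only simulation yields almost no deletion classes", {
  set.seed(82)
  fam <- sim_family("Line", n_copies = 120, length = 1000,
                    divergence = 0.10,
                    truncation = list(fraction = 0.3, min_frac = 0.1,
                                      max_frac = 0.9),
                    minus_prob = 0.5)
  sim <- simulate_genome(list(fam), genome_length = 160000, gc = 0.35,
                         seed = 82)
  hits <- find_hits(sim$genome, sim$library, min_score = 60)
  ds <- deletion_evidence_summary(hits, nchar(sim$library))
  expect_lte(ds$frac_deletion_classes, 0.02)
  expect_gte(ds$five_prime_truncated / ds$n, 0.15)
})

test_that("planted 3'/internal deletions are recovered within 5 points", {
  set.seed(83)
  fam <- sim_family("Line", n_copies = 150, length = 1000,
                    divergence = 0.10,
                    truncation = list(fraction = 0.3, min_frac = 0.1,
                                      max_frac = 0.9),
                    deletion = list(fraction = 0.3, min_len = 100,
                                    max_len = 400, end3_bias = 0.5),
                    minus_prob = 0.5)
  sim <- simulate_genome(list(fam), genome_length = 200000, gc = 0.35,
                         seed = 83)
  hits <- find_hits(sim$genome, sim$library, min_score = 60)
  ds <- deletion_evidence_summary(hits, nchar(sim$library))
  # internal deletions split a copy into one deletion-class and one
  # 3'-retaining fragment, diluting the hit-level fraction below the
  # planted copy-level 30%; the recovered fraction stays within 5 points
  expect_gte(ds$frac_deletion_classes, 0.25 - 0.05)
  expect_lte(ds$frac_deletion_classes, 0.30 + 0.05)
})
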