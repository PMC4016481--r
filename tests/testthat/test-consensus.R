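# Iterative consensus building: copy extraction, majority rule, boundary
# detection and full recovery of a simulated master.

test_that("majority rule follows the stated column rules", {
  m <- rbind(c("A", "A", "A", "-"),
             c("A", "A", "C", "-"),
             c("A", "C", "C", "-"),
             c("C", "C", "G", "A"))
  # col1 {A,A,A,C} -> A; col2 {A,A,C,C} tie -> N; col3 {A,C,C,G} 50% C with
  # unique max -> C; col4 three gaps of four -> dropped
  expect_equal(majority_consensus(m), "ANC")
  expect_error(majority_consensus(matrix("A", 1, 3)), ">= 2 rows")
  # identical rows reproduce the sequence
  mm <- do.call(rbind, rep(list(strsplit("ACGT", "")[[1]]), 4))
  expect_equal(majority_consensus(mm), "ACGT")
})

test_that("extract_copies honours ranking, span filter and contig edges", {
  set.seed(61)
  probe <- random_dna(200, 0.5)
  copies <- c(vapply(1:12, function(i) mutate_k2p(probe, 0.03, 2)$seq, ""),
              substr(probe, 1, 90))          # sub-min_span fragment
  bg <- random_dna(20000, 0.4)
  offs <- seq(20, 19000, length.out = 13)    # first copy 20 bp from the edge
  planted <- plant_copies(bg, copies, offs)
  ec <- extract_copies(c(chr1 = planted$genome), probe, max_copies = 10,
                       min_span = 100, flank = 300, min_score = 60)
  expect_equal(length(ec$seqs), 10)          # capped at max_copies
  # the 90-bp fragment is excluded by the span filter
  expect_true(all(ec$hits$consensus_end - ec$hits$consensus_start + 1 >= 100))
  # flank truncation at the contig start
  edge <- which(ec$hits$genome_start < 300)
  if (length(edge) > 0) {
    expect_lt(ec$left_flank[edge[1]], 300)
  }
  expect_equal(length(ec$seqs),
               length(ec$left_flank))
})

test_that("minus-strand copies come back in probe orientation", {
  set.seed(62)
  probe <- random_dna(200, 0.5)
  planted <- plant_copies(random_dna(6000, 0.4),
                          TElandscape:::revcomp(probe), 3000)
  ec <- extract_copies(c(chr1 = planted$genome), probe, flank = 50,
                       min_score = 100)
  core <- substr(ec$seqs[[1]], ec$left_flank[1] + 1, ec$left_flank[1] + 200)
  expect_equal(core, probe)
})

test_that("single-copy boundaries: random flanks yes, 2 rows undetermined", {
  set.seed(63)
  core <- random_dna(150, 0.5)
  seqs <- vapply(1:10, function(i) {
    paste0(random_dna(100, 0.5), mutate_k2p(core, 0.03, 2)$seq,
           random_dna(100, 0.5))
  }, "")
  msa <- build_msa(seqs)
  m <- TElandscape:::msa_matrix(msa)
  # locate core columns via the first row
  pos <- cumsum(m[1, ] != "-")
  cs <- which(pos == 101 & m[1, ] != "-")[1]
  ce <- which(pos == 250 & m[1, ] != "-")[1]
  bd <- single_copy_boundary(msa, cs, ce)
  expect_true(bd$left_single_copy)
  expect_true(bd$right_single_copy)
  # boundary stays near the true core edges
  expect_lte(abs(bd$left_col - cs), 12)
  expect_lte(abs(bd$right_col - ce), 12)

  two <- build_msa(seqs[1:2])
  bd2 <- single_copy_boundary(two, 100, 200)
  expect_false(bd2$left_single_copy)
  expect_false(bd2$right_single_copy)
})

test_that("a shared flanking element pushes the boundary outward", {
  set.seed(64)
  core <- random_dna(150, 0.5)
  shared <- random_dna(80, 0.5)   # second repeat shared by all copies
  seqs <- vapply(1:10, function(i) {
    paste0(random_dna(60, 0.5), mutate_k2p(shared, 0.03, 2)$seq,
           mutate_k2p(core, 0.03, 2)$seq, random_dna(60, 0.5))
  }, "")
  msa <- build_msa(seqs)
  m <- TElandscape:::msa_matrix(msa)
  pos <- cumsum(m[1, ] != "-")
  cs <- which(pos == 141 & m[1, ] != "-")[1]
  ce <- which(pos == 290 & m[1, ] != "-")[1]
  bd <- single_copy_boundary(msa, cs, ce)
  # boundary moves left across the shared 80-mer
  expect_lte(bd$left_col, cs - 70)
})

test_that("a simulated family's master is recovered to near-identity", {
  set.seed(65)
  master <- random_dna(267, 0.5)
  fam <- sim_family("Fam", n_copies = 20, master = master,
                    divergence = 0.05, minus_prob = 0.3)
  sim <- simulate_genome(list(fam), genome_length = 30000, gc = 0.35,
                         seed = 65)
  rec <- extend_to_single_copy(sim$genome, substr(master, 60, 210),
                               flank = 200, max_copies = 30,
                               min_score = 80, window = 40)
  expect_true(rec$complete)
  expect_lte(adist(rec$seq, master)[1, 1], 3)
  # probe equal to the full element with random flanks: one round
  rec2 <- extend_to_single_copy(sim$genome, master, flank = 200,
                                max_copies = 30, min_score = 80,
                                window = 40)
  expect_true(rec2$complete)
  expect_equal(rec2$rounds, 1)
  expect_lte(adist(rec2$seq, master)[1, 1], 3)
})

test_that("consensus length grows from a truncated probe until completion", {
  set.seed(66)
  master <- random_dna(300, 0.5)
  fam <- sim_family("Fam", n_copies = 20, master = master,
                    divergence = 0.05, minus_prob = 0)
  sim <- simulate_genome(list(fam), genome_length = 30000, gc = 0.35,
                         seed = 66)
  rec <- extend_to_single_copy(sim$genome, substr(master, 1, 150),
                               flank = 250, max_copies = 30,
                               min_score = 60, window = 40)
  lens <- vapply(rec$log, function(x) {
    if (is.null(x$consensus_length)) NA_real_ else x$consensus_length
  }, numeric(1))
  lens <- lens[!is.na(lens)]
  expect_true(all(diff(lens) >= -3))   # non-decreasing up to edge jitter
  expect_gte(nchar(rec$seq), 290)
})

test_that("too few copies yields an incomplete best-effort record", {
  set.seed(67)
  probe <- random_dna(200, 0.5)
  planted <- plant_copies(random_dna(5000, 0.4), probe, 2500)
  rec <- extend_to_single_copy(c(chr1 = planted$genome), probe,
                               flank = 100, min_score = 80)
  expect_false(rec$complete)
  expect_equal(rec$seq, probe)
})

test_that("classification finds parents and rejects noise", {
  set.seed(68)
  ref <- setNames(vapply(1:3, function(i) random_dna(400, 0.5), ""),
                  c("ElemA", "ElemB", "ElemC"))
  expect_equal(classify_consensus(ref[["ElemB"]], ref), "ElemB")
  expect_equal(classify_consensus(random_dna(400, 0.5), ref),
               "Unclassified")
  # internally deleted variant still maps to its parent
  deleted <- paste0(substr(ref[["ElemA"]], 1, 150),
                    substr(ref[["ElemA"]], 251, 400))
  expect_equal(classify_consensus(deleted, ref), "ElemA")
  labels <- c(ElemA = "DNA/Tc1", ElemB = "LINE/L2", ElemC = "SINE")
  expect_equal(classify_consensus(deleted, ref, labels = labels), "DNA/Tc1")
  expect_error(classify_consensus("ACGT", character(0)), "empty")
})
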