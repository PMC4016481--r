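# Subfamily discovery from co-segregating diagnostic sites.

intact_window <- function(L, tol = 0.10) c(floor(L * (1 - tol)),
                                           ceiling(L * (1 + tol)))

test_that("the intact-insertion length window matches the 10% rule", {
  expect_equal(intact_window(267), c(240, 294))
  set.seed(71)
  cons <- random_dna(267, 0.5)
  genome <- c(chr1 = paste0(random_dna(300, 0.4), cons,
                            random_dna(300, 0.4)))
  mk <- function(len, cs, ce) make_hit(gs = 301, ge = 300 + len, cs = cs,
                                       ce = ce)
  # 239 bp: under the window -> rejected
  expect_equal(length(collect_intact_insertions(mk(239, 1, 239), genome,
                                                cons)), 0)
  # 294 bp covering the consensus -> accepted
  expect_equal(length(collect_intact_insertions(mk(267, 1, 267), genome,
                                                cons)), 1)
  # right length but poor consensus coverage -> rejected
  expect_equal(length(collect_intact_insertions(mk(250, 1, 150), genome,
                                                cons)), 0)
})

# shared planted-diagnostic scenario builder
planted_two_subfamilies <- function(n = 120, minor = 0.4, d = 0.05, seed = 72) {
  set.seed(seed)
  master <- random_dna(267, 0.5)
  substr(master, 40, 40) <- "C"
  substr(master, 120, 120) <- "C"
  fam <- sim_family("Met", n_copies = n, master = master, divergence = d,
                    subfamilies = list(list(
                      name = "minor",
                      sites = data.frame(pos = c(40, 120),
                                         base = c("T", "T")),
                      fraction = minor)))
  sim <- simulate_genome(list(fam), genome_length = n * 600, gc = 0.35,
                         seed = seed)
  hits <- find_hits(sim$genome, sim$library, min_score = 100)
  ins <- collect_intact_insertions(hits, sim$genome, master)
  list(sim = sim, hits = hits, ins = ins, master = master)
}

test_that("a clean family stays one subfamily; planted diagnostics split it", {
  set.seed(73)
  master <- random_dna(267, 0.5)
  null_ins <- setNames(vapply(1:120, function(i)
    mutate_k2p(master, 0.05, 2)$seq, ""), paste0("i", 1:120))
  asn0 <- find_cosegregating_subfamilies(null_ins, master, min_size = 30)
  expect_equal(nrow(asn0$subfamilies), 1)

  sc <- planted_two_subfamilies()
  asn <- find_cosegregating_subfamilies(sc$ins, sc$master, min_size = 30)
  expect_equal(nrow(asn$subfamilies), 2)
  expect_setequal(asn$splits[[1]]$sites$column, c(40, 120))
  expect_lt(asn$splits[[1]]$p_adjusted, 0.001)
})

test_that("below 2*min_size no test is attempted", {
  set.seed(74)
  master <- random_dna(267, 0.5)
  ins <- setNames(vapply(1:30, function(i) mutate_k2p(master, 0.05, 2)$seq,
                         ""), paste0("i", 1:30))
  asn <- find_cosegregating_subfamilies(ins, master, min_size = 50)
  expect_equal(nrow(asn$subfamilies), 1)
  expect_equal(length(asn$splits), 0)
})

test_that("splitting is monotone in alpha", {
  sc <- planted_two_subfamilies(seed = 75)
  n_at <- vapply(c(1e-30, 1e-3, 0.5), function(a) {
    nrow(find_cosegregating_subfamilies(sc$ins, sc$master, min_size = 30,
                                        alpha = a)$subfamilies)
  }, numeric(1))
  expect_true(all(diff(n_at) >= 0))
})

test_that("refinement reproduces the subfamily masters and is accurate", {
  sc <- planted_two_subfamilies(seed = 76)
  asn <- find_cosegregating_subfamilies(sc$ins, sc$master, min_size = 30)
  ref <- refine_subfamily_consensus(asn, sc$ins, min_size = 30)
  expect_equal(length(ref$consensi), 2)
  c1 <- strsplit(ref$consensi[[1]], "")[[1]]
  c2 <- strsplit(ref$consensi[[2]], "")[[1]]
  expect_equal(length(c1), length(c2))
  expect_setequal(which(c1 != c2), c(40, 120))
  # membership accuracy vs simulator truth
  rows <- attr(sc$ins, "hit_rows")
  truth <- sc$sim$truth
  lab_truth <- vapply(rows, function(r) {
    h <- sc$hits[r, ]
    truth$subfamily[truth$start <= h$genome_end &
                    truth$end >= h$genome_start][1]
  }, character(1))
  tab <- table(ref$labels, lab_truth)
  acc <- max(sum(diag(tab)), tab[1, 2] + tab[2, 1]) / sum(tab)
  expect_gte(acc, 0.95)
})

test_that("single-subfamily refinement returns the family consensus", {
  set.seed(77)
  master <- random_dna(267, 0.5)
  ins <- setNames(vapply(1:60, function(i) mutate_k2p(master, 0.03, 2)$seq,
                         ""), paste0("i", 1:60))
  asn <- find_cosegregating_subfamilies(ins, master, min_size = 50)
  ref <- refine_subfamily_consensus(asn, ins, min_size = 50)
  expect_equal(length(ref$consensi), 1)
  expect_lte(adist(ref$consensi[[1]], master)[1, 1], 2)
})

test_that("subfamily presence confirmation counts hits and flags twins", {
  set.seed(78)
  consA <- random_dna(267, 0.5)
  consB <- random_dna(267, 0.5)
  copies <- vapply(1:20, function(i) mutate_k2p(consA, 0.02, 2)$seq, "")
  planted <- plant_copies(random_dna(30000, 0.4), copies,
                          seq(1000, 29000, length.out = 20))
  genome <- c(chr1 = planted$genome)
  rep_ <- confirm_subfamily_presence(
    c(sfA = consA, sfB = consB, sfA2 = consA), genome, min_score = 150)
  expect_equal(rep_$n_hits[rep_$subfamily == "sfA"], 20)
  expect_equal(rep_$n_hits[rep_$subfamily == "sfB"], 0)
  expect_gte(rep_$mean_identity[rep_$subfamily == "sfA"], 0.95)
  expect_true(all(rep_$ambiguous[rep_$subfamily %in% c("sfA", "sfA2")]))
  expect_false(rep_$ambiguous[rep_$subfamily == "sfB"])
})

test_that("composite subfamilies (members embedded in a host) are flagged", {
  set.seed(79)
  host <- random_dna(800, 0.5)
  sine <- random_dna(267, 0.5)
  # composite copies: SINE inside the host element; free copies: alone
  comp <- paste0(substr(host, 1, 400), sine, substr(host, 401, 800))
  copies <- c(rep(comp, 6), rep(sine, 6))
  planted <- plant_copies(random_dna(40000, 0.4), copies,
                          seq(1500, 39000, length.out = 12))
  genome <- c(chr1 = planted$genome)
  hits <- find_hits(genome, c(Host = host, Sine = sine))
  sh <- which(hits$family == "Sine")
  labels <- setNames(ifelse(seq_along(sh) <= 6, "comp", "free"), NULL)
  labels <- vapply(sh, function(r) {
    near <- hits$genome_start[r]
    if (any(hits$family == "Host" &
            abs(hits$genome_end - near) < 50)) "comp" else "free"
  }, character(1))
  flags <- flag_composite_subfamilies(labels, sh, hits)
  expect_true(flags[["comp"]])
  expect_false(flags[["free"]])
})
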