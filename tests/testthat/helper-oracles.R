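# Independent oracles and small fixture builders shared across tests.

# score a complete alignment (two equal-length gapped rows) under the
# affine scheme: a gap run of length L costs gap_open + L * gap_extend
score_alignment_rows <- function(ra, rb, scoring) {
  a <- strsplit(ra, "")[[1]]
  b <- strsplit(rb, "")[[1]]
  s <- 0
  for (k in seq_along(a)) {
    if (a[k] != "-" && b[k] != "-") {
      s <- s + if (a[k] == b[k] && a[k] != "N") scoring$match else
        scoring$mismatch
    }
  }
  for (row in list(a, b)) {
    r <- rle(row == "-")
    for (len in r$lengths[r$values]) {
      s <- s + scoring$gap_open + len * scoring$gap_extend
    }
  }
  s
}

# brute-force optimal global alignment score by enumerating every monotone
# alignment (exponential; for short sequences only)
brute_force_global_score <- function(a, b, scoring) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, ra, rb) {
    if (i > length(ca) && j > length(cb)) {
      s <- score_alignment_rows(paste(ra, collapse = ""),
                                paste(rb, collapse = ""), scoring)
      if (s > best) best <<- s
      return(invisible(NULL))
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, c(ra, ca[i]), c(rb, cb[j]))
    }
    if (i <= length(ca)) rec(i + 1, j, c(ra, ca[i]), c(rb, "-"))
    if (j <= length(cb)) rec(i, j + 1, c(ra, "-"), c(rb, cb[j]))
  }
  rec(1, 1, character(0), character(0))
  best
}

# brute-force K2P distance by explicit per-column case analysis
brute_force_k2p <- function(ra, rb) {
  a <- strsplit(toupper(ra), "")[[1]]
  b <- strsplit(toupper(rb), "")[[1]]
  n <- 0; ts <- 0; tv <- 0
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(a)) {
    x <- a[k]; y <- b[k]
    if (!(x %in% bases) || !(y %in% bases)) next
    n <- n + 1
    if (x == y) next
    pur_x <- x %in% c("A", "G")
    pur_y <- y %in% c("A", "G")
    if (pur_x == pur_y) ts <- ts + 1 else tv <- tv + 1
  }
  if (n == 0) return(NA_real_)
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NaN)
  -0.5 * log(w1 * sqrt(w2))
}

# random aligned pair with optional gaps and Ns, for oracle comparisons
random_aligned_pair <- function(len, p_gap = 0.05, p_n = 0.03, p_sub = 0.2) {
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, len, replace = TRUE)
  b <- a
  sub <- runif(len) < p_sub
  b[sub] <- sample(bases, sum(sub), replace = TRUE)
  a[runif(len) < p_n] <- "N"
  b[runif(len) < p_n] <- "N"
  a[runif(len) < p_gap] <- "-"
  gb <- runif(len) < p_gap & a != "-"
  b[gb] <- "-"
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# plant exact copy sequences into random background at given 1-based
# offsets (offsets refer to the background; copies are inserted, shifting
# downstream coordinates); returns genome string and the final intervals
plant_copies <- function(background, copies, offsets) {
  stopifnot(length(copies) == length(offsets), !is.unsorted(offsets))
  pieces <- character(0)
  iv <- matrix(0L, nrow = length(copies), ncol = 2)
  cursor <- 0L; glen <- 0L
  for (i in seq_along(copies)) {
    pieces <- c(pieces, substr(background, cursor + 1, offsets[i]))
    glen <- glen + (offsets[i] - cursor)
    iv[i, 1] <- glen + 1L
    pieces <- c(pieces, copies[i])
    glen <- glen + nchar(copies[i])
    iv[i, 2] <- glen
    cursor <- offsets[i]
  }
  pieces <- c(pieces, substr(background, cursor + 1, nchar(background)))
  list(genome = paste(pieces, collapse = ""), intervals = iv)
}

# element with a 1089-nt ORF (362 aa + stop) at positions 120-1208,
# guarded so no upstream in-frame start extends it
make_orf_master <- function(total_len = 1400) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  safe <- setdiff(codons, c("TAA", "TAG", "TGA"))
  orf <- paste0("ATG", paste(sample(safe, 361, replace = TRUE),
                             collapse = ""), "TGA")
  paste0(random_dna(116, 0.5), "TAA", orf,
         random_dna(total_len - 1208, 0.5))
}

# a valid hit table row for constructed-coordinate tests
make_hit <- function(seq_id = "chr1", gs, ge, strand = "+", family = "F",
                     cs, ce, score = 100, div = NA_real_) {
  data.frame(seq_id = seq_id, genome_start = gs, genome_end = ge,
             strand = strand, family = family, consensus_start = cs,
             consensus_end = ce, score = score, divergence = div)
}
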