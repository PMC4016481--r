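## alignment_core: pairwise and multiple alignment primitives shared by the
## masker, the consensus builder and the horizontal-transfer screen.
## Pairwise DP is delegated to Biostrings; the center-star MSA, identity
## bookkeeping and N semantics (N matches nothing, and N columns are
## excluded from identity) are defined here.

#' Alignment scoring scheme
#'
#' Affine-gap scoring: a gap of length L costs `gap_open + L * gap_extend`
#' (both negative). N scores as a mismatch against everything, including N.
#'
#' @param match match score (default +1)
#' @param mismatch mismatch score (default -1)
#' @param gap_open gap opening penalty (default -4)
#' @param gap_extend per-base gap extension penalty (default -1)
#' @return a `scoring_scheme` list
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap_open = -4,
                           gap_extend = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

substitution_matrix <- function(scoring) {
  m <- matrix(scoring$mismatch, 5, 5,
              dimnames = list(VALID_BASES, VALID_BASES))
  diag(m)[1:4] <- scoring$match
  m
}

# identity / coverage over a pair of equal-length gapped strings.
# Columns where either row is N are excluded from the identity fraction.
alignment_stats <- function(aligned_a, aligned_b, query_length) {
  a <- seq_chars(aligned_a)
  b <- seq_chars(aligned_b)
  pair <- a != "-" & b != "-"
  comp <- pair & a != "N" & b != "N"
  identity <- if (sum(comp) == 0) 0 else sum(a[comp] == b[comp]) / sum(comp)
  coverage <- sum(a != "-") / query_length
  list(identity = identity, coverage = coverage)
}

do_pairwise <- function(a, b, scoring, type) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence in alignment",
                                     call. = FALSE)
  a <- normalize_seq(a)
  b <- normalize_seq(b)
  ba <- batch_align(a, b, scoring, type)
  if (type == "local" && ba$score <= 0) {
    # best local segment is empty: report the empty alignment at score 0
    return(structure(list(aligned_a = "", aligned_b = "", score = 0,
                          identity = 0, query_coverage = 0,
                          a_start = 0L, a_end = -1L,
                          b_start = 0L, b_end = -1L, type = type),
                     class = "pairwise_alignment"))
  }
  st <- alignment_stats(ba$pattern, ba$subject, nchar(a))
  structure(list(aligned_a = ba$pattern, aligned_b = ba$subject,
                 score = ba$score,
                 identity = st$identity, query_coverage = st$coverage,
                 a_start = ba$pattern_start, a_end = ba$pattern_end,
                 b_start = ba$subject_start, b_end = ba$subject_end,
                 type = type),
            class = "pairwise_alignment")
}

#' Global (Needleman-Wunsch) affine-gap alignment
#'
#' @param a,b nucleotide sequences (single strings)
#' @param scoring a [scoring_scheme()]
#' @return a `pairwise_alignment` with gapped rows, score, identity (over
#'   non-gap, non-N columns) and query coverage
#' @export
global_align <- function(a, b, scoring = scoring_scheme()) {
  do_pairwise(a, b, scoring, "global")
}

#' Local (Smith-Waterman) affine-gap alignment
#'
#' Coordinates of the aligned span on both sequences are 1-based inclusive;
#' when no segment scores above zero an empty alignment with score 0 is
#' returned.
#'
#' @inheritParams global_align
#' @return a `pairwise_alignment` with span coordinates `a_start`/`a_end`,
#'   `b_start`/`b_end`
#' @export
local_align <- function(a, b, scoring = scoring_scheme()) {
  do_pairwise(a, b, scoring, "local")
}

# insert gap runs into a sequence: `ranges` gives, in original sequence
# coordinates, the position each gap run precedes and its width
insert_gap_runs <- function(seqn, starts, widths) {
  if (length(starts) == 0) return(seqn)
  o <- order(starts)
  starts <- starts[o]; widths <- widths[o]
  cuts <- c(1L, starts)
  ends <- c(starts - 1L, nchar(seqn))
  pieces <- substring(seqn, cuts, ends)
  gaps <- c(strrep("-", widths), "")
  paste(rbind(pieces, gaps), collapse = "")
}

# vectorised alignment of many patterns against one subject; returns
# column-consistent gapped strings, rebuilt from the indel ranges to
# avoid per-pair S4 extraction overhead
batch_align <- function(patterns, subject, scoring = scoring_scheme(),
                        type = "global") {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    substitutionMatrix = substitution_matrix(scoring),
    gapOpening = abs(scoring$gap_open),
    gapExtension = abs(scoring$gap_extend),
    type = type)
  pat <- Biostrings::pattern(aln)
  subj <- Biostrings::subject(aln)
  ps <- Biostrings::start(pat); pe <- Biostrings::end(pat)
  ss <- Biostrings::start(subj); se <- Biostrings::end(subj)
  del <- Biostrings::deletion(aln)    # gap runs in the pattern row
  ins <- Biostrings::insertion(aln)   # gap runs in the subject row
  patterns <- as.character(patterns)
  subject <- as.character(subject)
  n <- length(patterns)
  out_p <- character(n); out_s <- character(n)
  for (i in seq_len(n)) {
    p0 <- substr(patterns[i], ps[i], pe[i])
    s0 <- substr(subject, ss[i], se[i])
    d <- del[[i]]; j <- ins[[i]]
    pr <- insert_gap_runs(p0, IRanges::start(d), IRanges::width(d))
    sr <- insert_gap_runs(s0, IRanges::start(j), IRanges::width(j))
    if (type == "global") {
      # restore end-gap columns clipped from the reported spans
      if (ps[i] > 1) {
        pr <- paste0(substr(patterns[i], 1, ps[i] - 1), pr)
        sr <- paste0(strrep("-", ps[i] - 1), sr)
      }
      if (ss[i] > 1) {
        sr <- paste0(substr(subject, 1, ss[i] - 1), sr)
        pr <- paste0(strrep("-", ss[i] - 1), pr)
      }
      if (pe[i] < nchar(patterns[i])) {
        w <- nchar(patterns[i]) - pe[i]
        pr <- paste0(pr, substr(patterns[i], pe[i] + 1, nchar(patterns[i])))
        sr <- paste0(sr, strrep("-", w))
      }
      if (se[i] < nchar(subject)) {
        w <- nchar(subject) - se[i]
        sr <- paste0(sr, substr(subject, se[i] + 1, nchar(subject)))
        pr <- paste0(pr, strrep("-", w))
      }
    }
    out_p[i] <- pr
    out_s[i] <- sr
  }
  list(pattern = out_p, subject = out_s,
       score = Biostrings::score(aln),
       subject_start = ss, subject_end = se,
       pattern_start = ps, pattern_end = pe)
}

# vectorised score-only alignment of many patterns against one subject
align_scores <- function(patterns, subject, scoring = scoring_scheme(),
                         type = "global") {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    substitutionMatrix = substitution_matrix(scoring),
    gapOpening = abs(scoring$gap_open),
    gapExtension = abs(scoring$gap_extend),
    type = type, scoreOnly = TRUE)
}

#' Best-local-alignment identity and query coverage
#'
#' Identity is computed over the best local alignment's aligned columns;
#' coverage is the fraction of query bases inside that alignment. This is
#' the quantity the horizontal-transfer screen thresholds
#' (identity > 0.95 over >= 80% of the query).
#'
#' @param query,subject nucleotide sequences
#' @param scoring a [scoring_scheme()]
#' @return list with `identity` and `coverage`
#' @export
pairwise_identity_and_coverage <- function(query, subject,
                                           scoring = scoring_scheme()) {
  aln <- local_align(query, subject, scoring)
  list(identity = aln$identity, coverage = aln$query_coverage)
}

## --- center-star multiple alignment --------------------------------------

choose_center <- function(seqs, scoring, exact_max = 30) {
  n <- length(seqs)
  if (n <= exact_max) {
    sums <- vapply(seq_len(n), function(i) {
      sum(align_scores(seqs[-i], seqs[[i]], scoring))
    }, numeric(1))
  } else {
    # deterministic k-mer-profile proxy for the max-sum center at scale
    kf <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(seqs), width = 6)
    kf <- kf / pmax(1, sqrt(rowSums(kf^2)))
    sims <- kf %*% t(kf)
    sums <- rowSums(sims)
  }
  which.max(sums)  # ties resolved by input order
}

#' Center-star progressive multiple alignment
#'
#' The center is the input maximising the summed pairwise global alignment
#' scores against the others (for large inputs a deterministic k-mer
#' similarity proxy selects it); the remaining sequences are merged against
#' the center under "once a gap, always a gap". Deterministic given input
#' order.
#'
#' @param seqs character vector (>= 2) of sequences, optionally named
#' @param scoring a [scoring_scheme()]
#' @param exact_center_max above this many sequences the k-mer proxy picks
#'   the center
#' @return an `msa` object: list with `ids`, `rows` (equal-length gapped
#'   strings) and `ncol`
#' @export
build_msa <- function(seqs, scoring = scoring_scheme(),
                      exact_center_max = 30) {
  seqs <- as_seq_vector(seqs)
  n <- length(seqs)
  if (n < 2) stop("build_msa needs at least 2 sequences", call. = FALSE)
  center <- choose_center(seqs, scoring, exact_center_max)
  L <- nchar(seqs[[center]])
  others <- setdiff(seq_len(n), center)

  # per other sequence: insertion block before each center position
  # (slot L+1 = after the last position) and the character aligned to it
  ins <- matrix("", nrow = n, ncol = L + 1)
  chr <- matrix("-", nrow = n, ncol = L)
  chr[center, ] <- seq_chars(seqs[[center]])
  ba <- if (length(others) > 0) {
    batch_align(seqs[others], seqs[[center]], scoring, "global")
  }
  for (oi in seq_along(others)) {
    i <- others[oi]
    ca <- seq_chars(ba$subject[oi])   # center row
    cb <- seq_chars(ba$pattern[oi])   # other sequence
    pos <- 0L
    buf <- character(0)
    for (k in seq_along(ca)) {
      if (ca[k] == "-") {
        buf <- c(buf, cb[k])
      } else {
        pos <- pos + 1L
        ins[i, pos] <- paste(buf, collapse = "")
        buf <- character(0)
        chr[i, pos] <- cb[k]
      }
    }
    ins[i, L + 1] <- paste(buf, collapse = "")
  }
  maxins <- apply(ins, 2, function(x) max(nchar(x)))
  pad <- function(s, w) paste0(s, strrep("-", w - nchar(s)))
  rows <- vapply(seq_len(n), function(i) {
    parts <- character(0)
    for (j in seq_len(L)) {
      if (maxins[j] > 0) parts <- c(parts, pad(ins[i, j], maxins[j]))
      parts <- c(parts, chr[i, j])
    }
    if (maxins[L + 1] > 0) parts <- c(parts, pad(ins[i, L + 1], maxins[L + 1]))
    paste(parts, collapse = "")
  }, character(1))
  structure(list(ids = names(seqs), rows = setNames(rows, names(seqs)),
                 ncol = nchar(rows[[1]]), center = center),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("multiple alignment: %d sequences x %d columns\n",
              length(x$rows), x$ncol))
  invisible(x)
}

# character matrix view of an msa (rows x columns)
msa_matrix <- function(msa) {
  do.call(rbind, lapply(msa$rows, seq_chars))
}

# drop columns that are all gaps (idempotent)
drop_allgap_columns <- function(msa) {
  m <- msa_matrix(msa)
  keep <- colSums(m != "-") > 0
  rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  structure(list(ids = msa$ids, rows = setNames(rows, msa$ids),
                 ncol = sum(keep), center = msa$center), class = "msa")
}
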