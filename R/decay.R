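## decay: map every hit onto its consensus, classify which element ends
## survive, and profile the length distribution of fragments as evidence
## of post-insertion deletion. An abundance of fragments retaining the 3'
## end is the expected footprint of 5'-truncated retrotransposition;
## fragments missing their 3' ends, or purely internal fragments, are
## evidence of genomic deletion.

FRAGMENT_CLASSES <- c("FULL_LENGTH", "FIVE_PRIME_TRUNCATED",
                      "THREE_PRIME_ABSENT", "INTERNAL_ONLY")

#' Classify a fragment by which consensus ends it retains
#'
#' The 5' end counts as present when `consensus_start <= epsilon`, the 3'
#' end when `consensus_end >= L - epsilon`. Both ends present with a span
#' of at least `min_full` is FULL_LENGTH; 3' only is FIVE_PRIME_TRUNCATED
#' (the classic incomplete-retrotransposition product); 5' only is
#' THREE_PRIME_ABSENT; neither (or both ends but an implausibly short
#' span) is INTERNAL_ONLY.
#'
#' @param consensus_start,consensus_end hit span on the consensus
#'   (1-based inclusive); vectorised
#' @param L consensus length
#' @param epsilon end-presence tolerance in bases (default 5% of `L`)
#' @param min_full minimum span for FULL_LENGTH (default 90% of `L`)
#' @return character vector of fragment classes
#' @export
classify_fragment <- function(consensus_start, consensus_end, L,
                              epsilon = 0.05 * L, min_full = 0.90 * L) {
  five <- consensus_start <= epsilon
  three <- consensus_end >= L - epsilon
  span <- consensus_end - consensus_start + 1
  out <- rep("INTERNAL_ONLY", length(consensus_start))
  out[five & three & span >= min_full] <- "FULL_LENGTH"
  out[three & !five] <- "FIVE_PRIME_TRUNCATED"
  out[five & !three] <- "THREE_PRIME_ABSENT"
  out
}

#' Re-join fragments of one insertion split by a nested element
#'
#' Two same-family, same-strand hits whose consensus spans continue within
#' `join_tol` bases and whose genomic gap is mostly occupied by another
#' family's hit are two masker segments of a single insertion interrupted
#' by a nested element; they are merged (consensus span unioned) so that
#' nesting is not mistaken for deletion.
#'
#' @param hits hit table
#' @param join_tol consensus-span continuation tolerance in bases
#' @param min_gap_cover fraction of the genomic gap that must be covered
#'   by other-family hits
#' @return hit table with merged rows (an `n_segments` column counts the
#'   segments each row came from)
#' @export
rejoin_split_fragments <- function(hits, join_tol = 30,
                                   min_gap_cover = 0.5) {
  hits <- hit_table(hits)
  hits$n_segments <- 1L
  if (nrow(hits) < 2) return(hits)
  out <- list()
  for (key in unique(paste(hits$seq_id, hits$family, hits$strand))) {
    parts <- strsplit(key, " ")[[1]]
    grp <- hits[hits$seq_id == parts[1] & hits$family == parts[2] &
                hits$strand == parts[3], , drop = FALSE]
    grp <- grp[order(grp$genome_start), , drop = FALSE]
    other <- hits[hits$seq_id == parts[1] & hits$family != parts[2], ,
                  drop = FALSE]
    other_ir <- IRanges::reduce(IRanges::IRanges(other$genome_start,
                                                 other$genome_end))
    i <- 1
    while (i < nrow(grp)) {
      a <- grp[i, ]; b <- grp[i + 1, ]
      cont <- if (parts[3] == "+") b$consensus_start - a$consensus_end - 1L
              else a$consensus_start - b$consensus_end - 1L
      gap_s <- a$genome_end + 1L; gap_e <- b$genome_start - 1L
      occupied <- FALSE
      if (gap_e >= gap_s && length(other_ir) > 0) {
        ov <- IRanges::intersect(other_ir, IRanges::IRanges(gap_s, gap_e))
        occupied <- sum(IRanges::width(ov)) / (gap_e - gap_s + 1) >=
          min_gap_cover
      }
      if (abs(cont) <= join_tol && occupied && gap_e >= gap_s) {
        grp$genome_end[i] <- b$genome_end
        grp$consensus_start[i] <- min(a$consensus_start, b$consensus_start)
        grp$consensus_end[i] <- max(a$consensus_end, b$consensus_end)
        grp$score[i] <- a$score + b$score
        grp$divergence[i] <- mean(c(a$divergence, b$divergence), na.rm = TRUE)
        grp$n_segments[i] <- a$n_segments + b$n_segments
        grp <- grp[-(i + 1), , drop = FALSE]
      } else {
        i <- i + 1
      }
    }
    out[[key]] <- grp
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$genome_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fragment decay profile for one family
#'
#' Hit spans on the consensus are ordered by length descending (the
#' longest insertions sit at the bottom of the stacked plot) and reported
#' both in consensus coordinates and normalised to `[0,1]`, together with
#' the fragment class histogram.
#'
#' @param hits hit table rows for one family
#' @param L consensus length
#' @param epsilon_frac end tolerance as a fraction of `L`
#' @return a `decay_profile`: list with `family`, `n`, `intervals`
#'   (data.frame: consensus_start/end, norm_start/end, class, sorted by
#'   length descending then start) and `class_counts`
#' @export
decay_profile <- function(hits, L, epsilon_frac = 0.05) {
  hits <- hit_table(hits)
  if (nrow(hits) == 0) stop("decay_profile needs at least one hit",
                            call. = FALSE)
  fam <- unique(hits$family)
  cls <- classify_fragment(hits$consensus_start, hits$consensus_end, L,
                           epsilon = epsilon_frac * L)
  len <- hits$consensus_end - hits$consensus_start + 1
  ord <- order(-len, hits$consensus_start)
  iv <- data.frame(consensus_start = hits$consensus_start[ord],
                   consensus_end = hits$consensus_end[ord],
                   norm_start = (hits$consensus_start[ord] - 1) / L,
                   norm_end = hits$consensus_end[ord] / L,
                   class = cls[ord])
  counts <- table(factor(cls, levels = FRAGMENT_CLASSES))
  structure(list(family = if (length(fam) == 1) fam else "mixed",
                 n = nrow(hits), L = L, intervals = iv,
                 class_counts = counts),
            class = "decay_profile")
}

#' @export
print.decay_profile <- function(x, ...) {
  cat(sprintf("decay profile for %s: %d fragments on a %d-bp consensus\n",
              x$family, x$n, x$L))
  print(x$class_counts)
  invisible(x)
}

#' Per-family deletion-evidence summary
#'
#' Aggregates fragment classes per family (after re-joining nested-split
#' fragments) and reports the retrotransposition-consistency ratio
#' `(FULL_LENGTH + FIVE_PRIME_TRUNCATED) / max(1, THREE_PRIME_ABSENT +
#' INTERNAL_ONLY)`: pure 5'-truncated retrotransposition keeps the 3' end,
#' so fragments lacking it indicate deletion.
#'
#' @param hits hit table across families
#' @param consensus_lengths named integer vector of consensus lengths
#' @param epsilon_frac end tolerance fraction
#' @param join_tol see [rejoin_split_fragments()]
#' @return data.frame per family: n, the four class counts and fractions,
#'   and `retro_ratio`
#' @export
deletion_evidence_summary <- function(hits, consensus_lengths,
                                      epsilon_frac = 0.05, join_tol = 30) {
  hits <- rejoin_split_fragments(hits, join_tol)
  rows <- lapply(sort(unique(hits$family)), function(fam) {
    fh <- hits[hits$family == fam, , drop = FALSE]
    L <- consensus_lengths[[fam]]
    if (is.null(L)) stop("no consensus length for family ", fam,
                         call. = FALSE)
    cls <- classify_fragment(fh$consensus_start, fh$consensus_end, L,
                             epsilon = epsilon_frac * L)
    ct <- table(factor(cls, levels = FRAGMENT_CLASSES))
    n <- nrow(fh)
    data.frame(family = fam, n = n,
               full_length = as.integer(ct["FULL_LENGTH"]),
               five_prime_truncated = as.integer(ct["FIVE_PRIME_TRUNCATED"]),
               three_prime_absent = as.integer(ct["THREE_PRIME_ABSENT"]),
               internal_only = as.integer(ct["INTERNAL_ONLY"]),
               frac_deletion_classes =
                 (ct[["THREE_PRIME_ABSENT"]] + ct[["INTERNAL_ONLY"]]) / n,
               retro_ratio = (ct[["FULL_LENGTH"]] +
                              ct[["FIVE_PRIME_TRUNCATED"]]) /
                 max(1, ct[["THREE_PRIME_ABSENT"]] + ct[["INTERNAL_ONLY"]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
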