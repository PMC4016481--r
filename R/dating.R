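## dating: Kimura 2-parameter divergence of each insertion from its
## (sub)family consensus, summarised per family and converted to activity
## windows in millions of years.

TRANSITION_PAIRS <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)

is_transition <- function(a, b) {
  !is.na(TRANSITION_PAIRS[paste0(a, b)])
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with `P` and `Q` the
#' transition and transversion fractions over columns where both characters
#' are in A/C/G/T (gap and N columns are excluded; CpG sites are not given
#' any special treatment).
#'
#' @param aligned_a,aligned_b equal-length aligned strings (gaps as `-`)
#' @param on_saturation what to do when the log argument is non-positive:
#'   `"error"` (default) raises a condition of class `k2p_saturation`,
#'   `"nan"` returns NaN
#' @return the distance in substitutions/site, with attributes `P`, `Q`
#'   and `sites` (number of comparable columns)
#' @export
k2p_distance <- function(aligned_a, aligned_b,
                         on_saturation = c("error", "nan")) {
  on_saturation <- match.arg(on_saturation)
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  a <- seq_chars(toupper(aligned_a))
  b <- seq_chars(toupper(aligned_b))
  comp <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(comp)
  if (n == 0) stop("no comparable columns for K2P distance", call. = FALSE)
  a <- a[comp]; b <- b[comp]
  diff <- a != b
  ts <- sum(diff & is_transition(a, b))
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    if (on_saturation == "error") {
      stop(structure(class = c("k2p_saturation", "error", "condition"),
                     list(message = sprintf(
                       "K2P distance saturated (P=%.3f, Q=%.3f over %d sites)",
                       P, Q, n), call = NULL)))
    }
    return(structure(NaN, P = P, Q = Q, sites = n))
  }
  structure(-0.5 * log(w1 * sqrt(w2)), P = P, Q = Q, sites = n)
}

#' Convert a divergence summary to an activity window in Mya
#'
#' The window is `(mean - sd, mean + sd) / rate`, rounded half-up to one
#' decimal; a negative lower bound is clamped to 0.
#'
#' @param mean mean K2P distance
#' @param sd standard deviation of the distances
#' @param rate neutral substitution rate in substitutions/site/My
#'   (default 0.01909, a Papilioninae estimate)
#' @return numeric vector `c(time_low_mya, time_high_mya)` (or a 2-column
#'   matrix for vector input)
#' @export
divergence_to_time <- function(mean, sd, rate = 0.01909) {
  stopifnot(rate > 0, all(sd >= 0))
  low <- pmax(0, round_half_up((mean - sd) / rate, 1))
  high <- round_half_up((mean + sd) / rate, 1)
  if (length(mean) == 1) c(time_low_mya = low, time_high_mya = high)
  else cbind(time_low_mya = low, time_high_mya = high)
}

# library segment used for dating comparisons, per family.
# mode "consensus": whole consensus; "orf": the ORF span; "orf3p": the
# 3'-most `orf3p_len` bases of the ORF (the library design used for dating
# autonomous non-LTR elements). `orfs` is a data.frame with columns
# family, start, end.
dating_segment <- function(family, library, mode, orfs = NULL,
                           orf3p_len = 500) {
  cons <- library[[family]]
  if (is.null(cons)) stop("family missing from library: ", family,
                          call. = FALSE)
  if (mode == "consensus") return(c(1L, nchar(cons)))
  if (is.null(orfs)) stop("orfs table required for ORF dating modes",
                          call. = FALSE)
  row <- orfs[orfs$family == family, , drop = FALSE]
  if (nrow(row) == 0) return(c(1L, nchar(cons)))
  s <- row$start[1]; e <- row$end[1]
  if (mode == "orf") return(c(s, e))
  c(max(s, e - orf3p_len + 1L), e)  # orf3p
}

#' Per-family divergence summaries
#'
#' Each hit is extracted from the genome (reverse-complemented for minus
#' strand), globally aligned to its consensus span and its K2P distance to
#' the consensus computed over the selected comparison segment. Saturated
#' pairs are excluded and counted, never imputed. The per-family summary
#' reports n, mean, SD (population SD by default), range = mean +/- SD and
#' the activity window in Mya.
#'
#' @param hits hit table
#' @param genome named character vector of genome sequences
#' @param library named character vector of family consensi
#' @param mode comparison segment: `"consensus"`, `"orf"` or `"orf3p"`
#' @param orfs optional data.frame (family, start, end) of consensus ORF
#'   coordinates for the ORF modes
#' @param rate substitution rate in subs/site/My
#' @param sd_type `"population"` (n denominator) or `"sample"` (n - 1)
#' @param min_overlap minimum overlap (bases) between a hit's consensus
#'   span and the comparison segment
#' @param extend_max hit ends falling within this many bases of the
#'   consensus ends are restored before dating: local alignment trims
#'   mismatch-dense termini, which would otherwise bias distances downward
#'   for old families; ends further away are treated as genuine truncation
#'   and left alone
#' @param scoring a [scoring_scheme()]
#' @return data.frame with one row per family: n, n_saturated,
#'   mean_distance, sd, range_low, range_high, time_low_mya, time_high_mya
#' @export
family_divergence <- function(hits, genome, library, mode = "consensus",
                              orfs = NULL, rate = 0.01909,
                              sd_type = c("population", "sample"),
                              min_overlap = 30, extend_max = 25,
                              scoring = scoring_scheme()) {
  sd_type <- match.arg(sd_type)
  stopifnot(mode %in% c("consensus", "orf", "orf3p"))
  hits <- hit_table(hits)
  genome <- as_seq_vector(genome, "genome")
  library <- as_seq_vector(library, "library")
  out <- list()
  for (fam in sort(unique(hits$family))) {
    seg <- dating_segment(fam, library, mode, orfs)
    cons <- library[[fam]]
    fh <- hits[hits$family == fam, , drop = FALSE]
    ov <- pmin(fh$consensus_end, seg[2]) - pmax(fh$consensus_start, seg[1]) + 1
    fh <- fh[ov >= min_overlap, , drop = FALSE]
    dists <- numeric(0)
    n_sat <- 0L
    if (nrow(fh) > 0) {
      L <- nchar(cons)
      copies <- vapply(seq_len(nrow(fh)), function(r) {
        h <- fh[r, ]
        e5 <- h$consensus_start - 1L
        e3 <- L - h$consensus_end
        if (e5 > extend_max) e5 <- 0L
        if (e3 > extend_max) e3 <- 0L
        gl <- nchar(genome[[h$seq_id]])
        if (h$strand == "+") {
          s <- substr(genome[[h$seq_id]], max(1L, h$genome_start - e5),
                      min(gl, h$genome_end + e3))
        } else {
          s <- revcomp(substr(genome[[h$seq_id]],
                              max(1L, h$genome_start - e3),
                              min(gl, h$genome_end + e5)))
        }
        s
      }, character(1))
      # each copy aligned end-to-end inside the consensus (fit alignment)
      ba <- batch_align(copies, cons, scoring, type = "global-local")
      for (r in seq_len(nrow(fh))) {
        cs <- seq_chars(ba$subject[r])
        pos <- ba$subject_start[r] - 1L + cumsum(cs != "-")
        # restrict the comparison to the segment: mask consensus columns
        # outside [seg1, seg2] so k2p_distance ignores them
        mask <- cs != "-" & (pos < seg[1] | pos > seg[2])
        cs[mask] <- "N"
        d <- tryCatch(
          k2p_distance(paste(cs, collapse = ""), ba$pattern[r]),
          k2p_saturation = function(e) NaN,
          error = function(e) NA_real_)
        if (is.na(d)) { if (is.nan(d)) n_sat <- n_sat + 1L; next }
        dists <- c(dists, as.numeric(d))
      }
    }
    n <- length(dists)
    if (n == 0) {
      out[[fam]] <- data.frame(family = fam, n = 0L, n_saturated = n_sat,
                               mean_distance = NA_real_, sd = NA_real_,
                               range_low = NA_real_, range_high = NA_real_,
                               time_low_mya = NA_real_,
                               time_high_mya = NA_real_)
      next
    }
    m <- mean(dists)
    s <- if (n < 2) NA_real_
         else if (sd_type == "population") sqrt(mean((dists - m)^2))
         else sd(dists)
    s_eff <- if (is.na(s)) 0 else s
    tw <- divergence_to_time(m, s_eff, rate)
    out[[fam]] <- data.frame(family = fam, n = n, n_saturated = n_sat,
                             mean_distance = m, sd = s,
                             range_low = m - s_eff, range_high = m + s_eff,
                             time_low_mya = tw[[1]], time_high_mya = tw[[2]])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
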