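## masker: simplified RepeatMasker-style annotator. Exact k-mer seeds on
## both strands define candidate windows; each window is aligned locally
## against the consensus, iterating with hard masking so tandem or nested
## copies in one window are all recovered; alignments are split at long
## gaps so an insertion interrupted by another element yields one hit per
## contiguous segment.

# k-mer seed positions of `probe` in `subject_seq` -> implied element
# windows (IRanges), padded and merged
seed_windows <- function(probe, subject_seq, k, pad) {
  Lp <- nchar(probe)
  Ls <- nchar(subject_seq)
  if (Lp < k || Ls < k) return(IRanges::IRanges())
  starts <- seq_len(Lp - k + 1)
  kmers <- substring(probe, starts, starts + k - 1)
  ok <- !grepl("N", kmers, fixed = TRUE)
  if (!any(ok)) return(IRanges::IRanges())
  kmers <- kmers[ok]; kpos <- starts[ok]
  uniq <- !duplicated(kmers)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[uniq]))
  mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(subject_seq))
  hit_starts <- IRanges::start(mi)
  upos <- kpos[uniq]
  ws <- integer(0); we <- integer(0)
  for (i in seq_along(hit_starts)) {
    g <- hit_starts[[i]]
    if (length(g) == 0) next
    impl <- g - (upos[i] - 1L)
    ws <- c(ws, impl - pad)
    we <- c(we, impl + Lp - 1L + pad)
  }
  if (length(ws) == 0) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(pmax(1L, ws), pmin(Ls, we)))
}

# split one local alignment at gap runs longer than split_gap; returns a
# list of pieces with genome/consensus spans, score and divergence
split_alignment <- function(aln, win_offset, probe_len, strand, scoring,
                            split_gap, min_len) {
  a <- seq_chars(aln$aligned_a)   # probe (consensus, possibly revcomp)
  b <- seq_chars(aln$aligned_b)   # genomic window
  ncol <- length(a)
  # gap run ids: columns belonging to a gap run in either row
  gap <- a == "-" | b == "-"
  runs <- rle(gap)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  breaklong <- runs$values & runs$lengths > split_gap
  # piece boundaries: non-gap stretches between long gap runs
  piece_id <- integer(ncol)
  cur <- 1L
  for (r in seq_along(runs$lengths)) {
    if (breaklong[r]) {
      piece_id[starts[r]:ends[r]] <- 0L
      cur <- cur + 1L
    } else {
      piece_id[starts[r]:ends[r]] <- cur
    }
  }
  apos <- cumsum(a != "-") + aln$a_start - 1L   # probe coordinate per column
  bpos <- cumsum(b != "-") + aln$b_start - 1L   # window coordinate per column
  mat <- substitution_matrix(scoring)
  pieces <- list()
  for (p in unique(piece_id[piece_id > 0])) {
    cols <- which(piece_id == p)
    cols <- cols[a[cols] != "-" | b[cols] != "-"]
    keep <- cols[a[cols] != "-" & b[cols] != "-"]
    if (length(keep) == 0) next
    g1 <- bpos[min(keep)]; g2 <- bpos[max(keep)]
    c1 <- apos[min(keep)]; c2 <- apos[max(keep)]
    if (g2 - g1 + 1 < min_len) next
    # rescore the piece (affine gaps within the piece)
    sub <- cols[cols >= min(keep) & cols <= max(keep)]
    ap <- a[sub]; bp <- b[sub]
    both <- ap != "-" & bp != "-"
    msc <- sum(mat[cbind(ap[both], bp[both])])
    for (row in list(ap, bp)) {
      gr <- rle(row == "-")
      glen <- gr$lengths[gr$values]
      if (length(glen) > 0) {
        msc <- msc + sum(scoring$gap_open + glen * scoring$gap_extend)
      }
    }
    aligned_a <- paste(ap, collapse = "")
    aligned_b <- paste(bp, collapse = "")
    div <- tryCatch(as.numeric(k2p_distance(aligned_a, aligned_b,
                                            on_saturation = "nan")),
                    error = function(e) NA_real_)
    if (strand == "-") {
      cc <- c(probe_len - c2 + 1L, probe_len - c1 + 1L)
    } else {
      cc <- c(c1, c2)
    }
    pieces[[length(pieces) + 1]] <- data.frame(
      genome_start = win_offset + g1 - 1L,
      genome_end = win_offset + g2 - 1L,
      consensus_start = cc[1], consensus_end = cc[2],
      score = msc, divergence = div)
  }
  pieces
}

#' Annotate a genome with a TE consensus library
#'
#' Seed-and-extend search of every library consensus against every genome
#' sequence on both strands. A hit is retained when its (whole-alignment)
#' score reaches `min_score`; alignments are split at gap runs longer than
#' `split_gap` bases into per-segment hits, and segments shorter than
#' `min_len` are dropped. Overlapping hits are resolved best-score-first
#' (ties: longer hit, then lexicographic family name), leaving no two
#' retained hits overlapping by more than `overlap_tol` bases.
#'
#' @param genome named character vector (or XStringSet) of genome sequences
#' @param library named character vector of consensus sequences (>= 30 bp)
#' @param k seed k-mer length
#' @param min_score minimum local alignment score for a hit
#' @param min_len minimum hit length in bases
#' @param overlap_tol maximum residual overlap between retained hits
#' @param split_gap gap length above which an alignment is split into
#'   separate hits
#' @param pad window padding around the implied element span
#' @param min_piece_score minimum score of an individual split segment
#' @param max_iter_per_window cap on masked re-alignment rounds per window
#' @param scoring a [scoring_scheme()]
#' @return a hit table (see [hit_table()]) with per-hit K2P divergence
#' @export
find_hits <- function(genome, library, k = 12, min_score = 150,
                      min_len = 30, overlap_tol = 10, split_gap = 40,
                      pad = 50, min_piece_score = 25,
                      max_iter_per_window = 25,
                      scoring = scoring_scheme()) {
  genome <- as_seq_vector(genome, "genome")
  library <- as_seq_vector(library, "library")
  if (length(library) == 0) stop("empty consensus library", call. = FALSE)
  if (any(nchar(library) < 30)) {
    stop("library consensi must be at least 30 bp", call. = FALSE)
  }
  cand <- list()
  for (sid in names(genome)) {
    gseq <- genome[[sid]]
    for (fam in names(library)) {
      cons <- library[[fam]]
      Lp <- nchar(cons)
      for (strand in c("+", "-")) {
        probe <- if (strand == "+") cons else revcomp(cons)
        wins <- seed_windows(probe, gseq, k, pad)
        for (w in seq_along(wins)) {
          ws <- IRanges::start(wins)[w]; we <- IRanges::end(wins)[w]
          wseq <- substr(gseq, ws, we)
          for (iter in seq_len(max_iter_per_window)) {
            aln <- local_align(probe, wseq, scoring)
            if (aln$score < min_score) break
            pieces <- split_alignment(aln, ws, Lp, strand, scoring,
                                      split_gap, min_len)
            for (pc in pieces) {
              if (pc$score < min_piece_score) next
              pc$seq_id <- sid; pc$strand <- strand; pc$family <- fam
              cand[[length(cand) + 1]] <- pc
            }
            # hard-mask the aligned subject span and search again
            substr(wseq, aln$b_start, aln$b_end) <-
              strrep("N", aln$b_end - aln$b_start + 1)
          }
        }
      }
    }
  }
  if (length(cand) == 0) return(hit_table(data.frame()))
  cand <- do.call(rbind, cand)
  cand <- cand[!duplicated(cand[, c("seq_id", "genome_start", "genome_end",
                                    "strand", "family")]), , drop = FALSE]
  resolve_overlaps(cand, overlap_tol)
}

# greedy best-score-first overlap resolution across all families. A lower
# scoring hit overlapping a kept hit by a small margin is clipped back to
# the kept hit's boundary (alignment ends wobble across exact junctions);
# only hits that still overlap after clipping are discarded.
resolve_overlaps <- function(cand, overlap_tol, trim_max = 40,
                             min_len = 30) {
  len <- cand$genome_end - cand$genome_start + 1
  ord <- order(-cand$score, -len, cand$family, cand$seq_id,
               cand$genome_start)
  cand <- cand[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  kept_by_seq <- split(seq_len(nrow(cand)), cand$seq_id)
  clip <- function(i, side, t) {
    # adjust genome and consensus coordinates together; approximate for
    # gapped alignments, exact for substitution-only hits
    if (side == "left") {
      cand$genome_start[i] <<- cand$genome_start[i] + t
      if (cand$strand[i] == "+") {
        cand$consensus_start[i] <<- cand$consensus_start[i] + t
      } else {
        cand$consensus_end[i] <<- cand$consensus_end[i] - t
      }
    } else {
      cand$genome_end[i] <<- cand$genome_end[i] - t
      if (cand$strand[i] == "+") {
        cand$consensus_end[i] <<- cand$consensus_end[i] - t
      } else {
        cand$consensus_start[i] <<- cand$consensus_start[i] + t
      }
    }
  }
  for (idxs in kept_by_seq) {
    ks <- integer(0); ke <- integer(0)
    for (i in idxs) {
      ok <- TRUE
      for (pass in 1:2) {
        s <- cand$genome_start[i]; e <- cand$genome_end[i]
        if (length(ks) == 0) break
        ov <- pmin(e, ke) - pmax(s, ks) + 1
        w <- which(ov > overlap_tol)
        if (length(w) == 0) break
        if (pass == 2) { ok <- FALSE; break }
        for (j in w) {
          o <- ov[j]
          if (o > trim_max) { ok <- FALSE; break }
          if (ks[j] <= s) clip(i, "left", o) else clip(i, "right", o)
        }
        if (!ok) break
        if (cand$genome_end[i] - cand$genome_start[i] + 1 < min_len ||
            cand$consensus_end[i] < cand$consensus_start[i]) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      kept[i] <- TRUE
      ks <- c(ks, cand$genome_start[i]); ke <- c(ke, cand$genome_end[i])
    }
  }
  hit_table(cand[kept, , drop = FALSE])
}

#' Genome-fraction summary of masked bases
#'
#' Per-base union coverage per family, per class (via `taxonomy`) and in
#' total; overlapping hits are counted once per base, so class totals are
#' unions, not sums. Families absent from the taxonomy are reported under
#' "Unclassified".
#'
#' @param hits hit table
#' @param genome_lengths named integer vector of sequence lengths
#' @param taxonomy optional named character vector mapping family -> class
#' @return data.frame with columns level ("family"/"class"/"total"), name,
#'   masked_bases, percent (rounded to 2 decimals)
#' @export
genome_fraction <- function(hits, genome_lengths, taxonomy = NULL) {
  hits <- hit_table(hits)
  gtot <- sum(as.numeric(genome_lengths))
  union_bases <- function(df) {
    if (nrow(df) == 0) return(0)
    sum(vapply(split(df, df$seq_id), function(d) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(d$genome_start, d$genome_end))))
    }, numeric(1)))
  }
  fams <- sort(unique(hits$family))
  cls_of <- function(f) {
    if (is.null(taxonomy) || is.na(taxonomy[f] %||% NA)) "Unclassified"
    else unname(taxonomy[f])
  }
  fam_rows <- lapply(fams, function(f) {
    mb <- union_bases(hits[hits$family == f, ])
    data.frame(level = "family", name = f, class = cls_of(f),
               masked_bases = mb, percent = round(100 * mb / gtot, 2))
  })
  classes <- sort(unique(vapply(fams, cls_of, character(1))))
  cls_rows <- lapply(classes, function(cl) {
    members <- fams[vapply(fams, cls_of, character(1)) == cl]
    mb <- union_bases(hits[hits$family %in% members, ])
    data.frame(level = "class", name = cl, class = cl,
               masked_bases = mb, percent = round(100 * mb / gtot, 2))
  })
  tot <- union_bases(hits)
  out <- rbind(do.call(rbind, fam_rows), do.call(rbind, cls_rows),
               data.frame(level = "total", name = "Total", class = NA,
                          masked_bases = tot,
                          percent = round(100 * tot / gtot, 2)))
  rownames(out) <- NULL
  out
}
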