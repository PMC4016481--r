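## orf_analysis: ORF discovery in consensi and the intact-ORF census among
## genomic copies. Intactness uses three criteria: >= 90% of the expected
## amino-acid length, a methionine start codon, and a single stop codon at
## the terminus of the trimmed span.

STOP_CODONS <- c("TAA", "TAG", "TGA")

codons_of <- function(seqn) {
  n3 <- floor(nchar(seqn) / 3)
  if (n3 == 0) return(character(0))
  starts <- seq(1, by = 3, length.out = n3)
  substring(seqn, starts, starts + 2)
}

orfs_in_frame <- function(seqn, offset, min_len_nt) {
  cod <- codons_of(substr(seqn, offset, nchar(seqn)))
  if (length(cod) == 0) return(NULL)
  out <- list()
  start_at <- NA_integer_
  for (i in seq_along(cod)) {
    if (is.na(start_at) && cod[i] == "ATG") start_at <- i
    if (!is.na(start_at) && cod[i] %in% STOP_CODONS) {
      len_nt <- (i - start_at + 1) * 3
      if (len_nt >= min_len_nt) {
        s <- offset + (start_at - 1) * 3
        out[[length(out) + 1]] <- c(start = s, end = s + len_nt - 1)
      }
      start_at <- NA_integer_
    }
  }
  out
}

#' Find long open reading frames in a consensus
#'
#' Six-frame scan; an ORF runs from a methionine start codon to the first
#' in-frame stop codon (the reported span includes the stop codon, so the
#' expected amino-acid length is `span/3 - 1`). Only ORFs of at least
#' `min_len_nt` bases are reported, longest first. Reverse-strand ORFs are
#' reported with strand `-` and forward-strand coordinates.
#'
#' @param consensus consensus sequence
#' @param min_len_nt minimum ORF span in bases (default 1000)
#' @return data.frame: start, end (1-based inclusive, forward strand),
#'   strand, length_nt, expected_aa
#' @export
find_orfs <- function(consensus, min_len_nt = 1000) {
  consensus <- normalize_seq(consensus, "consensus")
  L <- nchar(consensus)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") consensus else revcomp(consensus)
    for (offset in 1:3) {
      for (orf in orfs_in_frame(s, offset, min_len_nt)) {
        if (strand == "+") {
          st <- orf[["start"]]; en <- orf[["end"]]
        } else {
          st <- L - orf[["end"]] + 1L; en <- L - orf[["start"]] + 1L
        }
        rows[[length(rows) + 1]] <- data.frame(
          start = st, end = en, strand = strand,
          length_nt = en - st + 1L,
          expected_aa = as.integer((en - st + 1L) / 3) - 1L)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), length_nt = integer(),
                      expected_aa = integer()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$length_nt, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# map a consensus position to the subject coordinate through a local
# alignment (pattern = consensus); returns the subject position aligned to
# the first pattern position >= p (for ends: <= p) with a subject base
map_consensus_pos <- function(aln, p, side) {
  ca <- seq_chars(aln$aligned_a)
  cb <- seq_chars(aln$aligned_b)
  apos <- cumsum(ca != "-") + aln$a_start - 1L
  bpos <- cumsum(cb != "-") + aln$b_start - 1L
  usable <- ca != "-" & cb != "-"
  if (side == "start") {
    k <- which(usable & apos >= p)
    if (length(k) == 0) return(NA_integer_)
    bpos[min(k)]
  } else {
    k <- which(usable & apos <= p)
    if (length(k) == 0) return(NA_integer_)
    bpos[max(k)]
  }
}

#' Census of intact ORFs among genomic copies
#'
#' Takes the top `max_candidates` hits (by score; ties broken by length
#' then position) whose consensus span covers at least `min_cover` of the
#' ORF span, extracts each with `buffer` bases of context, aligns it to
#' the consensus, trims it to the ORF boundaries, and translates frame 1
#' of the trimmed sequence. A copy is intact iff the translated length
#' before the first stop is at least `min_aa_frac` of the expected
#' amino-acid length, the first codon is ATG, and there is exactly one
#' stop codon, at the terminus. Frameshifted copies are caught by the stop
#' criteria; no frame correction is attempted.
#'
#' @param genome named character vector of genome sequences
#' @param hits hit table rows for the element
#' @param consensus the element consensus
#' @param orf one row of [find_orfs()] output (or a list with `start`,
#'   `end`, `expected_aa`)
#' @param max_candidates examine at most this many hits (default 50)
#' @param buffer context bases extracted on each side (default 1000)
#' @param min_cover minimum fraction of the ORF span a hit must cover
#' @param min_aa_frac minimum fraction of the expected aa length
#' @param scoring a [scoring_scheme()]
#' @return an `orf_census`: list with `examined`, `intact`,
#'   `mean_identity_intact` (mean pairwise identity among intact copies)
#'   and a per-candidate data.frame `detail`
#' @export
count_intact_orfs <- function(genome, hits, consensus, orf,
                              max_candidates = 50, buffer = 1000,
                              min_cover = 0.80, min_aa_frac = 0.90,
                              scoring = scoring_scheme()) {
  genome <- as_seq_vector(genome, "genome")
  consensus <- normalize_seq(consensus, "consensus")
  hits <- hit_table(hits)
  ospan <- orf$end - orf$start + 1
  cover <- (pmin(hits$consensus_end, orf$end) -
            pmax(hits$consensus_start, orf$start) + 1) / ospan
  cand <- hits[cover >= min_cover, , drop = FALSE]
  len <- cand$genome_end - cand$genome_start + 1
  cand <- cand[order(-cand$score, -len, cand$seq_id, cand$genome_start), ,
               drop = FALSE]
  cand <- head(cand, max_candidates)
  detail <- list()
  trimmed_intact <- character(0)
  for (i in seq_len(nrow(cand))) {
    h <- cand[i, ]
    gl <- nchar(genome[[h$seq_id]])
    s <- max(1L, h$genome_start - buffer)
    e <- min(gl, h$genome_end + buffer)
    ext <- substr(genome[[h$seq_id]], s, e)
    if (h$strand == "-") ext <- revcomp(ext)
    aln <- local_align(consensus, ext, scoring)
    ts <- map_consensus_pos(aln, orf$start, "start")
    te <- map_consensus_pos(aln, orf$end, "end")
    flag <- if (h$genome_start - buffer < 1 || h$genome_end + buffer > gl)
      "contig_edge" else ""
    if (is.na(ts) || is.na(te) || te <= ts) {
      detail[[i]] <- data.frame(row = i, intact = FALSE, aa_len = 0L,
                                note = paste0("unmappable ", flag))
      next
    }
    trimmed <- substr(ext, ts, te)
    cod <- codons_of(trimmed)
    stops <- which(cod %in% STOP_CODONS)
    aa_before_stop <- if (length(stops) == 0) length(cod) else stops[1] - 1L
    intact <- length(cod) > 0 &&
      cod[1] == "ATG" &&
      length(stops) == 1 && stops[1] == length(cod) &&
      aa_before_stop >= min_aa_frac * orf$expected_aa
    if (intact) trimmed_intact <- c(trimmed_intact, trimmed)
    detail[[i]] <- data.frame(row = i, intact = intact,
                              aa_len = aa_before_stop, note = flag)
  }
  detail <- if (length(detail) == 0)
    data.frame(row = integer(), intact = logical(), aa_len = integer(),
               note = character())
  else do.call(rbind, detail)
  mean_ident <- NA_real_
  k <- length(trimmed_intact)
  if (k >= 2) {
    # sample a deterministic subset of pairs if there are many copies
    idx <- if (k > 25) seq_len(25) else seq_len(k)
    prs <- combn(idx, 2)
    ids <- vapply(seq_len(ncol(prs)), function(j) {
      a <- trimmed_intact[prs[1, j]]; b <- trimmed_intact[prs[2, j]]
      if (nchar(a) == nchar(b)) {
        ac <- seq_chars(a); bc <- seq_chars(b)
        comp <- ac != "N" & bc != "N"
        sum(ac[comp] == bc[comp]) / max(1, sum(comp))
      } else {
        global_align(a, b, scoring)$identity
      }
    }, numeric(1))
    mean_ident <- mean(ids)
  }
  structure(list(examined = nrow(cand), intact = sum(detail$intact),
                 mean_identity_intact = mean_ident, detail = detail),
            class = "orf_census")
}

#' @export
print.orf_census <- function(x, ...) {
  cat(sprintf("ORF census: %d intact of %d examined copies\n",
              x$intact, x$examined))
  invisible(x)
}
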