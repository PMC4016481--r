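## consensus_builder: iterative consensus construction. Top-scoring copies
## are extracted with flanking sequence, aligned, reduced to a 50%
## majority-rule consensus, and the consensus is extended/trimmed until the
## flanks are single-copy DNA (low mean pairwise identity), i.e. the
## element boundaries have been reached.

#' Extract top-scoring copies of a probe with flanking sequence
#'
#' Hits are found with the masker machinery, ranked by score, and up to
#' `max_copies` hits spanning at least `min_span` bases of the probe are
#' extracted together with up to `flank` bases of flanking sequence
#' (truncated at contig ends). Minus-strand copies are reverse-complemented
#' into probe orientation.
#'
#' @param genome named character vector of genome sequences
#' @param probe probe sequence (single string, >= `min_span` bases)
#' @param max_copies maximum number of copies returned
#' @param min_span minimum aligned probe span (bases)
#' @param flank flanking bases to include on each side
#' @param ... further arguments to [find_hits()] (e.g. `min_score`)
#' @return list with `seqs` (character vector), `left_flank`/`right_flank`
#'   (realised flank lengths per copy, in returned orientation) and `hits`
#' @export
extract_copies <- function(genome, probe, max_copies = 50, min_span = 100,
                           flank = 1000, ...) {
  genome <- as_seq_vector(genome, "genome")
  probe <- normalize_seq(probe, "probe")
  if (nchar(probe) < min_span) {
    stop("probe is shorter than min_span", call. = FALSE)
  }
  hits <- find_hits(genome, setNames(probe, "probe"), ...)
  if (nrow(hits) == 0) {
    return(list(seqs = character(0), left_flank = integer(0),
                right_flank = integer(0), hits = hits))
  }
  span <- hits$consensus_end - hits$consensus_start + 1
  hits <- hits[span >= min_span, , drop = FALSE]
  hits <- hits[order(-hits$score,
                     -(hits$genome_end - hits$genome_start)), , drop = FALSE]
  hits <- head(hits, max_copies)
  seqs <- character(nrow(hits))
  lf <- integer(nrow(hits)); rf <- integer(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    gl <- nchar(genome[[h$seq_id]])
    s <- max(1L, h$genome_start - flank)
    e <- min(gl, h$genome_end + flank)
    copy <- substr(genome[[h$seq_id]], s, e)
    lfl <- h$genome_start - s
    rfl <- e - h$genome_end
    if (h$strand == "-") {
      copy <- revcomp(copy)
      tmp <- lfl; lfl <- rfl; rfl <- tmp
    }
    seqs[i] <- copy; lf[i] <- lfl; rf[i] <- rfl
  }
  names(seqs) <- if (length(seqs) == 0) character(0) else
    paste0("copy", seq_along(seqs))
  list(seqs = seqs, left_flank = lf, right_flank = rf, hits = hits)
}

#' 50% majority-rule consensus of a multiple alignment
#'
#' Per column: the most frequent non-gap character is emitted if its
#' frequency among non-gap characters reaches `threshold` and it is the
#' unique maximum; ties (including a tie exactly at the threshold) give N.
#' Columns in which more than half of the rows are gaps are dropped.
#'
#' @param msa an `msa` object (see [build_msa()]) or character matrix
#' @param threshold majority threshold (default 0.5)
#' @return consensus sequence (single string, may contain N)
#' @export
majority_consensus <- function(msa, threshold = 0.5) {
  m <- if (is.matrix(msa)) msa else msa_matrix(msa)
  if (nrow(m) < 2) stop("majority consensus needs >= 2 rows", call. = FALSE)
  out <- apply(m, 2, function(col) {
    gaps <- sum(col == "-")
    if (gaps > length(col) / 2) return("")      # gap-majority: drop column
    col <- col[col != "-"]
    tab <- sort(table(col), decreasing = TRUE)
    if (tab[1] / sum(tab) < threshold) return("N")
    if (length(tab) > 1 && tab[2] == tab[1]) return("N")  # tie
    names(tab)[1]
  })
  paste(out, collapse = "")
}

# mean pairwise identity among rows of a character matrix restricted to
# some columns; rows need >= min_sites comparable positions per pair
window_identity <- function(m, cols, min_sites = 10) {
  sub <- m[, cols, drop = FALSE]
  present <- rowSums(sub != "-") > 0
  if (sum(present) < 3) return(list(identity = NA_real_, n_rows = sum(present)))
  sub <- sub[present, , drop = FALSE]
  n <- nrow(sub)
  ids <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- sub[i, ] != "-" & sub[j, ] != "-" &
              sub[i, ] != "N" & sub[j, ] != "N"
      if (sum(comp) < min_sites) next
      ids <- c(ids, sum(sub[i, comp] == sub[j, comp]) / sum(comp))
    }
  }
  if (length(ids) == 0) return(list(identity = NA_real_, n_rows = n))
  list(identity = mean(ids), n_rows = n)
}

#' Locate single-copy boundaries in an alignment of flanked copies
#'
#' Scanning outward from the repeat core in `window`-column steps, a flank
#' window is called single-copy when the mean pairwise identity among the
#' rows present in it falls below `max_flank_identity` (random DNA gives
#' about 0.25, repeat-derived flanks about 1 - divergence). The boundary
#' returned on each side is the innermost single-copy window edge, i.e. the
#' column range to keep. Windows with fewer than 3 informative rows leave
#' the side undetermined.
#'
#' @param msa an `msa` of flanked copies
#' @param core_start_col,core_end_col columns of the repeat core in the MSA
#' @param window window width in columns
#' @param max_flank_identity identity threshold below which a flank window
#'   counts as single-copy
#' @return list: `left_col`, `right_col` (columns to keep),
#'   `left_single_copy`, `right_single_copy`
#' @export
single_copy_boundary <- function(msa, core_start_col, core_end_col,
                                 window = 50, max_flank_identity = 0.60) {
  m <- msa_matrix(msa)
  nc <- ncol(m)
  # fraction of the most common base among non-gap rows in one column;
  # sparse columns (under half the rows present) cannot count as repeat
  col_majority <- function(col) {
    x <- m[, col]
    x <- x[x %in% c("A", "C", "G", "T")]
    if (length(x) < max(3, nrow(m) / 2)) return(0)
    max(table(x)) / length(x)
  }
  scan_side <- function(side, max_bad_run = 3) {
    # coarse scan in window-sized steps decides whether single-copy
    # sequence is reachable on this side at all
    if (side == "left") {
      edges <- seq(core_start_col - 1, 1, by = -window)
    } else {
      edges <- seq(core_end_col + 1, nc, by = window)
    }
    single <- FALSE
    for (edge in edges) {
      cols <- if (side == "left") max(1, edge - window + 1):edge
              else edge:min(nc, edge + window - 1)
      wi <- window_identity(m, cols)
      if (is.na(wi$identity)) break
      if (wi$identity < max_flank_identity) { single <- TRUE; break }
    }
    # column-resolution boundary: walk outward from the core edge while
    # columns stay repeat-like, tolerating short noisy runs
    step <- if (side == "left") -1L else 1L
    core_edge <- if (side == "left") core_start_col else core_end_col
    last_good <- core_edge
    bad_run <- 0L
    col <- core_edge + step
    while (col >= 1 && col <= nc) {
      if (col_majority(col) >= max_flank_identity) {
        last_good <- col
        bad_run <- 0L
      } else {
        bad_run <- bad_run + 1L
        if (bad_run > max_bad_run) break
      }
      col <- col + step
    }
    list(col = last_good, single = single)
  }
  if (nrow(m) < 3) {
    return(list(left_col = 1L, right_col = nc,
                left_single_copy = FALSE, right_single_copy = FALSE))
  }
  l <- scan_side("left")
  r <- scan_side("right")
  list(left_col = max(1L, l$col), right_col = min(nc, r$col),
       left_single_copy = l$single, right_single_copy = r$single)
}

# strip edge regions whose base calls are mostly ambiguous: residual
# flank columns survive boundary trimming as isolated bases among N runs
trim_noisy_edges <- function(cons, window = 10, max_n = 3) {
  repeat {
    cons <- gsub("^N+|N+$", "", cons)
    if (nchar(cons) <= window) break
    w <- seq_chars(substr(cons, 1, window))
    if (sum(w == "N") > max_n) {
      cons <- substr(cons, max(which(w == "N")) + 1, nchar(cons))
      next
    }
    n <- nchar(cons)
    w <- seq_chars(substr(cons, n - window + 1, n))
    if (sum(w == "N") > max_n) {
      cons <- substr(cons, 1, n - window + min(which(w == "N")) - 1)
      next
    }
    break
  }
  cons
}

# MSA column index of the k-th non-gap character of row i
row_pos_to_col <- function(row_chars, k) {
  nz <- which(row_chars != "-")
  if (k < 1 || k > length(nz)) return(NA_integer_)
  nz[k]
}

#' Iteratively extend a probe to a complete consensus
#'
#' Repeats extract-copies / align / majority-consensus / boundary-check
#' rounds, each round replacing the probe by the consensus trimmed to the
#' detected boundaries, until single-copy sequence flanks the element on
#' both sides (`complete = TRUE`) or `max_rounds` is reached.
#'
#' @param genome named character vector of genome sequences
#' @param probe starting probe sequence
#' @param name name for the resulting consensus
#' @param max_rounds maximum refinement rounds
#' @param max_copies,min_span,flank see [extract_copies()]
#' @param window,max_flank_identity see [single_copy_boundary()]
#' @param scoring a [scoring_scheme()]
#' @param ... further arguments to [find_hits()]
#' @return a `consensus_record`: list with `name`, `seq`, `classification`,
#'   `source_copy_count`, `complete`, `rounds` and a per-round `log`
#' @export
extend_to_single_copy <- function(genome, probe, name = "consensus",
                                  max_rounds = 10, max_copies = 50,
                                  min_span = 100, flank = 1000,
                                  window = 50, max_flank_identity = 0.60,
                                  scoring = scoring_scheme(), ...) {
  genome <- as_seq_vector(genome, "genome")
  cur <- normalize_seq(probe, "probe")
  log <- list()
  complete <- FALSE
  n_copies <- 0L
  for (round in seq_len(max_rounds)) {
    ec <- extract_copies(genome, cur, max_copies = max_copies,
                         min_span = min_span, flank = flank,
                         scoring = scoring, ...)
    n_copies <- length(ec$seqs)
    if (n_copies < 3) {
      log[[round]] <- list(round = round, copies = n_copies,
                           note = "fewer than 3 copies; stopping")
      break
    }
    msa <- build_msa(ec$seqs, scoring)
    m <- msa_matrix(msa)
    core_start <- median(vapply(seq_len(nrow(m)), function(i) {
      row_pos_to_col(m[i, ], ec$left_flank[i] + 1L)
    }, numeric(1)), na.rm = TRUE)
    core_len <- nchar(ec$seqs) - ec$left_flank - ec$right_flank
    core_end <- median(vapply(seq_len(nrow(m)), function(i) {
      row_pos_to_col(m[i, ], ec$left_flank[i] + core_len[i])
    }, numeric(1)), na.rm = TRUE)
    bd <- single_copy_boundary(msa, round(core_start), round(core_end),
                               window = window,
                               max_flank_identity = max_flank_identity)
    cons <- majority_consensus(m[, bd$left_col:bd$right_col, drop = FALSE])
    cons <- trim_noisy_edges(cons)
    log[[round]] <- list(round = round, copies = n_copies,
                         consensus_length = nchar(cons),
                         left_single_copy = bd$left_single_copy,
                         right_single_copy = bd$right_single_copy)
    if (bd$left_single_copy && bd$right_single_copy) {
      cur <- cons
      complete <- TRUE
      break
    }
    if (nchar(cons) < min_span || identical(cons, cur)) {
      cur <- if (nchar(cons) >= min_span) cons else cur
      break
    }
    cur <- cons
  }
  structure(list(name = name, seq = cur, classification = NA_character_,
                 source_copy_count = n_copies, complete = complete,
                 rounds = length(log), log = log),
            class = "consensus_record")
}

#' @export
print.consensus_record <- function(x, ...) {
  cat(sprintf("consensus '%s': %d bp, %d source copies, %s (%d round%s)\n",
              x$name, nchar(x$seq), x$source_copy_count,
              if (x$complete) "complete" else "incomplete",
              x$rounds, if (x$rounds == 1) "" else "s"))
  invisible(x)
}

#' Classify a consensus against a reference library
#'
#' Best local-alignment hit wins if it reaches `min_score`; otherwise the
#' element is reported as "Unclassified".
#'
#' @param consensus consensus sequence
#' @param reference_library named character vector of reference elements
#' @param labels optional named character vector mapping reference name to
#'   a class label (defaults to the reference names themselves)
#' @param min_score minimum alignment score to accept a classification
#' @param scoring a [scoring_scheme()]
#' @return classification label (single string)
#' @export
classify_consensus <- function(consensus, reference_library, labels = NULL,
                               min_score = 100, scoring = scoring_scheme()) {
  reference_library <- as_seq_vector(reference_library, "reference library")
  if (length(reference_library) == 0) {
    stop("reference library is empty", call. = FALSE)
  }
  consensus <- normalize_seq(consensus, "consensus")
  scores <- align_scores(reference_library, consensus, scoring,
                         type = "local")
  best <- which.max(scores)
  if (scores[best] < min_score) return("Unclassified")
  ref <- names(reference_library)[best]
  if (is.null(labels) || is.na(labels[ref])) ref else unname(labels[ref])
}
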