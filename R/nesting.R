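## nesting: detection of transposition-in-transposition. An element B
## inserted into an existing copy of A leaves two A segments whose
## consensus spans continue across the interruption; B sits between them
## on the genome. Younger families nest into older ones, so the count
## matrix is informative about relative activity order.

#' Detect nested insertions
#'
#' For every pair of same-family, same-strand hits that are adjacent on
#' the genome and whose consensus spans continue within `join_tol` bases,
#' every hit lying strictly between them is recorded as nested in that
#' family.
#'
#' @param hits hit table
#' @param join_tol consensus continuation tolerance in bases
#' @param edge_tol bases of boundary jitter tolerated when testing that
#'   the inner hit lies between the outer segments (alignment ends wobble
#'   by a few bases at exact junctions)
#' @return data.frame of events: inner_row, inner_family, outer_family,
#'   outer_left_row, outer_right_row, seq_id, span_start, span_end
#' @export
detect_nested_insertions <- function(hits, join_tol = 30, edge_tol = 10) {
  hits <- hit_table(hits)
  hits$.row <- seq_len(nrow(hits))
  events <- list()
  for (sid in unique(hits$seq_id)) {
    sh <- hits[hits$seq_id == sid, , drop = FALSE]
    for (fam in unique(sh$family)) {
      for (strand in c("+", "-")) {
        grp <- sh[sh$family == fam & sh$strand == strand, , drop = FALSE]
        if (nrow(grp) < 2) next
        grp <- grp[order(grp$genome_start), , drop = FALSE]
        for (i in seq_len(nrow(grp) - 1)) {
          a <- grp[i, ]; b <- grp[i + 1, ]
          cont <- if (strand == "+") b$consensus_start - a$consensus_end - 1L
                  else a$consensus_start - b$consensus_end - 1L
          if (abs(cont) > join_tol) next
          inner <- sh[sh$genome_start > a$genome_end - edge_tol &
                      sh$genome_end < b$genome_start + edge_tol &
                      sh$genome_start > a$genome_start &
                      sh$genome_end < b$genome_end &
                      sh$.row != a$.row & sh$.row != b$.row, , drop = FALSE]
          for (r in seq_len(nrow(inner))) {
            events[[length(events) + 1]] <- data.frame(
              inner_row = inner$.row[r],
              inner_family = inner$family[r],
              outer_family = fam,
              outer_left_row = a$.row,
              outer_right_row = b$.row,
              seq_id = sid,
              span_start = a$genome_start,
              span_end = b$genome_end)
          }
        }
      }
    }
  }
  if (length(events) == 0) {
    return(data.frame(inner_row = integer(), inner_family = character(),
                      outer_family = character(),
                      outer_left_row = integer(),
                      outer_right_row = integer(), seq_id = character(),
                      span_start = integer(), span_end = integer()))
  }
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Family-by-family nesting count matrix
#'
#' @param events events from [detect_nested_insertions()]
#' @param families families to cover (rows = inner, columns = outer);
#'   defaults to those present in the events
#' @return integer matrix `counts[inner family, outer family]`
#' @export
nesting_matrix <- function(events, families = NULL) {
  if (is.null(families)) {
    families <- sort(unique(c(events$inner_family, events$outer_family)))
  }
  m <- matrix(0L, length(families), length(families),
              dimnames = list(inner = families, outer = families))
  for (r in seq_len(nrow(events))) {
    inf <- events$inner_family[r]; onf <- events$outer_family[r]
    if (inf %in% families && onf %in% families) {
      m[inf, onf] <- m[inf, onf] + 1L
    }
  }
  m
}
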