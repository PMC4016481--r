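## ht_screen: horizontal-transfer candidate screening. A library element
## found in a foreign genome at >95% identity over at least 80% of its
## length is too similar for its age to be explained by vertical descent.

#' Screen a TE library against foreign genomes for horizontal transfer
#'
#' For every (query element, subject sequence) pair the best local
#' alignment is computed; the pair passes when identity is strictly
#' greater than `min_identity` and query coverage is at least
#' `min_coverage`. All pairs are reported with their `passes` flag.
#' After recording a locus the subject is hard-masked and re-searched, so
#' multiple disjoint loci in one subject are each reported.
#'
#' @param library named character vector of query consensi
#' @param subject_genomes named character vector of subject sequences
#'   (use names like "species:contig")
#' @param min_identity identity threshold (strict `>`; default 0.95)
#' @param min_coverage query-coverage threshold (`>=`; default 0.80)
#' @param min_report_score loci scoring below this are not reported
#' @param max_loci_per_subject cap on re-search rounds per pair
#' @param scoring a [scoring_scheme()]
#' @return data.frame: query, subject, subject_start, subject_end,
#'   identity, query_coverage, score, passes
#' @export
screen_horizontal_transfer <- function(library, subject_genomes,
                                       min_identity = 0.95,
                                       min_coverage = 0.80,
                                       min_report_score = 30,
                                       max_loci_per_subject = 5,
                                       scoring = scoring_scheme()) {
  library <- as_seq_vector(library, "library")
  subject_genomes <- as_seq_vector(subject_genomes, "subjects")
  rows <- list()
  for (q in names(library)) {
    qseq <- library[[q]]
    for (s in names(subject_genomes)) {
      sseq <- subject_genomes[[s]]
      for (i in seq_len(max_loci_per_subject)) {
        best <- NULL
        for (strand in c("+", "-")) {
          probe <- if (strand == "+") qseq else revcomp(qseq)
          aln <- local_align(probe, sseq, scoring)
          if (is.null(best) || aln$score > best$aln$score) {
            best <- list(aln = aln, strand = strand)
          }
        }
        aln <- best$aln
        if (aln$score < min_report_score) {
          if (i == 1) {
            rows[[length(rows) + 1]] <- data.frame(
              query = q, subject = s, subject_start = NA_integer_,
              subject_end = NA_integer_, strand = NA_character_,
              identity = 0, query_coverage = 0, score = aln$score,
              passes = FALSE)
          }
          break
        }
        rows[[length(rows) + 1]] <- data.frame(
          query = q, subject = s,
          subject_start = aln$b_start, subject_end = aln$b_end,
          strand = best$strand,
          identity = aln$identity, query_coverage = aln$query_coverage,
          score = aln$score,
          passes = aln$identity > min_identity &&
                   aln$query_coverage >= min_coverage)
        substr(sseq, aln$b_start, aln$b_end) <-
          strrep("N", aln$b_end - aln$b_start + 1)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
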